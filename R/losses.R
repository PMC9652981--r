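# Training loss: soft multi-class Dice loss plus mean voxelwise
# cross-entropy, summed. Gradients are taken with respect to the logits
# (softmax Jacobian applied analytically).

one_hot <- function(target, n_classes = 2L) {
  t1 <- as.numeric(target)
  rbind(1 - t1, t1)
}

as_prob_matrix <- function(probs) {
  if (inherits(probs, "fmap")) return(probs$x)
  if (is.array(probs) && length(dim(probs)) == 4) return(matrix(probs, dim(probs)[1]))
  if (is.matrix(probs)) return(probs)
  stop_gtv("probs must be an fmap, a C x D x H x W array, or a C x V matrix")
}

as_target_vector <- function(target) {
  if (inherits(target, "ct_mask")) target <- target$data
  as.numeric(target)
}

#' Soft Dice loss
#'
#' `1 - mean` over classes of `(2 * sum(p*t) + eps) / (sum(p) + sum(t) + eps)`
#' with probability-weighted (soft) overlaps, `eps = 1e-5`. Lies in `[0, 1]`;
#' near 0 for a perfect prediction.
#'
#' @param probs Per-voxel class probabilities: an `fmap`, a
#'   `C x D x H x W` array, or a `C x V` matrix (channels sum to 1).
#' @param target A binary mask (`ct_mask`, array, or vector) with the same
#'   number of voxels.
#' @param eps Stabilizer (default `1e-5`).
#' @return A single number.
#' @export
dice_loss <- function(probs, target, eps = 1e-5) {
  p <- as_prob_matrix(probs)
  tt <- one_hot(as_target_vector(target), nrow(p))
  stopifnot(ncol(p) == ncol(tt))
  S <- rowSums(p * tt)
  U <- rowSums(p) + rowSums(tt)
  1 - mean((2 * S + eps) / (U + eps))
}

#' Cross-entropy loss
#'
#' Mean voxelwise negative log-probability of the true class.
#'
#' @inheritParams dice_loss
#' @return A single number.
#' @export
ce_loss <- function(probs, target) {
  p <- as_prob_matrix(probs)
  tt <- one_hot(as_target_vector(target), nrow(p))
  -sum(tt * log(pmax(p, 1e-12))) / ncol(p)
}

#' Total training loss: Dice loss + cross-entropy
#'
#' The two components are computed separately and summed.
#'
#' @inheritParams dice_loss
#' @return A single number equal to `dice_loss(probs, target) +
#'   ce_loss(probs, target)`.
#' @export
total_loss <- function(probs, target, eps = 1e-5) {
  dice_loss(probs, target, eps) + ce_loss(probs, target)
}

# Loss value and d(loss)/d(logits) in one pass; target is the flat 0/1
# foreground vector over the batch.
loss_and_grad <- function(probs_x, target_vec, eps = 1e-5) {
  p <- probs_x
  C <- nrow(p); M <- ncol(p)
  tt <- one_hot(target_vec, C)

  ce <- -sum(tt * log(pmax(p, 1e-12))) / M
  dp_ce_dlogit <- (p - tt) / M          # softmax + CE shortcut

  S <- rowSums(p * tt)
  U <- rowSums(p) + rowSums(tt)
  dice <- 1 - mean((2 * S + eps) / (U + eps))
  # d(dice)/dp_c(v) = -(1/C) * (2 t_c(v) (U_c+eps) - (2 S_c+eps)) / (U_c+eps)^2
  dnum <- (2 * tt * (U + eps) - (2 * S + eps)) / (U + eps)^2
  dp <- -dnum / C
  # softmax Jacobian: dlogit_c = p_c * (dp_c - sum_k p_k dp_k)
  inner <- colSums(p * dp)
  dl_dice <- p * (dp - rep(inner, each = C))

  list(total = dice + ce, dice = dice, ce = ce,
       dlogits = dp_ce_dlogit + dl_dice)
}

## ---- Adam ------------------------------------------------------------------

# Classical Adam with coupled L2 weight decay (decay added to the gradient of
# every parameter). State lives on each layer environment.
adam_step <- function(net, lr, weight_decay = 0, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (ly in net$layers) {
    if (length(ly$params) == 0) next
    if (is.null(ly$grads))
      stop_gtv("adam_step called with no gradients on a '%s' layer", ly$kind)
    if (is.null(ly$opt)) {
      ly$opt <- list(t = 0,
                     m = lapply(ly$params, function(p) p * 0),
                     v = lapply(ly$params, function(p) p * 0))
    }
    ly$opt$t <- ly$opt$t + 1
    b1t <- 1 - beta1^ly$opt$t
    b2t <- 1 - beta2^ly$opt$t
    for (nm in names(ly$params)) {
      g <- ly$grads[[nm]] + weight_decay * ly$params[[nm]]
      ly$opt$m[[nm]] <- beta1 * ly$opt$m[[nm]] + (1 - beta1) * g
      ly$opt$v[[nm]] <- beta2 * ly$opt$v[[nm]] + (1 - beta2) * g * g
      mhat <- ly$opt$m[[nm]] / b1t
      vhat <- ly$opt$v[[nm]] / b2t
      ly$params[[nm]] <- ly$params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  invisible(net)
}
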