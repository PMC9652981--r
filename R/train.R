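# Training protocol: Adam with coupled weight decay, polynomial
# learning-rate decay applied per epoch, random-crop + augmented training
# batches, deterministic GTV-centered validation crops, and best-model
# checkpointing on strict validation-DSC improvement.

#' Configure a training run
#'
#' Defaults follow the reference protocol: batch size 4, Adam with initial
#' learning rate 1e-3 and weight decay 1e-4, polynomial decay with power
#' 0.9 over 500 epochs, 32 x 256 x 256 patches. A scaled-down profile for
#' CPU-sized experiments overrides `patch` and `epochs`.
#'
#' @param batch_size Cases per optimization step (default 4).
#' @param lr0 Initial learning rate (default 1e-3).
#' @param weight_decay Coupled L2 weight decay factor (default 1e-4).
#' @param poly_power Polynomial decay power (default 0.9).
#' @param epochs Total training epochs (default 500).
#' @param patch Training/validation patch size (default `c(32, 256, 256)`).
#' @param seed Master seed; all shuffling, cropping and augmentation derive
#'   child streams from it.
#' @param crops_per_case Random crops drawn per case per epoch (default 1).
#' @param augment An [augment_config()]; `NULL` disables augmentation.
#' @param window_width,window_level CT windowing applied to raw HU cases.
#' @return A `train_config`.
#' @export
train_config <- function(batch_size = 4L, lr0 = 1e-3, weight_decay = 1e-4,
                         poly_power = 0.9, epochs = 500L,
                         patch = c(32L, 256L, 256L), seed = 1L,
                         crops_per_case = 1L, augment = augment_config(),
                         window_width = 400, window_level = 40) {
  stopifnot(lr0 > 0, epochs >= 1, batch_size >= 1, poly_power >= 0)
  structure(list(batch_size = as.integer(batch_size), lr0 = lr0,
                 weight_decay = weight_decay, poly_power = poly_power,
                 epochs = as.integer(epochs), patch = as.integer(patch),
                 seed = as.integer(seed), crops_per_case = as.integer(crops_per_case),
                 augment = augment, window_width = window_width,
                 window_level = window_level),
            class = "train_config")
}

#' Polynomial learning-rate schedule
#'
#' `lr = lr0 * (1 - epoch / epochs)^power`, evaluated at 0-based epoch
#' indices: epoch 0 gives `lr0`, epoch `epochs` gives 0. Strictly decreasing
#' in between for positive power.
#'
#' @param epoch 0-based epoch index in `[0, epochs]`.
#' @param cfg A [train_config()].
#' @return The learning rate.
#' @export
poly_lr <- function(epoch, cfg) {
  if (epoch < 0 || epoch > cfg$epochs)
    stop_gtv("epoch %d out of range [0, %d]", epoch, cfg$epochs)
  cfg$lr0 * (1 - epoch / cfg$epochs)^cfg$poly_power
}

# Window + normalize a raw case once; accepts phantom_case or a
# list(volume, mask) where the volume may already be normalized.
prepare_case <- function(case, cfg) {
  v <- case$volume; m <- case$mask
  if (v$domain == "HU") v <- window_ct(v, cfg$window_width, cfg$window_level)
  if (v$domain == "mapped_0_255") v <- normalize_volume(v)
  list(volume = v, mask = m)
}

dsc_vec <- function(pred, tar) {
  np <- sum(pred); nt <- sum(tar)
  if (np == 0 && nt == 0) return(1)
  if (np == 0 || nt == 0) return(0)
  2 * sum(pred & tar) / (np + nt)
}

#' Validate a network on GTV-centered crops
#'
#' Evaluation mode (frozen BN statistics), no augmentation; deterministic
#' given the weights. Validation DSC is computed on hardened (argmax)
#' predictions and averaged over cases.
#'
#' @param net A `gtv_network`.
#' @param val_crops List of prepared crops, each `list(volume, mask)` with a
#'   normalized volume at the configured patch size.
#' @return List with mean `dsc` and mean `loss`.
#' @export
validate_network <- function(net, val_crops) {
  ds <- numeric(length(val_crops)); ls <- numeric(length(val_crops))
  for (i in seq_along(val_crops)) {
    cr <- val_crops[[i]]
    r <- net_forward(net, array(cr$volume$data, c(1L, dim(cr$volume$data))),
                     training = FALSE)
    tar <- as.numeric(cr$mask$data)
    ls[i] <- loss_and_grad(r$probs$x, tar)$total
    ds[i] <- dsc_vec(r$probs$x[2, ] > 0.5, tar == 1)
  }
  list(dsc = mean(ds), loss = mean(ls))
}

make_batch <- function(prep, ids, cfg, epoch) {
  vx <- NULL; tx <- NULL
  for (j in seq_along(ids)) {
    i <- ids[j]
    cs <- child_seed(cfg$seed, sprintf("crop-e%d-c%d-j%d", epoch, i, j))
    cr <- random_crop(prep[[i]]$volume, prep[[i]]$mask, cfg$patch, cs)
    if (!is.null(cfg$augment)) {
      as_ <- child_seed(cfg$seed, sprintf("aug-e%d-c%d-j%d", epoch, i, j))
      cr <- augment_patch(cr$volume, cr$mask, cfg$augment, as_)
    }
    vx <- cbind(vx, matrix(cr$volume$data, 1))
    tx <- c(tx, as.numeric(cr$mask$data))
  }
  list(x = fmap(vx, length(ids), cfg$patch), target = tx)
}

#' Train a segmentation network
#'
#' Runs the full protocol: per epoch, shuffled random-crop (augmented)
#' training batches optimized on the summed Dice + cross-entropy loss with
#' the polynomial learning-rate schedule; validation on deterministic
#' GTV-centered crops; and checkpointing of the model whenever the
#' validation DSC strictly exceeds all previous epochs. A non-finite loss
#' aborts with the offending epoch and batch.
#'
#' @param net A `gtv_network` whose configured patch matches `cfg$patch`.
#' @param train_cases,val_cases Nonempty lists of cases (`phantom_case` or
#'   `list(volume, mask)`); raw HU volumes are windowed and normalized.
#' @param cfg A [train_config()].
#' @param out_dir Optional directory for `best_model.rds` (+ JSON sidecar)
#'   and `history.csv`.
#' @param validate_fn Validation override, `function(net, epoch)` returning
#'   `list(dsc, loss)`; the default evaluates GTV-centered crops. Intended
#'   for testing the checkpoint rule against a prescribed DSC trace.
#' @return A `train_history` list: `history` (one data.frame row per epoch:
#'   epoch, lr, train_loss, train_dsc, val_loss, val_dsc), `best_epoch`,
#'   `best_val_dsc`, `best_state` (network state at the best epoch), and
#'   `net` (final-epoch network).
#' @export
train_network <- function(net, train_cases, val_cases, cfg, out_dir = NULL,
                          validate_fn = NULL) {
  stopifnot(length(train_cases) >= 1, length(val_cases) >= 1)
  if (!all(net$cfg$patch == cfg$patch))
    stop_gtv("network patch (%s) and training patch (%s) differ",
             paste(net$cfg$patch, collapse = "x"), paste(cfg$patch, collapse = "x"))
  prep <- lapply(train_cases, prepare_case, cfg = cfg)
  if (is.null(validate_fn)) {
    val_prep <- lapply(val_cases, prepare_case, cfg = cfg)
    val_crops <- lapply(val_prep, function(cs)
      center_crop_on_gtv(cs$volume, cs$mask, cfg$patch))
    validate_fn <- function(net, epoch) validate_network(net, val_crops)
  }
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  n <- length(prep)
  hist_rows <- vector("list", cfg$epochs)
  best_val <- -Inf; best_epoch <- NA_integer_; best_state <- NULL
  for (epoch in seq_len(cfg$epochs)) {
    lr <- poly_lr(epoch - 1, cfg)
    order <- with_seed_(child_seed(cfg$seed, sprintf("shuffle%d", epoch)),
                        sample.int(n))
    ids_all <- rep(order, cfg$crops_per_case)
    batches <- split(ids_all, ceiling(seq_along(ids_all) / cfg$batch_size))
    tl <- 0; tw <- 0; tp <- NULL; tt <- NULL
    for (bi in seq_along(batches)) {
      b <- make_batch(prep, batches[[bi]], cfg, epoch)
      r <- net_forward(net, b$x, training = TRUE)
      lg <- loss_and_grad(r$probs$x, b$target)
      if (!is.finite(lg$total))
        stop_gtv("non-finite training loss at epoch %d, batch %d", epoch, bi)
      net_backward(net, fmap(lg$dlogits, b$x$n, r$logits$dims), r$cache)
      adam_step(net, lr, cfg$weight_decay)
      tl <- tl + lg$total * length(batches[[bi]]); tw <- tw + length(batches[[bi]])
      tp <- c(tp, sum(r$probs$x[2, ] > 0.5 & b$target == 1),
              sum(r$probs$x[2, ] > 0.5), sum(b$target == 1))
    }
    inter <- sum(tp[seq(1, length(tp), 3)]); pr <- sum(tp[seq(2, length(tp), 3)])
    gt <- sum(tp[seq(3, length(tp), 3)])
    train_dsc <- if (pr + gt == 0) 1 else 2 * inter / (pr + gt)
    val <- validate_fn(net, epoch)
    hist_rows[[epoch]] <- data.frame(epoch = epoch, lr = lr,
                                     train_loss = tl / tw, train_dsc = train_dsc,
                                     val_loss = val$loss, val_dsc = val$dsc)
    if (val$dsc > best_val) {
      best_val <- val$dsc; best_epoch <- epoch
      best_state <- net_state(net)
      if (!is.null(out_dir))
        save_checkpoint(net, file.path(out_dir, "best_model.rds"),
                        meta = list(epoch = epoch, val_dsc = val$dsc))
    }
  }
  history <- do.call(rbind, hist_rows)
  cpp_free_buffers()     # release per-layer conv scratch buffers
  if (!is.null(out_dir))
    utils::write.csv(history, file.path(out_dir, "history.csv"), row.names = FALSE)
  structure(list(history = history, best_epoch = best_epoch,
                 best_val_dsc = best_val, best_state = best_state, net = net),
            class = "train_history")
}

#' @export
print.train_history <- function(x, ...) {
  cat(sprintf("<train_history> %d epochs, best val DSC %.4f at epoch %d\n",
              nrow(x$history), x$best_val_dsc, x$best_epoch))
  invisible(x)
}

#' Train and evaluate several architecture variants on shared data
#'
#' Each variant is trained with the same data, training configuration and
#' seed, restored to its best-validation checkpoint, and evaluated by
#' full-volume sliding-window inference on the test cases (whole-volume DSC
#' and HD95 per case, aggregated as mean and sample sd).
#'
#' @param variants Character vector of variant names (see [network_config()]).
#' @param train_cases,val_cases,test_cases Case lists as in [train_network()].
#' @param net_cfg_args Named list of arguments passed to [network_config()]
#'   besides `variant` (channel plan, patch, transformer geometry).
#' @param cfg A [train_config()].
#' @param out_dir Optional directory; writes `comparison.csv`.
#' @return A data.frame with one row per variant: dsc mean/sd, hd95 mean/sd,
#'   best validation DSC and parameter count.
#' @export
run_comparison <- function(variants, train_cases, val_cases, test_cases,
                           net_cfg_args = list(), cfg = train_config(),
                           out_dir = NULL) {
  rows <- vector("list", length(variants))
  for (k in seq_along(variants)) {
    ncfg <- do.call(network_config,
                    c(list(variant = variants[k], patch = cfg$patch), net_cfg_args))
    net <- build_network(ncfg, seed = cfg$seed)
    th <- train_network(net, train_cases, val_cases, cfg)
    net_load_state(net, th$best_state)
    prep <- lapply(test_cases, prepare_case, cfg = cfg)
    preds <- lapply(prep, function(cs) predict_volume(net, cs$volume))
    refs <- lapply(prep, function(cs) cs$mask)
    ev <- evaluate_cases(preds, refs)
    sm <- ev$summary
    rows[[k]] <- data.frame(variant = variants[k],
                            dsc_mean = sm$mean[sm$metric == "dsc"],
                            dsc_sd = sm$sd[sm$metric == "dsc"],
                            hd95_mean = sm$mean[sm$metric == "hd95_mm"],
                            hd95_sd = sm$sd[sm$metric == "hd95_mm"],
                            best_val_dsc = th$best_val_dsc,
                            n_params = net$n_params)
  }
  out <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(out, file.path(out_dir, "comparison.csv"), row.names = FALSE)
  }
  out
}

#' Plot training curves
#'
#' Writes a four-panel PNG (train loss, train DSC, validation loss,
#' validation DSC per epoch).
#'
#' @param history The `history` data.frame of a [train_network()] result.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
plot_history <- function(history, path) {
  grDevices::png(path, width = 900, height = 700)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(2, 2))
  graphics::plot(history$epoch, history$train_loss, type = "l",
                 xlab = "epoch", ylab = "train loss", main = "Training loss")
  graphics::plot(history$epoch, history$train_dsc, type = "l",
                 xlab = "epoch", ylab = "train DSC", main = "Training DSC")
  graphics::plot(history$epoch, history$val_loss, type = "l",
                 xlab = "epoch", ylab = "val loss", main = "Validation loss")
  graphics::plot(history$epoch, history$val_dsc, type = "l",
                 xlab = "epoch", ylab = "val DSC", main = "Validation DSC")
  invisible(path)
}
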