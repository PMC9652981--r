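# Overlap and surface-distance evaluation. DSC is the voxel-count Dice
# coefficient 2|A n B| / (|A| + |B|); HD95 is the average of the two directed
# 95th-percentile surface distances in mm, with surfaces defined by
# 6-connectivity (out-of-bounds counts as background), distances taken voxel
# center to voxel center using the anisotropic spacing, and the percentile
# computed by linear interpolation between order statistics.

#' Dice similarity coefficient between two masks
#'
#' `2 |A n B| / (|A| + |B|)`, symmetric in its arguments. If exactly one
#' mask is empty the DSC is 0; two empty masks are an error (0/0 undefined).
#'
#' @param a,b Aligned binary masks (`ct_mask` or 3D arrays).
#' @return A number in `[0, 1]`.
#' @export
dsc <- function(a, b) {
  A <- mask_data(a); B <- mask_data(b)
  if (!all(dim(A) == dim(B))) stop_gtv("masks are not aligned")
  na <- sum(A == 1); nb <- sum(B == 1)
  if (na == 0 && nb == 0)
    stop_gtv("DSC undefined: both masks are empty (0/0)")
  if (na == 0 || nb == 0) return(0)
  2 * sum(A == 1 & B == 1) / (na + nb)
}

# DSC with the convention needed during training summaries: both-empty -> 1
# (a correctly predicted empty crop), one-empty -> 0.
dsc_safe <- function(a, b) {
  A <- mask_data(a); B <- mask_data(b)
  na <- sum(A == 1); nb <- sum(B == 1)
  if (na == 0 && nb == 0) return(1)
  if (na == 0 || nb == 0) return(0)
  2 * sum(A == 1 & B == 1) / (na + nb)
}

#' Extract the surface voxels of a mask
#'
#' A surface voxel is a foreground voxel with at least one background
#' 6-neighbor; voxels on the array boundary count the outside as background.
#'
#' @param m A `ct_mask` or 3D binary array.
#' @param spacing_mm Spacing override when `m` is a bare array.
#' @return A `surface_set`: list with `coords` (n x 3 matrix of 1-based voxel
#'   indices) and `spacing_mm`.
#' @export
extract_surface <- function(m, spacing_mm = NULL) {
  arr <- mask_data(m)
  sp <- spacing_mm %||% (if (inherits(m, "ct_mask")) m$spacing_mm else c(1, 1, 1))
  if (sum(arr) == 0) stop_gtv("cannot extract the surface of an empty mask")
  d <- dim(arr)
  # pad with background so boundary faces are surface
  p <- array(0L, d + 2L)
  p[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- arr
  core <- p[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
  nb_min <-
    pmin(p[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)], p[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)],
         p[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)], p[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)],
         p[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]], p[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)])
  surf <- core == 1L & nb_min == 0L
  coords <- which(array(surf, d), arr.ind = TRUE)
  colnames(coords) <- c("d", "h", "w")
  structure(list(coords = coords, spacing_mm = as.numeric(sp)),
            class = "surface_set")
}

surface_mm <- function(ss) {
  sweep(ss$coords, 2, ss$spacing_mm, `*`)
}

# Linear-interpolation percentile (R type 7) of the directed surface
# distances, computed in C++ for speed.
directed_p95 <- function(from_mm, to_mm) {
  d <- cpp_min_dists(from_mm, to_mm)
  as.numeric(quantile(d, 0.95, type = 7, names = FALSE))
}

#' 95th-percentile Hausdorff distance between two masks, in mm
#'
#' `0.5 * [P95 over surface of B of d(z, S_A) + P95 over surface of A of
#' d(z, S_B)]` with Euclidean distances in mm; symmetric by construction.
#' Either mask being empty is an error.
#'
#' @param a,b Aligned binary masks (`ct_mask` or 3D arrays).
#' @param spacing_mm Spacing override when the masks are bare arrays.
#' @param case_id Optional identifier used in error messages.
#' @return A nonnegative number (mm).
#' @export
hd95 <- function(a, b, spacing_mm = NULL, case_id = NULL) {
  tag <- if (is.null(case_id)) "" else sprintf(" (case %s)", case_id)
  A <- mask_data(a); B <- mask_data(b)
  if (!all(dim(A) == dim(B))) stop_gtv("masks are not aligned%s", tag)
  if (sum(A) == 0 || sum(B) == 0)
    stop_gtv("HD95 undefined for an empty mask%s", tag)
  sp <- spacing_mm %||% (if (inherits(a, "ct_mask")) a$spacing_mm else c(1, 1, 1))
  sa <- surface_mm(extract_surface(A, sp))
  sb <- surface_mm(extract_surface(B, sp))
  0.5 * (directed_p95(sb, sa) + directed_p95(sa, sb))
}

#' Evaluate predicted masks against references, case by case
#'
#' Computes whole-volume DSC and HD95 per case plus the aggregate mean and
#' sample standard deviation (sd is 0 for a single case). A prediction with
#' no foreground gets DSC 0 and HD95 `NA` (undefined), which is excluded
#' from the HD95 aggregate with a warning.
#'
#' @param preds,refs Paired lists of masks (`ct_mask` or arrays).
#' @param spacings A single spacing vector, or a list of per-case spacings
#'   (unneeded when masks are `ct_mask`).
#' @param case_ids Optional identifiers (defaults to `case1`, `case2`, ...).
#' @return A list with `per_case` (data.frame: case_id, dsc, hd95_mm) and
#'   `summary` (data.frame: metric, mean, sd, n).
#' @export
evaluate_cases <- function(preds, refs, spacings = NULL, case_ids = NULL) {
  if (length(preds) != length(refs))
    stop_gtv("preds (%d) and refs (%d) differ in length", length(preds), length(refs))
  n <- length(preds)
  case_ids <- case_ids %||% paste0("case", seq_len(n))
  get_sp <- function(i) {
    if (inherits(preds[[i]], "ct_mask")) return(preds[[i]]$spacing_mm)
    if (is.null(spacings)) return(c(1, 1, 1))
    if (is.list(spacings)) spacings[[i]] else spacings
  }
  ds <- numeric(n); hs <- numeric(n)
  for (i in seq_len(n)) {
    ds[i] <- dsc_safe(preds[[i]], refs[[i]])
    hs[i] <- if (sum(mask_data(preds[[i]])) == 0 || sum(mask_data(refs[[i]])) == 0) {
      NA_real_
    } else {
      hd95(mask_data(preds[[i]]), mask_data(refs[[i]]), get_sp(i), case_ids[i])
    }
  }
  if (anyNA(hs)) warning("HD95 undefined for some cases (empty mask); excluded from the aggregate")
  per_case <- data.frame(case_id = case_ids, dsc = ds, hd95_mm = hs,
                         stringsAsFactors = FALSE)
  agg <- function(x) {
    x <- x[!is.na(x)]
    c(mean = mean(x), sd = if (length(x) > 1) sd(x) else 0, n = length(x))
  }
  sm <- rbind(dsc = agg(ds), hd95_mm = agg(hs))
  summary <- data.frame(metric = rownames(sm), mean = sm[, "mean"],
                        sd = sm[, "sd"], n = sm[, "n"],
                        row.names = NULL, stringsAsFactors = FALSE)
  list(per_case = per_case, summary = summary)
}
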