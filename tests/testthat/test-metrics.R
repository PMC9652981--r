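mk <- function(shape, idx = NULL) {
  m <- array(0L, shape)
  if (!is.null(idx)) m[idx] <- 1L
  m
}

test_that("DSC matches voxel-count enumeration and handles empty masks", {
  a <- mk(c(4, 4, 4)); a[1, 1, 1:3] <- 1L; a[2, 1, 1:3] <- 1L   # |A| = 6
  b <- mk(c(4, 4, 4)); b[1, 1, 1:3] <- 1L; b[3, 3, 3] <- 1L      # |B| = 4, n = 3
  expect_equal(dsc(a, b), 2 * 3 / (6 + 4))
  expect_equal(dsc(a, b), dsc(b, a))
  expect_equal(dsc(a, a), 1)
  disj <- mk(c(4, 4, 4)); disj[4, 4, 4] <- 1L
  expect_equal(dsc(a, disj), 0)
  empty <- mk(c(4, 4, 4))
  expect_equal(dsc(a, empty), 0)
  expect_error(dsc(empty, empty), "both masks are empty")
  expect_error(dsc(a, mk(c(4, 4, 5))), "aligned")
})

test_that("DSC is invariant under an identical translation of both masks", {
  set.seed(1)
  a <- random_blob_mask(); b <- random_blob_mask()
  big_a <- mk(c(14, 24, 24)); big_a[3:12, 3:22, 3:22] <- a
  big_b <- mk(c(14, 24, 24)); big_b[3:12, 3:22, 3:22] <- b
  pad_a <- mk(c(14, 24, 24)); pad_a[1:10, 1:20, 1:20] <- a
  pad_b <- mk(c(14, 24, 24)); pad_b[1:10, 1:20, 1:20] <- b
  expect_equal(dsc(big_a, big_b), dsc(pad_a, pad_b))
})

test_that("surface extraction matches 6-neighborhood enumeration", {
  single <- mk(c(3, 3, 3)); single[2, 2, 2] <- 1L
  s <- extract_surface(single)
  expect_equal(unname(s$coords), matrix(c(2L, 2L, 2L), 1))

  cube <- mk(c(6, 6, 6)); cube[2:5, 2:5, 2:5] <- 1L
  expect_equal(nrow(extract_surface(cube)$coords), 4^3 - 2^3)  # 56

  solid <- array(1L, c(3, 4, 5))                # out-of-bounds is background
  expect_equal(nrow(extract_surface(solid)$coords), 3 * 4 * 5 - 1 * 2 * 3)

  set.seed(2)
  blob <- random_blob_mask()
  impl <- extract_surface(blob)$coords
  orac <- oracle_surface(blob)
  expect_equal(impl[order(impl[, 1], impl[, 2], impl[, 3]), , drop = FALSE],
               unname(orac[order(orac[, 1], orac[, 2], orac[, 3]), , drop = FALSE]),
               ignore_attr = TRUE)
  expect_error(extract_surface(mk(c(3, 3, 3))), "empty")
})

test_that("HD95 reproduces hand-checkable geometries in mm", {
  a <- mk(c(20, 5, 5)); a[3, 3, 3] <- 1L
  b <- mk(c(20, 5, 5)); b[13, 3, 3] <- 1L
  expect_equal(hd95(a, b, spacing_mm = c(1, 1, 1)), 10)
  expect_equal(hd95(a, b, spacing_mm = c(2, 1, 1)), 20)  # linear in spacing
  expect_equal(hd95(a, a, spacing_mm = c(5, 1, 1)), 0)

  # cube vs the same cube shifted 2 slices at 5 mm slice spacing
  cube <- mk(c(12, 8, 8)); cube[3:6, 3:6, 3:6] <- 1L
  shft <- mk(c(12, 8, 8)); shft[5:8, 3:6, 3:6] <- 1L
  expect_equal(hd95(cube, shft, spacing_mm = c(5, 1, 1)),
               oracle_hd95(cube, shft, c(5, 1, 1)), tolerance = 1e-12)

  expect_error(hd95(a, mk(c(20, 5, 5)), case_id = "p7"), "p7")
})

test_that("HD95 is symmetric and matches the brute-force oracle on random pairs", {
  set.seed(3)
  for (i in 1:10) {
    a <- random_blob_mask(); b <- random_blob_mask()
    sp <- c(5, 1, 1)
    h1 <- hd95(a, b, sp); h2 <- hd95(b, a, sp)
    expect_equal(h1, h2)
    expect_equal(h1, oracle_hd95(a, b, sp), tolerance = 1e-9)
  }
})

test_that("soft Dice loss and cross-entropy evaluate the stated formulas", {
  # uniform probabilities 0.5/0.5 with a half-foreground target
  M <- 8L
  probs <- matrix(0.5, 2, M)
  target <- rep(c(0, 1), each = M / 2)
  eps <- 1e-5
  S <- M / 4; U <- M / 2 + M / 2
  expect_equal(dice_loss(probs, target), 1 - (2 * S + eps) / (U + eps))
  expect_equal(ce_loss(probs, target), log(2))
  expect_equal(total_loss(probs, target),
               dice_loss(probs, target) + ce_loss(probs, target))

  # one-hot correct prediction: both components at the eps floor
  hard <- rbind(1 - target, target)
  expect_lt(dice_loss(hard, target), 1e-4)
  expect_lt(ce_loss(hard, target), 1e-10)
})

test_that("the loss gradient descends the total loss on a toy problem", {
  set.seed(4)
  logits <- matrix(rnorm(2 * 2), 2, 2)
  target <- c(1, 0)
  probs <- gtvseg:::softmax_channels(logits)
  lg <- gtvseg:::loss_and_grad(probs, target)
  expect_equal(lg$total, lg$dice + lg$ce)
  stepped <- logits - 0.1 * lg$dlogits
  lg2 <- gtvseg:::loss_and_grad(gtvseg:::softmax_channels(stepped), target)
  expect_lt(lg2$total, lg$total)

  # analytic logit gradient agrees with finite differences
  eps <- 1e-6
  for (j in 1:4) {
    lp <- logits; lp[j] <- lp[j] + eps
    lm <- logits; lm[j] <- lm[j] - eps
    gnum <- (gtvseg:::loss_and_grad(gtvseg:::softmax_channels(lp), target)$total -
               gtvseg:::loss_and_grad(gtvseg:::softmax_channels(lm), target)$total) /
      (2 * eps)
    expect_equal(gnum, lg$dlogits[j], tolerance = 1e-5)
  }
})

test_that("per-case evaluation aggregates like a spreadsheet", {
  set.seed(5)
  preds <- list(); refs <- list()
  for (i in 1:5) {
    preds[[i]] <- random_blob_mask()
    refs[[i]] <- random_blob_mask()
  }
  ev <- evaluate_cases(preds, refs, spacings = c(5, 1, 1))
  expect_equal(nrow(ev$per_case), 5)
  ds <- vapply(1:5, function(i) {
    A <- preds[[i]]; B <- refs[[i]]
    2 * sum(A & B) / (sum(A) + sum(B))
  }, 1)
  hs <- vapply(1:5, function(i) oracle_hd95(preds[[i]], refs[[i]], c(5, 1, 1)), 1)
  expect_equal(ev$per_case$dsc, ds)
  expect_equal(ev$per_case$hd95_mm, hs, tolerance = 1e-9)
  expect_equal(ev$summary$mean[ev$summary$metric == "dsc"], mean(ds))
  expect_equal(ev$summary$sd[ev$summary$metric == "hd95_mm"], sd(hs), tolerance = 1e-9)

  one <- evaluate_cases(preds[1], refs[1], spacings = c(5, 1, 1))
  expect_equal(one$summary$sd, c(0, 0))   # single case: sd defined as 0
  expect_error(evaluate_cases(preds, refs[1:3]), "differ in length")

  # two cases with known DSC values average arithmetically
  a <- mk(c(3, 3, 3)); a[1:2, 1, 1] <- 1L
  a8 <- mk(c(3, 3, 3)); a8[1:3, 1, 1] <- 1L            # DSC 2*2/(2+3) = 0.8
  c1 <- mk(c(10, 2, 2)); c1[1:9, 1, 1] <- 1L
  c2 <- mk(c(10, 2, 2)); c2[2:10, 1, 1] <- 1L          # DSC 2*8/(9+9) = 8/9
  ev2 <- evaluate_cases(list(a, c1), list(a8, c2), spacings = c(1, 1, 1))
  expect_equal(ev2$per_case$dsc, c(0.8, 8 / 9))
  expect_equal(ev2$summary$mean[1], mean(c(0.8, 8 / 9)))
})
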