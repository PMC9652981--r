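make_hu_volume <- function(vals, spacing = c(5, 1, 1)) {
  new_volume(array(vals, c(2, 2, 2)), spacing, "HU")
}

test_that("CT windowing maps the soft-tissue window bounds correctly", {
  v <- make_hu_volume(c(-160, 40, 240, -1000, 1000, 0, 40, 40))
  w <- window_ct(v, width = 400, level = 40)
  expect_equal(w$domain, "mapped_0_255")
  expect_equal(w$data[1, 1, 1], 0)        # lower bound: level - width/2
  expect_equal(w$data[2, 1, 1], 127.5)    # window midpoint
  expect_equal(w$data[1, 2, 1], 255)      # upper bound
  expect_equal(w$data[2, 2, 1], 0)        # clipped below
  expect_equal(w$data[1, 1, 2], 255)      # clipped above
  expect_error(window_ct(v, width = 0), "width")
  expect_error(window_ct(w), "HU")
})

test_that("windowing is monotone nondecreasing in the input", {
  hu <- sort(runif(64, -1200, 1200))
  v <- new_volume(array(hu, c(4, 4, 4)), c(5, 1, 1), "HU")
  w <- window_ct(v)
  expect_true(all(diff(as.numeric(w$data)) >= 0))
})

test_that("normalization is the exact linear bijection from 0-255 to [0,1]", {
  v <- new_volume(array(c(0, 255, 127.5, 51), c(1, 2, 2)), c(5, 1, 1),
                  "mapped_0_255")
  nv <- normalize_volume(v)
  expect_equal(as.numeric(nv$data), c(0, 1, 0.5, 0.2))
  expect_identical(nv$data * 255, v$data)
  expect_error(normalize_volume(nv), "mapped_0_255")
})

test_that("random_crop returns the requested shape and pads symmetrically", {
  sp <- tiny_phantom_spec()
  pc <- generate_phantom(sp, 2)
  cr <- random_crop(pc$volume, pc$mask, c(8L, 32L, 32L), seed = 4)
  expect_equal(dim(cr$volume$data), c(8L, 32L, 32L))
  expect_equal(dim(cr$mask$data), c(8L, 32L, 32L))
  expect_equal(cr$volume$spacing_mm, pc$volume$spacing_mm)

  # input exactly the patch size -> identity crop
  idv <- new_volume(array(runif(8 * 32 * 32), c(8, 32, 32)), c(5, 1, 1),
                    "normalized_0_1")
  idm <- new_mask(array(0L, c(8, 32, 32)), c(5, 1, 1))
  out <- random_crop(idv, idm, c(8L, 32L, 32L), seed = 1)
  expect_identical(out$volume$data, idv$data)

  # depth 4 padded to 8: 4 zero slices split 2/2
  small_v <- new_volume(array(1, c(4, 32, 32)), c(5, 1, 1), "normalized_0_1")
  small_m <- new_mask(array(1L, c(4, 32, 32)), c(5, 1, 1))
  pad <- random_crop(small_v, small_m, c(8L, 32L, 32L), seed = 1)
  expect_true(all(pad$volume$data[1:2, , ] == 0))
  expect_true(all(pad$volume$data[7:8, , ] == 0))
  expect_true(all(pad$volume$data[3:6, , ] == 1))
  expect_true(all(pad$mask$data[3:6, , ] == 1L))
})

test_that("center_crop_on_gtv centers on the centroid and clamps at borders", {
  # lesion with known centroid well in the interior
  m <- array(0L, c(16, 64, 64)); m[7:9, 30:34, 40:44] <- 1L
  v <- array(runif(16 * 64 * 64), c(16, 64, 64))
  vol <- new_volume(v, c(5, 1, 1), "normalized_0_1")
  msk <- new_mask(m, c(5, 1, 1))
  cc <- center_crop_on_gtv(vol, msk, c(8L, 16L, 16L))
  # centroid (0-based) is (7, 31, 41); start = centroid - size/2
  expect_identical(cc$volume$data, v[4:11, 24:39, 34:49])
  expect_identical(cc$mask$data, m[4:11, 24:39, 34:49])

  # GTV touching the first slice: crop clamped to start at slice 0, full size
  m2 <- array(0L, c(16, 64, 64)); m2[1:2, 1:4, 1:4] <- 1L
  cc2 <- center_crop_on_gtv(vol, new_mask(m2, c(5, 1, 1)), c(8L, 16L, 16L))
  expect_identical(cc2$volume$data, v[1:8, 1:16, 1:16])

  expect_error(center_crop_on_gtv(vol, new_mask(array(0L, c(16, 64, 64)),
                                                c(5, 1, 1)), c(8L, 16L, 16L)),
               "no foreground")
})

test_that("augmentation identity, involution, and alignment contracts hold", {
  sp <- tiny_phantom_spec()
  pc <- generate_phantom(sp, 6)
  v <- normalize_volume(window_ct(pc$volume))
  cr <- center_crop_on_gtv(v, pc$mask, c(8L, 32L, 32L))

  off <- augment_config(enabled = list(mirror = FALSE, rotate = FALSE,
                                       scale = FALSE, translate = FALSE,
                                       noise = FALSE))
  ident <- augment_patch(cr$volume, cr$mask, off, seed = 3)
  expect_identical(ident$volume$data, cr$volume$data)
  expect_identical(ident$mask$data, cr$mask$data)

  # mirror along width applied twice restores the input
  m1 <- augment_apply(cr$volume, cr$mask, list(mirror = c(FALSE, FALSE, TRUE)))
  m2 <- augment_apply(m1$volume, m1$mask, list(mirror = c(FALSE, FALSE, TRUE)))
  expect_identical(m2$volume$data, cr$volume$data)
  expect_identical(m2$mask$data, cr$mask$data)

  # random augmentation keeps the mask binary and is seed-deterministic
  a1 <- augment_patch(cr$volume, cr$mask, augment_config(), seed = 11)
  a2 <- augment_patch(cr$volume, cr$mask, augment_config(), seed = 11)
  expect_true(all(a1$mask$data %in% c(0L, 1L)))
  expect_identical(a1$volume$data, a2$volume$data)
  expect_equal(dim(a1$volume$data), dim(cr$volume$data))
})

test_that("in-plane rotation round trip loses little mask overlap", {
  sp <- phantom_spec(shape_voxels = c(10L, 64L, 64L), spacing_mm = c(5, 1, 1),
                     lesion_semiaxes_mm = c(12, 20, 20), noise_sd_hu = 0)
  pc <- generate_phantom(sp, 4)
  v <- normalize_volume(window_ct(pc$volume))
  r1 <- augment_apply(v, pc$mask, list(angle = 10))
  r2 <- augment_apply(r1$volume, r1$mask, list(angle = -10))
  expect_gte(dsc(r2$mask$data, pc$mask$data), 0.98)
})
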