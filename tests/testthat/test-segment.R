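test_that("bicubic magnification reproduces constants, identity and ramps", {
  const <- matrix(7, 32, 32)
  expect_equal(magnify(const, 4), matrix(7, 128, 128))

  r <- outer(0:63, 0:63, function(i, j) 2 * i + 3 * j)
  expect_identical(magnify(r, 1), r)

  m <- magnify(r, 4)
  truth <- outer(((1:256) - 0.5) / 4 - 0.5, ((1:256) - 0.5) / 4 - 0.5,
                 function(i, j) 2 * i + 3 * j)
  interior <- 9:248 # clamping distorts only a border band
  expect_lt(max(abs(m[interior, interior] - truth[interior, interior])), 1e-6)

  expect_error(magnify(r, 0), class = "lvtrab_validation_error")

  s <- slice_image(r + 1, pixel_spacing = c(1.6, 1.6))
  expect_equal(magnify(s, 4)$pixel_spacing, c(0.4, 0.4))
})

test_that("level set recovers a noise-free two-level disk exactly up to a 1-px band", {
  d <- disk_image()
  roi <- roi_spec(c(48.5, 48.5), 45, dim(d$img))
  pool <- segment_blood_pool(d$img, roi)
  # oracle: global threshold at the midpoint intensity
  oracle <- d$img >= (400 + 120) / 2 & roi$mask
  expect_gte(dice_coef(pool$mask, oracle), 0.999)
  # disagreement confined to a 1-pixel boundary band
  mism <- which(pool$mask != d$pool, arr.ind = TRUE)
  if (nrow(mism)) {
    ctr <- (nrow(d$img) + 1) / 2
    rho <- sqrt((mism[, 1] - ctr)^2 + (mism[, 2] - ctr)^2)
    expect_true(all(abs(rho - 28) <= 1.5))
  }
})

test_that("segmentation of a noisy trabeculated phantom reaches Dice 0.95", {
  ph <- make_lv_stack(lv_phantom_spec(complexity = 0.5, noise_sd = 10, seed = 9))
  mag <- magnify(ph$stack$slices[[6]], 4)
  pool <- segment_blood_pool(mag, phantom_roi(ph, 4))
  gt <- phantom_truth_mask(ph, 6, 4)
  expect_gte(dice_coef(pool$mask, gt), 0.95)
})

test_that("constant ROI raises a no-contrast error", {
  img <- matrix(50, 96, 96)
  roi <- roi_spec(c(48, 48), 30, dim(img))
  expect_error(segment_blood_pool(img, roi), class = "lvtrab_segmentation_error")
})

test_that("segmentation is deterministic", {
  d <- disk_image(noise_sd = 10, seed = 4)
  roi <- roi_spec(c(48.5, 48.5), 45, dim(d$img))
  e1 <- detect_edges(segment_blood_pool(d$img, roi))
  e2 <- detect_edges(segment_blood_pool(d$img, roi))
  expect_identical(e1$edges, e2$edges)
})

test_that("edge maps are translation-equivariant for integer shifts", {
  d <- disk_image(n = 128, noise_sd = 5, seed = 8)
  sh <- c(3, 5)
  img2 <- matrix(40, 128, 128)
  img2[(1:96) + sh[1], (1:96) + sh[2]] <- d$img[1:96, 1:96]
  roi1 <- roi_spec(c(48.5, 48.5), 45, c(128, 128))
  roi2 <- roi_spec(c(48.5, 48.5) + sh, 45, c(128, 128))
  e1 <- detect_edges(segment_blood_pool(d$img[1:96, 1:96] |>
    (\(m) { out <- matrix(40, 128, 128); out[1:96, 1:96] <- m; out })(), roi1))
  e2 <- detect_edges(segment_blood_pool(img2, roi2))
  shifted <- matrix(FALSE, 128, 128)
  shifted[(1:(128 - sh[1])) + sh[1], (1:(128 - sh[2])) + sh[2]] <-
    e1$edges[1:(128 - sh[1]), 1:(128 - sh[2])]
  expect_identical(e2$edges, shifted)
})

test_that("Sobel border of a filled square matches the boundary enumeration", {
  m <- matrix(FALSE, 128, 128)
  m[30:79, 40:89] <- TRUE # 50 x 50 square
  e <- detect_edges(m)
  n_edge <- sum(e$edges)
  expect_gte(n_edge, 4 * 50 - 4)
  expect_lte(n_edge, 2 * 4 * 50)
  # oracle: explicit boundary band of the square
  band <- matrix(FALSE, 128, 128)
  band[30:79, 40:89] <- TRUE
  band[31:78, 41:88] <- FALSE
  expect_true(all(e$edges[!band] == FALSE))
})

test_that("single-pixel masks and degenerate masks behave per contract", {
  m <- matrix(FALSE, 64, 64); m[10, 10] <- TRUE
  e <- detect_edges(m)
  expect_true(any(e$edges))
  expect_true(e$edges[10, 10])

  expect_error(detect_edges(matrix(FALSE, 64, 64)), class = "lvtrab_validation_error")
  img <- disk_image()$img
  roi <- roi_spec(c(48.5, 48.5), 20, dim(img)) # ROI entirely inside the pool
  pool <- structure(list(mask = roi$mask, roi = roi), class = "lv_pool")
  expect_error(detect_edges(pool), class = "lvtrab_validation_error")
})

test_that("every edge pixel touches both pool and non-pool (sandwich property)", {
  ph <- make_lv_stack(lv_phantom_spec(complexity = 0.7, seed = 13))
  mag <- magnify(ph$stack$slices[[5]], 4)
  pool <- segment_blood_pool(mag, phantom_roi(ph, 4))
  e <- detect_edges(pool)
  pts <- which(e$edges, arr.ind = TRUE)
  m <- pool$mask
  ok <- apply(pts, 1, function(p) {
    rs <- max(1, p[1] - 1):min(nrow(m), p[1] + 1)
    cs <- max(1, p[2] - 1):min(ncol(m), p[2] + 1)
    nb <- m[rs, cs]
    any(nb) && !all(nb)
  })
  expect_true(all(ok))
})

test_that("ROI validation enforces bounds and minimum area", {
  expect_error(roi_spec(c(5, 5), 10, c(64, 64)), class = "lvtrab_validation_error")
  expect_error(roi_spec(c(32, 32), 3, c(64, 64)), class = "lvtrab_validation_error")
  roi <- roi_spec(c(32, 32), 20, c(64, 64))
  expect_true(sum(roi$mask) >= 100)
})
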