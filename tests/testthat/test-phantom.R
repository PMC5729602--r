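test_that("fractal rasterizations are deterministic with correct analytic FDs", {
  expect_equal(make_fractal("line")$analytic_fd, 1)
  expect_equal(make_fractal("koch")$analytic_fd, log(4) / log(3))
  expect_equal(make_fractal("quadratic-koch")$analytic_fd, 1.5)
  expect_equal(make_fractal("sierpinski-triangle")$analytic_fd, log(3) / log(2))
  a <- make_fractal("koch")
  b <- make_fractal("koch")
  expect_identical(a$image, b$image)
  expect_true(any(a$image))
  expect_error(make_fractal("koch", canvas = 128), class = "lvtrab_validation_error")
})

test_that("phantom stacks are pure functions of spec and seed", {
  a <- make_lv_stack(lv_phantom_spec(seed = 14))
  b <- make_lv_stack(lv_phantom_spec(seed = 14))
  expect_identical(a$stack$slices[[4]]$pixels, b$stack$slices[[4]]$pixels)
  c_ <- make_lv_stack(lv_phantom_spec(seed = 15))
  expect_false(identical(a$stack$slices[[4]]$pixels, c_$stack$slices[[4]]$pixels))
})

test_that("phantom truth masks partition tissue and stay connected", {
  ph <- make_lv_stack(lv_phantom_spec(complexity = 0.8, seed = 23))
  for (sl in c(2, 6, 9)) {
    tr <- ph$truth[[sl]]
    expect_equal(sum(tr$pool & tr$myo), 0) # disjoint tissues
    expect_true(sum(tr$pool) > 0 && sum(tr$myo) > 0)
    # recesses contiguous with the cavity: pool is one 8-connected component
    expect_equal(sum(lvtrab:::largest_cc8(tr$pool)), sum(tr$pool))
    # trabecular fingers and papillaries attach to the wall: so does myocardium
    expect_equal(sum(lvtrab:::largest_cc8(tr$myo)), sum(tr$myo))
  }
})

test_that("per-slice complexity follows the mid-ventricular axial profile", {
  ph <- make_lv_stack(lv_phantom_spec(seed = 3))
  cx <- vapply(ph$truth, function(t) t$complexity, numeric(1))
  expect_gt(which.max(cx), 1)
  expect_lt(which.max(cx), length(cx))
})

test_that("phantom geometry validation rejects impossible radii", {
  expect_error(lv_phantom_spec(r_epi = 0.6), class = "lvtrab_validation_error")
  expect_error(lv_phantom_spec(r_endo = 0.45, r_epi = 0.42),
               class = "lvtrab_validation_error")
  expect_error(lv_phantom_spec(n_slices = 3), class = "lvtrab_validation_error")
  expect_error(lv_phantom_spec(noise_sd = -1), class = "lvtrab_validation_error")
})

test_that("simulated cohorts follow their generating lines", {
  co <- simulate_cohort(n_per_sex = 30, resid_sd = 0, seed = 4)
  m <- co[co$sex == "male", ]
  expect_equal(m$value, 1.198 + 4e-4 * m$age, tolerance = 1e-12)
  f <- co[co$sex == "female", ]
  expect_equal(f$value, 1.177 + 4e-4 * f$age, tolerance = 1e-12)

  expect_error(simulate_cohort(n_per_sex = 5), class = "lvtrab_validation_error")
  expect_error(simulate_cohort(resid_sd = -0.1), class = "lvtrab_validation_error")
})

test_that("cohort generator supports sex-gap recovery downstream", {
  co <- simulate_cohort(n_per_sex = 500, slope = 4e-4,
                        intercepts = c(female = 1.177, male = 1.198),
                        resid_sd = 0.029, seed = 3)
  m <- fit_reference(co)
  gap <- (m$by_sex$male$intercept + 45 * m$by_sex$male$slope) -
         (m$by_sex$female$intercept + 45 * m$by_sex$female$slope)
  expect_lt(abs(gap - 0.021), 0.004)
})

test_that("rating simulator hits its variance-component targets", {
  r0 <- icc_2way_random_agreement(simulate_raters(n = 50, error_sd = 0, seed = 5))
  expect_equal(r0$icc, 1)

  rm_ <- simulate_raters(n = 200, subject_sd = sqrt(0.9), error_sd = sqrt(0.1),
                         seed = 7)
  expect_lt(abs(icc_2way_random_agreement(rm_)$icc - 0.9), 0.03)

  base <- icc_2way_random_agreement(
    simulate_raters(n = 60, seed = 9))$icc
  shifted <- icc_2way_random_agreement(
    simulate_raters(n = 60, rater_shifts = c(0, 1.5), seed = 9))$icc
  expect_lt(shifted, base)

  expect_error(simulate_raters(n = 3), class = "lvtrab_validation_error")
  expect_error(simulate_raters(error_sd = -1), class = "lvtrab_validation_error")
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(make_lv_stack(lv_phantom_spec(n_slices = 5, seed = 2)))
  invisible(simulate_cohort(n_per_sex = 20, seed = 2))
  after <- runif(1)
  expect_identical(before, after)
})
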