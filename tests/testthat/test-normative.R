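test_that("reference fitting recovers generating parameters", {
  co <- simulate_cohort(n_per_sex = 500,
                        intercepts = c(female = 1.18, male = 1.18),
                        slope = 4e-4, resid_sd = 0.02, seed = 7)
  m <- fit_reference(co, metric = "global_fd")
  slopes <- vapply(m$by_sex, function(f) f$slope, numeric(1))
  expect_lt(abs(mean(slopes) - 4e-4), 1e-4)
  sds <- vapply(m$by_sex, function(f) f$resid_sd, numeric(1))
  expect_true(all(abs(sds - 0.02) < 3e-3))
})

test_that("zero-noise cohorts collapse the prediction band onto the line", {
  co <- simulate_cohort(n_per_sex = 50, resid_sd = 0, seed = 2)
  m <- fit_reference(co)
  rr <- reference_limits(m, "male", 40, n_boot = 300, seed = 1)
  expect_lt(rr$upper_hi - rr$lower_lo, 1e-6)
})

test_that("single-sex cohorts fit with a warning; undersized cohorts error", {
  co <- simulate_cohort(n_per_sex = 50, seed = 5)
  expect_warning(m <- fit_reference(co[co$sex == "female", ]), "only one sex")
  expect_named(m$by_sex, "female")

  small <- simulate_cohort(n_per_sex = 12, seed = 5)
  expect_error(fit_reference(small[1:15, ]), class = "lvtrab_validation_error")

  narrow <- simulate_cohort(n_per_sex = 50, age_range = c(40, 50), seed = 5)
  expect_error(fit_reference(narrow), class = "lvtrab_validation_error")
})

test_that("reference limits are deterministic and validate their inputs", {
  co <- simulate_cohort(n_per_sex = 80, seed = 11)
  m <- fit_reference(co)
  r1 <- reference_limits(m, "female", 35, n_boot = 400, seed = 9)
  r2 <- reference_limits(m, "female", 35, n_boot = 400, seed = 9)
  expect_identical(r1, r2)
  expect_true(r1$lower_lo < r1$lower_hi && r1$lower_hi < r1$mean &&
              r1$mean < r1$upper_lo && r1$upper_lo < r1$upper_hi)
  expect_error(reference_limits(m, "female", 35, n_boot = 100),
               class = "lvtrab_validation_error")
  expect_error(reference_limits(m, "female", 95), class = "lvtrab_validation_error")
})

test_that("indeterminate band width shrinks as cohort size grows", {
  widths <- vapply(c(50, 200, 800), function(n) {
    co <- simulate_cohort(n_per_sex = n, seed = 31)
    m <- fit_reference(co)
    rr <- reference_limits(m, "male", 45, n_boot = 500, seed = 2)
    rr$lower_hi - rr$lower_lo
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("delta-method indeterminate regions approximate the bootstrap", {
  co <- simulate_cohort(n_per_sex = 300, seed = 13)
  m <- fit_reference(co)
  b <- reference_limits(m, "male", 45, n_boot = 2000, seed = 3)
  d <- reference_limits(m, "male", 45, method = "delta")
  expect_lt(abs((b$lower_hi - b$lower_lo) - (d$lower_hi - d$lower_lo)),
            0.5 * (b$lower_hi - b$lower_lo))
})

test_that("packaged tables carry the published decade rows", {
  tab <- packaged_reference()
  row <- tab[tab$metric == "global_fd" & tab$sex == "male" & tab$decade == "20-29", ]
  expect_equal(unlist(row[c("lower_lo", "lower_hi", "mean", "upper_lo", "upper_hi")],
                      use.names = FALSE),
               c(1.141, 1.156, 1.199, 1.243, 1.257))
  row <- tab[tab$metric == "max_apical_fd" & tab$sex == "female" & tab$decade == "60-69", ]
  expect_equal(unlist(row[c("lower_lo", "lower_hi", "mean", "upper_lo", "upper_hi")],
                      use.names = FALSE),
               c(1.169, 1.191, 1.259, 1.327, 1.350))
  # every row is strictly ordered
  expect_true(all(tab$lower_lo < tab$lower_hi & tab$lower_hi < tab$mean &
                  tab$mean < tab$upper_lo & tab$upper_lo < tab$upper_hi))
  # full coverage: 6 metrics x 2 sexes x 5 decades
  expect_equal(nrow(tab), 60)
})

test_that("classification bands follow the worked example and stay monotone", {
  vals <- c(1.10, 1.15, 1.199, 1.25, 1.30)
  labels <- vapply(vals, function(v) {
    as.character(classify_value(v, "global_fd", "male", 25)$label)
  }, character(1))
  expect_equal(labels, c("abnormal-low", "indeterminate-low", "normal",
                         "indeterminate-high", "abnormal-high"))

  # monotone in value: labels never move leftward as the value increases
  grid <- seq(1.05, 1.35, by = 0.002)
  lab <- vapply(grid, function(v) {
    as.numeric(classify_value(v, "global_fd", "female", 52)$label)
  }, numeric(1))
  expect_true(all(diff(lab) >= 0))

  expect_error(classify_value(1.2, "global_fd", "male", 75),
               class = "lvtrab_validation_error")
})

test_that("classification against a fitted model uses continuous-age limits", {
  co <- simulate_cohort(n_per_sex = 200, seed = 19)
  m <- fit_reference(co, metric = "global_fd")
  cl <- classify_value(1.6, "global_fd", "male", 44.5, source = m,
                       n_boot = 300, seed = 1)
  expect_equal(as.character(cl$label), "abnormal-high")
  cl2 <- classify_value(1.197, "global_fd", "male", 44.5, source = m,
                        n_boot = 300, seed = 1)
  expect_equal(as.character(cl2$label), "normal")
})

test_that("negative strain metrics classify on signed values", {
  # male 20-29 circumferential: numerically below -23.6 is abnormal-low
  cl <- classify_value(-25, "strain_circumferential", "male", 25)
  expect_equal(as.character(cl$label), "abnormal-low")
  cl <- classify_value(-19.4, "strain_circumferential", "male", 25)
  expect_equal(as.character(cl$label), "normal")
  cl <- classify_value(-13, "strain_circumferential", "male", 25)
  expect_equal(as.character(cl$label), "abnormal-high")
})
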