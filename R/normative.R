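# Sex-stratified, age-dependent normative reference ranges.
#
# Reference ranges are 95% prediction intervals from a univariable linear
# regression of the metric on age, fitted separately per sex. Each outer
# limit carries an indeterminate region: the 95% confidence interval of the
# limit itself, estimated by case-resampling bootstrap (or a delta-method
# approximation), reflecting sampling uncertainty of the range. Values are
# classified into five ordered bands by the resulting four breakpoints.

CLASS_LABELS <- c("abnormal-low", "indeterminate-low", "normal",
                  "indeterminate-high", "abnormal-high")

#' Fit sex-stratified reference models
#'
#' @param cohort Data frame with columns `age` (years), `sex` (`"male"` /
#'   `"female"`) and `value`.
#' @param metric Metric name recorded in the model (e.g. `"global_fd"`).
#' @param level Prediction-interval level (default 0.95).
#' @return An `lv_refmodel`: per-sex intercept, slope, residual SD, n, mean
#'   age, age sum of squares, t quantile, and the fitting data (kept for the
#'   bootstrap).
#' @export
fit_reference <- function(cohort, metric = "value", level = 0.95) {
  need <- c("age", "sex", "value")
  if (!all(need %in% names(cohort))) {
    abort_validation("cohort must have columns age, sex, value")
  }
  sexes <- intersect(c("male", "female"), unique(cohort$sex))
  if (length(sexes) == 0) abort_validation("sex must be 'male' or 'female'")
  if (length(sexes) == 1) {
    warning(sprintf("only one sex present (%s); fitting that sex only", sexes),
            call. = FALSE)
  }
  fits <- lapply(sexes, function(sx) {
    d <- cohort[cohort$sex == sx & is.finite(cohort$value) & is.finite(cohort$age), ]
    if (nrow(d) < 10) abort_validation(sprintf("fewer than 10 records for sex %s", sx))
    if (diff(range(d$age)) < 20) {
      abort_validation("ages must span at least 20 years per sex")
    }
    fit <- stats::lm(value ~ age, data = d)
    s <- summary(fit)$sigma
    list(
      sex = sx,
      intercept = unname(stats::coef(fit)[1]),
      slope = unname(stats::coef(fit)[2]),
      resid_sd = max(s, 1e-12),
      n = nrow(d),
      age_mean = mean(d$age),
      age_ss = sum((d$age - mean(d$age))^2),
      t_crit = stats::qt(1 - (1 - level) / 2, df = nrow(d) - 2),
      age_range = range(d$age),
      data = d[, c("age", "value")]
    )
  })
  names(fits) <- sexes
  structure(list(metric = metric, level = level, by_sex = fits),
            class = "lv_refmodel")
}

# outer prediction limits at one age, from closed-form components
pred_limits <- function(f, age) {
  mid <- f$intercept + f$slope * age
  half <- f$t_crit * f$resid_sd *
    sqrt(1 + 1 / f$n + (age - f$age_mean)^2 / f$age_ss)
  c(lower = mid - half, mean = mid, upper = mid + half)
}

# closed-form refit of value ~ age used inside the bootstrap loop
refit_limits <- function(age_v, val_v, age, t_crit_df) {
  n <- length(age_v)
  xb <- mean(age_v); yb <- mean(val_v)
  sxx <- sum((age_v - xb)^2)
  b <- sum((age_v - xb) * (val_v - yb)) / sxx
  a <- yb - b * xb
  res <- val_v - a - b * age_v
  s <- sqrt(sum(res^2) / (n - 2))
  mid <- a + b * age
  half <- t_crit_df * s * sqrt(1 + 1 / n + (age - xb)^2 / sxx)
  c(mid - half, mid + half)
}

#' Reference limits with indeterminate regions at a given age
#'
#' The outer limits are the 95% prediction bounds; each limit's indeterminate
#' region is its 95% confidence interval over case resamples of the fitting
#' cohort (percentile bootstrap), or a delta-method approximation.
#'
#' @param model An `lv_refmodel`.
#' @param sex `"male"` or `"female"`.
#' @param age Age in years; must lie within the fitted span plus 10 years.
#' @param n_boot Bootstrap resamples (>= 200; default 2000).
#' @param seed Bootstrap seed (recorded in the result).
#' @param method `"bootstrap"` (default) or `"delta"`.
#' @return An `lv_rangerow`: `lower_lo < lower_hi < mean < upper_lo <
#'   upper_hi` plus provenance fields.
#' @export
reference_limits <- function(model, sex, age, n_boot = 2000, seed = 1,
                             method = c("bootstrap", "delta")) {
  stopifnot(inherits(model, "lv_refmodel"))
  method <- match.arg(method)
  f <- model$by_sex[[sex]]
  if (is.null(f)) abort_validation(sprintf("no fitted model for sex %s", sex))
  if (age < f$age_range[1] - 10 || age > f$age_range[2] + 10) {
    abort_validation("age is outside the fitted span plus 10 years")
  }
  lim <- pred_limits(f, age)
  if (method == "bootstrap") {
    if (n_boot < 200) abort_validation("n_boot must be at least 200")
    bs <- with_seed(seed, {
      idx <- matrix(sample.int(f$n, f$n * n_boot, replace = TRUE), nrow = f$n)
      apply(idx, 2, function(i) {
        refit_limits(f$data$age[i], f$data$value[i], age, f$t_crit)
      })
    })
    lo_ci <- stats::quantile(bs[1, ], c(0.025, 0.975), names = FALSE)
    hi_ci <- stats::quantile(bs[2, ], c(0.025, 0.975), names = FALSE)
  } else {
    # delta method: var(limit) ~ var of the conditional mean plus the
    # half-width term driven by var(s), with var(s) ~ s^2 / (2 (n - 2))
    g <- sqrt(1 + 1 / f$n + (age - f$age_mean)^2 / f$age_ss)
    v_mid <- f$resid_sd^2 * (1 / f$n + (age - f$age_mean)^2 / f$age_ss)
    v_half <- (f$t_crit * g)^2 * f$resid_sd^2 / (2 * (f$n - 2))
    se <- sqrt(v_mid + v_half)
    lo_ci <- lim[["lower"]] + c(-1, 1) * 1.96 * se
    hi_ci <- lim[["upper"]] + c(-1, 1) * 1.96 * se
  }
  structure(
    list(metric = model$metric, sex = sex, age = age,
         lower_lo = lo_ci[1], lower_hi = lo_ci[2], mean = lim[["mean"]],
         upper_lo = hi_ci[1], upper_hi = hi_ci[2],
         source = "fitted model", method = method,
         n_boot = if (method == "bootstrap") n_boot else NA_integer_,
         seed = if (method == "bootstrap") seed else NA_integer_),
    class = "lv_rangerow"
  )
}

#' Outer 95% prediction band over a vector of ages
#'
#' Closed-form prediction limits (no indeterminate regions); vectorised over
#' `age` for coverage checks and plotting.
#'
#' @param model An `lv_refmodel`.
#' @param sex `"male"` or `"female"`.
#' @param age Numeric vector of ages in years.
#' @return Data frame with columns `age`, `lower`, `mean`, `upper`.
#' @export
prediction_band <- function(model, sex, age) {
  stopifnot(inherits(model, "lv_refmodel"))
  f <- model$by_sex[[sex]]
  if (is.null(f)) abort_validation(sprintf("no fitted model for sex %s", sex))
  mid <- f$intercept + f$slope * age
  half <- f$t_crit * f$resid_sd *
    sqrt(1 + 1 / f$n + (age - f$age_mean)^2 / f$age_ss)
  data.frame(age = age, lower = mid - half, mean = mid, upper = mid + half)
}

#' Packaged decade reference tables
#'
#' Sex- and decade-specific reference limits for LV trabeculation (global,
#' mean apical, maximal apical FD) and global myocardial strain
#' (circumferential, radial, longitudinal), ages 20-69, as shipped with the
#' package. Pairs are stored in increasing numeric order; for the negative
#' strain metrics the numerically low side corresponds to high strain
#' magnitude.
#'
#' @return Data frame with columns `metric, sex, decade, age_lo, age_hi,
#'   lower_lo, lower_hi, mean, upper_lo, upper_hi`.
#' @export
packaged_reference <- function() {
  path <- system.file("extdata", "reference_ranges.csv", package = "lvtrab")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

range_breaks <- function(row) {
  unlist(row[c("lower_lo", "lower_hi", "upper_lo", "upper_hi")], use.names = FALSE)
}

#' Classify a value against reference ranges
#'
#' Five-way ordered classification by the four breakpoints at (sex, age):
#' below the lower indeterminate pair is abnormal-low, inside it
#' indeterminate-low, between the pairs normal, inside the upper pair
#' indeterminate-high, above it abnormal-high. With the packaged tables the
#' decade row containing `age` is used as-is; with a fitted model the
#' continuous-age limits are used.
#'
#' @param value Measured value (signed, in the metric's native units).
#' @param metric Metric name; for the packaged tables one of
#'   `unique(packaged_reference()$metric)`.
#' @param sex `"male"` or `"female"`.
#' @param age Age in years (packaged tables cover 20-69).
#' @param source `"packaged"` (default), an `lv_refmodel`, or an
#'   `lv_rangerow`.
#' @param ... Passed to [reference_limits()] when `source` is a model.
#' @return An `lv_classification`: ordered factor `label` plus the breakpoints
#'   used.
#' @export
classify_value <- function(value, metric = "global_fd", sex = c("male", "female"),
                           age = NULL, source = "packaged", ...) {
  sex <- match.arg(sex)
  if (inherits(source, "lv_refmodel")) {
    row <- reference_limits(source, sex, age, ...)
    src <- "fitted model"
  } else if (inherits(source, "lv_rangerow")) {
    row <- source
    src <- row$source
  } else {
    tab <- packaged_reference()
    hit <- tab[tab$metric == metric & tab$sex == sex &
                 tab$age_lo <= age & age <= tab$age_hi, ]
    if (nrow(hit) != 1) {
      abort_validation("metric/sex/age not covered by the packaged tables (ages 20-69)")
    }
    row <- as.list(hit[1, ])
    src <- "packaged table"
  }
  br <- range_breaks(row)
  label <- if (value <= br[1]) "abnormal-low"
    else if (value < br[2]) "indeterminate-low"
    else if (value <= br[3]) "normal"
    else if (value < br[4]) "indeterminate-high"
    else "abnormal-high"
  structure(
    list(label = factor(label, levels = CLASS_LABELS, ordered = TRUE),
         metric = metric, value = value, sex = sex, age = age,
         breakpoints = br, source = src),
    class = "lv_classification"
  )
}

#' @export
print.lv_classification <- function(x, ...) {
  cat(sprintf("<lv_classification> %s = %.4g (%s, age %s): %s [%s]\n",
              x$metric, x$value, x$sex, format(x$age), as.character(x$label),
              x$source))
  invisible(x)
}
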