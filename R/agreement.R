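# Intra-/inter-observer reproducibility: two-way random-effects,
# absolute-agreement, single-measure intraclass correlation, ICC(2,1), with
# the F-based 95% confidence interval for that variant (McGraw & Wong
# convention). Averaged-measures ICC(2,k) is available behind a flag.

#' Construct a rating matrix
#'
#' @param values Numeric matrix, subjects in rows and raters in columns, or a
#'   long data frame with columns `subject_id`, `rater`, `value`.
#' @param metric Metric name for reporting.
#' @return An `lv_ratings` object. Rows with any missing cell are dropped
#'   (listwise deletion) with a message reporting the count.
#' @export
rating_matrix <- function(values, metric = "value") {
  if (is.data.frame(values)) {
    need <- c("subject_id", "rater", "value")
    if (!all(need %in% names(values))) {
      abort_validation("long format needs columns subject_id, rater, value")
    }
    wide <- stats::reshape(values[need], idvar = "subject_id",
                           timevar = "rater", direction = "wide")
    values <- as.matrix(wide[, -1, drop = FALSE])
  }
  values <- as.matrix(values)
  drop <- apply(values, 1, function(r) any(!is.finite(r)))
  if (any(drop)) {
    message(sprintf("%d subject(s) dropped by listwise deletion", sum(drop)))
    values <- values[!drop, , drop = FALSE]
  }
  if (nrow(values) < 5 || ncol(values) < 2) {
    abort_validation("rating matrix needs at least 5 subjects and 2 raters")
  }
  structure(list(values = unname(values), metric = metric), class = "lv_ratings")
}

# two-way ANOVA mean squares (subjects x raters, one observation per cell)
anova_ms <- function(m) {
  n <- nrow(m); k <- ncol(m)
  d <- data.frame(value = as.vector(m),
                  subject = factor(rep(seq_len(n), times = k)),
                  rater = factor(rep(seq_len(k), each = n)))
  tab <- stats::anova(stats::aov(value ~ subject + rater, data = d))
  list(msr = tab["subject", "Mean Sq"], msc = tab["rater", "Mean Sq"],
       mse = tab["Residuals", "Mean Sq"], n = n, k = k)
}

#' Two-way random, absolute-agreement intraclass correlation
#'
#' Single-measure ICC(2,1) from the two-way ANOVA decomposition:
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`, with the F-based
#' confidence interval for this variant (Satterthwaite degrees of freedom for
#' the lower bound's denominator).
#'
#' @param m An `lv_ratings` object or a plain numeric matrix (subjects x
#'   raters).
#' @param alpha Two-sided significance level for the CI (default 0.05).
#' @param type `"single"` for ICC(2,1) (default) or `"average"` for ICC(2,k).
#' @return An `lv_icc`: `icc`, `ci_low`, `ci_high`, `n`, `k`, `variant`.
#' @export
icc_2way_random_agreement <- function(m, alpha = 0.05, type = c("single", "average")) {
  type <- match.arg(type)
  if (!inherits(m, "lv_ratings")) m <- rating_matrix(m)
  v <- m$values
  if (stats::var(as.vector(v)) == 0) abort_validation("constant ratings: zero total variance")
  ms <- anova_ms(v)
  n <- ms$n; k <- ms$k
  icc <- (ms$msr - ms$mse) / (ms$msr + (k - 1) * ms$mse + (k / n) * (ms$msc - ms$mse))

  if (icc >= 1 - 1e-12) {
    # perfect agreement: the F-based interval degenerates
    out <- structure(list(icc = 1, ci_low = 1, ci_high = 1, n = n, k = k,
                          alpha = alpha, metric = m$metric,
                          variant = "ICC(2,1) absolute agreement"),
                     class = "lv_icc")
    return(out)
  }
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v_df <- (a * ms$msc + b * ms$mse)^2 /
    ((a * ms$msc)^2 / (k - 1) + (b * ms$mse)^2 / ((n - 1) * (k - 1)))
  f_l <- stats::qf(1 - alpha / 2, n - 1, v_df)
  f_u <- stats::qf(1 - alpha / 2, v_df, n - 1)
  lo <- n * (ms$msr - f_l * ms$mse) /
    (f_l * (k * ms$msc + (k * n - k - n) * ms$mse) + n * ms$msr)
  hi <- n * (f_u * ms$msr - ms$mse) /
    (k * ms$msc + (k * n - k - n) * ms$mse + n * f_u * ms$msr)

  if (type == "average") {
    step <- function(x) k * x / (1 + (k - 1) * x) # Spearman-Brown
    icc <- step(icc); lo <- step(lo); hi <- step(hi)
  }
  structure(
    list(icc = icc, ci_low = lo, ci_high = hi, n = n, k = k,
         alpha = alpha, metric = m$metric,
         variant = if (type == "single") "ICC(2,1) absolute agreement"
                   else sprintf("ICC(2,%d) absolute agreement", k)),
    class = "lv_icc"
  )
}

#' @export
print.lv_icc <- function(x, ...) {
  cat(sprintf("<lv_icc> %s: %.3f, 95%% CI [%.3f, %.3f] (n = %d, k = %d)\n",
              x$variant, x$icc, x$ci_low, x$ci_high, x$n, x$k))
  invisible(x)
}
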