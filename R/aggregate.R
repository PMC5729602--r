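# Slice-inclusion rules and regional aggregation of per-slice FDs.
#
# The most apical slice is excluded from fractal analysis wholesale (partial
# volume effects), so it contributes neither to global FD nor to the regional
# split. For the apical/basal halving of an odd-numbered analyzed stack the
# middle slice is excluded from the split only; it still counts toward the
# global mean.

#' Split an analyzed stack into basal and apical halves
#'
#' @param n Number of analyzed slices (base to apex), or a numeric vector of
#'   per-slice FDs whose length is used.
#' @return List with integer index vectors `basal` and `apical` (1-based,
#'   base to apex) and `excluded_middle` (the middle index for odd `n`, else
#'   `NULL`).
#' @export
split_halves <- function(n) {
  if (length(n) > 1) n <- length(n)
  n <- as.integer(n)
  if (n < 2) abort_validation("at least 2 analyzed slices are needed for the split")
  h <- n %/% 2
  list(
    basal = seq_len(h),
    apical = seq.int(n - h + 1L, n),
    excluded_middle = if (n %% 2 == 1) h + 1L else NULL
  )
}

#' Aggregate per-slice FDs into subject-level measures
#'
#' Computes global FD (arithmetic mean over analyzed slices), and mean and
#' maximal apical FD over the apical half from [split_halves()].
#'
#' @param fds Numeric vector of per-slice FDs, ordered base to apex, for the
#'   analyzed slices (most apical slice already excluded).
#' @param slice_indices Integer stack indices matching `fds`.
#' @param subject_id Subject identifier.
#' @param excluded_indices Stack indices excluded from analysis.
#' @return An `lv_subject_fd` object.
#' @export
aggregate_fds <- function(fds, slice_indices = seq_along(fds) - 1L,
                          subject_id = "subject", excluded_indices = integer(0)) {
  if (length(fds) < 2) abort_validation("at least 2 analyzed slice FDs required")
  if (any(!is.finite(fds))) abort_validation("all FDs must be finite")
  halves <- split_halves(length(fds))
  apical <- fds[halves$apical]
  structure(
    list(
      subject_id = subject_id,
      per_slice = data.frame(slice_index = as.integer(slice_indices), fd = fds),
      global_fd = mean(fds),
      mean_apical_fd = mean(apical),
      max_apical_fd = max(apical),
      n_slices_analyzed = length(fds),
      excluded_indices = as.integer(excluded_indices),
      halves = halves
    ),
    class = "lv_subject_fd"
  )
}

#' @export
print.lv_subject_fd <- function(x, ...) {
  cat(sprintf(
    "<lv_subject_fd> '%s': global FD %.3f, mean apical %.3f, max apical %.3f (%d slices analyzed)\n",
    x$subject_id, x$global_fd, x$mean_apical_fd, x$max_apical_fd,
    x$n_slices_analyzed))
  invisible(x)
}

#' Full fractal analysis of an end-diastolic stack
#'
#' Drops the most apical slice, runs [slice_fd()] on every remaining slice and
#' aggregates with [aggregate_fds()].
#'
#' @param stack An `lv_stack` ordered base to apex (set
#'   `orientation = "apex-first"` if the stored order is reversed).
#' @param roi_set Optional list of `lv_roi` objects keyed by position (same
#'   length as the stack) in magnified coordinates; `NULL` entries fall back
#'   to the automatic ROI.
#' @param params [fd_params()] record.
#' @param orientation `"base-first"` (default) or `"apex-first"`.
#' @return An `lv_subject_fd`, with per-slice `r_squared` in `per_slice`.
#' @export
analyze_stack <- function(stack, roi_set = NULL, params = fd_params(),
                          orientation = c("base-first", "apex-first")) {
  stopifnot(inherits(stack, "lv_stack"))
  orientation <- match.arg(orientation)
  slices <- stack$slices
  if (orientation == "apex-first") {
    slices <- rev(slices)
    if (!is.null(roi_set)) roi_set <- rev(roi_set)
  }
  n <- length(slices)
  apical_idx <- slices[[n]]$slice_index
  slices <- slices[-n] # most apical slice excluded from fractal analysis
  if (!is.null(roi_set)) roi_set <- roi_set[-n]
  if (length(slices) < 3) abort_validation("fewer than 3 analyzed slices")
  fits <- lapply(seq_along(slices), function(i) {
    slice_fd(slices[[i]], roi = if (is.null(roi_set)) NULL else roi_set[[i]],
             params = params)
  })
  fds <- vapply(fits, function(f) f$fd, numeric(1))
  out <- aggregate_fds(
    fds,
    slice_indices = vapply(slices, function(s) s$slice_index, integer(1)),
    subject_id = stack$subject_id,
    excluded_indices = apical_idx
  )
  out$per_slice$r_squared <- vapply(fits, function(f) f$r_squared, numeric(1))
  out
}
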