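# Box-counting fractal dimension of a binary edge map.
#
# A single grid is anchored at the top-left corner of the edge bounding box
# (no offset averaging), partial boxes at the right/bottom margins count, and
# FD is minus the OLS slope of log N(s) on log s.

#' Construct a box-count curve
#'
#' @param sizes Strictly increasing box side lengths in pixels, all >= 2.
#' @param counts Positive occupied-box counts, non-increasing in size.
#' @return An `lv_boxcount` object.
#' @export
box_count_curve <- function(sizes, counts) {
  if (length(sizes) < 4) abort_validation("at least 4 box sizes are required")
  if (any(sizes < 2) || any(diff(sizes) <= 0)) {
    abort_validation("sizes must be strictly increasing and >= 2")
  }
  if (length(counts) != length(sizes) || any(counts <= 0)) {
    abort_validation("counts must be positive, one per size")
  }
  if (any(diff(counts) > 0)) {
    abort_validation("counts must be non-increasing in box size")
  }
  structure(list(sizes = as.numeric(sizes), counts = as.numeric(counts)),
            class = "lv_boxcount")
}

#' Default box-size progression for an image
#'
#' Powers of two from 2 px up to the largest power of two not exceeding 45%
#' of the smaller image dimension.
#'
#' @param dim Image dimensions (rows, cols).
#' @return Integer vector of box sizes.
#' @export
default_box_sizes <- function(dim) {
  smax <- 0.45 * min(dim)
  if (smax < 2) return(integer(0))
  2^(1:floor(log2(smax)))
}

#' Count occupied boxes over a size progression
#'
#' Default sizes come from [default_box_sizes()] applied to the analysis
#' region: the bounding box of the edge pixels (falling back to the full
#' image for degenerate, e.g. single-row, objects). Boxes much larger than
#' the object measure its planar extent rather than its boundary scaling and
#' would only bias the fit.
#'
#' @param edges An `lv_edges` object or logical/binary matrix.
#' @param sizes Optional explicit box sizes overriding the default.
#' @return An `lv_boxcount` curve.
#' @export
box_count <- function(edges, sizes = NULL) {
  e <- if (inherits(edges, "lv_edges")) edges$edges else edges > 0
  pts <- which(e, arr.ind = TRUE)
  if (nrow(pts) == 0) abort_validation("edge map is empty")
  if (is.null(sizes)) {
    bdim <- c(diff(range(pts[, 1])) + 1, diff(range(pts[, 2])) + 1)
    sizes <- default_box_sizes(bdim)
    if (length(sizes) < 4) sizes <- default_box_sizes(dim(e))
  }
  if (length(sizes) < 4) {
    abort_validation("fewer than 4 usable box sizes: image too small")
  }
  r0 <- min(pts[, 1]); c0 <- min(pts[, 2])
  counts <- vapply(sizes, function(s) {
    br <- (pts[, 1] - r0) %/% s
    bc <- (pts[, 2] - c0) %/% s
    length(unique(br * (max(bc) + 1L) + bc))
  }, numeric(1))
  box_count_curve(sizes, counts)
}

#' Fit the fractal dimension from a box-count curve
#'
#' FD is minus the slope of the unweighted ordinary least-squares line of
#' log N(s) against log s (natural logarithm; the base cancels in the slope).
#'
#' @param curve An `lv_boxcount`.
#' @return An `lv_fd` object: `fd`, `r_squared`, `curve`, `n_scales`.
#' @export
fit_fd <- function(curve) {
  stopifnot(inherits(curve, "lv_boxcount"))
  x <- log(curve$sizes); y <- log(curve$counts)
  if (stats::var(x) == 0) abort_validation("zero variance in log box sizes")
  fit <- stats::lm.fit(cbind(1, x), y)
  fd <- -fit$coefficients[[2]]
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(fit$residuals^2) / ss_tot
  structure(list(fd = fd, r_squared = r2, curve = curve,
                 n_scales = length(curve$sizes)), class = "lv_fd")
}

#' @export
print.lv_fd <- function(x, ...) {
  cat(sprintf("<lv_fd> FD = %.4f (R^2 = %.4f over %d scales)\n",
              x$fd, x$r_squared, x$n_scales))
  invisible(x)
}

#' Analysis parameters for per-slice fractal dimension
#'
#' @param magnification Bicubic magnification factor applied before
#'   segmentation (default 4).
#' @param segment [segment_params()] record.
#' @param sizes Optional explicit box sizes.
#' @return Parameter record (list).
#' @export
fd_params <- function(magnification = 4L, segment = segment_params(), sizes = NULL) {
  list(magnification = magnification, segment = segment, sizes = sizes)
}

#' Fractal dimension of one short-axis slice
#'
#' Composition of the full per-slice chain: magnify, segment the blood pool,
#' extract the Sobel border, box count, fit FD.
#'
#' @param slice An `lv_slice`.
#' @param roi `lv_roi` in magnified coordinates, or `NULL` for the automatic
#'   ROI.
#' @param params [fd_params()] record.
#' @return An `lv_fd` with the slice index attached as attribute
#'   `slice_index`.
#' @export
slice_fd <- function(slice, roi = NULL, params = fd_params()) {
  res <- tryCatch({
    mag <- magnify(slice, params$magnification)
    pool <- segment_blood_pool(mag, roi, params$segment)
    edges <- detect_edges(pool)
    fit_fd(box_count(edges, params$sizes))
  }, lvtrab_error = function(e) {
    lvtrab_abort(sprintf("slice %d: %s", slice$slice_index, conditionMessage(e)),
                 class(e)[1])
  })
  attr(res, "slice_index") <- slice$slice_index
  res
}
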