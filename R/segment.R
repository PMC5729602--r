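# Per-slice segmentation chain: bicubic magnification, ROI restriction,
# region-based level-set segmentation of the bright blood pool, Sobel edge
# extraction of the trabeculated endocardial border.

# shift a matrix by (dr, dc), padding with `pad` (or replicating the border).
shift_mat <- function(m, dr, dc, pad = 0, replicate = FALSE) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- seq_len(nr) - dr
  ci <- seq_len(nc) - dc
  if (replicate) {
    ri <- pmin(pmax(ri, 1L), nr)
    ci <- pmin(pmax(ci, 1L), nc)
    m[ri, ci, drop = FALSE]
  } else {
    out <- matrix(pad, nr, nc)
    rok <- ri >= 1 & ri <= nr
    cok <- ci >= 1 & ci <= nc
    out[rok, cok] <- m[ri[rok], ci[cok]]
    out
  }
}

# Keys cubic-convolution kernel, a = -1/2 (Catmull-Rom): exact on linear ramps.
cubic_kernel <- function(t) {
  a <- -0.5
  t <- abs(t)
  w <- numeric(length(t))
  i1 <- t <= 1
  i2 <- t > 1 & t < 2
  w[i1] <- (a + 2) * t[i1]^3 - (a + 3) * t[i1]^2 + 1
  w[i2] <- a * t[i2]^3 - 5 * a * t[i2]^2 + 8 * a * t[i2] - 4 * a
  w
}

# interpolation weight matrix mapping n input samples to n*factor outputs;
# border handled by index clamping (sample replication), so weights still sum
# to one and constants are reproduced exactly.
bicubic_weights <- function(n, factor) {
  nout <- n * factor
  x <- (seq_len(nout) - 0.5) / factor - 0.5   # 0-based input coordinate
  i0 <- floor(x)
  W <- matrix(0, nout, n)
  for (k in -1:2) {
    idx <- pmin(pmax(i0 + k, 0), n - 1) + 1
    w <- cubic_kernel(x - (i0 + k))
    W[cbind(seq_len(nout), idx)] <- W[cbind(seq_len(nout), idx)] + w
  }
  W
}

#' Magnify a slice by bicubic interpolation
#'
#' Separable cubic convolution (Catmull-Rom kernel). Output dimensions are
#' `factor` times the input; pixel spacing is divided by `factor`.
#'
#' @param slice An `lv_slice` or a plain numeric matrix.
#' @param factor Positive integer magnification factor (default 4).
#' @return Object of the same kind as `slice`, magnified.
#' @export
magnify <- function(slice, factor = 4L) {
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1) abort_validation("magnification factor must be >= 1")
  px <- if (inherits(slice, "lv_slice")) slice$pixels else slice
  if (factor > 1) {
    Wr <- bicubic_weights(nrow(px), factor)
    Wc <- bicubic_weights(ncol(px), factor)
    px <- Wr %*% px %*% t(Wc)
  }
  if (inherits(slice, "lv_slice")) {
    out <- slice
    out$pixels <- pmax(px, 0) # cubic overshoot cannot produce negative intensity
    out$pixel_spacing <- slice$pixel_spacing / factor
    out
  } else {
    px
  }
}

#' Define a circular or mask region of interest
#'
#' @param center Numeric length-2, (row, col) center in pixels (1-based).
#' @param radius Radius in pixels.
#' @param dim Image dimensions (rows, cols) the ROI must fit inside.
#' @param mask Optional explicit logical matrix overriding the circle.
#' @return An `lv_roi` object.
#' @export
roi_spec <- function(center, radius, dim, mask = NULL) {
  if (is.null(mask)) {
    if (center[1] - radius < 1 || center[1] + radius > dim[1] ||
        center[2] - radius < 1 || center[2] + radius > dim[2]) {
      abort_validation("ROI circle must lie entirely within the image")
    }
    rr <- matrix(seq_len(dim[1]), dim[1], dim[2])
    cc <- matrix(seq_len(dim[2]), dim[1], dim[2], byrow = TRUE)
    mask <- (rr - center[1])^2 + (cc - center[2])^2 <= radius^2
  } else {
    if (!identical(dim(mask), as.integer(dim))) {
      abort_validation("ROI mask dimensions must match the image")
    }
    mask <- mask > 0
  }
  if (sum(mask) < 100) abort_validation("ROI area must be at least 100 pixels")
  structure(list(center = center, radius = radius, mask = mask, dim = dim),
            class = "lv_roi")
}

#' Automatic ROI around the blood pool
#'
#' Circle centred on the centroid of the brightest intensity decile, with
#' radius 1.3 times the equivalent-area radius of that region (clipped to the
#' image). Intended as a starting point; ROIs can always be supplied
#' explicitly.
#'
#' @param pixels Numeric matrix.
#' @return An `lv_roi`.
#' @export
default_roi <- function(pixels) {
  thr <- stats::quantile(pixels, 0.9)
  pts <- which(pixels >= thr, arr.ind = TRUE)
  ctr <- colMeans(pts)
  r <- 1.3 * sqrt(nrow(pts) / pi)
  r <- min(r, ctr[1] - 1, ctr[2] - 1, nrow(pixels) - ctr[1], ncol(pixels) - ctr[2])
  roi_spec(ctr, r, dim(pixels))
}

#' Segmentation parameters
#'
#' @param segmenter `"level-set"` (default) or `"threshold"` (plain Otsu
#'   threshold, useful for testing and noise-free images).
#' @param nu Curvature regularisation weight of the level set.
#' @param dt Explicit time step.
#' @param eps Heaviside/delta smoothing width (in level-set units).
#' @param max_iter Iteration cap.
#' @param tol Convergence threshold on the mean absolute level-set change.
#' @return A parameter record (list).
#' @export
segment_params <- function(segmenter = c("level-set", "threshold"), nu = 0.1,
                           dt = 0.5, eps = 1.5, max_iter = 200, tol = 1e-3) {
  list(segmenter = match.arg(segmenter), nu = nu, dt = dt, eps = eps,
       max_iter = max_iter, tol = tol)
}

# mean-curvature of the level-set function by central differences
curvature_of <- function(phi) {
  px <- (shift_mat(phi, 0, -1, replicate = TRUE) - shift_mat(phi, 0, 1, replicate = TRUE)) / 2
  py <- (shift_mat(phi, -1, 0, replicate = TRUE) - shift_mat(phi, 1, 0, replicate = TRUE)) / 2
  pxx <- shift_mat(phi, 0, -1, replicate = TRUE) - 2 * phi + shift_mat(phi, 0, 1, replicate = TRUE)
  pyy <- shift_mat(phi, -1, 0, replicate = TRUE) - 2 * phi + shift_mat(phi, 1, 0, replicate = TRUE)
  pxy <- (shift_mat(phi, -1, -1, replicate = TRUE) + shift_mat(phi, 1, 1, replicate = TRUE) -
          shift_mat(phi, -1, 1, replicate = TRUE) - shift_mat(phi, 1, -1, replicate = TRUE)) / 4
  (pxx * py^2 - 2 * px * py * pxy + pyy * px^2) / ((px^2 + py^2)^1.5 + 1e-8)
}

# largest 8-connected component of a logical mask. EBImage::bwlabel is
# 4-connected, so labels touching diagonally are merged with a union-find.
largest_cc8 <- function(mask) {
  lab <- matrix(as.integer(EBImage::bwlabel(mask * 1)), nrow(mask), ncol(mask))
  nl <- max(lab)
  if (nl <= 1) return(mask & lab > 0)
  parent <- seq_len(nl)
  find <- function(i) { i <- as.integer(i); while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[rj] <<- ri }
  for (d in list(c(1, 1), c(1, -1))) {
    sh <- shift_mat(lab, d[1], d[2])
    pr <- cbind(lab[lab > 0 & sh > 0 & lab != sh], sh[lab > 0 & sh > 0 & lab != sh])
    if (nrow(pr)) apply(unique(pr), 1, function(p) union(p[1], p[2]))
  }
  root <- vapply(seq_len(nl), find, integer(1))
  merged <- matrix(0L, nrow(lab), ncol(lab))
  merged[lab > 0] <- root[lab[lab > 0]]
  sizes <- tabulate(merged[merged > 0], nbins = nl)
  merged == which.max(sizes)
}

#' Segment the blood pool of a magnified slice
#'
#' Two-phase region-based level-set evolution (piecewise-constant model with
#' curvature regularisation), initialised from an Otsu threshold of the ROI
#' and restricted to it. The bright phase is taken as blood pool; dark
#' trabecular fingers and papillary muscles fall in the myocardial phase. The
#' final mask is the largest 8-connected bright component, so inter-trabecular
#' recesses contiguous with the cavity are retained and isolated bright specks
#' are dropped. Deterministic for fixed inputs.
#'
#' @param slice `lv_slice` or numeric matrix (already magnified).
#' @param roi `lv_roi`, or `NULL` for [default_roi()].
#' @param params [segment_params()] record.
#' @return An `lv_pool` object: `mask` (logical), `roi`, `params_used`,
#'   `converged` flag.
#' @export
segment_blood_pool <- function(slice, roi = NULL, params = segment_params()) {
  px <- if (inherits(slice, "lv_slice")) slice$pixels else slice
  if (is.null(roi)) roi <- default_roi(px)
  rm_ <- roi$mask
  vals <- px[rm_]
  rng <- range(vals)
  if (diff(rng) == 0) abort_segmentation("no contrast: zero intensity variance in ROI")
  I <- (px - rng[1]) / diff(rng)
  I[I < 0] <- 0; I[I > 1] <- 1
  thr <- EBImage::otsu(matrix(I[rm_], nrow = 1), range = c(0, 1))
  init <- I >= thr & rm_

  converged <- TRUE
  if (params$segmenter == "threshold") {
    mask <- init
  } else {
    # evolve on the ROI bounding box only; phi is clamped to [-1, 1] so the
    # interior saturates and the convergence measure tracks the moving front
    rws <- range(which(rowSums(rm_) > 0)); cls <- range(which(colSums(rm_) > 0))
    rs <- max(1, rws[1] - 2):min(nrow(I), rws[2] + 2)
    cs <- max(1, cls[1] - 2):min(ncol(I), cls[2] + 2)
    Ic <- I[rs, cs]; rmc <- rm_[rs, cs]
    phi <- pmin(pmax(2 * (Ic - thr), -1), 1)
    phi[!rmc] <- -1
    for (it in seq_len(params$max_iter)) {
      inside <- phi > 0 & rmc
      c1 <- mean(Ic[inside]); c2 <- mean(Ic[rmc & !inside])
      if (!is.finite(c1)) c1 <- 1
      if (!is.finite(c2)) c2 <- 0
      kap <- curvature_of(phi)
      delta <- params$eps / (pi * (params$eps^2 + phi^2))
      force <- params$nu * kap - (Ic - c1)^2 + (Ic - c2)^2
      phi_new <- pmin(pmax(phi + params$dt * delta * force, -1), 1)
      phi_new[!rmc] <- -1
      dphi <- phi_new - phi
      phi <- phi_new
      if (mean(abs(dphi[rmc])) < params$tol) break
    }
    if (it == params$max_iter) {
      converged <- FALSE
      warning("level set did not converge within iteration cap", call. = FALSE)
    }
    # orient so that the pool is the brighter phase
    m1 <- mean(Ic[phi > 0 & rmc]); m2 <- mean(Ic[phi <= 0 & rmc])
    maskc <- if (is.finite(m1) && is.finite(m2) && m2 > m1) phi <= 0 & rmc else phi > 0 & rmc
    mask <- matrix(FALSE, nrow(I), ncol(I))
    mask[rs, cs] <- maskc
  }
  if (!any(mask)) abort_segmentation("segmentation produced an empty pool mask")
  mask <- largest_cc8(mask)
  structure(list(mask = mask, roi = roi, params_used = params,
                 converged = converged), class = "lv_pool")
}

#' Extract the endocardial border with a Sobel filter
#'
#' The Sobel gradient magnitude of the binary pool mask is computed; pool
#' pixels with a strictly positive response form the border (on a binary
#' input the response is quantised, so the zero threshold is exact). The
#' response is restricted to the pool side so the border is the
#' one-pixel endocardial contour, including its trabecular and
#' papillary-muscle indentations, rather than a two-sided gradient band.
#' Pool pixels touching background whose centred-difference response cancels
#' by symmetry (isolated pixels, one-pixel-wide strands) are kept as border.
#'
#' @param pool An `lv_pool`, or a logical matrix.
#' @return An `lv_edges` object with logical matrix `edges`.
#' @export
detect_edges <- function(pool) {
  mask <- if (inherits(pool, "lv_pool")) pool$mask else pool > 0
  roi <- if (inherits(pool, "lv_pool")) pool$roi else NULL
  if (!any(mask)) abort_validation("pool mask is empty")
  cover <- if (!is.null(roi)) roi$mask else TRUE
  if (all(mask[cover])) abort_validation("pool mask covers the full ROI: no boundary inside")
  m <- mask * 1
  gx <- (shift_mat(m, -1, 1) + 2 * shift_mat(m, 0, 1) + shift_mat(m, 1, 1)) -
        (shift_mat(m, -1, -1) + 2 * shift_mat(m, 0, -1) + shift_mat(m, 1, -1))
  gy <- (shift_mat(m, 1, -1) + 2 * shift_mat(m, 1, 0) + shift_mat(m, 1, 1)) -
        (shift_mat(m, -1, -1) + 2 * shift_mat(m, -1, 0) + shift_mat(m, -1, 1))
  bg <- 1 - m
  touches_bg <- (shift_mat(bg, -1, -1, pad = 1) + shift_mat(bg, -1, 0, pad = 1) +
                 shift_mat(bg, -1, 1, pad = 1) + shift_mat(bg, 0, -1, pad = 1) +
                 shift_mat(bg, 0, 1, pad = 1) + shift_mat(bg, 1, -1, pad = 1) +
                 shift_mat(bg, 1, 0, pad = 1) + shift_mat(bg, 1, 1, pad = 1)) > 0
  edges <- mask & ((gx^2 + gy^2) > 0 | touches_bg)
  structure(list(edges = edges, source = if (inherits(pool, "lv_pool")) pool else NULL),
            class = "lv_edges")
}
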