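# Synthetic data generators: fractals with analytically known dimension,
# parametric bSSFP-like short-axis LV slices and stacks with ground-truth
# masks, cohort tables with a linear age trend and sex offset, and rating
# matrices for agreement studies. All generators are pure functions of their
# arguments and seed.

#' Rasterize a fractal with analytically known dimension
#'
#' Supported kinds: `line` (dimension 1), `koch` (the triadic Koch curve,
#' log 4 / log 3), `quadratic-koch` (the eight-segment quadratic Koch /
#' Minkowski curve, log 8 / log 4 = 1.5) and `sierpinski-triangle`
#' (log 3 / log 2). The grid-aligned kinds (line, quadratic-koch,
#' sierpinski-triangle) rasterize exactly; the Koch curve is drawn by dense
#' sampling of its segments.
#'
#' @param kind Fractal kind (see above).
#' @param canvas Canvas side in pixels (>= 256; default 1024).
#' @param depth Recursion depth; defaults: koch 6, quadratic-koch 5,
#'   sierpinski-triangle 7 (ignored for line).
#' @return List with logical matrix `image`, `analytic_fd`, `kind`, `depth`,
#'   `canvas`.
#' @export
make_fractal <- function(kind = c("line", "koch", "quadratic-koch", "sierpinski-triangle"),
                         canvas = 1024L, depth = NULL) {
  kind <- match.arg(kind)
  canvas <- as.integer(canvas)
  if (canvas < 256) abort_validation("canvas must be at least 256 pixels")
  if (is.null(depth)) {
    depth <- switch(kind, line = 0L, koch = 6L, `quadratic-koch` = 5L,
                    `sierpinski-triangle` = 7L)
  }
  img <- switch(kind,
    "line" = {
      m <- matrix(FALSE, canvas, canvas)
      m[canvas %/% 2, ] <- TRUE
      m
    },
    "koch" = raster_segments(koch_segments(canvas, depth), canvas),
    "quadratic-koch" = raster_segments(quad_koch_segments(canvas, depth), canvas),
    "sierpinski-triangle" = sierpinski_raster(canvas, depth)
  )
  fd <- switch(kind, line = 1, koch = log(4) / log(3),
               `quadratic-koch` = 1.5, `sierpinski-triangle` = log(3) / log(2))
  list(image = img, analytic_fd = fd, kind = kind, depth = depth, canvas = canvas)
}

# Koch curve: repeatedly replace each segment by the 4-segment generator.
koch_segments <- function(canvas, depth) {
  L <- canvas - 1
  p <- complex(real = c(0, L), imaginary = c(0, 0))
  rot <- exp(1i * pi / 3)
  for (d in seq_len(depth)) {
    a <- p[-length(p)]; b <- p[-1]
    v <- (b - a) / 3
    p1 <- a + v
    p2 <- p1 + v * rot
    p3 <- a + 2 * v
    p <- as.vector(rbind(a, p1, p2, p3))
    p <- c(p, b[length(b)])
  }
  # place baseline low on the canvas; curve bulges upward (negative imag)
  cbind(x = Re(p), y = 0.75 * canvas + Im(p) * -1)
}

# Quadratic (Minkowski) Koch: 8-segment generator, all moves axis-aligned.
quad_koch_segments <- function(canvas, depth) {
  L <- canvas - 1
  # turtle turns for one generator application: F L F R F R F F L F L F R F
  # encoded as the cumulative direction pattern of the 8 sub-segments
  dirs <- c(0, 1, 0, -1, -1, 0, 1, 0) # relative heading of each sub-segment
  p <- complex(real = c(0, L), imaginary = c(0, 0))
  for (d in seq_len(depth)) {
    a <- p[-length(p)]; b <- p[-1]
    v <- (b - a) / 4
    out <- vector("list", length(a))
    for (j in seq_along(a)) {
      pt <- a[j]
      pts <- pt
      for (s in dirs) {
        pt <- pt + v[j] * 1i^s
        pts <- c(pts, pt)
      }
      out[[j]] <- pts[-length(pts)]
    }
    p <- c(unlist(out), b[length(b)])
  }
  cbind(x = Re(p), y = canvas / 2 + Im(p))
}

# rasterize a polyline by dense sampling along each segment
raster_segments <- function(pts, canvas) {
  m <- matrix(FALSE, canvas, canvas)
  x0 <- pts[-nrow(pts), 1]; y0 <- pts[-nrow(pts), 2]
  x1 <- pts[-1, 1]; y1 <- pts[-1, 2]
  len <- sqrt((x1 - x0)^2 + (y1 - y0)^2)
  for (j in seq_along(len)) {
    nstep <- max(2L, ceiling(len[j] / 0.35) + 1L)
    t <- seq(0, 1, length.out = nstep)
    xs <- round(x0[j] + t * (x1[j] - x0[j])) + 1L
    ys <- round(y0[j] + t * (y1[j] - y0[j])) + 1L
    ok <- xs >= 1 & xs <= canvas & ys >= 1 & ys <= canvas
    m[cbind(ys[ok], xs[ok])] <- TRUE
  }
  m
}

# Sierpinski right triangle: cells (i, j) with bitwAnd(i, j) == 0 at the
# chosen depth, each cell filled with the similar right triangle u + v < cell.
sierpinski_raster <- function(canvas, depth) {
  ncell <- 2^depth
  cell <- canvas %/% ncell
  if (cell < 1) abort_validation("depth too large for canvas")
  idx <- 0:(ncell - 1)
  keep <- outer(idx, idx, function(i, j) bitwAnd(i, j) == 0)
  cells <- which(keep, arr.ind = TRUE) - 1L
  m <- matrix(FALSE, canvas, canvas)
  uv <- which(outer(0:(cell - 1), 0:(cell - 1), `+`) < cell, arr.ind = TRUE) - 1L
  for (q in seq_len(nrow(cells))) {
    r <- cells[q, 1] * cell + uv[, 1] + 1L
    c <- cells[q, 2] * cell + uv[, 2] + 1L
    m[cbind(r, c)] <- TRUE
  }
  m
}

#' Specification of a parametric LV short-axis phantom
#'
#' Emulates a bSSFP end-diastolic short-axis slice stack: bright circular
#' blood pool inside a darker myocardial annulus, with dark trabecular
#' fingers and papillary bodies protruding into the pool. The endocardial
#' radius tapers from base to apex and the trabeculation complexity follows a
#' raised-cosine axial profile peaking mid-ventricle.
#'
#' @param canvas Slice side in pixels (default 128).
#' @param n_slices Number of slices, base to apex (>= 5; default 10).
#' @param complexity Trabeculation complexity c in `[0, 1]`; maps linearly to
#'   the number of fingers (up to 24) and their depth (up to 0.35 of the
#'   endocardial radius).
#' @param r_epi,r_endo Epicardial / basal endocardial radius as fractions of
#'   the canvas (defaults 0.42 / 0.30).
#' @param intensities Named vector `c(pool=, myo=, bg=)` in arbitrary units.
#' @param noise_sd Additive Gaussian noise SD (default 5).
#' @param bias_amp Amplitude of the multiplicative low-order polynomial bias
#'   field (default 0.1, i.e. 10%).
#' @param taper Fractional reduction of the endocardial radius at the apex
#'   (default 0.55).
#' @param peak Axial position (0 base, 1 apex) of maximal complexity
#'   (default 0.6).
#' @param n_frames Cine frames per slice (1 = end-diastole only).
#' @param pixel_spacing In-plane spacing in mm (default 1.5).
#' @param seed Generator seed.
#' @return A spec list for [make_lv_stack()].
#' @export
lv_phantom_spec <- function(canvas = 128L, n_slices = 10L, complexity = 0.5,
                            r_epi = 0.42, r_endo = 0.30,
                            intensities = c(pool = 400, myo = 120, bg = 40),
                            noise_sd = 5, bias_amp = 0.1, taper = 0.55,
                            peak = 0.6, n_frames = 1L, pixel_spacing = 1.5,
                            seed = 1L) {
  if (r_epi >= 0.5 || r_endo >= r_epi) {
    abort_validation("radii must satisfy r_endo < r_epi < 0.5 of the canvas")
  }
  if (n_slices < 5) abort_validation("phantom stacks need at least 5 slices")
  if (complexity < 0 || complexity > 1) abort_validation("complexity must be in [0, 1]")
  if (noise_sd < 0) abort_validation("noise_sd must be non-negative")
  as.list(environment())
}

# axial complexity profile: raised cosine peaking at `peak`, floor 0.3
axial_profile <- function(z, peak) {
  w <- 0.5 * (1 + cos(pi * pmin(abs(z - peak) / 0.6, 1)))
  0.3 + 0.7 * w
}

# per-slice boundary geometry: finger angles/amplitudes/widths, papillaries
slice_geometry <- function(spec, z) {
  c_eff <- spec$complexity * axial_profile(z, spec$peak)
  r_end <- spec$r_endo * spec$canvas * (1 - spec$taper * z^1.5)
  K <- round(24 * c_eff)
  geom <- list(z = z, complexity = c_eff, r_endo = r_end,
               r_epi = spec$r_epi * spec$canvas)
  if (K > 0) {
    ang <- sort((seq_len(K) - 1) * 2 * pi / K + stats::runif(K, 0, 0.6 * pi / K))
    # finger width scales with the angular spacing so that fingers stay
    # distinct (non-overlapping) as their number grows
    geom$fingers <- data.frame(
      angle = ang,
      amp = 0.35 * c_eff * r_end * stats::runif(K, 0.6, 1),
      width = stats::runif(K, 0.12, 0.28) * 2 * pi / max(K, 6)
    )
  } else {
    geom$fingers <- data.frame(angle = numeric(0), amp = numeric(0),
                               width = numeric(0))
  }
  if (c_eff > 0.15) {
    # two papillary bodies attached to the wall
    geom$papillary <- data.frame(
      angle = c(110, 250) * pi / 180 + stats::runif(2, -0.2, 0.2),
      radius = 0.16 * r_end * c(1, 0.85)
    )
  } else {
    geom$papillary <- data.frame(angle = numeric(0), radius = numeric(0))
  }
  geom
}

# endocardial boundary radius r(theta) with smooth finger indentations
boundary_radius <- function(theta, geom) {
  r <- rep(geom$r_endo, length(theta))
  fg <- geom$fingers
  for (j in seq_len(nrow(fg))) {
    d <- atan2(sin(theta - fg$angle[j]), cos(theta - fg$angle[j]))
    r <- r - fg$amp[j] * exp(-0.5 * (d / fg$width[j])^2)
  }
  r
}

# render one slice's truth masks at an integer scale factor
render_truth <- function(spec, geom, scale = 1L) {
  n <- spec$canvas * scale
  ctr <- (n + 1) / 2
  rr <- matrix(seq_len(n), n, n) - ctr
  cc <- matrix(seq_len(n), n, n, byrow = TRUE) - ctr
  rho <- sqrt(rr^2 + cc^2) / scale
  theta <- atan2(rr, cc)
  rb <- boundary_radius(theta, geom)
  pool <- rho <= rb
  myo <- rho <= geom$r_epi & !pool
  pp <- geom$papillary
  for (j in seq_len(nrow(pp))) {
    pr <- rb_at <- boundary_radius(pp$angle[j], geom)
    py <- pr * sin(pp$angle[j]); px <- pr * cos(pp$angle[j])
    inpap <- (rr / scale - py)^2 + (cc / scale - px)^2 <= pp$radius[j]^2
    myo <- myo | (inpap & rho <= geom$r_epi + pp$radius[j])
    pool <- pool & !inpap
  }
  list(pool = pool, myo = myo)
}

#' Generate a synthetic LV short-axis stack with ground truth
#'
#' @param spec An [lv_phantom_spec()].
#' @return List with `stack` (an `lv_stack`, or `lv_cine` when
#'   `spec$n_frames > 1`), `truth` (per-slice list: `pool` and `myo` logical
#'   masks at native resolution, `complexity`, and the boundary `geometry`
#'   for re-rendering at other scales) and `spec`.
#' @export
make_lv_stack <- function(spec = lv_phantom_spec()) {
  with_seed(spec$seed, {
    n <- spec$canvas
    zs <- seq(0, 1, length.out = spec$n_slices)
    geoms <- lapply(zs, function(z) slice_geometry(spec, z))
    # one shared low-order polynomial bias field
    u <- stats::runif(3, -1, 1)
    xn <- (matrix(seq_len(n), n, n, byrow = TRUE) / n) - 0.5
    yn <- (matrix(seq_len(n), n, n) / n) - 0.5
    bias_raw <- u[1] * xn + u[2] * yn + u[3] * xn * yn
    bias <- 1 + spec$bias_amp * bias_raw / max(abs(bias_raw), 1e-9)

    slices <- vector("list", spec$n_slices)
    truth <- vector("list", spec$n_slices)
    for (i in seq_len(spec$n_slices)) {
      g <- geoms[[i]]
      tr <- render_truth(spec, g, scale = 1L)
      img <- matrix(spec$intensities[["bg"]], n, n)
      img[tr$myo] <- spec$intensities[["myo"]]
      img[tr$pool] <- spec$intensities[["pool"]]
      img <- img * bias
      if (spec$noise_sd > 0) img <- img + stats::rnorm(n * n, 0, spec$noise_sd)
      img <- pmax(img, 0)
      if (spec$n_frames > 1) {
        frames <- array(0, dim = c(n, n, spec$n_frames))
        for (t in seq_len(spec$n_frames)) {
          gt <- g
          shrink <- 1 - 0.25 * sin(pi * (t - 1) / spec$n_frames)
          gt$r_endo <- g$r_endo * shrink
          if (nrow(gt$fingers)) gt$fingers$amp <- g$fingers$amp * shrink
          trt <- render_truth(spec, gt, scale = 1L)
          f <- matrix(spec$intensities[["bg"]], n, n)
          f[trt$myo] <- spec$intensities[["myo"]]
          f[trt$pool] <- spec$intensities[["pool"]]
          f <- f * bias
          if (spec$noise_sd > 0) f <- f + stats::rnorm(n * n, 0, spec$noise_sd)
          frames[, , t] <- pmax(f, 0)
        }
        slices[[i]] <- frames
      } else {
        slices[[i]] <- slice_image(img, rep(spec$pixel_spacing, 2),
                                   slice_location = 10 * i, slice_index = i - 1L)
      }
      truth[[i]] <- list(pool = tr$pool, myo = tr$myo,
                         complexity = g$complexity, geometry = g)
    }
    stack <- if (spec$n_frames > 1) {
      structure(list(frames = slices, pixel_spacing = rep(spec$pixel_spacing, 2),
                     subject_id = sprintf("phantom-seed%d", spec$seed)),
                class = "lv_cine")
    } else {
      lv_stack(slices, sprintf("phantom-seed%d", spec$seed))
    }
    list(stack = stack, truth = truth, spec = spec)
  })
}

#' Render one phantom slice's ground-truth pool mask at a magnified scale
#'
#' @param phantom Result of [make_lv_stack()].
#' @param slice 1-based slice position.
#' @param scale Integer magnification factor.
#' @return Logical pool mask at `canvas * scale` resolution.
#' @export
phantom_truth_mask <- function(phantom, slice, scale = 1L) {
  g <- phantom$truth[[slice]]$geometry
  render_truth(phantom$spec, g, scale = as.integer(scale))$pool
}

#' User-style ROI for a phantom slice
#'
#' Circle centred on the phantom's ventricle covering the epicardium with a
#' 10% margin, mimicking the manual region-of-interest selection step of the
#' analysis workflow.
#'
#' @param phantom Result of [make_lv_stack()].
#' @param scale Integer magnification factor the ROI coordinates refer to.
#' @return An `lv_roi`.
#' @export
phantom_roi <- function(phantom, scale = 1L) {
  n <- phantom$spec$canvas * scale
  ctr <- rep((n + 1) / 2, 2)
  r <- min(1.1 * phantom$spec$r_epi * n, (n - 1) / 2 - 1)
  roi_spec(ctr, r, c(n, n))
}

#' Per-slice ROI set for [analyze_stack()] on a phantom
#'
#' @param phantom Result of [make_lv_stack()].
#' @param scale Magnification factor used by the analysis (default 4).
#' @return List of identical `lv_roi` objects, one per slice.
#' @export
phantom_roi_set <- function(phantom, scale = 4L) {
  roi <- phantom_roi(phantom, scale)
  rep(list(roi), phantom$spec$n_slices)
}

#' Simulate a cohort table with a linear age trend and sex offset
#'
#' Defaults emulate a healthy adult cohort: global FD rising slowly with age,
#' higher in males, with Gaussian residuals.
#'
#' @param n_per_sex Records per sex (default 500).
#' @param age_range Uniform age range in years (default 20-69).
#' @param slope Common age slope (default 4e-4 per year).
#' @param intercepts Named vector `c(female=, male=)` (defaults 1.177 /
#'   1.198, i.e. a male-female gap of 0.021).
#' @param resid_sd Residual SD (default 0.029; 0 gives exact lines).
#' @param seed Seed.
#' @param metric Metric name attached to the table.
#' @return Data frame `subject_id, age, sex, value`.
#' @export
simulate_cohort <- function(n_per_sex = 500, age_range = c(20, 69),
                            slope = 4e-4,
                            intercepts = c(female = 1.177, male = 1.198),
                            resid_sd = 0.029, seed = 1, metric = "global_fd") {
  if (n_per_sex < 10) abort_validation("need at least 10 records per sex")
  if (resid_sd < 0) abort_validation("resid_sd must be non-negative")
  with_seed(seed, {
    out <- do.call(rbind, lapply(names(intercepts), function(sx) {
      age <- stats::runif(n_per_sex, age_range[1], age_range[2])
      val <- intercepts[[sx]] + slope * age +
        if (resid_sd > 0) stats::rnorm(n_per_sex, 0, resid_sd) else 0
      data.frame(subject_id = paste0(sx, "-", seq_len(n_per_sex)),
                 age = age, sex = sx, value = val)
    }))
    attr(out, "metric") <- metric
    out
  })
}

#' Simulate a rating matrix with known variance components
#'
#' `value[i, j] = subject_i + shift_j + noise`, with subject effects
#' `N(0, subject_sd^2)` and noise `N(0, error_sd^2)`; the generating
#' intraclass correlation is `subject_sd^2 / (subject_sd^2 + error_sd^2)`
#' when shifts are zero.
#'
#' @param n Subjects (>= 5; default 20). @param k Raters (>= 2; default 2).
#' @param subject_sd Between-subject SD. @param error_sd Residual SD.
#' @param rater_shifts Length-`k` systematic rater offsets (default zero).
#' @param grand_mean Overall mean (default 1.2, an FD-like scale).
#' @param seed Seed.
#' @return An `lv_ratings` object.
#' @export
simulate_raters <- function(n = 20, k = 2, subject_sd = sqrt(0.9),
                            error_sd = sqrt(0.1), rater_shifts = rep(0, k),
                            grand_mean = 1.2, seed = 1) {
  if (n < 5 || k < 2) abort_validation("need n >= 5 subjects and k >= 2 raters")
  if (subject_sd < 0 || error_sd < 0) abort_validation("SDs must be non-negative")
  if (length(rater_shifts) != k) abort_validation("rater_shifts must have length k")
  with_seed(seed, {
    subj <- stats::rnorm(n, 0, subject_sd)
    m <- outer(subj, rater_shifts, `+`) + grand_mean +
      matrix(stats::rnorm(n * k, 0, error_sd), n, k)
    rating_matrix(m, metric = "simulated")
  })
}
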