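# Independent oracles used across tests: these deliberately re-derive
# quantities by the dumbest correct route (explicit loops, closed forms) so
# they share no code with the implementation under test.

# brute-force box count: loop over every grid box and inspect the submatrix
brute_box_count <- function(edges, sizes) {
  pts <- which(edges, arr.ind = TRUE)
  r0 <- min(pts[, 1]); c0 <- min(pts[, 2])
  nr <- nrow(edges); nc <- ncol(edges)
  vapply(sizes, function(s) {
    n <- 0L
    for (br in seq(r0, nr, by = s)) {
      for (bc in seq(c0, nc, by = s)) {
        sub <- edges[br:min(br + s - 1, nr), bc:min(bc + s - 1, nc), drop = FALSE]
        if (any(sub)) n <- n + 1L
      }
    }
    as.numeric(n)
  }, numeric(1))
}

# brute-force two-way ANOVA mean squares and ICC(2,1) with F-based CI,
# written from the textbook sums of squares with explicit loops
brute_icc21 <- function(m, alpha = 0.05) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  row_means <- numeric(n); col_means <- numeric(k)
  for (i in seq_len(n)) row_means[i] <- mean(m[i, ])
  for (j in seq_len(k)) col_means[j] <- mean(m[, j])
  ssr <- 0; ssc <- 0; sse <- 0
  for (i in seq_len(n)) ssr <- ssr + k * (row_means[i] - grand)^2
  for (j in seq_len(k)) ssc <- ssc + n * (col_means[j] - grand)^2
  for (i in seq_len(n)) for (j in seq_len(k)) {
    sse <- sse + (m[i, j] - row_means[i] - col_means[j] + grand)^2
  }
  msr <- ssr / (n - 1); msc <- ssc / (k - 1); mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  fl <- qf(1 - alpha / 2, n - 1, v)
  fu <- qf(1 - alpha / 2, v, n - 1)
  lo <- n * (msr - fl * mse) / (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
  hi <- n * (fu * msr - mse) / (k * msc + (k * n - k - n) * mse + n * fu * msr)
  list(icc = icc, ci_low = lo, ci_high = hi)
}

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# small disk phantom image: bright pool on darker myocardium ring on background
disk_image <- function(n = 96, r_pool = 28, r_myo = 40, pool = 400, myo = 120,
                       bg = 40, noise_sd = 0, seed = 1) {
  ctr <- (n + 1) / 2
  rr <- matrix(seq_len(n), n, n) - ctr
  cc <- matrix(seq_len(n), n, n, byrow = TRUE) - ctr
  rho <- sqrt(rr^2 + cc^2)
  img <- matrix(bg, n, n)
  img[rho <= r_myo] <- myo
  img[rho <= r_pool] <- pool
  if (noise_sd > 0) {
    set.seed(seed)
    img <- pmax(img + rnorm(n * n, 0, noise_sd), 0)
  }
  list(img = img, pool = rho <= r_pool)
}
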