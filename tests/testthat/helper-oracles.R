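# Independent oracles and small fixture builders shared across tests.

# Exhaustive maximum-probability path search over all 2^L state sequences
# of the two-state wheel-marker HMM (0 = bottom, 1 = top).  Returns the
# best log-probability and all paths attaining it.
brute_force_viterbi <- function(p_top, p_stay = 0.98, init = c(0.5, 0.5)) {
  L <- length(p_top)
  eps <- 1e-12
  p <- pmin(pmax(p_top, eps), 1 - eps)
  paths <- as.matrix(expand.grid(rep(list(0:1), L)))[, seq_len(L), drop = FALSE]
  em <- matrix(0, nrow(paths), L)
  for (j in seq_len(L)) {
    em[, j] <- ifelse(paths[, j] == 1, log(p[j]), log(1 - p[j]))
  }
  lp <- log(init[paths[, 1] + 1]) + rowSums(em)
  if (L > 1) {
    stay <- paths[, -1, drop = FALSE] == paths[, -L, drop = FALSE]
    lp <- lp + rowSums(ifelse(stay, log(p_stay), log(1 - p_stay)))
  }
  best <- max(lp)
  list(logp = best, paths = paths[lp >= best - 1e-9, , drop = FALSE])
}

# log-probability of one specific state path under the same HMM
path_log_prob <- function(states01, p_top, p_stay = 0.98, init = c(0.5, 0.5)) {
  eps <- 1e-12
  p <- pmin(pmax(p_top, eps), 1 - eps)
  em <- ifelse(states01 == 1, log(p), log(1 - p))
  lp <- log(init[states01[1] + 1]) + sum(em)
  L <- length(states01)
  if (L > 1) {
    stay <- states01[-1] == states01[-L]
    lp <- lp + sum(ifelse(stay, log(p_stay), log(1 - p_stay)))
  }
  lp
}

# Weighted least squares through the explicit normal equations
wls_oracle <- function(x, y, w) {
  X <- cbind(1, x)
  A <- t(X) %*% (w * X)
  b <- t(X) %*% (w * y)
  beta <- solve(A, b)
  list(intercept = beta[1], slope = beta[2])
}

# Per-pixel 3x3 Sobel convolution (loops; no vectorisation tricks)
sobel_oracle <- function(img, mask) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  ky <- t(kx)
  nr <- nrow(img); nc <- ncol(img)
  vals <- c()
  for (i in 2:(nr - 1)) {
    for (j in 2:(nc - 1)) {
      if (!mask[i, j]) next
      gx <- 0; gy <- 0
      for (di in -1:1) for (dj in -1:1) {
        gx <- gx + kx[di + 2, dj + 2] * img[i + di, j + dj]
        gy <- gy + ky[di + 2, dj + 2] * img[i + di, j + dj]
      }
      vals <- c(vals, sqrt(gx^2 + gy^2))
    }
  }
  mean(vals)
}

# type-7 percentile by explicit sort-and-interpolate
percentile_oracle <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# fixture: a 2-full-day measurement period starting at UTC midnight
make_period <- function(n_days = 2, start = "2026-01-06",
                        mouse_id = "m1") {
  t0 <- as.POSIXct(start, tz = "UTC")
  data.frame(mouse_id = mouse_id, cage_position = "pos1",
             first_full_day = as.Date(start), n_full_days = n_days,
             start = t0, end = t0 + n_days * 86400,
             stringsAsFactors = FALSE)
}

# fixture: a track channel from explicit positions
make_track <- function(times, x, y, conf = rep(1, length(times))) {
  channel("track", data.frame(time = times, x_px = x, y_px = y,
                              confidence = conf))
}

utc <- function(s) as.POSIXct(s, tz = "UTC")
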