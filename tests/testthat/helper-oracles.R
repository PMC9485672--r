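# Independent brute-force reference implementations used as oracles.
# These deliberately use naive loops / base primitives, not the package's
# computational paths.

# per-pixel motion energy count, explicit loops
oracle_motion_energy <- function(frames_array, mask, threshold) {
  n <- dim(frames_array)[3L]
  out <- numeric(n - 1L)
  for (t in 2:n) {
    cnt <- 0L
    for (i in seq_len(dim(frames_array)[1L])) {
      for (j in seq_len(dim(frames_array)[2L])) {
        if (mask[i, j] &&
            abs(frames_array[i, j, t] - frames_array[i, j, t - 1L]) > threshold)
          cnt <- cnt + 1L
      }
    }
    out[t - 1L] <- cnt
  }
  out
}

# windowed lagged Pearson correlations, triple loop with stats::cor
oracle_wlcc <- function(x, y, W, L) {
  N <- length(x)
  lags <- -L:L
  n_win <- N %/% W
  r <- matrix(NA_real_, n_win, length(lags))
  for (w in seq_len(n_win)) {
    s <- (w - 1L) * W + 1L
    for (j in seq_along(lags)) {
      l <- lags[j]
      a <- s + max(-l, 0L)
      b <- s + max(l, 0L)
      if (max(a, b) + W - 1L > N) next
      xv <- x[a:(a + W - 1L)]
      yv <- y[b:(b + W - 1L)]
      if (sd(xv) == 0 || sd(yv) == 0) r[w, j] <- 0
      else r[w, j] <- cor(xv, yv)
    }
  }
  r
}

# centered moving average by direct summation, shrinking at edges
oracle_moving_average <- function(x, width) {
  if (width <= 1L) return(x)
  h <- (width - 1L) %/% 2L
  hi <- width - 1L - h
  vapply(seq_along(x), function(t) {
    idx <- max(1L, t - h):min(length(x), t + hi)
    mean(x[idx])
  }, numeric(1L))
}

# exact two-sided signed-rank p by exhaustive sign-flip enumeration:
# proportion of the 2^n sign assignments whose smaller rank sum is <= W_obs
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n <= 16)
  rk <- rank(abs(d))
  w_obs <- min(sum(rk[d > 0]), sum(rk[d < 0]))
  total <- sum(rk)
  hits <- 0L
  for (mask in 0:(2^n - 1)) {
    signs <- bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L) == 1L
    tp <- sum(rk[signs])
    if (min(tp, total - tp) <= w_obs) hits <- hits + 1L
  }
  hits / 2^n
}

# simple regression by explicit normal equations
oracle_ols <- function(y, x) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% beta
  sst <- sum((y - mean(y))^2)
  ssr <- sum(res^2)
  n <- length(y)
  sigma2 <- ssr / (n - 2)
  se_b <- sqrt(sigma2 * solve(t(X) %*% X)[2, 2])
  list(slope = beta[2], intercept = beta[1],
       r_squared = 1 - ssr / sst,
       t_slope = beta[2] / se_b,
       f_stat = (sst - ssr) / sigma2)
}

# descriptives from textbook formulas
oracle_describe <- function(v) {
  n <- length(v)
  m <- sum(v) / n
  s <- sort(v)
  med <- if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
  list(mean = m, sd = sqrt(sum((v - m)^2) / (n - 1)), median = med)
}
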