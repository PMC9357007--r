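## Independent oracles used across the suite. These deliberately use the
## plainest possible formulations (explicit loops, closed forms) and never
## call the package code paths they check.

## absolute axial (period-180) angular difference in degrees
axial_diff <- function(a, b) {
  d <- (a - b + 90) %% 180 - 90
  abs(d)
}

## brute-force grey-level co-occurrence: enumerate every pixel pair at the
## offset and apply the correlation formula term by term
oracle_glcm_counts <- function(q, dy, dx, levels) {
  counts <- matrix(0L, levels, levels)
  for (r in seq_len(nrow(q))) for (cc in seq_len(ncol(q))) {
    r2 <- r + dy; c2 <- cc + dx
    if (r2 >= 1 && r2 <= nrow(q) && c2 >= 1 && c2 <= ncol(q)) {
      i <- q[r, cc] + 1L; j <- q[r2, c2] + 1L
      counts[i, j] <- counts[i, j] + 1L
    }
  }
  counts
}

oracle_haralick_correlation <- function(counts) {
  p <- counts / sum(counts)
  lev <- seq_len(nrow(p)) - 1
  mu_i <- 0; mu_j <- 0
  for (i in seq_along(lev)) for (j in seq_along(lev)) {
    mu_i <- mu_i + lev[i] * p[i, j]
    mu_j <- mu_j + lev[j] * p[i, j]
  }
  v_i <- 0; v_j <- 0; cv <- 0
  for (i in seq_along(lev)) for (j in seq_along(lev)) {
    v_i <- v_i + (lev[i] - mu_i)^2 * p[i, j]
    v_j <- v_j + (lev[j] - mu_j)^2 * p[i, j]
    cv <- cv + (lev[i] - mu_i) * (lev[j] - mu_j) * p[i, j]
  }
  if (v_i <= 0 || v_j <= 0) return(NA_real_)
  cv / sqrt(v_i * v_j)
}

## Benjamini-Hochberg step-up, written directly from the definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (k in m:1) {
    prev <- min(prev, m * p[o[k]] / k)
    adj[o[k]] <- prev
  }
  adj
}

## two-sided Fisher exact p by hypergeometric enumeration over the table
## family with fixed margins
oracle_fisher_p <- function(a, b, c_, d) {
  m <- a + b; n <- c_ + d; k <- a + c_
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

## full width at half maximum of a sampled profile by linear interpolation
## of the half-max crossings around the global maximum
oracle_fwhm <- function(x, y) {
  i <- which.max(y)
  half <- (max(y) + min(y)) / 2
  li <- i; while (li > 1 && y[li - 1] > half) li <- li - 1
  ri <- i; while (ri < length(y) && y[ri + 1] > half) ri <- ri + 1
  xl <- x[li - 1] + (x[li] - x[li - 1]) * (half - y[li - 1]) / (y[li] - y[li - 1])
  xr <- x[ri] + (x[ri + 1] - x[ri]) * (y[ri] - half) / (y[ri] - y[ri + 1])
  xr - xl
}

## axial von Mises density over angle bins (degrees on (-90, 90]), for
## chi-square goodness of fit against generated ground-truth angles
axial_vm_bin_probs <- function(breaks_deg, mu_deg, kappa) {
  dens <- function(th_deg) {
    psi <- 2 * (th_deg - mu_deg) * pi / 180
    exp(kappa * cos(psi)) / (pi * besselI(kappa, 0, expon.scaled = FALSE)) *
      (pi / 180)
  }
  vapply(seq_len(length(breaks_deg) - 1), function(i)
    stats::integrate(dens, breaks_deg[i], breaks_deg[i + 1])$value, numeric(1))
}

## sinusoidal grating image: intensity varies perpendicular to fibres at
## `angle_deg` (anticlockwise from +x, y up), period in px
grating <- function(n, angle_deg, period, amplitude = 80, offset = 100) {
  x <- matrix(rep(seq_len(n), each = n), n)
  yup <- matrix(rep(n:1, times = n), n)
  a <- angle_deg * pi / 180
  offset + amplitude * sin(2 * pi * (-x * sin(a) + yup * cos(a)) / period)
}
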