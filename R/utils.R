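#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_data <- function(...) stop(..., call. = FALSE)

assert_scalar_num <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi)
    stop_data(sprintf("`%s` must be a finite number in [%s, %s]", name, lo, hi))
  invisible(x)
}

## wrap angles (degrees) to the half-open axial range (-90, 90]
wrap_axial <- function(theta) {
  th <- (theta + 90) %% 180 - 90
  th[th == -90] <- 90
  th
}

## circular moving average, window must be odd
circular_ma <- function(x, window = 3L) {
  n <- length(x)
  if (window <= 1L || n < window) return(x)
  half <- (window - 1L) %/% 2L
  xx <- c(x[(n - half + 1L):n], x, x[1:half])
  as.numeric(stats::filter(xx, rep(1 / window, window), sides = 2))[(half + 1L):(half + n)]
}

## bilinear interpolation of matrix `m` at (row, col) positions (1-based, fractional)
bilinear <- function(m, r, c) {
  nr <- nrow(m); nc <- ncol(m)
  r0 <- pmin(pmax(floor(r), 1L), nr - 1L)
  c0 <- pmin(pmax(floor(c), 1L), nc - 1L)
  fr <- pmin(pmax(r - r0, 0), 1)
  fc <- pmin(pmax(c - c0, 0), 1)
  m[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    m[cbind(r0 + 1L, c0)] * fr * (1 - fc) +
    m[cbind(r0, c0 + 1L)] * (1 - fr) * fc +
    m[cbind(r0 + 1L, c0 + 1L)] * fr * fc
}
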