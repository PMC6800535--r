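# Internal numeric helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_arg <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_arg("`%s` must be a single finite number", name)
  if (positive && x <= 0) stop_arg("`%s` must be > 0 (got %g)", name, x)
  if (nonneg && x < 0) stop_arg("`%s` must be >= 0 (got %g)", name, x)
  invisible(x)
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state. seed = NULL leaves the stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Centered running mean with shrinking edge windows (cumsum based, O(n)).
run_mean <- function(x, width) {
  n <- length(x)
  if (width <= 1L || n == 0L) return(x)
  half <- (width - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(0L, seq_len(n) - half - 1L)
  hi <- pmin(n, seq_len(n) + half)
  (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
}

# Centered sliding minimum, van Herk / Gil-Werman: two cummin passes per
# block, O(n) regardless of window width. Edges use truncated windows.
run_min <- function(x, width) {
  n <- length(x)
  if (width <= 1L || n == 0L) return(x)
  half <- (width - 1L) %/% 2L
  w <- 2L * half + 1L
  xp <- c(rep(Inf, half), x, rep(Inf, half + w))   # pad so blocks divide evenly
  np <- length(xp)
  nb <- ceiling(np / w)
  blk <- matrix(c(xp, rep(Inf, nb * w - np)), nrow = w)
  fwd <- apply(blk, 2L, cummin)
  bwd <- apply(blk[w:1, , drop = FALSE], 2L, cummin)[w:1, , drop = FALSE]
  fwd <- as.vector(fwd); bwd <- as.vector(bwd)
  i <- seq_len(n) + half            # index of window start in padded vector
  pmin(bwd[i], fwd[i + w - 1L])
}

# Savitzky-Golay convolution coefficients: least-squares fit of a degree-p
# polynomial over 2m+1 points, evaluated at the centre (row `at` of the
# pseudo-inverse gives other evaluation offsets, used for edge handling).
sg_coefficients <- function(window_points, poly_order) {
  m <- (window_points - 1L) %/% 2L
  X <- outer(seq(-m, m), 0:poly_order, `^`)
  solve(crossprod(X), t(X))   # (p+1) x window matrix of fit coefficients
}
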