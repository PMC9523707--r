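# Internal numeric and RNG helpers.

# Round half away from zero (the 0-999 match-factor convention), unlike
# base round()'s round-half-even.
round_half_up <- function(x) floor(x + 0.5)

# Park-Miller multiplicative congruential generator, used where results must
# be reproducible independently of R's global RNG (per-compound reference
# spectra). State and draws are exact in double arithmetic (16807 * (2^31-1)
# < 2^53).
lcg_new <- function(seed) {
  state <- as.numeric(seed) %% 2147483647
  if (state <= 0) state <- state + 2147483646
  env <- new.env(parent = emptyenv())
  env$state <- state
  env
}

lcg_next <- function(gen) {
  gen$state <- (16807 * gen$state) %% 2147483647
  gen$state / 2147483647
}

lcg_draw <- function(gen, n) vapply(seq_len(n), function(i) lcg_next(gen), numeric(1))

# Deterministic, platform-independent string hash (polynomial rolling hash
# modulo 2^31 - 1).
hash_string <- function(x) {
  codes <- utf8ToInt(x)
  h <- 0
  for (c in codes) h <- (h * 131 + c) %% 2147483647
  h
}

# Evaluate a block with a local RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

# Separable Gaussian blur of a matrix with reflective borders.
gaussian_blur <- function(m, sigma_row, sigma_col) {
  blur1 <- function(mat, sigma, along_rows) {
    if (sigma <= 0) return(mat)
    half <- max(1L, ceiling(3 * sigma))
    k <- exp(-((-half):half)^2 / (2 * sigma^2))
    k <- k / sum(k)
    n <- if (along_rows) nrow(mat) else ncol(mat)
    idx <- seq_len(n)
    out <- 0
    for (o in (-half):half) {
      j <- idx + o
      j <- ifelse(j < 1L, 2L - j, ifelse(j > n, 2L * n - j, j))  # reflect
      out <- out + k[o + half + 1L] * (if (along_rows) mat[j, , drop = FALSE]
                                       else mat[, j, drop = FALSE])
    }
    out
  }
  blur1(blur1(m, sigma_row, TRUE), sigma_col, FALSE)
}

# Bilinear interpolation of matrix m at (fractional) row/col coordinates.
# Coordinates outside the grid return `outside`.
bilinear <- function(m, row, col, outside = 0) {
  nr <- nrow(m); nc <- ncol(m)
  r0 <- floor(row); c0 <- floor(col)
  fr <- row - r0; fc <- col - c0
  ok <- r0 >= 1 & c0 >= 1 & r0 + 1 <= nr & c0 + 1 <= nc
  out <- rep(outside, length(row))
  if (any(ok)) {
    r0k <- r0[ok]; c0k <- c0[ok]; frk <- fr[ok]; fck <- fc[ok]
    v00 <- m[cbind(r0k, c0k)]
    v10 <- m[cbind(r0k + 1, c0k)]
    v01 <- m[cbind(r0k, c0k + 1)]
    v11 <- m[cbind(r0k + 1, c0k + 1)]
    out[ok] <- v00 * (1 - frk) * (1 - fck) + v10 * frk * (1 - fck) +
      v01 * (1 - frk) * fck + v11 * frk * fck
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
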