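#' Construct a stick mass spectrum
#'
#' A mass spectrum is a set of nominal (unit-mass) m/z channels in the
#' acquired range 35--350 with non-negative intensities. At least one
#' intensity must be positive.
#'
#' @param mz Integer m/z values, strictly increasing, within \[35, 350\].
#' @param intensity Non-negative intensities, same length as `mz`.
#' @return An object of class `mass_spectrum` with fields `mz` and
#'   `intensity`.
#' @examples
#' s <- mass_spectrum(c(43, 58, 71), c(999, 310, 120))
#' base_peak(s)
#' @export
mass_spectrum <- function(mz, intensity) {
  mz <- as.integer(mz)
  intensity <- as.numeric(intensity)
  if (length(mz) == 0L) stop("empty spectrum: no channels")
  if (length(mz) != length(intensity))
    stop("mz and intensity lengths differ")
  if (any(diff(mz) <= 0L)) stop("mz channels must be strictly increasing")
  if (any(mz < 35L | mz > 350L)) stop("m/z channels must lie in [35, 350]")
  if (any(intensity < 0)) stop("intensities must be non-negative")
  if (all(intensity == 0)) stop("invalid spectrum: all intensities zero")
  structure(list(mz = mz, intensity = intensity), class = "mass_spectrum")
}

#' @rdname mass_spectrum
#' @param x A `mass_spectrum`.
#' @return `base_peak()`: the m/z of the most intense channel.
#' @export
base_peak <- function(x) {
  stopifnot(inherits(x, "mass_spectrum"))
  x$mz[which.max(x$intensity)]
}

#' @export
print.mass_spectrum <- function(x, ...) {
  cat("mass_spectrum:", length(x$mz), "channels, base peak m/z",
      base_peak(x), "\n")
  invisible(x)
}

weighted_sticks <- function(s, mz_weight, int_power) {
  s$intensity^int_power * as.numeric(s$mz)^mz_weight
}

match_factor_core <- function(a, b, mz_weight, int_power) {
  # Weighted squared-cosine on the union of channels, 0-999 scale.
  channels <- sort(union(a$mz, b$mz))
  ia <- numeric(length(channels)); ib <- numeric(length(channels))
  ia[match(a$mz, channels)] <- a$intensity
  ib[match(b$mz, channels)] <- b$intensity
  sa <- ia^int_power * channels^mz_weight
  sb <- ib^int_power * channels^mz_weight
  den <- sum(sa^2) * sum(sb^2)
  if (den == 0) return(0L)
  as.integer(round_half_up(999 * sum(sa * sb)^2 / den))
}

#' Direct and reverse mass-spectral match factors
#'
#' NIST-search-style similarity between an analyzed and a reference stick
#' spectrum on the conventional 0--999 scale. Channel sticks are weighted as
#' \eqn{s_k = I_k^{p} \, (m/z)_k^{w}} (defaults: intensity power 0.5, m/z
#' weight 1, the Stein--Scott choice) and the score is the squared cosine of
#' the weighted stick vectors over the union of channels, scaled by 999 and
#' rounded half-up. Disjoint channel supports score 0.
#'
#' `rmf()` applies the same formula restricted to the channels where the
#' reference spectrum has positive intensity, so extra channels in the
#' analyzed spectrum (matrix interferences, co-elution) are ignored; it is
#' intentionally asymmetric and satisfies `rmf(a, ref) >= dmf(a, ref)`
#' whenever the reference support is a subset of the analyzed support.
#'
#' @param analyzed,reference `mass_spectrum` objects.
#' @param mz_weight m/z weighting exponent (default 1).
#' @param int_power intensity power (default 0.5).
#' @return Integer match factor in \[0, 999\].
#' @examples
#' a <- mass_spectrum(c(50, 60), c(100, 100))
#' b <- mass_spectrum(50, 100)
#' dmf(a, b)  # 409
#' rmf(a, b)  # 999
#' @export
dmf <- function(analyzed, reference, mz_weight = 1, int_power = 0.5) {
  stopifnot(inherits(analyzed, "mass_spectrum"),
            inherits(reference, "mass_spectrum"))
  match_factor_core(analyzed, reference, mz_weight, int_power)
}

#' @rdname dmf
#' @export
rmf <- function(analyzed, reference, mz_weight = 1, int_power = 0.5) {
  stopifnot(inherits(analyzed, "mass_spectrum"),
            inherits(reference, "mass_spectrum"))
  keep <- reference$mz[reference$intensity > 0]
  if (length(keep) == 0L) stop("reference spectrum has no positive channels")
  sel <- analyzed$mz %in% keep
  if (!any(sel)) return(0L)
  a <- list(mz = analyzed$mz[sel], intensity = analyzed$intensity[sel])
  r <- list(mz = reference$mz[reference$intensity > 0],
            intensity = reference$intensity[reference$intensity > 0])
  match_factor_core(a, r, mz_weight, int_power)
}
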