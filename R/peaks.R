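#' Robust noise estimate of a TIC raster
#'
#' Scale estimate of the baseline noise: 1.4826 times the median absolute
#' deviation from the raster median, computed over the lower half of the
#' values only (points below the median). Chromatographic peaks only inflate
#' the upper tail, so the estimate is insensitive even to very large peaks;
#' on pure Gaussian noise it is consistent for the SD.
#'
#' @param chrom A `gc2d_chromatogram`, or a TIC raster matrix.
#' @return Noise SD in counts; 0 (with a warning) for an all-constant
#'   raster.
#' @export
estimate_noise <- function(chrom) {
  tic <- if (inherits(chrom, "gc2d_chromatogram")) tic_raster(chrom)
         else as.matrix(chrom)
  if (length(tic) == 0L) stop("empty raster")
  m <- median(tic)
  lower <- tic[tic < m]
  if (length(lower) == 0L) {
    warning("raster has no spread below its median; noise estimate is 0")
    return(0)
  }
  1.4826 * median(m - lower)
}

#' Detect 2D peaks on the TIC raster
#'
#' Lightly smooths the TIC raster (separable Gaussian, default SD of 1
#' modulation by 0.03 s), finds local maxima by watershed segmentation,
#' assigns each peak a footprint of raster points flooding down from its
#' apex, and discards peaks below the signal-to-noise threshold (method
#' default 100). The apex spectrum is taken from the single largest raw data
#' point of the footprint; channels below `3 x` the per-channel noise floor
#' are zeroed (baseline denoising) before use.
#'
#' Heights are apex TIC above the flat baseline (the raster median); volumes
#' sum baseline-subtracted counts over the footprint. Footprints are
#' pairwise disjoint, so the summed volumes never exceed the raster total.
#' The footprint floor is `baseline + noise_floor_k * noise` with an
#' additional small fractional-height floor (`frac_floor` of the apex, so a
#' noiseless Gaussian's volume is recovered to ~0.1%).
#'
#' @param chrom A `gc2d_chromatogram`.
#' @param snr_min Minimum signal-to-noise ratio (default 100).
#' @param noise_floor_k Footprint floor in noise SDs above baseline.
#' @param frac_floor Fractional-height floor relative to the apex.
#' @param smooth_sigma SDs of the smoothing kernel: modulations, seconds.
#' @return A data frame of class `gc2d_peaks`: `rt1_min`, `rt2_s`, `height`,
#'   `volume`, `snr`, `base_peak_mz`, `mod`, `pt` (1-based apex grid
#'   indices), with the apex spectra in `attr(, "spectra")` and the
#'   footprints (linear raster indices) in `attr(, "footprints")`.
#' @export
detect_peaks <- function(chrom, snr_min = 100, noise_floor_k = 2,
                         frac_floor = 0.001,
                         smooth_sigma = c(mod = 1, s = 0.03)) {
  stopifnot(inherits(chrom, "gc2d_chromatogram"))
  tic <- tic_raster(chrom)
  noise <- suppressWarnings(estimate_noise(tic))
  baseline <- median(tic)
  sm <- gaussian_blur(tic, smooth_sigma[["mod"]],
                      max(0.5, smooth_sigma[["s"]] * chrom$acq_hz))
  sm_noise <- suppressWarnings(estimate_noise(sm))
  sm_base <- median(sm)

  mask <- sm > sm_base + noise_floor_k * sm_noise
  if (!any(mask)) return(empty_peaks(chrom))
  topo <- (sm - sm_base) * mask
  labels <- EBImage::imageData(EBImage::watershed(
    EBImage::as.Image(topo), tolerance = max(sm_noise, 1e-9), ext = 1))
  ids <- sort(unique(labels[labels > 0]))

  peaks <- list(); spectra <- list(); feet <- list()
  for (id in ids) {
    cells <- which(labels == id)
    # per-peak fractional-height floor on the raw raster
    apex_cell <- cells[which.max(tic[cells])]
    apex_h <- tic[apex_cell] - baseline
    keep <- tic[cells] - baseline >= frac_floor * apex_h
    cells <- cells[keep | cells == apex_cell]
    snr <- if (noise > 0) apex_h / noise else Inf
    if (snr < snr_min) next
    vol <- sum(tic[cells] - baseline)
    ij <- arrayInd(apex_cell, dim(tic))
    spec <- apex_spectrum(chrom, ij[1], ij[2], noise)
    if (is.null(spec)) next
    peaks[[length(peaks) + 1L]] <- data.frame(
      rt1_min = (ij[1] - 1) * chrom$p_m / 60,
      rt2_s = (ij[2] - 1) / chrom$acq_hz,
      height = apex_h, volume = vol, snr = snr,
      base_peak_mz = base_peak(spec), mod = ij[1], pt = ij[2])
    spectra[[length(spectra) + 1L]] <- spec
    feet[[length(feet) + 1L]] <- cells
  }
  if (length(peaks) == 0L) return(empty_peaks(chrom))
  out <- do.call(rbind, peaks)
  o <- order(out$rt1_min, out$rt2_s)
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "spectra") <- spectra[o]
  attr(out, "footprints") <- feet[o]
  attr(out, "noise") <- noise
  attr(out, "baseline") <- baseline
  attr(out, "meta") <- chrom$meta
  attr(out, "geometry") <- list(n_mod = dim(chrom$cube)[1],
                                n_pts = dim(chrom$cube)[2],
                                p_m = chrom$p_m, acq_hz = chrom$acq_hz)
  class(out) <- c("gc2d_peaks", "data.frame")
  out
}

empty_peaks <- function(chrom) {
  out <- data.frame(rt1_min = numeric(), rt2_s = numeric(),
                    height = numeric(), volume = numeric(), snr = numeric(),
                    base_peak_mz = integer(), mod = integer(),
                    pt = integer())
  attr(out, "spectra") <- list()
  attr(out, "footprints") <- list()
  attr(out, "noise") <- suppressWarnings(estimate_noise(chrom))
  attr(out, "baseline") <- median(tic_raster(chrom))
  attr(out, "meta") <- chrom$meta
  attr(out, "geometry") <- list(n_mod = dim(chrom$cube)[1],
                                n_pts = dim(chrom$cube)[2],
                                p_m = chrom$p_m, acq_hz = chrom$acq_hz)
  class(out) <- c("gc2d_peaks", "data.frame")
  out
}

# Denoised spectrum at one cube point: channels below 3x the per-channel
# noise SD are dropped (the TIC noise spreads over the 316 channels).
apex_spectrum <- function(chrom, mod, pt, tic_noise) {
  v <- chrom$cube[mod, pt, ]
  ch_noise <- tic_noise / sqrt(length(v))
  v[v < 3 * ch_noise] <- 0
  if (all(v == 0)) return(NULL)
  sel <- v > 0
  mass_spectrum(chrom$mz[sel], v[sel])
}

#' @export
`[.gc2d_peaks` <- function(x, i, j, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && !missing(i)) {
    attr(out, "spectra") <- attr(x, "spectra")[i]
    attr(out, "footprints") <- attr(x, "footprints")[i]
    for (a in c("noise", "baseline", "meta", "geometry"))
      attr(out, a) <- attr(x, a)
    class(out) <- class(x)
  }
  out
}

#' @export
print.gc2d_peaks <- function(x, ...) {
  cat("gc2d_peaks:", nrow(x), "peaks (noise SD",
      format(attr(x, "noise"), digits = 3), ")\n")
  if (nrow(x)) print.data.frame(head(as.data.frame(x), 10))
  invisible(x)
}

#' Export a peak table as delimited text
#'
#' @param peaks A `gc2d_peaks`.
#' @param path Output CSV path.
#' @export
export_peak_table <- function(peaks, path) {
  stopifnot(inherits(peaks, "gc2d_peaks"))
  out <- data.frame(sample_id = attr(peaks, "meta")$sample_id %||% NA,
                    as.data.frame(peaks)[, c("rt1_min", "rt2_s", "height",
                                             "volume", "snr",
                                             "base_peak_mz")])
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
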