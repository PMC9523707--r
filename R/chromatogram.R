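#' GC x GC-TOF MS run as a 2D chromatogram data cube
#'
#' A run is a 3-D array of detector counts indexed by modulation (first
#' dimension, one slot per modulation period), within-period sampling point
#' (second dimension) and nominal m/z channel 35--350 (third dimension, 316
#' channels). The modulation period `p_m` (seconds; instrument setting 3.5 s)
#' and within-period acquisition rate `acq_hz` (Hz; instrument setting 100,
#' i.e. 350 points per period) define the retention-plane geometry; the
#' number of within-period points must equal `round(p_m * acq_hz)`.
#'
#' @param cube Numeric 3-D array `[n_mod, n_pts, 316]` of non-negative
#'   counts (arbitrary detector units).
#' @param p_m Modulation period in seconds.
#' @param acq_hz Within-period sampling rate in Hz.
#' @param meta Named list of run metadata (`sample_id`, `class_label`,
#'   `replicate_id`, `analytical_replicate`, `acq_order`).
#' @return Object of class `gc2d_chromatogram`.
#' @export
gc2d_chromatogram <- function(cube, p_m = 3.5, acq_hz = 100,
                              meta = list()) {
  if (!is.array(cube) || length(dim(cube)) != 3L)
    stop("cube must be a 3-D array [n_mod, n_pts, n_mz]")
  mz <- 35:350
  if (dim(cube)[3] != length(mz))
    stop("cube must have ", length(mz), " m/z channels (nominal 35-350); got ",
         dim(cube)[3])
  if (dim(cube)[2] != round(p_m * acq_hz))
    stop("within-period points (", dim(cube)[2], ") must equal ",
         "round(p_m * acq_hz) = ", round(p_m * acq_hz))
  if (any(cube < 0)) stop("cube contains negative counts")
  structure(list(cube = cube, p_m = p_m, acq_hz = acq_hz, mz = mz,
                 meta = meta),
            class = "gc2d_chromatogram")
}

#' @export
print.gc2d_chromatogram <- function(x, ...) {
  d <- dim(x$cube)
  cat("gc2d_chromatogram:", d[1], "modulations x", d[2], "points x", d[3],
      "m/z channels; P_M =", x$p_m, "s at", x$acq_hz, "Hz\n")
  if (!is.null(x$meta$sample_id))
    cat("  sample:", x$meta$sample_id, "(", x$meta$class_label %||% "?", ")\n")
  invisible(x)
}

#' Retention-plane coordinates of cube grid indices
#'
#' Maps 0-based grid indices to retention coordinates: the first-dimension
#' retention time is `mod_index * p_m / 60` minutes and the second-dimension
#' (within-period) time is `pt_index / acq_hz` seconds, so `rt2` always lies
#' in `[0, p_m)`. The mapping is a bijection on the index grid.
#'
#' @param chrom A `gc2d_chromatogram`.
#' @param mod_index,pt_index 0-based indices (vectorised).
#' @return Data frame with columns `rt1_min` and `rt2_s`.
#' @examples
#' ch <- gc2d_chromatogram(array(0, c(4, 350, 316)))
#' coords_of(ch, 0, 0)
#' @export
coords_of <- function(chrom, mod_index, pt_index) {
  stopifnot(inherits(chrom, "gc2d_chromatogram"))
  d <- dim(chrom$cube)
  if (any(mod_index < 0 | mod_index >= d[1]) ||
      any(pt_index < 0 | pt_index >= d[2]))
    stop("index out of cube bounds")
  data.frame(rt1_min = mod_index * chrom$p_m / 60,
             rt2_s = pt_index / chrom$acq_hz)
}

# Inverse of coords_of: nearest 0-based grid indices for retention coords.
index_of <- function(chrom, rt1_min, rt2_s) {
  list(mod = round(rt1_min * 60 / chrom$p_m),
       pt = round(rt2_s * chrom$acq_hz))
}

#' Total ion current raster of a run
#'
#' Channel-sum of the cube: a `[n_mod, n_pts]` matrix whose total equals the
#' cube total.
#' @param chrom A `gc2d_chromatogram`.
#' @return Numeric matrix.
#' @export
tic_raster <- function(chrom) {
  stopifnot(inherits(chrom, "gc2d_chromatogram"))
  d <- dim(chrom$cube)
  matrix(rowSums(matrix(chrom$cube, ncol = d[3])), d[1], d[2])
}

#' Read and write run containers
#'
#' Runs round-trip losslessly through a single-file container holding the
#' named cube array, the geometry scalars and the metadata block
#' (R serialisation, format version tagged). `read_run()` validates the
#' container and names the violated invariant on failure.
#'
#' @param path File path.
#' @return `read_run()`: a `gc2d_chromatogram`.
#' @export
read_run <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$format, "gcxgcfp-run-v1"))
    stop("format error: not a gcxgcfp run container")
  for (f in c("cube", "p_m", "acq_hz"))
    if (is.null(obj[[f]])) stop("format error: container missing '", f, "'")
  gc2d_chromatogram(obj$cube, p_m = obj$p_m, acq_hz = obj$acq_hz,
                    meta = obj$meta %||% list())
}

#' @rdname read_run
#' @param chrom A `gc2d_chromatogram`.
#' @export
write_run <- function(chrom, path) {
  stopifnot(inherits(chrom, "gc2d_chromatogram"))
  saveRDS(list(format = "gcxgcfp-run-v1", cube = chrom$cube, p_m = chrom$p_m,
               acq_hz = chrom$acq_hz, meta = chrom$meta), path)
  invisible(path)
}

#' Export a TIC raster as delimited text
#'
#' @param chrom A `gc2d_chromatogram`.
#' @param path Output CSV path (rows = modulations, columns = points).
#' @export
export_tic <- function(chrom, path) {
  write.table(tic_raster(chrom), path, sep = ",", row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
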