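#' n-Alkane retention-index calibration
#'
#' Ordered (carbon number, first-dimension retention time) anchor points for
#' linear retention indices under temperature programming. Times must
#' increase strictly with carbon number. Gaps in the ladder (a missing
#' homologue) are allowed: interpolation then spans the gap with the
#' corresponding multiple of 100 index units.
#'
#' @param carbons Integer carbon numbers (e.g. 9:25).
#' @param rt1_min First-dimension retention times, minutes.
#' @return Object of class `alkane_calibration`.
#' @export
alkane_calibration <- function(carbons, rt1_min) {
  carbons <- as.integer(carbons)
  rt1_min <- as.numeric(rt1_min)
  stopifnot(length(carbons) == length(rt1_min))
  if (length(carbons) < 2L) stop("need at least two alkane anchors")
  o <- order(carbons)
  carbons <- carbons[o]; rt1_min <- rt1_min[o]
  if (anyDuplicated(carbons)) stop("duplicate carbon numbers")
  if (any(diff(rt1_min) <= 0))
    stop("retention times must increase strictly with carbon number")
  structure(list(carbons = carbons, rt1_min = rt1_min),
            class = "alkane_calibration")
}

#' @export
print.alkane_calibration <- function(x, ...) {
  cat("alkane_calibration: C", min(x$carbons), "-C", max(x$carbons), " (",
      length(x$carbons), " anchors)\n", sep = "")
  invisible(x)
}

#' Read/write a calibration as two-column delimited text
#' @param path CSV with columns `carbon_number`, `rt1_min`.
#' @export
read_alkane_calibration <- function(path) {
  d <- read.csv(path)
  alkane_calibration(d$carbon_number, d$rt1_min)
}

#' @rdname read_alkane_calibration
#' @param cal An `alkane_calibration`.
#' @export
write_alkane_calibration <- function(cal, path) {
  write.csv(data.frame(carbon_number = cal$carbons, rt1_min = cal$rt1_min),
            path, row.names = FALSE)
  invisible(path)
}

#' Linear retention index
#'
#' Temperature-programmed linear index by van den Dool & Kratz
#' interpolation between the bracketing alkane anchors:
#' \deqn{I^T = 100 n_{lo} + 100 (n_{hi} - n_{lo})
#'   \frac{t - t_{lo}}{t_{hi} - t_{lo}}}
#' Strictly increasing in `t` inside the ladder. Times outside the ladder
#' return `NA` with the out-of-range positions flagged in
#' `attr(, "out_of_range")` (the table convention ">2500" / "NC").
#'
#' @param t First-dimension retention time(s), minutes.
#' @param cal An `alkane_calibration`.
#' @return Numeric vector of index values.
#' @examples
#' cal <- alkane_calibration(c(10, 11), c(10, 12))
#' retention_index(11, cal)  # 1050
#' @export
retention_index <- function(t, cal) {
  stopifnot(inherits(cal, "alkane_calibration"))
  oor <- t < min(cal$rt1_min) | t > max(cal$rt1_min)
  idx <- findInterval(t, cal$rt1_min, rightmost.closed = TRUE)
  idx[oor] <- NA_integer_
  lo <- cal$rt1_min[idx]; hi <- cal$rt1_min[idx + 1L]
  n_lo <- cal$carbons[idx]; n_hi <- cal$carbons[idx + 1L]
  out <- 100 * n_lo + 100 * (n_hi - n_lo) * (t - lo) / (hi - lo)
  out[oor] <- NA_real_
  if (any(oor)) attr(out, "out_of_range") <- oor
  out
}

#' Derive a synthetic alkane ladder from the target library
#'
#' Builds a C9--C25 calibration consistent with the packaged library's own
#' (retention time, experimental index) pairs, by monotone (isotonic)
#' interpolation of time against index and evaluation at each multiple of
#' 100 units. This makes closed-loop identification self-consistent: a peak
#' simulated at a library compound's retention time computes back an index
#' within a few units of the library value. The ladder is synthetic -- it is
#' an interpolation of the transcribed table, not measured alkane data --
#' and extrapolates linearly for anchors beyond the last tabulated index.
#'
#' @param lib A `target_library`.
#' @param carbons Anchor carbon numbers (default 9:25).
#' @return An `alkane_calibration`.
#' @export
derive_alkane_ladder <- function(lib, carbons = 9:25) {
  ok <- !lib$it_unbounded & !is.na(lib$it_exp) & !is.na(lib$rt1_min)
  pts <- aggregate(rt1_min ~ it_exp, data = lib[ok, ], FUN = mean)
  pts <- pts[order(pts$it_exp), ]
  iso <- isoreg(pts$it_exp, pts$rt1_min)  # enforce monotone time vs index
  fit_t <- iso$yf
  targets <- 100 * carbons
  t_at <- approx(pts$it_exp, fit_t, xout = targets, rule = 1)$y
  # linear extrapolation at the ends from the outermost fitted span
  extrapolate <- function(x0, x1, y0, y1, x) y0 + (y1 - y0) * (x - x0) / (x1 - x0)
  n <- length(pts$it_exp)
  lo_span <- which(pts$it_exp >= pts$it_exp[1] &
                     pts$it_exp <= pts$it_exp[1] + 150)
  hi_span <- which(pts$it_exp >= pts$it_exp[n] - 150)
  for (k in seq_along(targets)) {
    if (!is.na(t_at[k])) next
    if (targets[k] < pts$it_exp[1]) {
      i <- range(lo_span)
      t_at[k] <- extrapolate(pts$it_exp[i[1]], pts$it_exp[i[2]],
                             fit_t[i[1]], fit_t[i[2]], targets[k])
    } else {
      i <- range(hi_span)
      t_at[k] <- extrapolate(pts$it_exp[i[1]], pts$it_exp[i[2]],
                             fit_t[i[1]], fit_t[i[2]], targets[k])
    }
  }
  # strict monotonicity guard against flat isotonic segments
  t_at <- cummax(t_at) + seq_along(t_at) * 1e-9
  alkane_calibration(carbons, t_at)
}

#' Calibration from a detected alkane run
#'
#' Detects peaks in an alkane calibration run and pairs them, in retention
#' order, with the supplied carbon numbers.
#'
#' @param chrom A `gc2d_chromatogram` from [simulate_alkane_run()] (or a
#'   real alkane run).
#' @param carbons Carbon numbers in elution order; default from run
#'   metadata.
#' @param snr_min Detection threshold.
#' @return An `alkane_calibration`.
#' @export
calibrate_from_run <- function(chrom, carbons = chrom$meta$carbons,
                               snr_min = 100) {
  pk <- detect_peaks(chrom, snr_min = snr_min)
  if (nrow(pk) != length(carbons))
    stop("detected ", nrow(pk), " alkane peaks for ", length(carbons),
         " carbon numbers")
  alkane_calibration(carbons, pk$rt1_min[order(pk$rt1_min)])
}

#' Assign a targeted identity to a peak
#'
#' Identification combines the spectral gates (direct match factor above
#' `dmf_min`, default 900; reverse match factor above `rmf_min`, default
#' 950) with a retention-index window (`it_tol`, default +/-10 units; the
#' library's own convention of +/-15 is available via the argument). Among
#' the library candidates passing all gates the highest DMF wins; ties break
#' toward the smaller index deviation, then library order.
#'
#' @param peak One-row `gc2d_peaks` slice, or a list with `rt1_min` and
#'   `spectrum`.
#' @param library A `target_library`.
#' @param cal An `alkane_calibration`.
#' @param spectra Reference spectra, as [library_spectra()].
#' @param dmf_min,rmf_min,it_tol Gates (see Details).
#' @return The matched library row (one-row data frame) with `dmf`, `rmf`,
#'   `it_dev` appended, or `NULL` when nothing passes.
#' @export
assign_identity <- function(peak, library, cal,
                            spectra = library_spectra(library),
                            dmf_min = 900, rmf_min = 950, it_tol = 10) {
  stopifnot(inherits(library, "target_library"))
  if (inherits(peak, "gc2d_peaks")) {
    stopifnot(nrow(peak) == 1L)
    spec <- attr(peak, "spectra")[[1]]
    rt1 <- peak$rt1_min
  } else {
    spec <- peak$spectrum
    rt1 <- peak$rt1_min
  }
  it <- retention_index(rt1, cal)
  if (is.na(it)) return(NULL)
  dev <- abs(library$it_exp - as.numeric(it))
  cand <- which(!library$it_unbounded & !is.na(dev) & dev <= it_tol)
  if (!length(cand)) return(NULL)
  d <- vapply(cand, function(i) dmf(spec, spectra[[i]]), numeric(1))
  r <- vapply(cand, function(i) rmf(spec, spectra[[i]]), numeric(1))
  pass <- d >= dmf_min & r >= rmf_min
  if (!any(pass)) return(NULL)
  cand <- cand[pass]; d <- d[pass]; r <- r[pass]
  best <- order(-d, dev[cand], cand)[1]
  out <- library[cand[best], , drop = FALSE]
  out$dmf <- d[best]; out$rmf <- r[best]; out$it_dev <- dev[cand[best]]
  rownames(out) <- NULL
  out
}
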