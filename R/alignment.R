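#' Retention-plane transform between a run and the template frame
#'
#' Least-squares polynomial mapping fitted on matched peak pairs: degree 2
#' in the first dimension, degree 1 in the second (run-to-run variation is
#' dominated by smooth drift and a second-dimension scale change). One
#' reweighting pass refits after dropping pairs whose residual exceeds 3
#' robust SDs, giving tolerance to a moderate fraction of mismatches. Both
#' directions (run to template, template to run) are fitted so rasters can
#' be resampled without inverting the polynomial.
#'
#' @param run Data frame / list with `rt1_min`, `rt2_s` (run frame).
#' @param template Same, in the template frame.
#' @return Object of class `gc2d_transform` with `predict()` support
#'   (argument `inverse = TRUE` maps template to run).
#' @export
fit_retention_transform <- function(run, template) {
  stopifnot(length(run$rt1_min) == length(template$rt1_min),
            length(run$rt1_min) >= 4)
  fit_dir <- function(x1, x2, y1, y2) {
    f1 <- lm(y1 ~ x1 + I(x1^2))
    f2 <- lm(y2 ~ x2)
    r <- sqrt(resid(f1)^2 + resid(f2)^2)
    keep <- r <= 3 * (mad(r) + 1e-12)
    if (sum(keep) >= 4 && any(!keep)) {
      f1 <- lm(y1 ~ x1 + I(x1^2), subset = keep)
      f2 <- lm(y2 ~ x2, subset = keep)
    }
    list(rt1 = coef(f1), rt2 = coef(f2))
  }
  structure(list(
    fwd = fit_dir(run$rt1_min, run$rt2_s, template$rt1_min, template$rt2_s),
    bwd = fit_dir(template$rt1_min, template$rt2_s, run$rt1_min, run$rt2_s),
    n = length(run$rt1_min)
  ), class = "gc2d_transform")
}

#' Identity transform (no retention correction)
#' @export
identity_transform <- function() {
  structure(list(fwd = list(rt1 = c(0, 1, 0), rt2 = c(0, 1)),
                 bwd = list(rt1 = c(0, 1, 0), rt2 = c(0, 1)), n = 0L),
            class = "gc2d_transform")
}

#' @export
predict.gc2d_transform <- function(object, rt1_min, rt2_s, inverse = FALSE,
                                   ...) {
  cf <- if (inverse) object$bwd else object$fwd
  list(rt1_min = cf$rt1[1] + cf$rt1[2] * rt1_min + cf$rt1[3] * rt1_min^2,
       rt2_s = cf$rt2[1] + cf$rt2[2] * rt2_s)
}

#' @export
print.gc2d_transform <- function(x, ...) {
  cat("gc2d_transform fitted on", x$n, "pairs\n")
  invisible(x)
}

#' Match template entries to the peaks of one run
#'
#' Candidate peaks must fall inside the retention search window around the
#' (transformed) expected coordinates and pass the spectral-similarity
#' gates (direct and reverse match factors >= 750 against the entry's
#' reference spectrum). Assignment is greedy in descending DMF; each peak
#' is used at most once.
#'
#' @param template A `gc2d_template`.
#' @param peaks A `gc2d_peaks` table for one run.
#' @param transform Optional `gc2d_transform` mapping the run into the
#'   template frame before windowing.
#' @param window Search window: c(minutes, seconds); default the template's
#'   constraint.
#' @param dmf_min,rmf_min Spectral gates; default the template's.
#' @return Integer vector over entries: matching row of `peaks`, or `NA`.
#' @export
match_peaks <- function(template, peaks, transform = NULL, window = NULL,
                        dmf_min = NULL, rmf_min = NULL) {
  stopifnot(inherits(template, "gc2d_template"),
            inherits(peaks, "gc2d_peaks"))
  window <- window %||% template$constraints$window
  dmf_min <- dmf_min %||% template$constraints$dmf_min
  rmf_min <- rmf_min %||% template$constraints$rmf_min
  ent <- template$entries
  n_ent <- nrow(ent)
  assignment <- rep(NA_integer_, n_ent)
  if (nrow(peaks) == 0L || n_ent == 0L) return(assignment)
  p1 <- peaks$rt1_min; p2 <- peaks$rt2_s
  if (!is.null(transform)) {
    tp <- predict(transform, p1, p2)
    p1 <- tp$rt1_min; p2 <- tp$rt2_s
  }
  specs <- attr(peaks, "spectra")
  cand <- list()
  for (e in seq_len(n_ent)) {
    hits <- which(abs(p1 - ent$rt1_min[e]) <= window[1] &
                    abs(p2 - ent$rt2_s[e]) <= window[2])
    for (h in hits) {
      d <- dmf(specs[[h]], template$spectra[[e]])
      if (d < dmf_min) next
      if (rmf(specs[[h]], template$spectra[[e]]) < rmf_min) next
      cand[[length(cand) + 1L]] <- c(entry = e, peak = h, dmf = d)
    }
  }
  if (!length(cand)) return(assignment)
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand[, "dmf"]), , drop = FALSE]
  used_peak <- logical(nrow(peaks))
  for (k in seq_len(nrow(cand))) {
    e <- cand[k, "entry"]; h <- cand[k, "peak"]
    if (!is.na(assignment[e]) || used_peak[h]) next
    assignment[e] <- h
    used_peak[h] <- TRUE
  }
  assignment
}

new_template <- function(entries, spectra, constraints) {
  structure(list(entries = entries, spectra = spectra,
                 constraints = constraints),
            class = "gc2d_template")
}

#' @export
print.gc2d_template <- function(x, ...) {
  cat("gc2d_template:", nrow(x$entries), "reliable peaks; window +/-",
      x$constraints$window[1], "min /", x$constraints$window[2], "s\n")
  invisible(x)
}

#' Build an alignment template from the peak sets of a study
#'
#' Seeds the template from the medoid run (the run whose peaks collect the
#' highest total matched DMF in a pilot all-versus-all pass), then
#' iteratively aligns every run to it: match, fit the retention transform on
#' the matched pairs, re-match with the transform applied, and update each
#' entry's expected coordinates to the mean of its matched (transformed)
#' positions. Entries retained are the *reliable peaks*: those positively
#' matched in at least `min_presence` of the runs (default all but one, the
#' most constrained option).
#'
#' @param peak_sets List of `gc2d_peaks`, one per run (>= 2).
#' @param min_presence Minimum number of runs an entry must match; default
#'   `length(peak_sets) - 1`.
#' @param window Search window c(minutes, seconds).
#' @param dmf_min,rmf_min Spectral-similarity gates for template matching.
#' @param iterations Alignment refinement passes.
#' @return A `gc2d_template` with attributes `matches` (entries x runs peak
#'   indices), `transforms` (per-run `gc2d_transform`) and `presence`
#'   (per-entry match counts).
#' @export
build_template <- function(peak_sets, min_presence = length(peak_sets) - 1,
                           window = c(0.30, 0.20), dmf_min = 750,
                           rmf_min = 750, iterations = 2) {
  n_runs <- length(peak_sets)
  if (n_runs < 2L) stop("need at least two runs to build a template")
  constraints <- list(window = window, dmf_min = dmf_min, rmf_min = rmf_min)

  as_template <- function(pk) {
    new_template(data.frame(rt1_min = pk$rt1_min, rt2_s = pk$rt2_s),
                 attr(pk, "spectra"), constraints)
  }
  # pilot: medoid run by total matched DMF against all other runs
  score <- numeric(n_runs)
  for (i in seq_len(n_runs)) {
    ti <- as_template(peak_sets[[i]])
    for (j in seq_len(n_runs)[-i]) {
      m <- match_peaks(ti, peak_sets[[j]])
      for (e in which(!is.na(m)))
        score[i] <- score[i] +
          dmf(attr(peak_sets[[j]], "spectra")[[m[e]]], ti$spectra[[e]])
    }
  }
  medoid <- which.max(score)

  tmpl <- as_template(peak_sets[[medoid]])
  transforms <- rep(list(identity_transform()), n_runs)
  matches <- NULL
  for (it in seq_len(iterations)) {
    matches <- matrix(NA_integer_, nrow(tmpl$entries), n_runs)
    sum1 <- numeric(nrow(tmpl$entries)); sum2 <- numeric(nrow(tmpl$entries))
    cnt <- integer(nrow(tmpl$entries))
    for (j in seq_len(n_runs)) {
      pk <- peak_sets[[j]]
      m0 <- match_peaks(tmpl, pk, transform = transforms[[j]])
      ok <- which(!is.na(m0))
      if (length(ok) >= 4) {
        transforms[[j]] <- fit_retention_transform(
          list(rt1_min = pk$rt1_min[m0[ok]], rt2_s = pk$rt2_s[m0[ok]]),
          list(rt1_min = tmpl$entries$rt1_min[ok],
               rt2_s = tmpl$entries$rt2_s[ok]))
      }
      m <- match_peaks(tmpl, pk, transform = transforms[[j]])
      matches[, j] <- m
      ok <- which(!is.na(m))
      tp <- predict(transforms[[j]], pk$rt1_min[m[ok]], pk$rt2_s[m[ok]])
      sum1[ok] <- sum1[ok] + tp$rt1_min
      sum2[ok] <- sum2[ok] + tp$rt2_s
      cnt[ok] <- cnt[ok] + 1L
    }
    upd <- cnt > 0
    tmpl$entries$rt1_min[upd] <- sum1[upd] / cnt[upd]
    tmpl$entries$rt2_s[upd] <- sum2[upd] / cnt[upd]
  }
  presence <- rowSums(!is.na(matches))
  keep <- presence >= min_presence
  tmpl$entries <- tmpl$entries[keep, , drop = FALSE]
  rownames(tmpl$entries) <- NULL
  tmpl$spectra <- tmpl$spectra[keep]
  tmpl$entries$entry_id <- seq_len(nrow(tmpl$entries))
  attr(tmpl, "matches") <- matches[keep, , drop = FALSE]
  attr(tmpl, "transforms") <- transforms
  attr(tmpl, "presence") <- presence[keep]
  attr(tmpl, "medoid") <- medoid
  tmpl
}

# Resample a run raster into the template frame (bilinear, template-frame
# grid point -> run coordinates via the backward transform).
warp_raster <- function(raster, transform, geometry) {
  n_mod <- nrow(raster); n_pts <- ncol(raster)
  grid1 <- ((seq_len(n_mod) - 1) * geometry$p_m) / 60
  grid2 <- (seq_len(n_pts) - 1) / geometry$acq_hz
  g <- expand.grid(rt1 = grid1, rt2 = grid2)
  run_coords <- predict(transform, g$rt1, g$rt2, inverse = TRUE)
  rows <- run_coords$rt1_min * 60 / geometry$p_m + 1
  cols <- run_coords$rt2_s * geometry$acq_hz + 1
  matrix(bilinear(raster, rows, cols), n_mod, n_pts)
}

#' Composite chromatogram of aligned runs
#'
#' Per-point mean of the TIC rasters after resampling each run into the
#' template frame through its fitted retention transform.
#'
#' @param rasters List of TIC raster matrices (same shape).
#' @param transforms Optional list of per-run `gc2d_transform` (as stored on
#'   the template); `NULL` means the rasters are already aligned.
#' @param geometry List with `p_m` and `acq_hz` (needed when warping).
#' @return Mean raster matrix.
#' @export
build_composite <- function(rasters, transforms = NULL, geometry = NULL) {
  if (length(rasters) == 0L) stop("empty run collection")
  acc <- 0
  for (j in seq_along(rasters)) {
    r <- rasters[[j]]
    if (!is.null(transforms)) {
      stopifnot(!is.null(geometry))
      r <- warp_raster(r, transforms[[j]], geometry)
    }
    acc <- acc + r
  }
  acc / length(rasters)
}

#' Delineate peak-region features on a composite chromatogram
#'
#' Watershed segmentation of the composite raster above its noise floor.
#' Regions whose footprint contains a template entry's apex are
#' targeted-covered (the template already tracks them); every remaining
#' region becomes an untargeted peak-region feature. Regions are pairwise
#' disjoint and each contains at least one point above the floor.
#'
#' @param composite Composite raster matrix (template frame).
#' @param template A `gc2d_template`.
#' @param geometry List with `p_m`, `acq_hz`.
#' @param noise_floor_k Floor in composite noise SDs above baseline.
#' @param snr_min Minimum apex S/N for a region to be kept.
#' @return Data frame of regions (`region_id`, `rt1_min`, `rt2_s`,
#'   `covered`) with the footprints (linear indices into the composite) in
#'   `attr(, "footprints")`.
#' @export
delineate_regions <- function(composite, template, geometry,
                              noise_floor_k = 2, snr_min = 100) {
  noise <- suppressWarnings(estimate_noise(composite))
  baseline <- median(composite)
  mask <- composite > baseline + noise_floor_k * noise
  empty <- data.frame(region_id = integer(), rt1_min = numeric(),
                      rt2_s = numeric(), covered = logical())
  attr(empty, "footprints") <- list()
  if (!any(mask)) return(empty)
  topo <- (composite - baseline) * mask
  labels <- EBImage::imageData(EBImage::watershed(
    EBImage::as.Image(topo), tolerance = max(noise, 1e-9), ext = 1))
  ids <- sort(unique(labels[labels > 0]))
  ent_cells <- cbind(round(template$entries$rt1_min * 60 / geometry$p_m) + 1,
                     round(template$entries$rt2_s * geometry$acq_hz) + 1)
  ent_lab <- labels[pmin(pmax(ent_cells[, 1], 1), nrow(composite)) +
                      (pmin(pmax(ent_cells[, 2], 1), ncol(composite)) - 1) *
                      nrow(composite)]
  out <- list(); feet <- list()
  for (id in ids) {
    cells <- which(labels == id)
    apex <- cells[which.max(composite[cells])]
    if (noise > 0 && (composite[apex] - baseline) / noise < snr_min) next
    ij <- arrayInd(apex, dim(composite))
    out[[length(out) + 1L]] <- data.frame(
      region_id = id,
      rt1_min = (ij[1] - 1) * geometry$p_m / 60,
      rt2_s = (ij[2] - 1) / geometry$acq_hz,
      covered = id %in% ent_lab)
    feet[[length(feet) + 1L]] <- cells
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "footprints") <- feet
  res
}

#' Assemble the combined untargeted + targeted feature table
#'
#' One row per template entry and per uncovered peak region; one column per
#' run. Entry responses are the matched peak's 2D volume (0 with a missing
#' flag when unmatched); region responses integrate the run's aligned,
#' baseline-subtracted raster over the region footprint. Internal-standard
#' entries are recognised by proximity to the supplied IS coordinates and
#' provide the *% normalized response* denominator (100 x volume / mean IS
#' volume of the same run); a run in which no IS was matched is an error.
#'
#' @param template A `gc2d_template` (with matches/transforms attributes).
#' @param regions Output of [delineate_regions()] (may be `NULL`).
#' @param peak_sets List of per-run `gc2d_peaks`.
#' @param rasters List of per-run TIC rasters (needed for region rows).
#' @param meta Data frame of per-run metadata (one row per run).
#' @param is_coords Data frame with `rt1_min`, `rt2_s` of the internal
#'   standards (default [default_internal_standards()]).
#' @param is_tol Window (minutes, seconds) for recognising IS entries.
#' @param identities Optional precomputed identity per entry (see
#'   [assign_template_identities()]).
#' @return Object of class `gc2d_feature_table`: list with `features`
#'   (id, kind, identity, rt1, rt2), `responses`, `normalized`, `missing`
#'   matrices (features x runs) and `meta`.
#' @export
assemble_feature_table <- function(template, regions, peak_sets,
                                   rasters = NULL, meta = NULL,
                                   is_coords = default_internal_standards(),
                                   is_tol = c(0.3, 0.2),
                                   identities = NULL) {
  matches <- attr(template, "matches")
  transforms <- attr(template, "transforms")
  n_runs <- length(peak_sets)
  ent <- template$entries
  n_ent <- nrow(ent)

  resp_ent <- matrix(0, n_ent, n_runs)
  miss_ent <- matrix(FALSE, n_ent, n_runs)
  for (j in seq_len(n_runs)) {
    m <- matches[, j]
    ok <- !is.na(m)
    resp_ent[ok, j] <- peak_sets[[j]]$volume[m[ok]]
    miss_ent[!ok, j] <- TRUE
  }

  is_entry <- rep(FALSE, n_ent)
  if (!is.null(is_coords)) {
    for (k in seq_len(nrow(is_coords))) {
      hit <- which(abs(ent$rt1_min - is_coords$rt1_min[k]) <= is_tol[1] &
                     abs(ent$rt2_s - is_coords$rt2_s[k]) <= is_tol[2])
      if (length(hit)) is_entry[hit[1]] <- TRUE
    }
  }

  targeted <- if (is.null(identities)) rep(FALSE, n_ent) else !is.na(identities)
  feat <- data.frame(
    feature_id = paste0("P", seq_len(n_ent)),
    kind = ifelse(is_entry, "is", ifelse(targeted, "targeted", "untargeted")),
    identity = if (is.null(identities)) NA_character_ else identities,
    rt1_min = ent$rt1_min, rt2_s = ent$rt2_s,
    stringsAsFactors = FALSE)

  resp <- resp_ent; miss <- miss_ent
  if (!is.null(regions) && nrow(regions) > 0) {
    unc <- which(!regions$covered)
    if (length(unc)) {
      stopifnot(!is.null(rasters))
      geometry <- attr(peak_sets[[1]], "geometry")
      feet <- attr(regions, "footprints")[unc]
      resp_reg <- matrix(0, length(unc), n_runs)
      for (j in seq_len(n_runs)) {
        r <- warp_raster(rasters[[j]], transforms[[j]], geometry)
        b <- median(r)
        for (q in seq_along(feet))
          resp_reg[q, j] <- max(0, sum(r[feet[[q]]] - b))
      }
      feat <- rbind(feat, data.frame(
        feature_id = paste0("R", regions$region_id[unc]),
        kind = "untargeted", identity = NA_character_,
        rt1_min = regions$rt1_min[unc], rt2_s = regions$rt2_s[unc],
        stringsAsFactors = FALSE))
      resp <- rbind(resp, resp_reg)
      miss <- rbind(miss, matrix(FALSE, length(unc), n_runs))
    }
  }

  is_rows <- which(feat$kind == "is")
  normalized <- matrix(NA_real_, nrow(resp), n_runs)
  if (length(is_rows)) {
    for (j in seq_len(n_runs)) {
      iv <- resp[is_rows, j]
      iv <- iv[iv > 0]
      if (!length(iv))
        stop("run ", j, " (", meta$sample_id[j] %||% "?",
             ") lacks both internal standards")
      normalized[, j] <- 100 * resp[, j] / mean(iv)
    }
  }
  cn <- if (!is.null(meta)) meta$sample_id else paste0("run_", seq_len(n_runs))
  dimnames(resp) <- list(feat$feature_id, cn)
  dimnames(normalized) <- dimnames(resp)
  dimnames(miss) <- dimnames(resp)
  structure(list(features = feat, responses = resp, normalized = normalized,
                 missing = miss, meta = meta),
            class = "gc2d_feature_table")
}

#' @export
print.gc2d_feature_table <- function(x, ...) {
  k <- table(x$features$kind)
  cat("gc2d_feature_table:", nrow(x$features), "features x",
      ncol(x$responses), "samples (",
      paste(names(k), k, sep = "=", collapse = ", "), ")\n")
  invisible(x)
}

#' Assign identities to all template entries
#'
#' Runs [assign_identity()] on every template entry (expected coordinates
#' and reference spectrum), implementing the method's convention that
#' analyte targeting is the last step, applied to the aligned template
#' rather than to individual runs.
#'
#' @param template A `gc2d_template`.
#' @param library A `target_library`.
#' @param cal An `alkane_calibration`.
#' @param spectra Reference spectra, as [library_spectra()].
#' @param ... Passed to [assign_identity()].
#' @return Character vector of analyte names (NA where unidentified).
#' @export
assign_template_identities <- function(template, library, cal,
                                       spectra = library_spectra(library),
                                       ...) {
  vapply(seq_len(nrow(template$entries)), function(e) {
    hit <- assign_identity(
      list(rt1_min = template$entries$rt1_min[e],
           spectrum = template$spectra[[e]]),
      library, cal, spectra = spectra, ...)
    if (is.null(hit)) NA_character_ else hit$name
  }, character(1))
}

#' Export a feature table as delimited text
#'
#' @param ft A `gc2d_feature_table`.
#' @param path Output CSV path.
#' @param normalized Write the %-normalized responses instead of volumes.
#' @export
export_feature_table <- function(ft, path, normalized = FALSE) {
  stopifnot(inherits(ft, "gc2d_feature_table"))
  m <- if (normalized) ft$normalized else ft$responses
  write.csv(cbind(ft$features, as.data.frame(m, check.names = FALSE)),
            path, row.names = FALSE)
  invisible(path)
}
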