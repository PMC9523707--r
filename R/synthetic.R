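#' Deterministic synthetic reference spectrum for a compound
#'
#' Stands in for a spectral database: generates a stick spectrum (8--20
#' channels in m/z 35--350, base peak scaled to 999) from a hash of the
#' compound identifier and a seed base, through the package's own
#' multiplicative congruential generator. The same identifier always yields
#' the same spectrum, on any platform, independently of R's global RNG; the
#' global RNG state is not touched. Distinct identifiers yield spectra that
#' are almost surely dissimilar (pairwise direct match factor < 750).
#'
#' @param cas Compound identifier (CAS registry number for library records;
#'   any non-empty string for synthetic unknowns).
#' @param seed_base Integer mixed into the hash (default 1).
#' @return A `mass_spectrum`.
#' @examples
#' identical(simulate_spectrum("79-09-4"), simulate_spectrum("79-09-4"))
#' @export
simulate_spectrum <- function(cas, seed_base = 1L) {
  if (!is.character(cas) || length(cas) != 1L || !nzchar(cas))
    stop("cas must be a non-empty string")
  gen <- lcg_new((hash_string(cas) * 31 + as.numeric(seed_base)) %%
                   2147483647)
  n_peaks <- 8L + as.integer(floor(lcg_next(gen) * 13))  # 8..20 sticks
  ch <- integer(0)
  while (length(ch) < n_peaks) {
    cand <- 35L + as.integer(floor(lcg_next(gen) * 316))
    if (!(cand %in% ch)) ch <- c(ch, cand)
  }
  # Heavy-tailed intensities keep random cross-matches low.
  raw <- lcg_draw(gen, n_peaks)^3
  ints <- pmax(1, round_half_up(999 * raw / max(raw)))
  o <- order(ch)
  mass_spectrum(ch[o], ints[o])
}

#' Default internal standards of the synthetic runs
#'
#' Two standards preloaded in every simulated run, mirroring the two
#' SPME-preloaded standards of the method (a thujone and methyl
#' 2-octynoate); retention coordinates are synthetic choices placed clear of
#' the default analyte panel. Their volumes are identical across runs up to
#' the response noise and provide the denominator of the *% normalized
#' response*.
#' @return Data frame with columns `name`, `cas`, `rt1_min`, `rt2_s`,
#'   `volume`.
#' @export
default_internal_standards <- function() {
  data.frame(
    name = c("alpha/beta-thujone", "methyl 2-octynoate"),
    cas = c("IS-thujone", "IS-methyl-2-octynoate"),
    rt1_min = c(21.30, 19.60),
    rt2_s = c(1.05, 1.15),
    volume = c(6e6, 6e6),
    stringsAsFactors = FALSE
  )
}

# Analytes of the default simulated panel: 40 library compounds spanning all
# ten chemical classes, including the propionic-acid / 1-propanol /
# propionate-ester signature so the published class effects can be planted.
# Members are chosen to be mutually resolvable at the generator's peak
# widths (pairwise retention-plane separation > 4.5 combined SDs, ISs and
# planted unknowns included) and index-consistent with the derived alkane
# ladder (|I^T residual| < 5 units).
default_panel_names <- c(
  "1-Propanol", "1-Pentanol", "3-Methyl-2-butanol", "(Z)-2-Hexen-1-ol",
  "6-Methyl-5-hepten-2-ol",
  "3-Methylbutanal", "Hexanal", "(E)-2-Hexenal", "(E)-2-Heptenal",
  "Decanal",
  "Methyl benzoate", "p-Xylene", "2-Phenylethanol", "p-Cresol",
  "2-Methoxy-4-(1-propen-1-yl)phenol (isoeugenol)",
  "Acetic acid", "Propionic acid", "Pentanoic acid", "Hexanoic acid",
  "Nonanoic acid",
  "Ethyl octanoate", "Ethyl propionate", "Propyl propionate",
  "Isoamyl propionate", "Ethyl hexanoate",
  "Propanoic acid, 2-hydroxy-, ethyl ester (ethyl lactate)",
  "Ethyl nonanoate", "2-Phenylethyl acetate",
  "2-Ethyl-3-methyl maleimide", "2-Furanmethanol (furfuryl alcohol)",
  "1-Undecene", "1-Tetradecene",
  "2-Octanone", "3-Hydroxy-2-butanone (acetoin)", "2-Nonanone",
  "2-Undecanone",
  "Hexanenitrile", "1-Nitrohexane",
  "Linalool", "\u03b2-Damascenone"
)

#' Default simulated analyte panel
#'
#' Selects the documented 40-analyte subset of the packaged library used by
#' the default study design. Retention coordinates come from the library;
#' per-analyte base volumes (arbitrary detector units) are drawn
#' deterministically per compound so signal-to-noise ratios sit well above
#' the detection threshold, spanning roughly 1e6--6e6 units.
#'
#' @param lib A `target_library` (default: the packaged one).
#' @return Data frame `name`, `cas`, `chem_class`, `rt1_min`, `rt2_s`,
#'   `it_exp`, `base_volume`.
#' @export
default_panel <- function(lib = load_target_library(
                            gcxgcfp_example("target_library.csv"))) {
  idx <- match(default_panel_names, lib$name)
  if (anyNA(idx))
    stop("panel analytes missing from library: ",
         paste(default_panel_names[is.na(idx)], collapse = ", "))
  p <- lib[idx, c("name", "cas", "chem_class", "rt1_min", "rt2_s", "it_exp")]
  rownames(p) <- NULL
  p$base_volume <- vapply(p$cas, function(cc) {
    10^(6 + 0.8 * lcg_next(lcg_new(hash_string(cc) + 7)))
  }, numeric(1))
  p
}

# Planted class effects (multiplicative fold-changes over the herbage
# baseline of 1) for the default panel, mirroring the fermentation
# signatures the study reports: the Lpar silages dominated by propionic acid
# (46x) and 1-propanol (9x) with their esters (isoamyl propionate 45x,
# ethyl nonanoate 219x, furfuryl alcohol 15x); Lbuc with ethyl-ester and
# phenol up-modulation (isoeugenol 22x, pentanoic acid 7x vs herbage);
# C6 lipoxygenase aldehydes and xylenes depleted in all silages.
default_effects <- list(
  "Propionic acid" = c(con = 5.75, lbuc = 18, lpar = 46),
  "1-Propanol" = c(con = 1.5, lbuc = 2, lpar = 9),
  "Ethyl propionate" = c(con = 2, lbuc = 4, lpar = 20),
  "Propyl propionate" = c(con = 2, lbuc = 2, lpar = 20),
  "Isoamyl propionate" = c(con = 1.5, lbuc = 1.5, lpar = 45),
  "Ethyl nonanoate" = c(con = 2, lbuc = 50, lpar = 219),
  "2-Furanmethanol (furfuryl alcohol)" = c(con = 3, lbuc = 3, lpar = 15),
  "3-Methyl-2-butanol" = c(con = 1.5, lbuc = 2, lpar = 4.5),
  "Acetic acid" = c(con = 4, lbuc = 10, lpar = 15),
  "Pentanoic acid" = c(con = 2, lbuc = 7, lpar = 7),
  "2-Methoxy-4-(1-propen-1-yl)phenol (isoeugenol)" =
    c(con = 5, lbuc = 22, lpar = 22),
  "p-Cresol" = c(con = 3, lbuc = 5, lpar = 8),
  "Propanoic acid, 2-hydroxy-, ethyl ester (ethyl lactate)" =
    c(con = 5, lbuc = 8, lpar = 12),
  "2-Phenylethyl acetate" = c(con = 2, lbuc = 3, lpar = 3),
  "Hexanal" = c(con = 0.3, lbuc = 0.3, lpar = 0.3),
  "(E)-2-Hexenal" = c(con = 0.3, lbuc = 0.3, lpar = 0.3),
  "Decanal" = c(con = 0.5, lbuc = 0.5, lpar = 0.5),
  "3-Methylbutanal" = c(con = 2, lbuc = 2, lpar = 2),
  "p-Xylene" = c(con = 0.45, lbuc = 0.45, lpar = 0.45),
  "3-Hydroxy-2-butanone (acetoin)" = c(con = 2, lbuc = 3, lpar = 2),
  "Linalool" = c(con = 3, lbuc = 3, lpar = 3),
  "\u03b2-Damascenone" = c(con = 3, lbuc = 3, lpar = 3)
)

#' Default class-by-analyte effect matrix
#'
#' Fold-change matrix (rows: the five biological classes; columns: panel
#' analytes) planting the study's published fermentation signatures in the
#' simulated silage classes; herbage classes are the baseline of 1. Analytes
#' without a documented effect default to 1 in every class.
#'
#' @param analyte_names Panel analyte names (columns).
#' @return Numeric matrix `5 x length(analyte_names)`.
#' @export
default_effect_matrix <- function(analyte_names) {
  cls <- c("herbage_low", "herbage_high", "con", "lbuc", "lpar")
  eff <- matrix(1, nrow = length(cls), ncol = length(analyte_names),
                dimnames = list(cls, analyte_names))
  for (nm in intersect(names(default_effects), analyte_names)) {
    e <- default_effects[[nm]]
    eff[names(e), nm] <- e
  }
  eff
}

#' Specify a synthetic study design
#'
#' Bundles everything the generator needs: the class layout (default: 3
#' herbage replicates per dry-matter level, 6 replicates each of the
#' untreated control and the two inoculated classes, 6 quality-control
#' mixtures, plus one analytical duplicate per biological class, 35 runs in
#' all), the analyte panel with base volumes, the class-by-analyte
#' fold-change matrix, retention jitter, the noise model, internal standards
#' and geometry.
#'
#' Retention jitter is modelled as a run-level multiplicative drift common
#' to all peaks of a run (`rt_jitter`, relative SDs, defaults 0.008 for the
#' first and 0.04 for the second dimension -- the printed across-run %RSD
#' scale of the method) plus a small per-peak residual (`rt_resid`, absolute
#' SDs in min / s). Response noise is multiplicative log-normal
#' (`response_sdlog`, default 0.12, the printed mean response %RSD scale);
#' baseline noise is additive Gaussian truncated at zero. `correlated`
#' groups share a run-level log-normal latent factor, planting the
#' acid/alcohol/ester correlation structure fermentation produces.
#'
#' @param analytes Panel data frame (`name`, `cas`, `rt1_min`, `rt2_s`,
#'   `base_volume`); default [default_panel()].
#' @param classes Named replicate counts per class label.
#' @param extra_analytical Class labels whose first replicate is acquired in
#'   analytical duplicate.
#' @param effect Fold-change matrix, classes x analytes.
#' @param qc_parents Class rows averaged to form the QC expectation
#'   (physically, QC samples are mixtures of the parent-class material).
#' @param unknowns Data frame of planted non-library compounds
#'   (`name`, `cas`, `rt1_min`, `rt2_s`, `base_volume`); these become
#'   untargeted features.
#' @param internal_standards Data frame as [default_internal_standards()].
#' @param rt_jitter,rt_resid,peak_sigma,baseline_sd,response_sdlog,correlated
#'   Noise-model parameters (see Details).
#' @param p_m,acq_hz,run_end_min Geometry of the simulated runs. The
#'   modulation period matches the instrument (3.5 s); the default
#'   within-period rate of 20 Hz and 44.5 min window keep desk-scale cubes.
#' @param seed Integer; every random draw of the study flows from it.
#' @return Object of class `study_design`.
#' @export
study_design <- function(analytes = default_panel(),
                         classes = c(herbage_low = 3, herbage_high = 3,
                                     con = 6, lbuc = 6, lpar = 6, qc = 6),
                         extra_analytical = c("herbage_low", "herbage_high",
                                              "con", "lbuc", "lpar"),
                         effect = default_effect_matrix(analytes$name),
                         qc_parents = "con",
                         unknowns = default_unknowns(),
                         internal_standards = default_internal_standards(),
                         rt_jitter = c(rt1 = 0.008, rt2 = 0.04),
                         rt_resid = c(rt1 = 0.010, rt2 = 0.020),
                         peak_sigma = c(mod = 2.5, s = 0.06),
                         baseline_sd = 5,
                         response_sdlog = 0.12,
                         correlated = default_correlated_groups(),
                         p_m = 3.5, acq_hz = 20,
                         run_end_min = 44.5,
                         seed = 1L) {
  stopifnot(all(classes >= 1), nrow(analytes) >= 1)
  if (any(effect <= 0)) stop("fold-changes must be positive")
  if (ncol(effect) != nrow(analytes) ||
      !identical(colnames(effect), analytes$name))
    stop("effect matrix columns must match the analyte panel")
  if (!all(qc_parents %in% rownames(effect)))
    stop("qc_parents must name effect rows")
  design <- list(analytes = analytes, classes = classes,
                 extra_analytical = extra_analytical, effect = effect,
                 qc_parents = qc_parents, unknowns = unknowns,
                 internal_standards = internal_standards,
                 rt_jitter = rt_jitter, rt_resid = rt_resid,
                 peak_sigma = peak_sigma, baseline_sd = baseline_sd,
                 response_sdlog = response_sdlog, correlated = correlated,
                 p_m = p_m, acq_hz = acq_hz, run_end_min = run_end_min,
                 seed = as.integer(seed))
  class(design) <- "study_design"
  design
}

#' @rdname study_design
#' @export
default_unknowns <- function() {
  data.frame(name = paste0("unknown-", 1:3),
             cas = paste0("UNK-", 1:3),
             rt1_min = c(16.20, 25.90, 34.00),
             rt2_s = c(1.80, 1.90, 1.30),
             base_volume = c(2e6, 3e6, 2.5e6),
             stringsAsFactors = FALSE)
}

#' @rdname study_design
#' @export
default_correlated_groups <- function() {
  # The acid/alcohol/ester correlation structure (e.g. 1-propanol with
  # propionic acid) already arises from the shared class fold-changes --
  # the common biosynthetic pathway is expressed at the class level -- so
  # no extra within-class latent factor is planted by default. Supply
  # groups as list(list(analytes = ..., sdlog = ...)) to add run-level
  # shared variation beyond the stated response noise.
  list()
}

#' @export
print.study_design <- function(x, ...) {
  cat("study_design:", sum(x$classes) + length(x$extra_analytical), "runs (",
      paste(names(x$classes), x$classes, sep = "=", collapse = ", "),
      "+", length(x$extra_analytical), "analytical duplicates )\n")
  cat("  panel:", nrow(x$analytes), "analytes,", nrow(x$unknowns),
      "unknowns; seed", x$seed, "\n")
  invisible(x)
}

#' Expected QC response from parent-class expectations
#'
#' QC samples are mixtures of the parent control material, so the expected
#' response of every analyte is the arithmetic mean of the parent-class
#' expectations (before noise).
#' @param ... Parent-class expected responses (vectors recycle).
#' @export
qc_expectation <- function(...) {
  Reduce(`+`, list(...)) / length(list(...))
}

# Expected (noise-free) per-analyte volumes for one class.
class_expectation <- function(design, class_label) {
  base <- c(design$analytes$base_volume, design$unknowns$base_volume)
  names(base) <- c(design$analytes$name, design$unknowns$name)
  eff <- rep(1, length(base))
  names(eff) <- names(base)
  if (class_label == "qc") {
    e <- colMeans(design$effect[design$qc_parents, , drop = FALSE])
    eff[names(e)] <- e
  } else if (class_label %in% rownames(design$effect)) {
    e <- design$effect[class_label, ]
    eff[names(e)] <- e
  }
  base * eff
}

# Discrete separable Gaussian cell integrals for one peak: window +/- 4
# sigma clipped at the grid bounds; mod_c/pt_c are 1-based fractional
# centres. Returns the index ranges, the TIC block and the per-channel
# fractions; the caller adds it to its cube in place (avoids copying the
# full data cube per compound).
peak_block <- function(dims, mod_c, pt_c, sig_mod, sig_pt, volume,
                       spectrum) {
  i <- max(1L, floor(mod_c - 4 * sig_mod)):min(dims[1],
                                               ceiling(mod_c + 4 * sig_mod))
  j <- max(1L, floor(pt_c - 4 * sig_pt)):min(dims[2],
                                             ceiling(pt_c + 4 * sig_pt))
  w1 <- pnorm((i + 0.5 - mod_c) / sig_mod) - pnorm((i - 0.5 - mod_c) / sig_mod)
  w2 <- pnorm((j + 0.5 - pt_c) / sig_pt) - pnorm((j - 0.5 - pt_c) / sig_pt)
  list(i = i, j = j, block = volume * outer(w1, w2),
       ch = spectrum$mz - 34L,
       frac = spectrum$intensity / sum(spectrum$intensity))
}

add_peak <- function(cube, mod_c, pt_c, sig_mod, sig_pt, volume, spectrum) {
  b <- peak_block(dim(cube), mod_c, pt_c, sig_mod, sig_pt, volume, spectrum)
  for (k in seq_along(b$ch))
    cube[b$i, b$j, b$ch[k]] <- cube[b$i, b$j, b$ch[k]] + b$block * b$frac[k]
  cube
}

#' Simulate one GC x GC-TOF MS run
#'
#' Places every panel analyte, planted unknown and internal standard as a
#' separable 2D Gaussian (default widths 2.5 modulations and 0.06 s) whose
#' integrated volume is `base x class fold-change x log-normal noise`, with
#' every cube point's spectrum proportional to the compound's reference
#' spectrum; adds truncated-Gaussian baseline noise; jitters retention
#' centres by the run-level drift plus per-peak residuals. Deterministic
#' given the design seed, class label and replicate indices.
#'
#' @param design A `study_design`.
#' @param class_label One of the design's class labels.
#' @param replicate Biological replicate number.
#' @param analytical Analytical replicate number (default 1).
#' @param acq_order Acquisition-order index stored in the metadata.
#' @return A `gc2d_chromatogram`.
#' @export
simulate_run <- function(design, class_label, replicate, analytical = 1L,
                         acq_order = NA_integer_) {
  stopifnot(inherits(design, "study_design"))
  if (!class_label %in% names(design$classes))
    stop("unknown class label: ", class_label)
  run_key <- paste(class_label, replicate, analytical, sep = "/")
  run_seed <- (design$seed * 7919 + hash_string(run_key)) %% 2147483647
  with_local_seed(run_seed, {
    n_mod <- ceiling(design$run_end_min * 60 / design$p_m)
    n_pts <- round(design$p_m * design$acq_hz)
    n <- n_mod * n_pts * 316L
    cube <- if (design$baseline_sd > 0)
      pmax(rnorm(n, 0, design$baseline_sd), 0) else numeric(n)
    dim(cube) <- c(n_mod, n_pts, 316L)

    drift1 <- rnorm(1, 0, design$rt_jitter[["rt1"]])
    drift2 <- rnorm(1, 0, design$rt_jitter[["rt2"]])

    expect <- class_expectation(design, class_label)
    # run-level latent factors shared within correlated analyte groups
    for (g in design$correlated) {
      eta <- rnorm(1, 0, g$sdlog)
      sel <- intersect(g$analytes, names(expect))
      expect[sel] <- expect[sel] * exp(eta)
    }

    comp <- rbind(
      data.frame(name = design$analytes$name, cas = design$analytes$cas,
                 rt1 = design$analytes$rt1_min, rt2 = design$analytes$rt2_s,
                 volume = expect[design$analytes$name],
                 stringsAsFactors = FALSE),
      data.frame(name = design$unknowns$name, cas = design$unknowns$cas,
                 rt1 = design$unknowns$rt1_min, rt2 = design$unknowns$rt2_s,
                 volume = expect[design$unknowns$name],
                 stringsAsFactors = FALSE),
      data.frame(name = design$internal_standards$name,
                 cas = design$internal_standards$cas,
                 rt1 = design$internal_standards$rt1_min,
                 rt2 = design$internal_standards$rt2_s,
                 volume = design$internal_standards$volume,
                 stringsAsFactors = FALSE)
    )
    comp$volume <- comp$volume *
      exp(rnorm(nrow(comp), 0, design$response_sdlog))

    sig_mod <- design$peak_sigma[["mod"]]
    sig_pt <- design$peak_sigma[["s"]] * design$acq_hz
    apexes <- character(0)
    for (r in seq_len(nrow(comp))) {
      rt1 <- comp$rt1[r] * (1 + drift1) +
        rnorm(1, 0, design$rt_resid[["rt1"]])
      rt2 <- comp$rt2[r] * (1 + drift2) +
        rnorm(1, 0, design$rt_resid[["rt2"]])
      mod_c <- rt1 * 60 / design$p_m + 1
      pt_c <- rt2 * design$acq_hz + 1
      key <- paste(round(mod_c), round(pt_c))
      if (key %in% apexes)
        warning("co-eluting compounds at identical apex cell (",
                comp$name[r], "); volumes superpose", call. = FALSE)
      apexes <- c(apexes, key)
      b <- peak_block(dim(cube), mod_c, pt_c, sig_mod, sig_pt,
                      comp$volume[r], simulate_spectrum(comp$cas[r]))
      for (k in seq_along(b$ch))
        cube[b$i, b$j, b$ch[k]] <- cube[b$i, b$j, b$ch[k]] +
          b$block * b$frac[k]
    }
    gc2d_chromatogram(cube, p_m = design$p_m, acq_hz = design$acq_hz,
                      meta = list(sample_id = paste0(class_label, "_",
                                                     replicate,
                                                     if (analytical > 1) "b"),
                                  class_label = class_label,
                                  replicate_id = replicate,
                                  analytical_replicate = analytical,
                                  acq_order = acq_order,
                                  seed = run_seed))
  })
}

#' Simulate an n-alkane calibration run
#'
#' One run containing only the n-alkane ladder peaks (plus baseline noise),
#' at the stated first-dimension retention times, for linear retention-index
#' calibration. Retention times must increase strictly with carbon number.
#'
#' @param alkanes Named numeric vector: names are carbon numbers, values
#'   first-dimension retention times in minutes.
#' @param design Optional `study_design` supplying geometry and noise
#'   defaults.
#' @param rt2_s Second-dimension coordinate given to every alkane peak.
#' @param volume Planted volume per alkane.
#' @return A `gc2d_chromatogram`.
#' @export
simulate_alkane_run <- function(alkanes, design = NULL, rt2_s = 1.5,
                                volume = 5e6) {
  if (length(alkanes) == 0L) stop("empty alkane map")
  carbons <- as.integer(names(alkanes))
  if (anyNA(carbons)) stop("alkane names must be carbon numbers")
  o <- order(carbons)
  carbons <- carbons[o]; times <- as.numeric(alkanes[o])
  if (any(diff(times) <= 0))
    stop("alkane retention times must increase strictly with carbon number")
  p_m <- if (is.null(design)) 3.5 else design$p_m
  acq_hz <- if (is.null(design)) 20 else design$acq_hz
  baseline_sd <- if (is.null(design)) 5 else design$baseline_sd
  sig_mod <- if (is.null(design)) 2.5 else design$peak_sigma[["mod"]]
  sig_s <- if (is.null(design)) 0.06 else design$peak_sigma[["s"]]
  seed <- if (is.null(design)) 1L else design$seed
  with_local_seed(seed * 131 + 17, {
    n_mod <- ceiling((max(times) + 1.5) * 60 / p_m)
    n_pts <- round(p_m * acq_hz)
    n <- n_mod * n_pts * 316L
    cube <- if (baseline_sd > 0) pmax(rnorm(n, 0, baseline_sd), 0)
            else numeric(n)
    dim(cube) <- c(n_mod, n_pts, 316L)
    for (k in seq_along(carbons)) {
      b <- peak_block(dim(cube), times[k] * 60 / p_m + 1,
                      rt2_s * acq_hz + 1, sig_mod, sig_s * acq_hz, volume,
                      simulate_spectrum(paste0("ALK-", carbons[k])))
      for (q in seq_along(b$ch))
        cube[b$i, b$j, b$ch[q]] <- cube[b$i, b$j, b$ch[q]] +
          b$block * b$frac[q]
    }
    gc2d_chromatogram(cube, p_m = p_m, acq_hz = acq_hz,
                      meta = list(sample_id = "alkane_calibration",
                                  class_label = "calibration",
                                  carbons = carbons))
  })
}

#' Run table of a study design
#'
#' Expands the design into its 35-run layout (class, biological replicate,
#' analytical replicate) and assigns a seeded random acquisition order.
#' @param design A `study_design`.
#' @return Data frame, one row per run, in acquisition order.
#' @export
study_run_table <- function(design) {
  stopifnot(inherits(design, "study_design"))
  rows <- do.call(rbind, lapply(names(design$classes), function(cl) {
    data.frame(class_label = cl, replicate_id = seq_len(design$classes[[cl]]),
               analytical_replicate = 1L, stringsAsFactors = FALSE)
  }))
  if (length(design$extra_analytical)) {
    dup <- data.frame(class_label = design$extra_analytical,
                      replicate_id = 1L, analytical_replicate = 2L,
                      stringsAsFactors = FALSE)
    rows <- rbind(rows, dup)
  }
  ord <- with_local_seed(design$seed, sample.int(nrow(rows)))
  rows <- rows[ord, , drop = FALSE]
  rows$acq_order <- seq_len(nrow(rows))
  rows$sample_id <- paste0(rows$class_label, "_", rows$replicate_id,
                           ifelse(rows$analytical_replicate > 1, "b", ""))
  rownames(rows) <- NULL
  rows
}

#' Simulate a whole study
#'
#' Simulates every run of the design in its randomized acquisition order.
#' With `outdir` set, each run is written as a container file and dropped
#' from memory (the data cubes of a full study are large); otherwise the
#' chromatograms are returned in memory.
#'
#' @param design A `study_design`.
#' @param outdir Optional directory for run container files.
#' @return List with `meta` (the run table, plus `path` when `outdir` is
#'   used) and `runs` (list of `gc2d_chromatogram`, or `NULL`).
#' @export
simulate_study <- function(design, outdir = NULL) {
  meta <- study_run_table(design)
  runs <- if (is.null(outdir)) vector("list", nrow(meta)) else NULL
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    meta$path <- file.path(outdir, paste0(meta$sample_id, ".rds"))
  }
  for (r in seq_len(nrow(meta))) {
    ch <- simulate_run(design, meta$class_label[r], meta$replicate_id[r],
                       meta$analytical_replicate[r], acq_order = r)
    if (is.null(outdir)) runs[[r]] <- ch else write_run(ch, meta$path[r])
  }
  list(meta = meta, runs = runs)
}

#' Simulate a response-level feature table (no chromatograms)
#'
#' Draws feature responses directly from the generator's response model --
#' per-feature base level times class fold-change times log-normal noise --
#' without building data cubes. Used to study the operating characteristics
#' of the statistical layer (e.g. the null false-positive rate of the
#' Fisher-ratio sieve) at scales where full chromatogram simulation is
#' unnecessary.
#'
#' @param n_features Number of features.
#' @param classes Named replicate counts.
#' @param effect Optional fold-change matrix (classes x features); default
#'   all 1 (a null study).
#' @param response_sdlog Log-normal response SD.
#' @param seed Integer seed.
#' @return List with `responses` (features x samples), `classes` (per-sample
#'   labels).
#' @export
simulate_response_table <- function(n_features = 100,
                                    classes = c(herbage_low = 3,
                                                herbage_high = 3, con = 6,
                                                lbuc = 6, lpar = 6),
                                    effect = NULL,
                                    response_sdlog = 0.12, seed = 1L) {
  labels <- rep(names(classes), classes)
  with_local_seed(seed, {
    base <- 10^(6 + 0.8 * runif(n_features))
    eff <- if (is.null(effect))
      matrix(1, length(classes), n_features,
             dimnames = list(names(classes), NULL)) else effect
    resp <- vapply(labels, function(cl) {
      base * eff[cl, ] * exp(rnorm(n_features, 0, response_sdlog))
    }, numeric(n_features))
    resp <- matrix(resp, nrow = n_features,
                   dimnames = list(paste0("feature_", seq_len(n_features)),
                                   make.unique(labels)))
    list(responses = resp, classes = labels)
  })
}
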