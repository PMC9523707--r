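# Shared fixtures. Everything is generated in code; the only file fixture is
# the packaged target library.

packaged_library <- local({
  lib <- NULL
  function() {
    if (is.null(lib))
      lib <<- suppressWarnings(
        load_target_library(gcxgcfp_example("target_library.csv")))
    lib
  }
})

# A small, fast study design: four resolvable panel analytes in a 13-minute
# window, internal standards moved inside the window.
small_panel <- function() {
  lib <- packaged_library()
  idx <- match(c("1-Propanol", "Hexanal", "3-Methyl-2-butanol", "p-Xylene"),
               lib$name)
  p <- lib[idx, c("name", "cas", "chem_class", "rt1_min", "rt2_s", "it_exp")]
  rownames(p) <- NULL
  p$base_volume <- c(4e6, 2e6, 3e6, 2.5e6)
  p
}

small_is <- function() {
  data.frame(name = c("is_a", "is_b"), cas = c("IS-A", "IS-B"),
             rt1_min = c(8.0, 8.8), rt2_s = c(1.5, 1.6),
             volume = c(6e6, 6e6), stringsAsFactors = FALSE)
}

no_unknowns <- function() {
  data.frame(name = character(), cas = character(), rt1_min = numeric(),
             rt2_s = numeric(), base_volume = numeric(),
             stringsAsFactors = FALSE)
}

small_design <- function(classes = c(herbage_low = 2, lpar = 2), seed = 42,
                         ...) {
  p <- small_panel()
  study_design(analytes = p, classes = classes, extra_analytical = character(),
               effect = default_effect_matrix(p$name), unknowns = no_unknowns(),
               internal_standards = small_is(), correlated = list(),
               run_end_min = 13.5, seed = seed, ...)
}

# Deterministic clean design: one analyte, no noise of any kind.
clean_one_analyte_design <- function(seed = 5) {
  p <- small_panel()[1, ]
  study_design(analytes = p, classes = c(herbage_low = 1),
               extra_analytical = character(),
               effect = default_effect_matrix(p$name),
               unknowns = no_unknowns(), internal_standards = small_is(),
               correlated = list(), baseline_sd = 0, response_sdlog = 0,
               rt_jitter = c(rt1 = 0, rt2 = 0), rt_resid = c(rt1 = 0, rt2 = 0),
               run_end_min = 13.5, seed = seed)
}

# Build a gc2d_peaks object from bare coordinates/volumes plus spectra,
# for alignment tests that do not need chromatograms.
fake_peaks <- function(rt1, rt2, volume, spectra,
                       geometry = list(n_mod = 300, n_pts = 70, p_m = 3.5,
                                       acq_hz = 20)) {
  out <- data.frame(rt1_min = rt1, rt2_s = rt2, height = volume / 10,
                    volume = volume, snr = 1000,
                    base_peak_mz = vapply(spectra, base_peak, integer(1)),
                    mod = round(rt1 * 60 / geometry$p_m) + 1,
                    pt = round(rt2 * geometry$acq_hz) + 1)
  attr(out, "spectra") <- spectra
  attr(out, "footprints") <- replicate(length(rt1), integer(0),
                                       simplify = FALSE)
  attr(out, "noise") <- 1
  attr(out, "baseline") <- 0
  attr(out, "meta") <- list(sample_id = "fake")
  attr(out, "geometry") <- geometry
  class(out) <- c("gc2d_peaks", "data.frame")
  out
}

# Random stick spectrum through R's RNG (independent of simulate_spectrum).
random_spectrum <- function() {
  n <- sample(5:25, 1)
  mass_spectrum(sort(sample(35:350, n)), runif(n, 1, 999))
}

# Brute-force NIST-style weighted-cosine oracle: explicit loops over the
# full channel range, no vectorised shortcuts shared with the
# implementation.
brute_match_factor <- function(a, b, mz_weight = 1, int_power = 0.5,
                               reverse = FALSE) {
  ia <- numeric(316); ib <- numeric(316)
  for (k in seq_along(a$mz)) ia[a$mz[k] - 34] <- a$intensity[k]
  for (k in seq_along(b$mz)) ib[b$mz[k] - 34] <- b$intensity[k]
  num <- 0; da <- 0; db <- 0
  for (c in 1:316) {
    if (reverse && ib[c] == 0) next
    mz <- c + 34
    sa <- ia[c]^int_power * mz^mz_weight
    sb <- ib[c]^int_power * mz^mz_weight
    num <- num + sa * sb
    da <- da + sa^2
    db <- db + sb^2
  }
  if (da == 0 || db == 0) return(0L)
  as.integer(floor(999 * num^2 / (da * db) + 0.5))
}

# The full-scale closed-loop study used by the acceptance checks; built
# once per test session.
acceptance_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      design <- suppressWarnings(study_design(seed = 20220914))
      cache <<- list(design = design,
                     result = suppressWarnings(fingerprint_study(design)))
    }
    cache
  }
})
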