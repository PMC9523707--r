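make_run_peaks <- function(shift1 = 0, shift2 = 0, scale1 = 1, n = 8,
                           volumes = NULL) {
  # n synthetic compounds on a diagonal of the retention plane
  rt1 <- seq(6, 30, length.out = n) * scale1 + shift1
  rt2 <- seq(0.6, 2.2, length.out = n) + shift2
  spectra <- lapply(paste0("CMP-", seq_len(n)), simulate_spectrum)
  fake_peaks(rt1, rt2, volumes %||% rep(1e6, n), spectra)
}

template_of <- function(pk, window = c(0.3, 0.2)) {
  gcxgcfp:::new_template(
    data.frame(rt1_min = pk$rt1_min, rt2_s = pk$rt2_s),
    attr(pk, "spectra"),
    list(window = window, dmf_min = 750, rmf_min = 750))
}

test_that("template matching honours window and spectral gates", {
  base <- make_run_peaks()
  tmpl <- template_of(base)
  # identical run: everything matches, in order
  expect_identical(match_peaks(tmpl, base), seq_len(nrow(base)))
  # +0.1 min shift stays inside the +/-0.3 min window
  expect_identical(match_peaks(tmpl, make_run_peaks(shift1 = 0.1)),
                   seq_len(nrow(base)))
  # +1.0 min shift leaves the window: nothing matches
  expect_true(all(is.na(match_peaks(tmpl, make_run_peaks(shift1 = 1.0)))))
  # spectra inside the window but dissimilar: nothing matches
  alien <- make_run_peaks()
  attr(alien, "spectra") <- lapply(paste0("ALIEN-", 1:8), simulate_spectrum)
  expect_true(all(is.na(match_peaks(tmpl, alien))))
})

test_that("each peak is used at most once (greedy by DMF)", {
  base <- make_run_peaks(n = 4)
  tmpl <- template_of(base)
  # duplicate first entry: only one of the two entries can claim peak 1
  tmpl$entries <- rbind(tmpl$entries[1, ], tmpl$entries)
  tmpl$spectra <- c(tmpl$spectra[1], tmpl$spectra)
  m <- match_peaks(tmpl, base)
  expect_identical(anyDuplicated(m[!is.na(m)]), 0L)
})

test_that("reliable-peak rule keeps all-but-one presence", {
  runs <- c(replicate(5, make_run_peaks(), simplify = FALSE))
  # drop compound 3 from run 2 only -> present in 4/5 runs: retained;
  # drop compound 5 from runs 2 and 3 -> present in 3/5: dropped
  runs[[2]] <- runs[[2]][-c(3, 5), ]
  runs[[3]] <- runs[[3]][-5, ]
  tmpl <- build_template(runs)
  expect_identical(nrow(tmpl$entries), 7L)
  expect_error(build_template(runs[1]), "at least two runs")
})

test_that("the retention transform recovers a planted drift", {
  base <- make_run_peaks(n = 12)
  drifted <- make_run_peaks(n = 12, scale1 = 1.01, shift2 = 0.05)
  tr <- fit_retention_transform(
    list(rt1_min = drifted$rt1_min, rt2_s = drifted$rt2_s),
    list(rt1_min = base$rt1_min, rt2_s = base$rt2_s))
  mapped <- predict(tr, drifted$rt1_min, drifted$rt2_s)
  expect_equal(mapped$rt1_min, base$rt1_min, tolerance = 1e-6)
  expect_equal(mapped$rt2_s, base$rt2_s, tolerance = 1e-6)
  back <- predict(tr, base$rt1_min, base$rt2_s, inverse = TRUE)
  expect_equal(back$rt1_min, drifted$rt1_min, tolerance = 1e-6)
})

test_that("template matching with transform recovers runs beyond the window", {
  # 1.2% run-level stretch pushes late peaks ~0.35 min off; the fitted
  # transform must bring them all back
  runs <- list(make_run_peaks(n = 12),
               make_run_peaks(n = 12, scale1 = 1.012),
               make_run_peaks(n = 12, scale1 = 0.99, shift2 = 0.06))
  tmpl <- build_template(runs)
  expect_identical(nrow(tmpl$entries), 12L)
  expect_true(all(!is.na(attr(tmpl, "matches"))))
})

test_that("composites are per-point means of aligned rasters", {
  r <- matrix(rnorm(200, 100, 5), 20, 10)
  expect_equal(build_composite(list(r)), r)
  expect_equal(build_composite(list(r, r)), r)
  expect_equal(build_composite(list(r, 3 * r)), 2 * r)
  expect_error(build_composite(list()), "empty")
})

test_that("region delineation separates untargeted from covered regions", {
  # composite with three Gaussian blobs; template covers the first two
  g <- function(m, cx, cy, h) {
    for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m)))
      m[i, j] <- m[i, j] + h * exp(-((i - cx)^2 / 18 + (j - cy)^2 / 3.4))
    m
  }
  comp <- matrix(0, 120, 40)
  comp <- g(comp, 30, 12, 5000)
  comp <- g(comp, 60, 25, 8000)
  comp <- g(comp, 95, 15, 6000)   # the planted extra, not in the template
  set.seed(41); comp <- comp + abs(rnorm(length(comp), 0, 1))
  geometry <- list(p_m = 3.5, acq_hz = 20)
  spectra <- lapply(c("T-1", "T-2"), simulate_spectrum)
  tmpl <- gcxgcfp:::new_template(
    data.frame(rt1_min = c(29, 59) * 3.5 / 60, rt2_s = c(11, 24) / 20),
    spectra, list(window = c(0.3, 0.2), dmf_min = 750, rmf_min = 750))
  reg <- delineate_regions(comp, tmpl, geometry, snr_min = 100)
  expect_identical(sum(!reg$covered), 1L)
  unc <- reg[!reg$covered, ]
  expect_equal(unc$rt1_min, 94 * 3.5 / 60, tolerance = 0.1)
  # blank composite -> no regions
  blank <- matrix(abs(rnorm(4800, 0, 1)), 120, 40)
  expect_identical(nrow(delineate_regions(blank, tmpl, geometry)), 0L)
})

test_that("feature table: responses, missing flags and IS normalization", {
  spectra <- lapply(c("F-1", "F-2", "F-3"), simulate_spectrum)
  mk <- function(vol3) fake_peaks(c(10, 12, 14), c(0.8, 1.2, 1.6),
                                  c(9000, 11000, vol3), spectra)
  runs <- list(mk(5000), mk(5000)[-3, ])  # feature 3 missing in run 2
  tmpl <- build_template(runs, min_presence = 1)
  ft <- assemble_feature_table(
    tmpl, NULL, runs,
    meta = data.frame(sample_id = c("r1", "r2"), class_label = "con"),
    is_coords = data.frame(rt1_min = c(10, 12), rt2_s = c(0.8, 1.2)))
  expect_identical(sort(unique(ft$features$kind)), c("is", "untargeted"))
  f3 <- which(ft$features$rt1_min > 13)
  # % normalized response: 100 * 5000 / mean(9000, 11000)
  expect_equal(ft$normalized[f3, "r1"], 50)
  expect_identical(ft$responses[f3, "r2"], 0)
  expect_true(ft$missing[f3, "r2"])
  expect_false(ft$missing[f3, "r1"])
})

test_that("a run without any internal standard is an error", {
  spectra <- lapply(c("G-1", "G-2"), simulate_spectrum)
  mk <- function() fake_peaks(c(10, 12), c(0.8, 1.2), c(9000, 11000),
                              spectra)
  runs <- list(mk(), mk()[-c(1, 2), ])
  tmpl <- build_template(runs, min_presence = 1)
  expect_error(
    assemble_feature_table(
      tmpl, NULL, runs,
      meta = data.frame(sample_id = c("r1", "r2"), class_label = "con"),
      is_coords = data.frame(rt1_min = c(10, 12), rt2_s = c(0.8, 1.2))),
    "lacks both internal standards")
})

test_that("feature responses do not depend on run processing order", {
  runs <- list(make_run_peaks(volumes = seq(1e6, 8e6, length.out = 8)),
               make_run_peaks(shift1 = 0.05,
                              volumes = seq(2e6, 9e6, length.out = 8)),
               make_run_peaks(shift1 = -0.05,
                              volumes = seq(3e6, 10e6, length.out = 8)))
  meta <- data.frame(sample_id = c("a", "b", "c"), class_label = "con")
  ft1 <- assemble_feature_table(build_template(runs), NULL, runs,
                                meta = meta, is_coords = NULL)
  perm <- c(3, 1, 2)
  ft2 <- assemble_feature_table(build_template(runs[perm]), NULL, runs[perm],
                                meta = meta[perm, ], is_coords = NULL)
  o1 <- order(ft1$features$rt1_min)
  o2 <- order(ft2$features$rt1_min)
  expect_equal(ft1$responses[o1, c("a", "b", "c")],
               ft2$responses[o2, c("a", "b", "c")],
               tolerance = 1e-9, ignore_attr = TRUE)
})
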