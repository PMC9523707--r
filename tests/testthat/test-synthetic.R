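test_that("simulated spectra are deterministic, valid and dissimilar", {
  s1 <- simulate_spectrum("79-09-4")
  s2 <- simulate_spectrum("79-09-4")
  expect_identical(s1, s2)
  expect_identical(dmf(s1, s1), 999L)
  expect_true(length(s1$mz) >= 8 && length(s1$mz) <= 20)
  expect_identical(max(s1$intensity), 999)
  expect_true(all(s1$mz >= 35 & s1$mz <= 350))
  # different seed base -> different spectrum
  expect_false(identical(s1, simulate_spectrum("79-09-4", seed_base = 2)))
  # RNG state untouched
  set.seed(99); before <- .Random.seed
  invisible(simulate_spectrum("64-17-5"))
  expect_identical(.Random.seed, before)
})

test_that("noise-free planted Gaussian volume is recovered within 1%", {
  d <- clean_one_analyte_design()
  ch <- simulate_run(d, "herbage_low", 1)
  pk <- detect_peaks(ch)
  hit <- which(abs(pk$rt1_min - d$analytes$rt1_min) < 0.2 &
                 abs(pk$rt2_s - d$analytes$rt2_s) < 0.2)
  expect_length(hit, 1L)
  expect_equal(pk$volume[hit], d$analytes$base_volume, tolerance = 0.01)
})

test_that("the same seed reproduces a run exactly", {
  d <- small_design(seed = 7)
  ch1 <- simulate_run(d, "lpar", 1)
  ch2 <- simulate_run(d, "lpar", 1)
  expect_identical(ch1$cube, ch2$cube)
  d2 <- small_design(seed = 8)
  expect_false(identical(simulate_run(d2, "lpar", 1)$cube, ch1$cube))
})

test_that("alkane runs validate input and yield one peak per alkane", {
  expect_error(simulate_alkane_run(numeric(0)), "empty")
  expect_error(simulate_alkane_run(c(`10` = 10, `11` = 9)),
               "increase strictly")
  alk <- simulate_alkane_run(c(`10` = 10.0, `11` = 12.0))
  pk <- detect_peaks(alk)
  expect_identical(nrow(pk), 2L)
  expect_equal(sort(pk$rt1_min), c(10, 12), tolerance = 0.01)
})

test_that("full C9-C25 ladder run detects all 17 alkanes", {
  lad <- derive_alkane_ladder(packaged_library())
  alk <- simulate_alkane_run(setNames(lad$rt1_min, lad$carbons))
  cal <- calibrate_from_run(alk)
  expect_identical(length(cal$carbons), 17L)
  expect_equal(cal$rt1_min, lad$rt1_min, tolerance = 0.03)
})

test_that("QC expectation is the mean of the parent-class expectations", {
  expect_identical(qc_expectation(100, 300), 200)
  # through the generator: a design with split control classes
  p <- small_panel()
  eff <- matrix(1, 2, 4, dimnames = list(c("con_low", "con_high"), p$name))
  eff["con_low", 1] <- 2; eff["con_high", 1] <- 6
  d <- study_design(analytes = p, classes = c(con_low = 1, con_high = 1,
                                              qc = 1),
                    extra_analytical = character(), effect = eff,
                    qc_parents = c("con_low", "con_high"),
                    unknowns = no_unknowns(), internal_standards = small_is(),
                    correlated = list(), run_end_min = 13.5, seed = 1)
  e <- gcxgcfp:::class_expectation(d, "qc")
  expect_equal(unname(e[p$name[1]]), p$base_volume[1] * 4)  # mean(2, 6)
})

test_that("study layout has the configured runs and seeded order", {
  d <- suppressWarnings(study_design(seed = 3))
  rt <- study_run_table(d)
  expect_identical(nrow(rt), 35L)
  expect_identical(sum(rt$analytical_replicate == 2), 5L)
  expect_identical(as.vector(table(rt$class_label)[c("con", "qc")]),
                   c(7L, 6L))
  rt2 <- study_run_table(suppressWarnings(study_design(seed = 3)))
  expect_identical(rt, rt2)
  expect_false(identical(rt$sample_id,
                         study_run_table(suppressWarnings(study_design(seed = 4)))$sample_id))
})

test_that("retention %RSD across replicates converges to the configured jitter", {
  d <- small_design(classes = c(con = 30), seed = 21)
  rt1 <- matrix(NA_real_, 30, nrow(d$analytes))
  for (r in 1:30) {
    pk <- detect_peaks(simulate_run(d, "con", r))
    for (a in seq_len(nrow(d$analytes))) {
      hit <- which(abs(pk$rt1_min - d$analytes$rt1_min[a]) < 0.3 &
                     abs(pk$rt2_s - d$analytes$rt2_s[a]) < 0.3)
      if (length(hit) == 1) rt1[r, a] <- pk$rt1_min[hit]
    }
  }
  expect_true(all(colSums(!is.na(rt1)) >= 28))
  rsds <- apply(rt1, 2, function(x) rsd(x[!is.na(x)]))
  # configured first-dimension jitter is 0.8% (run-level drift dominates)
  expect_true(all(rsds > 0.8 * 0.75 & rsds < 0.8 * 1.25),
              info = paste(round(rsds, 3), collapse = ", "))
})

test_that("response-table generator is seeded and honours effects", {
  r1 <- simulate_response_table(n_features = 20, seed = 5)
  r2 <- simulate_response_table(n_features = 20, seed = 5)
  expect_identical(r1, r2)
  eff <- matrix(1, 5, 20, dimnames = list(
    c("herbage_low", "herbage_high", "con", "lbuc", "lpar"), NULL))
  eff["lpar", 1] <- 50
  r3 <- simulate_response_table(n_features = 20, effect = eff, seed = 6)
  m <- tapply(r3$responses[1, ], r3$classes, mean)
  expect_gt(m[["lpar"]] / m[["con"]], 25)
})
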