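test_that("van den Dool & Kratz interpolation matches hand values", {
  cal <- alkane_calibration(10:13, c(10.0, 12.0, 14.38, 17.48))
  expect_equal(retention_index(10.0, cal), 1000)
  expect_equal(retention_index(11.0, cal), 1050)
  expect_equal(retention_index(15.00, cal), 1220)
  expect_equal(retention_index(12.0, cal), 1100)   # anchor point
})

test_that("out-of-ladder times are flagged, not extrapolated", {
  cal <- alkane_calibration(c(10, 11), c(10, 12))
  out <- retention_index(c(9, 10.5, 13), cal)
  expect_true(is.na(out[1]) && is.na(out[3]))
  expect_equal(out[2], 1025)
  expect_identical(attr(out, "out_of_range"), c(TRUE, FALSE, TRUE))
})

test_that("a missing homologue interpolates across a 200-unit span", {
  cal <- alkane_calibration(c(10, 12), c(10, 14))
  expect_equal(retention_index(12, cal), 1100)
  expect_equal(retention_index(13, cal), 1150)
})

test_that("retention_index is strictly increasing within the ladder", {
  cal <- derive_alkane_ladder(packaged_library())
  t <- seq(min(cal$rt1_min), max(cal$rt1_min), length.out = 500)
  ri <- retention_index(t, cal)
  expect_true(all(diff(ri) > 0))
})

test_that("calibration input validation", {
  expect_error(alkane_calibration(c(10, 11), c(12, 10)), "increase strictly")
  expect_error(alkane_calibration(c(10, 10), c(10, 11)), "duplicate")
  expect_error(alkane_calibration(10, 10), "two alkane anchors")
})

test_that("the derived ladder reproduces the library's own indices", {
  lib <- packaged_library()
  cal <- derive_alkane_ladder(lib)
  ok <- !lib$it_unbounded & !is.na(lib$it_exp)
  ri <- retention_index(lib$rt1_min[ok], cal)
  dev <- ri - lib$it_exp[ok]
  # transcription noise aside, the bulk of the table must be consistent
  expect_lt(median(abs(dev), na.rm = TRUE), 3)
  expect_gt(mean(abs(dev) <= 10, na.rm = TRUE), 0.95)
})

test_that("identity assignment applies spectral and index gates", {
  lib <- packaged_library()
  cal <- derive_alkane_ladder(lib)
  spectra <- library_spectra(lib)
  target <- lib[lib$name == "Propionic acid", ]
  peak <- list(rt1_min = target$rt1_min, spectrum = spectra[[target$cas]])
  hit <- assign_identity(peak, lib, cal, spectra = spectra)
  expect_identical(hit$name, "Propionic acid")
  expect_identical(hit$dmf, 999)
  expect_lte(hit$it_dev, 1)

  # index deviation beyond the tolerance: no assignment
  far <- list(rt1_min = target$rt1_min + 0.8, spectrum = peak$spectrum)
  expect_null(assign_identity(far, lib, cal, spectra = spectra))
  # deviation of ~25 units rejected at +/-10 but allowed at the +/-15
  # table convention only if within it
  dev25 <- list(rt1_min = target$rt1_min + 25 * 0.0272,
                spectrum = peak$spectrum)
  expect_null(assign_identity(dev25, lib, cal, spectra = spectra,
                              it_tol = 10))

  # RMF gate: a spectrum with strong extra channels keeps DMF moderate but
  # must fail the reverse gate if reference channels are distorted
  distorted <- spectra[[target$cas]]
  d2 <- mass_spectrum(distorted$mz,
                      rev(distorted$intensity))
  gated <- assign_identity(list(rt1_min = target$rt1_min, spectrum = d2),
                           lib, cal, spectra = spectra)
  expect_null(gated)
})

test_that("identity assignment is invariant to intensity scaling", {
  lib <- packaged_library()
  cal <- derive_alkane_ladder(lib)
  spectra <- library_spectra(lib)
  target <- lib[lib$name == "Linalool", ]
  s <- spectra[[target$cas]]
  for (c in c(0.01, 1, 250)) {
    hit <- assign_identity(
      list(rt1_min = target$rt1_min,
           spectrum = mass_spectrum(s$mz, s$intensity * c)),
      lib, cal, spectra = spectra)
    expect_identical(hit$name, "Linalool")
  }
})

test_that("closed loop: a simulated library compound is assigned itself", {
  lib <- packaged_library()
  cal <- derive_alkane_ladder(lib)
  d <- clean_one_analyte_design()   # 1-Propanol at its tabulated coordinates
  ch <- simulate_run(d, "herbage_low", 1)
  pk <- detect_peaks(ch)
  hit <- which(abs(pk$rt1_min - d$analytes$rt1_min) < 0.2 &
                 abs(pk$rt2_s - d$analytes$rt2_s) < 0.2)
  res <- assign_identity(pk[hit, ], lib, cal)
  expect_identical(res$name, "1-Propanol")
  expect_gte(res$rmf, 950)
})
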