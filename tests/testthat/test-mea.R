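test_that("Fridericia correction is the cube-root rate normalization", {
  expect_equal(fpdc_fridericia(0.4, 1.0), 0.4)
  expect_equal(fpdc_fridericia(0.4, 8.0), 0.2)
  expect_equal(fpdc_fridericia(0.4, 0.8), 0.4 / 0.8^(1 / 3))
  expect_error(fpdc_fridericia(-0.1, 1), "positive")
  expect_error(fpdc_fridericia(0.4, 0), "positive")
})

test_that("the formula is only meaningful in seconds: rescaling both
          inputs does not rescale FPDc proportionally", {
  f_s <- fpdc_fridericia(0.4, 0.9)
  f_ms <- fpdc_fridericia(400, 900)   # misapplied in milliseconds
  expect_false(isTRUE(all.equal(f_ms, 1000 * f_s)))
  # correct conversion back to seconds recovers the value
  expect_equal(fpdc_fridericia(400 / 1000, 900 / 1000), f_s)
})

test_that("amplitude QC retains boundary values and rejects below", {
  wells <- data.frame(depol_uV = c(250, 199, 200, 300),
                      repol_uV = c(25, 25, 20, 19))
  kept <- qc_filter(wells)
  expect_equal(nrow(kept), 2)     # (250,25) and the exact-boundary well
  expect_true(all(kept$depol_uV >= 200 & kept$repol_uV >= 20))
  expect_equal(nrow(qc_filter(wells[0, ])), 0)
})

test_that("vehicle correction subtracts drift in percentage points", {
  expect_equal(vehicle_corrected_response(1, 1, 1, 1), 100)
  # treated at 120% of baseline while vehicle drifted to 105%
  expect_equal(vehicle_corrected_response(1.2, 1, 1.05, 1), 115)
  expect_error(vehicle_corrected_response(1, 0, 1, 1), "positive")
})

test_that("correction inverts the generator's injected drift exactly", {
  wells <- gen_mea_crc(seed = 9, well_sd_pct = 0,
                       drift_pct_per_step = -2)
  crc <- build_concentration_response(wells)
  tr <- attr(wells, "truth")
  truth <- 100 + tr$emax_pct * crc$conc_uM^tr$hill /
    (tr$ec50_uM^tr$hill + crc$conc_uM^tr$hill)
  expect_equal(crc$response_mean, truth, tolerance = 1e-10)
})

test_that("irregular concentrations are excluded with reasons and low-n
          concentrations dropped", {
  wells <- gen_mea_crc(seed = 2)
  crc <- build_concentration_response(wells)
  excl <- attr(crc, "excluded")
  expect_true(all(c(3, 10) %in% excl$conc_uM[
    excl$reason == "arrhythmia-like waveform"]))
  expect_true(30 %in% excl$conc_uM[excl$reason == "beating arrest"])
  expect_false(any(crc$conc_uM >= 3))
  expect_true(all(crc$n >= 3))
  # dropping one experiment leaves n = 2 < 3: everything excluded
  w1 <- wells[wells$experiment %in% c("exp1", "exp2"), ]
  expect_error(suppressWarnings(build_concentration_response(w1)))
})

test_that("MEA CSV reader round-trips the generator output", {
  wells <- gen_mea_crc(seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(wells, path, row.names = FALSE)
  back <- read_mea_csv(path)
  expect_equal(back$fpd_s, wells$fpd_s)
  expect_identical(back$is_vehicle, wells$is_vehicle)
})

test_that("significance annotation flags strong effects only", {
  set.seed(17)
  resp <- do.call(rbind, lapply(1:6, function(e) data.frame(
    conc_uM = c(0.01, 1), response = c(100 + stats::rnorm(1, 0, 0.5),
                                       130 + stats::rnorm(1, 0, 0.5)))))
  out <- response_significance(resp)
  expect_equal(out$signif[out$conc_uM == 1], "***")
  expect_equal(out$signif[out$conc_uM == 0.01], "")
})
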