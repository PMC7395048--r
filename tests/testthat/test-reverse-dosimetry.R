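test_that("the dose-Cmax map is monotone and matches direct simulation", {
  map <- cached_map()
  expect_true(all(diff(map$cmax) > 0))
  # interpolation against a simulation at an off-grid dose
  ss <- cached_metrics(45, n_days = 30)
  expect_equal(map$predict(45), ss$Cmax_heart_venous_uM,
               tolerance = 1e-3)
  expect_equal(map$invert(ss$Cmax_heart_venous_uM), 45,
               tolerance = 1e-3)
  expect_error(map$invert(max(map$cmax) * 10), "outside")
})

test_that("forward simulation and dose inversion agree within 0.1%", {
  mod <- default_model()
  D <- 60
  ss <- cached_metrics(D, n_days = 30)
  target <- ss$Cmax_heart_venous_uM * mod$methadone$fu_p /
    mod$methadone$BPr
  Dinv <- dose_for_target(mod, "methadone", target, BW = 70)
  expect_equal(Dinv, D, tolerance = 1e-3)
  expect_equal(dose_for_target(mod, "methadone", 0), 0)
})

test_that("unreachable targets raise an out-of-range error", {
  expect_error(dose_for_target(default_model(), "methadone", 1e6,
                               bracket = c(1e-3, 10), n_days = 5),
               "outside the achievable range")
})

test_that("translated curves preserve responses and are ordered by
          fu_p", {
  crc <- noise_free_crc()
  map <- cached_map()
  preds <- translate_crc_scenarios(crc, default_model(), map = map)
  for (p in preds) {
    expect_true(all(diff(p$dose_mg_day) > 0))
    expect_equal(p$response_mean, crc$response_mean[
      crc$conc_uM %in% p$conc_uM])
  }
  # lower fu_p -> higher predicted dose at the same response
  dose_at_first <- vapply(preds, function(p) p$dose_mg_day[1], numeric(1))
  fup <- vapply(methadone_binding_scenarios(), function(s) s$fu_p,
                numeric(1))
  expect_true(all(diff(dose_at_first[order(fup)]) < 0))
  # exact scaling: doses differ by the fu_p ratio at equal response
  expect_equal(preds[[1]]$dose_mg_day[1] / preds[[2]]$dose_mg_day[1],
               map$invert(invitro_to_total_blood(
                 crc$conc_uM[1], methadone_binding_scenarios()[[1]])) /
                 map$invert(invitro_to_total_blood(
                   crc$conc_uM[1], methadone_binding_scenarios()[[2]])))
})

test_that("doubling in vitro concentrations doubles predicted doses in
          the linear regime", {
  crc <- concentration_response(conc_uM = c(0.02, 0.05, 0.1, 0.2),
                                response_mean = c(101, 103, 106, 112),
                                response_sd = 2, n = 3)
  sc <- methadone_binding_scenarios()[["Simcyp 0.15"]]
  map <- cached_map()
  p1 <- translate_crc(crc, sc, default_model(), map = map)
  crc2 <- crc; crc2$conc_uM <- crc$conc_uM * 2
  p2 <- translate_crc(crc2, sc, default_model(), map = map)
  expect_equal(p2$dose_mg_day / p1$dose_mg_day, rep(2, 4),
               tolerance = 0.01)
})

test_that("identity scenario maps a concentration to the dose with that
          total blood Cmax", {
  mod <- default_model()
  sc_id <- binding_scenario(fu_m = mod$methadone$fu_p / mod$methadone$BPr,
                            fu_p = mod$methadone$fu_p,
                            BPr = mod$methadone$BPr)
  map <- cached_map()
  crc <- concentration_response(conc_uM = c(0.05, 0.1, 0.5, 1),
                                response_mean = c(102, 105, 115, 125),
                                response_sd = 2, n = 3)
  pred <- translate_crc(crc, sc_id, mod, map = map)
  expect_equal(pred$dose_mg_day, map$invert(crc$conc_uM),
               tolerance = 1e-10)
})

test_that("BMDL10 of the translated curve decreases as fu_p increases", {
  crc <- noise_free_crc()
  crc$response_sd <- 5
  preds <- translate_crc_scenarios(crc, default_model(),
                                   map = cached_map())
  bmdl <- vapply(preds, function(p) {
    est <- model_averaged_bmd(fit_families(p), BMR = 0.10,
                              n_bootstrap = 40, seed = 1)
    est$BMDL
  }, numeric(1))
  fup <- vapply(methadone_binding_scenarios(), function(s) s$fu_p,
                numeric(1))
  expect_true(all(diff(bmdl[order(fup)]) < 0))
})

test_that("QTc percent of baseline uses the population default", {
  expect_equal(qtc_percent(407), 100)
  expect_equal(qtc_percent(450, 407), 100 * 450 / 407)
  expect_equal(qtc_percent(405, 405), 100)
})
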