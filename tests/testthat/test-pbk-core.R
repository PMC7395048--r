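test_that("a zero dose yields identically zero concentrations", {
  sim <- pbk_simulate(default_model(), dose_regimen(0, n_days = 2))
  expect_equal(max(abs(sim$m_conc_ven)), 0)
  expect_equal(max(abs(sim$e_conc_ven)), 0)
  expect_equal(mass_balance(sim), 0)
})

test_that("mass is conserved to 1e-6 across the dose range", {
  for (dose in c(0.1, 70, 3000)) {
    sim <- cached_sim(dose, n_days = 10)
    expect_lt(mass_balance(sim), 1e-6)
  }
})

test_that("mass-balance residual is stable under grid refinement", {
  params <- default_model()
  r1 <- mass_balance(pbk_simulate(params, dose_regimen(70, n_days = 3),
                                  points_per_interval = 100))
  r2 <- mass_balance(pbk_simulate(params, dose_regimen(70, n_days = 3),
                                  points_per_interval = 200))
  expect_lt(abs(r1 - r2), 1e-8)
})

test_that("kinetics are dose-proportional at low dose and supralinear
          near metabolic saturation", {
  c1 <- cached_metrics(1, n_days = 20)$Cmax_blood_uM
  c2 <- cached_metrics(2, n_days = 20)$Cmax_blood_uM
  expect_equal(c2 / c1, 2, tolerance = 0.01)
  c2000 <- cached_metrics(2000, n_days = 20)$Cmax_blood_uM
  expect_gt(c2000 / 2000, c1 / 1)   # saturation raises normalized exposure
})

test_that("steady-state Cmax is strictly increasing in dose", {
  doses <- c(1, 2, 20, 70, 2000)
  cmax <- vapply(doses, function(d)
    cached_metrics(d, n_days = 20)$Cmax_blood_uM, numeric(1))
  expect_true(all(diff(cmax) > 0))
})

test_that("steady state is reached within 30 daily doses", {
  sim <- cached_sim(70, n_days = 31)
  cc <- sim$m_conc_ven
  t_end <- max(sim$time_h)
  c_last <- max(cc[sim$time_h >= t_end - 24])
  c_prev <- max(cc[sim$time_h >= t_end - 48 & sim$time_h <= t_end - 24])
  expect_lt(abs(c_last - c_prev) / c_last, 0.005)
})

test_that("EDDP is secondary: zero at t0 and formed 1:1 from metabolism", {
  sim <- cached_sim(70, n_days = 10)
  expect_equal(sim$e_conc_ven[1], 0)
  # total EDDP ever present equals methadone cumulatively metabolized
  last <- sim[nrow(sim), ]
  e_total <- last$e_liv + last$e_fat + last$e_lun + last$e_kid +
    last$e_hrt + last$e_slw + last$e_rpd + last$e_art + last$e_ven +
    last$e_urn + last$e_bil
  expect_equal(e_total, last$m_met, tolerance = 1e-8)
  # EDDP lags methadone: its venous concentration peaks later on day 1
  day1 <- sim[sim$time_h <= 24, ]
  expect_gt(day1$time_h[which.max(day1$e_conc_ven)],
            day1$time_h[which.max(day1$m_conc_ven)])
})

test_that("simulation refuses flow fractions that do not sum to 1", {
  mod <- default_model()
  mod$physiology$QLc <- mod$physiology$QLc * 1.05
  expect_error(pbk_simulate(mod, dose_regimen(70, n_days = 1)), "sum to 1")
  # explicit override allowed (used by one-at-a-time sensitivity)
  sim <- pbk_simulate(mod, dose_regimen(70, n_days = 1),
                      check_flows = FALSE)
  expect_s3_class(sim, "pbk_sim")
})

test_that("interval metrics: trapezoidal AUC matches the closed form on a
          mono-exponential decay at the default grid density", {
  k <- 0.2; C0 <- 5
  tt <- seq(0, 24, length.out = 101)   # default 100 points per interval
  auc_trap <- sum(diff(tt) * (head(C0 * exp(-k * tt), -1) +
                                (C0 * exp(-k * tt))[-1]) / 2)
  auc_exact <- C0 / k * (1 - exp(-k * 24))
  expect_equal(auc_trap, auc_exact, tolerance = 1e-3)
})

test_that("steady-state metrics are self-consistent", {
  ss <- cached_metrics(70, n_days = 20)
  expect_equal(ss$Cmax_blood_ng_per_ml, ss$Cmax_blood_uM * 309.45)
  mod <- default_model()
  expect_equal(ss$Cmax_unbound_blood_uM,
               ss$Cmax_blood_uM * mod$methadone$fu_p / mod$methadone$BPr)
  sim <- cached_sim(70, n_days = 20)
  idx <- sim$time_h >= max(sim$time_h) - 24
  expect_gte(ss$Cmax_blood_uM, mean(sim$m_conc_ven[idx]))
  expect_error(steady_state_metrics(sim, "emdp"))
})

test_that("EDDP clearance fitting recovers a known parameter", {
  mod <- default_model()
  mod$clearance$RCLeddp <- 10
  target <- steady_state_metrics(
    pbk_simulate(mod, dose_regimen(57.5, n_days = 12)),
    "eddp")$Cmax_blood_uM
  fit <- fit_eddp_clearance(default_model(), 57.5, BW = 70,
                            target_blood_cmax_eddp = target,
                            free_param = "RCLeddp", n_days = 12)
  expect_equal(fit$RCLeddp, 10, tolerance = 0.01)
  expect_error(
    fit_eddp_clearance(default_model(), 57.5, 70, target,
                       free_param = "both"),
    "under-determined")
})

test_that("tidy export carries consistent units", {
  sim <- cached_sim(70, n_days = 10)
  tidy <- pbk_sim_tidy(sim)
  expect_setequal(names(tidy), c("time_h", "compound", "compartment",
                                 "amount_umol", "conc_uM",
                                 "conc_ng_per_ml"))
  liver <- tidy[tidy$compound == "methadone" &
                  tidy$compartment == "liver", ]
  expect_equal(liver$conc_ng_per_ml, liver$conc_uM * 309.45)
  ven <- tidy[tidy$compound == "methadone" &
                tidy$compartment == "venous_blood", ]
  expect_equal(ven$conc_uM, sim$m_conc_ven)
})
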