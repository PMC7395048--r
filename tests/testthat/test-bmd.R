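hill_mean <- function(x, a, b, c, d) a * (1 + (c - 1) * x^d / (b^d + x^d))

test_that("noise-free Hill data are recovered to 4 significant digits", {
  x <- c(0.01, 0.03, 0.1, 0.3, 1, 3)
  dat <- data.frame(dose = x, mean = hill_mean(x, 100, 0.5, 1.4, 1.2),
                    sd = 2, n = 4)
  fit <- fit_family(dat, "hill")
  expect_equal(fit$theta$a, 100, tolerance = 1e-4)
  expect_equal(fit$theta$b, 0.5, tolerance = 1e-4)
  expect_equal(fit$theta$c, 1.4, tolerance = 1e-4)
  expect_equal(fit$theta$d, 1.2, tolerance = 1e-4)
})

test_that("flat data carry a no-trend flag and refuse a BMD", {
  dat <- data.frame(dose = c(0.1, 0.3, 1, 3), mean = rep(100, 4),
                    sd = 3, n = 4)
  fit <- fit_family(dat, "hill")
  expect_true(fit$no_trend)
  expect_error(model_averaged_bmd(list(fit), BMR = 0.2), "no dose-related")
})

test_that("a single converged model gets full weight", {
  x <- c(0.03, 0.1, 0.3, 1, 3)
  dat <- data.frame(dose = x, mean = hill_mean(x, 100, 0.5, 1.5, 1.5),
                    sd = 2, n = 4)
  fit <- fit_family(dat, "hill")
  est <- model_averaged_bmd(list(fit), BMR = 0.2, n_bootstrap = 10,
                            seed = 1)
  expect_equal(unname(est$weights), 1)
  expect_equal(est$BMD, unname(est$per_model_bmd), tolerance = 1e-8)
})

test_that("model-averaged BMD matches the analytic Hill inversion on
          noise-free data", {
  a <- 100; b <- 0.6; cc <- 1.6; dd <- 1.5
  x <- c(0.01, 0.03, 0.1, 0.3, 1, 3, 10)
  dat <- data.frame(dose = x, mean = hill_mean(x, a, b, cc, dd),
                    sd = 2, n = 4)
  # analytic dose with a 20% increase over control:
  # (c-1) x^d/(b^d+x^d) = 0.2  =>  x = b (0.2/(c-1-0.2))^(1/d)
  bmd_true <- b * (0.2 / (cc - 1 - 0.2))^(1 / dd)
  est <- model_averaged_bmd(fit_families(dat), BMR = 0.2,
                            n_bootstrap = 30, seed = 1)
  expect_equal(est$BMD, bmd_true, tolerance = 0.01)
  expect_true(est$BMDL <= est$BMD && est$BMD <= est$BMDU)
  expect_equal(sum(est$weights), 1)
})

test_that("BMD ordering and equivariance invariants hold on seeded
          synthetic curves", {
  for (s in 1:5) {
    crc <- build_concentration_response(gen_mea_crc(seed = s))
    est <- bmc20(crc, n_bootstrap = 25, seed = s)
    expect_true(est$BMDL <= est$BMD && est$BMD <= est$BMDU)
    # dose-unit equivariance: concentrations in nM scale the BMD by 1000
    crc_nM <- crc
    crc_nM$conc_uM <- crc$conc_uM * 1000
    est_nM <- bmc20(crc_nM, n_bootstrap = 25, seed = s)
    expect_equal(est_nM$BMD / est$BMD, 1000, tolerance = 0.01)
    # larger BMR requires a larger dose on an increasing curve
    fits <- fit_families(crc)
    b10 <- model_averaged_bmd(fits, 0.10, n_bootstrap = 1, seed = 1)
    b20 <- model_averaged_bmd(fits, 0.20, n_bootstrap = 1, seed = 1)
    expect_gt(b20$BMD, b10$BMD)
  }
})

test_that("bootstrap confidence limits are reproducible under a seed", {
  crc <- build_concentration_response(gen_mea_crc(seed = 3))
  e1 <- bmc20(crc, n_bootstrap = 40, seed = 7)
  e2 <- bmc20(crc, n_bootstrap = 40, seed = 7)
  expect_identical(e1$BMDL, e2$BMDL)
  expect_identical(e1$BMDU, e2$BMDU)
})

test_that("Hill data favour the Hill family over the exponential in AIC
          on most noisy replicates", {
  wins <- 0L
  for (s in 1:60) {
    x <- c(0.01, 0.05, 0.2, 0.5, 1, 3)
    mu <- hill_mean(x, 100, 0.4, 1.6, 3)   # steep: distinguishable
    set.seed(s)
    dat <- data.frame(dose = x, mean = mu + stats::rnorm(6, 0, 1),
                      sd = 2, n = 4)
    fh <- fit_family(dat, "hill")
    fe <- fit_family(dat, "exponential-3")
    wins <- wins + (fh$AIC <= fe$AIC)
  }
  expect_gte(wins, 54)   # >= 90% of replicates
})

test_that("control-only or degenerate inputs error cleanly", {
  expect_error(bmc20(data.frame(conc_uM = c(0, 0, 0, 0),
                                response_mean = rep(100, 4),
                                response_sd = 1, n = 3)))
  expect_error(fit_family(data.frame(dose = c(1, 2, 3), mean = 1:3,
                                     sd = 1, n = 2), "hill"),
               "4 dose levels")
})

test_that("4PL fitting recovers its own curve and the EC50 midpoint", {
  x <- c(0.01, 0.03, 0.1, 0.3, 1, 3, 10)
  y <- 100 + (160 - 100) / (1 + (0.5 / x)^1.3)
  fit <- fit_4pl(x, y)
  expect_equal(fit$lower, 100, tolerance = 1e-4)
  expect_equal(fit$upper, 160, tolerance = 1e-4)
  expect_equal(fit$EC50, 0.5, tolerance = 1e-4)
  expect_equal(fit$slope, 1.3, tolerance = 1e-4)
  expect_equal(predict_4pl(fit, fit$EC50), (fit$lower + fit$upper) / 2,
               tolerance = 1e-6)
  # seeded noisy recovery within 10%
  set.seed(11)
  fitn <- fit_4pl(rep(x, 3), rep(y, 3) + stats::rnorm(21, 0, 2))
  expect_equal(fitn$EC50, 0.5, tolerance = 0.1)
})
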