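mm_rate <- function(S, Vmax, Km) Vmax * S / (Km + S)
design_8pt <- c(10, 25, 50, 100, 250, 500, 1000, 1500)

test_that("noise-free Michaelis-Menten data are recovered exactly", {
  fit <- fit_michaelis_menten(substrate_uM = design_8pt,
                              rate = mm_rate(design_8pt, 0.82, 275))
  expect_equal(fit$Vmax, 0.82, tolerance = 1e-5)
  expect_equal(fit$Km, 275, tolerance = 1e-5)
  # midpoint identity: fitted curve at S = Km gives Vmax/2
  expect_equal(mm_rate(fit$Km, fit$Vmax, fit$Km), fit$Vmax / 2)
})

test_that("catalytic efficiency is Vmax/Km x 1000", {
  expect_equal(catalytic_efficiency(0.82, 275), 2.98, tolerance = 0.002)
  expect_equal(catalytic_efficiency(1, 1000), 1.0)
  expect_error(catalytic_efficiency(1, 0), "Km")
})

test_that("noisy fits agree with a brute-force RSS grid oracle", {
  d <- gen_mm_incubation(seed = 42, cv = 0.05, n_replicates = 3)
  fit <- fit_michaelis_menten(d)
  expect_equal(fit$Vmax, 0.82, tolerance = 0.10)
  expect_equal(fit$Km, 275, tolerance = 0.10)
  # independent oracle: exhaustive RSS over a (Vmax, Km) lattice
  grid <- expand.grid(Vmax = seq(0.6, 1.1, length.out = 81),
                      Km = seq(150, 450, length.out = 81))
  rss <- vapply(seq_len(nrow(grid)), function(i)
    sum((d$rate_nmol_min_mg -
           mm_rate(d$substrate_uM, grid$Vmax[i], grid$Km[i]))^2),
    numeric(1))
  best <- grid[which.min(rss), ]
  expect_equal(fit$Vmax, best$Vmax, tolerance = 0.01)
  expect_equal(fit$Km, best$Km, tolerance = 0.02)
  expect_lte(fit$rss, min(rss))   # optimizer at least as good as the grid
})

test_that("fit is scale-equivariant in the rates", {
  d <- gen_mm_incubation(seed = 5, cv = 0.05)
  f1 <- fit_michaelis_menten(d)
  d2 <- d; d2$rate_nmol_min_mg <- 3 * d2$rate_nmol_min_mg
  f2 <- fit_michaelis_menten(d2)
  expect_equal(f2$Vmax, 3 * f1$Vmax, tolerance = 1e-6)
  expect_equal(f2$Km, f1$Km, tolerance = 1e-6)
})

test_that("parameter recovery is nearly unbiased at the 8-point design", {
  est <- t(vapply(1:100, function(s) {
    f <- fit_michaelis_menten(gen_mm_incubation(seed = s, cv = 0.05))
    c(f$Vmax, f$Km)
  }, numeric(2)))
  expect_lt(abs(stats::median(est[, 1]) / 0.82 - 1), 0.03)
  expect_lt(abs(stats::median(est[, 2]) / 275 - 1), 0.08)
})

test_that("Km far beyond the tested range is flagged unreliable", {
  S <- c(10, 20, 40, 80)          # all far below the true Km
  expect_warning(
    fit <- fit_michaelis_menten(substrate_uM = S,
                                rate = mm_rate(S, 1, 5e4)),
    "unreliable")
  expect_false(fit$reliable)
})

test_that("fitting preconditions are enforced", {
  expect_error(fit_michaelis_menten(substrate_uM = c(1, 2, 3),
                                    rate = c(0.1, 0.2, 0.3)),
               ">= 4 distinct")
})

test_that("in vivo Vmax scaling is linear and matches direct arithmetic", {
  expect_equal(scale_vmax_in_vivo(0.82, 32, 0.0257, 70),
               0.82 * 60 / 1000 * 32 * 0.0257 * 70 * 1000)
  expect_equal(scale_vmax_in_vivo(0.82, 32, 0.0257, 70), 2832,
               tolerance = 3e-4)
  expect_equal(scale_vmax_in_vivo(0, 32, 0.0257, 70), 0)
  expect_equal(scale_vmax_in_vivo(0.82, 32, 0.0257, 140),
               2 * scale_vmax_in_vivo(0.82, 32, 0.0257, 70))
})

test_that("intestinal rates below the floor are reported negligible", {
  out <- assess_intestinal_rates(c(0.058, 0.057), c(0.80, 0.81))
  expect_true(out$negligible)
  out2 <- assess_intestinal_rates(0.2, 0.8)
  expect_false(out2$negligible)
})

test_that("incubation CSV round-trips through the reader", {
  d <- gen_mm_incubation(seed = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(as.data.frame(d), path, row.names = FALSE)
  back <- read_incubation_csv(path)
  expect_equal(back$rate_nmol_min_mg, d$rate_nmol_min_mg)
  expect_s3_class(back, "incubation")
})
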