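test_that("fraction unbound is the buffer/sample ratio", {
  expect_equal(fraction_unbound(1, 1)$fu, 1)
  expect_equal(fraction_unbound(0.5, 1)$fu, 0.5)
  expect_equal(fraction_unbound(c(0.4, 0.6), c(1, 1))$fu, 0.5)
  expect_error(fraction_unbound(0.5, 0), "> 0")
})

test_that("fu above 1 is flagged, not truncated", {
  expect_warning(out <- fraction_unbound(1.2, 1), "exceeds 1")
  expect_equal(out$fu, 1.2)
  expect_true(out$exceeds_one)
})

test_that("noise-free dialysis data return the generating fu", {
  for (fu in c(0.79, 0.055)) {
    d <- gen_red_assay(seed = 1, fu = fu, cv = 0)
    est <- fraction_unbound(d$buffer_conc, d$sample_conc)
    expect_equal(est$fu, fu)
  }
})

test_that("noisy dialysis estimates fall within 2 SEM of the truth", {
  d <- gen_red_assay(seed = 8, fu = 0.055, cv = 0.03)
  est <- fraction_unbound(d$buffer_conc, d$sample_conc)
  expect_lt(abs(est$fu - 0.055), 2 * est$fu_sd / sqrt(est$n))
})

test_that("in vitro to blood conversion implements the unbound
          equivalence", {
  sc <- binding_scenario(fu_m = 0.79, fu_p = 0.15, BPr = 0.70)
  expect_equal(invitro_to_total_blood(0.6, sc), 0.6 * 0.79 * 0.70 / 0.15)
  expect_equal(invitro_to_total_blood(0, sc), 0)
  # identity when medium and blood unbound fractions match
  sc_id <- binding_scenario(fu_m = 0.15 / 0.70, fu_p = 0.15, BPr = 0.70)
  expect_equal(invitro_to_total_blood(2.5, sc_id), 2.5)
})

test_that("unbound blood concentration uses fu_p/BPr", {
  expect_equal(unbound_blood(1, 0.3, 0.87), 0.3 / 0.87)
  expect_equal(unbound_blood(2, 0.5, 0.5), 2)
  expect_equal(unbound_blood(0, 0.3, 0.87), 0)
})

test_that("conversion composed with unbound recovery returns the unbound
          in vitro concentration exactly", {
  sc <- binding_scenario(fu_m = 0.79, fu_p = 0.055, BPr = 0.70)
  C <- c(0.01, 0.3, 30)
  expect_equal(unbound_blood(invitro_to_total_blood(C, sc), sc$fu_p,
                             sc$BPr),
               C * sc$fu_m)
})

test_that("the four binding scenarios are ordered by fu_p", {
  scs <- methadone_binding_scenarios()
  fup <- vapply(scs, function(s) s$fu_p, numeric(1))
  expect_equal(sort(unname(fup), decreasing = TRUE),
               c(0.22, 0.15, 0.055, 0.034))
  expect_true(all(vapply(scs, function(s) s$fu_m == 0.79, logical(1))))
})

test_that("dialysis CSV reader validates its schema", {
  d <- gen_red_assay(seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(as.data.frame(d), path, row.names = FALSE)
  back <- read_dialysis_csv(path)
  expect_equal(back$buffer_conc, d$buffer_conc)
  expect_error(read_dialysis_csv(
    withr::local_tempfile(lines = "a,b\n1,2", fileext = ".csv")),
    "missing columns")
})
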