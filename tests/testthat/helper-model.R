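# shared fixtures: the default model and memoised simulations, so that
# test files (and the acceptance suite) do not re-integrate identical
# scenarios
.sim_cache <- new.env(parent = emptyenv())

default_model <- function() default_methadone_model()

cached_sim <- function(dose, BW = 70, n_days = 30) {
  key <- sprintf("d%g_bw%g_n%d", dose, BW, n_days)
  if (is.null(.sim_cache[[key]])) {
    params <- with_body_weight(default_methadone_model(), BW)
    .sim_cache[[key]] <- pbk_simulate(params,
                                      dose_regimen(dose, n_days = n_days))
  }
  .sim_cache[[key]]
}

cached_metrics <- function(dose, BW = 70, n_days = 30,
                           compound = "methadone") {
  steady_state_metrics(cached_sim(dose, BW, n_days), compound)
}

# one dose-Cmax map reused by reverse-dosimetry and acceptance tests
cached_map <- function() {
  if (is.null(.sim_cache$map))
    .sim_cache$map <- dose_cmax_map(default_methadone_model(), BW = 70,
                                    bracket = c(1e-2, 1e4), n_grid = 19)
  .sim_cache$map
}

# noise-free synthetic concentration-response with a nominal SD for the
# likelihood (means are exact)
noise_free_crc <- function(seed = 3, sd_nominal = 2) {
  wells <- gen_mea_crc(seed = seed, well_sd_pct = 0,
                       drift_pct_per_step = 0)
  crc <- build_concentration_response(wells)
  crc$response_sd <- sd_nominal
  attr(crc, "truth") <- attr(wells, "truth")
  crc
}
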