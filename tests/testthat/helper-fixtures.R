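# Shared fixtures. Heavy fits are memoized so several test files can reuse
# the same parameter-recovery run.

.fixture_env <- new.env(parent = emptyenv())

# exact log records (no 1-second flooring): recovery targets the generator's
# exact inverse link
log_records <- function(panel) {
  r <- panel$rt_records
  r$log_rt <- log(r$rt_seconds)
  r
}

# time-intensity table built from generator truth (zero estimation error)
ti_truth <- function(panel) {
  data.frame(item_id = panel$item_truth$item_id,
             ti_log = panel$item_truth$ti_true,
             ti_centered = panel$item_truth$ti_true_centered,
             ti_se = 0)
}

# true latent components in the shape extract_person_components() returns
true_components <- function(panel) {
  data.frame(person_id = panel$person_truth$person_id,
             mean_rt = panel$person_truth$u0,
             rt_adjustment = panel$person_truth$u1,
             log_resid_var = panel$person_truth$u2)
}

# The main parameter-recovery run: 300 persons x 150 items from the expanded
# generative model, time intensities estimated by REML, expanded model fitted
# with the default sampler length.
recovery_fixture <- function() {
  if (!is.null(.fixture_env$recovery)) return(.fixture_env$recovery)
  cfg <- panel_config(n_persons = 300, n_surveys = 6, items_per_survey = 25,
                      gamma00 = 2.33, gamma10 = 1.0, omega = -1.66,
                      tau = diag(c(0.16, 0.04, 0.25)),
                      contamination_rate = 0, seed = 101)
  panel <- generate_panel(cfg)
  clean <- log_records(panel)
  ti <- estimate_time_intensities(clean, method = "reml")
  fit <- fit_expanded_location_scale(
    clean, ti, ls_spec(chains = 2, iterations = 4000, burn_in = 2000,
                       seed = 7))
  comps <- extract_person_components(fit)
  .fixture_env$recovery <- list(config = cfg, panel = panel, clean = clean,
                                ti = ti, fit = fit, components = comps)
  .fixture_env$recovery
}

# small helper to build RT record frames by hand
make_records <- function(person_id, item_id, survey_id, rt_seconds,
                         survey_date = as.Date("2020-01-01")) {
  data.frame(person_id = person_id, item_id = item_id,
             survey_id = survey_id, survey_date = survey_date,
             rt_seconds = rt_seconds)
}
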