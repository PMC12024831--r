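# Shared fixtures: oral simulations are expensive, so the five standard
# 75 mg runs (IR tablet + four formulation presets) are computed once per
# test session and reused across files.

.sim_cache <- new.env(parent = emptyenv())

standard_physiology <- function() default_fasted_physiology()

oral_sim_cached <- function(name, t_end = 48, dt = 0.02) {
  key <- paste(name, t_end, dt, sep = "_")
  if (!is.null(.sim_cache[[key]])) return(.sim_cache[[key]])
  disp <- clopidogrel_disposition()
  phys <- standard_physiology()
  de <- dose_event("po", 75)
  sim <- if (name == "IR") {
    drug <- clopidogrel_parameters() # precipitation active for plain solid
    simulate_oral(drug, disp, phys, release_source_solid(drug$psd), de,
                  t_end = t_end, dt = dt)
  } else {
    drug <- clopidogrel_parameters(precipitation_time_s = Inf)
    prof <- generate_profile(formulation_presets()[[name]])
    simulate_oral(drug, disp, phys, release_source_dispersed(prof), de,
                  t_end = t_end, dt = dt)
  }
  .sim_cache[[key]] <- sim
  sim
}

# flat, very high solubility (never rate-limiting) for limit-case tests
unlimited_solubility <- function() {
  solubility_table(c(1, 8), c(1000, 1000))
}

# noise-free profile from a fitted-model closed form, for recovery tests
profile_from_model <- function(model, params, times = seq(5, 120, by = 5)) {
  fit <- list(model = model, params = params)
  dissolution_profile(times, predict_release(fit, times))
}
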