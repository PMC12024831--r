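disp <- clopidogrel_disposition()
phys <- standard_physiology()

test_that("unlimited solubility and instant release give near-complete,
          proximal absorption", {
  drug <- clopidogrel_parameters(precipitation_time_s = Inf)
  drug$solubility <- unlimited_solubility()
  instant <- dissolution_profile(c(0, 1, 2), c(100, 100, 100))
  sim <- simulate_oral(drug, disp, phys, release_source_dispersed(instant),
                       dose_event("po", 75), t_end = 24, dt = 0.05)
  expect_gt(sim$Fa, 99)
  reg <- regional_absorption_fractions(sim)
  expect_gt(sum(reg[c("duodenum", "jejunum1", "jejunum2")]), 50)
  expect_lt(sim$mass_balance_error, 1e-6)
})

test_that("without permeability nothing is absorbed", {
  drug <- clopidogrel_parameters(precipitation_time_s = Inf)
  drug$Peff <- 0
  prof <- generate_profile(formulation_presets()$C5)
  expect_warning(
    sim <- simulate_oral(drug, disp, phys, release_source_dispersed(prof),
                         dose_event("po", 75), t_end = 12, dt = 0.05),
    "all-zero")
  expect_lt(sim$Fa, 1e-4)
  expect_lt(max(sim$plasma_conc), 1e-6)
  expect_error(regional_absorption_fractions(sim), "undefined")
})

test_that("uniform first-pass extraction gives Fb = Fa x (1 - FPE) exactly", {
  for (nm in c("C9", "IR")) {
    sim <- oral_sim_cached(nm)
    expect_equal(sim$Fb / sim$Fa, 1 - 0.965, tolerance = 1e-10, label = nm)
  }
})

test_that("regional absorption fractions are a normalized distribution", {
  sim <- oral_sim_cached("C9")
  reg <- regional_absorption_fractions(sim)
  expect_equal(sum(reg), 100, tolerance = 1e-6)
  expect_equal(unname(reg["stomach"]), 0) # no gastric absorption

  # absorption confined to one compartment by zeroing all other scales
  overrides <- lapply(setdiff(phys$name, c("jejunum1")), function(nm) {
    list(absorption_scale = 0)
  })
  names(overrides) <- setdiff(phys$name, c("jejunum1"))
  phys1 <- with_overrides(phys, overrides)
  drug <- clopidogrel_parameters(precipitation_time_s = Inf)
  prof <- generate_profile(formulation_presets()$C5)
  sim1 <- simulate_oral(drug, disp, phys1, release_source_dispersed(prof),
                        dose_event("po", 75), t_end = 24, dt = 0.05)
  reg1 <- regional_absorption_fractions(sim1)
  expect_equal(unname(reg1["jejunum1"]), 100, tolerance = 1e-9)
})

test_that("fast-releasing formulations absorb more proximally than slow ones", {
  fast <- regional_absorption_fractions(oral_sim_cached("C5"))
  slow <- regional_absorption_fractions(oral_sim_cached("P9"))
  prox <- c("duodenum", "jejunum1", "jejunum2")
  expect_gt(sum(fast[prox]), sum(slow[prox]))
})

test_that("halving transit times shifts absorption proximally", {
  drug <- clopidogrel_parameters(precipitation_time_s = Inf)
  prof <- generate_profile(formulation_presets()$C9)
  halved <- lapply(seq_len(9), function(i) {
    list(transit_time = phys$transit_time[i] / 2)
  })
  names(halved) <- phys$name
  phys_fast <- with_overrides(phys, halved)
  base <- simulate_oral(drug, disp, phys, release_source_dispersed(prof),
                        dose_event("po", 75), t_end = 24, dt = 0.05)
  fast <- simulate_oral(drug, disp, phys_fast, release_source_dispersed(prof),
                        dose_event("po", 75), t_end = 24, dt = 0.05)
  prox <- c("stomach", "duodenum", "jejunum1", "jejunum2")
  expect_lt(sum(regional_absorption_fractions(fast)[prox]),
            sum(regional_absorption_fractions(base)[prox]))
})

test_that("oral AUC is consistent with Fb x dose / (CL x BW)", {
  sim <- oral_sim_cached("C9")
  theory <- (sim$Fb / 100) * 75e6 / (84 * 1000)
  expect_equal(sim$metrics$AUC_0_inf, theory, tolerance = 0.02)
})

test_that("mass balance holds to solver precision at all output times", {
  for (nm in c("IR", "C5", "P9")) {
    expect_lt(oral_sim_cached(nm)$mass_balance_error, 1e-6, label = nm)
  }
})

test_that("slow colonic delivery lowers the liver concentration peak", {
  # the slow-releasing formulation spreads portal inflow over many hours
  expect_lt(max(oral_sim_cached("P9")$liver_conc),
            max(oral_sim_cached("C5")$liver_conc))
})

test_that("configuration errors are caught before integration", {
  drug <- clopidogrel_parameters()
  expect_error(simulate_oral(drug, disp, phys,
                             release_source_solid(drug$psd),
                             dose_event("iv_bolus", 75)), "route 'po'")
})
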