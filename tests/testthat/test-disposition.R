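disp <- clopidogrel_disposition()

test_that("terminal half-life from the rate-matrix eigenvalue is 4.4 h", {
  expect_equal(round(terminal_half_life(disp), 1), 4.4)
})

test_that("half-life reduces to the one-compartment closed form", {
  # with no distributional transfer (and fast peripheral return so the
  # decoupled peripheral eigenvalues are not terminal), the half-life is
  # the one-compartment closed form ln2 Vc / CL
  d1 <- disposition_parameters(CL = 1.2, Vc = 0.073, k12 = 1e-10,
                               k21 = 100, k13 = 1e-10, k31 = 50)
  expect_equal(terminal_half_life(d1), log(2) * 0.073 / 1.2,
               tolerance = 1e-6)
})

test_that("eigenvalue half-life equals the simulated terminal slope", {
  # independent code path: log-linear regression on the simulated tail
  set.seed(42)
  for (i in 1:5) {
    d <- disposition_parameters(CL = runif(1, 0.5, 2),
                                Vc = runif(1, 0.05, 0.5),
                                k12 = runif(1, 1, 10), k21 = runif(1, 0.5, 3),
                                k13 = runif(1, 0.2, 2), k31 = runif(1, 0.05, 0.5))
    t_half <- terminal_half_life(d)
    sim <- simulate_iv(NULL, d, dose_event("iv_bolus", 10),
                       t_end = 12 * t_half, dt = t_half / 20)
    tail_idx <- sim$times > 6 * t_half
    slope <- coef(lm(log(sim$plasma_conc[tail_idx]) ~
                       sim$times[tail_idx]))[[2]]
    expect_equal(log(2) / (-slope), t_half, tolerance = 5e-3)
  }
})

test_that("i.v. AUC equals dose/(CL x BW) and scales linearly with dose", {
  doses <- c(1, 10, 100, 300)
  aucs <- vapply(doses, function(d) {
    simulate_iv(NULL, disp, dose_event("iv_bolus", d))$metrics$AUC_0_inf
  }, numeric(1))
  theory <- doses * 1e6 / (disp$CL * disp$body_weight) / 1000
  expect_equal(aucs, theory, tolerance = 5e-3)
  expect_equal(aucs / doses, rep(aucs[1], 4), tolerance = 1e-9) # superposition
})

test_that("infusion and bolus give identical AUC within 0.1%", {
  # fine grid: the bolus curve has a very fast distribution phase whose
  # trapezoid error would otherwise dominate the comparison
  bol <- simulate_iv(NULL, disp, dose_event("iv_bolus", 100),
                     t_end = 36, dt = 0.002)$metrics$AUC_0_inf
  inf <- simulate_iv(NULL, disp,
                     dose_event("iv_infusion", 100, infusion_duration = 1),
                     t_end = 36, dt = 0.002)$metrics$AUC_0_inf
  expect_equal(inf, bol, tolerance = 1e-3)
})

test_that("route and validity checks reject bad inputs", {
  expect_error(simulate_iv(NULL, disp, dose_event("po", 75)), "i.v.")
  expect_error(dose_event("iv_bolus", -1), "positive")
  expect_error(disposition_parameters(0, 0.073, 1, 1, 1, 1), "positive")
})

test_that("noise-free self-simulated data return the generating parameters", {
  truth <- c(CL = 1.2, Vc = 0.073, k12 = 9.285, k21 = 2.058,
             k13 = 1.243, k31 = 0.17)
  # sampling covers distribution and terminal phases
  t <- sort(unique(c(seq(0.02, 1, by = 0.02), seq(1.25, 24, by = 0.25))))
  am <- clopbbm:::.threecomp_amounts(disp, 10, t)
  conc <- 1000 * am[1, ] / (disp$Vc * disp$body_weight)
  fit <- fit_three_compartment(t, conc, dose = 10)
  expect_equal(unlist(fit[names(truth)]), truth, tolerance = 1e-3)
})

test_that("mono-exponential data collapse the distribution constants", {
  t <- seq(0.1, 24, by = 0.1)
  conc <- 100 * exp(-0.3 * t)
  fit <- fit_three_compartment(t, conc, dose = 10)
  # CL/Vc is the only identifiable rate: k10 must match the decay constant
  expect_equal(fit$k10, 0.3, tolerance = 0.05)
  expect_lt(fit$k12, 0.05)
  expect_lt(fit$k13, 0.05)
})

test_that("clearance recovery is nearly unbiased under 5% lognormal noise", {
  t <- sort(unique(c(seq(0.02, 1, by = 0.04), seq(1.25, 24, by = 0.5))))
  am <- clopbbm:::.threecomp_amounts(disp, 10, t)
  truth <- 1000 * am[1, ] / (disp$Vc * disp$body_weight)
  set.seed(99)
  bias <- vapply(1:9, function(i) {
    noisy <- truth * exp(rnorm(length(t), 0, 0.05))
    fit <- fit_three_compartment(t, noisy, dose = 10)
    fit$CL / 1.2 - 1
  }, numeric(1))
  expect_lte(median(abs(bias)), 0.02)
})
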