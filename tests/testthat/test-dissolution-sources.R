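test_that("particle size distribution discretization is correct", {
  # one bin collapses to the median diameter
  psd1 <- build_psd(150, 250, 1)
  expect_equal(psd1$bins$diameter_um, 150)

  psd <- build_psd(150, 250, 10)
  expect_equal(psd$sigma, log(250 / 150) / qnorm(0.9), tolerance = 1e-12)
  expect_true(all(diff(psd$bins$diameter_um) > 0))
  expect_equal(sum(psd$bins$number_fraction), 1, tolerance = 1e-9)
  expect_equal(sum(psd$bins$mass_fraction), 1, tolerance = 1e-9)

  # degenerate near-monodisperse limit
  psd_m <- build_psd(150, 150.0001, 10)
  expect_true(all(abs(psd_m$bins$diameter_um - 150) < 0.01))

  expect_error(build_psd(250, 150, 10), "D90 > D50")
})

test_that("particle dissolution rate handles limit cases", {
  expect_equal(particle_dissolution_rate(0, 75, 0.05, 0, 0.7397e-5), 0)
  expect_equal(particle_dissolution_rate(10, 75, 0.05, 0.05, 0.7397e-5), 0)
  # above saturation the rate clamps to zero (no particle growth)
  expect_equal(particle_dissolution_rate(10, 75, 0.05, 0.10, 0.7397e-5), 0)
  expect_error(particle_dissolution_rate(10, 75, 0.05, -1, 0.7397e-5),
               "non-negative")
  expect_error(particle_dissolution_rate(10, 75, 0, 0, 0.7397e-5),
               "positive")
})

test_that("rate matches an explicit shrinking-sphere oracle under sink", {
  # oracle: integrate dr/dt = -(Dw Cs)/(rho h) at dt = 1e-3 min and convert
  # the radius trajectory to mass; the rate function, integrated the same
  # way, must agree to 0.1% over the step span
  Dw <- 0.7397e-5 # cm^2/s
  Cs <- 0.05      # mg/mL
  rho <- 1.2 * 1000
  r0 <- 75 / 1e4  # cm
  m0 <- 5         # mg
  dt <- 1e-3      # min
  n_steps <- 1000

  r <- r0
  for (i in seq_len(n_steps)) {
    h <- min(r, 30 / 1e4)
    r <- max(r - (Dw * 60) * Cs / (rho * h) * dt, 0)
  }
  mass_oracle <- m0 * (r / r0)^3

  m <- m0
  rr <- r0
  for (i in seq_len(n_steps)) {
    rate <- particle_dissolution_rate(m, rr * 1e4, Cs, 0, Dw)
    m <- max(m - rate * dt, 0)
    rr <- r0 * (m / m0)^(1 / 3)
  }
  expect_equal(m, mass_oracle, tolerance = 1e-3)
})

test_that("time to complete dissolution shrinks with higher Cs and smaller r0", {
  dissolve_time <- function(r0_um, Cs) {
    m <- 1
    r0 <- r0_um / 1e4
    rr <- r0
    t <- 0
    dt <- 0.05
    while (m > 1e-4 && t < 1e4) {
      rate <- particle_dissolution_rate(m, rr * 1e4, Cs, 0, 0.7397e-5)
      m <- max(m - rate * dt, 0)
      rr <- r0 * m^(1 / 3)
      t <- t + dt
    }
    t
  }
  expect_lt(dissolve_time(75, 0.10), dissolve_time(75, 0.05))
  expect_lt(dissolve_time(40, 0.05), dissolve_time(75, 0.05))
})

test_that("tabulated release rate is the profile's piecewise slope", {
  p <- dissolution_profile(c(0, 50, 100), c(0, 50, 100))
  expect_equal(tabulated_release_rate(p, 50), 0.01) # fraction/min
  expect_equal(tabulated_release_rate(p, 25), 0.01)
  expect_equal(tabulated_release_rate(p, 150), 0)   # after the last point
  expect_equal(tabulated_release_rate(p, -5), 0)    # before dosing

  pn <- suppressWarnings(dissolution_profile(c(0, 10, 20, 30),
                                             c(0, 40, 38, 60)))
  expect_warning(tabulated_release_rate(pn, 15), "running maximum")
})

test_that("integrated release rate equals the final cumulative fraction", {
  prof <- generate_profile(formulation_presets()$C9)
  # midpoint rule is exact for a piecewise-constant rate
  tg <- seq(0, 400, by = 0.01)
  mid <- (tg[-1] + tg[-length(tg)]) / 2
  integral <- sum(tabulated_release_rate(prof, mid) * diff(tg))
  expect_equal(integral, max(prof$released) / 100, tolerance = 1e-9)
})

test_that("dispersed release drivers extend still-rising profiles only", {
  presets <- formulation_presets()
  drv_p9 <- clopbbm:::.release_driver(
    release_source_dispersed(generate_profile(presets$P9)))
  expect_gt(drv_p9$slope_ext_per_h, 0.01) # P9 still releasing at test end
  expect_equal(drv_p9$F(1e3), 1)          # extension completes release

  drv_c5 <- clopbbm:::.release_driver(
    release_source_dispersed(generate_profile(presets$C5)))
  expect_equal(drv_c5$slope_ext_per_h, 0) # plateaued: no extension
  expect_equal(drv_c5$F(1e3), max(generate_profile(presets$C5)$released) / 100,
               tolerance = 1e-9)

  drv_none <- clopbbm:::.release_driver(
    release_source_dispersed(generate_profile(presets$P9), extend = "none"))
  expect_equal(drv_none$slope_ext_per_h, 0)
})
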