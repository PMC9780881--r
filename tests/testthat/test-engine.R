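test_that("an isolated carbonyl oscillates at the configured wavenumber", {
  cfg <- quick_config(duration_ns = 0.002, occupancy = NULL,
                      injection = FALSE, boundaries = FALSE,
                      thermostat_rate_per_ps = 0, carbonyl_coupling = FALSE,
                      driving_mV = 0)
  g <- filter_geometry()
  ff <- force_field(driving_mV = 0)
  st <- displace_carbonyl(init_state(g, ff, NULL, temperature_K = 0), 1, 0.01)
  sim <- simulate_filter(cfg, state = st, record_ring = 1)
  # oxygen z relative to its ring plane
  z <- sim$oxygen_traj[, 3] - g$carbons[1, "z"]
  # analytic small-angle solution: z(t) = r sin(theta0) cos(w t); compare
  # pointwise over the first five periods (beyond that the integrator's
  # O(dt^2) phase error accumulates, which the period check covers)
  tt <- (seq_along(z) - 1) * 0.25
  amp <- 123 * sin(0.01)
  period <- 66.71281
  head5 <- tt <= 5 * period
  expect_lt(max(abs(z - amp * cos(2 * pi * tt / period))[head5]), 1e-3 * amp)
  # period from zero crossings over the whole run
  zc <- which(diff(sign(z)) != 0)
  expect_equal(2 * mean(diff(zc)) * 0.25, period, tolerance = 1e-3)
})

test_that("oscillator energy drifts less than 1e-4 over 1e5 steps", {
  cfg <- quick_config(duration_ns = 0.025, occupancy = NULL,
                      injection = FALSE, boundaries = FALSE,
                      thermostat_rate_per_ps = 0, carbonyl_coupling = FALSE,
                      driving_mV = 0)
  g <- filter_geometry()
  ff <- force_field(driving_mV = 0)
  st <- displace_carbonyl(init_state(g, ff, NULL, temperature_K = 0), 1, 0.01)
  # dense sampling so window means average out the bounded 2-omega ripple
  sim <- simulate_filter(cfg, state = st, energy_every_fs = 5)
  en <- sim$energy$total_ev
  # secular drift: difference between the first and last 10% window means
  # (the bounded symplectic ripple is not drift)
  n <- length(en)
  k <- max(1, n %/% 10)
  drift <- abs(mean(en[(n - k + 1):n]) - mean(en[1:k])) / en[1]
  expect_lt(drift, 1e-4)
})

test_that("Verlet dynamics are time-reversible without the thermostat", {
  cfg <- quick_config(duration_ns = 0.0025, occupancy = "K0W1K2W3K4W",
                      injection = FALSE, boundaries = FALSE,
                      thermostat_rate_per_ps = 0, seed = 9)
  sim <- simulate_filter(cfg)
  fin <- sim$final_state
  # reverse all velocities and integrate the same number of steps back
  rev <- fin
  rev$mobiles$vz <- -rev$mobiles$vz
  rev$w <- -rev$w
  rev$mobiles$om1 <- -rev$mobiles$om1
  rev$mobiles$om2 <- -rev$mobiles$om2
  rev$mobiles$om3 <- -rev$mobiles$om3
  back <- simulate_filter(cfg, state = rev)$final_state
  set.seed(cfg$seed)
  st0 <- init_state(sim$geometry, sim$force_field, cfg$occupancy, 310)
  # match particles by id (the engine keeps its list sorted by z)
  b <- back$mobiles[order(back$mobiles$id), ]
  o <- st0$mobiles[order(st0$mobiles$id), ]
  expect_equal(b$z, o$z, tolerance = 1e-6)
  expect_equal(unname(back$u), unname(as.matrix(st0$u)), tolerance = 1e-6)
})

test_that("identical seeds give bit-identical event logs", {
  cfg <- quick_config(duration_ns = 0.02, thermalization_ns = 0.002,
                      seed = 123)
  s1 <- simulate_filter(cfg)
  s2 <- simulate_filter(cfg)
  expect_identical(s1$events, s2$events)
  expect_identical(s1$final_state$mobiles, s2$final_state$mobiles)
  cfg$seed <- 124L
  s3 <- simulate_filter(cfg)
  expect_false(identical(s1$events, s3$events))
})

test_that("closed-system total energy is conserved with the bath off", {
  cfg <- quick_config(duration_ns = 0.01, occupancy = "K0W1K2W3K4W",
                      injection = FALSE, boundaries = FALSE,
                      thermostat_rate_per_ps = 0, seed = 41)
  sim <- simulate_filter(cfg, energy_every_fs = 50)
  en <- sim$energy
  ke <- mean(en$ke_carbonyl_ev + en$ke_translation_ev + en$ke_rotation_ev)
  drift <- max(abs(en$total_ev - en$total_ev[1]))
  expect_lt(drift / ke, 1e-3)
})

test_that("thermostatted carbonyls equilibrate to kT per rotor", {
  # two angular DOF per carbonyl: <KE> = 24 * k_B T at 310 K
  cfg <- quick_config(duration_ns = 0.2, thermalization_ns = 0.05,
                      occupancy = NULL, injection = FALSE,
                      carbonyl_coupling = FALSE, seed = 77)
  sim <- simulate_filter(cfg, energy_every_fs = 250)
  en <- sim$energy[sim$energy$time_fs > 5e4, ]
  expect_equal(mean(en$ke_carbonyl_ev), 24 * KB_EV * 310, tolerance = 0.1)
})

test_that("injection draws species 50/50 and respects steric blocking", {
  cfg <- quick_config(duration_ns = 0.4, thermalization_ns = 0,
                      occupancy = NULL, injection_rate_per_ps = 20,
                      seed = 5)
  sim <- simulate_filter(cfg)
  inj <- sim$events[sim$events$event == "injection", ]
  expect_gt(nrow(inj), 200)
  frac <- mean(inj$species == "K")
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / nrow(inj)))
  # an over-wide clearance blocks every attempt while a particle is present
  cfgb <- quick_config(duration_ns = 0.005, occupancy = "W5",
                       boundaries = FALSE, injection_clearance_pm = 5000,
                       injection_rate_per_ps = 50)
  simb <- simulate_filter(cfgb)
  expect_gt(simb$summary$injection_attempts, 0)
  expect_equal(sum(simb$events$event == "injection"), 0)
})

test_that("boundary crossings are logged and removed", {
  cfg <- quick_config(duration_ns = 0.0005, occupancy = "K0",
                      injection = FALSE, thermostat_rate_per_ps = 0)
  g <- filter_geometry()
  ff <- force_field()
  st <- init_state(g, ff, "K0", temperature_K = 0)
  st$mobiles$z <- g$z_exit - 1
  st$mobiles$vz <- 5
  sim <- simulate_filter(cfg, state = st)
  ev <- sim$events
  expect_equal(sum(ev$event == "emission_top" & ev$species == "K"), 1)
  expect_equal(nrow(sim$final_state$mobiles), 0)
})

test_that("particle bookkeeping balances exactly and order is preserved", {
  cfg <- quick_config(duration_ns = 0.05, thermalization_ns = 0.005,
                      seed = 19)
  sim <- simulate_filter(cfg)
  ev <- sim$events
  n0 <- sim$diagnostics$n_initial
  balance <- n0 + sum(ev$event == "injection") -
    sum(ev$event == "emission_top") -
    sum(ev$event == "return_to_cavity")
  expect_identical(balance, as.integer(sim$diagnostics$n_final))
  expect_identical(sim$summary$order_violations, 0)
  expect_true(all(diff(sim$events$time_fs) >= 0))
})

test_that("K+ thermal speed matches the 1D Maxwell-Boltzmann scale", {
  # sqrt(k_B T / m) for K+ at 310 K is ~257 m/s = 0.257 pm/fs, so a free
  # hop across one 300 pm site spacing takes on the order of a picosecond
  v <- sqrt(KB_EV * 310 * 96.4853322 / 39.0983)
  expect_equal(v * 1000, 257, tolerance = 0.01)   # m/s
  expect_equal(300 / v / 1000, 1.17, tolerance = 0.01)  # ps per site hop
})
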