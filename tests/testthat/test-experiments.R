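test_that("occupancy codes parse and format with the shorthand convention", {
  occ <- parse_occupancy("K1W2K3WW")
  expect_equal(occ$species, c("K", "W", "K", "W", "W"))
  expect_equal(occ$site_index, c(1L, 2L, 3L, 4L, 5L))
  expect_equal(format_occupancy(occ), "K1W2K3WW")
  occ2 <- parse_occupancy("K0W1K2W3K4")
  expect_equal(occ2$site_index, 0:4)
  expect_equal(format_occupancy(occ2), "K0W1K2W3K4")
  expect_equal(nrow(parse_occupancy("")), 0)
  expect_equal(format_occupancy(parse_occupancy("")), "")
  expect_error(parse_occupancy("K1K1"), "site")
  expect_error(parse_occupancy("K9"), "site")
  expect_error(parse_occupancy("X1"), "K and W")
})

test_that("occupancy round-trips through particle placement and coding", {
  g <- filter_geometry()
  ff <- force_field()
  for (code in c("K0W1K2W3K4", "K1W2K3WW", "K0W1K2W3K4W", "W0K1W2K3W4K5")) {
    st <- init_state(g, ff, code, temperature_K = 0)
    expect_equal(occupancy_pattern(st, g), code)
  }
  expect_equal(occupancy_pattern(init_state(g, ff, NULL, 0), g), "")
  # slightly displaced particles still map to their nearest site
  st <- init_state(g, ff, "K0W1K2W3K4", temperature_K = 0)
  st$mobiles$z <- st$mobiles$z + c(40, -60, 55, 30, -45)
  expect_equal(occupancy_pattern(st, g), "K0W1K2W3K4")
  # two particles captured by one site is an error
  st$mobiles$z <- c(610, 590, 0, -300, -600)
  expect_error(occupancy_pattern(st, g), "ambiguous")
})

test_that("current estimates are exact counts over the duration", {
  ev <- tibble::tibble(
    time_fs = c(1, 2, 3, 4, 5, 6, 7),
    species = c("K", "K", "W", "K", "K", "W", "K"),
    event = c("emission_top", "emission_top", "emission_top", "injection",
              "emission_top", "return_to_cavity", "emission_top"),
    particle_id = 0:6,
    phase = c(rep("production", 6), "thermalization")
  )
  cur <- current_estimate(ev, duration_us = 0.5)
  k <- cur[cur$species == "K", ]
  expect_equal(k$emissions, 3)             # thermalization row excluded
  expect_equal(k$current_per_us, 6)
  expect_equal(k$se_per_us, sqrt(3) / 0.5)
  # currents times duration recover integer counts exactly
  expect_equal(k$current_per_us * k$duration_us, 3)
  w <- cur[cur$species == "W", ]
  expect_equal(w$current_per_us, 2)
  empty <- current_estimate(ev[0, ], duration_us = 1)
  expect_equal(empty$current_per_us, c(0, 0))
  expect_error(current_estimate(ev, duration_us = 0), "positive")
})

test_that("Gaussian fit recovers known parameters from noisy curves", {
  xs <- seq(-8, 10, by = 2)
  truth <- c(I0 = 280, x0 = 0.949, w = 2.70)
  gauss <- function(x) truth["I0"] * exp(-(x - truth["x0"])^2 /
                                           (2 * truth["w"]^2))
  set.seed(31)
  df <- tibble::tibble(percent = xs,
                       mean_current = gauss(xs) + rnorm(length(xs), 0, 8),
                       sd_current = 22)
  fit <- fit_gaussian_current(df)
  td <- tidy(fit)
  for (p in names(truth)) {
    row <- td[td$term == p, ]
    expect_lt(abs(row$estimate - truth[[p]]), 3 * row$std.error)
  }
  gl <- glance(fit)
  expect_named(gl, c("I0", "x0", "w", "sigma", "df.residual", "nobs"))
  expect_gt(gl$w, 0)
})

test_that("Gaussian fit is unbiased across noise realizations", {
  xs <- seq(-8, 10, by = 2)
  gauss <- function(x) 280 * exp(-(x - 0.949)^2 / (2 * 2.7^2))
  set.seed(99)
  est <- t(vapply(1:100, function(i) {
    df <- tibble::tibble(percent = xs,
                         mean_current = pmax(0, gauss(xs) +
                                               rnorm(length(xs), 0, 10)))
    fit_gaussian_current(df, weighted = FALSE)$estimate
  }, numeric(3)))
  expect_lt(abs(mean(est[, "I0"]) / 280 - 1), 0.05)
  expect_lt(abs(mean(est[, "w"]) / 2.7 - 1), 0.05)
  expect_lt(abs(mean(est[, "x0"]) - 0.949), 0.05 * 2.7)
})

test_that("Gaussian fit handles symmetric and degenerate input sanely", {
  xs <- seq(-6, 6, by = 2)
  # exactly symmetric about 0, not exactly Gaussian
  df <- tibble::tibble(percent = xs,
                       mean_current = 100 * exp(-xs^2 / 8) + cos(xs))
  fit <- fit_gaussian_current(df)
  expect_equal(unname(fit$estimate["x0"]), 0, tolerance = 1e-6)
  # a perfect Gaussian is fitted exactly (perturbed-start fallback)
  df2 <- tibble::tibble(percent = xs, mean_current = 100 * exp(-xs^2 / 8))
  fit2 <- fit_gaussian_current(df2)
  expect_equal(unname(fit2$estimate["w"]), 2, tolerance = 1e-6)
  expect_error(fit_gaussian_current(
    tibble::tibble(percent = xs, mean_current = 0)), "zero")
  expect_error(fit_gaussian_current(
    tibble::tibble(percent = c(1, 2, 3), mean_current = c(1, 2, 1))),
    "4 distinct")
})

test_that("fluctuation statistics are exact for constructed trajectories", {
  # frozen trajectory: all deviations zero
  frozen <- matrix(rep(c(5, 6, 7, -1, 0, 2), each = 100), nrow = 100)
  fs <- oxygen_fluctuation_stats(frozen)
  expect_equal(fs$summary$mean_total_dev_pm, 0)
  expect_equal(fs$summary$tail_fraction, 0)
  expect_equal(fs$summary$n_oxygens, 2)
  # two-frame trajectory with a known displacement: dev = half the jump
  two <- matrix(c(0, 0, 0, 0, 0, 8), nrow = 2, byrow = TRUE)
  fs2 <- oxygen_fluctuation_stats(two, threshold_pm = 3)
  expect_equal(fs2$summary$mean_total_dev_pm, 4)
  expect_equal(fs2$summary$tail_fraction, 1)
  expect_error(oxygen_fluctuation_stats(matrix(0, 0, 3)), "trajectory")
})

test_that("potential profile matches a naive double-loop summation", {
  cfg <- quick_config()
  set.seed(8)
  g <- filter_geometry()
  ff <- force_field()
  st <- init_state(g, ff, NULL, temperature_K = 310)
  for (i in sample(24, 6)) st <- displace_carbonyl(st, i, runif(1, -0.1, 0.1))
  pp <- potential_profile(st, cfg, n_grid = 21, exclude = "mobiles",
                          include_field = FALSE,
                          geometry = g, force_field = ff)
  for (k in c(1, 7, 15, 21)) {
    expect_equal(pp$profile$energy_ev[k],
                 naive_profile_energy(pp$profile$z_pm[k], st, cfg),
                 tolerance = 1e-10)
  }
  expect_gte(pp$barrier_ev, 0)
})

test_that("profile exclusion modes and masking behave as documented", {
  cfg <- quick_config()
  st <- cold_state(cfg)
  # default: residents of the probed interval are excluded, K2 is not
  p1 <- potential_profile(st, cfg)
  p2 <- potential_profile(st, cfg, exclude = "mobiles")
  expect_false(isTRUE(all.equal(p1$profile$energy_ev, p2$profile$energy_ev)))
  # a source sitting on the grid is masked and reported
  p3 <- potential_profile(st, cfg, exclude = "none", n_grid = 301)
  expect_gt(p3$masked_points, 0)
  expect_true(any(is.na(p3$profile$energy_ev)))
})

test_that("a filter without charges gives a flat, barrier-free profile", {
  cfg <- quick_config(q_carbonyl_e = 0, driving_mV = 0)
  g <- filter_geometry()
  cts <- matrix(0, 6, 6, dimnames = dimnames(default_contacts()))
  ff <- force_field(charge = charge_model(q_carbonyl = 0),
                    repulsion = repulsion_model(contacts = cts),
                    driving_mV = 0)
  st <- init_state(g, ff, NULL, temperature_K = 0)
  pp <- potential_profile(st, cfg, geometry = g, force_field = ff,
                          include_field = FALSE)
  expect_equal(pp$profile$energy_ev, rep(0, 201))
  expect_equal(pp$barrier_ev, 0)
})

test_that("event statistics match hand-computed values", {
  ev <- tibble::tibble(
    time_fs = c(0, 2e6, 3e6, 8e6, 8.005e6, 8.013e6, 9e6),
    species = "K",
    event = c("injection", "injection", "emission_top", "emission_top",
              "emission_top", "emission_top", "emission_top"),
    particle_id = c(1, 2, 1, 2, 3, 4, 5),
    phase = "production"
  )
  es <- event_statistics(ev, gap_ps = 10)
  expect_equal(sort(es$residence$residence_ns), c(3, 6))
  expect_equal(es$intervals$interval_ns,
               c(5, 0.005, 0.008, 0.987))
  # emissions at 8, 8.005, 8.013 ns fall within 10 ps gaps: one burst of 3
  expect_equal(sort(es$bursts$size), c(1, 1, 3))
  expect_equal(es$summary$mean_burst_size, 5 / 3)
  expect_equal(es$summary$mean_residence_ns, 4.5)
})

test_that("length_scan degenerates to a single run and derives seeds", {
  cfg <- quick_config(duration_ns = 0.01, thermalization_ns = 0.001,
                      seed = 200)
  sc <- length_scan(cfg, fractions = 1, replicates = 1)
  expect_equal(nrow(sc$currents), 1)
  expect_equal(nrow(sc$failures), 0)
  cfg2 <- cfg
  cfg2$seed <- sc$currents$seed[1]
  cfg2$length_fraction <- 1
  ref <- simulate_filter(cfg2)
  expect_equal(sc$currents$k_current, ref$summary$k_current_per_us)
  # distinct replicate seeds
  sc2 <- length_scan(cfg, fractions = c(0.98, 1.02), replicates = 2)
  expect_equal(length(unique(sc2$currents$seed)), 4)
})
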