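test_that("lone pair sits on the C->O line beyond the oxygen", {
  cm <- charge_model()
  cpos <- c(440, 0, 0)
  u <- c(-1, 0, 0)
  lp <- lone_pair_position(cpos, u, cm)
  expect_equal(lp, c(440 - 205, 0, 0))
  # collinearity for an arbitrary direction
  u2 <- c(-1, 0.3, 0.2) / sqrt(1 + 0.09 + 0.04)
  lp2 <- lone_pair_position(cpos, u2, cm)
  expect_equal(pracma::cross(lp2 - cpos, u2), c(0, 0, 0), tolerance = 1e-12)
  # rigid rotation about the carbon
  th <- 0.3
  rotz <- function(v) c(cos(th) * v[1] - sin(th) * v[2],
                        sin(th) * v[1] + cos(th) * v[2], v[3])
  expect_equal(lone_pair_position(cpos, rotz(u2), cm) - cpos,
               rotz(lp2 - cpos), tolerance = 1e-12)
  expect_error(lone_pair_position(cpos, c(1, 1, 0), cm), "unit")
})

test_that("Coulomb pair energies match k_e e^2 = 1.44 eV nm", {
  expect_equal(coulomb_energy(1, 1, 1000), 1.44, tolerance = 1e-3)
  expect_equal(coulomb_energy(1, 1, 300), 4.80, tolerance = 1e-3)
  expect_error(coulomb_energy(1, 1, 0), "positive")
})

test_that("carbonyl charge groups and water are neutral", {
  cm <- charge_model(q_carbonyl = 0.63, lone_pair_fraction = 0.37)
  expect_equal(cm$q_carbonyl + cm$q_o + cm$q_lp, 0)
  expect_equal(cm$q_water_o + 2 * cm$q_water_h, 0)
  expect_error(charge_model(lone_pair_fraction = 1.2), "lone_pair_fraction")
})

test_that("bending stiffness follows kappa = m r^2 (2 pi c k)^2", {
  b <- bending_model(wavenumber = 500)
  expect_equal(b$period_fs, 1 / (2.99792458e10 * 500) * 1e15,
               tolerance = 1e-10)
  expect_equal(b$period_fs, 66.71, tolerance = 1e-3)
  expect_equal(b$kappa_ev, 22.25, tolerance = 1e-2)
  # tabulated conversions are self-consistent
  tab <- bending_constants(c(250, 500, 1000))
  expect_equal(tab$period_fs, 1e15 / (2.99792458e10 * tab$wavenumber_cm),
               tolerance = 1e-10)
  expect_equal(tab$kappa_ev_rad2[3] / tab$kappa_ev_rad2[1], 16)
})

test_that("repulsion wall is monotone below the cutoff and vanishes at it", {
  rm <- repulsion_model()
  expect_equal(repulsion_energy(rm$cutoff, 270, rm), 0)
  expect_equal(repulsion_energy(rm$cutoff + 50, 270, rm), 0)
  r <- seq(150, rm$cutoff, by = 5)
  e <- repulsion_energy(r, 270, rm)
  expect_true(all(diff(e) < 0))
  expect_true(all(e[-length(e)] > 0))
  # slope also vanishes at the cutoff (shifted-force continuity)
  h <- 0.01
  slope <- (repulsion_energy(rm$cutoff - h, 270, rm) -
              repulsion_energy(rm$cutoff - 2 * h, 270, rm)) / h
  expect_lt(abs(slope), 1e-8)
  # wall height at contact equals the strength up to the tiny cutoff shift
  expect_equal(repulsion_energy(270, 270, rm), rm$strength_ev,
               tolerance = 1e-4)
})

test_that("analytic forces are gradients of the potential energy", {
  cfg <- quick_config()
  st <- cold_state(cfg)
  # perturb so no symmetry hides errors
  set.seed(42)
  st <- displace_carbonyl(st, 3, 0.07)
  st <- displace_carbonyl(st, 17, -0.05)
  st$mobiles$z <- st$mobiles$z + runif(nrow(st$mobiles), -20, 20)
  f <- state_forces(st, cfg)
  pot <- function(s) state_energy(s, cfg)$potential_ev * 96.4853322
  h <- 0.05
  # axial force on each mobile
  for (m in seq_len(nrow(st$mobiles))) {
    sp <- st; sm <- st
    sp$mobiles$z[m] <- sp$mobiles$z[m] + h
    sm$mobiles$z[m] <- sm$mobiles$z[m] - h
    num <- -(pot(sp) - pot(sm)) / (2 * h)
    expect_equal(f$mobile_fz[m], num, tolerance = 1e-6)
  }
  # torque on a carbonyl about a chosen axis
  ha <- 1e-4
  for (cidx in c(3, 10)) {
    u <- st$u[cidx, ]
    axis <- c(0, 0, 1) - u * u[3]
    axis <- axis / sqrt(sum(axis^2))
    rot <- function(s, a) {
      s$u[cidx, ] <- kcsafilter:::rotate_about(s$u[cidx, ], axis, a)
      s
    }
    num <- -(pot(rot(st, ha)) - pot(rot(st, -ha))) / (2 * ha)
    expect_equal(sum(f$carbonyl_torque[cidx, ] * axis), num,
                 tolerance = 1e-6)
  }
  # torque on a water rotor about the x axis
  wm <- which(st$mobiles$species == "W")[1]
  rotw <- function(s, a) {
    m <- s$mobiles
    rot <- function(y, z) list(y = y * cos(a) - z * sin(a),
                               z = y * sin(a) + z * cos(a))
    d <- rot(m$d2[wm], m$d3[wm]); e <- rot(m$e12[wm], m$e13[wm])
    m$d2[wm] <- d$y; m$d3[wm] <- d$z
    m$e12[wm] <- e$y; m$e13[wm] <- e$z
    s$mobiles <- m
    s
  }
  num <- -(pot(rotw(st, ha)) - pot(rotw(st, -ha))) / (2 * ha)
  expect_equal(f$water_torque[wm, 1], num, tolerance = 1e-6)
})

test_that("mobile-mobile forces obey Newton's third law", {
  # switch off the filter charges and walls so only the pair interaction acts
  cfg <- quick_config(q_carbonyl_e = 0, driving_mV = 0)
  g <- filter_geometry()
  cts <- default_contacts()
  cts["Oc", ] <- cts[, "Oc"] <- 0
  cts["LP", ] <- cts[, "LP"] <- 0
  ff <- force_field(charge = charge_model(q_carbonyl = 0),
                    repulsion = repulsion_model(contacts = cts),
                    driving_mV = 0)
  st <- init_state(g, ff, "K2K3", temperature_K = 0)
  st$mobiles$z <- c(-120, 140)
  f <- state_forces(st, cfg, geometry = g, force_field = ff)
  expect_equal(f$mobile_fz[1], -f$mobile_fz[2], tolerance = 1e-12)
  expect_lt(0, abs(f$mobile_fz[1]))
})

test_that("forces on an axial ion respect the four-fold symmetry", {
  cfg <- quick_config()
  st <- cold_state(cfg, occupancy = "K2")
  f <- state_forces(st, cfg)
  expect_lt(abs(f$mobile_f3[1, 1]), 1e-10)
  expect_lt(abs(f$mobile_f3[1, 2]), 1e-10)
  # a cage center is a stable point: displaced ion is pulled back
  st$mobiles$z <- 50
  f2 <- state_forces(st, cfg)
  expect_lt(f2$mobile_fz[1], 0)
  st$mobiles$z <- -50
  f3 <- state_forces(st, cfg)
  expect_gt(f3$mobile_fz[1], 0)
})

test_that("potential energy is invariant under 90-degree rotation", {
  cfg <- quick_config()
  g <- filter_geometry()
  ff <- force_field()
  set.seed(11)
  st <- init_state(g, ff, "K0W1K2W3K4W", temperature_K = 310)
  for (i in c(2, 9, 21)) st <- displace_carbonyl(st, i, 0.1)
  e1 <- state_energy(st, cfg, geometry = g, force_field = ff)
  e2 <- state_energy(rotate_state_90(st), cfg, geometry = g,
                     force_field = ff)
  expect_equal(e1$potential_ev, e2$potential_ev, tolerance = 1e-10)
  expect_equal(e1$kinetic_ev, e2$kinetic_ev, tolerance = 1e-10)
})

test_that("coincident charges raise a singular-configuration error", {
  cfg <- quick_config()
  st <- cold_state(cfg, occupancy = "K2K3")
  st$mobiles$z <- c(0, 0)
  expect_error(state_energy(st, cfg), "singular")
})
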