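# Shared helpers and independent oracles for the test suite.

# Physical constants, written out independently of the package internals.
KE2_EV_PM <- 1439.96455      # k_e e^2 in eV pm
KB_EV <- 8.617333262e-5      # Boltzmann constant, eV/K

quick_config <- function(...) {
  args <- utils::modifyList(
    list(duration_ns = 0.002, thermalization_ns = 0, seed = 7),
    list(...))
  do.call(sim_config, args)
}

# Cold, deterministic state for force/energy oracles.
cold_state <- function(config, occupancy = "K0W1K2W3K4W") {
  g <- filter_geometry(length_fraction = config$length_fraction,
                       ring_radius = config$ring_radius_pm)
  ff <- force_field(
    charge = charge_model(q_carbonyl = config$q_carbonyl_e,
                          lone_pair_fraction = config$lone_pair_fraction),
    repulsion = repulsion_model(strength_ev = config$repulsion_strength_ev),
    driving_mV = config$driving_mV)
  init_state(g, ff, occupancy, temperature_K = 0)
}

# Naive double-loop Coulomb + repulsion sum for a test charge on the axis,
# written against the same physics but independently of the package's
# vectorized profile code.
naive_profile_energy <- function(z, state, config) {
  ff <- force_field(
    charge = charge_model(q_carbonyl = config$q_carbonyl_e,
                          lone_pair_fraction = config$lone_pair_fraction),
    repulsion = repulsion_model(strength_ev = config$repulsion_strength_ev),
    driving_mV = config$driving_mV)
  ch <- ff$charge
  geom <- state$geometry
  total <- 0
  for (i in seq_len(nrow(geom$carbons))) {
    cpos <- geom$carbons[i, ]
    u <- state$u[i, ]
    opos <- cpos + ch$bond_length_co * u
    lpos <- cpos + (ch$bond_length_co + ch$lone_pair_offset) * u
    for (site in list(list(p = cpos, q = ch$q_carbonyl, kind = "C"),
                      list(p = opos, q = ch$q_o, kind = "Oc"),
                      list(p = lpos, q = ch$q_lp, kind = "LP"))) {
      r <- sqrt(sum((site$p - c(0, 0, z))^2))
      total <- total + KE2_EV_PM * 1 * site$q / r
      c0 <- ff$repulsion$contacts["K", site$kind]
      if (c0 > 0 && r < ff$repulsion$cutoff)
        total <- total + repulsion_energy(r, c0, ff$repulsion)
    }
  }
  total
}

# Rotate a filter_state rigidly by 90 degrees about the pore axis, using the
# four-fold symmetry of the scaffold (strand s -> s + 1 within each ring).
rotate_state_90 <- function(state) {
  g <- state$geometry
  rot <- function(v) cbind(-v[, 2], v[, 1], v[, 3])
  # carbonyl i (ring r, strand s) lands on the slot of strand s + 1
  target <- (g$ring - 1) * g$n_strands + (g$strand %% g$n_strands) + 1
  out <- state
  out$u[target, ] <- rot(state$u)
  out$w[target, ] <- rot(state$w)
  m <- state$mobiles
  rotv <- function(a, b) list(x = -b, y = a)   # (x, y) -> (-y, x)
  d <- rotv(m$d1, m$d2); e <- rotv(m$e11, m$e12); o <- rotv(m$om1, m$om2)
  m$d1 <- d$x; m$d2 <- d$y
  m$e11 <- e$x; m$e12 <- e$y
  m$om1 <- o$x; m$om2 <- o$y
  out$mobiles <- m
  out
}
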