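# Assemble the parameter list handed to the compiled engine.
engine_params <- function(config, geometry, ff,
                          record_ring = 0L, record_stride = 1L,
                          snapshot_every_fs = 0, energy_every_fs = 0) {
  ch <- ff$charge
  bd <- ff$bending
  rp <- ff$repulsion
  wt <- ff$water
  kt <- .const$KB * config$temperature_K
  dt <- config$dt_fs
  domain <- geometry$z_exit - geometry$z_floor
  e_field <- ev_to_internal(config$driving_mV / 1000) / domain
  rec_idx <- integer(0)
  if (record_ring > 0) {
    if (record_ring > geometry$n_rings) abort("`record_ring` out of range.")
    rec_idx <- which(geometry$ring == record_ring) - 1L
  }
  list(
    carbons = unname(geometry$carbons),
    rest_orientations = unname(geometry$rest_orientations),
    r_co = ch$bond_length_co, lp_off = ch$lone_pair_offset,
    q_c = ch$q_carbonyl, q_o = ch$q_o, q_lp = ch$q_lp,
    kappa = bd$kappa, i_c = bd$inertia,
    q_k = ch$q_ion, m_k = .const$M_K,
    q_wo = ch$q_water_o, q_wh = ch$q_water_h,
    m_w = wt$mass, i_w = wt$inertia,
    w_ooff = wt$o_offset, w_hpar = wt$h_par, w_hperp = wt$h_perp,
    ke2 = .const$KE2,
    rep_b = rp$b, rep_rho = rp$rho, rep_cut = rp$cutoff,
    contact = unname(rp$contacts),
    e_field = e_field,
    dt = dt, kt = kt,
    thermo_prob = config$thermostat_rate_per_ps / 1000 * dt,
    inj_rate = config$injection_rate_per_ps / 1000,
    clearance = config$injection_clearance_pm,
    z_cav = unname(geometry$site_axial_coords["S_cav"]),
    z_exit = geometry$z_exit, z_floor = geometry$z_floor,
    coupling = isTRUE(config$carbonyl_coupling),
    injection_on = isTRUE(config$injection),
    boundaries_on = isTRUE(config$boundaries),
    n_therm = round(config$thermalization_ns * 1e6 / dt),
    n_prod = round(config$duration_ns * 1e6 / dt),
    seed = as.numeric(config$seed) %% 2^31,
    rec_idx = rec_idx,
    rec_stride = as.integer(record_stride),
    snap_stride = if (snapshot_every_fs > 0)
      max(1, round(snapshot_every_fs / dt)) else 0L,
    energy_stride = if (energy_every_fs > 0)
      max(1, round(energy_every_fs / dt)) else 0L
  )
}

event_names <- c("injection", "emission_top", "return_to_cavity")

#' Run a filter simulation
#'
#' Thermalizes the configured initial state, then runs the production phase,
#' logging injection and emission events throughout. All stochastic elements
#' (thermal initial velocities, the Andersen bath, injection) derive from
#' `config$seed`; identical configs give bit-identical event logs.
#'
#' @param config A [sim_config()].
#' @param geometry,force_field,state Optional explicit overrides; by default
#'   they are built from the config.
#' @param record_ring Ring index (1 = extracellular top) whose four oxygen
#'   positions are recorded every `record_stride` steps of the production
#'   phase; 0 disables recording.
#' @param record_stride Recording stride in steps.
#' @param snapshot_every_fs Interval between full state snapshots during
#'   production, fs; 0 disables snapshots.
#' @param energy_every_fs Interval between energy-trace records, fs
#'   (thermalization included); 0 disables the trace.
#' @return A `filter_sim` object with elements `events` (tibble of
#'   injection/emission records), `summary`, `oxygen_traj` (matrix of
#'   recorded oxygen coordinates, pm), `energy` (tibble, eV), `snapshots`
#'   (list of `filter_state`), `final_state`, plus the config, geometry and
#'   force field used.
#' @examples
#' \donttest{
#' cfg <- sim_config(duration_ns = 0.01, thermalization_ns = 0.002, seed = 7)
#' sim <- simulate_filter(cfg)
#' sim$summary
#' }
#' @export
simulate_filter <- function(config,
                            geometry = NULL,
                            force_field = NULL,
                            state = NULL,
                            record_ring = 0L,
                            record_stride = 1L,
                            snapshot_every_fs = 0,
                            energy_every_fs = 0) {
  stopifnot(inherits(config, "sim_config"))
  geometry <- geometry %||% config_geometry(config)
  ff <- force_field %||% config_force_field(config)
  if (is.null(state)) {
    withr_seed <- config$seed
    old <- .Random.seed_exists()
    set.seed(withr_seed)
    state <- init_state(geometry, ff, config$occupancy, config$temperature_K)
    .Random.seed_restore(old)
  }
  params <- engine_params(config, geometry, ff,
                          record_ring = record_ring,
                          record_stride = record_stride,
                          snapshot_every_fs = snapshot_every_fs,
                          energy_every_fs = energy_every_fs)
  raw <- cpp_run_md(params, state_to_cpp(state))

  ev <- as_tibble(raw$events)
  events <- tibble(
    time_fs = ev$time_fs,
    species = ifelse(ev$species == 0L, "K", "W"),
    event = event_names[ev$event + 1L],
    particle_id = ev$particle_id,
    phase = ifelse(ev$phase == 1L, "production", "thermalization")
  )
  duration_us <- config$duration_ns / 1000
  prod <- events[events$phase == "production", ]
  n_emit_k <- sum(prod$event == "emission_top" & prod$species == "K")
  n_emit_w <- sum(prod$event == "emission_top" & prod$species == "W")
  diag <- raw$diagnostics
  summary <- tibble(
    duration_us = duration_us,
    k_emissions = n_emit_k,
    w_emissions = n_emit_w,
    k_current_per_us = n_emit_k / duration_us,
    w_current_per_us = n_emit_w / duration_us,
    injections = sum(prod$event == "injection"),
    returns = sum(prod$event == "return_to_cavity"),
    injection_attempts = diag$injection_attempts,
    order_violations = diag$order_violations,
    n_final = diag$n_final
  )
  energy <- NULL
  if (energy_every_fs > 0) {
    en <- raw$energy
    energy <- tibble(
      time_fs = en[, 1],
      ke_carbonyl_ev = internal_to_ev(en[, 2]),
      ke_translation_ev = internal_to_ev(en[, 3]),
      ke_rotation_ev = internal_to_ev(en[, 4]),
      pe_ev = internal_to_ev(en[, 5]),
      total_ev = internal_to_ev(en[, 2] + en[, 3] + en[, 4] + en[, 5]),
      n_mobiles = en[, 6]
    )
  }
  oxy <- NULL
  if (record_ring > 0) {
    oxy <- raw$oxygen
    attr(oxy, "ring") <- record_ring
    attr(oxy, "stride_fs") <- record_stride * config$dt_fs
    attr(oxy, "carbonyl") <- which(geometry$ring == record_ring)
  }
  snapshots <- lapply(raw$snapshots, cpp_to_state, geometry = geometry)
  structure(list(
    events = events,
    summary = summary,
    oxygen_traj = oxy,
    energy = energy,
    snapshots = snapshots,
    final_state = cpp_to_state(raw$final_state, geometry),
    diagnostics = diag,
    config = config,
    geometry = geometry,
    force_field = ff
  ), class = "filter_sim")
}

#' @export
print.filter_sim <- function(x, ...) {
  s <- x$summary
  cat("<filter_sim>", format(s$duration_us * 1000, digits = 4),
      "ns production at", sprintf("%.0f%%", 100 * x$config$length_fraction),
      "length, seed", x$config$seed, "\n")
  cat(sprintf("  K+ current %.1f /us (%d emissions); water %.1f /us\n",
              s$k_current_per_us, s$k_emissions, s$w_current_per_us))
  cat(sprintf("  %d injections, %d returns, %d particles in filter at end\n",
              s$injections, s$returns, s$n_final))
  invisible(x)
}

# Save/restore R's RNG state so seeded helpers do not disturb the caller.
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

#' Potential and kinetic energy of a state
#'
#' Evaluates the full potential (Coulomb, repulsion, bending, driving field)
#' and kinetic energy of a `filter_state` under a config's force field.
#'
#' @param state A `filter_state`.
#' @param config A [sim_config()] providing the force field and geometry
#'   context.
#' @param geometry,force_field Optional explicit overrides.
#' @return A tibble with one row of energy components, eV.
#' @export
state_energy <- function(state, config, geometry = NULL, force_field = NULL) {
  geometry <- geometry %||% state$geometry %||% config_geometry(config)
  ff <- force_field %||% config_force_field(config)
  params <- engine_params(config, geometry, ff)
  e <- cpp_energy(params, state_to_cpp(state))
  tibble(
    total_ev = internal_to_ev(e$total),
    potential_ev = internal_to_ev(e$potential),
    kinetic_ev = internal_to_ev(e$kinetic),
    coulomb_ev = internal_to_ev(e$coulomb),
    repulsion_ev = internal_to_ev(e$repulsion),
    bending_ev = internal_to_ev(e$bending),
    field_ev = internal_to_ev(e$field)
  )
}

#' Forces and torques acting on a state
#'
#' Returns the analytic forces the integrator would use: torques on each
#' carbonyl rotor (internal units), the axial force on each mobile, the full
#' unprojected 3D force on each mobile, and water torques. Mainly intended
#' for force/energy consistency checks.
#'
#' @inheritParams state_energy
#' @return A list of matrices/vectors in internal units.
#' @export
state_forces <- function(state, config, geometry = NULL, force_field = NULL) {
  geometry <- geometry %||% state$geometry %||% config_geometry(config)
  ff <- force_field %||% config_force_field(config)
  params <- engine_params(config, geometry, ff)
  cpp_forces(params, state_to_cpp(state))
}
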