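#' Simulation configuration
#'
#' A validated, self-contained description of one simulation run: protocol
#' settings (time step 0.25 fs, bath temperature 310 K, 4 ns thermalization
#' before the production window), geometry scaling, all force-field knobs and
#' the random seed. A config plus the package version is sufficient to
#' reproduce a run exactly.
#'
#' @param duration_ns Production duration, ns (required).
#' @param dt_fs Verlet time step, fs.
#' @param temperature_K Bath temperature, K.
#' @param thermalization_ns Thermalization period before production, ns.
#' @param length_fraction Axial filter length relative to standard.
#' @param seed Integer seed for all stochastic elements of the run.
#' @param thermostat_rate_per_ps Andersen collision rate per carbonyl oxygen,
#'   1/ps; 0 disables the bath.
#' @param injection_rate_per_ps Poisson rate of injection attempts at S_cav,
#'   1/ps (a proxy for the cavity partial pressures; attempts are blocked
#'   while the site is sterically occupied).
#' @param driving_mV Axial driving potential drop across the domain, mV.
#' @param occupancy Initial occupancy code (see [parse_occupancy()]); the
#'   default places K+ at S0, S2, S4 and water at S1, S3 and S_cav.
#' @param injection Logical switch for stochastic injection at S_cav.
#' @param boundaries `TRUE` (open): particles crossing the exit plane or the
#'   cavity floor are removed and logged. `FALSE` (closed box): particles
#'   reflect elastically at those planes instead, which holds the particle
#'   set fixed -- used for coordination-mobility windows and conservation
#'   checks.
#' @param carbonyl_coupling If `FALSE`, carbonyl groups do not interact with
#'   each other (each remains coupled to the mobiles); used for closed-form
#'   fluctuation oracles.
#' @param injection_clearance_pm Steric clearance required at S_cav for an
#'   injection attempt to succeed, pm.
#' @param ring_radius_pm,ring_spacing_pm,stagger,tilt_deg Geometry settings,
#'   see [filter_geometry()].
#' @param wavenumber_cm Carbonyl bending wavenumber, cm^-1.
#' @param q_carbonyl_e,lone_pair_fraction,lone_pair_offset_pm,bond_length_pm,
#'   q_water_o_e Charge-model settings, see [charge_model()].
#' @param repulsion_strength_ev,repulsion_rho_pm,repulsion_cutoff_pm
#'   Short-range repulsion settings, see [repulsion_model()].
#' @return A `sim_config` list.
#' @export
sim_config <- function(duration_ns,
                       dt_fs = 0.25,
                       temperature_K = 310,
                       thermalization_ns = 4,
                       length_fraction = 1,
                       seed = 1L,
                       thermostat_rate_per_ps = 1,
                       injection_rate_per_ps = 5,
                       driving_mV = 100,
                       occupancy = "K0W1K2W3K4W",
                       injection = TRUE,
                       boundaries = TRUE,
                       carbonyl_coupling = TRUE,
                       injection_clearance_pm = 280,
                       ring_radius_pm = 440,
                       ring_spacing_pm = 300,
                       stagger = FALSE,
                       tilt_deg = 0,
                       wavenumber_cm = 500,
                       q_carbonyl_e = 0.51,
                       lone_pair_fraction = 0.5,
                       lone_pair_offset_pm = 82,
                       bond_length_pm = 123,
                       q_water_o_e = -0.82,
                       repulsion_strength_ev = 0.5,
                       repulsion_rho_pm = 33,
                       repulsion_cutoff_pm = 800) {
  cfg <- as.list(environment())
  check_num <- function(name, lo = NULL, hi = NULL, open = FALSE) {
    v <- cfg[[name]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v))
      abort(sprintf("config key `%s` must be a finite number.", name))
    if (!is.null(lo) && (if (open) v <= lo else v < lo))
      abort(sprintf("config key `%s` = %g is out of range.", name, v))
    if (!is.null(hi) && (if (open) v >= hi else v > hi))
      abort(sprintf("config key `%s` = %g is out of range.", name, v))
  }
  if (missing(duration_ns)) abort("config key `duration_ns` is required.")
  check_num("duration_ns", 0, open = TRUE)
  check_num("dt_fs", 0, open = TRUE)
  check_num("temperature_K", 0, open = TRUE)
  check_num("thermalization_ns", 0)
  check_num("length_fraction", 0.5, 2, open = TRUE)
  check_num("thermostat_rate_per_ps", 0)
  check_num("injection_rate_per_ps", 0)
  check_num("driving_mV")
  check_num("injection_clearance_pm", 0)
  check_num("ring_radius_pm", 0, open = TRUE)
  check_num("ring_spacing_pm", 0, open = TRUE)
  check_num("wavenumber_cm", 0, open = TRUE)
  check_num("lone_pair_fraction", 0, 1)
  check_num("bond_length_pm", 0, open = TRUE)
  check_num("repulsion_strength_ev", 0)
  check_num("repulsion_rho_pm", 0, open = TRUE)
  check_num("repulsion_cutoff_pm", 0, open = TRUE)
  if (cfg$ring_radius_pm <= cfg$bond_length_pm)
    abort("`ring_radius_pm` must exceed the C=O bond length.")
  if (!is.character(cfg$occupancy) && !is.null(cfg$occupancy))
    abort("config key `occupancy` must be a character code or NULL.")
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %g ns production after %g ns thermalization, dt %g fs\n",
              x$duration_ns, x$thermalization_ns, x$dt_fs))
  cat(sprintf("  T = %g K, length %g%%, seed %d\n",
              x$temperature_K, 100 * x$length_fraction, x$seed))
  cat(sprintf(
    "  injection %s (%g /ps), thermostat %g /ps, driving %g mV\n",
    if (x$injection) "on" else "off", x$injection_rate_per_ps,
    x$thermostat_rate_per_ps, x$driving_mV))
  cat(sprintf("  initial occupancy: %s\n",
              if (is.null(x$occupancy)) "(empty)" else x$occupancy))
  invisible(x)
}

# Build the geometry implied by a config.
config_geometry <- function(config) {
  filter_geometry(
    length_fraction = config$length_fraction,
    ring_radius = config$ring_radius_pm,
    ring_spacing = config$ring_spacing_pm,
    stagger = config$stagger,
    tilt_deg = config$tilt_deg
  )
}

# Build the force field implied by a config.
config_force_field <- function(config) {
  force_field(
    charge = charge_model(
      q_carbonyl = config$q_carbonyl_e,
      lone_pair_fraction = config$lone_pair_fraction,
      lone_pair_offset = config$lone_pair_offset_pm,
      bond_length_co = config$bond_length_pm,
      q_water_o = config$q_water_o_e
    ),
    bending = bending_model(
      wavenumber = config$wavenumber_cm,
      bond_length_co = config$bond_length_pm
    ),
    repulsion = repulsion_model(
      strength_ev = config$repulsion_strength_ev,
      rho = config$repulsion_rho_pm,
      cutoff = config$repulsion_cutoff_pm
    ),
    driving_mV = config$driving_mV
  )
}
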