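#' Charge model for the filter and its mobile species
#'
#' Carbonyl carbons carry `+q_carbonyl`; the balancing negative charge is
#' split between the oxygen center and a lone-pair point that sits on the
#' C->O line, `lone_pair_offset` beyond the oxygen, so that it tracks the
#' oxygen rigidly as the carbonyl swings. Water carries a negative charge on
#' its oxygen and half-magnitude positive charges on each hydrogen (neutral
#' molecule with a dipole moment); the ion carries one positive unit charge.
#'
#' @param q_carbonyl Carbonyl partial charge magnitude, e.
#' @param lone_pair_fraction Fraction of the carbonyl negative charge placed
#'   at the lone-pair point (the rest stays on the oxygen center), in 0..1.
#' @param lone_pair_offset Distance of the lone-pair point beyond the oxygen
#'   along the C->O axis, pm.
#' @param bond_length_co Rigid C=O bond length, pm.
#' @param q_water_o Water oxygen partial charge, e (negative); each hydrogen
#'   gets `-q_water_o / 2`.
#' @param q_ion Ion charge, e.
#' @return A `charge_model` list.
#' @export
charge_model <- function(q_carbonyl = 0.51,
                         lone_pair_fraction = 0.5,
                         lone_pair_offset = 82,
                         bond_length_co = 123,
                         q_water_o = -0.82,
                         q_ion = 1) {
  if (lone_pair_fraction < 0 || lone_pair_fraction > 1)
    abort("`lone_pair_fraction` must lie in [0, 1].")
  if (q_water_o >= 0) abort("`q_water_o` must be negative.")
  if (bond_length_co <= 0 || lone_pair_offset < 0)
    abort("bond length must be positive and lone-pair offset non-negative.")
  structure(list(
    q_carbonyl = q_carbonyl,
    lone_pair_fraction = lone_pair_fraction,
    lone_pair_offset = lone_pair_offset,
    bond_length_co = bond_length_co,
    q_o = -q_carbonyl * (1 - lone_pair_fraction),
    q_lp = -q_carbonyl * lone_pair_fraction,
    q_water_o = q_water_o,
    q_water_h = -q_water_o / 2,
    q_ion = q_ion
  ), class = "charge_model")
}

#' Harmonic carbonyl bending model
#'
#' The oxygen vibrates at constant bond length around its rest orientation;
#' the angular restoring torque is `-kappa * theta`. The torsional constant
#' is derived from a configured vibrational wavenumber via
#' `kappa = m_O r_CO^2 (2 pi c k)^2`, so that the harmonic mode oscillates
#' with period `1 / (c k)`.
#'
#' @param wavenumber Bending wavenumber, cm^-1.
#' @param bond_length_co C=O bond length, pm.
#' @param m_o Oxygen mass, u.
#' @return A `bending_model` list with the period (fs), moment of inertia
#'   (u pm^2) and stiffness both in internal units and eV/rad^2.
#' @export
bending_model <- function(wavenumber = 500,
                          bond_length_co = 123,
                          m_o = .const$M_O) {
  if (wavenumber <= 0) abort("`wavenumber` must be positive.")
  nu <- .const$C_CM_FS * wavenumber        # frequency, 1/fs
  omega <- 2 * pi * nu
  inertia <- m_o * bond_length_co^2
  kappa <- inertia * omega^2
  structure(list(
    wavenumber = wavenumber,
    bond_length_co = bond_length_co,
    m_o = m_o,
    frequency_fs = nu,
    period_fs = 1 / nu,
    inertia = inertia,
    kappa = kappa,
    kappa_ev = internal_to_ev(kappa)
  ), class = "bending_model")
}

#' Wavenumber conversion table for the carbonyl bending mode
#'
#' Analytic conversions between bending wavenumber, frequency, oscillation
#' period, torsional stiffness and the thermal root-mean-square angular
#' amplitude at a reference temperature.
#'
#' @param wavenumbers Wavenumbers to tabulate, cm^-1.
#' @param temperature_K Reference temperature for the thermal amplitude.
#' @param bond_length_co C=O bond length, pm.
#' @return A tibble with one row per wavenumber.
#' @examples
#' bending_constants(c(250, 500, 1000))
#' @export
bending_constants <- function(wavenumbers = c(100, 250, 500, 750, 1000, 1500),
                              temperature_K = 310,
                              bond_length_co = 123) {
  rows <- lapply(wavenumbers, function(k) {
    b <- bending_model(k, bond_length_co = bond_length_co)
    sig_th <- sqrt(.const$KB * temperature_K / b$kappa)
    tibble(
      wavenumber_cm = k,
      frequency_THz = b$frequency_fs * 1e3,
      period_fs = b$period_fs,
      kappa_ev_rad2 = b$kappa_ev,
      quantum_ev = 4.135667696 * b$frequency_fs,  # h * nu in eV (nu in 1/fs)
      sigma_theta_rad = sig_th,
      sigma_o_pm = bond_length_co * sig_th
    )
  })
  dplyr::bind_rows(rows)
}

#' Short-range Born-Mayer repulsion
#'
#' Exponential wall `B exp((r0 - r) / rho)` between selected site pairs,
#' shifted in value and slope so the energy and force vanish continuously at
#' the cutoff. It prevents charge collapse between oppositely charged sites
#' and enforces single-file ordering; contact distances `r0` come from
#' ionic / van-der-Waals radii.
#'
#' @param strength_ev Wall height at the contact distance, eV.
#' @param rho Decay length, pm.
#' @param cutoff Cutoff radius, pm.
#' @param contacts Named 6x6 matrix of contact distances (pm) indexed by the
#'   site kinds C, Oc, LP, K, Ow, Hw; zero entries disable repulsion for a
#'   pair. Defaults to [default_contacts()].
#' @return A `repulsion_model` list.
#' @export
repulsion_model <- function(strength_ev = 0.5,
                            rho = 33,
                            cutoff = 800,
                            contacts = default_contacts()) {
  if (strength_ev < 0 || rho <= 0 || cutoff <= 0)
    abort("repulsion parameters must be positive.")
  stopifnot(is.matrix(contacts), all(dim(contacts) == length(.kinds)))
  structure(list(
    strength_ev = strength_ev,
    b = ev_to_internal(strength_ev),
    rho = rho,
    cutoff = cutoff,
    contacts = contacts
  ), class = "repulsion_model")
}

#' Default contact-distance table for the short-range repulsion
#'
#' @return A named 6x6 symmetric matrix of contact distances in pm; zero
#'   disables the wall for a pair. Lone-pair points carry a Pauli-type wall
#'   against the ion and the water oxygen: the lone-pair electron density is
#'   what an approaching closed-shell particle actually runs into, and this
#'   wall is what turns the ring planes into the inter-site barriers while
#'   leaving the eight-fold coordinated cage centers attractive. Fixed
#'   carbons need no wall (they are shielded behind their oxygens).
#' @export
default_contacts <- function() {
  m <- matrix(0, length(.kinds), length(.kinds),
              dimnames = list(.kinds, .kinds))
  set <- function(a, b, v) {
    m[a, b] <<- v
    m[b, a] <<- v
  }
  set("K", "K", 300)
  set("K", "Ow", 270)
  set("K", "Oc", 270)
  set("K", "LP", 205)
  set("K", "Hw", 220)
  set("Ow", "Ow", 280)
  set("Ow", "Oc", 280)
  set("Ow", "LP", 205)
  set("Ow", "Hw", 180)
  set("Hw", "Oc", 180)
  set("Hw", "Hw", 150)
  set("Oc", "Oc", 250)
  m
}

# Rigid water geometry and derived rotor constants (internal units).
water_geometry <- function(oh_pm = 100, hoh_deg = 109.47) {
  half <- hoh_deg / 2 * pi / 180
  m_o <- .const$M_O
  m_h <- .const$M_H
  m <- m_o + 2 * m_h
  zpar <- oh_pm * cos(half)               # O->H bisector component
  perp <- oh_pm * sin(half)
  com <- 2 * m_h * zpar / m               # O -> COM distance along bisector
  h_par <- zpar - com
  i1 <- m_o * com^2 + 2 * m_h * h_par^2
  i2 <- i1 + 2 * m_h * perp^2
  i3 <- 2 * m_h * perp^2
  list(oh_pm = oh_pm, hoh_deg = hoh_deg, mass = m,
       o_offset = com, h_par = h_par, h_perp = perp,
       inertia = (i1 + i2 + i3) / 3)      # isotropic-rotor approximation
}

#' Assemble the full force field
#'
#' Bundles the charge, bending and repulsion models together with the rigid
#' water geometry and the uniform axial driving field. The driving potential
#' is the drop experienced by a unit positive charge across the simulated
#' domain (floor to exit plane); it is deliberately small compared to the
#' site-to-site barriers so that it biases, but does not prevent, backward
#' motion.
#'
#' @param charge A [charge_model()].
#' @param bending A [bending_model()].
#' @param repulsion A [repulsion_model()].
#' @param driving_mV Driving potential drop across the domain, mV.
#' @param water Rigid water geometry (advanced; see source).
#' @return A `force_field` list.
#' @export
force_field <- function(charge = charge_model(),
                        bending = bending_model(),
                        repulsion = repulsion_model(),
                        driving_mV = 100,
                        water = water_geometry()) {
  stopifnot(inherits(charge, "charge_model"),
            inherits(bending, "bending_model"),
            inherits(repulsion, "repulsion_model"))
  structure(list(charge = charge, bending = bending, repulsion = repulsion,
                 driving_mV = driving_mV, water = water),
            class = "force_field")
}

#' Lone-pair point position
#'
#' The lone-pair charge sits on the C->O line, `lone_pair_offset` beyond the
#' oxygen, and rotates rigidly with the carbonyl orientation.
#'
#' @param c_pos Carbon position, length-3 numeric (pm).
#' @param orientation C->O unit vector (normalized internally if slightly
#'   off unit length; an error is raised beyond 1e-6 deviation).
#' @param model A [charge_model()].
#' @return Length-3 numeric position (pm).
#' @export
lone_pair_position <- function(c_pos, orientation, model = charge_model()) {
  n <- sqrt(sum(orientation^2))
  if (abs(n - 1) > 1e-6)
    abort("`orientation` must be a unit vector.")
  c_pos + (model$bond_length_co + model$lone_pair_offset) * orientation / n
}

#' Coulomb pair energy
#'
#' @param q1,q2 Charges, e.
#' @param r_pm Separation, pm (must be positive).
#' @return Energy in eV.
#' @examples
#' coulomb_energy(1, 1, 1000)  # 1.44 eV
#' @export
coulomb_energy <- function(q1, q2, r_pm) {
  if (any(r_pm <= 0)) abort("separation must be positive.")
  .const$KE2_EV * q1 * q2 / r_pm
}

#' Shifted-force Born-Mayer repulsion energy
#'
#' @param r_pm Separation, pm.
#' @param contact_pm Contact distance for the pair, pm.
#' @param model A [repulsion_model()].
#' @return Energy in eV (zero at and beyond the cutoff).
#' @export
repulsion_energy <- function(r_pm, contact_pm, model = repulsion_model()) {
  if (any(r_pm <= 0)) abort("separation must be positive.")
  a <- model$strength_ev * exp(contact_pm / model$rho)
  ecut <- exp(-model$cutoff / model$rho)
  e <- a * (exp(-r_pm / model$rho) - ecut) +
    (r_pm - model$cutoff) * (a / model$rho) * ecut
  ifelse(r_pm >= model$cutoff, 0, e)
}
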