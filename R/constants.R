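# Internal unit system: length pm, time fs, mass u (Da), charge e.
# The derived energy unit is u pm^2 fs^-2; 1 eV = 96.4853322 u pm^2 fs^-2.
.const <- list(
  EV      = 96.4853322,              # 1 eV in internal energy units
  KE2_EV  = 1439.96455,              # k_e * e^2 in eV pm
  KB      = 8.31446262e-3,           # Boltzmann constant, internal / K
  C_CM_FS = 2.99792458e-5,           # speed of light in cm / fs
  M_O     = 15.999,                  # atomic masses, u
  M_H     = 1.008,
  M_K     = 39.0983
)
.const$KE2 <- .const$KE2_EV * .const$EV   # Coulomb constant, internal

# Interaction-site kinds used by the repulsion table (order matters: it is
# shared with the compiled engine).
.kinds <- c("C", "Oc", "LP", "K", "Ow", "Hw")

#' Convert internal energies to electron volts
#'
#' The simulation core works in units of pm, fs, u and e; its energy unit is
#' u pm^2 fs^-2. These helpers convert to and from electron volts.
#'
#' @param x Numeric vector of energies.
#' @return Numeric vector of converted energies.
#' @export
internal_to_ev <- function(x) x / .const$EV

#' @rdname internal_to_ev
#' @export
ev_to_internal <- function(x) x * .const$EV
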