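#' Parse an occupancy code
#'
#' Occupancy codes list the site occupants from the extracellular side
#' inwards: `K` for a potassium ion, `W` for a water, with an optional site
#' digit (0 = S0 through 4 = S4; S_cav has no digit). A bare letter occupies
#' the site after the previous entry, so `"K1W2K3WW"` reads: K+ at S1, water
#' at S2, K+ at S3, then waters at S4 and S_cav.
#'
#' @param code Occupancy string, possibly empty.
#' @return A tibble with columns `species` ("K"/"W") and `site_index`
#'   (0..5, where 5 is S_cav), ordered outside to inside.
#' @examples
#' parse_occupancy("K0W1K2W3K4")
#' @export
parse_occupancy <- function(code) {
  if (is.null(code) || !nzchar(code))
    return(tibble(species = character(), site_index = integer()))
  toks <- regmatches(code, gregexpr("[A-Za-z][0-9]*", code))[[1]]
  if (sum(nchar(toks)) != nchar(code))
    abort(sprintf("malformed occupancy code: %s", code))
  species <- substr(toks, 1, 1)
  if (!all(species %in% c("K", "W")))
    abort("occupancy code may only contain K and W entries.")
  digits <- suppressWarnings(as.integer(substring(toks, 2)))
  site <- integer(length(toks))
  prev <- -1L
  for (i in seq_along(toks)) {
    site[i] <- if (is.na(digits[i])) prev + 1L else digits[i]
    prev <- site[i]
  }
  if (any(site > 5L) || any(duplicated(site)) || is.unsorted(site))
    abort(sprintf("occupancy code maps outside S0..S_cav or reuses a site: %s",
                  code))
  tibble(species = species, site_index = site)
}

#' Format site occupants as an occupancy code
#'
#' Inverse of [parse_occupancy()]: K entries always carry their site digit;
#' waters carry one only when an ion sits further inside (trailing waters
#' are written bare, matching the conventional shorthand).
#'
#' @param occupants A tibble with `species` and `site_index` columns.
#' @return A single occupancy string.
#' @export
format_occupancy <- function(occupants) {
  if (nrow(occupants) == 0) return("")
  occupants <- dplyr::arrange(occupants, .data$site_index)
  k_sites <- occupants$site_index[occupants$species == "K"]
  last_k <- if (length(k_sites)) max(k_sites) else -1L
  paste(mapply(function(sp, si) {
    if (sp == "K" || si < last_k) paste0(sp, si) else sp
  }, occupants$species, occupants$site_index), collapse = "")
}

# Rotate a 3-vector about a unit axis by an angle (Rodrigues form).
rotate_about <- function(v, axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  v * cos(angle) + pracma_cross(axis, v) * sin(angle) +
    axis * sum(axis * v) * (1 - cos(angle))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Construct an initial simulation state
#'
#' Places mobiles at the coded sites with Maxwell-Boltzmann axial velocities,
#' sets every carbonyl to its rest orientation with thermal angular
#' velocities, and gives waters random up/down dipoles with thermal angular
#' velocities. Uses R's RNG; call `set.seed()` (or rely on
#' [simulate_filter()], which seeds from the config) for reproducibility.
#'
#' @param geometry A [filter_geometry()].
#' @param force_field A [force_field()].
#' @param occupancy Occupancy code or NULL/"" for an empty filter.
#' @param temperature_K Temperature for the thermal velocity draws; 0 gives
#'   a motionless cold start.
#' @return A `filter_state` list (carbonyl orientations `u`, angular
#'   velocities `w`, a mobile table, and the time stamp).
#' @export
init_state <- function(geometry, force_field = force_field(),
                       occupancy = "K0W1K2W3K4W", temperature_K = 310) {
  occ <- parse_occupancy(occupancy)
  n <- nrow(geometry$carbons)
  kt <- .const$KB * temperature_K
  u <- geometry$rest_orientations
  w <- matrix(0, n, 3)
  if (temperature_K > 0) {
    sg <- sqrt(kt / force_field$bending$inertia)
    w <- matrix(stats::rnorm(3 * n, 0, sg), n, 3)
    w <- w - u * rowSums(w * u)            # angular velocity perpendicular to u
  }
  sites <- site_positions(geometry)
  zmap <- setNames(sites$z_pm, sites$site_index)
  nm <- nrow(occ)
  mob <- tibble(
    species = occ$species,
    z = unname(zmap[as.character(occ$site_index)]),
    vz = 0, id = seq_len(nm) - 1L,
    d1 = 0, d2 = 0, d3 = 1, e11 = 1, e12 = 0, e13 = 0,
    om1 = 0, om2 = 0, om3 = 0
  )
  # canonical order: ascending z (inside to outside), as the engine keeps it
  if (nm > 0) mob <- dplyr::arrange(mob, .data$z)
  if (nm > 0 && temperature_K > 0) {
    mass <- ifelse(mob$species == "K", .const$M_K, force_field$water$mass)
    mob$vz <- stats::rnorm(nm, 0, sqrt(kt / mass))
    isw <- mob$species == "W"
    if (any(isw)) {
      up <- ifelse(stats::runif(sum(isw)) < 0.5, 1, -1)
      phi <- stats::runif(sum(isw), 0, 2 * pi)
      mob$d3[isw] <- up
      mob$e11[isw] <- cos(phi)
      mob$e12[isw] <- sin(phi)
      mob$e13[isw] <- 0
      sgw <- sqrt(kt / force_field$water$inertia)
      mob$om1[isw] <- stats::rnorm(sum(isw), 0, sgw)
      mob$om2[isw] <- stats::rnorm(sum(isw), 0, sgw)
      mob$om3[isw] <- stats::rnorm(sum(isw), 0, sgw)
    }
  }
  structure(list(u = u, w = w, mobiles = mob, t = 0,
                 geometry = geometry),
            class = "filter_state")
}

#' Displace one carbonyl orientation
#'
#' Rotates the orientation of carbonyl `index` away from its current
#' direction by `angle` about an axis perpendicular to it (the axial
#' direction projected out, i.e. a swing in the plane containing the pore
#' axis). Useful for constructing oscillator test states.
#'
#' @param state A `filter_state`.
#' @param index Carbonyl index (1-based).
#' @param angle Rotation angle, rad.
#' @return The modified state.
#' @export
displace_carbonyl <- function(state, index, angle) {
  u <- state$u[index, ]
  axis <- pracma_cross(u, c(0, 0, 1))
  if (sqrt(sum(axis^2)) < 1e-12) axis <- c(1, 0, 0)
  state$u[index, ] <- rotate_about(u, axis, angle)
  state$w[index, ] <- state$w[index, ] -
    u * sum(state$w[index, ] * u)
  state
}

#' @export
print.filter_state <- function(x, ...) {
  cat("<filter_state> t =", x$t, "fs;",
      nrow(x$mobiles), "mobile particle(s)\n")
  if (nrow(x$mobiles) > 0) {
    sp <- x$mobiles$species
    cat("  ", paste(sprintf("%s@%.0fpm", sp, x$mobiles$z), collapse = ", "),
        "\n")
  }
  invisible(x)
}

# Convert a filter_state to the list layout the compiled engine expects
# (mobiles in ascending-z order, matching the engine's internal order).
state_to_cpp <- function(state) {
  mob <- state$mobiles
  if (nrow(mob) > 1 && is.unsorted(mob$z)) mob <- dplyr::arrange(mob, .data$z)
  list(
    u = unname(as.matrix(state$u)),
    w = unname(as.matrix(state$w)),
    mob_species = as.integer(ifelse(mob$species == "K", 0L, 1L)),
    mob_z = as.numeric(mob$z),
    mob_vz = as.numeric(mob$vz),
    mob_id = as.integer(mob$id),
    mob_d = unname(cbind(mob$d1, mob$d2, mob$d3)),
    mob_e1 = unname(cbind(mob$e11, mob$e12, mob$e13)),
    mob_om = unname(cbind(mob$om1, mob$om2, mob$om3)),
    t = state$t
  )
}

# Convert the engine's state list back to a filter_state.
cpp_to_state <- function(s, geometry) {
  n <- length(s$mob_species)
  mob <- tibble(
    species = ifelse(s$mob_species == 0L, "K", "W"),
    z = as.numeric(s$mob_z), vz = as.numeric(s$mob_vz),
    id = as.integer(s$mob_id),
    d1 = s$mob_d[, 1][seq_len(n)], d2 = s$mob_d[, 2][seq_len(n)],
    d3 = s$mob_d[, 3][seq_len(n)],
    e11 = s$mob_e1[, 1][seq_len(n)], e12 = s$mob_e1[, 2][seq_len(n)],
    e13 = s$mob_e1[, 3][seq_len(n)],
    om1 = s$mob_om[, 1][seq_len(n)], om2 = s$mob_om[, 2][seq_len(n)],
    om3 = s$mob_om[, 3][seq_len(n)]
  )
  structure(list(u = s$u, w = s$w, mobiles = mob, t = s$t,
                 geometry = geometry),
            class = "filter_state")
}
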