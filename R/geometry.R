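#' Idealized selectivity-filter scaffold
#'
#' Builds the four-fold-symmetric carbonyl lattice of the KcsA selectivity
#' filter: `n_rings` equally spaced rings of `n_strands` carbonyl carbons,
#' each with a rest C->O orientation pointing radially toward the pore axis
#' (optionally tilted). The pore axis is z, pointing from the intracellular
#' cavity (bottom) to the extracellular exit (top), with the origin at the
#' axial midpoint of the lattice. At `length_fraction = 1` the six rings span
#' 1500 pm, giving the familiar ~0.3 nm hop distance between adjacent ion
#' binding sites.
#'
#' Sites are the cage centers midway between adjacent oxygen rings, labelled
#' S0 (extracellular end) through S4, plus S_cav one site spacing below S4.
#'
#' @param length_fraction Axial scale factor relative to the standard length
#'   (dimensionless, must lie in (0.5, 2)).
#' @param ring_radius Radial distance of the carbonyl carbons from the pore
#'   axis, pm.
#' @param ring_spacing Axial distance between adjacent rings at standard
#'   length, pm.
#' @param n_rings,n_strands Lattice dimensions (6 rings x 4 strands for the
#'   TVGYG filter).
#' @param stagger If `TRUE`, alternate rings are rotated by half the strand
#'   angle (45 degrees for 4 strands).
#' @param tilt_deg Tilt of the rest C->O orientation out of the ring plane,
#'   degrees; positive tilts toward the extracellular side. Default 0
#'   (purely radial, pointing at the axis).
#' @param exit_margin Distance above the top oxygen ring at which particles
#'   are counted as emitted, pm.
#' @param floor_margin Distance below the bottom ring at which particles are
#'   returned to the cavity, pm.
#' @return A `filter_geometry` object: carbon coordinate matrix (pm), rest
#'   orientations, ring/strand indices, site axial coordinates and boundary
#'   planes.
#' @examples
#' geom <- filter_geometry()
#' site_positions(geom)
#' @export
filter_geometry <- function(length_fraction = 1,
                            ring_radius = 440,
                            ring_spacing = 300,
                            n_rings = 6,
                            n_strands = 4,
                            stagger = FALSE,
                            tilt_deg = 0,
                            exit_margin = 150,
                            floor_margin = 450) {
  if (!is.numeric(ring_radius) || ring_radius <= 0)
    abort("`ring_radius` must be a positive length in pm.")
  if (!is.numeric(ring_spacing) || ring_spacing <= 0)
    abort("`ring_spacing` must be a positive length in pm.")
  if (!is.numeric(length_fraction) ||
      length_fraction <= 0.5 || length_fraction >= 2)
    abort("`length_fraction` must lie in (0.5, 2).")
  if (n_rings < 2 || n_strands < 1)
    abort("need at least 2 rings and 1 strand.")

  ring <- rep(seq_len(n_rings), each = n_strands)
  strand <- rep(seq_len(n_strands), times = n_rings)
  # ring 1 is the extracellular top; z decreases with ring index
  z_ring <- ((n_rings - 1) / 2 - (ring - 1)) * ring_spacing * length_fraction
  phi <- (strand - 1) * 2 * pi / n_strands
  if (stagger) phi <- phi + ifelse(ring %% 2 == 0, pi / n_strands, 0)
  carbons <- cbind(x = ring_radius * cos(phi),
                   y = ring_radius * sin(phi),
                   z = z_ring)
  tilt <- tilt_deg * pi / 180
  rest <- cbind(x = -cos(phi) * cos(tilt),
                y = -sin(phi) * cos(tilt),
                z = rep(sin(tilt), length(phi)))

  z_rings <- unique(z_ring)                       # top to bottom
  cages <- (head(z_rings, -1) + tail(z_rings, -1)) / 2
  spacing <- ring_spacing * length_fraction
  site_names <- c(paste0("S", seq_len(n_rings - 1) - 1), "S_cav")
  sites <- c(cages, min(cages) - spacing)
  names(sites) <- site_names

  structure(list(
    carbons = carbons,
    rest_orientations = rest,
    ring = ring,
    strand = strand,
    n_rings = n_rings,
    n_strands = n_strands,
    ring_radius = ring_radius,
    ring_spacing = ring_spacing,
    length_fraction = length_fraction,
    stagger = stagger,
    tilt_deg = tilt_deg,
    site_axial_coords = sites,
    site_spacing = spacing,
    z_exit = max(z_rings) + exit_margin,
    z_floor = min(z_rings) - floor_margin,
    exit_margin = exit_margin,
    floor_margin = floor_margin
  ), class = "filter_geometry")
}

#' Rescale the filter along its axis
#'
#' Scales all axial coordinates about the filter's axial midpoint by
#' `fraction`, leaving radial coordinates and rest orientations untouched.
#' Site coordinates and boundary planes are rescaled consistently. Scaling
#' composes multiplicatively: scaling by 1.10 and then by 1/1.10 recovers the
#' original geometry.
#'
#' @param geom A [filter_geometry()] object.
#' @param fraction Scale factor for this operation, in (0.5, 2).
#' @return A new `filter_geometry`.
#' @export
scale_filter_length <- function(geom, fraction) {
  stopifnot(inherits(geom, "filter_geometry"))
  if (!is.numeric(fraction) || fraction <= 0.5 || fraction >= 2)
    abort("`fraction` must lie in (0.5, 2).")
  filter_geometry(
    length_fraction = geom$length_fraction * fraction,
    ring_radius = geom$ring_radius,
    ring_spacing = geom$ring_spacing,
    n_rings = geom$n_rings,
    n_strands = geom$n_strands,
    stagger = geom$stagger,
    tilt_deg = geom$tilt_deg,
    exit_margin = geom$exit_margin,
    floor_margin = geom$floor_margin
  )
}

#' Axial site coordinates of the filter
#'
#' @param geom A [filter_geometry()] object.
#' @return A tibble with one row per site (S_cav, S4, ..., S0), ordered by
#'   increasing axial coordinate `z_pm`, plus the site index used by
#'   occupancy codes (0 for S0 through 5 for S_cav).
#' @export
site_positions <- function(geom) {
  stopifnot(inherits(geom, "filter_geometry"))
  s <- geom$site_axial_coords
  tibble(
    site = names(s)[order(s)],
    site_index = match(names(s)[order(s)], names(s)) - 1L,
    z_pm = sort(unname(s))
  )
}

#' @export
print.filter_geometry <- function(x, ...) {
  cat("<filter_geometry>\n")
  cat(sprintf("  %d carbonyl groups: %d rings x %d strands\n",
              nrow(x$carbons), x$n_rings, x$n_strands))
  cat(sprintf("  length fraction %.3f (ring spacing %.1f pm, radius %.1f pm)\n",
              x$length_fraction, x$site_spacing, x$ring_radius))
  ext <- diff(range(x$carbons[, "z"]))
  cat(sprintf("  axial extent %.0f pm; exit plane %+.0f pm, floor %+.0f pm\n",
              ext, x$z_exit, x$z_floor))
  cat("  sites (pm):",
      paste(sprintf("%s=%+.0f", names(x$site_axial_coords),
                    x$site_axial_coords), collapse = " "), "\n")
  invisible(x)
}
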