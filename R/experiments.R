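#' Occupancy pattern of a state
#'
#' Assigns every mobile particle to the nearest binding site (S0..S4, S_cav)
#' within a capture radius (default half the site spacing) and formats the
#' result as an occupancy code such as `"K0W1K2W3K4"`. Particles outside any
#' capture radius are omitted; two particles captured by one site raise an
#' error (sterically this should be impossible).
#'
#' @param state A `filter_state`.
#' @param geometry A [filter_geometry()]; defaults to the one carried by the
#'   state.
#' @param capture_fraction Capture radius as a fraction of the site spacing.
#' @return A single occupancy string (empty for an empty filter).
#' @export
occupancy_pattern <- function(state, geometry = NULL,
                              capture_fraction = 0.5) {
  geometry <- geometry %||% state$geometry
  mob <- state$mobiles
  if (nrow(mob) == 0) return("")
  sites <- site_positions(geometry)
  capture <- capture_fraction * geometry$site_spacing
  idx <- vapply(mob$z, function(z) {
    d <- abs(sites$z_pm - z)
    j <- which.min(d)
    if (d[j] <= capture) sites$site_index[j] else NA_integer_
  }, integer(1))
  keep <- !is.na(idx)
  if (any(duplicated(idx[keep])))
    abort("two particles captured by one site: ambiguous occupancy.")
  format_occupancy(tibble(species = mob$species[keep],
                          site_index = idx[keep]))
}

#' Ion current from an event log
#'
#' Counts production-phase emissions at the extracellular exit and divides
#' by the production duration; the uncertainty is the Poisson counting error
#' `sqrt(n) / duration`.
#'
#' @param x A `filter_sim` or an events tibble as produced by one.
#' @param duration_us Production duration in microseconds (taken from the
#'   sim when `x` is a `filter_sim`).
#' @return A tibble with one row per species: emission count, current and
#'   uncertainty in ions per microsecond.
#' @export
current_estimate <- function(x, duration_us = NULL) {
  if (inherits(x, "filter_sim")) {
    duration_us <- duration_us %||% x$summary$duration_us
    x <- x$events
  }
  if (is.null(duration_us) || duration_us <= 0)
    abort("`duration_us` must be a positive duration.")
  em <- x[x$event == "emission_top" & x$phase == "production", ]
  purrr::map_dfr(c("K", "W"), function(sp) {
    n <- sum(em$species == sp)
    tibble(species = sp, emissions = n, duration_us = duration_us,
           current_per_us = n / duration_us,
           se_per_us = sqrt(n) / duration_us)
  })
}

# Deterministic per-replicate seed derivation (31-bit).
derive_seed <- function(base_seed, index) {
  as.integer((as.numeric(base_seed) * 7919 + 104729 * index) %% 2147483629)
}

#' Conduction-rate scan over filter lengths
#'
#' Runs independent seeded replicates of the configured simulation at each
#' length fraction and collects the K+ (and water) currents. Replicate seeds
#' are derived deterministically from the base config seed. A replicate that
#' fails is recorded and the scan continues.
#'
#' @param config A [sim_config()]; its `length_fraction` is overridden by
#'   `fractions`.
#' @param fractions Length fractions to scan (1 = standard length).
#' @param replicates Independent replicates per length.
#' @return A `length_scan` object with `currents` (per-replicate tibble),
#'   `summary` (per-length mean and SD of the K+ current, with the length
#'   expressed as percent deviation from standard) and `failures`.
#' @export
length_scan <- function(config, fractions = seq(0.92, 1.10, by = 0.02),
                        replicates = 8) {
  grid <- tidyr::expand_grid(fraction = fractions,
                             replicate = seq_len(replicates))
  res <- purrr::pmap(grid, function(fraction, replicate) {
    cfg <- config
    cfg$length_fraction <- fraction
    cfg$seed <- derive_seed(config$seed,
                            match(fraction, fractions) * 1000 + replicate)
    out <- tryCatch(simulate_filter(cfg), error = function(e) e)
    if (inherits(out, "error")) {
      list(ok = FALSE, fraction = fraction, replicate = replicate,
           message = conditionMessage(out))
    } else {
      s <- out$summary
      list(ok = TRUE, fraction = fraction, replicate = replicate,
           seed = cfg$seed, k_current = s$k_current_per_us,
           w_current = s$w_current_per_us, k_emissions = s$k_emissions)
    }
  })
  ok <- purrr::keep(res, "ok")
  bad <- purrr::discard(res, "ok")
  currents <- purrr::map_dfr(ok, function(r) {
    tibble(fraction = r$fraction, percent = 100 * (r$fraction - 1),
           replicate = r$replicate, seed = r$seed,
           k_current = r$k_current, w_current = r$w_current,
           k_emissions = r$k_emissions)
  })
  summary <- currents |>
    dplyr::group_by(.data$fraction, .data$percent) |>
    dplyr::summarise(mean_current = mean(.data$k_current),
                     sd_current = if (dplyr::n() > 1) sd(.data$k_current)
                                  else NA_real_,
                     n = dplyr::n(), .groups = "drop")
  failures <- purrr::map_dfr(bad, function(r) {
    tibble(fraction = r$fraction, replicate = r$replicate,
           message = r$message)
  })
  structure(list(currents = currents, summary = summary,
                 failures = failures, config = config),
            class = "length_scan")
}

#' @export
print.length_scan <- function(x, ...) {
  cat("<length_scan>", nrow(x$currents), "runs over",
      nrow(x$summary), "lengths\n")
  print(x$summary)
  if (nrow(x$failures) > 0)
    cat(nrow(x$failures), "replicate(s) failed\n")
  invisible(x)
}

#' Gaussian fit to a conduction curve
#'
#' Fits `I(x) = I0 exp(-(x - x0)^2 / (2 w^2))` to per-length mean currents
#' by nonlinear least squares, weighted by `1 / SD^2` where replicate SDs
#' are available. `x` is the filter length as percent deviation from
#' standard.
#'
#' @param x A `length_scan` or a data frame with columns `percent` and
#'   `mean_current` (optionally `sd_current`).
#' @param weighted Use inverse-variance weights when SDs are present.
#' @return A `current_fit` object; see [tidy()] and [glance()] methods.
#' @export
fit_gaussian_current <- function(x, weighted = TRUE) {
  data <- if (inherits(x, "length_scan")) x$summary else as_tibble(x)
  if (!all(c("percent", "mean_current") %in% names(data)))
    abort("need columns `percent` and `mean_current`.")
  data <- data[is.finite(data$mean_current), ]
  if (length(unique(data$percent)) < 4)
    abort("Gaussian fit needs at least 4 distinct lengths.")
  if (all(data$mean_current == 0))
    abort("all currents are zero: no peak to fit.")
  wts <- rep(1, nrow(data))
  if (weighted && "sd_current" %in% names(data) &&
      any(is.finite(data$sd_current) & data$sd_current > 0)) {
    s <- data$sd_current
    s[!is.finite(s) | s <= 0] <- stats::median(s[is.finite(s) & s > 0])
    wts <- 1 / s^2
  }
  i0 <- max(data$mean_current)
  x0 <- data$percent[which.max(data$mean_current)]
  wsp <- sqrt(sum(wts * data$mean_current *
                    (data$percent - x0)^2) /
                sum(wts * data$mean_current))
  if (!is.finite(wsp) || wsp <= 0) wsp <- diff(range(data$percent)) / 4
  do_fit <- function(start) {
    minpack.lm::nlsLM(
      mean_current ~ I0 * exp(-(percent - x0)^2 / (2 * w^2)),
      data = data, weights = wts, start = start,
      control = minpack.lm::nls.lm.control(maxiter = 200))
  }
  start <- list(I0 = i0, x0 = x0, w = wsp)
  fit <- tryCatch(do_fit(start), error = function(e) e)
  if (inherits(fit, "error")) {
    # a start that already fits exactly has a singular gradient; nudge it
    fit <- tryCatch(
      do_fit(list(I0 = 1.1 * i0, x0 = x0 + 0.3 * wsp, w = 1.2 * wsp)),
      error = function(e) {
        abort(sprintf(
          "Gaussian fit did not converge (%s); starting values I0=%.3g x0=%.3g w=%.3g",
          conditionMessage(e), i0, x0, wsp))
      })
  }
  est <- coef(fit)
  est["w"] <- abs(est["w"])
  structure(list(fit = fit, data = data, estimate = est),
            class = "current_fit")
}

#' @export
print.current_fit <- function(x, ...) {
  e <- x$estimate
  cat(sprintf(
    "<current_fit> I(x) = %.1f * exp(-(x - %.3f)^2 / (2 * %.3f^2)) ions/us\n",
    e["I0"], e["x0"], e["w"]))
  invisible(x)
}

#' @rdname fit_gaussian_current
#' @param object,x A `current_fit`.
#' @param ... Unused.
#' @export
tidy.current_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2],
         statistic = s[, 3], p.value = s[, 4])
}

#' @rdname fit_gaussian_current
#' @export
glance.current_fit <- function(x, ...) {
  e <- x$estimate
  r <- stats::resid(x$fit)
  tibble(I0 = unname(e["I0"]), x0 = unname(e["x0"]), w = unname(e["w"]),
         sigma = sqrt(sum(r^2) / max(1, length(r) - 3)),
         df.residual = length(r) - 3, nobs = length(r))
}

#' Carbonyl-oxygen fluctuation statistics
#'
#' Computes, for each recorded oxygen, the deviation of its position from
#' its own trajectory mean, pools the four ring oxygens, and reports the
#' mean Euclidean (3D) deviation, the fraction of samples whose deviation
#' exceeds a threshold, per-axis standard deviations and binned histograms
#' of the z-deviation and the total deviation.
#'
#' @param x A `filter_sim` run with `record_ring` set, or a numeric matrix
#'   of recorded positions with 3 columns (x, y, z in pm) per oxygen.
#' @param threshold_pm Tail threshold for the total deviation, pm.
#' @param bin_pm Histogram bin width, pm.
#' @return A `fluctuation_stats` object: `summary` (one-row tibble),
#'   `per_axis`, and `histogram` tibbles.
#' @export
oxygen_fluctuation_stats <- function(x, threshold_pm = 12, bin_pm = 0.5) {
  traj <- if (inherits(x, "filter_sim")) x$oxygen_traj else x
  if (is.null(traj) || !is.matrix(traj) || nrow(traj) == 0)
    abort("no recorded oxygen trajectory; run with `record_ring`.")
  if (ncol(traj) %% 3 != 0)
    abort("trajectory matrix must have 3 columns per oxygen.")
  n_oxy <- ncol(traj) / 3
  devs <- vector("list", n_oxy)
  zdevs <- vector("list", n_oxy)
  ax_ss <- matrix(0, n_oxy, 3)
  for (k in seq_len(n_oxy)) {
    cols <- (3 * (k - 1) + 1):(3 * k)
    block <- traj[, cols, drop = FALSE]
    mu <- colMeans(block)
    block <- sweep(block, 2, mu)
    devs[[k]] <- sqrt(rowSums(block^2))
    zdevs[[k]] <- block[, 3]
    ax_ss[k, ] <- colMeans(block^2)
  }
  dev <- unlist(devs)
  zdev <- unlist(zdevs)
  summary <- tibble(
    n_frames = nrow(traj),
    n_oxygens = n_oxy,
    n_samples = length(dev),
    mean_total_dev_pm = mean(dev),
    sd_total_dev_pm = sd(dev),
    threshold_pm = threshold_pm,
    tail_fraction = mean(dev > threshold_pm)
  )
  per_axis <- tibble(
    axis = c("x", "y", "z"),
    sd_pm = sqrt(colMeans(ax_ss))
  )
  brk_t <- seq(0, max(dev) + bin_pm, by = bin_pm)
  ht <- graphics::hist(dev, breaks = brk_t, plot = FALSE)
  brk_z <- seq(min(zdev) - bin_pm, max(zdev) + bin_pm, by = bin_pm)
  hz <- graphics::hist(zdev, breaks = brk_z, plot = FALSE)
  histogram <- dplyr::bind_rows(
    tibble(quantity = "total", mid_pm = ht$mids, count = ht$counts,
           frequency = ht$counts / length(dev)),
    tibble(quantity = "z", mid_pm = hz$mids, count = hz$counts,
           frequency = hz$counts / length(zdev))
  )
  structure(list(summary = summary, per_axis = per_axis,
                 histogram = histogram),
            class = "fluctuation_stats")
}

#' @export
print.fluctuation_stats <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<fluctuation_stats> %d samples from %d oxygens\n  mean 3D deviation %.3f pm; P(> %g pm) = %.3f%%\n",
    s$n_samples, s$n_oxygens, s$mean_total_dev_pm, s$threshold_pm,
    100 * s$tail_fraction))
  invisible(x)
}

#' Test-charge potential profile between two sites
#'
#' Scans a unit positive test charge along the pore axis between two sites
#' and evaluates its potential energy (Coulomb plus short-range repulsion,
#' optionally the driving field) against the instantaneous charge
#' configuration of a state. Mobile particles inside the probed interval
#' (extended by half a site spacing on both ends) are excluded from the
#' source set by default, so the profile shows the landscape a transiting
#' ion would face. Grid points that coincide with a source charge are
#' masked (`NA`) and reported.
#'
#' The barrier height is the profile maximum minus the preceding minimum on
#' the lower-z (inner) side; both local minima are also reported.
#'
#' @param state A `filter_state` (e.g. a snapshot from [simulate_filter()]).
#' @param config A [sim_config()] providing the force field.
#' @param from,to Site labels bounding the scan (defaults S1 to S0).
#' @param n_grid Number of grid points.
#' @param exclude `"interval"` (default) removes mobiles inside the probed
#'   interval from the sources; `"mobiles"` removes every mobile particle,
#'   leaving the instantaneous filter (carbonyl + lone-pair) landscape that
#'   the vibrating oxygens modulate -- the convention for inter-site barrier
#'   snapshots, since any ion elsewhere in the file otherwise tilts the
#'   whole interval by its bare Coulomb tail; `"none"` keeps everything.
#' @param include_field Include the driving-field term.
#' @param geometry,force_field Optional explicit overrides.
#' @return A `potential_profile` object: `profile` tibble (`z_pm`,
#'   `energy_ev`), `barrier_ev`, `z_max_pm`, `minima` and bookkeeping.
#' @export
potential_profile <- function(state, config, from = "S1", to = "S0",
                              n_grid = 201,
                              exclude = c("interval", "mobiles", "none"),
                              include_field = TRUE,
                              geometry = NULL, force_field = NULL) {
  exclude <- match.arg(exclude)
  geometry <- geometry %||% state$geometry %||% config_geometry(config)
  ff <- force_field %||% config_force_field(config)
  sites <- geometry$site_axial_coords
  if (!from %in% names(sites) || !to %in% names(sites))
    abort("`from` and `to` must be site labels (S0..S4, S_cav).")
  z1 <- unname(sites[[from]])
  z2 <- unname(sites[[to]])
  zlo <- min(z1, z2); zhi <- max(z1, z2)
  src <- profile_sources(state, geometry, ff)
  if (exclude == "interval") {
    pad <- geometry$site_spacing / 2
    drop <- src$mobile & src$z_owner >= zlo - pad & src$z_owner <= zhi + pad
    src <- src[!drop, ]
  } else if (exclude == "mobiles") {
    src <- src[!src$mobile, ]
  }
  zg <- seq(zlo, zhi, length.out = n_grid)
  ch <- ff$charge
  rp <- ff$repulsion
  kkind <- match("K", .kinds)
  e <- vapply(zg, function(z) {
    dx <- src$x; dy <- src$y; dz <- src$z - z
    r <- sqrt(dx^2 + dy^2 + dz^2)
    if (any(r < 1)) return(NA_real_)
    ec <- sum(.const$KE2_EV * ch$q_ion * src$q / r)
    c0 <- rp$contacts[kkind, src$kind]
    sel <- c0 > 0 & r < rp$cutoff
    er <- if (any(sel))
      sum(repulsion_energy(r[sel], c0[sel], rp)) else 0
    ec + er
  }, numeric(1))
  if (include_field) {
    domain <- geometry$z_exit - geometry$z_floor
    e <- e - (config$driving_mV / 1000) * ch$q_ion * zg / domain
  }
  masked <- sum(is.na(e))
  imax <- which.max(e)
  pre <- e[seq_len(imax)]
  barrier <- if (imax > 1) e[imax] - min(pre, na.rm = TRUE) else 0
  minima <- tibble(
    side = c(from, to),
    energy_ev = c(min(e[seq_len(imax)], na.rm = TRUE),
                  min(e[imax:length(e)], na.rm = TRUE))
  )
  structure(list(
    profile = tibble(z_pm = zg, energy_ev = e),
    barrier_ev = barrier,
    z_max_pm = zg[imax],
    minima = minima,
    masked_points = masked,
    from = from, to = to,
    time_fs = state$t
  ), class = "potential_profile")
}

# Flatten a state into a table of source point charges.
profile_sources <- function(state, geometry, ff) {
  ch <- ff$charge
  n <- nrow(geometry$carbons)
  u <- state$u
  cpos <- geometry$carbons
  opos <- cpos + ch$bond_length_co * u
  lpos <- cpos + (ch$bond_length_co + ch$lone_pair_offset) * u
  src <- tibble(
    x = c(cpos[, 1], opos[, 1], lpos[, 1]),
    y = c(cpos[, 2], opos[, 2], lpos[, 2]),
    z = c(cpos[, 3], opos[, 3], lpos[, 3]),
    q = c(rep(ch$q_carbonyl, n), rep(ch$q_o, n), rep(ch$q_lp, n)),
    kind = c(rep(1L, n), rep(2L, n), rep(3L, n)),
    mobile = FALSE,
    z_owner = c(cpos[, 3], cpos[, 3], cpos[, 3])
  )
  mob <- state$mobiles
  if (nrow(mob) > 0) {
    wt <- ff$water
    rows <- purrr::pmap_dfr(mob, function(species, z, vz, id,
                                          d1, d2, d3, e11, e12, e13, ...) {
      if (species == "K") {
        tibble(x = 0, y = 0, z = z, q = ch$q_ion, kind = 4L,
               mobile = TRUE, z_owner = z)
      } else {
        d <- c(d1, d2, d3); e1 <- c(e11, e12, e13)
        o <- c(0, 0, z) - wt$o_offset * d
        h1 <- c(0, 0, z) + wt$h_par * d + wt$h_perp * e1
        h2 <- c(0, 0, z) + wt$h_par * d - wt$h_perp * e1
        tibble(x = c(o[1], h1[1], h2[1]),
               y = c(o[2], h1[2], h2[2]),
               z = c(o[3], h1[3], h2[3]),
               q = c(ch$q_water_o, ch$q_water_h, ch$q_water_h),
               kind = c(5L, 6L, 6L), mobile = TRUE, z_owner = z)
      }
    })
    src <- dplyr::bind_rows(src, rows)
  }
  src
}

#' @export
print.potential_profile <- function(x, ...) {
  cat(sprintf(
    "<potential_profile> %s -> %s at t = %.1f fs: barrier %.3f eV (max at %.0f pm)\n",
    x$from, x$to, x$time_fs, x$barrier_ev, x$z_max_pm))
  if (x$masked_points > 0)
    cat("  ", x$masked_points, "grid point(s) masked near source charges\n")
  invisible(x)
}

#' Event statistics: residence times, intervals, bursts
#'
#' Matches injections to emissions by particle id to obtain per-ion
#' residence times, computes inter-emission intervals for K+ ions, and
#' groups emissions separated by less than `gap_ps` into bursts.
#'
#' @param x A `filter_sim` or an events tibble.
#' @param gap_ps Burst gap threshold, ps.
#' @param species Species for the interval/burst statistics.
#' @return A list with tibbles `residence`, `intervals`, `bursts` and a
#'   one-row `summary`.
#' @export
event_statistics <- function(x, gap_ps = 10, species = "K") {
  ev <- if (inherits(x, "filter_sim")) x$events else x
  inj <- ev[ev$event == "injection", c("particle_id", "species", "time_fs")]
  out <- ev[ev$event == "emission_top", c("particle_id", "time_fs")]
  names(inj)[3] <- "t_in_fs"
  names(out)[2] <- "t_out_fs"
  residence <- dplyr::inner_join(inj, out, by = "particle_id") |>
    dplyr::mutate(residence_ns = (.data$t_out_fs - .data$t_in_fs) / 1e6)
  em <- ev[ev$event == "emission_top" & ev$species == species &
             ev$phase == "production", ]
  tt <- sort(em$time_fs)
  intervals <- tibble(interval_ns = diff(tt) / 1e6)
  bursts <- tibble(burst_id = integer(), size = integer(),
                   start_fs = numeric(), end_fs = numeric())
  if (length(tt) > 0) {
    gap_fs <- gap_ps * 1000
    grp <- cumsum(c(1, as.integer(diff(tt) > gap_fs)))
    bursts <- tibble(time_fs = tt, burst_id = grp) |>
      dplyr::group_by(.data$burst_id) |>
      dplyr::summarise(size = dplyr::n(), start_fs = min(.data$time_fs),
                       end_fs = max(.data$time_fs), .groups = "drop")
  }
  summary <- tibble(
    n_residence = nrow(residence),
    mean_residence_ns = if (nrow(residence)) mean(residence$residence_ns)
                        else NA_real_,
    mean_interval_ns = if (nrow(intervals)) mean(intervals$interval_ns)
                       else NA_real_,
    n_bursts = nrow(bursts),
    mean_burst_size = if (nrow(bursts)) mean(bursts$size) else NA_real_,
    gap_ps = gap_ps
  )
  list(residence = as_tibble(residence), intervals = intervals,
       bursts = bursts, summary = summary)
}
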