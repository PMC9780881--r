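#' Read a simulation configuration from a YAML file
#'
#' Keys mirror the arguments of [sim_config()]; absent keys take the
#' protocol defaults (0.25 fs step, 310 K, 4 ns thermalization). Unknown or
#' out-of-range keys raise a validation error naming the offending key.
#'
#' @param path Path to a YAML file.
#' @return A validated [sim_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  allowed <- names(formals(sim_config))
  unknown <- setdiff(names(vals), allowed)
  if (length(unknown) > 0)
    abort(sprintf("unknown config key(s): %s",
                  paste(unknown, collapse = ", ")))
  do.call(sim_config, vals)
}

config_hash <- function(config) {
  rlang::hash(unclass(config))
}

#' Write an event log to CSV
#'
#' Header comment lines carry the seed and a hash of the config so that any
#' analysis of the file can be traced back to the run that produced it.
#' [read_events()] restores the records exactly.
#'
#' @param x A `filter_sim` or an events tibble.
#' @param path Output path.
#' @param config Config for the header when `x` is a bare tibble.
#' @return The path, invisibly.
#' @export
write_events <- function(x, path, config = NULL) {
  if (inherits(x, "filter_sim")) {
    config <- config %||% x$config
    x <- x$events
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config)) {
    writeLines(sprintf("# seed=%d", config$seed), con)
    writeLines(sprintf("# config_hash=%s", config_hash(config)), con)
  }
  writeLines("# units: time_fs in femtoseconds", con)
  utils::write.csv(as.data.frame(x), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  as_tibble(utils::read.csv(path, comment.char = "#",
                            stringsAsFactors = FALSE))
}

# Flatten one filter_state into an atom table (element, x, y, z in pm).
state_atoms <- function(state, force_field, include_lone_pairs = FALSE) {
  geometry <- state$geometry
  ch <- force_field$charge
  wt <- force_field$water
  cpos <- geometry$carbons
  opos <- cpos + ch$bond_length_co * state$u
  out <- list(
    tibble(element = "C", x = cpos[, 1], y = cpos[, 2], z = cpos[, 3]),
    tibble(element = "O", x = opos[, 1], y = opos[, 2], z = opos[, 3])
  )
  if (include_lone_pairs) {
    lpos <- cpos + (ch$bond_length_co + ch$lone_pair_offset) * state$u
    out <- c(out, list(tibble(element = "X",
                              x = lpos[, 1], y = lpos[, 2], z = lpos[, 3])))
  }
  mob <- state$mobiles
  if (nrow(mob) > 0) {
    rows <- purrr::pmap_dfr(mob, function(species, z, vz, id,
                                          d1, d2, d3, e11, e12, e13, ...) {
      if (species == "K") {
        tibble(element = "K", x = 0, y = 0, z = z)
      } else {
        d <- c(d1, d2, d3); e1 <- c(e11, e12, e13)
        o <- c(0, 0, z) - wt$o_offset * d
        h1 <- c(0, 0, z) + wt$h_par * d + wt$h_perp * e1
        h2 <- c(0, 0, z) + wt$h_par * d - wt$h_perp * e1
        tibble(element = c("O", "H", "H"),
               x = c(o[1], h1[1], h2[1]),
               y = c(o[2], h1[2], h2[2]),
               z = c(o[3], h1[3], h2[3]))
      }
    })
    out <- c(out, list(rows))
  }
  dplyr::bind_rows(out)
}

#' Write simulation snapshots as a trajectory file
#'
#' Extended-XYZ (default) or minimal multi-model PDB. Coordinates are
#' converted from pm to Angstrom. Each XYZ frame's comment line carries the
#' snapshot time in fs; PDB frames are wrapped in MODEL/ENDMDL with a
#' CRYST1 record. Lone-pair points can be included as pseudo-atoms
#' (element X).
#'
#' @param sim A `filter_sim` run with `snapshot_every_fs` set, or a list of
#'   `filter_state` objects.
#' @param path Output path.
#' @param format `"xyz"` or `"pdb"`.
#' @param force_field Needed when `sim` is a bare list of states.
#' @param include_lone_pairs Write lone-pair pseudo-atoms.
#' @return The path, invisibly.
#' @export
write_trajectory <- function(sim, path, format = c("xyz", "pdb"),
                             force_field = NULL,
                             include_lone_pairs = FALSE) {
  format <- match.arg(format)
  if (inherits(sim, "filter_sim")) {
    force_field <- force_field %||% sim$force_field
    states <- sim$snapshots
  } else {
    states <- sim
  }
  if (length(states) == 0) abort("no snapshots to write.")
  if (is.null(force_field)) abort("`force_field` is required.")
  con <- file(path, "w")
  on.exit(close(con))
  for (si in seq_along(states)) {
    st <- states[[si]]
    at <- state_atoms(st, force_field, include_lone_pairs)
    if (format == "xyz") {
      writeLines(as.character(nrow(at)), con)
      writeLines(sprintf(
        "time_fs=%.4f units=Angstrom (converted from pm)", st$t), con)
      writeLines(sprintf("%-2s %12.6f %12.6f %12.6f", at$element,
                         at$x / 100, at$y / 100, at$z / 100), con)
    } else {
      writeLines(sprintf("MODEL     %4d", si), con)
      writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                         50, 50, 50, 90, 90, 90), con)
      for (i in seq_len(nrow(at))) {
        writeLines(sprintf(
          "ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          i, substr(at$element[i], 1, 1), "FIL", 1,
          at$x[i] / 100, at$y[i] / 100, at$z[i] / 100, 1, 0,
          substr(at$element[i], 1, 1)), con)
      }
      writeLines("ENDMDL", con)
    }
  }
  invisible(path)
}

#' Read an XYZ trajectory written by [write_trajectory()]
#'
#' @param path Path to an extended-XYZ file.
#' @return A list of tibbles (element, x, y, z in pm; time in attribute
#'   `time_fs`).
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    t_fs <- as.numeric(sub(".*time_fs=([0-9eE.+-]+).*", "\\1", lines[i + 1]))
    block <- lines[(i + 2):(i + 1 + n)]
    parts <- strsplit(trimws(block), "\\s+")
    fr <- tibble(
      element = vapply(parts, `[[`, "", 1),
      x = as.numeric(vapply(parts, `[[`, "", 2)) * 100,
      y = as.numeric(vapply(parts, `[[`, "", 3)) * 100,
      z = as.numeric(vapply(parts, `[[`, "", 4)) * 100
    )
    attr(fr, "time_fs") <- t_fs
    frames[[length(frames) + 1]] <- fr
    i <- i + 2 + n
  }
  frames
}

#' Run manifest
#'
#' A reproducibility record for a finished run: the full config snapshot,
#' seed, package version, event counts and the inventory of files written
#' from it.
#'
#' @param sim A `filter_sim`.
#' @param files Character vector of output files produced from this run.
#' @param path Optional path; when given the manifest is written as JSON.
#' @return The manifest list, invisibly when written.
#' @export
run_manifest <- function(sim, files = character(), path = NULL) {
  man <- list(
    package = "kcsafilter",
    version = as.character(utils::packageVersion("kcsafilter")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = sim$config$seed,
    config = unclass(sim$config),
    config_hash = config_hash(sim$config),
    event_counts = as.list(table(sim$events$event)),
    summary = as.list(sim$summary),
    outputs = as.list(files)
  )
  if (!is.null(path)) {
    jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    return(invisible(man))
  }
  man
}
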