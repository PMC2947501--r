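PULSE_LOG_SCHEMA <- "1.0"
AMBER_TIME_FACTOR <- 20.455 # AMBER velocity unit = A per 1/20.455 ps

#' Read an AMBER ASCII restart (rst7) file
#'
#' Parses the classic fixed-width ASCII restart dialect: a title line; a
#' line with the atom count and optionally the time in ps; coordinates
#' as six \%12.7f values per line; then optionally velocities in the
#' same layout and optionally one box line of six values. A file whose
#' value count matches neither "coordinates only" nor "coordinates +
#' velocities" (each with or without a box line) is rejected rather
#' than padded. "No velocities" is distinguished from "zero velocities"
#' by \code{has_velocities}.
#'
#' Restart velocities are left in AMBER units (A per 1/20.455 ps);
#' convert with [convert_velocity_units()] before building a
#' [particle_system()].
#'
#' @param path Path to the restart file.
#' @return List of class \code{rst7_state}: \code{title},
#'   \code{n_atoms}, \code{time_ps} (NA when absent), \code{coordinates}
#'   (n x 3, A), \code{velocities} (n x 3 or NULL),
#'   \code{has_velocities}, \code{box} (length 6 or NULL).
#' @export
read_rst7 <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3) {
    stop("truncated rst7 file: fewer than 3 lines", call. = FALSE)
  }
  title <- lines[1]
  hdr <- strsplit(trimws(lines[2]), "\\s+")[[1]]
  n_atoms <- suppressWarnings(as.integer(hdr[1]))
  if (is.na(n_atoms) || n_atoms < 1) {
    stop("rst7 parse error at line 2: bad atom count", call. = FALSE)
  }
  time_ps <- if (length(hdr) >= 2) suppressWarnings(as.numeric(hdr[2])) else NA_real_

  parse_fixed <- function(line, lineno, n_expected) {
    if (nchar(line) < 12 * n_expected) {
      stop(sprintf("rst7 parse error at line %d: line too short (%d chars, need %d)",
                   lineno, nchar(line), 12 * n_expected), call. = FALSE)
    }
    vals <- vapply(seq_len(n_expected), function(k) {
      field <- substr(line, 12 * (k - 1) + 1, 12 * k)
      suppressWarnings(as.numeric(field))
    }, numeric(1))
    if (any(is.na(vals))) {
      stop(sprintf("rst7 parse error at line %d: non-numeric field", lineno),
           call. = FALSE)
    }
    vals
  }
  read_block <- function(first_line, n_values) {
    n_lines <- ceiling(n_values / 6)
    if (first_line + n_lines - 1 > length(lines)) {
      stop(sprintf("truncated rst7 file: expected %d data lines from line %d",
                   n_lines, first_line), call. = FALSE)
    }
    vals <- numeric(0)
    for (li in seq_len(n_lines)) {
      n_here <- if (li < n_lines) 6 else n_values - 6 * (n_lines - 1)
      vals <- c(vals, parse_fixed(lines[first_line + li - 1],
                                  first_line + li - 1, n_here))
    }
    vals
  }

  nv <- 3 * n_atoms
  coord_lines <- ceiling(nv / 6)
  coords <- read_block(3, nv)
  remaining <- length(lines) - 2 - coord_lines
  # trailing blank lines do not count
  while (remaining > 0 &&
         !nzchar(trimws(lines[2 + coord_lines + remaining]))) {
    remaining <- remaining - 1
  }
  vel <- NULL; box <- NULL
  if (remaining == 0) {
    # coordinates only
  } else if (remaining == coord_lines) {
    vel <- read_block(3 + coord_lines, nv)
  } else if (remaining == coord_lines + 1) {
    vel <- read_block(3 + coord_lines, nv)
    box <- parse_fixed(lines[2 + 2 * coord_lines + 1], 2 + 2 * coord_lines + 1, 6)
  } else if (remaining == 1) {
    box <- parse_fixed(lines[2 + coord_lines + 1], 2 + coord_lines + 1, 6)
  } else {
    stop(sprintf(paste("rst7 structural error: %d data lines after the",
                       "coordinate block do not match velocities and/or box",
                       "for %d atoms"), remaining, n_atoms), call. = FALSE)
  }
  structure(
    list(
      title = title, n_atoms = n_atoms, time_ps = time_ps,
      coordinates = matrix(coords, ncol = 3, byrow = TRUE),
      velocities = if (is.null(vel)) NULL else matrix(vel, ncol = 3, byrow = TRUE),
      has_velocities = !is.null(vel),
      box = box
    ),
    class = "rst7_state"
  )
}

#' Write an AMBER ASCII restart (rst7) file
#'
#' Emits the dialect read by [read_rst7()]: \%12.7f fixed width, six
#' values per line. Writing the same state twice produces byte-identical
#' files.
#'
#' @param state A list with \code{title}, \code{coordinates} (n x 3) and
#'   optionally \code{velocities} (n x 3, AMBER units), \code{time_ps},
#'   \code{box} -- e.g. an \code{rst7_state} or the output of
#'   [system_to_rst7()].
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_rst7 <- function(state, path) {
  coords <- state$coordinates
  if (is.null(coords)) stop("state has no coordinates", call. = FALSE)
  n_atoms <- nrow(coords)
  fmt_block <- function(mat) {
    vals <- as.vector(t(mat))
    lines <- character(ceiling(length(vals) / 6))
    for (li in seq_along(lines)) {
      chunk <- vals[(6 * (li - 1) + 1):min(6 * li, length(vals))]
      lines[li] <- paste0(sprintf("%12.7f", chunk), collapse = "")
    }
    lines
  }
  hdr <- if (!is.null(state$time_ps) && !is.na(state$time_ps)) {
    sprintf("%5d%15.7e", n_atoms, state$time_ps)
  } else {
    sprintf("%5d", n_atoms)
  }
  out <- c(if (is.null(state$title)) "restart" else state$title, hdr,
           fmt_block(coords))
  if (!is.null(state$velocities)) out <- c(out, fmt_block(state$velocities))
  if (!is.null(state$box)) {
    out <- c(out, paste0(sprintf("%12.7f", state$box), collapse = ""))
  }
  writeLines(out, path)
  invisible(path)
}

#' Convert velocities between AMBER restart units and A/ps
#'
#' AMBER restart velocities are expressed in A per 1/20.455 ps, a
#' classic interop pitfall: internal velocities are always A/ps and the
#' factor is applied only at the restart-file boundary.
#'
#' @param velocities Numeric vector or matrix.
#' @param direction \code{"amber_to_internal"} (multiply by 20.455) or
#'   \code{"internal_to_amber"} (divide).
#' @return Converted velocities, same shape.
#' @export
convert_velocity_units <- function(velocities,
                                   direction = c("amber_to_internal",
                                                 "internal_to_amber")) {
  direction <- match.arg(direction)
  if (direction == "amber_to_internal") velocities * AMBER_TIME_FACTOR
  else velocities / AMBER_TIME_FACTOR
}

#' Convert between particle systems and restart states
#'
#' \code{system_to_rst7} drops masses and bonds (the restart format
#' carries only coordinates and velocities) and converts velocities to
#' AMBER units; \code{rst7_to_system} does the reverse, attaching the
#' masses and bonds supplied by the caller.
#'
#' @param system A [particle_system()].
#' @param title Title line for the restart.
#' @return An \code{rst7_state} (without class validation of box).
#' @export
system_to_rst7 <- function(system, title = "puffmd restart") {
  list(
    title = title, n_atoms = length(system$masses), time_ps = system$time,
    coordinates = system$positions,
    velocities = convert_velocity_units(system$velocities, "internal_to_amber"),
    has_velocities = TRUE, box = NULL
  )
}

#' @rdname system_to_rst7
#' @param state An \code{rst7_state} from [read_rst7()].
#' @param masses Masses, Da, one per atom.
#' @param bonds Bond list for the rebuilt system.
#' @export
rst7_to_system <- function(state, masses, bonds = list()) {
  vel <- if (isTRUE(state$has_velocities)) {
    convert_velocity_units(state$velocities, "amber_to_internal")
  } else NULL
  particle_system(
    masses = masses, positions = state$coordinates, velocities = vel,
    bonds = bonds,
    time = if (is.na(state$time_ps)) 0 else state$time_ps
  )
}

#' Write a pulse log (CSV) with a JSON run manifest
#'
#' One CSV row per pulse plus a JSON sidecar carrying the run
#' parameters, anchor groups, pulling mass, seed, schema version and
#' package version, so any analysis can be reproduced from the files
#' alone.
#'
#' @param trajectory A \code{puff_trajectory}.
#' @param path Output CSV path; the manifest is written next to it as
#'   \code{<path>.manifest.json}.
#' @return \code{path}, invisibly.
#' @export
write_pulse_log <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "puff_trajectory"))
  cols <- c("index", "time_ps", "separation", "pre_pulse_velocity",
            "delta_v", "applied_force")
  p <- trajectory$pulses
  if (is.null(p) || !nrow(p)) {
    p <- as.data.frame(stats::setNames(rep(list(numeric(0)), length(cols)), cols))
  } else {
    p <- p[, cols]
  }
  utils::write.csv(p, path, row.names = FALSE)
  manifest <- list(
    schema_version = PULSE_LOG_SCHEMA,
    package_version = as.character(utils::packageVersion("puffmd")),
    params = unclass(trajectory$params),
    anchors = list(group1 = trajectory$anchors$group1,
                   group2 = trajectory$anchors$group2),
    pulling_mass_da = trajectory$pulling_mass_da,
    error = trajectory$error
  )
  jsonlite::write_json(manifest, manifest_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

manifest_path <- function(path) paste0(path, ".manifest.json")

#' Read a pulse log written by [write_pulse_log()]
#'
#' Rebuilds a \code{puff_trajectory} (without systems or snapshots) from
#' the CSV and its manifest, refusing logs whose schema major version
#' does not match the reader's.
#'
#' @param path Path to the pulse-log CSV.
#' @return A \code{puff_trajectory} with \code{pulses}, \code{params},
#'   \code{anchors} and \code{pulling_mass_da}; \code{final_system} is
#'   NULL.
#' @export
read_pulse_log <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  mp <- manifest_path(path)
  if (!file.exists(mp)) stop("missing manifest: ", mp, call. = FALSE)
  manifest <- jsonlite::read_json(mp, simplifyVector = TRUE)
  major <- function(v) strsplit(as.character(v), ".", fixed = TRUE)[[1]][1]
  if (!identical(major(manifest$schema_version), major(PULSE_LOG_SCHEMA))) {
    stop(sprintf("pulse-log schema version %s is incompatible with reader %s",
                 manifest$schema_version, PULSE_LOG_SCHEMA), call. = FALSE)
  }
  pulses <- utils::read.csv(path)
  pr <- manifest$params
  params <- puff_params(
    v_target = pr$v_target, pulse_fs = pr$pulse_fs, dt_fs = pr$dt_fs,
    rescale_temp = if (is.null(pr$rescale_temp)) NA else pr$rescale_temp,
    n_pulses = pr$n_pulses, seed = pr$seed,
    remove_com_drift = isTRUE(pr$remove_com_drift)
  )
  structure(
    list(params = params,
         anchors = anchor_spec(manifest$anchors$group1, manifest$anchors$group2),
         pulses = if (nrow(pulses)) pulses else NULL,
         snapshots = list(), final_system = NULL,
         pulling_mass_da = manifest$pulling_mass_da,
         error = manifest$error),
    class = "puff_trajectory"
  )
}
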