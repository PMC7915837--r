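# File formats: extended XYZ, topology JSON, recipe YAML, observable CSVs.

fmt_num <- function(x) sprintf("%.17g", x)

#' Write configurations as extended XYZ
#'
#' One frame per configuration: a count line, a comment line carrying the
#' lattice, the column layout and the step index, then one row per bead with
#' species label, position and charge.  Floats are written with 17
#' significant digits, so a read/write round trip is exact.
#'
#' @param state A `dpd_state` (supplies species, charge and box).
#' @param file Output path.
#' @param frames Optional list of frames (`list(step, pos)`); defaults to
#'   the state itself as a single frame at step 0.
#' @return The file path, invisibly.
#' @export
write_xyz <- function(state, file, frames = NULL) {
  if (is.null(frames)) frames <- list(list(step = 0L, pos = state$pos))
  lab <- species_labels(state)
  con <- file(file, "w")
  on.exit(close(con))
  for (fr in frames) {
    n <- nrow(fr$pos)
    writeLines(as.character(n), con)
    writeLines(sprintf(
      'Lattice="%s 0 0 0 %s 0 0 0 %s" Properties=species:S:1:pos:R:3:charge:R:1 step=%d',
      fmt_num(state$L), fmt_num(state$L), fmt_num(state$L),
      as.integer(fr$step)), con)
    writeLines(paste(lab, fmt_num(fr$pos[, 1]), fmt_num(fr$pos[, 2]),
                     fmt_num(fr$pos[, 3]), fmt_num(state$charge)), con)
  }
  invisible(file)
}

#' Read an extended XYZ trajectory
#'
#' @param file Path written by [write_xyz()].
#' @return List of frames, each `list(step, pos, species, charge, L)`.
#' @export
read_xyz <- function(file) {
  lines <- readLines(file)
  frames <- list()
  i <- 1
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    header <- lines[i + 1]
    L <- as.numeric(sub('.*Lattice="([^ ]+) .*', "\\1", header))
    step <- as.integer(sub(".*step=([0-9]+).*", "\\1", header))
    rows <- strsplit(lines[i + 1 + seq_len(n)], " ", fixed = TRUE)
    m <- matrix(unlist(rows), ncol = 5, byrow = TRUE)
    frames[[length(frames) + 1]] <- list(
      step = step,
      pos = cbind(as.numeric(m[, 2]), as.numeric(m[, 3]),
                  as.numeric(m[, 4])),
      species = m[, 1],
      charge = as.numeric(m[, 5]),
      L = L
    )
    i <- i + 2 + n
  }
  frames
}

#' Write a columnar configuration dump
#'
#' One row per bead with step index, bead id, species label, position and
#' velocity; a self-describing CSV companion to the extended XYZ format for
#' tools that want velocities.
#'
#' @param state A `dpd_state`.
#' @param file Output path.
#' @param step Step index recorded in the dump.
#' @return The file path, invisibly.
#' @export
write_dump <- function(state, file, step = 0L) {
  df <- data.frame(step = as.integer(step), id = seq_len(n_beads(state)),
                   species = species_labels(state),
                   x = state$pos[, 1], y = state$pos[, 2], z = state$pos[, 3],
                   vx = state$vel[, 1], vy = state$vel[, 2],
                   vz = state$vel[, 3])
  write_csv_report(df, file, "per-bead configuration dump")
}

#' Write the topology of a state as JSON
#'
#' Everything needed to rebuild a `dpd_state` except positions and
#' velocities: box, species, molecule bookkeeping, bonds and rigid bodies.
#'
#' @param state A `dpd_state`.
#' @param file Output path.
#' @return The file path, invisibly.
#' @export
write_topology <- function(state, file) {
  top <- list(
    L = state$L,
    rho = state$rho,
    species = SPECIES_LEVELS[state$species],
    mol_id = state$mol_id,
    mol_type = state$mol_type,
    bonds = if (!is.null(state$bonds)) state$bonds,
    rigid_bodies = state$rigid_bodies
  )
  jsonlite::write_json(top, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Rebuild a state from topology JSON and an XYZ frame
#'
#' @param topology_file Path written by [write_topology()].
#' @param frame A frame from [read_xyz()] (positions; velocities are set to
#'   zero unless supplied).
#' @param vel Optional N x 3 velocity matrix.
#' @return A `dpd_state`.
#' @export
read_topology <- function(topology_file, frame, vel = NULL) {
  top <- jsonlite::read_json(topology_file, simplifyVector = TRUE)
  n <- length(top$species)
  if (is.null(vel)) vel <- matrix(0, n, 3)
  bonds <- if (!is.null(top$bonds) && length(top$bonds)) {
    matrix(as.integer(unlist(top$bonds)), ncol = 2)
  }
  rigid <- if (length(top$rigid_bodies)) {
    lapply(if (is.list(top$rigid_bodies)) top$rigid_bodies
           else as.list(as.data.frame(t(top$rigid_bodies))),
           as.integer)
  } else list()
  dpd_state(L = top$L, pos = frame$pos, vel = vel, species = top$species,
            bonds = bonds, mol_id = as.integer(top$mol_id),
            mol_type = top$mol_type, rigid_bodies = unname(rigid),
            rho = top$rho)
}

RECIPE_KEYS <- c("n_plus", "n_minus", "n_porphyrin", "n_salt_pairs", "L",
                 "rho", "mode", "seed", "n_a", "n_b", "porphyrin_edge",
                 "porphyrin_arm")

#' Read a scenario recipe from YAML
#'
#' @param file YAML file with a subset of the keys `n_plus`, `n_minus`,
#'   `n_porphyrin`, `n_salt_pairs`, `L`, `rho`, `mode`, `seed`, `n_a`,
#'   `n_b`, `porphyrin_edge`, `porphyrin_arm`.
#' @return A [scenario_recipe()].
#' @export
read_recipe <- function(file) {
  raw <- yaml::read_yaml(file)
  if (!is.list(raw)) stop("recipe file is not a YAML mapping")
  bad <- setdiff(names(raw), RECIPE_KEYS)
  if (length(bad)) {
    stop("unknown recipe key(s): ", paste(bad, collapse = ", "))
  }
  do.call(scenario_recipe, raw)
}

#' Write a scenario recipe (with derived counts) to YAML
#'
#' @param recipe A [scenario_recipe()].
#' @param file Output path.
#' @return The file path, invisibly.
#' @export
write_recipe <- function(recipe, file) {
  yaml::write_yaml(unclass(recipe), file)
  invisible(file)
}

csv_header <- function(what, extra = character()) {
  c(paste0("# ", what, " (reduced DPD units: r_c = kT = m = 1)"),
    paste0("# generated by ipecdpd ",
           as.character(utils::packageVersion("ipecdpd"))),
    extra)
}

#' Write a data frame as a self-describing CSV
#'
#' Adds `#` comment lines with the content description and units; read back
#' with `read.csv(..., comment.char = "#")`.
#'
#' @param df Data frame.
#' @param file Output path.
#' @param what One-line description for the header.
#' @param extra Additional comment lines.
#' @return The file path, invisibly.
#' @export
write_csv_report <- function(df, file, what, extra = character()) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(csv_header(what, extra), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(file)
}
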