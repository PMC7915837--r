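# The simulation state container: beads, topology and the periodic box.

#' Construct a simulation state
#'
#' Low-level constructor used by the builders.  A `dpd_state` holds per-bead
#' positions and velocities in a periodic cubic box, the species index of
#' every bead, the bond list, the molecule bookkeeping used by the cluster
#' analysis, and the rigid-body definitions for porphyrins.
#'
#' @param L Box edge (reduced length).
#' @param pos,vel N x 3 numeric matrices.
#' @param species Integer vector of species indices (see [dpd_species()]) or
#'   character vector of species labels.
#' @param bonds Two-column integer matrix of bonded bead pairs (1-based), or
#'   `NULL`.
#' @param mol_id Integer molecule id per bead.
#' @param mol_type Character vector, one entry per molecule id, with values
#'   in `c("PE+", "PE-", "P+", "CI+", "CI-", "S")`.
#' @param rigid_bodies List of integer vectors of bead indices, one per rigid
#'   body.
#' @param rho Target bead density the builder filled to, or `NULL` for
#'   synthetic fixtures that are not density-filled.
#' @return An object of class `dpd_state`.
#' @export
dpd_state <- function(L, pos, vel, species, bonds = NULL, mol_id = NULL,
                      mol_type = NULL, rigid_bodies = list(), rho = NULL) {
  if (is.character(species)) species <- species_index(species)
  n <- nrow(pos)
  stopifnot(L > 0, is.matrix(pos), ncol(pos) == 3,
            is.matrix(vel), nrow(vel) == n, ncol(vel) == 3,
            length(species) == n)
  if (is.null(mol_id)) mol_id <- seq_len(n)
  if (is.null(mol_type)) mol_type <- rep("S", max(mol_id))
  if (!is.null(bonds)) {
    bonds <- matrix(as.integer(bonds), ncol = 2)
    if (nrow(bonds) && (min(bonds) < 1 || max(bonds) > n)) {
      stop("bond indices out of range")
    }
  }
  st <- list(
    L = L,
    pos = unname(wrap_positions(pos, L)),
    vel = unname(vel),
    species = as.integer(species),
    charge = SPECIES_CHARGE[species],
    bonds = bonds,
    mol_id = as.integer(mol_id),
    mol_type = mol_type,
    rigid_bodies = rigid_bodies,
    rho = rho
  )
  names(st$charge) <- NULL
  class(st) <- "dpd_state"
  st
}

wrap_positions <- function(pos, L) {
  pos - L * floor(pos / L)
}

#' @export
print.dpd_state <- function(x, ...) {
  tab <- table(factor(SPECIES_LEVELS[x$species], levels = SPECIES_LEVELS))
  cat("<dpd_state> ", nrow(x$pos), " beads in L = ", format(x$L),
      " box; net charge ", total_charge(x), "\n", sep = "")
  print(tab)
  cat(length(x$rigid_bodies), "rigid bodies,",
      if (is.null(x$bonds)) 0 else nrow(x$bonds), "bonds\n")
  invisible(x)
}

#' Total charge of a state
#'
#' @param state A `dpd_state`.
#' @return Sum of bead valences (0 for every builder output).
#' @export
total_charge <- function(state) sum(state$charge)

#' Number of beads in a state
#' @param state A `dpd_state`.
#' @return Integer bead count.
#' @export
n_beads <- function(state) nrow(state$pos)

species_labels <- function(state) SPECIES_LEVELS[state$species]

# per-molecule net charge, indexed by molecule id (robust to id gaps)
molecule_charges <- function(state) {
  m <- rowsum(state$charge, state$mol_id)
  out <- numeric(max(state$mol_id))
  out[as.integer(rownames(m))] <- m[, 1]
  out
}

#' Kinetic temperature of a state
#'
#' Computes `2 E_kin / N_dof` with rigid-body degrees of freedom counted
#' correctly: 3 per free bead, 6 per rigid body (3 translational + 3
#' rotational), minus 3 for the conserved total momentum.  For rigid-body
#' beads, the centre-of-mass velocity and angular velocity are recovered by
#' projection of the stored bead velocities.
#'
#' @param state A `dpd_state` with at least 2 beads.
#' @return Kinetic temperature in reduced units (kT).
#' @export
measure_temperature <- function(state) {
  n <- n_beads(state)
  if (n < 2) stop("temperature needs at least 2 beads")
  rigid_beads <- unlist(state$rigid_bodies, use.names = FALSE)
  free <- setdiff(seq_len(n), rigid_beads)
  ekin <- 0.5 * sum(state$vel[free, , drop = FALSE]^2)
  for (body in state$rigid_bodies) {
    r <- body_unwrapped(state$pos[body, , drop = FALSE], state$L)
    v <- state$vel[body, , drop = FALSE]
    com <- colMeans(r)
    vcom <- colMeans(v)
    rr <- sweep(r, 2, com)
    vv <- sweep(v, 2, vcom)
    inertia <- inertia_tensor(rr)
    ang_mom <- colSums(cross3(rr, vv))
    omega <- solve(inertia, ang_mom)
    ekin <- ekin + 0.5 * length(body) * sum(vcom^2) +
      0.5 * sum(omega * (inertia %*% omega))
  }
  ndof <- 3 * length(free) + 6 * length(state$rigid_bodies) - 3
  2 * ekin / ndof
}

# unwrap a small body across the periodic boundary (minimum image relative
# to its first bead)
body_unwrapped <- function(r, L) {
  d <- sweep(r, 2, r[1, ])
  d <- d - L * round(d / L)
  sweep(d, 2, r[1, ], FUN = "+")
}

inertia_tensor <- function(rr) {
  r2 <- rowSums(rr^2)
  diag(sum(r2), 3) - crossprod(rr)
}

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# minimum-image difference
min_image <- function(d, L) d - L * round(d / L)
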