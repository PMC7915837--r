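# Independent oracles and small synthetic systems used across tests.

wrap_positions_for_test <- function(pos, L) pos - L * floor(pos / L)

SPECIES_LEVELS_FOR_TEST <- function(state) {
  dpd_species()$species[state$species]
}

# hand-written union-find (independent of igraph)
uf_new <- function(n) seq_len(n)
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}
uf_union <- function(parent, i, j) {
  ri <- uf_find(parent, i)
  rj <- uf_find(parent, j)
  if (ri != rj) parent[rj] <- ri
  parent
}

# brute-force single-linkage molecule clustering over the all-pairs contact
# graph; returns a canonical partition label per molecule
oracle_molecule_clusters <- function(pos, mol_of_bead, L, d_cut) {
  mols <- sort(unique(mol_of_bead))
  parent <- uf_new(length(mols))
  n <- nrow(pos)
  for (i in seq_len(n - 1)) {
    d <- sweep(pos[(i + 1):n, , drop = FALSE], 2, pos[i, ])
    d <- d - L * round(d / L)
    hit <- which(rowSums(d^2) < d_cut^2)
    for (j in hit + i) {
      mi <- match(mol_of_bead[i], mols)
      mj <- match(mol_of_bead[j], mols)
      if (mi != mj) parent <- uf_union(parent, mi, mj)
    }
  }
  roots <- vapply(seq_along(mols), function(i) uf_find(parent, i), integer(1))
  match(roots, unique(roots))
}

canonical_partition <- function(labels) match(labels, unique(labels))

# state of n two-bead (A+, A-) molecules at random positions: generic input
# for clustering oracle comparisons
random_dumbbell_state <- function(n_mol, L, seed) {
  set.seed(seed)
  pos <- matrix(0, 2 * n_mol, 3)
  for (m in seq_len(n_mol)) {
    c0 <- runif(3, 0, L)
    pos[2 * m - 1, ] <- c0
    pos[2 * m, ] <- c0 + 0.35 * rnorm(3)
  }
  dpd_state(L = L, pos = pos, vel = matrix(0, 2 * n_mol, 3),
            species = rep(c("A+", "A-"), n_mol),
            bonds = cbind(seq(1, 2 * n_mol, 2), seq(2, 2 * n_mol, 2)),
            mol_id = rep(seq_len(n_mol), each = 2),
            mol_type = rep("PE+", n_mol))
}

# uncharged random bead soup for force-level comparisons
random_solvent_state <- function(n, L, seed, species = "S") {
  set.seed(seed)
  dpd_state(L = L, pos = matrix(runif(3 * n, 0, L), ncol = 3),
            vel = matrix(rnorm(3 * n), ncol = 3),
            species = rep(species, n), mol_id = seq_len(n),
            mol_type = rep(species, n))
}

# neutral random charge configuration (pairs of +/- monovalent ions)
random_ion_state <- function(n_pairs, L, seed) {
  set.seed(seed)
  n <- 2 * n_pairs
  pos <- matrix(runif(3 * n_pairs, 0, L), ncol = 3)
  pos <- rbind(pos, pos + matrix(rnorm(3 * n_pairs, sd = 0.5), ncol = 3))
  dpd_state(L = L, pos = pos, vel = matrix(0, n, 3),
            species = c(rep("CI+", n_pairs), rep("CI-", n_pairs)),
            mol_id = seq_len(n),
            mol_type = c(rep("CI+", n_pairs), rep("CI-", n_pairs)))
}

# modified velocity-Verlet reference in plain R for a 1D harmonic dimer
# (no thermostat): mirrors the published update rule, independent of the
# C++ implementation
reference_dimer_trajectory <- function(x1, x2, v1, v2, k, dt, lambda_vv,
                                       n_steps, L) {
  force <- function(x1, x2) {
    d <- x1 - x2
    d <- d - L * round(d / L)
    r <- abs(d)
    f1 <- -k * r * sign(d)
    c(f1, -f1)
  }
  f <- force(x1, x2)
  for (s in seq_len(n_steps)) {
    x1n <- x1 + dt * v1 + 0.5 * dt^2 * f[1]
    x2n <- x2 + dt * v2 + 0.5 * dt^2 * f[2]
    x1 <- x1n - L * floor(x1n / L)
    x2 <- x2n - L * floor(x2n / L)
    fn <- force(x1, x2)
    v1 <- v1 + 0.5 * dt * (f[1] + fn[1])
    v2 <- v2 + 0.5 * dt * (f[2] + fn[2])
    f <- fn
  }
  list(x = c(x1, x2), v = c(v1, v2))
}
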