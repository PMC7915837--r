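# System builders: initial configurations for all study scenarios.

with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

sample_unit_vectors <- function(n) {
  v <- matrix(stats::rnorm(3 * n), ncol = 3)
  v / sqrt(rowSums(v^2))
}

# uniform random rotation matrix (random quaternion)
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

# self-avoiding-ish random walk of n beads with fixed bond length; retries
# steps that come closer than `excl` to earlier beads of the same chain
chain_walk <- function(n, start, bond = 0.7, excl = 0.5, max_try = 30) {
  xyz <- matrix(0, n, 3)
  xyz[1, ] <- start
  for (k in seq_len(n - 1)) {
    for (try in seq_len(max_try)) {
      cand <- xyz[k, ] + bond * sample_unit_vectors(1)[1, ]
      prev <- xyz[seq_len(max(1, k - 1)), , drop = FALSE]
      d2 <- rowSums(sweep(prev, 2, cand)^2)
      if (all(d2 > excl^2) || try == max_try) break
    }
    xyz[k + 1, ] <- cand
  }
  xyz
}

maxwell_velocities <- function(n, kT = 1) {
  v <- matrix(stats::rnorm(3 * n, sd = sqrt(kT)), ncol = 3)
  sweep(v, 2, colMeans(v))   # remove net momentum
}

# Accumulator used by the builders: grows bead/bond/molecule arrays.
new_build <- function() {
  env <- new.env(parent = emptyenv())
  env$pos <- list(); env$species <- list(); env$bonds <- list()
  env$mol_len <- integer(); env$mol_type <- character()
  env$rigid <- list(); env$n <- 0L
  env
}

add_molecule <- function(bd, xyz, species, bonds = NULL, type, rigid = FALSE) {
  k <- length(bd$pos) + 1L
  bd$pos[[k]] <- xyz
  bd$species[[k]] <- species
  if (!is.null(bonds)) bd$bonds[[length(bd$bonds) + 1L]] <- bonds + bd$n
  if (rigid) bd$rigid[[length(bd$rigid) + 1L]] <- bd$n + seq_len(nrow(xyz))
  bd$mol_len <- c(bd$mol_len, nrow(xyz))
  bd$mol_type <- c(bd$mol_type, type)
  bd$n <- bd$n + nrow(xyz)
  invisible(bd)
}

finish_build <- function(bd, L, rho, kT = 1) {
  pos <- do.call(rbind, bd$pos)
  species <- unlist(bd$species, use.names = FALSE)
  bonds <- if (length(bd$bonds)) do.call(rbind, bd$bonds) else NULL
  mol_id <- rep.int(seq_along(bd$mol_len), bd$mol_len)
  vel <- maxwell_velocities(nrow(pos), kT)
  dpd_state(L = L, pos = pos, vel = vel, species = species, bonds = bonds,
            mol_id = mol_id, mol_type = bd$mol_type,
            rigid_bodies = bd$rigid, rho = rho)
}

add_chains <- function(bd, recipe, place) {
  for (sign in c(1, -1)) {
    n_chain <- if (sign > 0) recipe$n_plus else recipe$n_minus
    tpl <- if (n_chain > 0) make_diblock(recipe$n_a, recipe$n_b, sign)
    for (i in seq_len(n_chain)) {
      xyz <- place(sign)
      add_molecule(bd, xyz, species_index(tpl$species), tpl$bonds,
                   type = tpl$type)
    }
  }
  invisible(bd)
}

add_porphyrin_at <- function(bd, tpl, com) {
  xyz <- tpl$xyz %*% t(random_rotation())
  xyz <- sweep(xyz, 2, com, FUN = "+")
  add_molecule(bd, xyz, species_index(tpl$species), NULL, type = "P+",
               rigid = TRUE)
}

# bulk insertion of n single-bead molecules (counterions, solvent);
# sampler(n) returns an n x 3 position matrix
add_small <- function(bd, n, species, type, sampler) {
  if (n == 0) return(invisible(bd))
  k <- length(bd$pos) + 1L
  bd$pos[[k]] <- sampler(n)
  bd$species[[k]] <- rep(species_index(species), n)
  bd$mol_len <- c(bd$mol_len, rep(1L, n))
  bd$mol_type <- c(bd$mol_type, rep(type, n))
  bd$n <- bd$n + n
  invisible(bd)
}

#' Assemble a randomly dispersed initial configuration
#'
#' Places all molecules of a recipe at random: diblock chains as
#' self-avoiding random walks with bond length 0.7, porphyrins with random
#' positions and orientations, then the derived counterions, added salt and
#' enough solvent to reach `round(rho * L^3)` beads.  Velocities are drawn
#' from the Maxwell distribution at kT = 1 with the net momentum removed.
#' The build is deterministic given the recipe seed.
#'
#' @param recipe A [scenario_recipe()] (any `mode`; the mode field is only
#'   used by [build_initial_state()]).
#' @return A `dpd_state`.
#' @export
#' @examples
#' st <- assemble_box(scenario_recipe(n_porphyrin = 1, L = 6, seed = 7))
#' total_charge(st)   # 0
assemble_box <- function(recipe) {
  check_recipe_fits(recipe)
  with_seed(recipe$seed, {
    L <- recipe$L
    bd <- new_build()
    add_chains(bd, recipe, place = function(sign) {
      chain_walk(recipe$n_a + recipe$n_b, start = stats::runif(3, 0, L))
    })
    if (recipe$n_porphyrin > 0) {
      tpl <- make_porphyrin(recipe$porphyrin_edge, recipe$porphyrin_arm)
      for (i in seq_len(recipe$n_porphyrin)) {
        add_porphyrin_at(bd, tpl, stats::runif(3, 0, L))
      }
    }
    unif <- function(n) matrix(stats::runif(3 * n, 0, L), ncol = 3)
    add_small(bd, recipe$n_ci_minus, "CI-", "CI-", unif)
    add_small(bd, recipe$n_ci_plus, "CI+", "CI+", unif)
    add_small(bd, recipe$n_solvent, "S", "S", unif)
    finish_build(bd, L, recipe$rho)
  })
}

#' Assemble a pre-aggregated initial configuration
#'
#' Builds the non-equilibrium "one large associate" starting state: the
#' charged A blocks of all chains are packed as confined random walks inside
#' a central sphere whose radius is chosen so that the local A-bead density
#' is approximately `rho`, and each neutral B block extends radially outward
#' from the core surface.  Counterions and solvent fill the remaining volume
#' outside the core.  At step 0 the configuration is a single associate whose
#' association number equals `n_plus + n_minus` under the cluster criterion,
#' and the core sphere contains no B beads.
#'
#' @param recipe A [scenario_recipe()] with chains (porphyrins, if any, are
#'   inserted into the bulk separately with [insert_porphyrins_bulk()]).
#' @return A `dpd_state`.
#' @export
assemble_preaggregated <- function(recipe) {
  check_recipe_fits(recipe)
  if (recipe$n_plus + recipe$n_minus < 1) {
    stop("pre-aggregated mode needs at least one chain")
  }
  if (recipe$n_porphyrin > 0) {
    stop("pre-aggregated mode builds chains only; add porphyrins with ",
         "insert_porphyrins_bulk()")
  }
  with_seed(recipe$seed, {
    L <- recipe$L
    center <- rep(L / 2, 3)
    n_a_beads <- recipe$n_a * (recipe$n_plus + recipe$n_minus)
    r_core <- (3 * n_a_beads / (4 * pi * recipe$rho))^(1 / 3)
    bd <- new_build()
    add_chains(bd, recipe, place = function(sign) {
      a <- confined_walk(recipe$n_a, center, r_core)
      u <- a[recipe$n_a, ] - center
      nu <- sqrt(sum(u^2))
      u <- if (nu > 1e-9) u / nu else sample_unit_vectors(1)[1, ]
      b <- excluded_walk(recipe$n_b, center + (r_core + 0.15) * u, center,
                         r_core, L)
      rbind(a, b)
    })
    outside <- function(n) {
      out <- matrix(0, 0, 3)
      while (nrow(out) < n) {
        p <- matrix(stats::runif(3 * max(n, 64), 0, L), ncol = 3)
        ok <- rowSums(sweep(p, 2, center)^2) > r_core^2
        out <- rbind(out, p[ok, , drop = FALSE])
      }
      out[seq_len(n), , drop = FALSE]
    }
    add_small(bd, recipe$n_ci_minus, "CI-", "CI-", outside)
    add_small(bd, recipe$n_ci_plus, "CI+", "CI+", outside)
    add_small(bd, recipe$n_solvent, "S", "S", outside)
    finish_build(bd, L, recipe$rho)
  })
}

# random walk kept outside a sphere (candidate steps whose wrapped image
# falls inside the core are re-drawn); used for the shell blocks of the
# pre-aggregated associate
excluded_walk <- function(n, start, center, radius, L, bond = 0.7,
                          max_try = 60) {
  xyz <- matrix(0, n, 3)
  xyz[1, ] <- start
  for (k in seq_len(n - 1)) {
    for (try in seq_len(max_try)) {
      cand <- xyz[k, ] + bond * sample_unit_vectors(1)[1, ]
      d <- min_image(cand - center, L)
      if (sum(d^2) > radius^2 || try == max_try) break
    }
    xyz[k + 1, ] <- cand
  }
  xyz
}

# random walk confined to a sphere (steps leaving the sphere are re-drawn)
confined_walk <- function(n, center, radius, bond = 0.7, max_try = 50) {
  xyz <- matrix(0, n, 3)
  repeat {
    start <- center + (stats::runif(3) - 0.5) * 2 * radius
    if (sum((start - center)^2) <= radius^2) break
  }
  xyz[1, ] <- start
  for (k in seq_len(n - 1)) {
    for (try in seq_len(max_try)) {
      cand <- xyz[k, ] + bond * sample_unit_vectors(1)[1, ]
      if (sum((cand - center)^2) <= radius^2 || try == max_try) break
    }
    xyz[k + 1, ] <- cand
  }
  xyz
}

#' Build the initial state selected by a recipe's mode
#'
#' Dispatches to [assemble_box()] or [assemble_preaggregated()].
#'
#' @param recipe A [scenario_recipe()].
#' @return A `dpd_state`.
#' @export
build_initial_state <- function(recipe) {
  switch(recipe$mode,
         random = assemble_box(recipe),
         preaggregated = assemble_preaggregated(recipe))
}

#' Insert porphyrins into the bulk solvent of an existing state
#'
#' Dissolved porphyrins are inserted at random positions and orientations
#' without touching the polymer associates: every inserted bead must be at
#' least `min_dist` away from every polymer bead (species A+, A-, B, P,
#' Pq+).  Each porphyrin together with its four derived CI- counterions
#' replaces twelve solvent beads, so the total bead count and the global
#' electroneutrality are preserved.  The replaced solvent beads donate their
#' velocities to the new beads, so the total momentum is preserved exactly.
#'
#' @param state A `dpd_state` with enough solvent beads.
#' @param n Number of porphyrins to insert (`n = 0` returns the state
#'   unchanged).
#' @param seed RNG seed.
#' @param edge,arm Porphyrin geometry, see [make_porphyrin()].
#' @param min_dist Contact cutoff to polymer beads (reduced length).
#' @param max_try Placement attempts per porphyrin before giving up.
#' @return The augmented `dpd_state`.
#' @export
insert_porphyrins_bulk <- function(state, n, seed = 1, edge = 0.7, arm = 0.7,
                                   min_dist = 1.0, max_try = 2000) {
  if (n == 0) return(state)
  stopifnot(n >= 1)
  lab <- species_labels(state)
  n_solvent <- sum(lab == "S")
  if (n_solvent < 12 * n) {
    stop(sprintf("need %d solvent beads to swap out, have %d", 12 * n,
                 n_solvent))
  }
  tpl <- make_porphyrin(edge, arm)
  with_seed(seed, {
    L <- state$L
    polymer <- state$pos[lab %in% c("A+", "A-", "B", "P", "Pq+"), ,
                         drop = FALSE]
    new_xyz <- vector("list", n)
    for (i in seq_len(n)) {
      placed <- FALSE
      for (try in seq_len(max_try)) {
        com <- stats::runif(3, 0, L)
        xyz <- sweep(tpl$xyz %*% t(random_rotation()), 2, com, FUN = "+")
        if (nrow(polymer) == 0 || min_sep2(xyz, polymer, L) >= min_dist^2) {
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop("could not place porphyrin ", i, " without polymer contact ",
             "after ", max_try, " attempts")
      }
      new_xyz[[i]] <- xyz
      polymer <- rbind(polymer, xyz)   # later insertions avoid earlier ones
    }
    swap_in_porphyrins(state, tpl, new_xyz, min_dist)
  })
}

min_sep2 <- function(a, b, L) {
  m <- Inf
  for (k in seq_len(nrow(a))) {
    d <- min_image(sweep(b, 2, a[k, ]), L)
    m <- min(m, min(rowSums(d^2)))
  }
  m
}

swap_in_porphyrins <- function(state, tpl, new_xyz, min_dist) {
  n <- length(new_xyz)
  lab <- species_labels(state)
  solv_idx <- which(lab == "S")
  drop_idx <- sample(solv_idx, 12 * n)
  keep <- setdiff(seq_len(n_beads(state)), drop_idx)
  remap <- integer(n_beads(state))
  remap[keep] <- seq_along(keep)

  n_mol_old <- length(state$mol_type)
  pos <- state$pos[keep, , drop = FALSE]
  vel <- state$vel[keep, , drop = FALSE]
  species <- state$species[keep]
  mol_id <- state$mol_id[keep]
  mol_type <- state$mol_type
  bonds <- if (!is.null(state$bonds)) {
    matrix(remap[state$bonds], ncol = 2)
  }
  rigid <- lapply(state$rigid_bodies, function(b) remap[b])
  donor_vel <- state$vel[drop_idx, , drop = FALSE]
  L <- state$L
  pcount <- 0L
  for (i in seq_len(n)) {
    xyz <- wrap_positions(new_xyz[[i]], L)
    base <- nrow(pos)
    pos <- rbind(pos, xyz)
    vel <- rbind(vel, donor_vel[pcount + 1:8, , drop = FALSE])
    species <- c(species, species_index(tpl$species))
    mol_id <- c(mol_id, rep(length(mol_type) + 1L, 8))
    mol_type <- c(mol_type, "P+")
    rigid[[length(rigid) + 1L]] <- base + 1:8
    pcount <- pcount + 8L
    # counterions of the inserted porphyrin go to random bulk positions
    for (k in 1:4) {
      repeat {
        p <- stats::runif(3, 0, L)
        d <- min_image(sweep(xyz, 2, p), L)
        if (min(rowSums(d^2)) >= min_dist^2) break
      }
      pos <- rbind(pos, matrix(p, 1, 3))
      pcount <- pcount + 1L
      vel <- rbind(vel, donor_vel[pcount, , drop = FALSE])
      species <- c(species, species_index("CI-"))
      mid <- length(mol_type) + 1L
      mol_id <- c(mol_id, mid)
      mol_type <- c(mol_type, "CI-")
    }
  }
  dpd_state(L = L, pos = pos, vel = vel, species = species, bonds = bonds,
            mol_id = mol_id, mol_type = mol_type, rigid_bodies = rigid,
            rho = state$rho)
}

#' Synthetic cluster fixture with known labels
#'
#' Builds a state containing molecules packed into clusters of prescribed
#' sizes, with intra-cluster contacts below the cluster cutoff and
#' inter-cluster gaps above twice the cutoff, and returns the ground-truth
#' labels.  Molecules are either neutral two-bead A+A- dumbbells (counted as
#' chains by the association statistics) or rigid porphyrins (with their
#' counterions parked far from every cluster).
#'
#' @param sizes Integer vector of cluster sizes.
#' @param L Box edge.
#' @param d_cut Cluster criterion cutoff the fixture is built for.
#' @param kind `"chain"` or `"porphyrin"` molecules.
#' @return A list with elements `state` and `labels` (integer vector, one
#'   entry per molecule in molecule-id order).
#' @export
#' @examples
#' fx <- make_cluster_fixture(c(1, 2, 3), L = 20)
#' table(fx$labels)
make_cluster_fixture <- function(sizes, L, d_cut = 0.7,
                                 kind = c("chain", "porphyrin")) {
  kind <- match.arg(kind)
  stopifnot(length(sizes) >= 1, all(sizes >= 1))
  step <- if (kind == "chain") 0.35 else 1.0
  mol_extent <- if (kind == "chain") 0.35 else 2.0
  extent <- max(sizes) * step + mol_extent
  pitch <- extent + 2 * d_cut + 0.6
  per_axis <- max(1, floor(L / pitch))
  if (per_axis^3 < length(sizes)) {
    stop("clusters do not fit in the box without inter-cluster contacts; ",
         "increase L")
  }
  tpl <- if (kind == "porphyrin") make_porphyrin()
  bd <- new_build()
  labels <- integer(0)
  cid <- 0L
  for (s in sizes) {
    cell <- c(cid %% per_axis, (cid %/% per_axis) %% per_axis,
              cid %/% per_axis^2)
    origin <- cell * pitch + 0.5
    for (i in seq_len(s) - 1L) {
      if (kind == "chain") {
        xyz <- rbind(origin + c(step * i, 0, 0),
                     origin + c(step * i + 0.2, 0, 0))
        add_molecule(bd, xyz, species_index(c("A+", "A-")),
                     bonds = cbind(1L, 2L), type = "PE+")
      } else {
        # stack porphyrins face-to-face along z at spacing < d_cut
        xyz <- sweep(tpl$xyz, 2, origin + c(0, 0, step * i * d_cut * 0.8),
                     FUN = "+")
        add_molecule(bd, xyz, species_index(tpl$species), NULL,
                     type = "P+", rigid = TRUE)
      }
      labels <- c(labels, cid + 1L)
    }
    cid <- cid + 1L
  }
  if (kind == "porphyrin") {
    # counterions keep the fixture neutral; parked on a far lattice
    n_ci <- 4 * sum(sizes)
    far <- cbind(seq_len(n_ci) %% floor(L), (seq_len(n_ci) %/% floor(L)) %% 2,
                 L - 0.25)
    for (k in seq_len(n_ci)) {
      add_molecule(bd, matrix(far[k, ], 1, 3), species_index("CI-"),
                   NULL, type = "CI-")
    }
  }
  st <- finish_build(bd, L, rho = NULL)
  st$vel[] <- 0
  list(state = st, labels = labels)
}
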