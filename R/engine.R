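# Integration driver and force-level primitives.

#' Conservative DPD pair force
#'
#' Soft linear repulsion `a_ij (1 - r/r_c)` along the unit separation vector
#' for `r < r_c = 1`, zero beyond the cutoff, and defined as the zero vector
#' at exact overlap (the direction is undefined for a soft potential).
#'
#' @param r_vec Separation vector (3-vector, from bead j to bead i).
#' @param a_ij Repulsion amplitude.
#' @return Force vector acting on bead i (bead j receives the opposite).
#' @export
#' @examples
#' pair_conservative_force(c(0.5, 0, 0), 25)   # magnitude 12.5
pair_conservative_force <- function(r_vec, a_ij) {
  r <- sqrt(sum(r_vec^2))
  if (r >= 1 || r < 1e-12) return(c(0, 0, 0))
  a_ij * (1 - r) * r_vec / r
}

#' Dissipative and random DPD pair forces
#'
#' The thermostat pair: dissipative term `-gamma w(r)^2 (rhat . v_rel) rhat`
#' and random term `sigma w(r) xi rhat / sqrt(dt)`, both with the standard
#' weight `w(r) = 1 - r/r_c` inside the cutoff.  The noise `xi` is shared by
#' the pair, so Newton's third law holds exactly for the random force too.
#'
#' @param r_vec Separation vector (from j to i).
#' @param v_rel Relative velocity `v_i - v_j`.
#' @param gamma,sigma Friction and noise amplitudes (`sigma^2 = 2 gamma kT`).
#' @param dt Timestep (the random force scales as `1/sqrt(dt)`).
#' @param xi The pair's symmetric random variate (zero mean, unit variance).
#' @return Force vector on bead i.
#' @export
pair_dissipative_random_force <- function(r_vec, v_rel, gamma, sigma, dt,
                                          xi = 0) {
  r <- sqrt(sum(r_vec^2))
  if (r >= 1 || r < 1e-12) return(c(0, 0, 0))
  rhat <- r_vec / r
  w <- 1 - r
  (-gamma * w^2 * sum(rhat * v_rel) + sigma * w * xi / sqrt(dt)) * rhat
}

#' Harmonic bond force
#'
#' @param r_vec Separation vector (from j to i).
#' @param k_bond Spring constant.
#' @param r0 Rest length.
#' @return Force vector on bead i: `-k_bond (r - r0) rhat`.
#' @export
bond_force <- function(r_vec, k_bond, r0 = 0) {
  r <- sqrt(sum(r_vec^2))
  if (r < 1e-12) return(c(0, 0, 0))
  -k_bond * (r - r0) * r_vec / r
}

state_bonds_matrix <- function(state) {
  if (is.null(state$bonds) || nrow(state$bonds) == 0) {
    matrix(integer(0), 0, 2)
  } else {
    state$bonds
  }
}

resolve_elec <- function(state, charge_model) {
  if (is.null(charge_model) || all(state$charge == 0)) return(elec_disabled())
  if (abs(total_charge(state)) > 1e-9) {
    stop("electrostatics requires an electroneutral state (net charge ",
         total_charge(state), ")")
  }
  ewald_setup(charge_model, state$L)
}

#' Run a DPD simulation
#'
#' Advances a state by `n_steps` timesteps of the modified velocity-Verlet
#' DPD update with harmonic bonds, rigid-body dynamics for porphyrins and,
#' optionally, smeared-charge Ewald electrostatics.  Thermodynamic
#' observables (kinetic temperature, bond and electrostatic energies, total
#' momentum) are logged every `thermo_stride` steps and configuration frames
#' every `frame_stride` steps.  The run is deterministic given the seed: the
#' random pair force is keyed by (seed, step, pair), independent of
#' iteration order.
#'
#' @param state A `dpd_state`.
#' @param params A [sim_params()] object.
#' @param charge_model A [charge_model()] or `NULL` for uncharged dynamics.
#' @param n_steps Number of timesteps (0 returns the state unchanged).
#' @param seed Integer RNG seed for the random force.
#' @param thermo_stride,frame_stride Observer strides in steps (0 disables).
#' @param step0 Global index of the first step (for continuing runs).
#' @return A `dpd_trajectory`: list with the advanced `state`, a `thermo`
#'   data frame, a list of `frames` (each with `step` and `pos`), and the
#'   degree-of-freedom count used for temperature.
#' @export
dpd_run <- function(state, params = sim_params(), charge_model = NULL,
                    n_steps = 1000, seed = 1, thermo_stride = 100,
                    frame_stride = 10000, step0 = 0) {
  stopifnot(inherits(state, "dpd_state"), n_steps >= 0)
  elec <- resolve_elec(state, charge_model)
  res <- cpp_dpd_run(state$pos, state$vel, state$species, state$charge,
                     state_bonds_matrix(state), state$rigid_bodies,
                     default_or(attr(state, "interaction"),
                                default_interaction_table()),
                     state$L, unclass(params), elec, as.integer(n_steps),
                     as.double(seed), as.integer(thermo_stride),
                     as.integer(frame_stride), as.integer(step0))
  out_state <- state
  out_state$pos <- res$pos
  out_state$vel <- res$vel
  thermo <- as.data.frame(res$thermo)
  frames <- Map(function(p, s) list(step = s, pos = p), res$frames,
                res$frame_steps)
  traj <- list(state = out_state, thermo = thermo, frames = unname(frames),
               ndof = res$ndof, n_steps = n_steps, step0 = step0)
  class(traj) <- "dpd_trajectory"
  traj
}

default_or <- function(x, default) if (is.null(x)) default else x

#' @export
print.dpd_trajectory <- function(x, ...) {
  cat("<dpd_trajectory>", x$n_steps, "steps from step", x$step0, ";",
      nrow(x$thermo), "thermo records,", length(x$frames), "frames\n")
  if (nrow(x$thermo) > 0) {
    cat("  final temperature:",
        format(x$thermo$temperature[nrow(x$thermo)], digits = 4), "\n")
  }
  invisible(x)
}

#' Evaluate forces on every bead of a state
#'
#' Single force evaluation used for force-level validation: conservative
#' soft repulsion and bonds, optionally the dissipative/random thermostat
#' pair (deterministic given `seed` and `step`) and smeared-charge Ewald
#' electrostatics.  `use_cells = FALSE` forces the all-pairs O(N^2) path,
#' which serves as the reference for the cell-list search.
#'
#' @param state A `dpd_state`.
#' @param params A [sim_params()].
#' @param charge_model Optional [charge_model()].
#' @param use_cells Use the cell-list neighbour search (default) or the
#'   all-pairs loop.
#' @param thermostat Include the dissipative and random pair forces.
#' @param seed,step Random-force key (only relevant with `thermostat`).
#' @return An N x 3 force matrix with energy components as attributes.
#' @export
compute_forces <- function(state, params = sim_params(), charge_model = NULL,
                           use_cells = TRUE, thermostat = FALSE, seed = 1,
                           step = 0) {
  elec <- resolve_elec(state, charge_model)
  cpp_forces(state$pos, state$vel, state$species, state$charge,
             state_bonds_matrix(state),
             default_or(attr(state, "interaction"),
                        default_interaction_table()),
             state$L, unclass(params), elec, use_cells, thermostat,
             as.double(seed), as.integer(step))
}

#' Candidate neighbour pairs within a cutoff
#'
#' Returns all unique bead pairs within `cutoff` under the minimum-image
#' convention, found with a cell list when the box holds at least three
#' cells per edge and by the all-pairs loop otherwise.
#'
#' @param state A `dpd_state`.
#' @param cutoff Pair distance cutoff (reduced length).
#' @return Two-column integer matrix of bead index pairs (i < j).
#' @export
neighbor_pairs <- function(state, cutoff = 1) {
  stopifnot(cutoff > 0)
  cpp_contact_pairs(state$pos, state$L, cutoff)
}
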