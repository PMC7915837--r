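# Smeared-charge electrostatics: closed-form pair interaction and Ewald sums.

# B(x) = 1 - exp(-2x)(1 + 11x/8 + 3x^2/4 + x^3/6): the cloud-cloud screening
# function of two Slater charge densities rho(r) ~ exp(-2r/lambda), x = r/lambda
slater_screen_energy <- function(x) {
  1 - exp(-2 * x) * (1 + x * (11 / 8 + x * (3 / 4 + x / 6)))
}

slater_screen_force <- function(x) {
  1 - exp(-2 * x) * (1 + x * (2 + x * (2 + x * (7 / 6 + x / 3))))
}

#' Pair force between two smeared charges
#'
#' Signed radial force between two Slater-smeared unit clouds,
#' `f(r) = Gamma q_i q_j / (4 pi) * (B(x) - x B'(x)) / r^2` with
#' `x = r/lambda`: finite (zero) at contact, Coulombic
#' `Gamma q_i q_j / (4 pi r^2)` at large separation.  Positive values are
#' repulsive.
#'
#' @param r Separation(s), reduced length (vectorized).
#' @param q_i,q_j Charges in units of the elementary charge.
#' @param model A [charge_model()].
#' @return Signed force magnitude(s).
#' @export
#' @examples
#' m <- charge_model()
#' smeared_pair_force(0, 1, 1, m)          # finite at overlap
#' smeared_pair_force(2, 1, 1, m)          # ~ point Coulomb at r = 10 lambda
smeared_pair_force <- function(r, q_i, q_j, model = charge_model()) {
  stopifnot(all(r >= 0))
  pref <- model$gamma_coupling * q_i * q_j / (4 * pi)
  out <- numeric(length(r))
  ok <- r > 1e-12
  x <- r[ok] / model$lambda
  out[ok] <- pref * slater_screen_force(x) / r[ok]^2
  out
}

#' Pair energy between two smeared charges
#'
#' `U(r) = Gamma q_i q_j B(x) / (4 pi r)`, finite at contact:
#' `U(0) = Gamma q_i q_j * 5 / (32 pi lambda)`.
#'
#' @inheritParams smeared_pair_force
#' @return Energy value(s), reduced units.
#' @export
smeared_pair_energy <- function(r, q_i, q_j, model = charge_model()) {
  stopifnot(all(r >= 0))
  pref <- model$gamma_coupling * q_i * q_j / (4 * pi)
  out <- rep(pref * 5 / (8 * model$lambda), length(r))
  ok <- r > 1e-12
  x <- r[ok] / model$lambda
  out[ok] <- pref * slater_screen_energy(x) / r[ok]
  out
}

#' Fraction of a smeared charge within a radius
#'
#' Radial integral of the Slater cloud `rho(r) ~ exp(-2r/lambda)`:
#' `P(r < R) = 1 - exp(-2R/lambda) (1 + 2R/lambda + 2(R/lambda)^2)`.  With
#' the default `lambda = 0.2`, more than 99% of the charge lies within one
#' bead radius, the property that motivates this smearing scale.
#'
#' @param R Radius (reduced length; vectorized).
#' @param lambda Smearing constant.
#' @return Enclosed charge fraction(s) in `[0, 1)`.
#' @export
charge_fraction_within <- function(R, lambda = 0.2) {
  x <- R / lambda
  1 - exp(-2 * x) * (1 + 2 * x + 2 * x^2)
}

#' Ewald forces and energy for a smeared-charge configuration
#'
#' Splits the periodic sum of smeared-charge interactions into a short-range
#' real-space part (the full cloud-cloud interaction minus the erf-screened
#' point part, which decays exponentially), a reciprocal-space point-charge
#' sum and the self term; with `boundary = "vacuum"` the surface dipole term
#' is added.  The splitting parameter and reciprocal cutoff are tuned to the
#' model's accuracy target for the state's box.
#'
#' @param state A `dpd_state` (must be electroneutral).
#' @param model A [charge_model()].
#' @return List with `forces` (N x 3 matrix), `energy`, and the `e_real` /
#'   `e_recip` components.
#' @export
ewald_forces <- function(state, model = charge_model()) {
  if (all(state$charge == 0)) {
    return(list(forces = matrix(0, n_beads(state), 3), energy = 0,
                e_real = 0, e_recip = 0))
  }
  if (abs(total_charge(state)) > 1e-9) {
    stop("ewald_forces requires an electroneutral state (net charge ",
         total_charge(state), ")")
  }
  es <- ewald_setup(model, state$L)
  cpp_ewald(state$pos, state$charge, state$L, es$lambda, es$C, es$alpha,
            es$rcut, es$nmax, es$surface)
}

#' Direct periodic-image sum (validation oracle)
#'
#' Explicit summation of the smeared pair interaction over cubic shells of
#' periodic images.  Cubic-shell ordering converges, for neutral systems, to
#' the Ewald result with vacuum (surface dipole) boundary conditions.  This
#' is a brute-force reference intended for small systems.
#'
#' @param state A `dpd_state` (intended for at most ~100 charged beads).
#' @param model A [charge_model()].
#' @param n_shells Number of image shells on each side of the home box.
#' @return List with `forces` and `energy`.
#' @export
direct_sum_reference <- function(state, model = charge_model(),
                                 n_shells = 5) {
  n_charged <- sum(state$charge != 0)
  if (n_charged > 100) {
    warning("direct sum over ", n_charged,
            " charges; this oracle is O(N^2 shells^3)")
  }
  cpp_direct_sum(state$pos, state$charge, state$L, model$lambda,
                 model$gamma_coupling / (4 * pi), as.integer(n_shells))
}
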