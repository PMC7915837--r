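# Scenario recipes: what goes into the box.

#' Scenario recipe for the system builders
#'
#' A recipe fixes the molecular contents of a simulation box: the numbers of
#' positively and negatively charged diblock chains, porphyrins and added
#' salt pairs, the box edge and the target bead density.  Counterion counts
#' are never user-set; they are derived from global electroneutrality: one
#' CI- per A+ bead, one CI+ per A- bead, one CI- per charged porphyrin
#' periphery bead, and one CI+/CI- pair per unit of added salt.  Solvent
#' fills the box to `round(rho * L^3)` beads.
#'
#' @param n_plus,n_minus Numbers of polycation (A+) and polyanion (A-)
#'   diblock chains.
#' @param n_porphyrin Number of rigid tetra-cationic porphyrin units.
#' @param n_salt_pairs Added salt, in CI+/CI- pairs.
#' @param L Box edge (reduced length).
#' @param rho Target bead density (beads per reduced volume, default 3).
#' @param mode Initial state: `"random"` (dispersed molecules) or
#'   `"preaggregated"` (all chains packed into one core-shell associate).
#' @param seed RNG seed making the build deterministic.
#' @param n_a,n_b Block lengths of the diblock chains (default A10B25).
#' @param porphyrin_edge,porphyrin_arm Porphyrin geometry, see
#'   [make_porphyrin()].
#' @return An object of class `scenario_recipe` with derived counterion and
#'   solvent counts.
#' @export
#' @examples
#' r <- scenario_recipe(n_plus = 2, n_minus = 2, L = 6, seed = 1)
#' r$n_ci_minus   # 20: one CI- per A+ bead
scenario_recipe <- function(n_plus = 0, n_minus = 0, n_porphyrin = 0,
                            n_salt_pairs = 0, L = 10, rho = 3,
                            mode = c("random", "preaggregated"), seed = 1,
                            n_a = 10, n_b = 25,
                            porphyrin_edge = 0.7, porphyrin_arm = 0.7) {
  mode <- match.arg(mode)
  stopifnot(L > 0, rho > 0, n_plus >= 0, n_minus >= 0, n_porphyrin >= 0,
            n_salt_pairs >= 0, n_a >= 1, n_b >= 1)
  n_chain_beads <- (n_a + n_b) * (n_plus + n_minus)
  n_ci_minus <- n_a * n_plus + 4 * n_porphyrin + n_salt_pairs
  n_ci_plus  <- n_a * n_minus + n_salt_pairs
  n_total <- round(rho * L^3)
  n_solvent <- n_total - n_chain_beads - 8 * n_porphyrin -
    n_ci_minus - n_ci_plus
  rec <- list(
    n_plus = n_plus, n_minus = n_minus, n_porphyrin = n_porphyrin,
    n_salt_pairs = n_salt_pairs, L = L, rho = rho, mode = mode, seed = seed,
    n_a = n_a, n_b = n_b,
    porphyrin_edge = porphyrin_edge, porphyrin_arm = porphyrin_arm,
    n_ci_minus = n_ci_minus, n_ci_plus = n_ci_plus,
    n_total = n_total, n_solvent = n_solvent
  )
  class(rec) <- "scenario_recipe"
  rec
}

#' @export
print.scenario_recipe <- function(x, ...) {
  cat("<scenario_recipe> ", x$n_plus, " A", x$n_a, "+B", x$n_b, " + ",
      x$n_minus, " A", x$n_a, "-B", x$n_b, " chains, ", x$n_porphyrin,
      " porphyrins, ", x$n_salt_pairs, " salt pairs\n", sep = "")
  cat("  L =", x$L, " rho =", x$rho, " mode =", x$mode,
      " seed =", x$seed, "\n")
  cat("  derived: ", x$n_ci_minus, " CI-, ", x$n_ci_plus, " CI+, ",
      x$n_solvent, " solvent of ", x$n_total, " beads\n", sep = "")
  invisible(x)
}

check_recipe_fits <- function(recipe) {
  if (recipe$n_solvent < 0) {
    stop(sprintf(paste0(
      "box too small: recipe needs %d non-solvent beads but round(rho*L^3) ",
      "is only %d"), recipe$n_total - recipe$n_solvent, recipe$n_total))
  }
  invisible(recipe)
}

#' Porphyrin volume fraction of a recipe
#'
#' Each bead occupies `1/rho` reduced volume on average, so `n` porphyrins of
#' 8 beads occupy a volume fraction `8 n / (rho L^3)`.
#'
#' @param recipe A `scenario_recipe`.
#' @return Porphyrin concentration in Vol%.
#' @export
porphyrin_vol_percent <- function(recipe) {
  100 * 8 * recipe$n_porphyrin / (recipe$rho * recipe$L^3)
}
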