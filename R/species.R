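# Bead species, valences and the soft-repulsion force field.

#' Bead species of the coarse-grained model
#'
#' The model uses eight bead species: the positively and negatively charged
#' polyelectrolyte beads (`A+`, `A-`), the neutral water-soluble block bead
#' (`B`), the hydrophobic porphyrin ring bead (`P`), the charged porphyrin
#' periphery bead (`Pq+`), monovalent counterions (`CI+`, `CI-`) and the
#' solvent (`S`).  All beads carry unit mass in reduced DPD units; charges are
#' integer multiples of the elementary charge.
#'
#' @return A data frame with columns `species` (label), `valence` (in units of
#'   the elementary charge) and `mass` (reduced units, always 1).
#' @export
#' @examples
#' dpd_species()
dpd_species <- function() {
  data.frame(
    species = SPECIES_LEVELS,
    valence = SPECIES_CHARGE,
    mass    = rep(1, length(SPECIES_LEVELS)),
    stringsAsFactors = FALSE
  )
}

SPECIES_LEVELS <- c("A+", "A-", "B", "P", "Pq+", "CI+", "CI-", "S")
SPECIES_CHARGE <- c(1, -1, 0, 0, 1, 1, -1, 0)
names(SPECIES_CHARGE) <- SPECIES_LEVELS

species_index <- function(labels) {
  idx <- match(labels, SPECIES_LEVELS)
  if (anyNA(idx)) {
    stop("unknown species label(s): ",
         paste(unique(labels[is.na(idx)]), collapse = ", "))
  }
  idx
}

#' Map a Flory interaction parameter to a DPD repulsion amplitude
#'
#' The conservative DPD repulsion between unlike beads is calibrated against
#' Flory-Huggins theory at the reference bead density rho = 3: the
#' like-bead baseline is a = 25 and the excess repulsion grows linearly with
#' the Flory chi parameter, `a = 25 + 3.27 * chi`.  Chi = 0 corresponds to an
#' athermal (good) solvent, chi = 0.5 to a theta solvent and chi = 4.5 to a
#' non-solvent.
#'
#' @param chi Flory interaction parameter (dimensionless); may be a vector.
#' @return Repulsion amplitude(s) in reduced DPD energy units.
#' @export
#' @examples
#' chi_to_repulsion(c(0, 0.5, 4.5))
chi_to_repulsion <- function(chi) {
  if (!is.numeric(chi) || any(!is.finite(chi))) {
    stop("'chi' must be finite numeric")
  }
  25 + 3.27 * chi
}

#' Default interaction table of the co-assembly model
#'
#' Returns the symmetric matrix of conservative repulsion amplitudes a_ij
#' between the eight bead species.  The signed variants of the
#' polyelectrolyte bead (`A+`/`A-`) and of the counterions (`CI+`/`CI-`)
#' share the same non-electrostatic parameters; charge discrimination is
#' entirely electrostatic.  Key entries: the hydrophobic polyelectrolyte
#' backbone (a(A,S) = 35), the marginally soluble neutral block
#' (a(B,S) = 26), the strongly hydrophobic, mutually attractive porphyrin
#' ring (a(P,P) = 18, a(P,S) = 39) and the ion-ring affinity a(A,CI) = 27.
#'
#' @return An 8 x 8 symmetric numeric matrix with species labels as dimnames.
#' @export
#' @examples
#' a <- default_interaction_table()
#' a["P", "P"]     # porphyrin ring stacking, attractive relative to 25
#' a["A+", "S"]    # hydrophobic polyelectrolyte backbone
default_interaction_table <- function() {
  groups <- c("A+" = "A", "A-" = "A", "B" = "B", "P" = "P", "Pq+" = "Pq",
              "CI+" = "CI", "CI-" = "CI", "S" = "S")
  g <- c("A", "B", "P", "Pq", "CI", "S")
  base <- matrix(NA_real_, 6, 6, dimnames = list(g, g))
  base["A", "A"]   <- 25
  base["B", "A"]   <- 35; base["B", "B"]   <- 25
  base["P", "A"]   <- 25; base["P", "B"]   <- 35; base["P", "P"]   <- 18
  base["Pq", "A"]  <- 25; base["Pq", "B"]  <- 35; base["Pq", "P"]  <- 25
  base["Pq", "Pq"] <- 25
  base["CI", "A"]  <- 27; base["CI", "B"]  <- 26; base["CI", "P"]  <- 39
  base["CI", "Pq"] <- 39; base["CI", "CI"] <- 25
  base["S", "A"]   <- 35; base["S", "B"]   <- 26; base["S", "P"]   <- 39
  base["S", "Pq"]  <- 39; base["S", "CI"]  <- 25; base["S", "S"]   <- 25
  base[upper.tri(base)] <- t(base)[upper.tri(base)]
  a <- base[groups[SPECIES_LEVELS], groups[SPECIES_LEVELS]]
  dimnames(a) <- list(SPECIES_LEVELS, SPECIES_LEVELS)
  a
}

#' Look up a pair repulsion amplitude
#'
#' @param table Interaction matrix as returned by
#'   [default_interaction_table()].
#' @param i,j Species labels.
#' @return The repulsion amplitude a_ij.
#' @export
interaction_lookup <- function(table, i, j) {
  table[species_index(i), species_index(j)]
}

validate_interaction_table <- function(a) {
  stopifnot(is.matrix(a), nrow(a) == 8, ncol(a) == 8)
  if (!isTRUE(all.equal(a, t(a)))) stop("interaction table must be symmetric")
  if (any(a <= 0)) stop("interaction amplitudes must be positive")
  invisible(a)
}
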