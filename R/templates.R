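# Molecular templates: diblock polyelectrolytes and the rigid porphyrin unit.

new_template <- function(species, bonds, rigid = FALSE, xyz = NULL,
                         type = "molecule") {
  tpl <- list(
    species = species,
    bonds   = bonds,
    rigid   = rigid,
    xyz     = xyz,
    type    = type,
    charge  = sum(SPECIES_CHARGE[species])
  )
  class(tpl) <- "dpd_template"
  tpl
}

#' @export
print.dpd_template <- function(x, ...) {
  cat("<dpd_template>", x$type, ":", length(x$species), "beads,",
      if (is.null(x$bonds)) 0 else nrow(x$bonds), "bonds, net charge",
      x$charge, if (x$rigid) "(rigid)" else "", "\n")
  invisible(x)
}

#' Diblock polyelectrolyte template
#'
#' Builds a linear A-block/B-block copolymer template: `n_a` charged
#' polyelectrolyte beads (species `A+` or `A-` according to `sign`) followed
#' by `n_b` neutral water-soluble beads (`B`), joined by consecutive harmonic
#' bonds.  The work-horse of the co-assembly study is the asymmetric
#' A10B25 chain carrying a net charge of +10 or -10.
#'
#' @param n_a Number of charged A beads (>= 1).
#' @param n_b Number of neutral B beads (>= 1).
#' @param sign +1 for a polycation block, -1 for a polyanion block.
#' @return A `dpd_template` with `n_a + n_b` beads and `n_a + n_b - 1` bonds.
#' @export
#' @examples
#' make_diblock(10, 25, +1)   # A10+B25, net charge +10
make_diblock <- function(n_a, n_b, sign = +1) {
  if (!isTRUE(n_a >= 1) || !isTRUE(n_b >= 1)) {
    stop("block lengths must be positive")
  }
  if (!sign %in% c(-1, 1)) stop("'sign' must be +1 or -1")
  n <- n_a + n_b
  a_species <- if (sign > 0) "A+" else "A-"
  species <- c(rep(a_species, n_a), rep("B", n_b))
  bonds <- cbind(seq_len(n - 1), seq_len(n - 1) + 1L)
  new_template(species, bonds, rigid = FALSE,
               type = if (sign > 0) "PE+" else "PE-")
}

#' Rigid tetra-cationic porphyrin template
#'
#' The coarse-grained porphyrin is a rigid, planar unit of eight beads: four
#' hydrophobic ring beads (`P`) at the corners of a square of side `edge`,
#' each carrying one charged periphery bead (`Pq+`) displaced outward along
#' the square diagonal by `arm`.  The whole unit is integrated as a rigid
#' body, so no bonds are defined; the stored reference coordinates are
#' coplanar and centred on the origin.
#'
#' @param edge Side of the P-bead square (reduced length, default 0.7, the
#'   bond-length scale of the model).
#' @param arm Outward diagonal displacement of each Pq+ bead from its P bead
#'   (reduced length, default 0.7).
#' @return A rigid `dpd_template` with 8 beads and net charge +4.
#' @export
#' @examples
#' p <- make_porphyrin()
#' p$charge                       # +4
#' colMeans(p$xyz)                # centred reference geometry
make_porphyrin <- function(edge = 0.7, arm = 0.7) {
  if (!isTRUE(edge > 0)) stop("'edge' must be positive")
  if (!isTRUE(arm >= 0)) stop("'arm' must be non-negative")
  h <- edge / 2
  # square corners in the z = 0 plane
  ring <- rbind(c( h,  h, 0), c(-h,  h, 0), c(-h, -h, 0), c( h, -h, 0))
  diag_out <- ring / sqrt(rowSums(ring^2))
  periph <- ring + arm * diag_out
  xyz <- rbind(ring, periph)
  xyz <- sweep(xyz, 2, colMeans(xyz))   # exact COM at origin
  new_template(c(rep("P", 4), rep("Pq+", 4)), bonds = NULL, rigid = TRUE,
               xyz = xyz, type = "P+")
}

#' Porphyrins needed to replace one polyelectrolyte chain
#'
#' Charge-equivalence ratio between a polyelectrolyte chain template and a
#' porphyrin template: the absolute chain net charge divided by the absolute
#' porphyrin net charge.  For the A10 block (+/-10) against the
#' tetra-cationic porphyrin (+4) the replacement of one chain requires the
#' equivalent of 2.5 porphyrins.
#'
#' @param chain_template,porphyrin_template `dpd_template` objects.
#' @return Number of porphyrins electrostatically equivalent to one chain.
#' @export
#' @examples
#' charge_equivalence(make_diblock(10, 25, +1), make_porphyrin())
charge_equivalence <- function(chain_template, porphyrin_template) {
  qp <- porphyrin_template$charge
  if (qp == 0) stop("porphyrin template carries no net charge")
  qc <- chain_template$charge
  if (qc == 0) stop("chain template carries no net charge")
  abs(qc) / abs(qp)
}
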