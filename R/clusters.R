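# Associate/aggregate identification and association statistics.

#' Identify associates by the close-approach criterion
#'
#' Single-linkage clustering of molecules: two molecules are linked when any
#' bead of one, restricted to the core-forming member species, lies within
#' `d_cut` of a bead of the other under the minimum-image convention;
#' transitive closure defines the clusters.  The default member set (A+, A-,
#' P, Pq+) makes association a core-contact criterion, so shell-brushing
#' contacts between B blocks do not merge distinct associates.  The default
#' cutoff 0.7 is the bond-length scale of the model.
#'
#' @param state A `dpd_state` (supplies topology and box).
#' @param pos Optional position matrix overriding `state$pos` (a trajectory
#'   frame).
#' @param d_cut Contact cutoff (> 0, reduced length).
#' @param member_species Species whose beads mediate linkage.
#' @param molecule_types Molecule types that take part in clustering.
#' @param step Step index recorded in the report.
#' @return A `cluster_report`: list with `molecules` (mol_id, mol_type,
#'   cluster label) and `clusters` (per-cluster association number `as` =
#'   number of copolymer chains, chain and porphyrin counts, net charge).
#' @export
#' @examples
#' fx <- make_cluster_fixture(c(1, 2, 3), L = 20)
#' rep <- identify_clusters(fx$state)
#' rep$clusters$as
identify_clusters <- function(state, pos = NULL, d_cut = 0.7,
                              member_species = c("A+", "A-", "P", "Pq+"),
                              molecule_types = c("PE+", "PE-", "P+"),
                              step = NA_integer_) {
  stopifnot(d_cut > 0)
  if (length(member_species) == 0) stop("member species set must be non-empty")
  if (is.null(pos)) pos <- state$pos
  lab <- species_labels(state)
  bead_type <- state$mol_type[state$mol_id]
  sel <- which(lab %in% member_species & bead_type %in% molecule_types)
  mols <- sort(unique(state$mol_id[sel]))
  if (length(mols) == 0) {
    return(empty_cluster_report(step, d_cut))
  }
  cl <- rep(NA_integer_, length(mols))
  names(cl) <- as.character(mols)
  if (length(sel) > 1) {
    pairs <- cpp_contact_pairs(pos[sel, , drop = FALSE], state$L, d_cut)
    mi <- state$mol_id[sel[pairs[, 1]]]
    mj <- state$mol_id[sel[pairs[, 2]]]
    keep <- mi != mj
    edges <- cbind(match(mi[keep], mols), match(mj[keep], mols))
  } else {
    edges <- matrix(integer(0), 0, 2)
  }
  g <- igraph::make_empty_graph(n = length(mols), directed = FALSE)
  if (nrow(edges) > 0) g <- igraph::add_edges(g, t(edges))
  membership <- igraph::components(g)$membership
  mol_charge <- molecule_charges(state)
  molecules <- data.frame(
    mol_id = mols,
    mol_type = state$mol_type[mols],
    cluster = as.integer(membership),
    stringsAsFactors = FALSE
  )
  clusters <- cluster_summary(molecules, mol_charge[mols])
  rep <- list(step = step, d_cut = d_cut, molecules = molecules,
              clusters = clusters)
  class(rep) <- "cluster_report"
  rep
}

empty_cluster_report <- function(step, d_cut) {
  rep <- list(step = step, d_cut = d_cut,
              molecules = data.frame(mol_id = integer(0),
                                     mol_type = character(0),
                                     cluster = integer(0)),
              clusters = data.frame(cluster = integer(0), as = integer(0),
                                    n_pe_plus = integer(0),
                                    n_pe_minus = integer(0),
                                    n_p = integer(0),
                                    net_charge = numeric(0)))
  class(rep) <- "cluster_report"
  rep
}

cluster_summary <- function(molecules, charges) {
  f <- factor(molecules$cluster)
  nplus <- tapply(molecules$mol_type == "PE+", f, sum)
  nminus <- tapply(molecules$mol_type == "PE-", f, sum)
  np <- tapply(molecules$mol_type == "P+", f, sum)
  qc <- tapply(charges, f, sum)
  data.frame(
    cluster = as.integer(levels(f)),
    as = as.integer(nplus + nminus),
    n_pe_plus = as.integer(nplus),
    n_pe_minus = as.integer(nminus),
    n_p = as.integer(np),
    net_charge = as.numeric(qc),
    row.names = NULL
  )
}

#' @export
print.cluster_report <- function(x, ...) {
  cat("<cluster_report> step", x$step, ":", nrow(x$clusters), "clusters over",
      nrow(x$molecules), "molecules (d_cut =", x$d_cut, ")\n")
  invisible(x)
}

#' Cluster every frame of a trajectory
#'
#' @param state A `dpd_state` providing the topology.
#' @param frames List of frames (`list(step, pos)`), e.g. from [dpd_run()].
#' @param ... Passed to [identify_clusters()].
#' @return List of `cluster_report`s.
#' @export
analyze_frames <- function(state, frames, ...) {
  lapply(frames, function(fr) {
    identify_clusters(state, pos = fr$pos, step = fr$step, ...)
  })
}

as_report_list <- function(reports) {
  if (inherits(reports, "cluster_report")) list(reports) else reports
}

discard_equilibration <- function(reports, discard_frac) {
  n <- length(reports)
  drop <- floor(discard_frac * n)
  if (drop > 0 && drop < n) reports[(drop + 1):n] else reports
}

#' Association-number statistics over frames
#'
#' Ensemble- and time-averaged number and weight distributions of
#' association numbers.  With `count = "chains"` the association number AS
#' of a cluster is its number of copolymer chains, single chains (AS = 1)
#' are included and porphyrins are not counted; with `count = "porphyrins"`
#' the sizes are porphyrin aggregate sizes (monomer = 1).  The first
#' `discard_frac` of the frames is discarded as equilibration.
#'
#' @param reports A `cluster_report` or list of them.
#' @param count What the association number counts.
#' @param discard_frac Fraction of initial frames to drop.
#' @return An `as_distribution`: data frame `dist` with columns `as`, `n`
#'   (cluster count), `n_frac`, `f_w` (weight fraction, proportional to
#'   `as * n`), plus the number average `asn`.
#' @export
#' @examples
#' fx <- make_cluster_fixture(c(1, 2, 3), L = 20)
#' s <- association_statistics(identify_clusters(fx$state))
#' s$asn      # (1 + 2 + 3) / 3 = 2
#' s$dist$f_w # 1/6, 2/6, 3/6
association_statistics <- function(reports, count = c("chains", "porphyrins"),
                                   discard_frac = 0) {
  count <- match.arg(count)
  reports <- discard_equilibration(as_report_list(reports), discard_frac)
  sizes <- unlist(lapply(reports, function(r) {
    if (count == "chains") {
      r$clusters$as[r$clusters$as >= 1]
    } else {
      r$clusters$n_p[r$clusters$n_p >= 1]
    }
  }))
  if (length(sizes) == 0) {
    out <- list(dist = data.frame(as = integer(0), n = integer(0),
                                  n_frac = numeric(0), f_w = numeric(0)),
                asn = NA_real_, n_clusters = 0L, n_frames = length(reports))
    class(out) <- "as_distribution"
    return(out)
  }
  tab <- table(sizes)
  as_vals <- as.integer(names(tab))
  n <- as.integer(tab)
  n_frac <- n / sum(n)
  f_w <- as_vals * n / sum(as_vals * n)
  out <- list(dist = data.frame(as = as_vals, n = n, n_frac = n_frac,
                                f_w = f_w),
              asn = sum(as_vals * n) / sum(n),
              n_clusters = sum(n), n_frames = length(reports))
  class(out) <- "as_distribution"
  out
}

#' @export
print.as_distribution <- function(x, ...) {
  cat("<as_distribution> <AS>_n =", format(x$asn, digits = 4), "over",
      x$n_clusters, "clusters in", x$n_frames, "frames\n")
  print(x$dist, row.names = FALSE)
  invisible(x)
}

#' Weight distribution of porphyrin aggregate sizes
#'
#' Clusters each frame with linkage restricted to porphyrin beads (P, Pq+)
#' and returns the weight-fraction distribution F_w over aggregate sizes,
#' counting monomers as size 1.
#'
#' @param state A `dpd_state` containing porphyrins.
#' @param frames List of frames; defaults to the current state as a single
#'   frame.
#' @param d_cut Contact cutoff.
#' @param discard_frac Equilibration fraction to discard.
#' @return An `as_distribution` over porphyrin aggregate sizes.
#' @export
porphyrin_aggregate_distribution <- function(state, frames = NULL,
                                             d_cut = 0.7, discard_frac = 0) {
  if (!any(state$mol_type == "P+")) stop("state contains no porphyrins")
  if (is.null(frames)) frames <- list(list(step = 0L, pos = state$pos))
  reports <- analyze_frames(state, frames, d_cut = d_cut,
                            member_species = c("P", "Pq+"),
                            molecule_types = "P+")
  association_statistics(reports, count = "porphyrins",
                         discard_frac = discard_frac)
}

#' Solubilized porphyrin fraction over time
#'
#' A porphyrin counts as solubilized when it shares a cluster with at least
#' one copolymer chain.  Reports must come from the combined clustering
#' (chains and porphyrins together, the default of [identify_clusters()]).
#'
#' @param reports A `cluster_report` or list of them.
#' @return Data frame with columns `step`, `n_solubilized`, `f_p` (fraction
#'   of all porphyrins residing in polymer associates).
#' @export
solubilized_fraction <- function(reports) {
  reports <- as_report_list(reports)
  rows <- lapply(reports, function(r) {
    total <- sum(r$clusters$n_p)
    if (total == 0) stop("no porphyrins in cluster report")
    n_sol <- sum(r$clusters$n_p[r$clusters$as >= 1])
    data.frame(step = r$step, n_solubilized = n_sol, f_p = n_sol / total)
  })
  do.call(rbind, rows)
}

#' Per-cluster core composition
#'
#' Counts of positive and negative chains and porphyrins per cluster, with
#' the net core charge.  For the A10 diblock / tetra-cationic porphyrin
#' system the net charge is `10 (n_PE+ - n_PE-) + 4 n_P+`.
#'
#' @param report A `cluster_report`.
#' @return The per-cluster composition data frame.
#' @export
core_composition <- function(report) {
  stopifnot(inherits(report, "cluster_report"))
  report$clusters
}

#' Net core charge from (possibly time-averaged) composition counts
#'
#' @param n_pe_plus,n_pe_minus,n_p Chain and porphyrin counts (may be
#'   fractional when time-averaged).
#' @param q_chain,q_porphyrin Absolute net charges of the chain and
#'   porphyrin templates.
#' @return Net core charge in units of the elementary charge.
#' @export
#' @examples
#' core_net_charge(14.6, 15, 9.0)    # +32.0
core_net_charge <- function(n_pe_plus, n_pe_minus, n_p, q_chain = 10,
                            q_porphyrin = 4) {
  q_chain * (n_pe_plus - n_pe_minus) + q_porphyrin * n_p
}
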