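# Associate identification and association statistics.

test_that("fixture clusters are recovered exactly", {
  fx <- make_cluster_fixture(c(1, 2, 3), L = 20)
  rep <- identify_clusters(fx$state)
  got <- canonical_partition(rep$molecules$cluster)
  want <- canonical_partition(fx$labels)
  expect_equal(got, want)
  expect_equal(sort(rep$clusters$as), c(1, 2, 3))
  # all unimers
  fx1 <- make_cluster_fixture(rep(1, 4), L = 20)
  s1 <- association_statistics(identify_clusters(fx1$state))
  expect_equal(s1$dist$f_w, 1)
  expect_equal(s1$dist$as, 1)
  # one cluster takes all the weight
  fx5 <- make_cluster_fixture(5, L = 20)
  s5 <- association_statistics(identify_clusters(fx5$state))
  expect_equal(s5$dist$as, 5)
  expect_equal(s5$dist$f_w, 1)
})

test_that("clustering equals the brute-force union-find oracle", {
  for (seed in c(101, 102, 103, 104)) {
    st <- random_dumbbell_state(60, 7, seed)
    rep <- identify_clusters(st, d_cut = 0.7,
                             member_species = c("A+", "A-"))
    oracle <- oracle_molecule_clusters(st$pos, st$mol_id, st$L, 0.7)
    expect_equal(canonical_partition(rep$molecules$cluster),
                 canonical_partition(oracle),
                 label = paste("seed", seed))
  }
})

test_that("clustering is invariant under translation and rewrapping", {
  st <- random_dumbbell_state(40, 7, 111)
  ref <- canonical_partition(identify_clusters(st)$molecules$cluster)
  for (shift in list(c(3.1, 0, 0), c(-1.2, 5.9, 2.2))) {
    st2 <- st
    st2$pos <- wrap_positions_for_test(
      st$pos + rep(shift, each = nrow(st$pos)), st$L)
    got <- canonical_partition(identify_clusters(st2)$molecules$cluster)
    expect_equal(got, ref)
  }
})

test_that("association statistics follow the counting convention", {
  fx <- make_cluster_fixture(c(1, 2, 3), L = 20)
  s <- association_statistics(identify_clusters(fx$state))
  expect_equal(s$asn, 2)
  expect_equal(s$dist$f_w, c(1, 2, 3) / 6)
  expect_equal(sum(s$dist$n_frac), 1, tolerance = 1e-12)
  expect_equal(sum(s$dist$f_w), 1, tolerance = 1e-12)
  # porphyrin-only content yields an empty chain distribution
  fxp <- make_cluster_fixture(c(2, 1), L = 20, kind = "porphyrin")
  sp <- association_statistics(identify_clusters(fxp$state))
  expect_equal(sp$n_clusters, 0)
  expect_true(is.na(sp$asn))
  # equilibration discard drops early frames
  r1 <- identify_clusters(fx$state, step = 0)
  r2 <- identify_clusters(fx$state, step = 10)
  s2 <- association_statistics(rep(list(r1, r2), 5), discard_frac = 0.5)
  expect_equal(s2$n_frames, 5)
})

test_that("porphyrin aggregates are sized by porphyrin count", {
  fx <- make_cluster_fixture(c(2, rep(1, 8)), L = 24, kind = "porphyrin")
  pd <- porphyrin_aggregate_distribution(fx$state)
  # one dimer among 8 monomers: F_w(1) = 0.8, F_w(2) = 0.2
  expect_equal(pd$dist$f_w[pd$dist$as == 1], 0.8)
  expect_equal(pd$dist$f_w[pd$dist$as == 2], 0.2)
  # stacked porphyrins at inter-ring distance < d_cut form one aggregate
  fx2 <- make_cluster_fixture(2, L = 20, kind = "porphyrin")
  pd2 <- porphyrin_aggregate_distribution(fx2$state)
  expect_equal(pd2$dist$as, 2)
  expect_error(porphyrin_aggregate_distribution(
    make_cluster_fixture(2, L = 20)$state), "porphyrin")
})

test_that("solubilized fraction counts porphyrins sharing chain clusters", {
  # two chain dimers; one porphyrin touching the first, one far away
  fx <- make_cluster_fixture(c(2, 2), L = 24)
  st <- fx$state
  tpl <- make_porphyrin()
  near <- sweep(tpl$xyz, 2, st$pos[1, ] + c(0, 0.3, 0), "+")
  far <- sweep(tpl$xyz, 2, c(12, 12, 12), "+")
  n0 <- n_beads(st)
  pos <- rbind(st$pos, near, far)
  st2 <- dpd_state(st$L, pos, matrix(0, nrow(pos), 3),
                   species = c(SPECIES_LEVELS_FOR_TEST(st), rep(tpl$species, 2)),
                   bonds = st$bonds,
                   mol_id = c(st$mol_id, rep(max(st$mol_id) + 1, 8),
                              rep(max(st$mol_id) + 2, 8)),
                   mol_type = c(st$mol_type, "P+", "P+"),
                   rigid_bodies = list(n0 + 1:8, n0 + 9:16))
  rep <- identify_clusters(st2)
  fp <- solubilized_fraction(rep)
  expect_equal(fp$n_solubilized, 1)
  expect_equal(fp$f_p, 0.5)
  # all solubilized / none solubilized limits
  expect_error(solubilized_fraction(identify_clusters(fx$state)),
               "porphyrin")
})

test_that("core composition reports counts and net charge", {
  rec <- scenario_recipe(n_plus = 2, n_minus = 2, L = 10,
                         mode = "preaggregated", seed = 61)
  st <- assemble_preaggregated(rec)
  comp <- core_composition(identify_clusters(st))
  expect_equal(comp$n_pe_plus, 2)
  expect_equal(comp$n_pe_minus, 2)
  expect_equal(comp$n_p, 0)
  expect_equal(comp$net_charge, 0)  # stoichiometric: 10*(2-2) + 4*0
  # charge arithmetic on time-averaged compositions
  expect_equal(core_net_charge(15, 15, 0), 0)
  expect_equal(core_net_charge(12.1, 15, 15.2), 31.8)
  expect_equal(core_net_charge(14.6, 15, 9.0), 32.0)
})

test_that("empty member species set is rejected", {
  fx <- make_cluster_fixture(2, L = 20)
  expect_error(identify_clusters(fx$state, member_species = character(0)),
               "member species")
  expect_error(identify_clusters(fx$state, d_cut = 0), "d_cut")
})
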