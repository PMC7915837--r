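# System builders: electroneutrality, density fill, determinism, geometry.

test_that("recipe derives counterion counts from electroneutrality", {
  rec <- scenario_recipe(n_plus = 137, n_minus = 137, L = 30, seed = 1)
  expect_equal(rec$n_ci_minus, 1370)
  expect_equal(rec$n_ci_plus, 1370)
  expect_equal(rec$n_total, round(3 * 30^3))

  # each porphyrin adds 4 CI-, salt adds both in equal numbers
  rec2 <- scenario_recipe(n_porphyrin = 3, n_salt_pairs = 7, L = 10, seed = 1)
  expect_equal(rec2$n_ci_minus, 12 + 7)
  expect_equal(rec2$n_ci_plus, 7)

  # fill arithmetic: 1 porphyrin in L = 10 leaves 2988 solvent of 3000
  rec3 <- scenario_recipe(n_porphyrin = 1, L = 10, seed = 1)
  expect_equal(rec3$n_total, 3000)
  expect_equal(rec3$n_solvent, 2988)

  expect_error(assemble_box(scenario_recipe(n_plus = 50, n_minus = 50, L = 5)),
               "too small")
})

test_that("random assembly is neutral, filled to rho L^3 and deterministic", {
  rec <- scenario_recipe(n_plus = 2, n_minus = 2, n_porphyrin = 1,
                         n_salt_pairs = 5, L = 7, seed = 42)
  st <- assemble_box(rec)
  expect_equal(total_charge(st), 0)
  expect_equal(n_beads(st), round(3 * 7^3))
  expect_true(all(st$pos >= 0 & st$pos < 7))
  # no net momentum in Maxwell velocities
  expect_equal(colSums(st$vel), c(0, 0, 0), tolerance = 1e-10)
  # template round trip: each chain occupies a contiguous disjoint range
  # with the template's species sequence
  tpl <- make_diblock(2, 5, +1)
  rec2 <- scenario_recipe(n_plus = 3, L = 6, n_a = 2, n_b = 5, seed = 9)
  st2 <- assemble_box(rec2)
  for (m in 1:3) {
    beads <- which(st2$mol_id == m)
    expect_equal(length(beads), 7)
    expect_equal(SPECIES_LEVELS_FOR_TEST(st2)[beads], tpl$species)
  }
  # determinism: identical recipe and seed give identical states
  st_b <- assemble_box(rec)
  expect_identical(st$pos, st_b$pos)
  expect_identical(st$vel, st_b$vel)
  expect_identical(st$species, st_b$species)
})

test_that("empty recipe builds a pure solvent box", {
  st <- assemble_box(scenario_recipe(L = 5, seed = 3))
  expect_equal(n_beads(st), round(3 * 125))
  expect_equal(total_charge(st), 0)
  expect_true(all(SPECIES_LEVELS_FOR_TEST(st) == "S"))
})

test_that("pre-aggregated state is one associate with B blocks outside", {
  rec <- scenario_recipe(n_plus = 4, n_minus = 4, L = 12,
                         mode = "preaggregated", seed = 7)
  st <- assemble_preaggregated(rec)
  expect_equal(total_charge(st), 0)
  expect_equal(n_beads(st), round(3 * 12^3))
  rep <- identify_clusters(st)
  expect_equal(nrow(rep$clusters), 1)
  expect_equal(rep$clusters$as, 8)
  # core sphere contains no B beads at step 0
  lab <- SPECIES_LEVELS_FOR_TEST(st)
  r_core <- (3 * 80 / (4 * pi * 3))^(1 / 3)
  center <- rep(6, 3)
  d <- sweep(st$pos[lab == "B", ], 2, center)
  d <- d - st$L * round(d / st$L)
  expect_true(all(sqrt(rowSums(d^2)) > r_core))
  # trivial two-chain associate
  st2 <- assemble_preaggregated(scenario_recipe(
    n_plus = 1, n_minus = 1, L = 8, mode = "preaggregated", seed = 5))
  expect_equal(identify_clusters(st2)$clusters$as, 2)
  expect_error(assemble_preaggregated(scenario_recipe(L = 8)), "chain")
})

test_that("porphyrin insertion swaps solvent, keeps neutrality and distance", {
  st <- assemble_box(scenario_recipe(n_plus = 2, n_minus = 2, L = 8,
                                     seed = 21))
  n0 <- n_beads(st)
  st2 <- insert_porphyrins_bulk(st, 3, seed = 22)
  expect_equal(n_beads(st2), n0)
  expect_equal(total_charge(st2), 0)
  expect_equal(sum(st2$mol_type == "P+"), 3)
  expect_equal(length(st2$rigid_bodies), 3)
  # molecule bookkeeping: every porphyrin molecule owns exactly 8 beads of
  # the porphyrin species, and every counterion molecule one bead
  for (m in which(st2$mol_type == "P+")) {
    beads <- which(st2$mol_id == m)
    expect_equal(length(beads), 8)
    expect_true(all(SPECIES_LEVELS_FOR_TEST(st2)[beads] %in% c("P", "Pq+")))
  }
  expect_true(all(tabulate(st2$mol_id)[st2$mol_type == "CI-"] == 1))
  # total momentum preserved by the velocity hand-over
  expect_equal(colSums(st2$vel), colSums(st$vel), tolerance = 1e-9)
  # every porphyrin bead at least the contact cutoff from polymer beads
  lab <- SPECIES_LEVELS_FOR_TEST(st2)
  poly <- st2$pos[lab %in% c("A+", "A-", "B"), ]
  por <- st2$pos[lab %in% c("P", "Pq+"), ]
  dmin <- min(vapply(seq_len(nrow(por)), function(k) {
    d <- sweep(poly, 2, por[k, ])
    d <- d - st2$L * round(d / st2$L)
    sqrt(min(rowSums(d^2)))
  }, numeric(1)))
  expect_gte(dmin, 1.0)
  # bonds survived the index remap: chain species at both bond ends
  expect_true(all(lab[st2$bonds] %in% c("A+", "A-", "B")))
  # n = 0 is the identity
  expect_identical(insert_porphyrins_bulk(st, 0), st)
  expect_error(insert_porphyrins_bulk(st, 10000), "solvent")
})

test_that("cluster fixture places clusters with known labels", {
  fx <- make_cluster_fixture(c(1, 2, 3), L = 20)
  expect_equal(length(fx$labels), 6)
  expect_equal(total_charge(fx$state), 0)
  fxp <- make_cluster_fixture(c(5), L = 20, kind = "porphyrin")
  expect_equal(sum(fxp$state$mol_type == "P+"), 5)
  expect_equal(total_charge(fxp$state), 0)
  expect_error(make_cluster_fixture(rep(3, 100), L = 6), "fit")
})
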