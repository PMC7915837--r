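# Smeared-charge pair interaction and Ewald sums.

test_that("smeared pair force is finite, signed and Coulombic at range", {
  m <- charge_model()
  expect_equal(smeared_pair_force(0, 1, 1, m), 0)   # finite at overlap
  expect_true(is.finite(smeared_pair_energy(0, 1, 1, m)))
  expect_equal(smeared_pair_energy(0, 1, 1, m),
               13.87 / (4 * pi) * 5 / (8 * 0.2))
  # attraction for opposite charges at every separation
  r <- seq(0.05, 3, by = 0.05)
  expect_true(all(smeared_pair_force(r, 1, -1, m) < 0))
  expect_true(all(smeared_pair_force(r, 1, 1, m) > 0))
  # point-Coulomb limit at r = 10 lambda
  r10 <- 10 * m$lambda
  coulomb <- m$gamma_coupling / (4 * pi * r10^2)
  expect_equal(smeared_pair_force(r10, 1, 1, m), coulomb, tolerance = 0.01)
  # force is the negative derivative of the energy (numeric check)
  h <- 1e-6
  num <- -(smeared_pair_energy(1.1 + h, 1, 1, m) -
             smeared_pair_energy(1.1 - h, 1, 1, m)) / (2 * h)
  expect_equal(smeared_pair_force(1.1, 1, 1, m), num, tolerance = 1e-6)
})

test_that("the smearing keeps the whole charge inside one bead", {
  # closed form vs numerical integration of the Slater cloud
  lam <- 0.2
  dens <- function(r) r^2 * 4 * pi * exp(-2 * r / lam) / (pi * lam^3)
  num <- stats::integrate(dens, 0, 1)$value
  expect_equal(charge_fraction_within(1, lam), num, tolerance = 1e-8)
  expect_gte(charge_fraction_within(1, lam), 0.99)
  # a broader cloud would not satisfy the one-bead condition
  expect_lt(charge_fraction_within(1, 0.67), 0.99)
})

test_that("Ewald agrees with the direct image-shell oracle", {
  st <- random_ion_state(10, 8, seed = 41)
  m <- charge_model(accuracy = 1e-5, boundary = "vacuum")
  ew <- ewald_forces(st, m)
  ds <- direct_sum_reference(st, m, n_shells = 6)
  scale <- max(abs(ds$forces))
  expect_lt(max(abs(ew$forces - ds$forces)) / scale, 1e-3)
  expect_equal(ew$energy, ds$energy, tolerance = 1e-3)
  # direct sum energies are Cauchy-convergent in the shell count
  e <- vapply(3:6, function(ns) direct_sum_reference(st, m, ns)$energy,
              numeric(1))
  expect_lt(abs(e[4] - e[3]), abs(e[2] - e[1]) + 1e-12)
  # zero net force on a neutral system
  expect_lt(max(abs(colSums(ew$forces))), 1e-8)
})

test_that("Ewald energy is translation invariant and rejects non-neutral", {
  st <- random_ion_state(8, 8, seed = 42)
  m <- charge_model(accuracy = 1e-6)
  e1 <- ewald_forces(st, m)$energy
  st2 <- st
  st2$pos <- wrap_positions_for_test(st$pos + rep(c(1.3, -2.1, 0.7),
                                                  each = nrow(st$pos)), 8)
  e2 <- ewald_forces(st2, m)$energy
  expect_equal(e1, e2, tolerance = 1e-8)
  # uncharged state: exactly zero
  s0 <- random_solvent_state(20, 8, seed = 43)
  z <- ewald_forces(s0, m)
  expect_equal(z$energy, 0)
  expect_equal(max(abs(z$forces)), 0)
  # a net-charged state is rejected
  bad <- st
  bad$charge[1] <- 2
  expect_error(ewald_forces(bad, m), "neutral")
  expect_error(charge_model(r_cut = 2), "3 r_c")
})

test_that("an isolated smeared pair is recovered in a large box", {
  L <- 30
  st <- dpd_state(L, rbind(c(5, 5, 5), c(6, 5, 5)), matrix(0, 2, 3),
                  species = c("CI+", "CI-"), mol_id = 1:2,
                  mol_type = c("CI+", "CI-"))
  ew <- ewald_forces(st, charge_model(accuracy = 1e-5))
  f_iso <- smeared_pair_force(1, 1, -1, charge_model())
  # attractive: force on the + charge points toward the - charge (+x)
  expect_equal(ew$forces[1, 1], -f_iso, tolerance = 1e-3)
  expect_equal(ew$forces[1, 1], -ew$forces[2, 1], tolerance = 1e-9)
})

test_that("counterions accumulate near an isolated polyelectrolyte chain", {
  # one A10- chain with its 10 CI+ in solvent: the CI+ density near the
  # chain must exceed the bulk value (counterion condensation)
  rec <- scenario_recipe(n_minus = 1, L = 8, n_a = 10, n_b = 2, seed = 51)
  st <- assemble_box(rec)
  tr <- dpd_run(st, sim_params(), charge_model(), n_steps = 1500, seed = 52,
                thermo_stride = 0, frame_stride = 250)
  lab <- SPECIES_LEVELS_FOR_TEST(st)
  a_idx <- which(lab == "A-")
  ci_idx <- which(lab == "CI+")
  enh <- vapply(tr$frames[3:6], function(fr) {
    near <- 0
    for (k in ci_idx) {
      d <- sweep(fr$pos[a_idx, , drop = FALSE], 2, fr$pos[k, ])
      d <- d - st$L * round(d / st$L)
      if (min(rowSums(d^2)) < 1.5^2) near <- near + 1
    }
    near / length(ci_idx)
  }, numeric(1))
  # expected fraction for a uniform ion gas: 10 spheres of r=1.5 at most
  uniform_frac <- min(1, 10 * 4 / 3 * pi * 1.5^3 / 8^3)
  expect_gt(mean(enh), 1.5 * uniform_frac)
})
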