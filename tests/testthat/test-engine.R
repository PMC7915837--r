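# Integrator, pair forces, neighbour search, thermostat bookkeeping.

test_that("conservative pair force has the soft-repulsion closed form", {
  expect_equal(pair_conservative_force(c(1, 0, 0), 25), c(0, 0, 0))
  expect_equal(pair_conservative_force(c(1.7, 0, 0), 25), c(0, 0, 0))
  f <- pair_conservative_force(c(0.5, 0, 0), 25)
  expect_equal(f, c(12.5, 0, 0))
  expect_equal(sqrt(sum(pair_conservative_force(c(0, 0.5, 0), 18)^2)), 9)
  # soft at overlap: defined as zero
  expect_equal(pair_conservative_force(c(0, 0, 0), 25), c(0, 0, 0))
})

test_that("dissipative and random pair forces follow the DPD weights", {
  expect_equal(pair_dissipative_random_force(c(1.2, 0, 0), c(1, 0, 0),
                                             4.5, 3, 0.04, 1), c(0, 0, 0))
  # perpendicular relative velocity and zero noise: no force
  expect_equal(pair_dissipative_random_force(c(0.5, 0, 0), c(0, 2, 0),
                                             4.5, 0, 0.04, 0), c(0, 0, 0))
  # head-on approach is damped along the axis
  f <- pair_dissipative_random_force(c(0.5, 0, 0), c(1, 0, 0), 4.5, 0, 0.04, 0)
  expect_equal(f, c(-4.5 * 0.25 * 1, 0, 0))
  # random part scales as sigma w xi / sqrt(dt)
  fr <- pair_dissipative_random_force(c(0.5, 0, 0), c(0, 0, 0), 4.5, 3,
                                      0.04, 1)
  expect_equal(fr[1], 3 * 0.5 / sqrt(0.04))
})

test_that("bond force is harmonic and linear in the spring constant", {
  expect_equal(bond_force(c(0.5, 0, 0), 4, 0.5), c(0, 0, 0))
  f <- bond_force(c(1, 0, 0), 4, 0)
  expect_equal(f, c(-4, 0, 0))  # magnitude 4 toward the partner
  expect_equal(bond_force(c(0, 0.8, 0), 8, 0.2),
               2 * bond_force(c(0, 0.8, 0), 4, 0.2))
})

test_that("fluctuation-dissipation is enforced in sim_params", {
  p <- sim_params(gamma = 2.25, kT = 2)
  expect_equal(p$sigma^2, 2 * 2.25 * 2)
  expect_null(p[["sigma_override"]])
})

test_that("kinetic temperature counts degrees of freedom correctly", {
  st <- random_solvent_state(200, 6, seed = 4)
  st$vel[] <- 0
  expect_equal(measure_temperature(st), 0)
  # sampled at kT = 1
  st2 <- random_solvent_state(3000, 10, seed = 5)
  expect_equal(measure_temperature(st2), 1, tolerance = 0.03)
  # one rigid porphyrin + 10 free beads, momentum removed: 6 + 30 - 3 dof
  tpl <- make_porphyrin()
  pos <- rbind(sweep(tpl$xyz, 2, c(3, 3, 3), "+"),
               matrix(runif(30, 0, 6), ncol = 3))
  st3 <- dpd_state(6, pos, matrix(rnorm(54), ncol = 3),
                   species = c(tpl$species, rep("S", 10)),
                   mol_id = c(rep(1, 8), 2:11),
                   mol_type = c("P+", rep("S", 10)),
                   rigid_bodies = list(1:8))
  tr <- dpd_run(st3, n_steps = 0, thermo_stride = 0, frame_stride = 0)
  expect_equal(tr$ndof, 33)
})

test_that("integration matches a plain-R reference for a harmonic dimer", {
  L <- 10
  x0 <- c(4, 5.8)
  st <- dpd_state(L, cbind(x0, c(5, 5), c(5, 5)), matrix(0, 2, 3),
                  species = c("B", "B"), bonds = cbind(1L, 2L),
                  mol_id = c(1L, 1L), mol_type = "PE+")
  # weak spring keeps the pair beyond r_c for the whole horizon, so the
  # bond is the only force and the thermostat weight w(r) vanishes
  p <- sim_params(dt = 0.04, gamma = 1e-12, k_bond = 0.25)
  tr <- dpd_run(st, p, n_steps = 30, seed = 1, thermo_stride = 0,
                frame_stride = 0)
  ref <- reference_dimer_trajectory(4, 5.8, 0, 0, k = 0.25, dt = 0.04,
                                    lambda_vv = p$lambda_vv, n_steps = 30,
                                    L = L)
  expect_equal(tr$state$pos[, 1], ref$x, tolerance = 1e-10)
  expect_equal(tr$state$vel[, 1], ref$v, tolerance = 1e-10)
  # zero forces, zero velocities: state unchanged
  st0 <- dpd_state(L, matrix(c(2, 2, 2), 1, 3), matrix(0, 1, 3),
                   species = "S", mol_id = 1L, mol_type = "S")
  tr0 <- dpd_run(st0, sim_params(), n_steps = 25, seed = 1,
                 thermo_stride = 0, frame_stride = 0)
  expect_equal(tr0$state$pos, st0$pos)
  expect_equal(tr0$state$vel, st0$vel)
  # zero-step run is the identity with empty logs
  trz <- dpd_run(st, n_steps = 0)
  expect_equal(trz$state$pos, st$pos)
  expect_equal(nrow(trz$thermo), 0)
  expect_equal(length(trz$frames), 0)
})

test_that("neighbour search finds pairs across periodic boundaries", {
  st <- dpd_state(10, rbind(c(1, 1, 1), c(1.5, 1, 1), c(9.8, 1, 1)),
                  matrix(0, 3, 3), species = rep("S", 3), mol_id = 1:3,
                  mol_type = rep("S", 3))
  pr <- neighbor_pairs(st, 1)
  keyed <- paste(pmin(pr[, 1], pr[, 2]), pmax(pr[, 1], pr[, 2]))
  expect_true("1 2" %in% keyed)    # direct pair at 0.5
  expect_false("1 3" %in% keyed)   # minimum-image distance 1.2 > cutoff
  # the periodic image at distance 1.2 appears once the cutoff allows it
  pr2 <- neighbor_pairs(st, 1.5)
  keyed2 <- paste(pmin(pr2[, 1], pr2[, 2]), pmax(pr2[, 1], pr2[, 2]))
  expect_true("1 3" %in% keyed2)
  expect_false(any(duplicated(keyed2)))
})

test_that("cell-list forces equal the all-pairs oracle", {
  st <- random_solvent_state(500, 6, seed = 11)
  f_cell <- compute_forces(st, use_cells = TRUE, thermostat = TRUE,
                           seed = 3, step = 17)
  f_all <- compute_forces(st, use_cells = FALSE, thermostat = TRUE,
                          seed = 3, step = 17)
  expect_lt(max(abs(f_cell - f_all)), 1e-10)
  # pairwise antisymmetry: total force vanishes, including random forces
  expect_lt(max(abs(colSums(f_cell))), 1e-9)
})

test_that("momentum is conserved and runs are deterministic", {
  st <- random_solvent_state(400, 6, seed = 12)
  st$vel <- sweep(st$vel, 2, colMeans(st$vel))
  tr1 <- dpd_run(st, n_steps = 400, seed = 7, thermo_stride = 100,
                 frame_stride = 0)
  drift <- max(abs(tr1$thermo[nrow(tr1$thermo), c("px", "py", "pz")]))
  expect_lt(drift, 1e-8)
  tr2 <- dpd_run(st, n_steps = 400, seed = 7, thermo_stride = 100,
                 frame_stride = 0)
  expect_identical(tr1$state$pos, tr2$state$pos)
  expect_identical(tr1$state$vel, tr2$state$vel)
  # a different seed gives a different trajectory
  tr3 <- dpd_run(st, n_steps = 400, seed = 8, thermo_stride = 0,
                 frame_stride = 0)
  expect_false(identical(tr1$state$pos, tr3$state$pos))
})

test_that("unstable integration aborts with a diagnostic", {
  st <- random_solvent_state(50, 6, seed = 13)
  st$vel[1, ] <- c(1e6, 0, 0)
  expect_error(dpd_run(st, n_steps = 10, seed = 1), "unstable")
})

test_that("athermal solvent stays spatially uniform", {
  st <- assemble_box(scenario_recipe(L = 8, seed = 31))
  tr <- dpd_run(st, n_steps = 600, seed = 32, thermo_stride = 0,
                frame_stride = 600)
  h <- hist(tr$state$pos[, 1], breaks = seq(0, 8, by = 1), plot = FALSE)
  expected <- n_beads(st) / 8
  # density per slab stays within 5 sigma of Poisson noise
  expect_true(all(abs(h$counts - expected) < 5 * sqrt(expected)))
})
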