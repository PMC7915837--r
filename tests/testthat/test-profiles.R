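# Radial density profiles around associate cores.

# a single small associate centred in a uniform solvent bath
uniform_bath_state <- function(L = 10, n_solvent = 3000, seed = 71) {
  set.seed(seed)
  chain <- rbind(c(L / 2, L / 2, L / 2), c(L / 2 + 0.3, L / 2, L / 2))
  solv <- matrix(runif(3 * n_solvent, 0, L), ncol = 3)
  pos <- rbind(chain, solv)
  dpd_state(L, pos, matrix(0, nrow(pos), 3),
            species = c("A+", "A-", rep("S", n_solvent)),
            bonds = cbind(1L, 2L),
            mol_id = c(1L, 1L, seq_len(n_solvent) + 1L),
            mol_type = c("PE+", rep("S", n_solvent)))
}

test_that("uniform solvent gives a flat profile at the bath density", {
  st <- uniform_bath_state()
  prof <- radial_density_profile(st, species = "S", bin_width = 0.5)
  rho_bath <- 3000 / 1000
  mid <- prof$S[prof$r_mid > 1.5 & prof$r_mid < 4]
  expect_equal(mean(mid), rho_bath, tolerance = 0.05)
  expect_true(all(abs(mid - rho_bath) / rho_bath < 0.3))
})

test_that("pre-aggregated associate shows the core-shell RDP shape", {
  rec <- scenario_recipe(n_plus = 6, n_minus = 6, L = 14,
                         mode = "preaggregated", seed = 72)
  st <- assemble_preaggregated(rec)
  prof <- radial_density_profile(st, species = c("A+", "A-", "B"),
                                 as_min = 12)
  a_tot <- prof$`A+` + prof$`A-`
  # A density is maximal near the centre (the innermost shells are tiny, so
  # the literal first bin is noisy); B peaks outside the A maximum
  expect_lt(prof$r_mid[which.max(a_tot)], 1)
  expect_gt(which.max(prof$B), which.max(a_tot))
  # no A beads beyond the B shell region
  r_core <- (3 * 120 / (4 * pi * 3))^(1 / 3)
  expect_true(all(a_tot[prof$r_mid > r_core + 0.5] == 0))
  # mass conservation: the A+ profile integrates to 60 beads (6 chains x 10)
  shell_vol <- 4 / 3 * pi * diff((0:nrow(prof) * attr(prof, "bin_width"))^3)
  expect_equal(sum(prof$`A+` * shell_vol), 60, tolerance = 0.05)
})

test_that("profiles are invariant under rigid translation of the frame", {
  rec <- scenario_recipe(n_plus = 3, n_minus = 3, L = 12,
                         mode = "preaggregated", seed = 73)
  st <- assemble_preaggregated(rec)
  p1 <- radial_density_profile(st, species = c("A+", "B"))
  st2 <- st
  st2$pos <- wrap_positions_for_test(
    st$pos + rep(c(4.2, -3.3, 1.1), each = nrow(st$pos)), st$L)
  p2 <- radial_density_profile(st2, species = c("A+", "B"))
  expect_equal(p1$`A+`, p2$`A+`, tolerance = 1e-12)
  expect_equal(p1$B, p2$B, tolerance = 1e-12)
})

test_that("charge profile of a stoichiometric associate is neutral", {
  rec <- scenario_recipe(n_plus = 4, n_minus = 4, L = 12,
                         mode = "preaggregated", seed = 74)
  st <- assemble_preaggregated(rec)
  cp <- core_charge_profile(st, as_min = 8)
  sp <- radial_density_profile(st, species = c("A+", "A-", "CI+", "CI-"),
                               as_min = 8)
  # the net-charge profile is the signed sum of the charged-species profiles
  expect_equal(cp$net_charge,
               sp$`A+` - sp$`A-` + sp$`CI+` - sp$`CI-`, tolerance = 1e-12)
  # the stoichiometric core is neutral: the A+ and A- profiles integrate to
  # the same bead count (40 each for 4 + 4 chains)
  shell_vol <- 4 / 3 * pi * diff((0:nrow(sp) * attr(sp, "bin_width"))^3)
  expect_equal(sum(sp$`A+` * shell_vol), sum(sp$`A-` * shell_vol),
               tolerance = 1e-9)
  expect_equal(sum(sp$`A+` * shell_vol), 40, tolerance = 1e-9)
  # a zero-charge system has an identically zero charge profile
  s0 <- uniform_bath_state(seed = 75)
  s0$charge[] <- 0
  cp0 <- core_charge_profile(s0)
  expect_true(all(cp0$net_charge == 0))
})

test_that("the profile filter rejects when nothing matches", {
  st <- uniform_bath_state()
  expect_error(radial_density_profile(st, as_min = 5), "filter")
})
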