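params <- energy_params()

test_that("environmental constants derive correctly", {
  expect_equal(params$kBT, 0.582, tolerance = 1e-3)
  # 150 mM, 293 K: inverse Debye length ~1.27 1/nm (Debye length ~0.79 nm)
  expect_equal(debye_kappa(0.15, 293, 80), 1.27, tolerance = 0.01)
  expect_equal(1 / debye_kappa(0.15, 293, 80), 0.79, tolerance = 0.01)
  # bending constant reproduces a 50 nm persistence length
  expect_equal(wlc_persistence_length(params$g, params$kBT, params$l0), 50,
               tolerance = 0.03)
})

test_that("stretching is harmonic in the segment extension", {
  ch <- dna_chain_system(3)
  expect_equal(stretching_energy(ch, params), 0)
  ch$linkers[[1]]$pos[3, 3] <- ch$linkers[[1]]$pos[3, 3] + 0.1
  # one segment at l0 + 0.1 with h = 100 -> 0.5 kcal/mol
  expect_equal(stretching_energy(ch, params), 0.5, tolerance = 1e-12)
})

test_that("bending is harmonic in the joint angle", {
  ch <- dna_chain_system(3)
  expect_equal(bending_energy(ch, params), 0, tolerance = 1e-12)
  # 90 degree kink: (g/2) (pi/2)^2
  ch$linkers[[1]]$pos[3, ] <- ch$linkers[[1]]$pos[2, ] + c(3, 0, 0)
  p10 <- energy_params(g = 10)
  expect_equal(bending_energy(ch, p10), 0.5 * 10 * (pi / 2)^2,
               tolerance = 1e-9)
  # doubling the angle quadruples the term
  ch30 <- dna_chain_system(3)
  th <- 0.2
  ch30$linkers[[1]]$pos[3, ] <- ch30$linkers[[1]]$pos[2, ] +
    3 * c(sin(th), 0, cos(th))
  ch60 <- dna_chain_system(3)
  ch60$linkers[[1]]$pos[3, ] <- ch60$linkers[[1]]$pos[2, ] +
    3 * c(sin(2 * th), 0, cos(2 * th))
  expect_equal(bending_energy(ch60, p10) / bending_energy(ch30, p10), 4,
               tolerance = 1e-9)
})

test_that("twist targets spread the nonintegral-turn deviation over segments", {
  sys <- build_fiber(5, nrl = 173)
  ta <- twist_assignment(sys, params)
  expect_equal(ta$tau[1], 26.47 / 10.3, tolerance = 1e-3)
  # 0.430 turns short of 3 full turns, spread over 3 segments
  expect_equal(abs(ta$tau[1] - round(ta$tau[1])), 0.430, tolerance = 1e-3)
  expect_identical(ta$n_seg[1], 3L)
  expect_equal(ta$phi_deg[1] * ta$n_seg[1] / 360,
               ta$tau[1] - round(ta$tau[1]), tolerance = 1e-12)
  # a linker of an integral number of turns has zero penalty angle
  sys$linkers[[2]]$length_bp <- 4 * 10.3
  ta2 <- twist_assignment(sys, params)
  expect_equal(ta2$phi_deg[2], 0)
  # segments twisted exactly to target contribute zero twist energy
  ch <- dna_chain_system(6)
  ch$linkers[[1]]$length_bp <- 5 * 10.3   # integral turns, target twist 0
  expect_equal(twisting_energy(ch, params), 0, tolerance = 1e-12)
})

test_that("electrostatics follows sign, screening and the zero-charge limit", {
  ch <- dna_chain_system(4, charged = TRUE)   # -24 e per bead
  e <- electrostatic_energy(ch, params)
  expect_gt(e, 0)        # like charges repel
  p0 <- energy_params(dna_bead_charge = 0)
  expect_identical(electrostatic_energy(ch, energy_params(dna_bead_charge = 0)),
                   0)
  # screening: higher salt weakens the repulsion
  e_salty <- electrostatic_energy(ch, energy_params(salt = 1))
  expect_lt(e_salty, e)
  # beyond the cutoff the energy vanishes
  far <- dna_chain_system(2, charged = TRUE)
  far$linkers[[1]]$pos[2, 3] <- 100
  expect_identical(electrostatic_energy(far, params), 0)
})

test_that("excluded volume has the 12-6 form with zero at r = sigma", {
  p <- energy_params(dna_bead_charge = 0, k_ev = 0.1, sigma_dna = 2.4)
  ch <- dna_chain_system(3)
  # beads 1 and 3 interact (adjacent pairs are bonded-excluded)
  ch$linkers[[1]]$pos[3, ] <- ch$linkers[[1]]$pos[1, ] + c(0, 0, 2.4)
  expect_equal(excluded_volume_energy(ch, p), 0, tolerance = 1e-12)
  ch$linkers[[1]]$pos[3, ] <- ch$linkers[[1]]$pos[1, ] +
    c(0, 0, 2^(1 / 6) * 2.4)
  expect_equal(excluded_volume_energy(ch, p), -0.1 * 0.25, tolerance = 1e-12)
})

test_that("restraint energy is k (l - l0)^2 without a half prefactor", {
  sys <- build_fiber(2, nrl = 173)
  d <- sqrt(sum((sys$core_pos[1, ] - sys$core_pos[2, ])^2))
  s1 <- add_restraints(sys, "custom", pairs = cbind(1, 2), k = 40, l0 = d - 1)
  expect_equal(restraint_energy(s1), 40, tolerance = 1e-9)
  s2 <- add_restraints(sys, "custom", pairs = cbind(1, 2), k = 40, l0 = d + 1)
  expect_equal(restraint_energy(s2), restraint_energy(s1), tolerance = 1e-9)
  s3 <- add_restraints(sys, "custom", pairs = cbind(1, 2), k = 40, l0 = d)
  expect_equal(restraint_energy(s3), 0)
})

test_that("the energy breakdown sums exactly to the total", {
  sys <- build_fiber(5, nrl = 191, lh_density = 0.4,
                     acetyl_regions = list(c(1, 2)))
  et <- total_energy(sys, params)
  expect_equal(sum(et$terms), et$total, tolerance = 1e-12)
  expect_named(et$terms, c("stretch", "bend", "twist", "elec", "ev",
                           "restraint"))
})

test_that("total energy is invariant under rigid-body transforms", {
  sys <- build_fiber(6, nrl = 191, lh_density = 0.5)
  e0 <- total_energy(sys, params)$total
  sys2 <- transform_system(sys, random_rotation(11), shift = c(13, -7, 4))
  e1 <- total_energy(sys2, params)$total
  expect_equal(e1, e0, tolerance = 1e-8)
})

test_that("nonbonded kernel agrees with the naive all-pairs oracle", {
  sys <- build_fiber(5, nrl = 191, lh_density = 0.4,
                     acetyl_regions = list(c(1, 2)), seed = 3)
  # decorrelate from the regular start so the comparison is not trivial
  tr <- run_mc(sys, 400, stride = 400, seed = 9)
  sys <- snapshot_system(tr, n_snapshots(tr))
  ref <- naive_nonbonded(sys, params)
  expect_equal(electrostatic_energy(sys, params), ref$elec,
               tolerance = 1e-8)
  expect_equal(excluded_volume_energy(sys, params), ref$ev,
               tolerance = 1e-8)
})

test_that("folding every tail removes all tail nonbonded contributions", {
  sys <- build_fiber(3, nrl = 173)
  folded <- fold_all_tails(sys)
  # reference: same geometry with all tail charges zeroed and tail EV off
  stripped <- sys
  for (ci in 1:3)
    for (k in 1:10)
      stripped$tails[[ci]][[k]]$charges <- rep(0, length(stripped$tails[[ci]][[k]]$charges))
  e_folded <- electrostatic_energy(folded, params)
  e_stripped <- electrostatic_energy(stripped, params)
  expect_equal(e_folded, e_stripped, tolerance = 1e-10)
  # and excluded volume: folded tails are fully inert, equal to a naive sum
  # over the non-tail elements only
  p_ev <- energy_params(dna_bead_charge = 0)
  base <- build_fiber(3, nrl = 173)
  no_tail_ev <- excluded_volume_energy(fold_all_tails(base), p_ev)
  fl <- mesofiber:::flatten_elements(base, p_ev)
  ref <- naive_nonbonded_subset(base, p_ev, keep = fl$kind != 2L)
  expect_equal(no_tail_ev, ref$ev, tolerance = 1e-10)
})
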