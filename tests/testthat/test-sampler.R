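test_that("Metropolis rule accepts downhill always and uphill by Boltzmann", {
  set.seed(1)
  expect_true(all(replicate(50, metropolis_accept(-1, 0.582))))
  expect_false(any(replicate(50, metropolis_accept(Inf, 0.582))))
  expect_error(metropolis_accept(1, 0), "kBT")
  expect_error(metropolis_accept(NaN, 0.582), "NaN")
  # at delta_E = 2 kBT the long-run rate is exp(-2)
  set.seed(7)
  acc <- mean(vapply(1:20000, function(i) metropolis_accept(2 * 0.582, 0.582),
                     TRUE))
  expect_equal(acc, exp(-2), tolerance = 0.05)
})

test_that("move_set validates its inputs", {
  expect_s3_class(move_set(), "move_set")
  expect_error(move_set(pivot = -1), "weights")
  expect_error(move_set(pivot = 0, local = 0, regrowth = 0, lh = 0,
                        swap_fold = 0), "weights")
  expect_error(move_set(amp_trans = 0), "amplitudes")
})

test_that("trajectories are reproducible and snapshot counting is exact", {
  sys <- build_fiber(4, nrl = 173)
  t1 <- run_mc(sys, 1200, stride = 300, seed = 5)
  t2 <- run_mc(sys, 1200, stride = 300, seed = 5)
  expect_identical(length(t1$snapshots), as.integer(floor(1200 / 300)) + 1L)
  expect_identical(t1$snapshots, t2$snapshots)
  t3 <- run_mc(sys, 1200, stride = 300, seed = 6)
  expect_false(identical(t1$snapshots[[5]]$P, t3$snapshots[[5]]$P))
  # steps = 0: a single snapshot equal to the input state
  t0 <- run_mc(sys, 0, seed = 1)
  expect_identical(length(t0$snapshots), 1L)
  expect_equal(t0$snapshots[[1]]$core_pos, sys$core_pos)
})

test_that("incrementally tracked energy matches a from-scratch recomputation", {
  sys <- build_fiber(6, nrl = 191, lh_density = 0.5,
                     acetyl_regions = list(c(1, 3)))
  sys <- add_restraints(sys, "custom", pairs = cbind(1, 6), k = 10, l0 = 30)
  tr <- run_mc(sys, 2500, stride = 2500, seed = 11)
  expect_equal(tr$meta$energy_tracked, tr$meta$energy_recomputed,
               tolerance = 1e-6)
  expect_equal(unname(tr$meta$terms_tracked),
               unname(tr$meta$terms_recomputed), tolerance = 1e-6)
  # every move type was exercised
  expect_true(all(tr$meta$attempted > 0))
})

test_that("moves preserve chain connectivity and rigid-body geometry", {
  sys <- build_fiber(5, nrl = 191)
  tr <- run_mc(sys, 1500, stride = 1500, seed = 13)
  fin <- snapshot_system(tr, n_snapshots(tr))
  expect_silent(validate_fiber_system(fin))
  # DNA segments stay near l0 under the harmonic stretch (h = 100)
  for (li in seq_along(fin$linkers)) {
    l <- mesofiber:::seg_lengths(mesofiber:::linker_points(fin, li))
    expect_true(all(abs(l - 3) < 1))
  }
  # core charge clouds remain rigid: body-frame radii unchanged
  fl <- mesofiber:::flatten_elements(fin, energy_params())
  for (ci in c(1, 5)) {
    rows <- fl$idx$core[[ci]]
    d <- sqrt(rowSums((fl$P[rows, ] -
                       rep(fin$core_pos[ci, ], each = 300))^2))
    d0 <- sqrt(rowSums(fin$charge_sets[[fin$core_type[ci]]][, 1:3]^2))
    expect_equal(d, d0, tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("swap-fold toggles tail states only on acetylated cores", {
  sys <- build_fiber(4, nrl = 191, acetyl_regions = list(c(2, 3)))
  ms <- move_set(pivot = 0, local = 0, regrowth = 0, lh = 0, swap_fold = 1)
  tr <- run_mc(sys, 300, stride = 300, seed = 3, ms = ms)
  fin <- snapshot_system(tr, n_snapshots(tr))
  states <- vapply(seq_len(4), function(ci)
    any(vapply(fin$tails[[ci]], function(t) t$state == "folded", TRUE)), TRUE)
  expect_false(states[1])   # unflagged cores never fold
  expect_false(states[4])
  expect_true(any(states[2:3]))  # eligible tails do fold at this length
  expect_equal(tr$meta$energy_tracked, tr$meta$energy_recomputed,
               tolerance = 1e-6)
})

test_that("LH moves displace only CTD beads; globular beads stay on the core", {
  sys <- build_fiber(4, nrl = 191, lh_density = 1)
  ms <- move_set(pivot = 0, local = 0, regrowth = 0, lh = 1, swap_fold = 0)
  tr <- run_mc(sys, 300, stride = 300, seed = 3, ms = ms)
  fin <- snapshot_system(tr, n_snapshots(tr))
  for (j in seq_along(fin$lhs))
    expect_equal(fin$lhs[[j]]$glob_pos, sys$lhs[[j]]$glob_pos)
  expect_false(identical(fin$lhs[[1]]$ctd_pos, sys$lhs[[1]]$ctd_pos))
  # a system without LHs simply runs without the LH move
  bare <- build_fiber(4, nrl = 191)
  tr2 <- run_mc(bare, 200, stride = 200, seed = 3)
  expect_identical(unname(tr2$meta$attempted["lh"]), 0)
})

test_that("replicas cycle residual twists and propagate seeds", {
  sys <- build_fiber(3, nrl = 173)
  trs <- run_replicas(sys, 4, steps = 50, stride = 50)
  expect_equal(vapply(trs, function(t) t$meta$residual_twist, 0),
               c(0, -12, 12, 0))
  expect_equal(vapply(trs, function(t) t$meta$seed, 0), 1:4)
  expect_warning(run_replicas(sys, 2, steps = 10, seeds = c(3, 3)),
                 "duplicate")
})

test_that("a free chain under pure bending samples wormlike-chain statistics", {
  # harmonic dimer: mean bond length matches the analytic p(l) ~ l^2 exp(...)
  p <- energy_params(electrostatics = FALSE, k_ev = 0)
  dimer <- dna_chain_system(2)
  ms <- move_set(pivot = 0, local = 1, regrowth = 0, lh = 0, swap_fold = 0,
                 amp_trans = 0.3)
  tr <- run_mc(dimer, 20000, stride = 50, seed = 21, params = p, ms = ms)
  ls <- vapply(tr$snapshots[-(1:40)], function(sn)
    sqrt(sum((sn$P[1, ] - sn$P[2, ])^2)), 0)
  dens <- function(l) l^2 * exp(-p$h * (l - 3)^2 / (2 * p$kBT))
  norm <- integrate(dens, 0, 6)$value
  mean_ref <- integrate(function(l) l * dens(l) / norm, 0, 6)$value
  expect_equal(mean(ls), mean_ref, tolerance = 0.02)
})
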