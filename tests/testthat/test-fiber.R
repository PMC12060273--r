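test_that("builder produces the requested topology", {
  sys <- build_fiber(10, nrl = 173)
  expect_identical(sys$n_cores, 10L)
  expect_length(sys$linkers, 9)
  expect_true(all(vapply(sys$linkers, `[[`, 0L, "n_beads") == 2L))
  expect_silent(validate_fiber_system(sys))

  sys191 <- build_fiber(6, nrl = 191)
  expect_true(all(vapply(sys191$linkers, `[[`, 0L, "n_beads") == 4L))

  one <- build_fiber(1)
  expect_identical(one$n_cores, 1L)
  expect_length(one$linkers, 0)
  expect_silent(validate_fiber_system(one))

  expect_error(build_fiber(5, nrl = 165), "minimum representable linker")
  expect_error(build_fiber(5, linker_beads = c(2, 2, 1, 2)), ">= 2 beads")
})

test_that("the initial zigzag is relaxed: segments at l0, frames orthonormal", {
  sys <- build_fiber(8, nrl = 191)
  for (li in seq_along(sys$linkers)) {
    pts <- mesofiber:::linker_points(sys, li)
    expect_equal(unname(mesofiber:::seg_lengths(pts)),
                 rep(3, nrow(pts) - 1), tolerance = 1e-9)
  }
  for (f in sys$core_frame)
    expect_equal(crossprod(f), diag(3), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(stretching_energy(sys), 0, tolerance = 1e-12)
  expect_equal(bending_energy(sys), 0, tolerance = 1e-9)
})

test_that("an NFR deletes its core and merges the flanking linkers", {
  sys <- build_fiber(10, nrl = 191, nfr_positions = 5)
  expect_identical(sys$n_cores, 9L)
  expect_length(sys$linkers, 8)
  expect_identical(sys$nfr_linkers, 4L)
  # merged contour: 44.12 + 167 + 44.12 bp -> 29 segments -> 28 beads
  expect_identical(sys$linkers[[4]]$n_beads,
                   beads_for_length(2 * linker_length_bp(4) + 167))
  expect_identical(sys$linkers[[4]]$n_beads, 28L)
  expect_true(sys$linkers[[4]]$nfr)
  expect_silent(validate_fiber_system(sys))
  expect_error(build_fiber(10, nrl = 191, nfr_positions = 1), "interior")
  expect_error(build_fiber(10, nrl = 191, nfr_positions = c(4, 5)),
               "adjacent NFR")
})

test_that("composition patterns set core types exactly and reproducibly", {
  sys <- build_fiber(10, nrl = 173)
  expect_identical(sum(assign_composition(sys, "all_canonical")$core_type ==
                         "macroH2A1"), 0L)
  expect_identical(sum(assign_composition(sys, "all_macroH2A1")$core_type ==
                         "macroH2A1"), 10L)
  alt <- assign_composition(sys, "alternating")
  expect_identical(unique(alt$core_type[c(2, 4)]), "macroH2A1")
  expect_identical(unique(alt$core_type[c(1, 3)]), "canonical")
  f1 <- assign_composition(sys, "fraction", p = 0.5, seed = 42)
  f2 <- assign_composition(sys, "fraction", p = 0.5, seed = 42)
  expect_identical(sum(f1$core_type == "macroH2A1"), 5L)
  expect_identical(f1$core_type, f2$core_type)
  f3 <- assign_composition(sys, "fraction", p = 0.5, seed = 43)
  expect_false(identical(f1$core_type, f3$core_type))
  # tail charges follow the reassigned types
  expect_equal(f1$tails[[which(f1$core_type == "macroH2A1")[1]]][[1]]$charges,
               c(1, 3, 2, 1))
  expect_error(assign_composition(sys, "fraction", p = 1.5), "\\[0, 1\\]")
})

test_that("linker histone placement matches round(density * N)", {
  sys <- build_fiber(10, nrl = 173)
  expect_identical(sum(place_linker_histones(sys, 0)$lh_bound), 0L)
  expect_identical(sum(place_linker_histones(sys, 1)$lh_bound), 10L)
  s3 <- place_linker_histones(sys, 0.25, seed = 7)
  expect_identical(sum(s3$lh_bound), 2L)  # round(2.5) -> 2 (banker's rounding)
  expect_identical(place_linker_histones(sys, 0.25, seed = 7)$lh_bound,
                   s3$lh_bound)
  expect_length(s3$lhs, 2)
  expect_identical(nrow(s3$lhs[[1]]$glob_pos), 6L)
  expect_identical(nrow(s3$lhs[[1]]$ctd_pos), 22L)
  expect_silent(validate_fiber_system(s3))
  expect_error(place_linker_histones(sys, 1.2), "\\[0, 1\\]")
})

test_that("acetylation flags exactly the requested ranges", {
  sys <- build_fiber(10, nrl = 173)
  s <- mark_acetylation(sys, list(c(1, 3), c(8, 8)))
  expect_identical(which(s$acetylated), c(1L, 2L, 3L, 8L))
  expect_identical(sum(mark_acetylation(sys, list())$acetylated), 0L)
  expect_error(mark_acetylation(sys, list(c(5, 20))), "out of range")
})

test_that("restraint conditions add the documented loop sets", {
  sys <- build_fiber(10, nrl = 173)
  cust <- add_restraints(sys, "custom", pairs = cbind(1, 10), k = 40, l0 = 50)
  expect_identical(nrow(cust$restraints), 1L)
  expect_equal(restraint_energy(cust) >= 0, TRUE)
  # at l = l0 the restraint energy vanishes
  d <- sqrt(sum((cust$core_pos[1, ] - cust$core_pos[10, ])^2))
  cust$restraints$l0 <- d
  expect_equal(restraint_energy(cust), 0)
  h <- add_restraints(sys, "healthy")
  expect_identical(nrow(h$restraints), 4L)
  dz <- add_restraints(sys, "diseased")
  expect_identical(nrow(dz$restraints), 3L)
  expect_true(all(dz$restraints$k == 40) && all(dz$restraints$l0 == 50))
  expect_error(add_restraints(sys, "custom", pairs = cbind(1, 11)),
               "out of range")
  expect_error(add_restraints(sys, "custom", pairs = cbind(2, 2)), "distinct")
})

test_that("CAG expansion adds 12 beads (~35 repeats) and reverts exactly", {
  sys <- build_fiber(5, nrl = 173)
  ex <- expand_cag(sys)
  expect_identical(ex$linkers[[1]]$n_beads, 14L)
  expect_identical(ex$cag$repeats, 35L)
  expect_identical(ex$linkers[[2]]$n_beads, 2L)
  expect_silent(validate_fiber_system(ex))
  back <- revert_cag(ex)
  expect_identical(back$linkers[[1]]$n_beads, 2L)
  expect_null(back$cag)
})

test_that("the validator rejects corrupted systems", {
  sys <- build_fiber(4, nrl = 173)
  bad <- sys; bad$linkers[[2]] <- NULL
  expect_error(validate_fiber_system(bad), "linkers")
  bad <- sys; bad$core_frame[[1]] <- matrix(1, 3, 3)
  expect_error(validate_fiber_system(bad), "orthonormal")
  bad <- sys; bad$charge_sets$canonical <- bad$charge_sets$canonical[1:10, ]
  expect_error(validate_fiber_system(bad), "300")
  bad <- sys
  bad$restraints <- data.frame(core_i = 1L, core_j = 9L, k = 40, l0 = 50)
  expect_error(validate_fiber_system(bad), "out of range")
})
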