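test_that("benchmark fibers have the documented geometries", {
  short <- make_hd_like("short_nrl", n_cores = 30)
  expect_identical(short$n_cores, 30L)
  expect_true(all(vapply(short$linkers, `[[`, 0L, "n_beads") == 2L))
  med <- make_hd_like("medium_nrl", n_cores = 30)
  expect_true(all(vapply(med$linkers, `[[`, 0L, "n_beads") == 4L))
  nfr <- make_hd_like("medium_nrl_nfr", n_cores = 30)
  expect_identical(nfr$n_cores, 30L - as.integer(round(0.13 * 30)))
  expect_identical(length(nfr$nfr_linkers), as.integer(round(0.13 * 30)))
  expect_silent(validate_fiber_system(nfr))
})

test_that("fifty-fifty composition is half variant and reproducible", {
  a <- make_hd_like("short_nrl", "fifty_fifty", n_cores = 30, seed = 5)
  b <- make_hd_like("short_nrl", "fifty_fifty", n_cores = 30, seed = 5)
  expect_identical(sum(a$core_type == "macroH2A1"), 15L)
  expect_identical(a$core_type, b$core_type)
  hyb <- make_hd_like("medium_nrl", "hybrid", n_cores = 10)
  expect_true(all(hyb$core_type == "hybrid"))
})

test_that("synthetic position tracks have the requested statistics", {
  # deterministic spacing when sd = 0 and no NFRs
  t0 <- sample_positions(10, mean_nrl = 191, sd = 0, nfr_rate = 0, seed = 1)
  expect_equal(unique(diff(t0$dyad)), 191)
  expect_identical(nrow(t0), 10L)
  expect_true(all(t0$end - t0$start == 147))
  # same seed, same track
  expect_identical(sample_positions(50, seed = 9), sample_positions(50, seed = 9))
  # span of a long track ~ (n - 1) * mean NRL
  tl <- sample_positions(688, mean_nrl = 191, sd = 15, seed = 2)
  expect_equal(diff(range(tl$dyad)), 687 * 191, tolerance = 0.05)
  # tracks pass the overlap filter unchanged
  expect_equal(filter_positions(tl$dyad), tl$dyad)
  # NFR gaps appear at roughly the requested rate
  tn <- sample_positions(400, mean_nrl = 191, sd = 5, nfr_rate = 0.2, seed = 3)
  expect_equal(mean(diff(tn$dyad) > 300), 0.2, tolerance = 0.3)
  expect_error(sample_positions(5, mean_nrl = 150), "mean_nrl")
})

test_that("track spacings survive bead discretization within half a segment", {
  trk <- sample_positions(40, mean_nrl = 191, sd = 12, seed = 7)
  linker_bp <- diff(trk$dyad) - 147
  rebuilt <- linker_length_bp(beads_for_length(linker_bp))
  expect_true(all(abs(rebuilt - linker_bp) <= 8.8235 / 2 + 1e-9))
})

test_that("gene models encode the two epigenetic conditions", {
  h <- make_htt_like("healthy", n_cores = 60, seed = 4)
  d <- make_htt_like("diseased", n_cores = 60, seed = 4)
  n <- h$n_cores
  expect_identical(d$n_cores, n)
  expect_true(all(h$core_type == "canonical"))
  expect_true(all(d$core_type == "macroH2A1"))
  expect_identical(sum(h$lh_bound), as.integer(round(0.5 * n)))
  expect_identical(sum(d$lh_bound), as.integer(round(0.07 * n)))
  expect_gt(sum(h$acetylated), 0)
  expect_identical(sum(d$acetylated), 0L)
  expect_identical(nrow(h$restraints), 4L)
  expect_identical(nrow(d$restraints), 3L)
  expect_null(h$cag)
  expect_identical(d$cag$extra_beads, 12L)
  # the two conditions differ only in the stated attributes: same linker
  # lengths except the CAG-expanded first linker
  bh <- vapply(h$linkers, `[[`, 0L, "n_beads")
  bd <- vapply(d$linkers, `[[`, 0L, "n_beads")
  expect_identical(bd[1], bh[1] + 12L)
  expect_identical(bd[-1], bh[-1])
  expect_identical(h$nfr_linkers, d$nfr_linkers)
  expect_silent(validate_fiber_system(h))
  expect_silent(validate_fiber_system(d))
  expect_error(make_htt_like("healthy", positions = c(1000)), ">= 2")
})

test_that("a supplied dyad track drives the gene model geometry", {
  trk <- sample_positions(30, mean_nrl = 200, sd = 0, seed = 1)
  h <- make_htt_like("healthy", positions = trk)
  expect_identical(h$n_cores, 30L)
  # 200 - 147 = 53 bp linkers -> 5 beads everywhere
  expect_true(all(vapply(h$linkers, `[[`, 0L, "n_beads") ==
                    beads_for_length(53)))
})

test_that("recipes rebuild identical systems through the YAML round trip", {
  rec <- system_recipe("demo", n_cores = 8, nrl = 191,
                       composition = "alternating", lh_density = 0.25,
                       acetyl_regions = list(c(1, 2)), restraints = "none",
                       seed = 3)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_recipe(rec, f)
  rec2 <- read_recipe(f)
  s1 <- build_from_recipe(rec)
  s2 <- build_from_recipe(rec2)
  expect_identical(s1$core_type, s2$core_type)
  expect_identical(s1$lh_bound, s2$lh_bound)
  expect_equal(s1$core_pos, s2$core_pos)
})

test_that("every generated system passes the validator", {
  for (w in c("short_nrl", "medium_nrl", "medium_nrl_nfr"))
    expect_silent(validate_fiber_system(make_hd_like(w, n_cores = 15)))
  expect_silent(validate_fiber_system(make_htt_like("diseased", n_cores = 25)))
})
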