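straight_cores <- function(n, spacing) cbind(0, 0, (seq_len(n) - 1) * spacing)

test_that("fiber axis length behaves for straight and curved fibers", {
  pos <- straight_cores(6, 10)
  ax <- fiber_axis(pos)
  expect_equal(ax$Fl, 50, tolerance = 0.01 * 50)
  # arc length of the axis is at least its own chord
  chord <- sqrt(sum((ax$points[1, ] - ax$points[nrow(ax$points), ])^2))
  expect_gte(ax$Fl, chord - 1e-9)
  expect_error(fiber_axis(pos[1:3, ]), ">= 4")
  # heavy smoothing of a noisy arc degenerates toward the chord
  set.seed(4)
  t <- seq(0, pi, length.out = 12)
  arc <- cbind(30 * cos(t), 30 * sin(t), 0) + matrix(rnorm(36, 0, 0.5), 12)
  ax_tight <- fiber_axis(arc, smoothing = "none")
  ax_smooth <- fiber_axis(arc, smoothing = 1.5)
  expect_lt(ax_smooth$Fl, ax_tight$Fl)
})

test_that("packing ratio is nucleosomes per 11 nm of axis", {
  expect_equal(packing_ratio(straight_cores(5, 13.75)), 1, tolerance = 0.02)
  expect_equal(packing_ratio(straight_cores(6, 2.2)), 6, tolerance = 0.1)
  # halving the axis length doubles the ratio
  expect_equal(packing_ratio(straight_cores(5, 6.875)) /
                 packing_ratio(straight_cores(5, 13.75)), 2, tolerance = 0.03)
})

test_that("sedimentation interpolates the mononucleosome limits and sums pairs", {
  expect_equal(sedimentation(matrix(0, 1, 3), rho = 0), 11.1)
  expect_equal(sedimentation(matrix(0, 1, 3), rho = 1), 12)
  expect_equal(sedimentation(matrix(0, 1, 3), rho = 0.5), 11.55)
  # two cores at 11 nm, rho = 0: 11.1 * (1 + (5.5/2) * (2/11)) = 16.65
  two <- rbind(c(0, 0, 0), c(0, 0, 11))
  expect_equal(sedimentation(two, rho = 0), 16.65, tolerance = 1e-10)
  # ordered-pair oracle on random coordinates
  set.seed(2)
  pos <- matrix(rnorm(24, sd = 20), 8)
  dm <- as.matrix(dist(pos))
  s_ref <- 11.1 * (1 + (5.5 / 8) * sum(1 / dm[row(dm) != col(dm)]))
  expect_equal(sedimentation(pos, rho = 0), s_ref, tolerance = 1e-10)
  expect_error(sedimentation(rbind(c(0, 0, 0), c(0, 0, 0)), rho = 0),
               "coincident")
})

test_that("radius of gyration matches its definition", {
  expect_equal(radius_of_gyration(matrix(1, 1, 3)), 0)
  expect_equal(radius_of_gyration(rbind(c(0, 0, 0), c(0, 0, 8))), 4)
  set.seed(5)
  pos <- matrix(rnorm(30, sd = 15), 10)
  ctr <- colMeans(pos)
  ref <- sqrt(mean(rowSums((pos - rep(ctr, each = 10))^2)))
  expect_equal(radius_of_gyration(pos), ref, tolerance = 1e-12)
})

test_that("end-to-end distance is the first-last core separation", {
  expect_equal(end_to_end(rbind(c(0, 0, 0), c(0, 10, 0))), 10)
  set.seed(6)
  pos <- matrix(rnorm(18, sd = 10), 6)
  R <- random_rotation(3)
  expect_equal(end_to_end(pos %*% t(R) + 5), end_to_end(pos),
               tolerance = 1e-10)
  expect_error(end_to_end(matrix(0, 1, 3)), ">= 2")
})

test_that("contact matrix matches the brute-force element-pair oracle", {
  sys <- build_fiber(5, nrl = 173, lh_density = 0.4, seed = 2)
  tr <- run_mc(sys, 600, stride = 600, seed = 8)
  fin <- snapshot_system(tr, n_snapshots(tr))
  cm <- contact_matrix(fin)
  expect_equal(unclass(cm), naive_contact_matrix(fin), ignore_attr = TRUE)
  expect_true(isSymmetric(unclass(cm)))
  expect_true(all(cm >= 0 & cm <= 1))
  expect_true(all(diag(cm) == 1))
  # single snapshots give frequencies exactly in {0, 1}
  expect_true(all(cm %in% c(0, 1)))
  # well-separated cores never contact
  far <- build_fiber(2, linker_beads = 30)
  cmf <- contact_matrix(far)
  expect_identical(cmf[1, 2], 0)
})

test_that("contact decomposition sums the k-th diagonal", {
  m <- diag(6)
  for (i in 1:4) m[i, i + 2] <- m[i + 2, i] <- 1
  cm <- structure(m, class = c("contact_matrix", "matrix"))
  prof <- contact_decomposition(cm)
  expect_equal(prof$value[2], 4 / 6)       # (N - k) ones over N
  expect_equal(prof$value[1], 0)
  # identity matrix decomposes to zero everywhere
  prof0 <- contact_decomposition(diag(5))
  expect_true(all(prof0$value == 0))
  # rearrangement: sum_k profile(k) * N equals total upper-tri contacts
  set.seed(3)
  mm <- matrix(runif(49), 7); mm <- (mm + t(mm)) / 2
  expect_equal(sum(contact_decomposition(mm)$value) * 7,
               sum(mm[upper.tri(mm)]))
  expect_equal(sum(contact_decomposition(mm, "pairs")$value *
                     (7 - seq_len(6))), sum(mm[upper.tri(mm)]))
  expect_error(contact_decomposition(matrix(runif(9), 3)), "symmetric")
})

test_that("local geometry reports distances, triplet angles and plane twist", {
  pos <- straight_cores(4, 7)
  lg <- local_geometry(pos)
  expect_equal(lg$distance, rep(7, 3))
  expect_equal(lg$angle, rep(180, 2))
  sys <- build_fiber(3, nrl = 173)
  id <- diag(3)
  sys$core_frame <- list(id, id, mesofiber:::rot_about(c(1, 0, 0), pi))
  lg2 <- local_geometry(sys)
  expect_equal(lg2$twist, c(0, 180), tolerance = 1e-10)
})

test_that("clutch analysis agrees with the exhaustive DBSCAN oracle", {
  # 3 mutually close cores form one clutch of 3
  tri <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0))
  cl <- clutch_analysis(tri)
  expect_equal(cl$n_clutches, 1)
  expect_equal(cl$mean_size, 3)
  # 2 isolated cores: below min_pts, no clutch
  cl2 <- clutch_analysis(tri[1:2, ])
  expect_equal(cl2$n_clutches, 0)
  expect_true(is.na(cl2$mean_size))
  # two well-separated triplets
  two_tri <- rbind(tri, tri + 500)
  cl3 <- clutch_analysis(two_tri)
  expect_equal(cl3$n_clutches, 2)
  expect_equal(cl3$mean_size, 3)
  # randomized configurations against the oracle
  for (s in 1:6) {
    set.seed(s)
    pos <- matrix(runif(3 * 15, 0, 120), 15)
    got <- clutch_analysis(pos)
    ref <- naive_dbscan(pos)
    expect_equal(got$n_clutches, ref$n_clutches)
    expect_equal(got$mean_size, ref$mean_size)
  }
})

test_that("persistence length handles straight axes and curved references", {
  ax <- fiber_axis(straight_cores(10, 10), smoothing = "none")
  lp <- persistence_length(ax)
  expect_identical(attr(lp, "flag"), "straight")
  expect_equal(as.numeric(lp), 1e6)
  # circle arcs: tangent correlation cos(ds/R); tighter curvature gives a
  # smaller fitted Lp
  arc_axis <- function(R) {
    t <- seq(0, pi * 0.9, length.out = 40)
    fiber_axis(cbind(R * cos(t), R * sin(t), 0), smoothing = "none")
  }
  lp_60 <- as.numeric(persistence_length(arc_axis(60)))
  lp_25 <- as.numeric(persistence_length(arc_axis(25)))
  expect_true(is.finite(lp_60) && is.finite(lp_25))
  expect_lt(lp_25, lp_60)
})

test_that("tail interaction frequencies are a normalized partition", {
  sys <- build_fiber(4, nrl = 173, seed = 2)
  tr <- run_mc(sys, 500, stride = 250, seed = 4)
  tp <- tail_interaction_profile(tr)
  cats <- c("parental", "nonparental_core", "nonparental_dna", "other_tails",
            "free")
  expect_true(all(abs(rowSums(tp[, cats]) - 1) < 1e-12))
  expect_setequal(unique(tp$tail_type),
                  c("H2A_N", "H2A_C", "H2B_N", "H3_N", "H4_N"))
  # isolated mononucleosome: no nonparental categories
  mono <- build_fiber(1)
  tpm <- tail_interaction_profile(mono)
  expect_true(all(tpm$nonparental_core == 0 & tpm$nonparental_dna == 0))
  # every tail folded -> free by convention
  tpf <- tail_interaction_profile(fold_all_tails(mono))
  expect_true(all(tpf$free == 1))
  # canonical / macroH2A1 ratio table with zero denominators flagged NaN
  mixed <- assign_composition(build_fiber(4, nrl = 173), "alternating")
  tpx <- tail_interaction_profile(mixed)
  rat <- tail_interaction_ratio(tpx)
  expect_true(nrow(rat) >= 1)
  expect_true(all(is.nan(unlist(rat[, -1])) | unlist(rat[, -1]) >= 0))
})

test_that("epigenetic contact classes partition the total contact weight", {
  sys <- build_fiber(6, nrl = 173)
  cm <- matrix(0.5, 6, 6); diag(cm) <- 1
  cls <- epigenetic_contact_classes(cm, sys)
  expect_equal(unname(cls["WT/WT"]), sum(cm[upper.tri(cm)]))
  expect_true(all(cls[names(cls) != "WT/WT"] == 0))
  sys2 <- mark_acetylation(sys, list(c(1, 2)))
  sys2 <- place_linker_histones(sys2, 0.5, seed = 3)
  cls2 <- epigenetic_contact_classes(cm, sys2)
  expect_equal(sum(cls2), sum(cm[upper.tri(cm)]))
  expect_gt(cls2["Ac/Ac"], 0)
  # precedence: an acetylated AND LH-bound core counts as acetylated
  sys3 <- place_linker_histones(build_fiber(2, nrl = 173), 1)
  sys3 <- mark_acetylation(sys3, list(c(1, 2)))
  cm2 <- matrix(c(1, 1, 1, 1), 2)
  expect_equal(unname(epigenetic_contact_classes(cm2, sys3)["Ac/Ac"]), 1)
})

test_that("convergence diagnostics produce flat running means for constant input", {
  sys <- build_fiber(5, nrl = 173)
  tr0 <- run_mc(sys, 0, seed = 1)
  tr0$snapshots <- rep(tr0$snapshots, 5)   # constant pseudo-trajectory
  cd <- convergence_diagnostics(list(tr0, tr0))
  s1 <- cd$series[[1]]
  for (m in unique(s1$metric)) {
    rm_ <- s1$running_mean[s1$metric == m]
    expect_true(all(abs(rm_ - rm_[1]) < 1e-12))
  }
  expect_identical(cd$series[[1]], cd$series[[2]])
  expect_false(cd$overlap_flag)
  # the final running mean equals the plain mean of the series
  tr <- run_mc(sys, 600, stride = 200, seed = 2)
  cd2 <- convergence_diagnostics(tr)
  s <- cd2$series[[1]]
  for (m in unique(s$metric)) {
    v <- s$value[s$metric == m]
    expect_equal(tail(s$running_mean[s$metric == m], 1), mean(v))
  }
})

test_that("ensemble metrics are invariant under rigid motion of all snapshots", {
  sys <- build_fiber(6, nrl = 191, seed = 3)
  tr <- run_mc(sys, 400, stride = 200, seed = 5)
  fin <- snapshot_system(tr, 3)
  R <- random_rotation(8)
  moved <- transform_system(fin, R, shift = c(5, 5, 5))
  expect_equal(radius_of_gyration(moved), radius_of_gyration(fin))
  expect_equal(packing_ratio(moved$core_pos), packing_ratio(fin$core_pos),
               tolerance = 1e-6)
  expect_equal(sedimentation(moved), sedimentation(fin))
  expect_equal(unclass(contact_matrix(moved)), unclass(contact_matrix(fin)),
               ignore_attr = TRUE)
  expect_equal(clutch_analysis(moved$core_pos)[1:2],
               clutch_analysis(fin$core_pos)[1:2])
})

test_that("metric_report assembles the ensemble summary", {
  sys <- build_fiber(6, nrl = 173, lh_density = 0.5, seed = 2)
  tr <- run_mc(sys, 400, stride = 200, seed = 6)
  mr <- metric_report(tr)
  expect_s3_class(mr, "metric_report")
  expect_identical(mr$n_cores, 6L)
  expect_identical(mr$n_frames, 3L)
  expect_true(all(is.finite(c(mr$packing_ratio, mr$sedimentation,
                              mr$radius_of_gyration, mr$end_to_end))))
  expect_s3_class(mr$contact_matrix, "contact_matrix")
  expect_output(print(mr), "packing ratio")
})
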