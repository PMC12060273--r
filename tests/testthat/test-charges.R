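test_that("H2A tail charge edits follow the variant substitution", {
  can <- apply_tail_charges("canonical")
  mac <- apply_tail_charges("macroH2A1")
  expect_equal(can$H2A_N.1, c(3, 1, 3, 2))
  expect_equal(can$H2A_C.1, c(1, 0, 2))
  expect_equal(mac$H2A_N.1, c(1, 3, 2, 1))
  expect_equal(mac$H2A_C.1, c(0, 0, 3))
  expect_equal(mac$H2A_N.2, mac$H2A_N.1)
  # the C-tail edit conserves the summed charge, the N-tail edit loses 2 e
  expect_equal(sum(mac$H2A_C.1) - sum(can$H2A_C.1), 0)
  expect_equal(sum(mac$H2A_N.1) - sum(can$H2A_N.1), -2)
  expect_error(apply_tail_charges("H2A.Z"), "unknown core type")
})

test_that("hybrid cores carry one canonical and one variant H2A copy", {
  hyb <- apply_tail_charges("hybrid")
  copies <- list(hyb$H2A_N.1, hyb$H2A_N.2)
  expect_true(any(vapply(copies, identical, TRUE, c(3, 1, 3, 2))))
  expect_true(any(vapply(copies, identical, TRUE, c(1, 3, 2, 1))))
  expect_false(identical(hyb$H2A_N.1, hyb$H2A_N.2))
  expect_false(identical(hyb$H2A_C.1, hyb$H2A_C.2))
  # non-H2A tails are unchanged by the variant
  expect_equal(hyb$H3_N.1, apply_tail_charges("canonical")$H3_N.1)
})

test_that("tail profile overrides replace the default charge vectors", {
  prof <- apply_tail_charges("canonical", profile = list(H3_N = rep(1, 8)))
  expect_equal(prof$H3_N.1, rep(1, 8))
  expect_equal(prof$H3_N.2, rep(1, 8))
  expect_equal(prof$H2A_N.1, c(3, 1, 3, 2))
})

test_that("synthetic core charge sets have 300 sites and the requested net charge", {
  for (ty in c("canonical", "macroH2A1", "hybrid")) {
    cs <- synthetic_core_charges(ty)
    expect_identical(nrow(cs), 300L)
    expect_equal(sum(cs[, "q"]), -150)
    # sites lie on the nucleosome cylinder surface
    r <- sqrt(cs[, "x"]^2 + cs[, "y"]^2)
    on_side <- abs(r - 5.5) < 1e-6
    on_cap <- abs(abs(cs[, "z"]) - 2.75) < 1e-6
    expect_true(all(on_side | on_cap))
  }
  # deterministic: two calls agree exactly
  expect_identical(synthetic_core_charges("canonical"),
                   synthetic_core_charges("canonical"))
  # patch perturbation conserves total charge
  cs2 <- synthetic_core_charges("macroH2A1", patch_delta = 5)
  expect_equal(sum(cs2[, "q"]), -150)
  expect_false(all(cs2[, "q"] == synthetic_core_charges("macroH2A1")[, "q"]))
})

test_that("charge profiles round-trip through the text format", {
  cs <- synthetic_core_charges("canonical")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_charge_profile(cs, "core-canonical", f)
  back <- read_charge_profile(f)
  expect_equal(unname(back[, c("x", "y", "z", "q")]),
               unname(cs[, c("x", "y", "z", "q")]))
  expect_identical(attr(back, "charge_set_id"), "core-canonical")
})
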