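# Synthetic input generation: ready-made fiber recipes and synthetic
# nucleosome-position tracks, so the whole pipeline runs without external
# data.

#' Ready-made benchmark fibers
#'
#' The three reference fiber geometries: `short_nrl` (100 cores, NRL 173 bp,
#' 2-bead linkers), `medium_nrl` (100 cores, NRL 191 bp, 4-bead linkers),
#' and `medium_nrl_nfr` (nominal 100 positions at NRL 191 bp of which 13
#' evenly spaced ones are nucleosome-free regions of 167 bp, leaving 87
#' cores). Composition is all-canonical, all-macroH2A1, all-hybrid,
#' alternating, or a random 50/50 mixture.
#'
#' @param which "short_nrl", "medium_nrl" or "medium_nrl_nfr".
#' @param composition "canonical", "macroH2A1", "hybrid", "alternating" or
#'   "fifty_fifty".
#' @param n_cores nominal number of nucleosome positions (default 100; the
#'   NFR variant deletes `round(0.13 * n_cores)` of them).
#' @param seed seed for the 50/50 mixture placement.
#' @return a `fiber_system`.
#' @export
make_hd_like <- function(which = c("short_nrl", "medium_nrl", "medium_nrl_nfr"),
                         composition = c("canonical", "macroH2A1", "hybrid",
                                         "alternating", "fifty_fifty"),
                         n_cores = 100, seed = 1L) {
  which <- match.arg(which)
  composition <- match.arg(composition)
  pattern <- switch(composition, canonical = "all_canonical",
                    macroH2A1 = "all_macroH2A1", hybrid = "all_hybrid",
                    alternating = "alternating", fifty_fifty = "fifty_fifty")
  nrl <- if (which == "short_nrl") 173 else 191
  nfr <- integer(0)
  if (which == "medium_nrl_nfr") {
    n_nfr <- round(0.13 * n_cores)
    nfr <- unique(pmax(2L, pmin(n_cores - 1L, as.integer(
      round(seq(2, n_cores - 1, length.out = n_nfr))))))
  }
  build_fiber(n_cores = n_cores, nrl = nrl, core_pattern = pattern,
              nfr_positions = nfr, seed = seed)
}

#' Synthetic nucleosome dyad track
#'
#' Emulates an MNase-derived nucleosome position track: dyad spacings drawn
#' from a normal distribution truncated from below at 165 bp (147 bp
#' footprint + the shortest representable linker), with nucleosome-free
#' regions inserted as additional +167 bp gaps at the given per-position
#' rate. The output passes [filter_positions()] unchanged.
#'
#' @param n number of nucleosomes.
#' @param mean_nrl mean dyad spacing, bp (>= 160).
#' @param sd spacing standard deviation, bp.
#' @param nfr_rate probability of an NFR gap after each position.
#' @param seed RNG seed.
#' @param start coordinate of the first dyad, bp.
#' @return data.frame with columns `chrom`, `start`, `end`, `dyad`
#'   (0-based half-open footprint intervals plus the dyad midpoint).
#' @export
sample_positions <- function(n, mean_nrl = 191, sd = 15, nfr_rate = 0,
                             seed = 1L, start = 1000) {
  stopifnot(n >= 1, mean_nrl >= 160, sd >= 0, nfr_rate >= 0, nfr_rate <= 1)
  min_spacing <- .mf$nuc_bp + 18
  dyads <- withr_seed(seed, {
    gaps <- if (n > 1) {
      g <- stats::rnorm(n - 1, mean_nrl, sd)
      g <- pmax(g, min_spacing)
      g + 167 * (stats::runif(n - 1) < nfr_rate)
    } else numeric(0)
    start + c(0, cumsum(gaps))
  })
  dyads <- round(dyads)
  # 147 bp footprint centered on the dyad, 0-based half-open
  data.frame(chrom = "synthetic", start = as.integer(dyads - 73),
             end = as.integer(dyads + 74), dyad = dyads)
}

# turn a dyad vector into per-linker bead counts and NFR flags
linkers_from_dyads <- function(dyads, nfr_threshold = 167) {
  spacing <- diff(dyads)
  linker_bp <- spacing - .mf$nuc_bp
  list(beads = beads_for_length(pmax(linker_bp, 1)),
       nfr = which(linker_bp >= nfr_threshold))
}

#' Healthy- and diseased-state gene fiber models
#'
#' Builds the two epigenetic states of a large gene fiber. The healthy
#' state has all-canonical cores, linker histone density 0.5, two
#' acetylation islands (cores 1-7 and 629-659 at the reference size of 688
#' cores; rescaled proportionally otherwise) and 4 harmonic loop
#' restraints. The diseased state has all-macroH2A1 cores, LH density 0.07
#' (a 7-fold reduction), no acetylation, a CAG-repeat expansion of the
#' first linker (+106 bp), and 3 loop restraints.
#'
#' Nucleosome positions come from a dyad track (e.g. [read_bed_track()] or
#' [sample_positions()]); by default a synthetic track of `n_cores`
#' positions at mean spacing 191 bp is generated.
#'
#' @param condition "healthy" or "diseased".
#' @param positions optional dyad coordinate vector or the data.frame
#'   produced by [sample_positions()].
#' @param n_cores number of nucleosomes for the default synthetic track.
#' @param seed RNG seed (track generation and LH placement).
#' @return a `fiber_system`.
#' @export
make_htt_like <- function(condition = c("healthy", "diseased"),
                          positions = NULL, n_cores = 688, seed = 1L) {
  condition <- match.arg(condition)
  if (is.null(positions))
    positions <- sample_positions(n_cores, mean_nrl = 191, sd = 15,
                                  nfr_rate = 0.01, seed = seed)
  dyads <- if (is.data.frame(positions)) positions$dyad else positions
  dyads <- filter_positions(sort(dyads))
  n <- length(dyads)
  if (n < 2) stop("positions must yield >= 2 nucleosomes", call. = FALSE)
  lk <- linkers_from_dyads(dyads)
  sys <- build_fiber(n_cores = n, linker_beads = lk$beads, seed = seed)
  for (li in lk$nfr) sys$linkers[[li]]$nfr <- TRUE
  sys$nfr_linkers <- lk$nfr
  scale_idx <- function(i) pmax(1L, pmin(n, as.integer(round(i * n / 688))))
  if (condition == "healthy") {
    sys <- assign_composition(sys, "all_canonical")
    sys <- place_linker_histones(sys, 0.5, seed = seed)
    regions <- list(c(scale_idx(1), scale_idx(7)),
                    c(scale_idx(629), scale_idx(659)))
    sys <- mark_acetylation(sys, regions)
    sys <- add_restraints(sys, "healthy", reference_n = 688)
  } else {
    sys <- assign_composition(sys, "all_macroH2A1")
    sys <- place_linker_histones(sys, 0.07, seed = seed)
    sys <- add_restraints(sys, "diseased", reference_n = 688)
    sys <- expand_cag(sys)
  }
  sys
}

#' System recipe: a declarative fiber specification
#'
#' A `system_recipe` captures everything needed to rebuild a fiber:
#' core count, linker bead counts or NRL, composition, NFR positions, LH
#' density, acetylation regions, restraint condition and CAG flag. Recipes
#' round-trip through YAML ([write_recipe()] / [read_recipe()]) and are
#' realized with [build_from_recipe()].
#'
#' @param name recipe name.
#' @param n_cores,nrl,linker_beads,composition,nfr_positions,lh_density,acetyl_regions,restraints,cag_expansion,seed
#'   fields as in [build_fiber()] and the decoration functions.
#' @return an object of class `system_recipe`.
#' @export
system_recipe <- function(name, n_cores, nrl = NULL, linker_beads = NULL,
                          composition = "all_canonical",
                          nfr_positions = integer(0), lh_density = 0,
                          acetyl_regions = list(), restraints = "none",
                          cag_expansion = FALSE, seed = 1L) {
  structure(list(name = name, n_cores = n_cores, nrl = nrl,
                 linker_beads = linker_beads, composition = composition,
                 nfr_positions = nfr_positions, lh_density = lh_density,
                 acetyl_regions = acetyl_regions, restraints = restraints,
                 cag_expansion = cag_expansion, seed = seed),
            class = "system_recipe")
}

#' @rdname system_recipe
#' @param recipe a `system_recipe`.
#' @export
build_from_recipe <- function(recipe) {
  stopifnot(inherits(recipe, "system_recipe"))
  sys <- build_fiber(n_cores = recipe$n_cores, nrl = recipe$nrl,
                     linker_beads = recipe$linker_beads,
                     core_pattern = recipe$composition,
                     nfr_positions = recipe$nfr_positions,
                     acetyl_regions = recipe$acetyl_regions,
                     lh_density = recipe$lh_density, seed = recipe$seed)
  if (!identical(recipe$restraints, "none"))
    sys <- add_restraints(sys, recipe$restraints)
  if (isTRUE(recipe$cag_expansion)) sys <- expand_cag(sys)
  sys
}
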