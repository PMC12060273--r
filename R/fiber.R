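# Fiber construction: cores, linker DNA, tails, linker histones, and the
# deterministic rules that turn a specification into an initial structure.

rot_about <- function(axis, theta) {
  a <- axis / sqrt(sum(axis^2))
  c <- cos(theta); s <- sin(theta); C <- 1 - c
  x <- a[1]; y <- a[2]; z <- a[3]
  matrix(c(x * x * C + c, x * y * C + z * s, x * z * C - y * s,
           y * x * C - z * s, y * y * C + c, y * z * C + x * s,
           z * x * C + y * s, z * y * C - x * s, z * z * C + c),
         3, 3)
}

normalize <- function(v) v / sqrt(sum(v^2))

# DNA entry/exit attachment sites in the core body frame. The two sites sit
# on the disk edge separated by the wedge opening angle, offset above/below
# the midplane by the gyre half-separation.
att_entry_local <- function() {
  a <- .mf$att_angle
  c(.mf$att_radius * cos(a), -.mf$att_radius * sin(a), -.mf$att_height)
}
att_exit_local <- function() {
  a <- .mf$att_angle
  c(.mf$att_radius * cos(a), .mf$att_radius * sin(a), .mf$att_height)
}

# Tail attachment sites (body frame): ten sites around the disk edge,
# alternating above/below the midplane.
tail_attach_local <- function() {
  k <- seq_len(10)
  psi <- (2 * pi * k / 10) + pi / 5
  r <- .mf$core_radius
  cbind(r * cos(psi), r * sin(psi), rep(c(1.5, -1.5), 5))
}

# world position of body-frame points
body_to_world <- function(center, frame, local) {
  if (is.null(dim(local))) local <- matrix(local, ncol = 3)
  t(frame %*% t(local)) + rep(center, each = nrow(local))
}

new_tail <- function(id, charges, attach_local) {
  n <- length(charges)
  # initial tails splay toward the disk faces (out of the fiber plane) so
  # the starting structure is free of clashes with neighboring cores
  u_xy <- normalize(c(attach_local[1], attach_local[2], 0))
  rad <- normalize(0.4 * u_xy + c(0, 0, sign(attach_local[3])))
  wt <- t(vapply(seq_len(n), function(j) attach_local + j * .mf$tail_l0 * rad,
                 numeric(3)))
  folded <- t(vapply(seq_len(n), function(j)
    attach_local + 0.6 * j * .mf$tail_l0 * rad, numeric(3)))
  list(id = id, charges = charges, state = "wildtype",
       wt_local = wt, folded_local = folded,
       pos = NULL, alt_pos = NULL, attach_local = attach_local)
}

# Fresh world coordinates for a core's tails from its body-frame templates.
reset_tail_coords <- function(tail, center, frame) {
  tail$pos <- body_to_world(center, frame, tail$wt_local)
  tail$alt_pos <- body_to_world(center, frame, tail$folded_local)
  tail$state <- "wildtype"
  tail
}

core_tails <- function(core_type, center, frame, profile = NULL) {
  charges <- apply_tail_charges(core_type, profile)
  att <- tail_attach_local()
  tails <- vector("list", 10)
  for (k in seq_len(10)) {
    tl <- new_tail(tail_ids()[k], charges[[k]], att[k, ])
    tails[[k]] <- reset_tail_coords(tl, center, frame)
  }
  tails
}

#' Build a chromatin fiber in an initial regular zigzag geometry
#'
#' Constructs a [fiber_system]: rigid nucleosome cores joined by linker DNA
#' bead chains, with histone tails attached and charge sets resolved per core
#' type. Linker lengths come either from a nucleosome repeat length (`nrl`,
#' applied uniformly: linker bp = NRL - 147, discretized with
#' [beads_for_length()]) or from an explicit per-linker bead count vector.
#' A nucleosome-free region deletes the core at the given position and merges
#' its two flanking linkers plus `nfr_bp` of extra DNA into one long linker.
#'
#' @param n_cores number of nucleosome positions before NFR deletion.
#' @param nrl nucleosome repeat length in bp (>= 147 + 26.47).
#' @param linker_beads alternative to `nrl`: integer vector of per-linker bead
#'   counts (length `n_cores - 1`), or a single value recycled.
#' @param core_pattern composition pattern passed to [assign_composition()]
#'   ("all_canonical" by default).
#' @param nfr_positions integer vector of core positions (1-based, before
#'   deletion) replaced by nucleosome-free regions.
#' @param nfr_bp NFR length in bp (default 167).
#' @param acetyl_regions list of 2-vectors `c(from, to)` of core index ranges
#'   to acetylate (after NFR deletion), passed to [mark_acetylation()].
#' @param lh_density linker histone density (LH per nucleosome) applied with
#'   [place_linker_histones()].
#' @param seed seed used for stochastic decorations (composition fraction,
#'   LH placement).
#' @param temperature,salt environmental conditions (K, mol/L monovalent).
#' @return a `fiber_system` object.
#' @export
build_fiber <- function(n_cores, nrl = NULL, linker_beads = NULL,
                        core_pattern = "all_canonical",
                        nfr_positions = integer(0), nfr_bp = 167,
                        acetyl_regions = list(), lh_density = 0,
                        seed = 1L, temperature = 293, salt = 0.15) {
  if (n_cores < 1) stop("`n_cores` must be >= 1", call. = FALSE)
  if (is.null(linker_beads)) {
    if (n_cores > 1) {
      if (is.null(nrl)) stop("give either `nrl` or `linker_beads`", call. = FALSE)
      # reject NRLs whose linker would round below the 2-bead minimum by
      # more than half a segment (e.g. NRL 173 -> 26 bp -> 2 beads is fine)
      if (nrl - .mf$nuc_bp < linker_length_bp(2) - bp_per_segment() / 2)
        stop("NRL below 147 bp + minimum representable linker (26.47 bp)",
             call. = FALSE)
      linker_beads <- rep(beads_for_length(nrl - .mf$nuc_bp), n_cores - 1)
    } else linker_beads <- integer(0)
  } else {
    if (length(linker_beads) == 1 && n_cores > 2)
      linker_beads <- rep(linker_beads, n_cores - 1)
    if (length(linker_beads) != max(n_cores - 1, 0))
      stop("`linker_beads` must have length n_cores - 1", call. = FALSE)
    if (any(linker_beads < 2)) stop("linkers need >= 2 beads", call. = FALSE)
  }
  nfr_positions <- sort(unique(as.integer(nfr_positions)))
  if (length(nfr_positions)) {
    if (any(nfr_positions < 2 | nfr_positions > n_cores - 1))
      stop("NFR positions must be interior core positions", call. = FALSE)
    if (any(diff(nfr_positions) < 2))
      stop("adjacent NFR positions are not representable", call. = FALSE)
  }

  # resolve NFRs: delete the core, merge flanking linkers + nfr_bp of DNA
  keep <- setdiff(seq_len(n_cores), nfr_positions)
  n_kept <- length(keep)
  beads <- list()    # per-surviving-linker bead counts
  is_nfr <- logical(0)
  if (n_kept > 1) {
    i <- 1L
    while (i < n_cores) {
      if ((i + 1L) %in% nfr_positions) {
        merged_bp <- linker_length_bp(linker_beads[i]) + nfr_bp +
          linker_length_bp(linker_beads[i + 1L])
        beads <- c(beads, beads_for_length(merged_bp))
        is_nfr <- c(is_nfr, TRUE)
        i <- i + 2L
      } else {
        beads <- c(beads, linker_beads[i])
        is_nfr <- c(is_nfr, FALSE)
        i <- i + 1L
      }
    }
    beads <- as.integer(unlist(beads))
  } else beads <- integer(0)

  sys <- structure(list(
    n_cores = n_kept, free_chain = FALSE,
    core_pos = matrix(0, n_kept, 3), core_frame = vector("list", n_kept),
    core_type = rep("canonical", n_kept),
    lh_bound = rep(FALSE, n_kept), acetylated = rep(FALSE, n_kept),
    linkers = lapply(seq_along(beads), function(i) list(
      n_beads = beads[i], pos = NULL, frames = NULL,
      length_bp = linker_length_bp(beads[i]), nfr = is_nfr[i])),
    tails = vector("list", n_kept), lhs = list(),
    restraints = data.frame(core_i = integer(0), core_j = integer(0),
                            k = numeric(0), l0 = numeric(0)),
    nfr_linkers = which(is_nfr),
    annotations = list(acetyl_regions = list(), lh_density = 0),
    conditions = list(temperature = temperature, salt = salt),
    charge_sets = list(canonical = synthetic_core_charges("canonical"),
                       macroH2A1 = synthetic_core_charges("macroH2A1"),
                       hybrid = synthetic_core_charges("hybrid")),
    residual_twist = 0,
    cag = NULL
  ), class = "fiber_system")

  sys <- rebuild_geometry(sys)
  sys <- switch(core_pattern,
    all_canonical = assign_composition(sys, "all_canonical"),
    all_macroH2A1 = assign_composition(sys, "all_macroH2A1"),
    all_hybrid = assign_composition(sys, "all_hybrid"),
    alternating = assign_composition(sys, "alternating"),
    fifty_fifty = assign_composition(sys, "fraction", p = 0.5, seed = seed),
    stop("unknown core_pattern: ", core_pattern, call. = FALSE))
  if (length(acetyl_regions)) sys <- mark_acetylation(sys, acetyl_regions)
  if (lh_density > 0) sys <- place_linker_histones(sys, lh_density, seed = seed)
  sys
}

# Regenerate all coordinates (cores, linkers, tails, LHs) as a regular planar
# zigzag from the per-linker bead counts. Decorations (types, flags,
# restraints, annotations) are preserved.
rebuild_geometry <- function(sys) {
  n <- sys$n_cores
  turn <- pi - 2 * .mf$att_angle       # zigzag turning angle
  half <- turn / 2
  udir <- function(i) {                # alternating linker directions
    s <- if (i %% 2 == 0) 1 else -1
    c(sin(s * half), 0, cos(s * half))
  }
  att_r <- .mf$att_radius
  pos <- matrix(0, n, 3)
  frames <- vector("list", n)
  for (i in seq_len(n)) {
    u_prev <- udir(i - 1); u_next <- udir(i)
    e1 <- normalize(u_next - u_prev)
    e2 <- normalize(u_next + u_prev)
    e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
            e1[3] * e2[1] - e1[1] * e2[3],
            e1[1] * e2[2] - e1[2] * e2[1])
    frames[[i]] <- cbind(e1, e2, e3)
    if (i > 1) {
      nb <- sys$linkers[[i - 1]]$n_beads
      # entry/exit sites project onto the center line at distance att_radius
      # from the center, so this spacing makes every DNA segment exactly l0
      D <- 2 * att_r + (nb + 1) * .mf$l0
      pos[i, ] <- pos[i - 1, ] + D * udir(i - 1)
    }
  }
  sys$core_pos <- pos
  sys$core_frame <- frames
  if (n > 1) {
    for (li in seq_len(n - 1)) {
      A <- pos[li, ] + as.vector(frames[[li]] %*% att_exit_local())
      B <- pos[li + 1, ] + as.vector(frames[[li + 1]] %*% att_entry_local())
      nb <- sys$linkers[[li]]$n_beads
      tseq <- seq_len(nb) / (nb + 1)
      bp <- t(vapply(tseq, function(t) A + t * (B - A), numeric(3)))
      tang <- normalize(B - A)
      # parallel-transport the exit core frame onto the linker tangent so
      # the initial twist at the junctions is zero
      Fc <- frames[[li]]
      e1 <- Fc[, 1]
      ax <- c(e1[2] * tang[3] - e1[3] * tang[2],
              e1[3] * tang[1] - e1[1] * tang[3],
              e1[1] * tang[2] - e1[2] * tang[1])
      fr <- if (sqrt(sum(ax^2)) > 1e-12) {
        ang <- atan2(sqrt(sum(ax^2)), sum(e1 * tang))
        rot_about(ax, ang) %*% Fc
      } else Fc
      sys$linkers[[li]]$pos <- bp
      sys$linkers[[li]]$frames <- rep(list(fr), nb)
    }
    # the planar zigzag leaves a fixed total junction twist per linker
    # (set by the end core frames); spread it evenly over the segments,
    # shifted by whole turns to sit nearest the twist target
    for (li in seq_len(n - 1)) {
      nb <- sys$linkers[[li]]$n_beads
      n_seg <- nb + 1
      tau <- frame_twists(linker_frames(sys, li))
      lb <- sys$linkers[[li]]$length_bp
      phi_t <- 2 * pi * (lb / .mf$bp_per_turn - round(lb / .mf$bp_per_turn)) / n_seg
      Tt <- sum(tau)
      u <- (Tt + 2 * pi * round((n_seg * phi_t - Tt) / (2 * pi))) / n_seg
      csum <- 0
      for (j in seq_len(nb)) {
        csum <- csum + (u - tau[j])
        fj <- sys$linkers[[li]]$frames[[j]]
        sys$linkers[[li]]$frames[[j]] <- rot_about(fj[, 1], csum) %*% fj
      }
    }
  }
  for (i in seq_len(n)) {
    if (is.null(sys$tails[[i]])) {
      sys$tails[[i]] <- core_tails(sys$core_type[i], pos[i, ], frames[[i]])
    } else {
      sys$tails[[i]] <- lapply(sys$tails[[i]], reset_tail_coords,
                               center = pos[i, ], frame = frames[[i]])
    }
  }
  for (k in seq_along(sys$lhs)) {
    sys$lhs[[k]] <- reset_lh_coords(sys$lhs[[k]], sys)
  }
  sys
}

reset_lh_coords <- function(lh, sys) {
  prof <- lh_profile()
  ci <- lh$core
  center <- sys$core_pos[ci, ]
  fr <- sys$core_frame[[ci]]
  glob <- body_to_world(center, fr, prof$glob_local)
  # CTD extends along the disk normal, clear of the fiber plane
  rad <- normalize(as.vector(fr %*% c(0.3, 0, 1)))
  last <- glob[nrow(glob), ]
  ctd <- t(vapply(seq_len(prof$n_ctd), function(j) last + j * prof$spacing * rad,
                  numeric(3)))
  lh$glob_pos <- glob
  lh$ctd_pos <- ctd
  lh$glob_q <- prof$glob_q
  lh$ctd_q <- prof$ctd_q
  lh
}

#' Assign core composition along the fiber
#'
#' @param sys a `fiber_system`.
#' @param pattern one of "all_canonical", "all_macroH2A1", "all_hybrid",
#'   "alternating" (variant cores on every other nucleosome), or "fraction".
#' @param p for `pattern = "fraction"`: fraction of macroH2A1 cores; exactly
#'   `round(p * n_cores)` cores become macroH2A1, placed by a seeded shuffle.
#' @param seed RNG seed for the fraction pattern (reproducible placement).
#' @return the system with `core_type` set and tail charges updated.
#' @export
assign_composition <- function(sys, pattern, p = 0.5, seed = 1L) {
  n <- sys$n_cores
  types <- switch(pattern,
    all_canonical = rep("canonical", n),
    all_macroH2A1 = rep("macroH2A1", n),
    all_hybrid = rep("hybrid", n),
    alternating = rep(c("canonical", "macroH2A1"), length.out = n),
    fraction = {
      if (p < 0 || p > 1) stop("`p` must be in [0, 1]", call. = FALSE)
      k <- round(p * n)
      out <- rep("canonical", n)
      idx <- withr_seed(seed, sample.int(n, k))
      out[idx] <- "macroH2A1"
      out
    },
    stop("unknown composition pattern: ", pattern, call. = FALSE))
  changed <- which(types != sys$core_type)
  sys$core_type <- types
  for (i in changed) {
    states <- vapply(sys$tails[[i]], `[[`, "", "state")
    sys$tails[[i]] <- core_tails(types[i], sys$core_pos[i, ],
                                 sys$core_frame[[i]])
    for (k in seq_along(states)) {
      if (states[k] == "folded") sys$tails[[i]][[k]] <- toggle_tail(sys$tails[[i]][[k]])
    }
  }
  sys
}

# evaluate expr under a temporary seed without disturbing the caller's RNG
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

toggle_tail <- function(tail) {
  tmp <- tail$pos
  tail$pos <- tail$alt_pos
  tail$alt_pos <- tmp
  tail$state <- if (tail$state == "wildtype") "folded" else "wildtype"
  tail
}

#' Place linker histones on a fiber
#'
#' `round(density * n_cores)` cores receive one on-dyad linker histone each
#' (6 rigid globular beads moving with the core, 22 flexible C-terminal
#' beads), chosen by seeded uniform sampling without replacement.
#'
#' @param sys a `fiber_system`.
#' @param density average LH per nucleosome in `[0, 1]`.
#' @param seed RNG seed (placement is reproducible).
#' @return the system with `lh_bound` flags and LH objects set.
#' @export
place_linker_histones <- function(sys, density, seed = 1L) {
  if (density < 0 || density > 1)
    stop("`density` must be in [0, 1]", call. = FALSE)
  k <- round(density * sys$n_cores)
  sys$lh_bound <- rep(FALSE, sys$n_cores)
  sys$lhs <- list()
  if (k > 0) {
    idx <- sort(withr_seed(seed, sample.int(sys$n_cores, k)))
    sys$lh_bound[idx] <- TRUE
    sys$lhs <- lapply(idx, function(ci) reset_lh_coords(list(core = ci), sys))
  }
  sys$annotations$lh_density <- density
  sys
}

#' Flag acetylation regions
#'
#' Cores in the given index ranges are flagged acetylated: their tails become
#' eligible for the swap-fold move (wildtype <-> compact folded coordinates)
#' and their tail stretching/bending constants are scaled by
#' `acetyl_stiffness_factor` of [energy_params()].
#'
#' @param sys a `fiber_system`.
#' @param regions list of 2-vectors `c(from, to)` of 1-based core index ranges.
#' @return the system with `acetylated` flags set.
#' @export
mark_acetylation <- function(sys, regions) {
  if (length(regions) && !is.list(regions)) regions <- list(regions)
  for (r in regions) {
    if (length(r) != 2 || r[1] > r[2])
      stop("each region must be c(from, to) with from <= to", call. = FALSE)
    if (r[1] < 1 || r[2] > sys$n_cores)
      stop("acetylation region out of range", call. = FALSE)
    sys$acetylated[r[1]:r[2]] <- TRUE
  }
  sys$annotations$acetyl_regions <- regions
  sys
}

#' Add genomic-loop harmonic restraints
#'
#' Adds harmonic core-core restraints with energy `k * (l - l0)^2` mimicking
#' chromosome-conformation loops. The two built-in conditions encode the
#' HTT-gene loop sets: healthy anchors core 1 to cores 357, 408, 442 and 519
#' (4 loops); diseased anchors core 1 to cores 531, 621 and 688 (3 loops);
#' both with k = 40 kcal/mol/nm^2 and l0 = 50 nm. For fibers shorter than the
#' reference 688 cores the anchor indices are rescaled proportionally.
#'
#' @param sys a `fiber_system`.
#' @param condition "healthy" or "diseased", or "custom" with `pairs`.
#' @param pairs for `condition = "custom"`: 2-column matrix of core indices.
#' @param k force constant, kcal/mol/nm^2.
#' @param l0 equilibrium distance, nm.
#' @param reference_n reference core count for which the built-in anchor
#'   indices are defined (688).
#' @return the system with restraints appended.
#' @export
add_restraints <- function(sys, condition = c("healthy", "diseased", "custom"),
                           pairs = NULL, k = 40, l0 = 50, reference_n = 688) {
  condition <- match.arg(condition)
  if (condition == "custom") {
    if (is.null(pairs)) stop("`pairs` required for custom restraints", call. = FALSE)
    pairs <- matrix(as.integer(pairs), ncol = 2)
  } else {
    anchors <- if (condition == "healthy") c(357, 408, 442, 519)
               else c(531, 621, 688)
    if (sys$n_cores != reference_n)
      anchors <- pmax(2L, pmin(sys$n_cores,
                               as.integer(round(anchors * sys$n_cores / reference_n))))
    pairs <- cbind(1L, anchors)
  }
  if (any(pairs < 1) || any(pairs > sys$n_cores))
    stop("restraint core index out of range", call. = FALSE)
  if (any(pairs[, 1] == pairs[, 2]))
    stop("restraints need two distinct cores", call. = FALSE)
  if (k < 0) stop("`k` must be >= 0", call. = FALSE)
  sys$restraints <- rbind(sys$restraints,
                          data.frame(core_i = pairs[, 1], core_j = pairs[, 2],
                                     k = k, l0 = l0))
  sys
}

#' Expand the first linker by a CAG-repeat tract
#'
#' Mimics a trinucleotide-repeat expansion by lengthening the first linker
#' DNA by the bead increment closest to `extra_bp` (default +106 bp, i.e.
#' +12 beads at ~8.82 bp per segment, a nominal ~35 extra CAG repeats).
#' Coordinates are regenerated for the expanded geometry.
#'
#' @param sys a `fiber_system` with at least one linker.
#' @param extra_bp expansion length in bp (default 106).
#' @return the system with the first linker lengthened and a `cag` record
#'   (`extra_beads`, `repeats`).
#' @export
expand_cag <- function(sys, extra_bp = 106) {
  if (length(sys$linkers) < 1) stop("fiber has no linker", call. = FALSE)
  extra_beads <- as.integer(round(extra_bp / bp_per_segment()))
  lk <- sys$linkers[[1]]
  lk$n_beads <- lk$n_beads + extra_beads
  lk$length_bp <- linker_length_bp(lk$n_beads)
  sys$linkers[[1]] <- lk
  sys$cag <- list(linker = 1L, extra_beads = extra_beads,
                  repeats = as.integer(round(extra_bp / 3)))
  rebuild_geometry(sys)
}

#' Undo a CAG expansion
#' @param sys a `fiber_system` previously expanded with [expand_cag()].
#' @return the system with the original first-linker bead count restored.
#' @export
revert_cag <- function(sys) {
  if (is.null(sys$cag)) return(sys)
  lk <- sys$linkers[[1]]
  lk$n_beads <- lk$n_beads - sys$cag$extra_beads
  lk$length_bp <- linker_length_bp(lk$n_beads)
  sys$linkers[[1]] <- lk
  sys$cag <- NULL
  rebuild_geometry(sys)
}

#' A free DNA bead chain (no nucleosomes)
#'
#' Utility system used for polymer-physics checks: a straight chain of
#' `n_beads` DNA beads (i.e. `n_beads - 1` segments between beads; there are
#' no core attachment segments) with wormlike-chain mechanics and optional
#' charges.
#'
#' @param n_beads number of beads (>= 2).
#' @param charged logical; if FALSE the beads carry zero charge.
#' @return a `fiber_system` with `free_chain = TRUE`, 0 cores and 1 chain.
#' @export
dna_chain_system <- function(n_beads, charged = FALSE) {
  if (n_beads < 2) stop("a chain needs >= 2 beads", call. = FALSE)
  n_beads <- as.integer(n_beads)
  pos <- cbind(0, 0, (seq_len(n_beads) - 1) * .mf$l0)
  fr <- cbind(c(0, 0, 1), c(1, 0, 0), c(0, 1, 0))
  structure(list(
    n_cores = 0L, free_chain = TRUE,
    core_pos = matrix(0, 0, 3), core_frame = list(),
    core_type = character(0), lh_bound = logical(0), acetylated = logical(0),
    linkers = list(list(n_beads = n_beads, pos = pos,
                        frames = rep(list(fr), n_beads),
                        length_bp = (n_beads - 1) * bp_per_segment(),
                        nfr = FALSE)),
    tails = list(), lhs = list(),
    restraints = data.frame(core_i = integer(0), core_j = integer(0),
                            k = numeric(0), l0 = numeric(0)),
    nfr_linkers = integer(0),
    annotations = list(acetyl_regions = list(), lh_density = 0),
    conditions = list(temperature = 293, salt = 0.15),
    charge_sets = list(),
    residual_twist = 0, cag = NULL,
    chain_charged = charged
  ), class = "fiber_system")
}

#' Validate a fiber system
#'
#' Checks the structural invariants: one linker per adjacent core pair,
#' >= 2 beads per linker, orthonormal core frames, 300 charges per charge
#' set, 10 tails per core with the expected bead counts, annotation and
#' restraint indices in range, and LH bookkeeping consistency.
#'
#' @param sys a `fiber_system`.
#' @return `TRUE` invisibly; errors on the first violated invariant.
#' @export
validate_fiber_system <- function(sys) {
  stopifnot(inherits(sys, "fiber_system"))
  n <- sys$n_cores
  if (!sys$free_chain && length(sys$linkers) != max(n - 1, 0))
    stop("expected ", max(n - 1, 0), " linkers, found ", length(sys$linkers))
  for (lk in sys$linkers) {
    if (lk$n_beads < 2) stop("linker with < 2 beads")
    if (nrow(lk$pos) != lk$n_beads) stop("linker bead count mismatch")
    want <- if (sys$free_chain) (lk$n_beads - 1) * bp_per_segment()
            else linker_length_bp(lk$n_beads)
    if (abs(lk$length_bp - want) > 1e-9)
      stop("linker length_bp inconsistent with bead count")
  }
  for (i in seq_len(n)) {
    F <- sys$core_frame[[i]]
    if (max(abs(crossprod(F) - diag(3))) > 1e-8)
      stop("core frame ", i, " not orthonormal")
    if (length(sys$tails[[i]]) != 10) stop("core ", i, " must carry 10 tails")
    for (tl in sys$tails[[i]]) {
      if (nrow(tl$pos) != length(tl$charges)) stop("tail bead count mismatch")
      if (!tl$state %in% c("wildtype", "folded")) stop("bad tail state")
    }
  }
  for (cs in sys$charge_sets) {
    if (nrow(cs) != .mf$n_core_charges)
      stop("charge sets must contain exactly ", .mf$n_core_charges, " charges")
  }
  for (r in sys$annotations$acetyl_regions) {
    if (r[1] < 1 || r[2] > n) stop("acetylation annotation out of range")
  }
  if (nrow(sys$restraints)) {
    if (any(sys$restraints$core_i == sys$restraints$core_j))
      stop("restraint joins a core to itself")
    if (any(unlist(sys$restraints[, 1:2]) > n)) stop("restraint index out of range")
    if (any(sys$restraints$k < 0)) stop("restraint force constant < 0")
  }
  if (length(sys$lhs) != sum(sys$lh_bound)) stop("LH bookkeeping inconsistent")
  for (lh in sys$lhs) {
    if (nrow(lh$glob_pos) != 6 || nrow(lh$ctd_pos) != 22)
      stop("LH must have 6 globular + 22 CTD beads")
    if (!sys$lh_bound[lh$core]) stop("LH bound to unflagged core")
  }
  invisible(TRUE)
}

#' @export
print.fiber_system <- function(x, ...) {
  if (x$free_chain) {
    cat("<fiber_system> free DNA chain,", x$linkers[[1]]$n_beads, "beads\n")
    return(invisible(x))
  }
  comp <- table(factor(x$core_type, c("canonical", "macroH2A1", "hybrid")))
  cat("<fiber_system> ", x$n_cores, " cores (",
      paste(names(comp)[comp > 0], comp[comp > 0], sep = ":", collapse = ", "),
      ")\n", sep = "")
  lb <- vapply(x$linkers, `[[`, 0L, "n_beads")
  if (length(lb))
    cat("  linkers: ", length(lb), " (", min(lb), "-", max(lb), " beads, ",
        length(x$nfr_linkers), " NFR)\n", sep = "")
  cat("  LHs: ", sum(x$lh_bound), "  acetylated cores: ", sum(x$acetylated),
      "  restraints: ", nrow(x$restraints), "\n", sep = "")
  if (!is.null(x$cag))
    cat("  CAG expansion: +", x$cag$extra_beads, " beads (~",
        x$cag$repeats, " repeats) on linker ", x$cag$linker, "\n", sep = "")
  invisible(x)
}
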