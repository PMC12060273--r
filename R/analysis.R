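# Per-structure and ensemble analysis: packing ratio, sedimentation,
# radius of gyration, contact maps and their 1D decomposition, local
# geometry, clutches, persistence length, tail interactions, epigenetic
# contact classes, convergence diagnostics.

core_positions <- function(x) {
  if (inherits(x, "fiber_system")) return(x$core_pos)
  if (is.matrix(x) && ncol(x) == 3) return(x)
  stop("expected a fiber_system or an n x 3 coordinate matrix", call. = FALSE)
}

# Normalize any ensemble argument to a list of snapshot records:
# list(P, group, active, core_pos, sys) where sys is the template system.
as_snapshot_list <- function(x, params = energy_params()) {
  if (inherits(x, "mc_trajectory")) {
    return(lapply(seq_along(x$snapshots), function(i) {
      sn <- x$snapshots[[i]]
      list(P = sn$P, group = x$flat_meta$group, active = sn$active,
           core_pos = sn$core_pos, core_frame = sn$core_frame,
           sys = x$template, flat_meta = x$flat_meta)
    }))
  }
  if (inherits(x, "fiber_system")) {
    fl <- flatten_elements(x, params)
    return(list(list(P = fl$P, group = fl$group, active = fl$active,
                     core_pos = x$core_pos, core_frame = x$core_frame,
                     sys = x, flat_meta = fl)))
  }
  if (is.list(x)) return(unlist(lapply(x, as_snapshot_list, params = params),
                                recursive = FALSE))
  stop("cannot interpret ensemble argument", call. = FALSE)
}

#' Smooth fiber axis through the nucleosome centers
#'
#' Fits a cubic smoothing spline to the core x, y, z coordinates as a
#' function of core index and samples it densely. With `smoothing = "auto"`
#' the spline is smoothed as much as possible while keeping the RMS residual
#' at the core centers within one nucleosome radius (5.5 nm); large fixed
#' `smoothing` values degenerate toward the least-squares line, and
#' `smoothing = "none"` interpolates.
#'
#' @param x a `fiber_system` or an n x 3 matrix of core centers (n >= 4).
#' @param smoothing "auto", "none", or a `spar` value passed to
#'   [stats::smooth.spline()].
#' @param oversample dense samples per core interval.
#' @return a `fiber_axis`: list with `points`, arc coordinate `s`, unit
#'   `tangents`, total arc length `Fl`, and the achieved `resid_rms`.
#' @export
fiber_axis <- function(x, smoothing = "auto", oversample = 10) {
  pos <- core_positions(x)
  n <- nrow(pos)
  if (n < 4) stop("fiber axis needs >= 4 cores", call. = FALSE)
  idx <- seq_len(n)
  dense <- seq(1, n, length.out = (n - 1) * oversample + 1)
  fit_coord <- function(y, spar) {
    if (stats::sd(y) < 1e-12)
      return(list(fitted = rep(y[1], n), dense = rep(y[1], length(dense))))
    f <- if (is.null(spar)) stats::smooth.spline(idx, y, cv = FALSE)
         else stats::smooth.spline(idx, y, spar = spar)
    list(fitted = stats::predict(f, idx)$y, dense = stats::predict(f, dense)$y)
  }
  interp_coord <- function(y) {
    f <- stats::spline(idx, y, xout = dense, method = "natural")
    list(fitted = y, dense = f$y)
  }
  eval_spar <- function(spar) {
    fx <- fit_coord(pos[, 1], spar)
    fy <- fit_coord(pos[, 2], spar)
    fz <- fit_coord(pos[, 3], spar)
    res <- cbind(fx$fitted - pos[, 1], fy$fitted - pos[, 2],
                 fz$fitted - pos[, 3])
    list(rms = sqrt(mean(rowSums(res^2))),
         pts = cbind(fx$dense, fy$dense, fz$dense))
  }
  if (identical(smoothing, "none")) {
    pts <- cbind(interp_coord(pos[, 1])$dense, interp_coord(pos[, 2])$dense,
                 interp_coord(pos[, 3])$dense)
    rms <- 0
  } else if (identical(smoothing, "auto")) {
    target <- .mf$core_radius
    lo <- 0; hi <- 1.5
    top <- eval_spar(hi)
    if (top$rms <= target) {
      pts <- top$pts; rms <- top$rms
    } else {
      for (it in 1:20) {
        mid <- (lo + hi) / 2
        e <- eval_spar(mid)
        if (e$rms <= target) lo <- mid else hi <- mid
      }
      e <- eval_spar(lo)
      pts <- e$pts; rms <- e$rms
    }
  } else {
    e <- eval_spar(as.numeric(smoothing))
    pts <- e$pts; rms <- e$rms
  }
  d <- diff(pts)
  seg <- sqrt(rowSums(d^2))
  seg[seg < 1e-12] <- 1e-12
  tangents <- d / seg
  s_mid <- cumsum(seg) - seg / 2
  structure(list(points = pts, s = c(0, cumsum(seg)), s_mid = s_mid,
                 tangents = tangents, Fl = sum(seg), resid_rms = rms),
            class = "fiber_axis")
}

#' Fiber packing ratio
#'
#' Nucleosomes per 11 nm of fiber-axis length: `N_C * 11 / Fl` with `Fl`
#' the arc length of the smoothed fiber axis.
#'
#' @param x a `fiber_system` or core-center matrix.
#' @param axis optional precomputed [fiber_axis()].
#' @param ... passed to [fiber_axis()].
#' @return nucleosomes per 11 nm (dimensionless).
#' @export
packing_ratio <- function(x, axis = NULL, ...) {
  pos <- core_positions(x)
  if (is.null(axis)) axis <- fiber_axis(pos, ...)
  if (axis$Fl <= 0) stop("degenerate fiber axis (zero length)", call. = FALSE)
  nrow(pos) * 11 / axis$Fl
}

#' Sedimentation coefficient
#'
#' Kirkwood-type double sum over nucleosome pairs,
#' `S = S_mono(rho) * (1 + (R1 / N_C) * sum_{i != j} 1 / R_ij)`, where
#' `S_mono` interpolates linearly between the mononucleosome values without
#' LH (11.1 S) and with LH (12 S) according to the LH density `rho`, and
#' `R1 = 5.5 nm` is the nucleosome radius.
#'
#' @param x a `fiber_system` or core-center matrix.
#' @param rho LH density in `[0, 1]`; defaults to the system's LH density.
#' @return sedimentation coefficient in Svedberg units.
#' @export
sedimentation <- function(x, rho = NULL) {
  pos <- core_positions(x)
  if (is.null(rho))
    rho <- if (inherits(x, "fiber_system") && x$n_cores > 0)
      mean(x$lh_bound) else 0
  if (rho < 0 || rho > 1) stop("`rho` must be in [0, 1]", call. = FALSE)
  n <- nrow(pos)
  if (n < 1) stop("need at least one nucleosome", call. = FALSE)
  s_mono <- .mf$s0 + rho * (.mf$s1 - .mf$s0)
  if (n == 1) return(s_mono)
  dm <- as.matrix(stats::dist(pos))
  off <- dm[upper.tri(dm)]
  if (any(off < 1e-9)) stop("coincident nucleosome centers", call. = FALSE)
  s_mono * (1 + (.mf$r1 / n) * 2 * sum(1 / off))
}

#' Radius of gyration of the nucleosome centers
#'
#' Root-mean-square distance of the cores from their centroid.
#'
#' @param x a `fiber_system` or core-center matrix.
#' @return nm.
#' @export
radius_of_gyration <- function(x) {
  pos <- core_positions(x)
  if (nrow(pos) < 1) stop("need at least one nucleosome", call. = FALSE)
  ctr <- colMeans(pos)
  sqrt(mean(rowSums(sweep(pos, 2, ctr)^2)))
}

#' End-to-end distance
#' @param x a `fiber_system` or core-center matrix (>= 2 cores).
#' @return distance between the first and last nucleosome, nm.
#' @export
end_to_end <- function(x) {
  pos <- core_positions(x)
  if (nrow(pos) < 2) stop("need >= 2 nucleosomes", call. = FALSE)
  sqrt(sum((pos[1, ] - pos[nrow(pos), ])^2))
}

#' Internucleosome contact matrix
#'
#' Two nucleosomes are in contact in a snapshot when any element of one
#' (core charge, linker DNA bead, tail bead, LH bead; linker beads are
#' assigned to the nearer flanking nucleosome) is closer than `cutoff` to
#' any element of the other. Folded tails still occupy space and count.
#' The entry (i, j) is the fraction of snapshots with the pair in contact;
#' for a list of trajectories, frequencies are computed per trajectory and
#' then averaged. The diagonal is 1 by convention.
#'
#' @param ensemble an `mc_trajectory`, a list of trajectories, a
#'   `fiber_system`, or a list of systems.
#' @param cutoff contact distance, nm (default 2).
#' @return a `contact_matrix` (numeric matrix with attributes `cutoff` and
#'   `n_frames`).
#' @export
contact_matrix <- function(ensemble, cutoff = 2) {
  per_traj <- if (inherits(ensemble, "mc_trajectory")) list(ensemble)
              else if (is.list(ensemble) && length(ensemble) &&
                       all(vapply(ensemble, inherits, TRUE, "mc_trajectory")))
                ensemble
              else list(ensemble)
  mats <- lapply(per_traj, function(tr) {
    snaps <- as_snapshot_list(tr)
    n <- nrow(snaps[[1]]$core_pos)
    if (n < 1) stop("ensemble has no nucleosomes", call. = FALSE)
    acc <- matrix(0, n, n)
    for (sn in snaps) {
      dmin <- group_contacts_cpp(sn$P, sn$group, n, cutoff)
      acc <- acc + (dmin < cutoff)
    }
    acc / length(snaps)
  })
  m <- Reduce(`+`, mats) / length(mats)
  diag(m) <- 1
  total_frames <- sum(vapply(per_traj, function(tr)
    length(as_snapshot_list(tr)), 0L))
  structure(m, cutoff = cutoff, n_frames = total_frames,
            class = c("contact_matrix", "matrix"))
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat("<contact_matrix> ", nrow(x), " x ", ncol(x), ", cutoff ",
      attr(x, "cutoff"), " nm, ", attr(x, "n_frames"), " frames\n", sep = "")
  cat("  mean off-diagonal frequency ",
      signif(mean(x[upper.tri(x)]), 4), "\n", sep = "")
  invisible(x)
}

#' Decompose a contact matrix into an i, i +/- k profile
#'
#' `profile(k) = (1/N_C) * sum_i I(i, i + k)` for k = 1 .. N_C - 1
#' (`normalization = "n_c"`); `normalization = "pairs"` divides by the
#' number of (i, i + k) pairs instead.
#'
#' @param mat a symmetric contact matrix.
#' @param normalization "n_c" or "pairs".
#' @return data.frame with columns `k` and `value`.
#' @export
contact_decomposition <- function(mat, normalization = c("n_c", "pairs")) {
  normalization <- match.arg(normalization)
  mat <- unclass(mat)
  if (!isSymmetric(mat, tol = 1e-8))
    stop("contact matrix must be symmetric", call. = FALSE)
  n <- nrow(mat)
  ks <- seq_len(n - 1)
  val <- vapply(ks, function(k) {
    i <- seq_len(n - k)
    s <- sum(mat[cbind(i, i + k)])
    if (normalization == "n_c") s / n else s / (n - k)
  }, 0)
  data.frame(k = ks, value = val)
}

#' Local fiber geometry distributions
#'
#' Consecutive core-core distances, the angle at each core triplet
#' (i, i+1, i+2), and the twisting angle between the disk normals of
#' consecutive cores.
#'
#' @param x a `fiber_system` (frames are needed for plane twisting; a bare
#'   coordinate matrix yields distances and triplet angles only).
#' @return list with `distance` (nm), `angle` (degrees), `twist` (degrees).
#' @export
local_geometry <- function(x) {
  pos <- core_positions(x)
  n <- nrow(pos)
  d <- if (n >= 2) sqrt(rowSums(diff(pos)^2)) else numeric(0)
  ang <- if (n >= 3) {
    vapply(seq_len(n - 2), function(i) {
      v1 <- pos[i, ] - pos[i + 1, ]
      v2 <- pos[i + 2, ] - pos[i + 1, ]
      ca <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
      acos(pmin(1, pmax(-1, ca))) * 180 / pi
    }, 0)
  } else numeric(0)
  tw <- if (inherits(x, "fiber_system") && n >= 2) {
    vapply(seq_len(n - 1), function(i) {
      n1 <- x$core_frame[[i]][, 3]
      n2 <- x$core_frame[[i + 1]][, 3]
      acos(pmin(1, pmax(-1, sum(n1 * n2)))) * 180 / pi
    }, 0)
  } else numeric(0)
  list(distance = d, angle = ang, twist = tw)
}

# plain DBSCAN on a distance matrix (minPts counts the point itself)
dbscan_labels <- function(pos, eps, min_pts) {
  n <- nrow(pos)
  if (n == 0) return(integer(0))
  dm <- as.matrix(stats::dist(pos))
  nb <- lapply(seq_len(n), function(i) which(dm[i, ] <= eps))
  is_core <- vapply(nb, length, 0L) >= min_pts
  labels <- integer(n)           # 0 = noise
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !is_core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- setdiff(nb[[i]], i)
    while (length(queue)) {
      j <- queue[1]
      queue <- queue[-1]
      if (labels[j] == 0L) {
        labels[j] <- cl
        if (is_core[j]) queue <- union(queue, setdiff(nb[[j]], j))
      }
    }
  }
  labels
}

#' Nucleosome clutch analysis
#'
#' Density-based clustering (DBSCAN) of the nucleosome centers with a 30 nm
#' search radius and a minimum of 3 nucleosomes per clutch.
#'
#' @param x a `fiber_system`, core-center matrix, `mc_trajectory` or list
#'   of trajectories (ensembles are averaged over snapshots).
#' @param eps search radius, nm.
#' @param min_pts minimum nucleosomes forming a clutch.
#' @return list with `n_clutches`, `mean_size` (NA when no clutch), and for
#'   single structures the per-core `labels` (0 = unclustered).
#' @export
clutch_analysis <- function(x, eps = 30, min_pts = 3) {
  if (inherits(x, "mc_trajectory") ||
      (is.list(x) && !inherits(x, "fiber_system") && !is.matrix(x))) {
    mats <- if (is.list(x) && all(vapply(x, is.matrix, TRUE)) &&
                !inherits(x, "mc_trajectory")) x
            else lapply(as_snapshot_list(x), `[[`, "core_pos")
    res <- lapply(mats, function(m) clutch_analysis(m, eps, min_pts))
    nc <- vapply(res, `[[`, 0, "n_clutches")
    ms <- vapply(res, `[[`, 0, "mean_size")
    return(list(n_clutches = mean(nc), mean_size = mean(ms, na.rm = TRUE),
                per_snapshot = data.frame(n_clutches = nc, mean_size = ms)))
  }
  pos <- core_positions(x)
  labels <- dbscan_labels(pos, eps, min_pts)
  sizes <- if (any(labels > 0)) as.vector(table(labels[labels > 0])) else integer(0)
  sizes <- sizes[sizes >= min_pts]
  list(n_clutches = length(sizes),
       mean_size = if (length(sizes)) mean(sizes) else NA_real_,
       labels = labels)
}

#' Fiber persistence length from tangent correlations
#'
#' Fits `<u(s) . u(s')> = exp(-|s - s'| / Lp)` to the unit tangents of the
#' fiber axis. `method = "all_pairs"` (default) pools all tangent pairs
#' binned by contour separation; `method = "start_anchored"` correlates the
#' initial tangent with all later ones. A list of axes (an ensemble) pools
#' correlations before fitting. Straight axes whose correlation does not
#' decay are reported as the capped sentinel `1e6` nm with attribute
#' `flag = "straight"`; fit failures carry `flag = "fit_failure"`.
#'
#' @param x a `fiber_axis` or list of `fiber_axis` objects.
#' @param method pairing rule for the correlation estimate.
#' @param n_bins histogram bins over contour separation.
#' @return persistence length in nm, with attribute `flag` when degenerate.
#' @export
persistence_length <- function(x, method = c("all_pairs", "start_anchored"),
                               n_bins = 50) {
  method <- match.arg(method)
  axes <- if (inherits(x, "fiber_axis")) list(x) else x
  stopifnot(length(axes) >= 1, all(vapply(axes, inherits, TRUE, "fiber_axis")))
  smax <- max(vapply(axes, `[[`, 0, "Fl"))
  if (smax <= 0) stop("axis length must be > 0", call. = FALSE)
  breaks <- seq(0, smax, length.out = n_bins + 1)
  num <- numeric(n_bins)
  cnt <- numeric(n_bins)
  for (ax in axes) {
    u <- ax$tangents
    s <- ax$s_mid
    m <- nrow(u)
    if (method == "all_pairs") {
      G <- tcrossprod(u)
      ds <- abs(outer(s, s, "-"))
      sel <- upper.tri(ds)
      b <- findInterval(ds[sel], breaks, rightmost.closed = TRUE)
      g <- G[sel]
    } else {
      ds <- s - s[1]
      b <- findInterval(ds[-1], breaks, rightmost.closed = TRUE)
      g <- as.vector(u[-1, , drop = FALSE] %*% u[1, ])
    }
    ok <- b >= 1 & b <= n_bins
    num <- num + tabulate_weighted(b[ok], g[ok], n_bins)
    cnt <- cnt + tabulate(b[ok], n_bins)
  }
  has <- cnt > 0
  corr <- num[has] / cnt[has]
  mids <- ((breaks[-1] + breaks[-length(breaks)]) / 2)[has]
  mask <- corr > 0
  if (sum(mask) < 3) {
    out <- .mf$lp_cap
    attr(out, "flag") <- "fit_failure"
    return(out)
  }
  fit <- stats::lm(log(corr[mask]) ~ 0 + mids[mask])
  slope <- unname(stats::coef(fit)[1])
  if (!is.finite(slope) || slope >= -1 / .mf$lp_cap) {
    out <- .mf$lp_cap
    attr(out, "flag") <- "straight"
    return(out)
  }
  -1 / slope
}

tabulate_weighted <- function(bin, w, nbins) {
  out <- numeric(nbins)
  for (k in seq_along(bin)) out[bin[k]] <- out[bin[k]] + w[k]
  out
}

#' Histone tail interaction profile
#'
#' For each tail type and core type, the frequency (over snapshots and tail
#' copies) of the tail being in contact (< `cutoff` nm) with: its parental
#' core or parental DNA, a nonparental core (including LH beads of that
#' core), nonparental DNA, other tails, or none of these ("free"). A tail
#' in a snapshot is assigned to the category of its closest contacted
#' element, so rows sum to 1; folded tails count as free.
#'
#' @param ensemble trajectory / system / list thereof.
#' @param cutoff contact distance, nm.
#' @return data.frame with columns `tail_type`, `core_type`, the five
#'   category frequencies, and `n_obs`.
#' @export
tail_interaction_profile <- function(ensemble, cutoff = 2) {
  snaps <- as_snapshot_list(ensemble)
  cats <- c("parental", "nonparental_core", "nonparental_dna",
            "other_tails", "free")
  acc <- list()
  bump <- function(key, cat) {
    if (is.null(acc[[key]]))
      acc[[key]] <<- setNames(numeric(5), cats)
    acc[[key]][cat] <<- acc[[key]][cat] + 1
  }
  for (sn in snaps) {
    fm <- sn$flat_meta
    sys <- sn$sys
    # per-element tail uid (0 for non-tail elements)
    tail_uid <- integer(fm$n)
    uid <- 0L
    tinfo <- list()
    for (ci in seq_len(sys$n_cores)) {
      for (k in seq_along(fm$idx$tail[[ci]])) {
        uid <- uid + 1L
        rows <- fm$idx$tail[[ci]][[k]]
        tail_uid[rows] <- uid
        tinfo[[uid]] <- list(core = ci,
                             type = sub("\\.\\d$", "", tail_ids()[k]),
                             core_type = sys$core_type[ci],
                             folded = !sn$active[rows[1]])
      }
    }
    if (uid == 0L) next
    best <- rep(Inf, uid)
    best_cat <- rep(NA_integer_, uid)
    prs <- pairs_within_cpp(sn$P, cutoff)
    if (nrow(prs)) {
      d <- sqrt(rowSums((sn$P[prs[, 1], , drop = FALSE] -
                         sn$P[prs[, 2], , drop = FALSE])^2))
      classify <- function(tu, other, dd) {
        info <- tinfo[[tu]]
        if (info$folded) return()
        ok <- fm$kind[other]
        cat <- if (tail_uid[other] > 0) {
          if (tail_uid[other] == tu) return() else 4L
        } else if (ok == 1L) {
          if (fm$group[other] == info$core) 1L else 3L
        } else {                       # core charge or LH bead
          if (fm$core_id[other] == info$core) 1L else 2L
        }
        if (dd < best[tu]) {
          best[tu] <<- dd
          best_cat[tu] <<- cat
        }
      }
      for (r in seq_len(nrow(prs))) {
        i <- prs[r, 1]; j <- prs[r, 2]
        if (tail_uid[i] > 0) classify(tail_uid[i], j, d[r])
        if (tail_uid[j] > 0) classify(tail_uid[j], i, d[r])
      }
    }
    for (tu in seq_len(uid)) {
      info <- tinfo[[tu]]
      cat <- if (info$folded || is.na(best_cat[tu])) 5L else best_cat[tu]
      bump(paste(info$type, info$core_type, sep = "|"), cat)
    }
  }
  if (!length(acc))
    return(data.frame(tail_type = character(0), core_type = character(0)))
  keys <- names(acc)
  out <- do.call(rbind, lapply(keys, function(key) {
    v <- acc[[key]]
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    data.frame(tail_type = parts[1], core_type = parts[2],
               as.list(v / sum(v)), n_obs = sum(v))
  }))
  out[order(out$tail_type, out$core_type), ]
}

#' Canonical / macroH2A1 tail interaction ratio
#'
#' Elementwise ratio of category frequencies between canonical-core and
#' macroH2A1-core tails of the same tail type. Ratios with a zero
#' denominator are returned as `NaN` (flagged undefined).
#'
#' @param profile output of [tail_interaction_profile()].
#' @return data.frame of ratios per tail type.
#' @export
tail_interaction_ratio <- function(profile) {
  cats <- c("parental", "nonparental_core", "nonparental_dna",
            "other_tails", "free")
  types <- intersect(unique(profile$tail_type),
                     profile$tail_type[profile$core_type == "canonical"])
  rows <- lapply(types, function(tt) {
    a <- profile[profile$tail_type == tt & profile$core_type == "canonical", ]
    b <- profile[profile$tail_type == tt & profile$core_type == "macroH2A1", ]
    if (!nrow(a) || !nrow(b)) return(NULL)
    r <- unlist(a[1, cats]) / unlist(b[1, cats])
    data.frame(tail_type = tt, as.list(r))
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(out)) data.frame(tail_type = character(0)) else out
}

#' Contacts by epigenetic class
#'
#' Assigns each core an epigenetic class with precedence acetylated > LH >
#' NFR-adjacent > unmarked (a core can carry several marks), then pools the
#' contact frequency of every off-diagonal pair into one of Ac/Ac, Ac/LH,
#' LH/LH, NFR/Ac, NFR/LH, or WT/WT (the last collects all remaining pairs,
#' i.e. pairs with at most one informative mark). Class sums equal the total
#' off-diagonal contact weight.
#'
#' @param mat a `contact_matrix`.
#' @param sys the annotated `fiber_system` the matrix belongs to.
#' @return named numeric vector of summed contact frequencies per class.
#' @export
epigenetic_contact_classes <- function(mat, sys) {
  n <- nrow(mat)
  stopifnot(inherits(sys, "fiber_system"), sys$n_cores == n)
  nfr_adj <- rep(FALSE, n)
  for (li in sys$nfr_linkers) nfr_adj[c(li, li + 1)] <- TRUE
  cls <- ifelse(sys$acetylated, "Ac",
                ifelse(sys$lh_bound, "LH", ifelse(nfr_adj, "NFR", "WT")))
  out <- c("Ac/Ac" = 0, "Ac/LH" = 0, "LH/LH" = 0, "NFR/Ac" = 0,
           "NFR/LH" = 0, "WT/WT" = 0)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      w <- mat[i, j]
      if (w == 0) next
      a <- cls[i]; b <- cls[j]
      key <- if (a == "Ac" && b == "Ac") "Ac/Ac"
        else if ((a == "Ac" && b == "LH") || (a == "LH" && b == "Ac")) "Ac/LH"
        else if (a == "LH" && b == "LH") "LH/LH"
        else if ((a == "NFR" && b == "Ac") || (a == "Ac" && b == "NFR")) "NFR/Ac"
        else if ((a == "NFR" && b == "LH") || (a == "LH" && b == "NFR")) "NFR/LH"
        else "WT/WT"
      out[key] <- out[key] + w
    }
  }
  out
}

#' Convergence diagnostics across replicas
#'
#' Running mean and standard error of packing ratio, radius of gyration and
#' sedimentation coefficient along each trajectory, plus a flag when the
#' final replica means do not mutually overlap within 2 standard errors.
#'
#' @param trajectories list of `mc_trajectory` objects (or a single one).
#' @return list with `series` (one data.frame per replica: step, metric,
#'   running_mean, running_se) and `overlap_flag`.
#' @export
convergence_diagnostics <- function(trajectories) {
  if (inherits(trajectories, "mc_trajectory")) trajectories <- list(trajectories)
  stopifnot(length(trajectories) >= 1)
  series <- lapply(trajectories, function(tr) {
    snaps <- as_snapshot_list(tr)
    vals <- lapply(snaps, function(sn) {
      pr <- if (nrow(sn$core_pos) >= 4) packing_ratio(sn$core_pos) else NA_real_
      c(packing = pr,
        rg = radius_of_gyration(sn$core_pos),
        sed = if (nrow(sn$core_pos) >= 1)
          sedimentation(sn$core_pos,
                        rho = if (tr$template$n_cores > 0)
                          mean(tr$template$lh_bound) else 0) else NA_real_)
    })
    steps <- vapply(tr$snapshots, `[[`, 0L, "step")
    do.call(rbind, lapply(c("packing", "rg", "sed"), function(m) {
      v <- vapply(vals, `[[`, 0, m)
      rm_ <- cumsum(ifelse(is.na(v), 0, v)) / cumsum(!is.na(v))
      rse <- vapply(seq_along(v), function(i) {
        vi <- v[seq_len(i)]
        vi <- vi[!is.na(vi)]
        if (length(vi) < 2) NA_real_ else stats::sd(vi) / sqrt(length(vi))
      }, 0)
      data.frame(step = steps, metric = m, value = v, running_mean = rm_,
                 running_se = rse)
    }))
  })
  finals <- lapply(series, function(df) df[!duplicated(df$metric, fromLast = TRUE), ])
  overlap_flag <- FALSE
  if (length(series) > 1) {
    for (m in c("packing", "rg", "sed")) {
      mu <- vapply(finals, function(df) df$running_mean[df$metric == m], 0)
      se <- vapply(finals, function(df) df$running_se[df$metric == m], 0)
      if (any(!is.finite(se)) || any(is.na(mu))) next
      for (a in seq_along(mu)) for (b in seq_along(mu)) {
        if (a < b && abs(mu[a] - mu[b]) > 2 * sqrt(se[a]^2 + se[b]^2 + 1e-12))
          overlap_flag <- TRUE
      }
    }
  }
  list(series = series, overlap_flag = overlap_flag)
}

#' One-call metric report for an ensemble
#'
#' Computes the ensemble means of packing ratio, sedimentation coefficient,
#' radius of gyration and end-to-end distance, the clutch statistics, the
#' contact matrix with its 1D decomposition, and (for >= 4 cores) the
#' ensemble persistence length.
#'
#' @param ensemble trajectory / system / list thereof.
#' @param cutoff contact cutoff, nm.
#' @return a `metric_report` (named list) with a compact print method.
#' @export
metric_report <- function(ensemble, cutoff = 2) {
  snaps <- as_snapshot_list(ensemble)
  n <- nrow(snaps[[1]]$core_pos)
  per <- lapply(snaps, function(sn) {
    ax <- if (n >= 4) fiber_axis(sn$core_pos) else NULL
    c(packing = if (!is.null(ax)) n * 11 / ax$Fl else NA_real_,
      rg = radius_of_gyration(sn$core_pos),
      e2e = if (n >= 2) end_to_end(sn$core_pos) else NA_real_,
      sed = sedimentation(sn$core_pos,
                          rho = if (length(snaps[[1]]$sys$lh_bound))
                            mean(snaps[[1]]$sys$lh_bound) else 0))
  })
  per <- do.call(rbind, per)
  cl <- clutch_analysis(if (length(snaps) == 1) snaps[[1]]$core_pos else
    lapply(snaps, `[[`, "core_pos"))
  cm <- contact_matrix(ensemble, cutoff = cutoff)
  lp <- if (n >= 4) {
    axes <- lapply(snaps, function(sn) fiber_axis(sn$core_pos))
    persistence_length(axes)
  } else NA_real_
  structure(list(
    n_cores = n, n_frames = length(snaps),
    packing_ratio = mean(per[, "packing"]),
    sedimentation = mean(per[, "sed"]),
    radius_of_gyration = mean(per[, "rg"]),
    end_to_end = mean(per[, "e2e"]),
    n_clutches = cl$n_clutches, clutch_mean_size = cl$mean_size,
    persistence_length = as.numeric(lp),
    contact_matrix = cm,
    contact_profile = contact_decomposition(cm)
  ), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("<metric_report> ", x$n_cores, " cores, ", x$n_frames, " frames\n",
      sep = "")
  fmt <- function(v) formatC(v, digits = 4, format = "g")
  cat("  packing ratio      ", fmt(x$packing_ratio), " nuc/11nm\n", sep = "")
  cat("  sedimentation      ", fmt(x$sedimentation), " S\n", sep = "")
  cat("  radius of gyration ", fmt(x$radius_of_gyration), " nm\n", sep = "")
  cat("  end-to-end         ", fmt(x$end_to_end), " nm\n", sep = "")
  cat("  clutches           ", fmt(x$n_clutches), " (mean size ",
      fmt(x$clutch_mean_size), ")\n", sep = "")
  cat("  persistence length ", fmt(x$persistence_length), " nm\n", sep = "")
  invisible(x)
}
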