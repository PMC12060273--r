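# Independent brute-force oracles and small utilities shared by the tests.
# The oracles are written directly from the model definitions (dense matrix
# algebra over all element pairs; no calls into the package's optimized
# kernels).

# All-pairs exclusion mask from the model's rules: intra-rigid-body pairs,
# bonded chain neighbors, and elements against their attachment core.
naive_exclusion_mask <- function(fl) {
  rigid <- fl$kind %in% c(0L, 3L)
  same_core <- outer(fl$core_id, fl$core_id, "==") &
    outer(fl$core_id != 0, fl$core_id != 0, "&")
  excl <- (same_core & outer(rigid, rigid, "&"))
  same_chain <- outer(fl$chain_id, fl$chain_id, "==") &
    outer(fl$chain_id != 0, fl$chain_id != 0, "&")
  excl <- excl | (same_chain &
                    abs(outer(fl$chain_pos, fl$chain_pos, "-")) <= 1)
  att <- outer(fl$excl_core, fl$core_id, "==") &
    outer(rep(TRUE, fl$n), fl$kind == 0L & fl$core_id != 0, "&")
  excl | att | t(att)
}

# Naive all-pairs Debye-Hueckel + Lennard-Jones energies of a system.
naive_nonbonded <- function(sys, params) {
  fl <- mesofiber:::flatten_elements(sys, params)
  ke <- if (params$electrostatics) 33.20637 / params$epsilon_r else 0
  D <- as.matrix(dist(fl$P))
  act <- outer(fl$active, fl$active, "&")
  ok <- upper.tri(D) & act & !naive_exclusion_mask(fl) &
    D < params$cutoff & D > 0
  r <- D[ok]
  qq <- outer(fl$q, fl$q)[ok]
  sg <- outer(fl$sigma, fl$sigma, "+")[ok] / 2
  list(elec = sum(ke * qq * exp(-params$kappa * r) / r),
       ev = sum(params$k_ev * ((sg / r)^12 - (sg / r)^6)))
}

# Same, restricted to a subset of elements (mask over rows of the flat
# arrays); used to show folded tails are energetically inert.
naive_nonbonded_subset <- function(sys, params, keep) {
  fl <- mesofiber:::flatten_elements(sys, params)
  ke <- if (params$electrostatics) 33.20637 / params$epsilon_r else 0
  D <- as.matrix(dist(fl$P))
  sub <- outer(keep, keep, "&")
  ok <- upper.tri(D) & sub & !naive_exclusion_mask(fl) &
    D < params$cutoff & D > 0
  r <- D[ok]
  qq <- outer(fl$q, fl$q)[ok]
  sg <- outer(fl$sigma, fl$sigma, "+")[ok] / 2
  list(elec = sum(ke * qq * exp(-params$kappa * r) / r),
       ev = sum(params$k_ev * ((sg / r)^12 - (sg / r)^6)))
}

# Brute-force contact matrix for one snapshot: minimum element distance per
# nucleosome pair from the dense distance matrix.
naive_contact_matrix <- function(sys, cutoff = 2) {
  fl <- mesofiber:::flatten_elements(sys, energy_params())
  n <- sys$n_cores
  D <- as.matrix(dist(fl$P))
  m <- diag(n)
  for (gi in seq_len(n - 1)) {
    ri <- which(fl$group == gi)
    for (gj in (gi + 1):n) {
      rj <- which(fl$group == gj)
      if (min(D[ri, rj]) < cutoff) {
        m[gi, gj] <- 1
        m[gj, gi] <- 1
      }
    }
  }
  m
}

# Exhaustive DBSCAN by reachability closure: core points have >= min_pts
# points (incl. self) within eps; clusters are connected components of the
# core-point graph; border points join a neighboring cluster.
naive_dbscan <- function(pos, eps = 30, min_pts = 3) {
  n <- nrow(pos)
  dm <- as.matrix(dist(pos))
  nb <- dm <= eps
  is_core <- rowSums(nb) >= min_pts
  labels <- integer(n)
  cl <- 0L
  for (i in which(is_core)) {
    if (labels[i]) next
    cl <- cl + 1L
    comp <- i
    repeat {
      grow <- which(is_core & !seq_len(n) %in% comp &
                    apply(nb[, comp, drop = FALSE], 1, any))
      if (!length(grow)) break
      comp <- c(comp, grow)
    }
    labels[comp] <- cl
  }
  for (i in which(!is_core & labels == 0)) {
    hit <- labels[nb[i, ] & labels > 0]
    if (length(hit)) labels[i] <- hit[1]
  }
  sizes <- if (any(labels > 0)) as.vector(table(labels[labels > 0])) else integer(0)
  sizes <- sizes[sizes >= min_pts]
  list(n_clutches = length(sizes),
       mean_size = if (length(sizes)) mean(sizes) else NA_real_)
}

# Rigid-body transform of a whole fiber system (rotation R then shift).
transform_system <- function(sys, R, shift = c(0, 0, 0)) {
  tf <- function(X) X %*% t(R) + rep(shift, each = nrow(X))
  sys$core_pos <- tf(sys$core_pos)
  sys$core_frame <- lapply(sys$core_frame, function(f) R %*% f)
  for (li in seq_along(sys$linkers)) {
    sys$linkers[[li]]$pos <- tf(sys$linkers[[li]]$pos)
    sys$linkers[[li]]$frames <- lapply(sys$linkers[[li]]$frames,
                                       function(f) R %*% f)
  }
  for (ci in seq_len(sys$n_cores)) {
    for (k in seq_along(sys$tails[[ci]])) {
      sys$tails[[ci]][[k]]$pos <- tf(sys$tails[[ci]][[k]]$pos)
      sys$tails[[ci]][[k]]$alt_pos <- tf(sys$tails[[ci]][[k]]$alt_pos)
    }
  }
  for (j in seq_along(sys$lhs)) {
    sys$lhs[[j]]$glob_pos <- tf(sys$lhs[[j]]$glob_pos)
    sys$lhs[[j]]$ctd_pos <- tf(sys$lhs[[j]]$ctd_pos)
  }
  sys
}

random_rotation <- function(seed) {
  set.seed(seed)
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  mesofiber:::rot_about(ax, runif(1, 0, 2 * pi))
}

# fold every tail of a system (test scaffolding for acetylation behavior)
fold_all_tails <- function(sys) {
  for (ci in seq_len(sys$n_cores))
    for (k in seq_along(sys$tails[[ci]]))
      sys$tails[[ci]][[k]] <- mesofiber:::toggle_tail(sys$tails[[ci]][[k]])
  sys
}
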