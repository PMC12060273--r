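# Metropolis Monte Carlo engine: global pivot, local translation/rotation,
# configurational-bias tail regrowth, linker-histone CTD moves, and the
# acetylation swap-fold move, with incremental energy bookkeeping.

#' Monte Carlo move mixture and amplitudes
#'
#' @param pivot,local,regrowth,lh,swap_fold relative move weights (>= 0,
#'   positive sum). Moves without eligible targets in a given system (no
#'   LHs, no acetylated cores, no wildtype tails) are disabled automatically.
#' @param amp_trans maximal local translation, nm.
#' @param amp_rot maximal local rotation, rad.
#' @param amp_pivot maximal pivot rotation, rad.
#' @param n_trial trial directions per bead in configurational-bias
#'   regrowth (1 reduces to plain single-bead resampling).
#' @return an object of class `move_set`.
#' @export
move_set <- function(pivot = 0.2, local = 0.4, regrowth = 0.2, lh = 0.1,
                     swap_fold = 0.1, amp_trans = 1, amp_rot = 0.6,
                     amp_pivot = 0.6, n_trial = 8) {
  w <- c(pivot = pivot, local = local, regrowth = regrowth, lh = lh,
         swap_fold = swap_fold)
  if (any(w < 0) || sum(w) <= 0)
    stop("move weights must be >= 0 with positive sum", call. = FALSE)
  if (any(c(amp_trans, amp_rot, amp_pivot) <= 0) || n_trial < 1)
    stop("amplitudes must be > 0 and n_trial >= 1", call. = FALSE)
  structure(list(weights = w, amp_trans = amp_trans, amp_rot = amp_rot,
                 amp_pivot = amp_pivot, n_trial = as.integer(n_trial)),
            class = "move_set")
}

#' Metropolis acceptance rule
#'
#' Accepts energy-lowering proposals always; otherwise accepts with
#' probability `exp(-delta_E / kBT)` using R's RNG stream.
#'
#' @param delta_E energy change, kcal/mol.
#' @param kBT thermal energy, kcal/mol (> 0).
#' @return logical.
#' @export
metropolis_accept <- function(delta_E, kBT) {
  if (kBT <= 0) stop("kBT must be > 0", call. = FALSE)
  if (is.nan(delta_E)) stop("NaN energy change in Metropolis step", call. = FALSE)
  delta_E <= 0 || stats::runif(1) < exp(-delta_E / kBT)
}

rand_unit <- function() {
  repeat {
    v <- stats::rnorm(3)
    n2 <- sum(v^2)
    if (n2 > 1e-12) return(v / sqrt(n2))
  }
}

rand_in_sphere <- function(radius) {
  rand_unit() * radius * stats::runif(1)^(1 / 3)
}

# ---- engine state ----------------------------------------------------------

mc_state_init <- function(sys, params, moveset) {
  flat <- flatten_elements(sys, params)
  nlk <- length(sys$linkers)
  lb <- matrix(0, max(nlk, 0), 3, dimnames = list(NULL, c("stretch", "bend", "twist")))
  for (li in seq_len(nlk)) lb[li, ] <- linker_bonded(sys, li, params)
  tb <- lapply(seq_len(sys$n_cores), function(ci)
    t(vapply(seq_along(sys$tails[[ci]]),
             function(k) tail_bonded(sys, ci, k, params), numeric(2))))
  hb <- if (length(sys$lhs))
    t(vapply(seq_along(sys$lhs), function(j) lh_bonded(sys, j, params),
             numeric(2))) else matrix(0, 0, 2)
  nb <- nonbonded_energy(sys, params, flat)
  terms <- c(
    stretch = sum(lb[, 1]) + sum(vapply(tb, function(m) sum(m[, 1]), 0)) +
      (if (nrow(hb)) sum(hb[, 1]) else 0),
    bend = sum(lb[, 2]) + sum(vapply(tb, function(m) sum(m[, 2]), 0)) +
      (if (nrow(hb)) sum(hb[, 2]) else 0),
    twist = sum(lb[, 3]),
    elec = nb$elec, ev = nb$ev, restraint = restraint_energy(sys))
  lh_of_core <- integer(sys$n_cores)
  for (j in seq_along(sys$lhs)) lh_of_core[sys$lhs[[j]]$core] <- j
  ke <- if (params$electrostatics) .mf$coulomb / params$epsilon_r else 0
  env <- new.env(parent = emptyenv())
  env$sys <- sys; env$flat <- flat; env$params <- params; env$ms <- moveset
  env$lb <- lb; env$tb <- tb; env$hb <- hb; env$terms <- terms
  env$lh_of_core <- lh_of_core; env$ke <- ke
  env$active_int <- as.integer(flat$active)
  env$nb_per <- vapply(sys$linkers, `[[`, 0L, "n_beads")
  # dormant-state tail coordinates (folded template or displaced wildtype),
  # kept in a parallel matrix so rigid moves are single in-place transforms
  env$alt_P <- matrix(0, flat$n, 3)
  env$wt <- matrix(FALSE, max(sys$n_cores, 1), 10)
  for (ci in seq_len(sys$n_cores))
    for (k in seq_along(sys$tails[[ci]])) {
      rows <- flat$idx$tail[[ci]][[k]]
      env$alt_P[rows, ] <- sys$tails[[ci]][[k]]$alt_pos
      env$wt[ci, k] <- sys$tails[[ci]][[k]]$state == "wildtype"
    }
  env
}

state_nb_delta <- function(st, moved, Pnew, active_new = NULL,
                           internal = FALSE) {
  if (is.null(active_new)) active_new <- st$flat$active[moved]
  nb_delta_cpp(st$flat$P, st$flat$q, st$flat$kind, st$flat$core_id,
               st$flat$chain_id, st$flat$chain_pos, st$flat$excl_core,
               st$active_int, st$flat$sigma,
               as.integer(moved), Pnew, as.integer(active_new), internal,
               st$ke, st$params$kappa, st$params$k_ev, st$params$cutoff)
}

# element row indices belonging to core ci (charges, tails, bound LH)
core_element_rows <- function(st, ci) {
  rows <- c(st$flat$idx$core[[ci]], unlist(st$flat$idx$tail[[ci]]))
  j <- st$lh_of_core[ci]
  if (j > 0) rows <- c(rows, st$flat$idx$lh_glob[[j]], st$flat$idx$lh_ctd[[j]])
  rows
}

# apply a rigid transform x -> R (x - c) + c + shift to a set of cores and
# (linker, bead-subset) pairs, updating sys, flat$P and DNA/core frames
apply_rigid <- function(st, cores, linker_beads, R, center, shift = c(0, 0, 0)) {
  off <- center + shift
  tf <- function(X) {
    if (is.null(dim(X))) X <- matrix(X, ncol = 3)
    Y <- cbind(X[, 1] - center[1], X[, 2] - center[2],
               X[, 3] - center[3]) %*% t(R)
    cbind(Y[, 1] + off[1], Y[, 2] + off[2], Y[, 3] + off[3])
  }
  all_rows <- integer(0)
  alt_rows <- integer(0)
  for (ci in cores) {
    st$sys$core_pos[ci, ] <- tf(st$sys$core_pos[ci, , drop = FALSE])
    st$sys$core_frame[[ci]] <- R %*% st$sys$core_frame[[ci]]
    all_rows <- c(all_rows, core_element_rows(st, ci))
    alt_rows <- c(alt_rows, unlist(st$flat$idx$tail[[ci]]))
  }
  for (lb in linker_beads) {
    li <- lb$linker
    lpos <- st$sys$linkers[[li]]$pos
    lpos[lb$beads, ] <- tf(lpos[lb$beads, , drop = FALSE])
    st$sys$linkers[[li]]$pos <- lpos
    for (b in lb$beads)
      st$sys$linkers[[li]]$frames[[b]] <- R %*% st$sys$linkers[[li]]$frames[[b]]
    all_rows <- c(all_rows, st$flat$idx$linker[[li]][lb$beads])
  }
  if (length(all_rows))
    transform_rows_cpp(st$flat$P, as.integer(all_rows), R, center, shift)
  if (length(alt_rows))
    transform_rows_cpp(st$alt_P, as.integer(alt_rows), R, center, shift)
  invisible(st)
}

# new world coordinates of the same rigid transform, without applying it
rigid_preview <- function(st, rows, R, center, shift = c(0, 0, 0)) {
  preview_rows_cpp(st$flat$P, as.integer(rows), R, center, shift)
}

refresh_linker_bonded <- function(st, lis) {
  for (li in lis) {
    new <- linker_bonded(st$sys, li, st$params)
    st$terms[c("stretch", "bend", "twist")] <-
      st$terms[c("stretch", "bend", "twist")] - st$lb[li, ] + new
    st$lb[li, ] <- new
  }
}

restraint_part <- function(sys, cores) {
  r <- sys$restraints
  if (!nrow(r)) return(0)
  hit <- r$core_i %in% cores | r$core_j %in% cores
  if (!any(hit)) return(0)
  r <- r[hit, , drop = FALSE]
  d <- sqrt(rowSums((sys$core_pos[r$core_i, , drop = FALSE] -
                     sys$core_pos[r$core_j, , drop = FALSE])^2))
  sum(r$k * (d - r$l0)^2)
}

# bonded energy of a tail / LH chain evaluated from the flat coordinates
tail_bonded_flat <- function(st, ci, k, pos = NULL, state_active = NULL) {
  rows <- st$flat$idx$tail[[ci]][[k]]
  if (is.null(state_active)) state_active <- st$flat$active[rows[1]]
  if (!state_active) return(c(stretch = 0, bend = 0))
  if (is.null(pos)) pos <- st$flat$P[rows, , drop = FALSE]
  tl <- st$sys$tails[[ci]][[k]]
  fac <- if (st$sys$acetylated[ci]) st$params$acetyl_stiffness_factor else 1
  attach <- st$sys$core_pos[ci, ] +
    as.vector(st$sys$core_frame[[ci]] %*% tl$attach_local)
  pts <- rbind(attach, pos)
  l <- seg_lengths(pts)
  th <- bend_angles(pts)
  c(stretch = sum(0.5 * fac * st$params$h_tail * (l - st$params$l0_tail)^2),
    bend = sum(0.5 * fac * st$params$g_tail * th^2))
}

lh_bonded_flat <- function(st, j) {
  g <- st$flat$idx$lh_glob[[j]]
  c_ <- st$flat$idx$lh_ctd[[j]]
  pts <- st$flat$P[c(g[length(g)], c_), , drop = FALSE]
  l <- seg_lengths(pts)
  th <- bend_angles(pts)
  c(stretch = sum(0.5 * st$params$h_lh * (l - st$params$l0_tail)^2),
    bend = sum(0.5 * st$params$g_lh * th^2))
}

# write the flat tail / LH coordinates back into the system object
sync_sys_from_flat <- function(st) {
  sys <- st$sys
  for (ci in seq_len(sys$n_cores)) {
    for (k in seq_along(sys$tails[[ci]])) {
      rows <- st$flat$idx$tail[[ci]][[k]]
      sys$tails[[ci]][[k]]$pos <- st$flat$P[rows, , drop = FALSE]
      sys$tails[[ci]][[k]]$alt_pos <- st$alt_P[rows, , drop = FALSE]
      sys$tails[[ci]][[k]]$state <-
        if (st$flat$active[rows[1]]) "wildtype" else "folded"
    }
  }
  for (j in seq_along(sys$lhs)) {
    sys$lhs[[j]]$glob_pos <- st$flat$P[st$flat$idx$lh_glob[[j]], , drop = FALSE]
    sys$lhs[[j]]$ctd_pos <- st$flat$P[st$flat$idx$lh_ctd[[j]], , drop = FALSE]
  }
  sys
}

# ---- individual moves ------------------------------------------------------
# Each attempt function performs proposal + Metropolis decision + state
# update, and returns TRUE if accepted.

attempt_local <- function(st) {
  sys <- st$sys
  n_beads_per_linker <- st$nb_per
  total <- sys$n_cores + sum(n_beads_per_linker)
  pick <- sample.int(total, 1)
  translate <- stats::runif(1) < 0.5
  if (pick <= sys$n_cores) {
    ci <- pick
    rows <- core_element_rows(st, ci)
    if (translate) {
      shift <- rand_in_sphere(st$ms$amp_trans)
      R <- diag(3); center <- c(0, 0, 0)
    } else {
      shift <- c(0, 0, 0)
      R <- rot_about(rand_unit(), stats::runif(1, -st$ms$amp_rot, st$ms$amp_rot))
      center <- sys$core_pos[ci, ]
    }
    Pnew <- rigid_preview(st, rows, R, center, shift)
    nb <- state_nb_delta(st, rows, Pnew)
    if (nb$overlaps > 0) return(FALSE)
    adj <- intersect(c(ci - 1L, ci), seq_along(sys$linkers))
    old_bonded <- if (length(adj)) colSums(st$lb[adj, , drop = FALSE]) else numeric(3)
    old_res <- restraint_part(sys, ci)
    # trial application on a copy of the geometry to evaluate bonded terms
    st$sys$core_pos[ci, ] <- as.vector(R %*% (sys$core_pos[ci, ] - center)) +
      center + shift
    st$sys$core_frame[[ci]] <- R %*% sys$core_frame[[ci]]
    new_bonded <- if (length(adj))
      colSums(t(vapply(adj, function(li) linker_bonded(st$sys, li, st$params),
                       numeric(3)))) else numeric(3)
    new_res <- restraint_part(st$sys, ci)
    dE <- (nb$elec_new + nb$ev_new - nb$elec_old - nb$ev_old) +
      sum(new_bonded - old_bonded) + (new_res - old_res)
    if (!metropolis_accept(dE, st$params$kBT)) {
      st$sys$core_pos[ci, ] <- sys$core_pos[ci, ]
      st$sys$core_frame[[ci]] <- sys$core_frame[[ci]]
      return(FALSE)
    }
    # core accepted: move dependent coordinates and refresh caches
    st$sys$core_pos[ci, ] <- sys$core_pos[ci, ]   # apply_rigid re-applies
    st$sys$core_frame[[ci]] <- sys$core_frame[[ci]]
    apply_rigid(st, ci, list(), R, center, shift)
    refresh_linker_bonded(st, adj)
    st$terms["restraint"] <- st$terms["restraint"] - old_res + new_res
    st$terms["elec"] <- st$terms["elec"] + nb$elec_new - nb$elec_old
    st$terms["ev"] <- st$terms["ev"] + nb$ev_new - nb$ev_old
    return(TRUE)
  }
  # DNA bead
  rem <- pick - sys$n_cores
  li <- 1L
  while (rem > n_beads_per_linker[li]) {
    rem <- rem - n_beads_per_linker[li]
    li <- li + 1L
  }
  b <- rem
  if (translate) {
    row <- st$flat$idx$linker[[li]][b]
    shift <- rand_in_sphere(st$ms$amp_trans)
    Pnew <- matrix(st$flat$P[row, ] + shift, 1)
    nb <- state_nb_delta(st, row, Pnew)
    if (nb$overlaps > 0) return(FALSE)
    old <- st$lb[li, ]
    oldpos <- sys$linkers[[li]]$pos[b, ]
    st$sys$linkers[[li]]$pos[b, ] <- oldpos + shift
    new <- linker_bonded(st$sys, li, st$params)
    dE <- (nb$elec_new + nb$ev_new - nb$elec_old - nb$ev_old) + sum(new - old)
    if (!metropolis_accept(dE, st$params$kBT)) {
      st$sys$linkers[[li]]$pos[b, ] <- oldpos
      return(FALSE)
    }
    set_rows_cpp(st$flat$P, as.integer(row), Pnew)
    st$terms[c("stretch", "bend", "twist")] <-
      st$terms[c("stretch", "bend", "twist")] - old + new
    st$lb[li, ] <- new
    st$terms["elec"] <- st$terms["elec"] + nb$elec_new - nb$elec_old
    st$terms["ev"] <- st$terms["ev"] + nb$ev_new - nb$ev_old
    return(TRUE)
  }
  # rotation of a DNA bead about an axis through itself: positions are
  # unchanged, only the bead frame (hence twist energy) changes
  R <- rot_about(rand_unit(), stats::runif(1, -st$ms$amp_rot, st$ms$amp_rot))
  oldfr <- sys$linkers[[li]]$frames[[b]]
  old <- st$lb[li, ]
  st$sys$linkers[[li]]$frames[[b]] <- R %*% oldfr
  new <- linker_bonded(st$sys, li, st$params)
  dE <- sum(new - old)
  if (!metropolis_accept(dE, st$params$kBT)) {
    st$sys$linkers[[li]]$frames[[b]] <- oldfr
    return(FALSE)
  }
  st$terms[c("stretch", "bend", "twist")] <-
    st$terms[c("stretch", "bend", "twist")] - old + new
  st$lb[li, ] <- new
  TRUE
}

attempt_pivot <- function(st) {
  sys <- st$sys
  nlk <- length(sys$linkers)
  nb_per <- st$nb_per
  # backbone nodes: core 1, linker 1 beads, core 2, ... (or bare chain)
  n_nodes <- sys$n_cores + sum(nb_per)
  if (n_nodes < 3) return(FALSE)
  node <- sample.int(n_nodes, 1)
  # resolve node -> (kind, core or linker/bead) and count nodes left of it
  if (sys$free_chain) {
    li <- 1L; b <- node; at_core <- FALSE; left_nodes <- node - 1L
  } else {
    i <- 1L; left_nodes <- 0L; at_core <- FALSE; ci <- 0L; li <- 0L; b <- 0L
    rem <- node
    for (c_i in seq_len(sys$n_cores)) {
      if (rem == 1L) { at_core <- TRUE; ci <- c_i; break }
      rem <- rem - 1L; left_nodes <- left_nodes + 1L
      if (c_i <= nlk) {
        if (rem <= nb_per[c_i]) { li <- c_i; b <- rem; break }
        rem <- rem - nb_per[c_i]; left_nodes <- left_nodes + nb_per[c_i]
      }
    }
  }
  right_nodes <- n_nodes - left_nodes - 1L
  if (left_nodes == 0L && right_nodes == 0L) return(FALSE)
  take_left <- left_nodes <= right_nodes
  if (left_nodes == 0L) take_left <- FALSE
  if (right_nodes == 0L) take_left <- TRUE

  if (at_core) {
    pivot_pt <- sys$core_pos[ci, ]
    if (take_left) {
      cores <- seq_len(ci - 1L)
      linkers <- lapply(seq_len(ci - 1L), function(l)
        list(linker = l, beads = seq_len(nb_per[l])))
      boundary <- ci - 1L
    } else {
      cores <- seq(ci + 1L, sys$n_cores)
      linkers <- lapply(seq(ci, nlk), function(l)
        list(linker = l, beads = seq_len(nb_per[l])))
      boundary <- ci
    }
  } else {
    pivot_pt <- sys$linkers[[li]]$pos[b, ]
    if (take_left) {
      cores <- if (sys$free_chain) integer(0) else seq_len(li)
      linkers <- c(if (li > 1L && !sys$free_chain)
        lapply(seq_len(li - 1L), function(l)
          list(linker = l, beads = seq_len(nb_per[l]))),
        if (b > 1L) list(list(linker = li, beads = seq_len(b - 1L))))
      boundary <- li
    } else {
      cores <- if (sys$free_chain || li + 1L > sys$n_cores) integer(0)
               else seq(li + 1L, sys$n_cores)
      linkers <- c(if (b < nb_per[li])
        list(list(linker = li, beads = seq(b + 1L, nb_per[li]))),
        if (li + 1L <= nlk) lapply(seq(li + 1L, nlk), function(l)
          list(linker = l, beads = seq_len(nb_per[l]))))
      boundary <- li
    }
  }
  linkers <- Filter(Negate(is.null), linkers)
  R <- rot_about(rand_unit(), stats::runif(1, -st$ms$amp_pivot, st$ms$amp_pivot))
  rows <- c(unlist(lapply(cores, core_element_rows, st = st)),
            unlist(lapply(linkers, function(lb)
              st$flat$idx$linker[[lb$linker]][lb$beads])))
  Pnew <- rigid_preview(st, rows, R, pivot_pt)
  nbd <- state_nb_delta(st, rows, Pnew)
  if (nbd$overlaps > 0) return(FALSE)
  boundary <- if (length(sys$linkers)) intersect(boundary, seq_len(nlk)) else integer(0)
  old_bonded <- if (length(boundary))
    colSums(st$lb[boundary, , drop = FALSE]) else numeric(3)
  old_res <- restraint_part(sys, cores)
  old_core_pos <- sys$core_pos
  old_core_frame <- sys$core_frame
  old_linker <- lapply(linkers, function(lb) st$sys$linkers[[lb$linker]])
  # apply transform to the backbone only (cheap) to evaluate bonded terms
  for (ci2 in cores) {
    st$sys$core_pos[ci2, ] <-
      as.vector(R %*% (sys$core_pos[ci2, ] - pivot_pt)) + pivot_pt
    st$sys$core_frame[[ci2]] <- R %*% sys$core_frame[[ci2]]
  }
  for (lb in linkers) {
    lpos <- st$sys$linkers[[lb$linker]]$pos
    lpos[lb$beads, ] <- sweep(tcrossprod(
      sweep(lpos[lb$beads, , drop = FALSE], 2, pivot_pt), R), 2, pivot_pt, "+")
    st$sys$linkers[[lb$linker]]$pos <- lpos
    for (bb in lb$beads)
      st$sys$linkers[[lb$linker]]$frames[[bb]] <-
        R %*% st$sys$linkers[[lb$linker]]$frames[[bb]]
  }
  new_bonded <- if (length(boundary))
    colSums(t(vapply(boundary, function(l2)
      linker_bonded(st$sys, l2, st$params), numeric(3)))) else numeric(3)
  new_res <- restraint_part(st$sys, cores)
  dE <- (nbd$elec_new + nbd$ev_new - nbd$elec_old - nbd$ev_old) +
    sum(new_bonded - old_bonded) + (new_res - old_res)
  if (!metropolis_accept(dE, st$params$kBT)) {
    st$sys$core_pos <- old_core_pos
    st$sys$core_frame <- old_core_frame
    for (k in seq_along(linkers))
      st$sys$linkers[[linkers[[k]]$linker]] <- old_linker[[k]]
    return(FALSE)
  }
  # accepted: finish moving the dependent elements (tails, LHs, charges)
  st$sys$core_pos <- old_core_pos
  st$sys$core_frame <- old_core_frame
  for (k in seq_along(linkers))
    st$sys$linkers[[linkers[[k]]$linker]] <- old_linker[[k]]
  apply_rigid(st, cores, linkers, R, pivot_pt)
  refresh_linker_bonded(st, boundary)
  st$terms["restraint"] <- st$terms["restraint"] - old_res + new_res
  st$terms["elec"] <- st$terms["elec"] + nbd$elec_new - nbd$elec_old
  st$terms["ev"] <- st$terms["ev"] + nbd$ev_new - nbd$ev_old
  TRUE
}

attempt_regrowth <- function(st) {
  sys <- st$sys
  wt_flat <- which(st$wt)
  if (!length(wt_flat)) return(FALSE)
  pick <- if (length(wt_flat) == 1) wt_flat else sample(wt_flat, 1)
  ci <- ((pick - 1L) %% nrow(st$wt)) + 1L
  k <- ((pick - 1L) %/% nrow(st$wt)) + 1L
  tl <- sys$tails[[ci]][[k]]
  rows <- st$flat$idx$tail[[ci]][[k]]
  nb <- length(rows)
  old_pos <- st$flat$P[rows, , drop = FALSE]
  fac <- if (sys$acetylated[ci]) st$params$acetyl_stiffness_factor else 1
  attach <- sys$core_pos[ci, ] +
    as.vector(sys$core_frame[[ci]] %*% tl$attach_local)
  # candidate partners: active, not this tail, within reach of any trial bead
  reach <- st$params$cutoff + nb * (st$params$l0_tail + 0.6) + 1
  d2 <- (st$flat$P[, 1] - attach[1])^2 + (st$flat$P[, 2] - attach[2])^2 +
    (st$flat$P[, 3] - attach[3])^2
  cand <- which(d2 < reach^2 & st$flat$active)
  cand <- as.integer(cand[!(cand %in% rows)])
  res <- cbmc_regrow_cpp(st$flat$P, st$flat$q, st$flat$kind, st$flat$core_id,
                         st$flat$chain_id, st$flat$chain_pos,
                         st$flat$excl_core, st$flat$sigma, cand,
                         old_pos, tl$charges, attach, st$params$sigma_tail,
                         ci, st$ms$n_trial, st$params$l0_tail,
                         fac * st$params$h_tail, fac * st$params$g_tail,
                         st$params$kBT, st$ke, st$params$kappa,
                         st$params$k_ev, st$params$cutoff)
  if (!is.finite(res$logratio)) return(FALSE)
  if (stats::runif(1) >= exp(min(0, res$logratio))) return(FALSE)
  # accepted: recompute this tail's bonded and nonbonded bookkeeping
  nbd <- state_nb_delta(st, rows, res$pos, internal = TRUE)
  old_bonded <- st$tb[[ci]][k, ]
  set_rows_cpp(st$flat$P, as.integer(rows), res$pos)
  new_bonded <- tail_bonded_flat(st, ci, k)
  st$tb[[ci]][k, ] <- new_bonded
  st$terms[c("stretch", "bend")] <-
    st$terms[c("stretch", "bend")] - old_bonded + new_bonded
  st$terms["elec"] <- st$terms["elec"] + nbd$elec_new - nbd$elec_old
  st$terms["ev"] <- st$terms["ev"] + nbd$ev_new - nbd$ev_old
  TRUE
}

attempt_lh <- function(st) {
  nlh <- length(st$sys$lhs)
  if (!nlh) return(FALSE)
  j <- if (nlh == 1) 1L else sample.int(nlh, 1)
  b <- sample.int(22L, 1)
  row <- st$flat$idx$lh_ctd[[j]][b]
  shift <- rand_in_sphere(st$ms$amp_trans)
  Pnew <- matrix(st$flat$P[row, ] + shift, 1)
  nbd <- state_nb_delta(st, row, Pnew)
  if (nbd$overlaps > 0) return(FALSE)
  old_bonded <- st$hb[j, ]
  oldpos <- st$flat$P[row, ]
  set_rows_cpp(st$flat$P, as.integer(row), Pnew)
  new_bonded <- lh_bonded_flat(st, j)
  dE <- (nbd$elec_new + nbd$ev_new - nbd$elec_old - nbd$ev_old) +
    sum(new_bonded - old_bonded)
  if (!metropolis_accept(dE, st$params$kBT)) {
    set_rows_cpp(st$flat$P, as.integer(row), matrix(oldpos, 1))
    return(FALSE)
  }
  st$hb[j, ] <- new_bonded
  st$terms[c("stretch", "bend")] <-
    st$terms[c("stretch", "bend")] - old_bonded + new_bonded
  st$terms["elec"] <- st$terms["elec"] + nbd$elec_new - nbd$elec_old
  st$terms["ev"] <- st$terms["ev"] + nbd$ev_new - nbd$ev_old
  TRUE
}

attempt_swap_fold <- function(st) {
  elig <- which(st$sys$acetylated)
  if (!length(elig)) return(FALSE)
  ci <- if (length(elig) == 1) elig else sample(elig, 1)
  k <- sample.int(10L, 1)
  rows <- st$flat$idx$tail[[ci]][[k]]
  folding <- st$flat$active[rows[1]]
  active_new <- rep(!folding, length(rows))
  Pnew <- st$alt_P[rows, , drop = FALSE]
  nbd <- state_nb_delta(st, rows, Pnew, active_new = active_new,
                        internal = TRUE)
  if (nbd$overlaps > 0) return(FALSE)
  old_bonded <- st$tb[[ci]][k, ]
  new_bonded <- tail_bonded_flat(st, ci, k, pos = Pnew,
                                 state_active = !folding)
  dE <- (nbd$elec_new + nbd$ev_new - nbd$elec_old - nbd$ev_old) +
    sum(new_bonded - old_bonded)
  if (!metropolis_accept(dE, st$params$kBT)) return(FALSE)
  old <- st$flat$P[rows, , drop = FALSE]
  set_rows_cpp(st$flat$P, as.integer(rows), Pnew)
  set_rows_cpp(st$alt_P, as.integer(rows), old)
  st$flat$active[rows] <- active_new
  st$active_int[rows] <- as.integer(active_new)
  st$wt[ci, k] <- !folding
  st$tb[[ci]][k, ] <- new_bonded
  st$terms[c("stretch", "bend")] <-
    st$terms[c("stretch", "bend")] - old_bonded + new_bonded
  st$terms["elec"] <- st$terms["elec"] + nbd$elec_new - nbd$elec_old
  st$terms["ev"] <- st$terms["ev"] + nbd$ev_new - nbd$ev_old
  TRUE
}

# ---- driver ----------------------------------------------------------------

effective_weights <- function(sys, ms) {
  w <- ms$weights
  nb_per <- vapply(sys$linkers, `[[`, 0L, "n_beads")
  if (sys$n_cores + sum(nb_per) < 3) w["pivot"] <- 0
  if (!length(sys$lhs)) w["lh"] <- 0
  if (!any(sys$acetylated)) w["swap_fold"] <- 0
  if (sys$n_cores == 0) w["regrowth"] <- 0
  if (sum(w) <= 0)
    stop("no eligible moves for this system", call. = FALSE)
  w / sum(w)
}

#' Run a Metropolis Monte Carlo simulation
#'
#' One step is one attempted move drawn from the (eligibility-filtered)
#' move weights. Snapshots (full coordinates plus the energy breakdown) are
#' recorded at step 0 and every `stride` steps. The tracked incremental
#' energy is compared with a from-scratch recomputation at the end and both
#' are stored in the trajectory metadata.
#'
#' @param sys a `fiber_system`.
#' @param steps number of attempted moves (>= 0).
#' @param params an [energy_params()] object.
#' @param ms a [move_set()].
#' @param stride snapshot interval in steps.
#' @param seed RNG seed; the same seed reproduces the trajectory exactly.
#' @param tune optional number of burn-in steps during which move
#'   amplitudes are adjusted toward ~40% acceptance and then frozen
#'   (tuning during production would violate detailed balance); the burn-in
#'   is discarded.
#' @return an `mc_trajectory`.
#' @export
run_mc <- function(sys, steps, params = energy_params(), ms = move_set(),
                   stride = 1e5, seed = 1L, tune = 0) {
  stopifnot(steps >= 0, stride >= 1)
  validate_fiber_system(sys)
  set.seed(seed)
  st <- mc_state_init(sys, params, ms)
  w <- effective_weights(sys, ms)
  movers <- list(pivot = attempt_pivot, local = attempt_local,
                 regrowth = attempt_regrowth, lh = attempt_lh,
                 swap_fold = attempt_swap_fold)
  if (tune > 0) {
    acc <- 0L; att <- 0L
    for (step in seq_len(tune)) {
      mv <- sample(names(w), 1, prob = w)
      ok <- movers[[mv]](st)
      acc <- acc + ok; att <- att + 1L
      if (att == 250L) {
        rate <- acc / att
        f <- if (rate > 0.45) 1.15 else if (rate < 0.35) 1 / 1.15 else 1
        st$ms$amp_trans <- min(st$ms$amp_trans * f, 10)
        st$ms$amp_rot <- min(st$ms$amp_rot * f, pi)
        st$ms$amp_pivot <- min(st$ms$amp_pivot * f, pi)
        acc <- 0L; att <- 0L
      }
    }
  }
  take_snapshot <- function(step) list(
    step = step, P = st$flat$P + 0,   # deep copy: P is updated in place
    active = c(st$flat$active),
    core_pos = st$sys$core_pos, core_frame = st$sys$core_frame,
    terms = st$terms)
  snaps <- list(take_snapshot(0L))
  attempted <- accepted <- setNames(numeric(length(w)), names(w))
  if (steps > 0) {
    mv_seq <- sample(names(w), steps, replace = TRUE, prob = w)
    for (step in seq_len(steps)) {
      mv <- mv_seq[step]
      ok <- movers[[mv]](st)
      attempted[mv] <- attempted[mv] + 1
      accepted[mv] <- accepted[mv] + ok
      if (!all(is.finite(st$terms)))
        stop("non-finite energy at step ", step, " (",
             paste(names(st$terms), signif(st$terms, 4), sep = "=",
                   collapse = ", "), ")", call. = FALSE)
      if (step %% stride == 0) snaps[[length(snaps) + 1L]] <- take_snapshot(step)
    }
  }
  st$sys <- sync_sys_from_flat(st)
  final <- total_energy(st$sys, params)
  structure(list(
    template = st$sys,
    flat_meta = st$flat[c("q", "kind", "core_id", "chain_id", "chain_pos",
                          "excl_core", "group", "sigma", "idx", "n")],
    snapshots = snaps,
    meta = list(seed = seed, residual_twist = sys$residual_twist,
                steps = steps, stride = stride, params = params,
                move_set = st$ms, attempted = attempted, accepted = accepted,
                energy_tracked = sum(st$terms),
                energy_recomputed = final$total,
                terms_tracked = st$terms, terms_recomputed = final$terms)
  ), class = "mc_trajectory")
}

#' Run independent replicas
#'
#' Replica `r` uses `seeds[r]` and a residual DNA twist cycling through 0,
#' -12, +12 degrees (mimicking natural torsional variability between
#' chromatin fibers).
#'
#' @param sys a `fiber_system`.
#' @param n_replicas number of replicas (>= 1).
#' @param steps attempted moves per replica.
#' @param seeds integer vector of length `n_replicas` (default `1:n`).
#' @param ... passed to [run_mc()].
#' @return list of `mc_trajectory` objects.
#' @export
run_replicas <- function(sys, n_replicas, steps, seeds = seq_len(n_replicas),
                         ...) {
  stopifnot(n_replicas >= 1, length(seeds) == n_replicas)
  if (anyDuplicated(seeds))
    warning("duplicate replica seeds: replicas will not be independent")
  twists <- c(0, -12, 12)
  lapply(seq_len(n_replicas), function(r) {
    sys$residual_twist <- twists[(r - 1) %% 3 + 1]
    run_mc(sys, steps, seed = seeds[r], ...)
  })
}

#' Number of snapshots in a trajectory
#' @param x an `mc_trajectory`.
#' @return integer.
#' @export
n_snapshots <- function(x) length(x$snapshots)

#' Reconstruct a fiber system from a trajectory snapshot
#'
#' @param traj an `mc_trajectory`.
#' @param i snapshot index (1 = initial state).
#' @return a `fiber_system` with the snapshot's coordinates.
#' @export
snapshot_system <- function(traj, i) {
  stopifnot(i >= 1, i <= length(traj$snapshots))
  sn <- traj$snapshots[[i]]
  sys <- traj$template
  idx <- traj$flat_meta$idx
  sys$core_pos <- sn$core_pos
  sys$core_frame <- sn$core_frame
  for (li in seq_along(sys$linkers))
    sys$linkers[[li]]$pos <- sn$P[idx$linker[[li]], , drop = FALSE]
  for (ci in seq_len(sys$n_cores)) {
    for (k in seq_along(sys$tails[[ci]])) {
      rows <- idx$tail[[ci]][[k]]
      sys$tails[[ci]][[k]]$pos <- sn$P[rows, , drop = FALSE]
      sys$tails[[ci]][[k]]$state <-
        if (sn$active[rows[1]]) "wildtype" else "folded"
    }
  }
  for (j in seq_along(sys$lhs)) {
    sys$lhs[[j]]$glob_pos <- sn$P[idx$lh_glob[[j]], , drop = FALSE]
    sys$lhs[[j]]$ctd_pos <- sn$P[idx$lh_ctd[[j]], , drop = FALSE]
  }
  sys
}

#' Energy time series of a trajectory
#' @param traj an `mc_trajectory`.
#' @return data.frame with `step`, per-term columns and `total`.
#' @export
energy_series <- function(traj) {
  tm <- t(vapply(traj$snapshots, `[[`, traj$snapshots[[1]]$terms, "terms"))
  df <- data.frame(step = vapply(traj$snapshots, `[[`, 0L, "step"), tm)
  df$total <- rowSums(tm)
  df
}

#' @export
print.mc_trajectory <- function(x, ...) {
  cat("<mc_trajectory> ", x$meta$steps, " steps, ", length(x$snapshots),
      " snapshots (stride ", x$meta$stride, ")\n", sep = "")
  cat("  seed ", x$meta$seed, ", residual twist ", x$meta$residual_twist,
      " deg\n", sep = "")
  rate <- sum(x$meta$accepted) / max(1, sum(x$meta$attempted))
  cat("  acceptance ", round(100 * rate, 1), "%, final energy ",
      signif(x$meta$energy_tracked, 6), " kcal/mol\n", sep = "")
  invisible(x)
}
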