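# Energy model: wormlike-chain bonded terms for DNA, harmonic chains for
# tails and linker histones, screened Debye-Hueckel electrostatics,
# Lennard-Jones excluded volume, and harmonic genomic restraints.

#' Force-field parameters and environmental conditions
#'
#' All constants of the energy model with physically motivated defaults, each
#' overridable. Units: nm, kcal/mol, elementary charges, radians.
#' Derived fields (`kBT`, `kappa`) are filled in from temperature and salt
#' unless given explicitly.
#'
#' Default stiffnesses are set from experimental DNA mechanics at the 3 nm
#' discretization: the bending constant `g` reproduces a 50 nm persistence
#' length (`g = Lp * kBT / l0`), the torsional constant `s` a torsional
#' rigidity C = 3e-19 erg cm (`s = C / l0`). The DNA bead charge is the
#' charged-cylinder effective value at 150 mM monovalent salt, approximately
#' -24 e per ~9 bp bead; it is an approximation and deliberately exposed.
#'
#' @param temperature kelvin.
#' @param salt monovalent salt concentration, mol/L.
#' @param epsilon_r relative dielectric constant of water.
#' @param l0 DNA segment equilibrium length, nm.
#' @param h DNA stretching constant, kcal/mol/nm^2.
#' @param g DNA bending constant, kcal/mol/rad^2 (default from Lp = 50 nm).
#' @param s DNA torsional constant, kcal/mol/rad^2 (default from
#'   C = 3e-19 erg cm).
#' @param bp_per_turn DNA helical repeat used for twist targets.
#' @param dna_bead_charge effective charge per DNA bead, e.
#' @param k_ev Lennard-Jones excluded-volume prefactor, kcal/mol.
#' @param sigma_core,sigma_dna,sigma_tail,sigma_lh per-element-type contact
#'   diameters, nm (pair sigma is the arithmetic mean).
#' @param cutoff nonbonded interaction cutoff, nm.
#' @param h_tail,g_tail tail stretching/bending constants.
#' @param l0_tail tail/LH bead equilibrium spacing, nm.
#' @param h_lh,g_lh linker-histone CTD stretching/bending constants.
#' @param acetyl_stiffness_factor multiplier on tail h and g for acetylated
#'   cores' tails.
#' @param electrostatics logical master switch for the Debye-Hueckel term.
#' @param kBT,kappa derived thermal energy (kcal/mol) and inverse Debye
#'   length (1/nm); computed when `NULL`.
#' @return an object of class `energy_params` (named list).
#' @export
energy_params <- function(temperature = 293, salt = 0.15, epsilon_r = 80,
                          l0 = 3, h = 100, g = NULL, s = NULL,
                          bp_per_turn = 10.3, dna_bead_charge = -24,
                          k_ev = 0.01, sigma_core = 1.2, sigma_dna = 2.4,
                          sigma_tail = 1.8, sigma_lh = 1.8, cutoff = 7,
                          h_tail = 10, g_tail = 2, l0_tail = 1.5,
                          h_lh = 10, g_lh = 2, acetyl_stiffness_factor = 2,
                          electrostatics = TRUE, kBT = NULL, kappa = NULL) {
  if (is.null(kBT)) kBT <- .mf$kcal_per_K * temperature
  if (is.null(g)) g <- 50 * kBT / l0
  if (is.null(s)) {
    C_torsion <- 3e-19 * 1e-9        # erg cm -> J m
    s <- C_torsion / (l0 * 1e-9)     # J/rad^2 per segment
    s <- s * 6.02214076e23 / 4184    # -> kcal/mol/rad^2
  }
  if (is.null(kappa)) kappa <- debye_kappa(salt, temperature, epsilon_r)
  p <- list(temperature = temperature, salt = salt, epsilon_r = epsilon_r,
            l0 = l0, h = h, g = g, s = s, bp_per_turn = bp_per_turn,
            dna_bead_charge = dna_bead_charge, k_ev = k_ev,
            sigma_core = sigma_core, sigma_dna = sigma_dna,
            sigma_tail = sigma_tail, sigma_lh = sigma_lh, cutoff = cutoff,
            h_tail = h_tail, g_tail = g_tail, l0_tail = l0_tail,
            h_lh = h_lh, g_lh = g_lh,
            acetyl_stiffness_factor = acetyl_stiffness_factor,
            electrostatics = electrostatics, kBT = kBT, kappa = kappa)
  stopifnot(all(vapply(p[c("l0", "h", "g", "s", "kBT", "kappa", "cutoff")],
                       function(x) is.finite(x) && x > 0, TRUE)))
  structure(p, class = "energy_params")
}

#' Inverse Debye screening length
#'
#' `kappa = sqrt(8 pi lB NA I)` for a 1:1 electrolyte, with the Bjerrum
#' length `lB = e^2 / (4 pi eps0 eps_r kB T)`. At 150 mM and 293 K in water
#' this gives ~1.27 1/nm (Debye length ~0.79 nm).
#'
#' @param salt molar concentration of monovalent salt.
#' @param temperature kelvin.
#' @param epsilon_r relative dielectric constant.
#' @return inverse Debye length in 1/nm.
#' @export
debye_kappa <- function(salt, temperature = 293, epsilon_r = 80) {
  e <- 1.602176634e-19; eps0 <- 8.8541878128e-12; kB <- 1.380649e-23
  lB <- e^2 / (4 * pi * eps0 * epsilon_r * kB * temperature) * 1e9  # nm
  rho <- salt * 6.02214076e23 * 1e-24   # ions per nm^3 per species
  sqrt(8 * pi * lB * rho)
}

kind_codes <- c(core = 0L, dna = 1L, tail = 2L, lh_glob = 3L, lh_ctd = 4L)

# Flatten a fiber system into parallel element arrays for the nonbonded
# kernels and the contact analysis. Folded tails are present (they occupy
# space for contact counting) but flagged inactive for energy.
flatten_elements <- function(sys, params = energy_params()) {
  P <- list(); q <- list(); kind <- list(); core_id <- list()
  chain_id <- list(); chain_pos <- list(); excl_core <- list()
  active <- list(); group <- list(); sig <- list()
  idx <- list(core = list(), linker = list(), tail = list(), lh_glob = list(),
              lh_ctd = list())
  m <- 0L
  push <- function(pos, qq, kk, ci, ch, cp, ex, ac, gr, sg) {
    n <- nrow(pos)
    P[[length(P) + 1L]] <<- pos
    q[[length(q) + 1L]] <<- qq
    kind[[length(kind) + 1L]] <<- rep(kk, n)
    core_id[[length(core_id) + 1L]] <<- rep(ci, n)
    chain_id[[length(chain_id) + 1L]] <<- rep(ch, n)
    chain_pos[[length(chain_pos) + 1L]] <<- cp
    excl_core[[length(excl_core) + 1L]] <<- ex
    active[[length(active) + 1L]] <<- rep(ac, n)
    group[[length(group) + 1L]] <<- gr
    sig[[length(sig) + 1L]] <<- rep(sg, n)
    out <- m + seq_len(n)
    m <<- m + n
    out
  }
  for (i in seq_len(sys$n_cores)) {
    cs <- sys$charge_sets[[sys$core_type[i]]]
    pos <- body_to_world(sys$core_pos[i, ], sys$core_frame[[i]], cs[, 1:3])
    idx$core[[i]] <- push(pos, cs[, 4], kind_codes["core"], i, 0L,
                          rep(0L, nrow(pos)), rep(0L, nrow(pos)), TRUE,
                          rep(i, nrow(pos)), params$sigma_core)
  }
  nlk <- length(sys$linkers)
  dna_q <- if (sys$free_chain && !isTRUE(sys$chain_charged)) 0 else params$dna_bead_charge
  for (li in seq_len(nlk)) {
    lk <- sys$linkers[[li]]
    nb <- lk$n_beads
    ex <- integer(nb)
    gr <- integer(nb)
    if (!sys$free_chain) {
      ex[1] <- li
      ex[nb] <- li + 1L
      gr <- ifelse(seq_len(nb) <= nb / 2, li, li + 1L)
    }
    idx$linker[[li]] <- push(lk$pos, rep(dna_q, nb), kind_codes["dna"], 0L,
                             li, seq_len(nb), ex, TRUE, gr, params$sigma_dna)
  }
  ch <- nlk
  for (i in seq_len(sys$n_cores)) {
    idx$tail[[i]] <- vector("list", length(sys$tails[[i]]))
    for (k in seq_along(sys$tails[[i]])) {
      tl <- sys$tails[[i]][[k]]
      ch <- ch + 1L
      nb <- nrow(tl$pos)
      idx$tail[[i]][[k]] <- push(tl$pos, tl$charges, kind_codes["tail"], i,
                                 ch, seq_len(nb), rep(i, nb),
                                 tl$state == "wildtype", rep(i, nb),
                                 params$sigma_tail)
    }
  }
  for (j in seq_along(sys$lhs)) {
    lh <- sys$lhs[[j]]
    ch <- ch + 1L
    idx$lh_glob[[j]] <- push(lh$glob_pos, lh$glob_q, kind_codes["lh_glob"],
                             lh$core, ch, 1:6, rep(lh$core, 6), TRUE,
                             rep(lh$core, 6), params$sigma_lh)
    idx$lh_ctd[[j]] <- push(lh$ctd_pos, lh$ctd_q, kind_codes["lh_ctd"],
                            lh$core, ch, 7:28, rep(0L, 22), TRUE,
                            rep(lh$core, 22), params$sigma_lh)
  }
  list(P = do.call(rbind, P), q = unlist(q), kind = unlist(kind),
       core_id = unlist(core_id), chain_id = unlist(chain_id),
       chain_pos = unlist(chain_pos), excl_core = unlist(excl_core),
       active = unlist(active), group = unlist(group), sigma = unlist(sig),
       idx = idx, n = m)
}

# ---- bonded helpers (per linker / tail / LH chain) -------------------------

seg_lengths <- function(pts) {
  d <- diff(pts)
  sqrt(rowSums(d^2))
}

bend_angles <- function(pts) {
  d <- diff(pts)
  l <- sqrt(rowSums(d^2))
  u <- d / l
  if (nrow(u) < 2) return(numeric(0))
  dots <- rowSums(u[-nrow(u), , drop = FALSE] * u[-1, , drop = FALSE])
  acos(pmin(1, pmax(-1, dots)))
}

# full point sequence of linker li including core attachment sites
linker_points <- function(sys, li) {
  lk <- sys$linkers[[li]]
  if (sys$free_chain) return(lk$pos)
  A <- sys$core_pos[li, ] +
    as.vector(sys$core_frame[[li]] %*% att_exit_local())
  B <- sys$core_pos[li + 1, ] +
    as.vector(sys$core_frame[[li + 1]] %*% att_entry_local())
  rbind(A, lk$pos, B)
}

# frame sequence of linker li (core frames at the ends for attached linkers)
linker_frames <- function(sys, li) {
  lk <- sys$linkers[[li]]
  if (sys$free_chain) return(lk$frames)
  c(list(sys$core_frame[[li]]), lk$frames, list(sys$core_frame[[li + 1]]))
}

# signed twist angles between consecutive frames via parallel transport of
# the material normal (column 2) along the tangent (column 1); vectorized
# Rodrigues rotation over all junctions
frame_twists <- function(frames) {
  n <- length(frames)
  if (n < 2) return(numeric(0))
  if (n <= 6) {
    # scalar path: cheaper than the matrix path for short linkers
    out <- numeric(n - 1)
    for (k in seq_len(n - 1)) {
      t1 <- frames[[k]][, 1]; n1 <- frames[[k]][, 2]
      t2 <- frames[[k + 1]][, 1]; n2 <- frames[[k + 1]][, 2]
      ax <- c(t1[2] * t2[3] - t1[3] * t2[2],
              t1[3] * t2[1] - t1[1] * t2[3],
              t1[1] * t2[2] - t1[2] * t2[1])
      s <- sqrt(sum(ax^2))
      cthe <- sum(t1 * t2)
      n1t <- if (s > 1e-12) {
        a <- ax / s
        n1 * cthe + c(a[2] * n1[3] - a[3] * n1[2],
                      a[3] * n1[1] - a[1] * n1[3],
                      a[1] * n1[2] - a[2] * n1[1]) * s +
          a * sum(a * n1) * (1 - cthe)
      } else n1
      cr <- c(n1t[2] * n2[3] - n1t[3] * n2[2],
              n1t[3] * n2[1] - n1t[1] * n2[3],
              n1t[1] * n2[2] - n1t[2] * n2[1])
      out[k] <- atan2(sum(cr * t2), sum(n1t * n2))
    }
    return(out)
  }
  Tm <- t(vapply(frames, function(f) f[, 1], numeric(3)))
  Nm <- t(vapply(frames, function(f) f[, 2], numeric(3)))
  rowcross <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                                   a[, 3] * b[, 1] - a[, 1] * b[, 3],
                                   a[, 1] * b[, 2] - a[, 2] * b[, 1])
  t1 <- Tm[-n, , drop = FALSE]; t2 <- Tm[-1, , drop = FALSE]
  n1 <- Nm[-n, , drop = FALSE]; n2 <- Nm[-1, , drop = FALSE]
  ax <- rowcross(t1, t2)
  s <- sqrt(rowSums(ax^2))
  cthe <- rowSums(t1 * t2)
  ok <- s > 1e-12
  a <- ax / ifelse(s > 1e-12, s, 1)
  adn <- rowSums(a * n1)
  n1t <- n1 * cthe + rowcross(a, n1) * s + a * adn * (1 - cthe)
  n1t[!ok, ] <- n1[!ok, ]
  atan2(rowSums(rowcross(n1t, n2) * t2), rowSums(n1t * n2))
}

#' Twist targets for every linker
#'
#' Each linker should make `tau = length_bp / bp_per_turn` helical turns.
#' The deviation of `tau` from its nearest integer is a twist penalty angle
#' spread evenly over the linker's segments; linkers whose length is an
#' integral number of turns get a zero penalty angle. The fiber's residual
#' twist (0, -12 or +12 degrees, set per replica) is added to each segment's
#' target.
#'
#' @param sys a `fiber_system`.
#' @param params an [energy_params()] object.
#' @return data.frame with columns `linker`, `length_bp`, `tau` (turns),
#'   `n_seg`, `phi_deg` (per-segment penalty angle, degrees),
#'   `residual_deg`.
#' @export
twist_assignment <- function(sys, params = energy_params()) {
  n <- length(sys$linkers)
  if (n == 0)
    return(data.frame(linker = integer(0), length_bp = numeric(0),
                      tau = numeric(0), n_seg = integer(0),
                      phi_deg = numeric(0), residual_deg = numeric(0)))
  lb <- vapply(sys$linkers, `[[`, 0, "length_bp")
  nb <- vapply(sys$linkers, `[[`, 0L, "n_beads")
  n_seg <- if (sys$free_chain) nb - 1L else nb + 1L
  tau <- lb / params$bp_per_turn
  dev <- tau - round(tau)
  phi <- 2 * pi * dev / n_seg
  data.frame(linker = seq_len(n), length_bp = lb, tau = tau, n_seg = n_seg,
             phi_deg = phi * 180 / pi,
             residual_deg = rep(sys$residual_twist, n))
}

linker_bonded <- function(sys, li, params) {
  pts <- linker_points(sys, li)
  l <- seg_lengths(pts)
  th <- bend_angles(pts)
  tw <- frame_twists(linker_frames(sys, li))
  lb <- sys$linkers[[li]]$length_bp
  tau <- lb / params$bp_per_turn
  phi <- 2 * pi * (tau - round(tau)) / length(tw)
  res <- sys$residual_twist * pi / 180
  c(stretch = sum(0.5 * params$h * (l - params$l0)^2),
    bend = sum(0.5 * params$g * th^2),
    twist = sum(0.5 * params$s * (tw - phi - res)^2))
}

tail_bonded <- function(sys, ci, k, params) {
  tl <- sys$tails[[ci]][[k]]
  if (tl$state == "folded") return(c(stretch = 0, bend = 0))
  fac <- if (sys$acetylated[ci]) params$acetyl_stiffness_factor else 1
  attach <- sys$core_pos[ci, ] +
    as.vector(sys$core_frame[[ci]] %*% tl$attach_local)
  pts <- rbind(attach, tl$pos)
  l <- seg_lengths(pts)
  th <- bend_angles(pts)
  c(stretch = sum(0.5 * fac * params$h_tail * (l - params$l0_tail)^2),
    bend = sum(0.5 * fac * params$g_tail * th^2))
}

lh_bonded <- function(sys, j, params) {
  lh <- sys$lhs[[j]]
  pts <- rbind(lh$glob_pos[nrow(lh$glob_pos), , drop = FALSE], lh$ctd_pos)
  l <- seg_lengths(pts)
  th <- bend_angles(pts)
  c(stretch = sum(0.5 * params$h_lh * (l - params$l0_tail)^2),
    bend = sum(0.5 * params$g_lh * th^2))
}

# ---- exported energy terms -------------------------------------------------

#' Bonded, nonbonded and restraint energy terms
#'
#' `stretching_energy()`, `bending_energy()` and `twisting_energy()` are the
#' wormlike-chain terms over DNA segments (plus harmonic chain terms for
#' wildtype tails and LH C-terminal domains in the stretching/bending sums).
#' `electrostatic_energy()` is the Debye-Hueckel sum over non-excluded
#' charge pairs within the cutoff; `excluded_volume_energy()` the
#' Lennard-Jones 12-6 sum. Folded (acetylated) tails contribute nothing to
#' either nonbonded term. `restraint_energy()` is `sum k (l - l0)^2` over
#' harmonic genomic restraints (no 1/2 prefactor).
#'
#' @param sys a `fiber_system`.
#' @param params an [energy_params()] object.
#' @return energy in kcal/mol.
#' @name energy_terms
NULL

#' @rdname energy_terms
#' @export
stretching_energy <- function(sys, params = energy_params()) {
  e <- 0
  for (li in seq_along(sys$linkers)) e <- e + linker_bonded(sys, li, params)["stretch"]
  for (ci in seq_len(sys$n_cores))
    for (k in seq_along(sys$tails[[ci]]))
      e <- e + tail_bonded(sys, ci, k, params)["stretch"]
  for (j in seq_along(sys$lhs)) e <- e + lh_bonded(sys, j, params)["stretch"]
  unname(e)
}

#' @rdname energy_terms
#' @export
bending_energy <- function(sys, params = energy_params()) {
  e <- 0
  for (li in seq_along(sys$linkers)) e <- e + linker_bonded(sys, li, params)["bend"]
  for (ci in seq_len(sys$n_cores))
    for (k in seq_along(sys$tails[[ci]]))
      e <- e + tail_bonded(sys, ci, k, params)["bend"]
  for (j in seq_along(sys$lhs)) e <- e + lh_bonded(sys, j, params)["bend"]
  unname(e)
}

#' @rdname energy_terms
#' @export
twisting_energy <- function(sys, params = energy_params()) {
  e <- 0
  for (li in seq_along(sys$linkers)) e <- e + linker_bonded(sys, li, params)["twist"]
  unname(e)
}

nonbonded_energy <- function(sys, params = energy_params(), flat = NULL) {
  if (is.null(flat)) flat <- flatten_elements(sys, params)
  ke <- if (params$electrostatics) .mf$coulomb / params$epsilon_r else 0
  res <- nb_total_cpp(flat$P, flat$q, flat$kind, flat$core_id, flat$chain_id,
                      flat$chain_pos, flat$excl_core, as.integer(flat$active),
                      flat$sigma, ke, params$kappa, params$k_ev, params$cutoff)
  if (res$overlaps > 0)
    stop("overlapping identical positions between interacting charges (r = 0)",
         call. = FALSE)
  res
}

#' @rdname energy_terms
#' @export
electrostatic_energy <- function(sys, params = energy_params()) {
  nonbonded_energy(sys, params)$elec
}

#' @rdname energy_terms
#' @export
excluded_volume_energy <- function(sys, params = energy_params()) {
  nonbonded_energy(sys, params)$ev
}

#' @rdname energy_terms
#' @export
restraint_energy <- function(sys) {
  if (!nrow(sys$restraints)) return(0)
  d <- sqrt(rowSums((sys$core_pos[sys$restraints$core_i, , drop = FALSE] -
                     sys$core_pos[sys$restraints$core_j, , drop = FALSE])^2))
  sum(sys$restraints$k * (d - sys$restraints$l0)^2)
}

#' Total potential energy with per-term breakdown
#'
#' @param sys a `fiber_system`.
#' @param params an [energy_params()] object.
#' @return list with `total` (kcal/mol) and `terms`, a named vector
#'   (stretch, bend, twist, elec, ev, restraint) summing exactly to `total`.
#' @export
total_energy <- function(sys, params = energy_params()) {
  nb <- nonbonded_energy(sys, params)
  terms <- c(stretch = stretching_energy(sys, params),
             bend = bending_energy(sys, params),
             twist = twisting_energy(sys, params),
             elec = nb$elec, ev = nb$ev,
             restraint = restraint_energy(sys))
  list(total = sum(terms), terms = terms)
}

# ---- discrete wormlike-chain closed forms ---------------------------------

#' Discrete wormlike-chain reference values
#'
#' For a chain of segments of length `l0` with bending energy
#' `(g/2) theta^2` per joint at thermal energy `kBT`:
#' `wlc_alpha()` is the mean joint cosine `<cos theta>` (numerical
#' integral over the sphere), `wlc_persistence_length()` the persistence
#' length `-l0 / log(alpha)`, and `wlc_mean_square_e2e()` the mean-square
#' end-to-end distance of an `n_seg`-segment chain,
#' `l0^2 * (n (1+a)/(1-a) - 2a(1-a^n)/(1-a)^2)`.
#'
#' @param g bending constant, kcal/mol/rad^2.
#' @param kBT thermal energy, kcal/mol.
#' @param l0 segment length, nm.
#' @param n_seg number of segments.
#' @return numeric scalar.
#' @export
wlc_alpha <- function(g, kBT) {
  b <- g / kBT
  num <- stats::integrate(function(t) cos(t) * sin(t) * exp(-b * t^2 / 2),
                          0, pi, rel.tol = 1e-10)$value
  den <- stats::integrate(function(t) sin(t) * exp(-b * t^2 / 2),
                          0, pi, rel.tol = 1e-10)$value
  num / den
}

#' @rdname wlc_alpha
#' @export
wlc_persistence_length <- function(g, kBT, l0 = 3) {
  -l0 / log(wlc_alpha(g, kBT))
}

#' @rdname wlc_alpha
#' @export
wlc_mean_square_e2e <- function(n_seg, g, kBT, l0 = 3) {
  a <- wlc_alpha(g, kBT)
  l0^2 * (n_seg * (1 + a) / (1 - a) - 2 * a * (1 - a^n_seg) / (1 - a)^2)
}
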