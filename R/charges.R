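#' Synthetic placeholder charge set for a nucleosome core
#'
#' Each nucleosome core carries exactly 300 discrete screened-Coulomb charges
#' fixed in the core body frame. The charge sets used in production work are
#' derived from atomistic nucleosome structures by an external optimization
#' and are supplied as plain-text profile files ([read_charge_profile()]).
#' This generator produces a deterministic synthetic stand-in: 300 sites laid
#' out on the surface of the nucleosome cylinder (radius 5.5 nm, height
#' 5.5 nm) by a golden-angle spiral, each carrying an equal share of the net
#' core charge. By default the three core types receive identical synthetic
#' sets, so in synthetic runs the macroH2A1 variant acts purely through its
#' published histone-tail charge edits; `patch_delta` can add a localized
#' charge perturbation to mimic a variant-specific surface patch.
#'
#' @param core_type "canonical", "macroH2A1" or "hybrid".
#' @param total_charge net core charge in elementary charges (147 bp DNA plus
#'   tailless histone octamer; default -150).
#' @param patch_delta charge (e) redistributed onto the 30 sites nearest the
#'   H2A docking region (z > 0 face), compensated elsewhere; default 0.
#' @return matrix with columns `x`, `y`, `z` (body frame, nm) and `q` (e),
#'   300 rows, with attributes `core_type` and `charge_set_id`.
#' @export
synthetic_core_charges <- function(core_type = c("canonical", "macroH2A1", "hybrid"),
                                   total_charge = -150, patch_delta = 0) {
  core_type <- match.arg(core_type)
  n <- .mf$n_core_charges
  R <- .mf$core_radius
  H <- .mf$core_height
  # deterministic golden-angle layout over the cylinder surface
  # (side plus both caps, area-weighted)
  a_side <- 2 * pi * R * H
  a_cap <- pi * R^2
  n_side <- round(n * a_side / (a_side + 2 * a_cap))
  n_cap <- floor((n - n_side) / 2)
  n_side <- n - 2L * n_cap
  ga <- pi * (3 - sqrt(5))
  i <- seq_len(n_side)
  side <- cbind(R * cos(i * ga), R * sin(i * ga), H * ((i - 0.5) / n_side - 0.5))
  j <- seq_len(n_cap)
  rr <- R * sqrt((j - 0.5) / n_cap)
  top <- cbind(rr * cos(j * ga), rr * sin(j * ga), rep(H / 2, n_cap))
  bot <- cbind(rr * cos(j * ga + 1), rr * sin(j * ga + 1), rep(-H / 2, n_cap))
  xyz <- rbind(side, top, bot)
  q <- rep(total_charge / n, n)
  if (patch_delta != 0) {
    patch <- order(-(xyz[, 3]))[1:30]
    q[patch] <- q[patch] + patch_delta / 30
    q[-patch] <- q[-patch] - patch_delta / (n - 30)
  }
  out <- cbind(xyz, q)
  colnames(out) <- c("x", "y", "z", "q")
  structure(out, core_type = core_type,
            charge_set_id = paste0("synthetic-", core_type))
}

#' Write / read a discrete charge profile as a plain-text table
#'
#' Columns: `id` (profile name), `bead` (1-based index), `charge` (e),
#' `x`, `y`, `z` (body-frame coordinates, nm). The same format is used for
#' core charge sets, tail charge profiles and linker-histone bead profiles.
#'
#' @param charges matrix as returned by [synthetic_core_charges()] (columns
#'   x, y, z, q).
#' @param id profile identifier written in the first column.
#' @param path file path.
#' @return `read_charge_profile()` returns the matrix with `charge_set_id`
#'   attribute; `write_charge_profile()` returns `path` invisibly.
#' @export
write_charge_profile <- function(charges, id, path) {
  df <- data.frame(id = id, bead = seq_len(nrow(charges)),
                   charge = charges[, "q"], x = charges[, "x"],
                   y = charges[, "y"], z = charges[, "z"])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_charge_profile
#' @export
read_charge_profile <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("id", "bead", "charge", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("charge profile must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  df <- df[order(df$bead), ]
  out <- cbind(x = df$x, y = df$y, z = df$z, q = df$charge)
  structure(out, charge_set_id = df$id[1])
}

# The ten histone tails of a core, in a fixed order. Two copies each of the
# N-terminal tails of H2A, H2B, H3, H4 and of the C-terminal tail of H2A.
tail_ids <- function() {
  c("H2A_N.1", "H2A_N.2", "H2A_C.1", "H2A_C.2", "H2B_N.1", "H2B_N.2",
    "H3_N.1", "H3_N.2", "H4_N.1", "H4_N.2")
}

# Per-bead tail charges (e), 5 residues per bead. H2A values are the
# published canonical -> macroH2A1 edits; the other tails are defaults from
# residue composition and are overridable through a tail profile.
.tail_charges <- list(
  canonical = list(H2A_N = c(3, 1, 3, 2), H2A_C = c(1, 0, 2),
                   H2B_N = c(2, 2, 2, 2, 1), H3_N = c(2, 1, 2, 1, 2, 1, 1, 1),
                   H4_N = c(2, 2, 1, 2, 1)),
  macroH2A1 = list(H2A_N = c(1, 3, 2, 1), H2A_C = c(0, 0, 3),
                   H2B_N = c(2, 2, 2, 2, 1), H3_N = c(2, 1, 2, 1, 2, 1, 1, 1),
                   H4_N = c(2, 2, 1, 2, 1))
)

#' Histone tail charge vectors for a core type
#'
#' Canonical cores use H2A N-tail beads (+3, +1, +3, +2) and H2A C-tail
#' beads (+1, 0, +2); macroH2A1 cores use (+1, +3, +2, +1) and (0, 0, +3).
#' A hybrid core applies the macroH2A1 profile to exactly one of its two H2A
#' copies (copy 2 by convention). H2B/H3/H4 N-tails are identical across
#' core types.
#'
#' @param core_type "canonical", "macroH2A1" or "hybrid".
#' @param profile optional named list overriding per-tail-type charge
#'   vectors, e.g. `list(H3_N = rep(1, 8))`; applied to both copies.
#' @return named list of per-bead charge vectors, one entry per tail in
#'   [tail_ids()] order.
#' @export
apply_tail_charges <- function(core_type, profile = NULL) {
  if (!core_type %in% c("canonical", "macroH2A1", "hybrid"))
    stop("unknown core type: ", core_type, call. = FALSE)
  pick <- function(variant, tail) {
    base <- .tail_charges[[variant]][[tail]]
    if (!is.null(profile[[tail]])) profile[[tail]] else base
  }
  variant_of_copy <- function(copy) {
    if (core_type == "hybrid") {
      if (copy == 1) "canonical" else "macroH2A1"
    } else core_type
  }
  out <- list()
  for (id in tail_ids()) {
    parts <- strsplit(id, ".", fixed = TRUE)[[1]]
    tail_type <- parts[1]
    copy <- as.integer(parts[2])
    variant <- if (grepl("^H2A", tail_type)) variant_of_copy(copy) else "canonical"
    out[[id]] <- pick(variant, tail_type)
  }
  out
}

# Synthetic linker histone charge profile: 6 rigid globular-domain beads,
# 22 flexible C-terminal-domain beads, 5 residues per bead. Globular beads
# sit on the dyad face of the host core (body frame); CTD extends outward.
lh_profile <- function() {
  glob_q <- rep(2, 6)       # globular domain, net +12 e
  ctd_q <- rep(2, 22)       # highly basic CTD, net +44 e
  # globular beads stacked along the dyad axis just outside the core surface
  gx <- .mf$core_radius + 1.0
  glob_local <- cbind(x = gx + c(0, 1, 0.5, 1.5, 0.8, 1.8),
                      y = c(0, 0, 1, 1, -1, -1) * 0.8,
                      z = c(0.6, 0.6, -0.6, -0.6, 0, 0))
  list(glob_local = glob_local, glob_q = glob_q, ctd_q = ctd_q,
       n_ctd = 22L, spacing = .mf$tail_l0)
}
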