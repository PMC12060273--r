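# File formats: BED-like position tracks, coarse-bead PDB export/import,
# YAML configs, contact-matrix and metric tables, provenance logs.

#' Read a BED-like nucleosome position track
#'
#' Parses a BED file (0-based half-open intervals, columns
#' chrom/start/end) and returns sorted dyad positions at the interval
#' midpoints.
#'
#' @param path file path.
#' @return data.frame with columns `chrom`, `start`, `end`, `dyad`, sorted
#'   by dyad; zero rows (with a warning) for an empty file.
#' @export
read_bed_track <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("empty BED track: ", path)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), dyad = numeric(0)))
  }
  nf <- vapply(strsplit(lines, "\t| +"), length, 0L)
  if (any(nf < 3))
    stop("malformed BED line ", which(nf < 3)[1], ": fewer than 3 columns",
         call. = FALSE)
  gr <- rtracklayer::import(path, format = "BED")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,  # back to 0-based
                   end = GenomicRanges::end(gr))
  df$dyad <- floor((df$start + df$end) / 2)
  df[order(df$dyad), , drop = FALSE]
}

#' Write a dyad track as BED
#'
#' @param track data.frame with `chrom`, `start`, `end` (0-based half-open)
#'   as produced by [sample_positions()] / [read_bed_track()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed_track <- function(track, path) {
  gr <- GenomicRanges::GRanges(track$chrom,
                               IRanges::IRanges(track$start + 1L, track$end))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Export a fiber as a coarse-bead PDB file
#'
#' One HETATM record per bead, coordinates in Angstrom (nm x 10). Chain IDs
#' distinguish the components: N = nucleosome centers, D = linker DNA,
#' T = histone tails, L = linker histones; the residue number is the
#' nucleosome/linker index. With `include_charges = TRUE` the 300 core
#' surface charges are written too (chain C). Files re-import with
#' [import_pdb_coords()] at PDB precision (0.001 A).
#'
#' @param sys a `fiber_system` (or a snapshot via [snapshot_system()]).
#' @param path output path.
#' @param include_charges write the discrete core charge clouds as well.
#' @return `path`, invisibly.
#' @export
export_pdb <- function(sys, path, include_charges = FALSE) {
  stopifnot(inherits(sys, "fiber_system"))
  xyz <- list(); chain <- c(); resno <- c(); elety <- c()
  add <- function(X, ch, rn, et) {
    if (is.null(dim(X))) X <- matrix(X, ncol = 3)
    xyz[[length(xyz) + 1L]] <<- X
    chain <<- c(chain, rep(ch, nrow(X)))
    resno <<- c(resno, rep(rn, nrow(X)))
    elety <<- c(elety, rep(et, nrow(X)))
  }
  for (i in seq_len(sys$n_cores)) add(sys$core_pos[i, ], "N", i, "NUC")
  for (li in seq_along(sys$linkers))
    add(sys$linkers[[li]]$pos, "D", li, "DNA")
  for (i in seq_len(sys$n_cores))
    for (tl in sys$tails[[i]]) add(tl$pos, "T", i, "TAL")
  for (lh in sys$lhs) {
    add(lh$glob_pos, "L", lh$core, "LHG")
    add(lh$ctd_pos, "L", lh$core, "LHC")
  }
  if (include_charges) {
    for (i in seq_len(sys$n_cores)) {
      cs <- sys$charge_sets[[sys$core_type[i]]]
      add(body_to_world(sys$core_pos[i, ], sys$core_frame[[i]], cs[, 1:3]),
          "C", i, "CHG")
    }
  }
  if (!length(xyz)) stop("empty system: nothing to export", call. = FALSE)
  X <- do.call(rbind, xyz) * 10   # nm -> Angstrom
  n <- nrow(X)
  bio3d::write.pdb(file = path, xyz = as.vector(t(X)),
                   type = rep("HETATM", n), resno = resno, chain = chain,
                   resid = rep("BEA", n), eleno = seq_len(n), elety = elety,
                   o = rep(1, n), b = rep(0, n))
  invisible(path)
}

#' Import coordinates from a coarse-bead PDB
#'
#' @param path a PDB written by [export_pdb()].
#' @return data.frame with `chain`, `resno`, `elety`, and `x`, `y`, `z` in
#'   nm.
#' @export
import_pdb_coords <- function(path) {
  pdb <- bio3d::read.pdb(path)
  a <- pdb$atom
  data.frame(chain = a$chain, resno = a$resno, elety = a$elety,
             x = a$x / 10, y = a$y / 10, z = a$z / 10)
}

#' Write / read a contact matrix
#'
#' `format = "dense"` writes a whitespace-delimited square matrix;
#' `format = "sparse"` a 3-column triplet table (i, j, frequency) of the
#' upper triangle plus diagonal. Both read back bit-exactly.
#'
#' @param mat a `contact_matrix`.
#' @param path file path.
#' @param format "dense" or "sparse".
#' @return read: the `contact_matrix`; write: `path` invisibly.
#' @export
write_contact_matrix <- function(mat, path, format = c("dense", "sparse")) {
  format <- match.arg(format)
  hdr <- sprintf("# contact_matrix n=%d cutoff=%s n_frames=%s format=%s",
                 nrow(mat), format(attr(mat, "cutoff")),
                 format(attr(mat, "n_frames")), format)
  if (format == "dense") {
    con <- file(path, "w")
    writeLines(hdr, con)
    utils::write.table(format(unclass(mat), digits = 17), con,
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
    close(con)
  } else {
    idx <- which(upper.tri(mat, diag = TRUE) & unclass(mat) != 0,
                 arr.ind = TRUE)
    con <- file(path, "w")
    writeLines(hdr, con)
    utils::write.table(data.frame(i = idx[, 1], j = idx[, 2],
                                  v = format(mat[idx], digits = 17)),
                       con, row.names = FALSE, col.names = FALSE, quote = FALSE)
    close(con)
  }
  invisible(path)
}

#' @rdname write_contact_matrix
#' @export
read_contact_matrix <- function(path) {
  hdr <- readLines(path, n = 1)
  get_field <- function(key, mode = "numeric") {
    m <- regmatches(hdr, regexpr(paste0(key, "=[^ ]+"), hdr))
    v <- sub(paste0(key, "="), "", m)
    if (mode == "numeric") as.numeric(v) else v
  }
  n <- as.integer(get_field("n"))
  fmt <- get_field("format", "char")
  if (fmt == "dense") {
    m <- as.matrix(utils::read.table(path, skip = 1))
  } else {
    tr <- utils::read.table(path, skip = 1)
    m <- matrix(0, n, n)
    m[cbind(tr[, 1], tr[, 2])] <- tr[, 3]
    m[cbind(tr[, 2], tr[, 1])] <- tr[, 3]
  }
  dimnames(m) <- NULL
  structure(m, cutoff = get_field("cutoff"), n_frames = get_field("n_frames"),
            class = c("contact_matrix", "matrix"))
}

#' Save / load recipes and energy parameters as YAML
#'
#' @param x a `system_recipe` or `energy_params` object.
#' @param path file path.
#' @return readers return the reconstructed object; writers return `path`
#'   invisibly.
#' @export
write_recipe <- function(x, path) {
  stopifnot(inherits(x, "system_recipe"))
  yaml::write_yaml(unclass(x), path)
  invisible(path)
}

#' @rdname write_recipe
#' @export
read_recipe <- function(path) {
  v <- yaml::read_yaml(path)
  v$acetyl_regions <- lapply(v$acetyl_regions, unlist)
  do.call(system_recipe, v)
}

#' @rdname write_recipe
#' @export
write_energy_params <- function(x, path) {
  stopifnot(inherits(x, "energy_params"))
  yaml::write_yaml(unclass(x), path, precision = 15)
  invisible(path)
}

#' @rdname write_recipe
#' @export
read_energy_params <- function(path) {
  do.call(energy_params, yaml::read_yaml(path))
}

#' Write a provenance log for a run
#'
#' Records the recipe, energy parameters, move set, seeds and package
#' version as YAML so a run can be reproduced from the log alone.
#'
#' @param path output path.
#' @param recipe,params,ms,steps,seeds run inputs.
#' @return `path`, invisibly.
#' @export
write_provenance <- function(path, recipe = NULL, params = NULL, ms = NULL,
                             steps = NULL, seeds = NULL) {
  log <- list(
    package = "mesofiber",
    version = as.character(utils::packageVersion("mesofiber")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    recipe = if (!is.null(recipe)) unclass(recipe),
    energy_params = if (!is.null(params)) unclass(params),
    move_set = if (!is.null(ms)) unclass(ms),
    steps = steps, seeds = seeds)
  yaml::write_yaml(log, path)
  invisible(path)
}

#' Save / load a trajectory
#'
#' Trajectories are plain R objects; persistence uses R serialization.
#' [write_energy_series()] exports the per-snapshot energy breakdown as a
#' delimited text table.
#'
#' @param traj an `mc_trajectory`.
#' @param path file path.
#' @return readers return the object; writers return `path` invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "mc_trajectory"))
  saveRDS(traj, path)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  traj <- readRDS(path)
  stopifnot(inherits(traj, "mc_trajectory"))
  traj
}

#' @rdname write_trajectory
#' @export
write_energy_series <- function(traj, path) {
  utils::write.table(energy_series(traj), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
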