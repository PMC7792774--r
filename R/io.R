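#' Read a coordinate trajectory
#'
#' The mandatory interchange format is multi-model PDB (`MODEL`/`ENDMDL`
#' records, one model per stored frame), parsed with \pkg{bio3d}.
#' Coordinates are converted to nanometres on ingest (PDB files are in
#' Angstrom).  GRO/XTC/DCD adapters are not provided in this build and
#' raise an informative error.
#'
#' @param path file path.
#' @param format one of `"pdb_multimodel"`, `"gro_series"`, `"xtc"`, `"dcd"`.
#' @param stride_ps time between stored frames (ps).
#' @param label system identifier attached to every frame.
#' @return a [trajectory()] object.
#' @export
read_trajectory <- function(path, format = "pdb_multimodel", stride_ps = 10,
                            label = "system") {
  format <- match.arg(format, c("pdb_multimodel", "gro_series", "xtc", "dcd"))
  if (format != "pdb_multimodel")
    stop(sprintf("format '%s' is not supported by this build; use pdb_multimodel",
                 format))
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  check_model_atom_counts(path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  nf <- nrow(xyz)
  na <- ncol(xyz) / 3L
  coords <- array(0, dim = c(na, 3L, nf))
  for (f in seq_len(nf))
    coords[, , f] <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE) * 0.1  # A -> nm
  atoms <- data.frame(residue_id = as.integer(pdb$atom$resno),
                      residue_name = pdb$atom$resid,
                      atom_name = pdb$atom$elety,
                      chain_id = ifelse(is.na(pdb$atom$chain), "A", pdb$atom$chain),
                      stringsAsFactors = FALSE)
  trajectory(coords, atoms, stride_ps = stride_ps, label = label)
}

# Validate that every MODEL block carries the same number of ATOM/HETATM
# records, naming the first offending model; single-structure files (no
# MODEL records) pass trivially.
check_model_atom_counts <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec == "ATOM  " | rec == "HETATM"
  model_starts <- which(rec == "MODEL ")
  if (length(model_starts) <= 1L) return(invisible(TRUE))
  model_of <- findInterval(which(is_atom), model_starts)
  counts <- tabulate(model_of, nbins = length(model_starts))
  bad <- which(counts != counts[1])
  if (length(bad) > 0L)
    stop(sprintf("inconsistent atom count at model %d (%d atoms, expected %d)",
                 bad[1], counts[bad[1]], counts[1]))
  invisible(TRUE)
}

#' Write a trajectory as a multi-model PDB file
#'
#' Inverse of [read_trajectory()]: nm coordinates are converted back to
#' Angstrom.  PDB fixed-width fields limit the round-trip precision to
#' 1e-3 A, i.e. 1e-4 nm per coordinate.
#'
#' @param traj a `loop_traj`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "loop_traj"))
  na <- n_atoms(traj)
  nf <- n_frames(traj)
  xyz <- matrix(0, nrow = nf, ncol = 3L * na)
  for (f in seq_len(nf))
    xyz[f, ] <- as.vector(t(traj$coords[, , f])) * 10  # nm -> A
  atom <- data.frame(type = rep("ATOM", na),
                     eleno = seq_len(na),
                     elety = traj$atoms$atom_name,
                     resid = traj$atoms$residue_name,
                     chain = traj$atoms$chain_id,
                     resno = traj$atoms$residue_id,
                     stringsAsFactors = FALSE)
  bio3d::write.pdb(file = path, xyz = xyz,
                   type = atom$type, resno = atom$resno, resid = atom$resid,
                   eleno = atom$eleno, elety = atom$elety, chain = atom$chain)
  invisible(path)
}

#' Define a named atom selection
#'
#' Selections name residue intervals (inclusive, author numbering) and an
#' atom-name filter; the default filter keeps only C-alpha atoms, matching
#' a backbone-level loop analysis.
#'
#' @param name selection name, e.g. `"loop"` or `"framework"`.
#' @param residue_ranges list of length-2 integer vectors `c(start, end)`,
#'   inclusive on both ends.
#' @param atom_names character vector of atom names to keep (default `"CA"`).
#' @param chain_id optional chain identifier; if `NULL` the first chain
#'   containing matching atoms is used.
#' @return an object of class `loop_selection`.
#' @export
selection <- function(name, residue_ranges, atom_names = "CA", chain_id = NULL) {
  if (is.numeric(residue_ranges)) residue_ranges <- list(residue_ranges)
  stopifnot(is.list(residue_ranges), length(residue_ranges) >= 1L)
  for (r in residue_ranges) {
    if (length(r) != 2L || !is.numeric(r) || r[1] > r[2])
      stop("each residue range must be c(start, end) with start <= end")
  }
  structure(list(name = name,
                 residue_ranges = lapply(residue_ranges, as.integer),
                 atom_names = atom_names,
                 chain_id = chain_id),
            class = "loop_selection")
}

#' Resolve a selection to atom indices
#'
#' Returns the indices (in atom-table order) of atoms whose residue id
#' falls in one of the selection's ranges and whose atom name matches the
#' filter.  Every residue id present in the structure within a selected
#' range must contribute at least one matching atom; a residue with a
#' missing C-alpha is a hard error, never a silent skip.
#'
#' @param traj a `loop_traj`.
#' @param sel a [selection()].
#' @return strictly increasing integer vector of atom indices.
#' @export
resolve_selection <- function(traj, sel) {
  stopifnot(inherits(traj, "loop_traj"), inherits(sel, "loop_selection"))
  at <- traj$atoms
  chain <- sel$chain_id
  if (is.null(chain)) {
    in_range <- rep(FALSE, nrow(at))
    for (r in sel$residue_ranges)
      in_range <- in_range | (at$residue_id >= r[1] & at$residue_id <= r[2])
    hit <- in_range & at$atom_name %in% sel$atom_names
    if (!any(hit)) stop(sprintf("empty selection '%s'", sel$name))
    chain <- at$chain_id[which(hit)[1]]  # first matching chain only
  }
  on_chain <- at$chain_id == chain
  idx <- integer(0)
  for (r in sel$residue_ranges) {
    in_r <- on_chain & at$residue_id >= r[1] & at$residue_id <= r[2]
    present <- sort(unique(at$residue_id[in_r]))
    if (length(present) == 0L) next
    for (res in present) {
      m <- which(in_r & at$residue_id == res & at$atom_name %in% sel$atom_names)
      if (length(m) == 0L)
        stop(sprintf("selection '%s': residue %d has no %s atom",
                     sel$name, res, paste(sel$atom_names, collapse = "/")))
      idx <- c(idx, m)
    }
  }
  idx <- sort(unique(idx))
  if (length(idx) == 0L) stop(sprintf("empty selection '%s'", sel$name))
  idx
}

#' Check that two selections resolve to disjoint atom sets
#'
#' The loop and the framework must not share atoms, otherwise the fitted
#' loop RMSD would partly measure the fitting target itself.
#'
#' @param traj a `loop_traj`.
#' @param sel_a,sel_b two [selection()]s.
#' @return invisibly, a list with both resolved index vectors.
#' @export
resolve_disjoint <- function(traj, sel_a, sel_b) {
  ia <- resolve_selection(traj, sel_a)
  ib <- resolve_selection(traj, sel_b)
  ov <- intersect(ia, ib)
  if (length(ov) > 0L)
    stop(sprintf("selections '%s' and '%s' overlap on %d atom(s)",
                 sel_a$name, sel_b$name, length(ov)))
  invisible(list(a = ia, b = ib))
}

#' Read a pipeline configuration file
#'
#' The configuration is a single YAML file naming the trajectories, the
#' loop and framework residue ranges, and the analysis parameters:
#'
#' ```yaml
#' trajectories:
#'   - {path: apo.pdb, label: apo}
#'   - {path: lig.pdb, label: ligand}
#' loop: [[41, 47]]
#' framework: [[1, 40]]
#' atom_names: [CA]
#' cutoff_nm: 0.15
#' top_n: 25
#' linkage_threshold_nm: 0.30
#' stride_ps: 10
#' prefix_step_ns: 5
#' seed: 0
#' ```
#'
#' @param path YAML file path.
#' @return named list of configuration values with defaults filled in.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
}

validate_config <- function(cfg) {
  if (is.null(cfg$loop)) stop("config missing loop range")
  if (is.null(cfg$framework)) stop("config missing framework range")
  if (is.null(cfg$trajectories) || length(cfg$trajectories) < 1L)
    stop("config names no trajectories")
  defaults <- list(atom_names = "CA", cutoff_nm = 0.15, top_n = 25L,
                   linkage_threshold_nm = 0.30, stride_ps = 10,
                   prefix_step_ns = NULL, seed = 0L, n_restarts = 8L)
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  cfg
}

#' Write / read a distance matrix as plain text
#'
#' Square tab-separated matrix; the header row holds global frame ids
#' (`system:frame`).
#'
#' @param dm a `loop_dm` distance matrix (see [pairwise_matrix()]).
#' @param path output path.
#' @return `path` (write) or a `loop_dm` (read), invisibly for write.
#' @export
write_distance_matrix <- function(dm, path) {
  stopifnot(inherits(dm, "loop_dm"))
  ids <- sprintf("%s:%d", dm$ids$system, dm$ids$frame)
  m <- format(dm$values, digits = 10, trim = TRUE, scientific = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(ids, collapse = "\t"), con)
  write.table(m, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  vals <- as.matrix(read.table(path, skip = 1L, sep = "\t",
                               colClasses = "numeric"))
  dimnames(vals) <- NULL
  parts <- strsplit(header, ":", fixed = TRUE)
  ids <- data.frame(system = vapply(parts, `[`, "", 1L),
                    frame = as.integer(vapply(parts, `[`, "", 2L)),
                    stringsAsFactors = FALSE)
  distance_matrix(vals, ids)
}

# Deterministic TSV writer shared by all result tables (no quoting, fixed
# number formatting, LF endings) so identical inputs give identical bytes.
write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE) & !vapply(df, is.integer, TRUE)
  for (nm in names(df)[num])
    df[[nm]] <- format(df[[nm]], digits = 10, trim = TRUE, scientific = FALSE)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df) > 0L)
    writeLines(do.call(paste, c(unname(as.list(df)), sep = "\t")), con)
  invisible(path)
}
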