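#' Construct a trajectory object
#'
#' A `loop_traj` holds an ordered series of coordinate frames for a fixed
#' set of atoms, together with per-atom metadata, the time spacing between
#' stored frames and a system label.  Coordinates are always stored in
#' nanometres; readers convert on ingest.
#'
#' @param coords numeric array of dimension `c(n_atoms, 3, n_frames)`, in nm.
#'   A single `n_atoms x 3` matrix is promoted to a one-frame trajectory.
#' @param atoms data.frame with one row per atom and columns `residue_id`
#'   (integer author numbering), `residue_name`, `atom_name`, `chain_id`.
#' @param stride_ps time between stored frames, picoseconds (> 0).
#' @param label system identifier string (e.g. `"apo"`).
#'
#' @return An object of class `loop_traj` with elements `coords`, `atoms`,
#'   `stride_ps`, `label`.
#' @export
trajectory <- function(coords, atoms, stride_ps = 10, label = "system") {
  if (is.matrix(coords)) coords <- array(coords, dim = c(dim(coords), 1L))
  stopifnot(is.array(coords), length(dim(coords)) == 3L, dim(coords)[2] == 3L)
  if (!all(is.finite(coords)))
    stop("trajectory coordinates must be finite")
  if (!is.data.frame(atoms) ||
      !all(c("residue_id", "residue_name", "atom_name", "chain_id") %in% names(atoms)))
    stop("'atoms' needs columns residue_id, residue_name, atom_name, chain_id")
  if (nrow(atoms) != dim(coords)[1])
    stop("atom table and coordinate array disagree on atom count")
  if (!is.numeric(stride_ps) || length(stride_ps) != 1L || stride_ps <= 0)
    stop("stride_ps must be a single positive number")
  structure(
    list(coords = coords, atoms = atoms,
         stride_ps = as.numeric(stride_ps), label = as.character(label)),
    class = "loop_traj")
}

#' Number of frames in a trajectory
#' @param traj a `loop_traj`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) {
  stopifnot(inherits(traj, "loop_traj"))
  dim(traj$coords)[3]
}

#' Number of atoms in a trajectory
#' @param traj a `loop_traj`.
#' @return integer atom count.
#' @export
n_atoms <- function(traj) {
  stopifnot(inherits(traj, "loop_traj"))
  dim(traj$coords)[1]
}

#' Extract one frame as an n_atoms x 3 coordinate matrix (nm)
#' @param traj a `loop_traj`.
#' @param i frame index (1-based).
#' @return numeric matrix `n_atoms x 3`.
#' @export
get_frame <- function(traj, i) {
  stopifnot(inherits(traj, "loop_traj"))
  i <- as.integer(i)
  if (i < 1L || i > n_frames(traj)) stop("frame index out of range")
  traj$coords[, , i, drop = TRUE]
}

#' Keep only the first frames of a trajectory
#' @param traj a `loop_traj`.
#' @param n number of leading frames to keep.
#' @return a `loop_traj` with `min(n, n_frames(traj))` frames.
#' @export
head_frames <- function(traj, n) {
  stopifnot(inherits(traj, "loop_traj"))
  n <- min(as.integer(n), n_frames(traj))
  if (n < 1L) stop("need at least one frame")
  trajectory(traj$coords[, , seq_len(n), drop = FALSE], traj$atoms,
             traj$stride_ps, traj$label)
}

#' Concatenate trajectories from several systems
#'
#' Frames keep their system of origin: the result carries a global frame-id
#' table mapping every concatenated frame back to `(system, local frame)`.
#' All inputs must share atom count and ordering (checked on residue id and
#' atom name) and time stride.
#'
#' @param trajs list of `loop_traj` objects.
#' @return list with `coords` (joined array), `ids` (data.frame `system`,
#'   `frame`), `atoms`, `stride_ps`.
#' @export
concatenate_trajectories <- function(trajs) {
  stopifnot(is.list(trajs), length(trajs) >= 1L)
  lapply(trajs, function(t) stopifnot(inherits(t, "loop_traj")))
  ref <- trajs[[1]]
  for (t in trajs[-1]) {
    if (n_atoms(t) != n_atoms(ref) ||
        !identical(t$atoms$residue_id, ref$atoms$residue_id) ||
        !identical(t$atoms$atom_name, ref$atoms$atom_name))
      stop("trajectories do not share atom ordering")
    if (t$stride_ps != ref$stride_ps)
      stop("trajectories do not share time stride")
  }
  coords <- array(0, dim = c(n_atoms(ref), 3L, sum(vapply(trajs, n_frames, 1L))))
  ids <- data.frame(system = character(0), frame = integer(0),
                    stringsAsFactors = FALSE)
  at <- 0L
  for (t in trajs) {
    nf <- n_frames(t)
    coords[, , at + seq_len(nf)] <- t$coords
    ids <- rbind(ids, data.frame(system = rep(t$label, nf),
                                 frame = seq_len(nf),
                                 stringsAsFactors = FALSE))
    at <- at + nf
  }
  list(coords = coords, ids = ids, atoms = ref$atoms, stride_ps = ref$stride_ps)
}

#' @export
print.loop_traj <- function(x, ...) {
  cat(sprintf("<loop_traj '%s': %d frames x %d atoms, stride %.3g ps (%.4g ns total)>\n",
              x$label, n_frames(x), n_atoms(x), x$stride_ps,
              n_frames(x) * x$stride_ps / 1000))
  invisible(x)
}
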