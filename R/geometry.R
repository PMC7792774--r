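#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation `R` and translation `t` minimising the RMSD
#' between `R %*% x + t` over the mobile fit atoms and the corresponding
#' reference atoms.  Reflections are excluded: the returned rotation always
#' has determinant +1, even for near-planar atom sets.
#'
#' @param mobile,reference `n_atoms x 3` coordinate matrices (nm).
#' @param fit_atoms integer indices of the atoms used for fitting
#'   (at least 3, not collinear).
#' @return list of class `fit_result` with `rotation` (3x3), `translation`
#'   (length-3, nm) and `fit_rmsd_nm`.  The fitted mobile frame is
#'   `t(rotation %*% t(x)) + translation` for coordinates `x`.
#' @export
superpose <- function(mobile, reference, fit_atoms) {
  stopifnot(is.matrix(mobile), is.matrix(reference),
            ncol(mobile) == 3L, ncol(reference) == 3L)
  fit_atoms <- as.integer(fit_atoms)
  if (length(fit_atoms) < 3L) stop("need at least 3 fit atoms")
  A <- mobile[fit_atoms, , drop = FALSE]
  B <- reference[fit_atoms, , drop = FALSE]
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2, ca); Bc <- sweep(B, 2, cb)
  s <- svd(crossprod(Ac, Bc))          # 3x3 covariance  M = Ac' Bc
  if (s$d[2] < 1e-10)
    stop("degenerate (collinear) fit-atom configuration")
  sgn <- sign(det(s$v %*% t(s$u)))
  if (sgn == 0) sgn <- 1
  R <- s$v %*% diag(c(1, 1, sgn)) %*% t(s$u)
  t_vec <- cb - as.vector(R %*% ca)
  fitted <- t(R %*% t(Ac))
  rmsd <- sqrt(mean(rowSums((fitted - Bc)^2)))
  structure(list(rotation = R, translation = t_vec, fit_rmsd_nm = rmsd),
            class = "fit_result")
}

#' Apply a fit result to a coordinate frame
#' @param fit a `fit_result` from [superpose()].
#' @param frame `n_atoms x 3` matrix (nm).
#' @return the transformed coordinates.
#' @export
apply_fit <- function(fit, frame) {
  stopifnot(inherits(fit, "fit_result"))
  sweep(t(fit$rotation %*% t(frame)), 2, -fit$translation)
}

#' Framework-fitted loop RMSD between two frames
#'
#' Superposes `frame_a` onto `frame_b` using only `fit_atoms` (the
#' framework), then evaluates the unweighted RMSD
#' \deqn{\mathrm{RMSD} = \sqrt{\frac{1}{N}\sum_{i=1}^{N} \|x_i - y_i\|^2}}
#' over `calc_atoms` (the loop) only.  Because the fit minimises the
#' framework deviation rather than the loop deviation, the statistic
#' isolates loop motion relative to the molecular frame.
#'
#' @param frame_a,frame_b `n_atoms x 3` coordinate matrices (nm).
#' @param fit_atoms atoms used for superposition.
#' @param calc_atoms atoms entering the RMSD sum.
#' @return RMSD in nm (symmetric in its two frames up to numerical noise).
#' @export
loop_rmsd <- function(frame_a, frame_b, fit_atoms, calc_atoms) {
  fit <- superpose(frame_a, frame_b, fit_atoms)
  a <- apply_fit(fit, frame_a[calc_atoms, , drop = FALSE])
  b <- frame_b[calc_atoms, , drop = FALSE]
  sqrt(mean(rowSums((a - b)^2)))
}

#' Loop RMSD time series against a reference frame
#'
#' @param traj a `loop_traj`.
#' @param reference_index frame used as reference (default 1, i.e. the
#'   first stored configuration).
#' @param fit_atoms,calc_atoms see [loop_rmsd()].
#' @return data.frame with `time_ps` and `rmsd_nm`; the entry at the
#'   reference frame is exactly 0.
#' @export
rmsd_timeseries <- function(traj, reference_index = 1L, fit_atoms, calc_atoms) {
  stopifnot(inherits(traj, "loop_traj"))
  reference_index <- as.integer(reference_index)
  if (reference_index < 1L || reference_index > n_frames(traj))
    stop("reference_index out of range")
  ref <- get_frame(traj, reference_index)
  vals <- cpp_rmsd_to_reference(traj$coords, ref,
                                as.integer(fit_atoms) - 1L,
                                as.integer(calc_atoms) - 1L)
  vals[reference_index] <- 0
  data.frame(time_ps = (seq_len(n_frames(traj)) - 1L) * traj$stride_ps,
             rmsd_nm = vals)
}

#' Per-atom root-mean-square fluctuation (RMSF)
#'
#' Each frame is first superposed onto the *first frame of its own
#' trajectory* using `fit_atoms`; the per-atom mean position is then taken
#' over the fitted frames and
#' \deqn{\mathrm{RMSF}(x) = \sqrt{\frac{1}{T}\sum_{t=1}^{T}\|x(t)-\bar x\|^2}}
#' is evaluated for every atom in `atoms`.  With several trajectories
#' (e.g. independent replicate sub-simulations) the per-trajectory RMSFs
#' are combined per atom; the default combines as the root of the mean of
#' squared RMSFs, which preserves the second-moment interpretation, while
#' `aggregate = "mean"` averages the RMSF values directly.
#'
#' @param trajs a `loop_traj` or list of them (shared atom ordering).
#' @param atoms atom indices to report.
#' @param fit_atoms atoms used for the per-frame fit.
#' @param aggregate `"rms"` (default) or `"mean"` across trajectories.
#' @return data.frame with `atom`, `residue_id`, `rmsf_nm`.
#' @export
compute_rmsf <- function(trajs, atoms, fit_atoms, aggregate = c("rms", "mean")) {
  aggregate <- match.arg(aggregate)
  if (inherits(trajs, "loop_traj")) trajs <- list(trajs)
  if (length(trajs) == 0L) stop("empty trajectory list")
  atoms <- as.integer(atoms)
  per_traj <- vapply(trajs, function(tr) {
    stopifnot(inherits(tr, "loop_traj"))
    fitted <- cpp_fit_frames(tr$coords, get_frame(tr, 1L),
                             as.integer(fit_atoms) - 1L)
    xbar <- apply(fitted[atoms, , , drop = FALSE], c(1, 2), mean)
    dev2 <- sweep(fitted[atoms, , , drop = FALSE], c(1, 2), xbar)^2
    sqrt(apply(dev2, 1, mean) * 3)    # mean over (xyz, frames) * 3 = E||d||^2
  }, numeric(length(atoms)))
  per_traj <- matrix(per_traj, nrow = length(atoms))
  rmsf <- if (aggregate == "rms") sqrt(rowMeans(per_traj^2)) else rowMeans(per_traj)
  data.frame(atom = atoms,
             residue_id = trajs[[1]]$atoms$residue_id[atoms],
             rmsf_nm = rmsf)
}
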