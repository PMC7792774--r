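#' Default arc geometry for a synthetic loop
#'
#' Places `n` CA-like points on a semicircular arc with a fixed
#' consecutive-point spacing, anchored at both ends on the x axis.  The
#' anchors define the hinge axis used by [make_templates()]; rotating the
#' arc about that axis leaves the anchors (and hence the connection to the
#' framework) in place.
#'
#' @param n number of loop pseudo-atoms (default 7, a short
#'   immunoglobulin-domain loop).
#' @param spacing consecutive CA-CA distance in nm (default 0.38, the
#'   trans-peptide CA-CA distance).
#' @return `n x 3` coordinate matrix (nm).
#' @export
loop_arc <- function(n = 7L, spacing = 0.38) {
  stopifnot(n >= 3L, spacing > 0)
  dtheta <- pi / (n - 1L)
  rho <- spacing / (2 * sin(dtheta / 2))
  theta <- pi - (seq_len(n) - 1L) * dtheta
  cbind(x = rho * cos(theta), y = rho * sin(theta), z = 0)
}

#' Default rigid framework reference positions
#'
#' A deterministic, clearly non-collinear arrangement: CA-like points on a
#' helical sweep surrounding the loop anchors, mimicking the beta-sandwich
#' scaffold around a loop.  The same `n` always yields the same
#' coordinates, so independently generated systems share their framework.
#'
#' @param n number of framework pseudo-atoms (default 40).
#' @return `n x 3` coordinate matrix (nm).
#' @export
make_framework <- function(n = 40L) {
  stopifnot(n >= 3L)
  t <- seq(0, 4 * pi, length.out = n)
  cbind(x = 1.2 * cos(t), y = 1.2 * sin(t) - 1.5, z = 0.08 * seq_len(n))
}

#' Template loop conformations related by hinge rotation
#'
#' For `kind = "open_turn_overturn"` the base loop is returned together
#' with copies rotated by 90 and 180 degrees about the hinge axis through
#' its two anchor (first and last) atoms -- an idealisation of a loop that
#' swings between an outward-pointing, a turned and an overturned pose.
#' For `kind = "custom"` the supplied templates are passed through
#' unchanged.
#'
#' @param kind `"open_turn_overturn"` or `"custom"`.
#' @param base_loop `n x 3` base loop coordinates (nm); default
#'   [loop_arc()].
#' @param templates list of coordinate matrices, required for
#'   `kind = "custom"`.
#' @param angles_deg rotation angles for the generated kinds (default
#'   `c(0, 90, 180)`).
#' @return list of class `loop_templates`: `coords` (list of K matrices),
#'   `names`, and `pairwise_rmsd_nm` (K x K matrix of plain loop RMSDs,
#'   the separations a clustering must resolve).
#' @export
make_templates <- function(kind = c("open_turn_overturn", "custom"),
                           base_loop = loop_arc(),
                           templates = NULL,
                           angles_deg = c(0, 90, 180)) {
  kind <- match.arg(kind)
  if (kind == "custom") {
    stopifnot(is.list(templates), length(templates) >= 1L)
    coords <- templates
    nms <- if (!is.null(names(templates))) names(templates)
           else sprintf("template%d", seq_along(templates))
  } else {
    stopifnot(is.matrix(base_loop), ncol(base_loop) == 3L,
              nrow(base_loop) >= 3L)
    a1 <- base_loop[1, ]
    a2 <- base_loop[nrow(base_loop), ]
    axis <- a2 - a1
    if (sqrt(sum(axis^2)) < 1e-9)
      stop("degenerate hinge: loop anchor atoms coincide")
    coords <- lapply(angles_deg, function(ang)
      rotate_about_axis(base_loop, a1, axis, ang * pi / 180))
    nms <- c("open", "turned", "overturned")[seq_along(angles_deg)]
    nms[is.na(nms)] <- sprintf("rot%g", angles_deg[is.na(nms)])
  }
  K <- length(coords)
  prmsd <- matrix(0, K, K, dimnames = list(nms, nms))
  for (i in seq_len(K)) for (j in seq_len(K))
    prmsd[i, j] <- sqrt(mean(rowSums((coords[[i]] - coords[[j]])^2)))
  structure(list(coords = coords, names = nms, pairwise_rmsd_nm = prmsd),
            class = "loop_templates")
}

# Rodrigues rotation of points about the axis through `origin` with
# direction `axis` by `angle` radians.
rotate_about_axis <- function(x, origin, axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
  sweep(tcrossprod(sweep(x, 2, origin), R), 2, -origin)
}

#' Configuration for a synthetic loop-switching trajectory
#'
#' Describes the statistical structure the analysis assumes: a rigid
#' framework with weak isotropic jitter, and a loop that hops among K
#' template conformations under a first-order Markov chain, with
#' isotropic Gaussian coordinate noise around the active template.  Two
#' frames in the same state then differ by an expected loop RMSD of about
#' `noise_sigma_nm * sqrt(6)` (two independent sigma-jittered copies in
#' 3D), which is recorded so cutoff choices can be made principled:
#' clusters resolve states whenever the minimum template separation
#' comfortably exceeds that noise scale and the cutoff lies between the
#' two.
#'
#' @param templates a `loop_templates` object (or list of K loop
#'   coordinate matrices).
#' @param transition_matrix K x K row-stochastic matrix.
#' @param initial_state starting state index, or `"stationary"` to draw
#'   it from the stationary distribution of the chain.
#' @param n_frames number of stored frames.
#' @param noise_sigma_nm per-coordinate Gaussian noise on loop atoms
#'   (default 0.03).
#' @param framework_sigma_nm per-coordinate jitter on framework atoms
#'   (default 0.01).
#' @param n_framework_atoms framework size (default 40).
#' @param stride_ps time between stored frames (default 10 ps).
#' @param seed RNG seed.
#' @param rigid_motion_per_frame if `TRUE`, a random global rotation and
#'   translation is applied to every frame (the framework fit must remove
#'   it).
#' @param label system label.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(templates, transition_matrix,
                         initial_state = "stationary",
                         n_frames = 2000L,
                         noise_sigma_nm = 0.03,
                         framework_sigma_nm = 0.01,
                         n_framework_atoms = 40L,
                         stride_ps = 10,
                         seed = 0L,
                         rigid_motion_per_frame = FALSE,
                         label = "synthetic") {
  if (inherits(templates, "loop_templates")) tl <- templates$coords
  else tl <- templates
  stopifnot(is.list(tl), length(tl) >= 1L)
  K <- length(tl)
  P <- as.matrix(transition_matrix)
  if (nrow(P) != K || ncol(P) != K)
    stop("transition matrix must be K x K for K templates")
  if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-12))
    stop("transition matrix rows must be non-negative and sum to 1")
  n_loop <- nrow(tl[[1]])
  for (t in tl) stopifnot(nrow(t) == n_loop, ncol(t) == 3L)
  min_sep <- if (K > 1) {
    seps <- outer(seq_len(K), seq_len(K), Vectorize(function(i, j)
      sqrt(mean(rowSums((tl[[i]] - tl[[j]])^2)))))
    min(seps[upper.tri(seps)])
  } else Inf
  structure(list(templates = tl,
                 template_names = if (inherits(templates, "loop_templates"))
                   templates$names else sprintf("template%d", seq_len(K)),
                 transition_matrix = P,
                 initial_state = initial_state,
                 n_frames = as.integer(n_frames),
                 noise_sigma_nm = noise_sigma_nm,
                 framework_sigma_nm = framework_sigma_nm,
                 n_framework_atoms = as.integer(n_framework_atoms),
                 stride_ps = stride_ps,
                 seed = as.integer(seed),
                 rigid_motion_per_frame = isTRUE(rigid_motion_per_frame),
                 label = label,
                 min_template_rmsd_nm = min_sep,
                 expected_noise_rmsd_nm = noise_sigma_nm * sqrt(6)),
            class = "synth_config")
}

#' Stationary distribution of a finite Markov chain
#' @param P row-stochastic transition matrix.
#' @return stationary probability vector.
#' @export
stationary_distribution <- function(P) {
  e <- eigen(t(P))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  v / sum(v)
}

sample_markov <- function(P, n, initial_state) {
  K <- nrow(P)
  s <- integer(n)
  if (identical(initial_state, "stationary")) {
    pi0 <- stationary_distribution(P)
    s[1] <- sample.int(K, 1L, prob = pi0)
  } else {
    s[1] <- as.integer(initial_state)
    stopifnot(s[1] >= 1L, s[1] <= K)
  }
  if (n > 1L)
    for (t in 2:n) s[t] <- sample.int(K, 1L, prob = P[s[t - 1L], ])
  s
}

#' Simulate a synthetic loop-switching trajectory
#'
#' Samples a hidden state path from the configured Markov chain and emits
#' frames in which the framework jitters weakly around its fixed
#' reference positions while the loop sits on the active template plus
#' isotropic Gaussian noise.  Optionally every frame is subjected to a
#' random global rigid motion, which exercises (and must be removed by)
#' the framework fitting of the analysis.  Fully reproducible from the
#' seed.
#'
#' @param cfg a [synth_config()].
#' @return list with `trajectory` (a `loop_traj`; framework atoms first,
#'   then loop atoms), `states` (integer state path), `state_names`,
#'   `loop_atoms` and `framework_atoms` (index vectors), and `config`.
#' @export
simulate_system <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  n_fw <- cfg$n_framework_atoms
  n_loop <- nrow(cfg$templates[[1]])
  na <- n_fw + n_loop
  nf <- cfg$n_frames
  fw_ref <- make_framework(n_fw)
  states <- sample_markov(cfg$transition_matrix, nf, cfg$initial_state)
  # conformational noise is drawn before any rigid-motion randomness, so
  # runs with and without per-frame rigid motion share their conformations
  fw_noise <- array(rnorm(n_fw * 3L * nf, sd = cfg$framework_sigma_nm),
                    dim = c(n_fw, 3L, nf))
  loop_noise <- array(rnorm(n_loop * 3L * nf, sd = cfg$noise_sigma_nm),
                      dim = c(n_loop, 3L, nf))
  coords <- array(0, dim = c(na, 3L, nf))
  for (f in seq_len(nf)) {
    coords[, , f] <- rbind(fw_ref + fw_noise[, , f],
                           cfg$templates[[states[f]]] + loop_noise[, , f])
  }
  if (cfg$rigid_motion_per_frame) {
    for (f in seq_len(nf)) {
      q <- rnorm(4)
      R <- quaternion_rotation(q / sqrt(sum(q^2)))
      shift <- rnorm(3, sd = 0.5)
      coords[, , f] <- sweep(tcrossprod(coords[, , f], R), 2, -shift)
    }
  }
  atoms <- data.frame(
    residue_id = c(seq_len(n_fw), n_fw + seq_len(n_loop)),
    residue_name = "ALA",
    atom_name = "CA",
    chain_id = "A",
    stringsAsFactors = FALSE)
  list(trajectory = trajectory(coords, atoms, cfg$stride_ps, cfg$label),
       states = states,
       state_names = cfg$template_names[states],
       framework_atoms = seq_len(n_fw),
       loop_atoms = n_fw + seq_len(n_loop),
       config = cfg)
}

quaternion_rotation <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Four-system study scenario with planted loop conformations
#'
#' A desk-scale emulation of a four-system loop-dynamics study: an
#' unbound receptor and three liganded systems, each a 2,000-frame
#' trajectory stored every 10 ps, sharing one framework and the three
#' hinge-rotation templates of [make_templates()]:
#' \describe{
#'   \item{apo}{switches between `open` and `turned` with stationary
#'     occupancy 0.2 / 0.8; switching is fast relative to the storage
#'     stride, so stored frames are effectively independent draws from
#'     the stationary mix.}
#'   \item{ligand}{natural-ligand analogue, confined to `turned`.}
#'   \item{ab1}{first antibody analogue, also confined to `turned`.}
#'   \item{ab2}{second antibody analogue, mostly `overturned` with brief
#'     visits to `turned` (stationary 0.9 / 0.1).}
#' }
#' Loop noise is 0.03 nm per coordinate (expected same-state RMSD about
#' 0.073 nm), framework jitter 0.01 nm; the minimum template separation
#' (about 0.68 nm) is far above both the noise scale and the default
#' 0.15 nm clustering cutoff, so state recovery is well-posed.
#'
#' Each system draws from its own RNG stream, derived from the master
#' seed by a fixed per-system offset, so adding or dropping a system
#' never perturbs the others.
#'
#' @param seed master seed.
#' @param systems subset of `c("apo", "ligand", "ab1", "ab2")` to
#'   generate (default all four).
#' @param n_frames frames per system (default 2000).
#' @return list of per-system results as returned by [simulate_system()],
#'   plus `templates` and `atoms` metadata at the top level.
#' @export
make_study_scenario <- function(seed = 0L,
                                systems = c("apo", "ligand", "ab1", "ab2"),
                                n_frames = 2000L) {
  systems <- match.arg(systems, several.ok = TRUE)
  tmpl <- make_templates("open_turn_overturn")
  specs <- list(
    apo = list(states = c(1L, 2L),
               P = matrix(c(0.2, 0.8, 0.2, 0.8), 2, byrow = TRUE),
               offset = 1000L),
    ligand = list(states = 2L, P = matrix(1, 1, 1), offset = 2000L),
    ab1 = list(states = 2L, P = matrix(1, 1, 1), offset = 3000L),
    ab2 = list(states = c(2L, 3L),
               P = matrix(c(0.55, 0.45, 0.05, 0.95), 2, byrow = TRUE),
               offset = 4000L))
  out <- list()
  for (nm in systems) {
    sp <- specs[[nm]]
    sub <- make_templates("custom",
                          templates = setNames(tmpl$coords[sp$states],
                                               tmpl$names[sp$states]))
    cfg <- synth_config(sub, sp$P, initial_state = "stationary",
                        n_frames = n_frames, seed = seed + sp$offset,
                        label = nm)
    out[[nm]] <- simulate_system(cfg)
  }
  out$templates <- tmpl
  out
}

#' Growing-sampling scenario for the convergence diagnostic
#'
#' One synthetic system whose loop explores only two template
#' conformations for the first three quarters of the run and first
#' reaches the third template in the final quarter.  The cluster-count
#' convergence curve over growing prefixes must therefore step up at the
#' prefix that first covers the late segment and stay flat afterwards.
#'
#' @param seed RNG seed.
#' @param n_frames total frames (default 2000); the third state appears
#'   from frame `3/4 * n_frames + 1` on.
#' @return as [simulate_system()], with `states` over the full run and
#'   `switch_frame` (first frame of the three-state segment).
#' @export
make_convergence_scenario <- function(seed = 0L, n_frames = 2000L) {
  tmpl <- make_templates("open_turn_overturn")
  n1 <- as.integer(3 * n_frames / 4)
  n2 <- n_frames - n1
  two <- make_templates("custom",
                        templates = setNames(tmpl$coords[1:2], tmpl$names[1:2]))
  cfg1 <- synth_config(two, matrix(c(0.3, 0.7, 0.3, 0.7), 2, byrow = TRUE),
                       initial_state = "stationary", n_frames = n1,
                       seed = seed + 11L, label = "grow")
  s1 <- simulate_system(cfg1)
  cfg2 <- synth_config(tmpl,
                       matrix(c(0.2, 0.4, 0.4,
                                0.2, 0.4, 0.4,
                                0.1, 0.1, 0.8), 3, byrow = TRUE),
                       initial_state = 3L, n_frames = n2,
                       seed = seed + 12L, label = "grow")
  s2 <- simulate_system(cfg2)
  coords <- array(0, dim = c(n_atoms(s1$trajectory), 3L, n_frames))
  coords[, , seq_len(n1)] <- s1$trajectory$coords
  coords[, , n1 + seq_len(n2)] <- s2$trajectory$coords
  traj <- trajectory(coords, s1$trajectory$atoms,
                     s1$trajectory$stride_ps, "grow")
  list(trajectory = traj,
       states = c(s1$states, s2$states),
       state_names = c(s1$state_names, s2$state_names),
       framework_atoms = s1$framework_atoms,
       loop_atoms = s1$loop_atoms,
       switch_frame = n1 + 1L)
}

#' Write a generated scenario to disk
#'
#' One multi-model PDB per system plus a `labels.tsv` with the planted
#' per-frame states, so an on-disk run of the pipeline can be scored
#' against ground truth.
#'
#' @param scenario result of [make_study_scenario()].
#' @param out_dir output directory.
#' @return invisibly, the written file paths.
#' @export
write_scenario <- function(scenario, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  labels <- list()
  for (nm in setdiff(names(scenario), c("templates", "atoms"))) {
    sys <- scenario[[nm]]
    p <- file.path(out_dir, paste0(nm, ".pdb"))
    write_trajectory(sys$trajectory, p)
    files <- c(files, p)
    labels[[nm]] <- data.frame(system = nm,
                               frame = seq_along(sys$states),
                               state = sys$state_names,
                               stringsAsFactors = FALSE)
  }
  lp <- file.path(out_dir, "labels.tsv")
  write_tsv(do.call(rbind, labels), lp)
  invisible(c(files, lp))
}
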