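# Independent oracles used throughout the suite.  These deliberately take
# different algorithmic routes from the package code: quaternion (Horn)
# eigendecomposition instead of SVD-based Kabsch, plain nested loops
# instead of vectorised greedy clustering.

# Horn's closed-form absolute-orientation solution: the optimal proper
# rotation is the unit quaternion maximising the correlation, found as the
# top eigenvector of the 4x4 key matrix.
horn_transform <- function(mobile, reference, fit) {
  A <- mobile[fit, , drop = FALSE]
  B <- reference[fit, , drop = FALSE]
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2, ca); Bc <- sweep(B, 2, cb)
  S <- crossprod(Ac, Bc)
  Sxx <- S[1,1]; Sxy <- S[1,2]; Sxz <- S[1,3]
  Syx <- S[2,1]; Syy <- S[2,2]; Syz <- S[2,3]
  Szx <- S[3,1]; Szy <- S[3,2]; Szz <- S[3,3]
  N <- matrix(c(
    Sxx+Syy+Szz, Syz-Szy,     Szx-Sxz,     Sxy-Syx,
    Syz-Szy,     Sxx-Syy-Szz, Sxy+Syx,     Szx+Sxz,
    Szx-Sxz,     Sxy+Syx,    -Sxx+Syy-Szz, Syz+Szy,
    Sxy-Syx,     Szx+Sxz,     Syz+Szy,    -Sxx-Syy+Szz), 4, 4, byrow = TRUE)
  ev <- eigen(N, symmetric = TRUE)
  lambda <- ev$values[1]
  q <- ev$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(1-2*(y^2+z^2), 2*(x*y-w*z), 2*(x*z+w*y),
                2*(x*y+w*z), 1-2*(x^2+z^2), 2*(y*z-w*x),
                2*(x*z-w*y), 2*(y*z+w*x), 1-2*(x^2+y^2)), 3, 3, byrow = TRUE)
  ss <- sum(Ac^2) + sum(Bc^2) - 2 * lambda
  list(R = R, ca = ca, cb = cb,
       fit_rmsd = sqrt(max(ss, 0) / nrow(A)))
}

# Direct-summation loop RMSD: Horn superposition on the fit atoms, then
# the explicit per-atom sum over the calc atoms.
oracle_loop_rmsd <- function(frame_a, frame_b, fit, calc) {
  tr <- horn_transform(frame_a, frame_b, fit)
  fitted <- sweep(sweep(frame_a, 2, tr$ca) %*% t(tr$R), 2, -tr$cb)
  s <- 0
  for (k in calc) s <- s + sum((fitted[k, ] - frame_b[k, ])^2)
  sqrt(s / length(calc))
}

# Naive transcription of the four enumerated greedy clustering steps.
naive_daura <- function(values, cutoff) {
  remaining <- seq_len(nrow(values))
  clusters <- list()
  while (length(remaining) > 0) {
    # step 1+2: each remaining structure is a candidate centre; its
    # neighbors are the *other* remaining structures below the cutoff
    best_center <- NA_integer_
    best_count <- -1L
    for (i in remaining) {
      cnt <- sum(values[i, remaining] < cutoff) - 1L  # drop self (d = 0)
      if (cnt > best_count) {   # ties: first (lowest index) wins
        best_count <- cnt
        best_center <- i
      }
    }
    # step 3: centre plus neighbors form the cluster and leave the pool
    members <- union(best_center,
                     remaining[values[best_center, remaining] < cutoff])
    clusters[[length(clusters) + 1]] <-
      list(center = best_center, members = sort(members))
    remaining <- setdiff(remaining, members)
    # step 4: repeat
  }
  clusters
}

# Direct-summation per-atom RMSF after fitting each frame to the first
# frame with the package's own superposition (the statistic under test is
# the fluctuation formula, not the fit).
oracle_rmsf <- function(traj, atoms, fit_atoms) {
  nf <- n_frames(traj)
  fitted <- lapply(seq_len(nf), function(f) {
    fr <- get_frame(traj, f)
    apply_fit(superpose(fr, get_frame(traj, 1), fit_atoms), fr)
  })
  vapply(atoms, function(a) {
    xs <- t(vapply(fitted, function(fr) fr[a, ], numeric(3)))
    xbar <- colMeans(xs)
    sqrt(mean(rowSums(sweep(xs, 2, xbar)^2)))
  }, numeric(1))
}

# Random symmetric distance matrix with zero diagonal.
random_distance_values <- function(n, max_d = 1) {
  v <- matrix(runif(n * n, 0, max_d), n, n)
  v <- (v + t(v)) / 2
  diag(v) <- 0
  v
}

# Random rigid motion applied to a whole frame.
random_rigid <- function(frame) {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(1-2*(y^2+z^2), 2*(x*y-w*z), 2*(x*z+w*y),
                2*(x*y+w*z), 1-2*(x^2+z^2), 2*(y*z-w*x),
                2*(x*z-w*y), 2*(y*z+w*x), 1-2*(x^2+y^2)), 3, 3, byrow = TRUE)
  sweep(frame %*% t(R), 2, -rnorm(3))
}

# Hand-written multi-model PDB fixture (independent of the package's
# writer).  coords_nm: list of n_atoms x 3 matrices.
write_fixture_pdb <- function(path, coords_nm, resno = NULL) {
  lines <- character(0)
  n <- nrow(coords_nm[[1]])
  if (is.null(resno)) resno <- seq_len(n)
  for (m in seq_along(coords_nm)) {
    lines <- c(lines, sprintf("MODEL     %4d", m))
    ang <- coords_nm[[m]] * 10
    for (i in seq_len(n))
      lines <- c(lines, sprintf(
        "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        i, resno[i], ang[i, 1], ang[i, 2], ang[i, 3]))
    lines <- c(lines, "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  path
}

# CA-only chain trajectory with author numbering resno, single frame of
# arbitrary coordinates.
chain_traj <- function(resno, atom_name = "CA", chain = "A") {
  n <- length(resno)
  atoms <- data.frame(residue_id = resno,
                      residue_name = "ALA",
                      atom_name = atom_name,
                      chain_id = chain,
                      stringsAsFactors = FALSE)
  trajectory(matrix(rnorm(3 * n), n, 3), atoms, 10, "chain")
}

# Build a daura_clustering object directly (for bookkeeping tests where
# the partition itself is prescribed).
manual_clustering <- function(member_systems, cutoff = 0.15) {
  ids <- data.frame(system = unlist(member_systems),
                    frame = unlist(lapply(member_systems, seq_along)),
                    stringsAsFactors = FALSE)
  offs <- c(0, cumsum(vapply(member_systems, length, 1L)))
  clusters <- lapply(seq_along(member_systems), function(k) {
    idx <- offs[k] + seq_along(member_systems[[k]])
    list(center = idx[1], members = idx)
  })
  structure(list(clusters = clusters, cutoff_nm = cutoff, ids = ids),
            class = "daura_clustering")
}

# Partition agreement (adjusted Rand index) via mclust.
ari <- function(a, b) mclust::adjustedRandIndex(a, b)
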