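#' Non-metric multidimensional scaling of central structures
#'
#' Embeds the central structures of the largest clusters into a
#' low-dimensional (by default 2D) space whose inter-point distances mimic
#' the rank order of the input loop RMSDs, so that groups of mutually
#' similar clusters appear as groups of nearby points.
#'
#' The fit alternates stress majorization (Guttman transform) with
#' monotone (isotonic, pool-adjacent-violators) regression of the embedded
#' distances on the dissimilarity order; ties in the dissimilarities are
#' handled by Kruskal's primary approach (no order constraint within a tie
#' block).  Goodness of fit is Kruskal's stress-1,
#' \deqn{\sigma_1 = \sqrt{\sum_{i<j} (d_{ij} - \hat d_{ij})^2 /
#'       \sum_{i<j} d_{ij}^2},}
#' with \eqn{d_{ij}} the embedded distances and \eqn{\hat d_{ij}} the
#' monotone disparities.  The first start is the classical (Torgerson)
#' scaling solution; the remaining starts are random.  The lowest-stress
#' solution over all starts is returned, centred at the origin.  The
#' configuration is determined only up to rotation/reflection, so
#' downstream comparisons should use its distance matrix, not raw
#' coordinates.
#'
#' @param dm a `loop_dm` of central-structure RMSDs (at least 3 points).
#' @param dims embedding dimension (default 2).
#' @param seed RNG seed for the random restarts (default 0).
#' @param n_restarts number of starts including the classical-scaling
#'   start (default 8).
#' @param max_iter,tol iteration cap and relative stress-change
#'   convergence tolerance per start.
#' @return object of class `loop_mds`: list with `points` (m x dims),
#'   `stress`, `input_ids`, `seed`, `n_restarts`, `restart_stress`
#'   (final stress of every start) and `stress_trace` (per-iteration
#'   stress of the winning start, non-increasing).
#' @export
nonmetric_mds <- function(dm, dims = 2L, seed = 0L, n_restarts = 8L,
                          max_iter = 500L, tol = 1e-6) {
  stopifnot(inherits(dm, "loop_dm"))
  m <- nrow(dm$values)
  if (m < 3L) stop("need at least 3 structures for MDS")
  d <- dm$values[lower.tri(dm$values)]
  ids <- sprintf("%s:%d", dm$ids$system, dm$ids$frame)
  if (all(d < 1e-12)) {
    pts <- matrix(0, m, dims)
    return(structure(list(points = pts, stress = 0, input_ids = ids,
                          seed = seed, n_restarts = n_restarts,
                          restart_stress = numeric(0),
                          stress_trace = 0),
                     class = "loop_mds"))
  }
  best <- NULL
  restart_stress <- numeric(n_restarts)
  scale0 <- mean(d)
  for (r in seq_len(n_restarts)) {
    if (r == 1L) {
      X0 <- cmdscale(stats::as.dist(dm$values), k = dims)
      if (ncol(X0) < dims)
        X0 <- cbind(X0, matrix(0, m, dims - ncol(X0)))
    } else {
      set.seed(seed + r - 1L)
      X0 <- matrix(rnorm(m * dims, sd = scale0), m, dims)
    }
    run <- smacof_run(d, X0, m, dims, max_iter, tol)
    restart_stress[r] <- run$stress
    # sub-epsilon stress differences are ties; the earliest start wins
    if (is.null(best) || run$stress < best$stress - 1e-12) best <- run
  }
  pts <- sweep(best$X, 2, colMeans(best$X))
  structure(list(points = pts, stress = best$stress, input_ids = ids,
                 seed = seed, n_restarts = n_restarts,
                 restart_stress = restart_stress,
                 stress_trace = best$trace),
            class = "loop_mds")
}

# One majorization run from a fixed start.  Keeps the best iterate: if an
# iteration fails to decrease stress it stops and returns the previous
# configuration, so the reported stress trace is non-increasing.
smacof_run <- function(d, X, m, dims, max_iter, tol) {
  ii <- which(lower.tri(matrix(0, m, m)), arr.ind = TRUE)
  trace <- numeric(0)
  prev_stress <- Inf
  prev_X <- X
  for (iter in seq_len(max_iter)) {
    D <- as.vector(stats::dist(X))
    dhat <- monotone_disparities(d, D)
    stress <- sqrt(sum((D - dhat)^2) / sum(D^2))
    if (stress > prev_stress + 1e-12) {          # monotonicity guard
      X <- prev_X
      break
    }
    trace <- c(trace, stress)
    converged <- is.finite(prev_stress) &&
      (prev_stress - stress) < tol * max(prev_stress, 1e-300)
    prev_stress <- stress
    prev_X <- X
    if (converged || stress < 1e-12) break
    # Guttman transform: X+ = B(X) X / m with b_ij = -dhat_ij / D_ij
    ratio <- ifelse(D > 1e-12, dhat / D, 0)
    B <- matrix(0, m, m)
    B[ii] <- -ratio
    B <- B + t(B)
    diag(B) <- -rowSums(B)
    X <- (B %*% X) / m
  }
  list(X = prev_X, stress = prev_stress, trace = trace)
}

# Isotonic (PAVA) regression of embedded distances on the dissimilarity
# order; primary approach to ties: within a block of tied dissimilarities
# the distances are pre-sorted, so no order is enforced inside the block.
monotone_disparities <- function(d, D) {
  o <- order(d, D)
  fit <- stats::isoreg(seq_along(D), D[o])
  dhat <- numeric(length(D))
  dhat[o] <- fit$yf
  dhat
}

#' @export
print.loop_mds <- function(x, ...) {
  cat(sprintf("<loop_mds: %d points in %dD, stress-1 %.4g (%d starts)>\n",
              nrow(x$points), ncol(x$points), x$stress, x$n_restarts))
  invisible(x)
}

#' Group clusters into meta-clusters
#'
#' The hand-drawn step of delineating groups of clusters on the 2D map is
#' automated by average-linkage agglomerative grouping *on the
#' central-structure RMSD matrix itself* (not on the 2D projection, which
#' is only a display proxy).  Two groups merge while their average
#' inter-centre RMSD is strictly below the threshold; a pair at exactly
#' the threshold stays separate.
#'
#' @param dm a `loop_dm` of central-structure RMSDs.
#' @param linkage_threshold_nm cut height in nm (default 0.30, twice the
#'   default clustering cutoff: two clusters whose centres are within two
#'   cutoff radii can share boundary structures).
#' @param sizes optional member counts of the clusters behind each central
#'   structure; meta-clusters are labelled 1, 2, ... by decreasing total
#'   member count (default: every centre counts 1).
#' @return object of class `meta_clustering`: list with `groups` (integer
#'   meta-cluster index per central structure), `linkage_threshold_nm`,
#'   `ids`.
#' @export
metacluster <- function(dm, linkage_threshold_nm = 0.30, sizes = NULL) {
  stopifnot(inherits(dm, "loop_dm"))
  if (!is.numeric(linkage_threshold_nm) || linkage_threshold_nm <= 0)
    stop("linkage threshold must be positive")
  m <- nrow(dm$values)
  if (is.null(sizes)) sizes <- rep(1L, m)
  stopifnot(length(sizes) == m)
  if (m == 1L) {
    grp <- 1L
  } else {
    tree <- hclust(stats::as.dist(dm$values), method = "average")
    k <- m - sum(tree$height < linkage_threshold_nm)  # strict < merges
    grp <- cutree(tree, k = k)
  }
  tot <- tapply(sizes, grp, sum)
  new_lab <- rank(-tot, ties.method = "first")        # 1 = biggest group
  grp <- as.integer(new_lab[as.character(grp)])
  structure(list(groups = grp,
                 linkage_threshold_nm = linkage_threshold_nm,
                 ids = dm$ids),
            class = "meta_clustering")
}

#' Per-meta-cluster, per-system composition
#'
#' Propagates every frame through its cluster to that cluster's
#' meta-cluster and tabulates counts and fractions per system.  Also flags
#' each cluster as homogeneous (all members from one system) or mixed.
#' Only frames belonging to the clusters whose centres were meta-clustered
#' (i.e. the `top_n` largest) are tabulated.
#'
#' @param clustering a `daura_clustering`.
#' @param meta a `meta_clustering` of the centres of the leading clusters
#'   (rank order must match [select_central_structures()]).
#' @return list with `meta` (data.frame `meta_cluster`, `system`,
#'   `n_frames`, `fraction_of_system` relative to that system's total
#'   frame count) and `clusters` (data.frame `cluster_rank`,
#'   `meta_cluster`, `n_systems`, `homogeneous`).
#' @export
composition_report <- function(clustering, meta) {
  stopifnot(inherits(clustering, "daura_clustering"),
            inherits(meta, "meta_clustering"))
  k <- length(meta$groups)
  if (k > length(clustering$clusters))
    stop("more meta-clustered centres than clusters")
  totals <- table(clustering$ids$system)
  rows <- list()
  cl_rows <- list()
  for (r in seq_len(k)) {
    members <- clustering$clusters[[r]]$members
    sys <- clustering$ids$system[members]
    tab <- table(sys)
    cl_rows[[r]] <- data.frame(cluster_rank = r, meta_cluster = meta$groups[r],
                               n_systems = length(tab),
                               homogeneous = length(tab) == 1L,
                               stringsAsFactors = FALSE)
    rows[[r]] <- data.frame(meta_cluster = meta$groups[r],
                            system = names(tab),
                            n_frames = as.integer(tab),
                            stringsAsFactors = FALSE)
  }
  comp <- do.call(rbind, rows)
  comp <- stats::aggregate(n_frames ~ meta_cluster + system, comp, sum)
  comp <- comp[order(comp$meta_cluster, comp$system), , drop = FALSE]
  comp$fraction_of_system <-
    comp$n_frames / as.numeric(totals[comp$system])
  rownames(comp) <- NULL
  list(meta = comp, clusters = do.call(rbind, cl_rows))
}

#' Frame-level meta-cluster assignment
#'
#' @param clustering a `daura_clustering`.
#' @param meta a `meta_clustering` of the leading clusters' centres.
#' @return integer vector over all frames: the meta-cluster of each
#'   frame's cluster, or `NA` for frames in clusters beyond the
#'   meta-clustered leaders.
#' @export
frame_metacluster <- function(clustering, meta) {
  stopifnot(inherits(clustering, "daura_clustering"),
            inherits(meta, "meta_clustering"))
  asg <- cluster_assignment(clustering)
  out <- rep(NA_integer_, length(asg))
  ok <- asg <= length(meta$groups)
  out[ok] <- meta$groups[asg[ok]]
  out
}

#' Scatter plot of an MDS embedding colored by system of origin
#'
#' @param emb a `loop_mds`.
#' @param meta optional `meta_clustering`; if given, convex-hull outlines
#'   are drawn around each meta-cluster.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the data.frame of plotted coordinates.
#' @export
plot_embedding <- function(emb, meta = NULL, ...) {
  stopifnot(inherits(emb, "loop_mds"))
  sys <- sub(":.*$", "", emb$input_ids)
  usys <- sort(unique(sys))
  cols <- setNames(grDevices::hcl.colors(max(4L, length(usys)), "Dark 3")[seq_along(usys)],
                   usys)
  graphics::plot(emb$points, col = cols[sys], pch = 19,
                 xlab = "MDS dimension 1", ylab = "MDS dimension 2", ...)
  if (!is.null(meta)) {
    for (g in unique(meta$groups)) {
      pts <- emb$points[meta$groups == g, , drop = FALSE]
      if (nrow(pts) >= 3L) {
        h <- grDevices::chull(pts)
        graphics::polygon(pts[h, ], border = "grey40", lty = 3)
      }
    }
  }
  graphics::legend("topright", legend = usys, col = cols, pch = 19, cex = 0.8)
  invisible(data.frame(dim1 = emb$points[, 1], dim2 = emb$points[, 2],
                       system = sys))
}
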