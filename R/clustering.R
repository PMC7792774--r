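#' Construct a distance-matrix object
#'
#' @param values symmetric numeric matrix of loop RMSDs (nm), zero diagonal.
#' @param ids data.frame with columns `system` and `frame`, one row per
#'   matrix row, recording each frame's system of origin; defaults to a
#'   single anonymous system.
#' @return object of class `loop_dm`.
#' @export
distance_matrix <- function(values, ids = NULL) {
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  if (any(is.na(values))) stop("NA/NaN in distance matrix")
  if (any(values < 0)) stop("negative distances")
  if (max(abs(values - t(values))) > 1e-9)
    stop("distance matrix is not symmetric")
  if (is.null(ids))
    ids <- data.frame(system = rep("system", nrow(values)),
                      frame = seq_len(nrow(values)), stringsAsFactors = FALSE)
  stopifnot(nrow(ids) == nrow(values),
            all(c("system", "frame") %in% names(ids)))
  values <- (values + t(values)) / 2
  diag(values) <- 0
  structure(list(values = values, ids = ids), class = "loop_dm")
}

#' Restrict a distance matrix to a subset of frames
#' @param dm a `loop_dm`.
#' @param idx integer row indices to keep.
#' @return a `loop_dm` over the subset (order preserved).
#' @export
subset_distance_matrix <- function(dm, idx) {
  stopifnot(inherits(dm, "loop_dm"))
  idx <- as.integer(idx)
  distance_matrix(dm$values[idx, idx, drop = FALSE], dm$ids[idx, , drop = FALSE])
}

#' All-pairs framework-fitted loop RMSD matrix
#'
#' Concatenates the given trajectories (frames keep their system of
#' origin) and computes [loop_rmsd()] between every pair of frames.  The
#' clustering that consumes this matrix is origin-blind; the system labels
#' only matter for post-hoc occupancy accounting.
#'
#' @param trajs a `loop_traj` or list of them with shared atom ordering.
#' @param fit_atoms,calc_atoms see [loop_rmsd()].
#' @return a `loop_dm` whose `ids` carry `(system, frame)` per row.
#' @export
pairwise_matrix <- function(trajs, fit_atoms, calc_atoms) {
  if (inherits(trajs, "loop_traj")) trajs <- list(trajs)
  cc <- concatenate_trajectories(trajs)
  vals <- cpp_pairwise_loop_rmsd(cc$coords,
                                 as.integer(fit_atoms) - 1L,
                                 as.integer(calc_atoms) - 1L)
  distance_matrix(vals, cc$ids)
}

#' Greedy neighbor-count (Daura) conformational clustering
#'
#' Implements the classic greedy RMSD-cutoff algorithm:
#' \enumerate{
#'   \item adopt each remaining structure as the centre of a candidate
#'     cluster;
#'   \item count its neighbors, i.e. the other remaining structures at
#'     distance strictly below the cutoff;
#'   \item take the centre with the most neighbors, designate centre plus
#'     neighbors as a cluster, and remove them from the pool;
#'   \item repeat until every structure is assigned.
#' }
#' Neighbor counts are recomputed on the remaining pool after each
#' removal.  Ties between candidate centres are broken towards the lowest
#' global frame index, making the procedure fully deterministic.
#'
#' @param dm a `loop_dm`.
#' @param cutoff_nm neighbor cutoff in nm (default 0.15); structures at
#'   distance exactly equal to the cutoff are *not* neighbors.
#' @return object of class `daura_clustering`: list with `clusters` (each
#'   a list with `center` and `members`, global row indices into `dm`),
#'   `cutoff_nm` and the `ids` table of `dm`.  Clusters are ordered by
#'   decreasing size (ties resolved by formation order, which the greedy
#'   procedure already makes non-increasing).
#' @export
daura_cluster <- function(dm, cutoff_nm = 0.15) {
  stopifnot(inherits(dm, "loop_dm"))
  if (!is.numeric(cutoff_nm) || length(cutoff_nm) != 1L || cutoff_nm <= 0)
    stop("cutoff_nm must be a single positive number")
  if (any(is.na(dm$values))) stop("NA/NaN in distance matrix")
  n <- nrow(dm$values)
  adj <- dm$values < cutoff_nm
  diag(adj) <- FALSE
  alive <- rep(TRUE, n)
  clusters <- list()
  while (any(alive)) {
    pool <- which(alive)
    counts <- colSums(adj[pool, pool, drop = FALSE])
    best <- pool[which.max(counts)]     # which.max takes first => lowest index
    members <- c(best, pool[adj[pool, best]])
    clusters[[length(clusters) + 1L]] <-
      list(center = best, members = sort(members))
    alive[members] <- FALSE
  }
  structure(list(clusters = clusters, cutoff_nm = cutoff_nm, ids = dm$ids),
            class = "daura_clustering")
}

#' Sizes of all clusters, in rank order
#' @param clustering a `daura_clustering`.
#' @return integer vector of member counts (centre included).
#' @export
cluster_sizes <- function(clustering) {
  stopifnot(inherits(clustering, "daura_clustering"))
  vapply(clustering$clusters, function(cl) length(cl$members), 1L)
}

#' Map every frame to its cluster rank
#' @param clustering a `daura_clustering`.
#' @return integer vector over all frames: the rank (1 = largest) of the
#'   cluster each frame belongs to.
#' @export
cluster_assignment <- function(clustering) {
  stopifnot(inherits(clustering, "daura_clustering"))
  n <- nrow(clustering$ids)
  out <- integer(n)
  for (k in seq_along(clustering$clusters))
    out[clustering$clusters[[k]]$members] <- k
  out
}

#' Central structures of the largest clusters
#'
#' The central structure of a cluster is its chosen centre: the member
#' that had the most within-cutoff neighbors when the cluster was formed,
#' i.e. the most characteristic structure of the cluster.
#'
#' @param clustering a `daura_clustering`.
#' @param top_n number of largest clusters to report (default 25); if
#'   fewer clusters exist, all are returned.
#' @return data.frame with `cluster_rank`, `center` (global frame index),
#'   `system`, `frame` (the centre's origin), `size`.
#' @export
select_central_structures <- function(clustering, top_n = 25L) {
  stopifnot(inherits(clustering, "daura_clustering"))
  top_n <- as.integer(top_n)
  if (top_n < 1L) stop("top_n must be >= 1")
  k <- min(top_n, length(clustering$clusters))
  centers <- vapply(clustering$clusters[seq_len(k)], `[[`, 1L, "center")
  data.frame(cluster_rank = seq_len(k),
             center = centers,
             system = clustering$ids$system[centers],
             frame = clustering$ids$frame[centers],
             size = cluster_sizes(clustering)[seq_len(k)],
             stringsAsFactors = FALSE)
}

#' @export
print.daura_clustering <- function(x, ...) {
  sz <- cluster_sizes(x)
  cat(sprintf("<daura_clustering: %d frames in %d clusters, cutoff %.3g nm>\n",
              nrow(x$ids), length(x$clusters), x$cutoff_nm))
  cat("sizes:", paste(head(sz, 10), collapse = " "),
      if (length(sz) > 10) "..." else "", "\n")
  invisible(x)
}
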