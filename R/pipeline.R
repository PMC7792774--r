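#' Cluster-count convergence over growing trajectory prefixes
#'
#' Sampling adequacy is judged by re-clustering concatenations of growing
#' per-system prefixes: take the first `prefix_step_ns` of every system,
#' concatenate, cluster, and record the number of clusters; then extend
#' every prefix by another step and repeat until the full trajectories are
#' used.  A levelling-off of the cluster count indicates that longer
#' simulation no longer samples new regions of loop conformational space.
#'
#' The full all-pairs matrix is computed once and prefixes are clustered
#' on sub-matrices.  Besides the raw cluster count the curve reports the
#' count of clusters holding at least `min_size` structures, because late
#' in a run new clusters typically hold only one or two structures; the
#' advisory plateau flag of [plateau_reached()] uses that filtered count.
#'
#' @param trajs list of `loop_traj` objects.
#' @param prefix_step_ns prefix growth step in ns; must not exceed the
#'   shortest trajectory.
#' @param fit_atoms,calc_atoms see [loop_rmsd()].
#' @param cutoff_nm clustering cutoff (default 0.15 nm).
#' @param min_size cluster size from which a cluster counts as
#'   substantial (default 3).
#' @param dm optional precomputed `loop_dm` over the concatenated systems
#'   (frames of each system contiguous and in time order) to avoid
#'   recomputation.
#' @return object of class `convergence_curve`: data.frame with
#'   `prefix_ns` (per-system prefix length), `total_time_ns`,
#'   `n_clusters`, `n_clusters_min_size`, plus attributes `plateau`
#'   (advisory flag, see [plateau_reached()]) and `min_size`.
#' @export
convergence_curve <- function(trajs, prefix_step_ns, fit_atoms, calc_atoms,
                              cutoff_nm = 0.15, min_size = 3L, dm = NULL) {
  if (inherits(trajs, "loop_traj")) trajs <- list(trajs)
  stopifnot(length(trajs) >= 1L)
  stride <- trajs[[1]]$stride_ps
  lens <- vapply(trajs, n_frames, 1L)
  step_frames <- as.integer(round(prefix_step_ns * 1000 / stride))
  if (step_frames < 1L) stop("prefix step below one frame")
  if (step_frames > min(lens))
    stop("prefix step exceeds the shortest trajectory")
  if (is.null(dm)) dm <- pairwise_matrix(trajs, fit_atoms, calc_atoms)
  stopifnot(inherits(dm, "loop_dm"), nrow(dm$ids) == sum(lens))
  offsets <- c(0L, cumsum(lens))
  n_steps <- ceiling(max(lens) / step_frames)
  rows <- vector("list", n_steps)
  for (k in seq_len(n_steps)) {
    keep <- unlist(lapply(seq_along(trajs), function(s) {
      offsets[s] + seq_len(min(k * step_frames, lens[s]))
    }))
    cl <- daura_cluster(subset_distance_matrix(dm, keep), cutoff_nm)
    sz <- cluster_sizes(cl)
    rows[[k]] <- data.frame(
      prefix_ns = k * step_frames * stride / 1000,
      total_time_ns = length(keep) * stride / 1000,
      n_clusters = length(sz),
      n_clusters_min_size = sum(sz >= min_size))
  }
  out <- do.call(rbind, rows)
  structure(out, class = c("convergence_curve", "data.frame"),
            min_size = min_size,
            plateau = curve_plateau(out$n_clusters_min_size))
}

# Advisory heuristic: the completed curve has levelled off if each of the
# last two increments of the (size-filtered) cluster count adds less than
# 5% of the current count.
curve_plateau <- function(nc) {
  k <- length(nc)
  if (k < 3L) return(FALSE)
  inc <- diff(nc)
  all(inc[c(k - 2L, k - 1L)] < 0.05 * nc[k])
}

#' Has the convergence curve levelled off?
#'
#' Advisory only: a flat stretch can also mean the sampling is stuck, and
#' a slow drizzle of tiny new clusters is expected even at convergence.
#'
#' @param curve a `convergence_curve`.
#' @return logical flag.
#' @export
plateau_reached <- function(curve) {
  stopifnot(inherits(curve, "convergence_curve"))
  isTRUE(attr(curve, "plateau"))
}

#' Occupancy and residence-time table
#'
#' The number of structures a system contributes to a cluster is
#' equivalent to the time that system's loop spent in the conformations
#' characteristic of the cluster: `time_ns = n_frames * stride_ps / 1000`,
#' exactly.  Systems contributing no frames to a cluster get no row.
#'
#' @param clustering a `daura_clustering`.
#' @param stride_ps time between stored frames (ps).
#' @return data.frame with `cluster_rank`, `system_label`, `n_frames`,
#'   `time_ns`, ordered by rank then label.
#' @export
occupancy_table <- function(clustering, stride_ps) {
  stopifnot(inherits(clustering, "daura_clustering"), stride_ps > 0)
  rows <- lapply(seq_along(clustering$clusters), function(r) {
    tab <- table(clustering$ids$system[clustering$clusters[[r]]$members])
    data.frame(cluster_rank = r, system_label = names(tab),
               n_frames = as.integer(tab), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$cluster_rank, out$system_label), , drop = FALSE]
  out$time_ns <- out$n_frames * stride_ps / 1000
  rownames(out) <- NULL
  out
}

#' Run the full loop-conformation analysis pipeline
#'
#' Executes, in order: trajectory loading, selection resolution (with a
#' loop/framework disjointness check), the all-pairs framework-fitted
#' loop-RMSD matrix, greedy cutoff clustering, central-structure
#' extraction, non-metric MDS of the centres, meta-clustering,
#' composition and occupancy accounting, and the prefix-convergence
#' diagnostic.  All tables are written as TSV together with an embedding
#' plot (PNG), a JSON run manifest and a plain-text run log.  Outputs are
#' deterministic given the seed; partially written outputs are removed if
#' any stage fails.
#'
#' @param config configuration list (see [read_config()]) or path to a
#'   YAML config file.  `trajectories` entries may carry `path` +
#'   `format` + `label`, or an in-memory `loop_traj` under `object`.
#' @param out_dir output directory (created if missing); defaults to
#'   `config$out_dir` or a temporary directory.
#' @return invisibly, a list with all intermediate objects (`dm`,
#'   `clustering`, `centers`, `embedding`, `meta`, `composition`,
#'   `occupancy`, `convergence`) and `files` naming the written outputs.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_config(config)
  config <- validate_config(config)
  if (is.null(out_dir)) out_dir <- config$out_dir
  if (is.null(out_dir)) out_dir <- tempfile("loopscape_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  on_fail <- function(e) {
    unlink(written)
    stop(e)
  }
  tryCatch({
    trajs <- lapply(config$trajectories, function(tr) {
      if (inherits(tr$object, "loop_traj")) return(tr$object)
      read_trajectory(tr$path,
                      format = if (is.null(tr$format)) "pdb_multimodel" else tr$format,
                      stride_ps = config$stride_ps,
                      label = tr$label)
    })
    sel_loop <- selection("loop", config$loop, config$atom_names)
    sel_fw <- selection("framework", config$framework, config$atom_names)
    res <- resolve_disjoint(trajs[[1]], sel_loop, sel_fw)
    calc_atoms <- res$a
    fit_atoms <- res$b

    dm <- pairwise_matrix(trajs, fit_atoms, calc_atoms)
    clustering <- daura_cluster(dm, config$cutoff_nm)
    centers <- select_central_structures(clustering, config$top_n)
    dm_centers <- subset_distance_matrix(dm, centers$center)
    embedding <- nonmetric_mds(dm_centers, seed = config$seed,
                               n_restarts = config$n_restarts)
    meta <- metacluster(dm_centers, config$linkage_threshold_nm,
                        sizes = centers$size)
    composition <- composition_report(clustering, meta)
    occupancy <- occupancy_table(clustering, config$stride_ps)
    step_ns <- config$prefix_step_ns
    if (is.null(step_ns))
      step_ns <- min(vapply(trajs, n_frames, 1L)) * config$stride_ps / 1000 / 4
    convergence <- convergence_curve(trajs, step_ns, fit_atoms, calc_atoms,
                                     config$cutoff_nm, dm = dm)

    path <- function(f) file.path(out_dir, f)
    cl_tab <- data.frame(
      cluster_rank = cluster_assignment(clustering),
      center_frame = vapply(clustering$clusters, `[[`, 1L,
                            "center")[cluster_assignment(clustering)],
      member_frame = seq_len(nrow(dm$ids)),
      system_label = dm$ids$system,
      local_frame = dm$ids$frame)
    cl_tab <- cl_tab[order(cl_tab$cluster_rank, cl_tab$member_frame), ]
    written <- c(written, write_tsv(cl_tab, path("clusters.tsv")))
    written <- c(written, write_tsv(centers, path("centers.tsv")))
    emb_tab <- data.frame(id = embedding$input_ids,
                          dim1 = embedding$points[, 1],
                          dim2 = embedding$points[, 2],
                          meta_cluster = meta$groups)
    written <- c(written, write_tsv(emb_tab, path("embedding.tsv")))
    meta_tab <- cbind(composition$clusters,
                      center = centers$center, size = centers$size)
    written <- c(written, write_tsv(meta_tab, path("meta.tsv")))
    written <- c(written, write_tsv(occupancy, path("occupancy.tsv")))
    written <- c(written, write_tsv(composition$meta, path("composition.tsv")))
    written <- c(written, write_tsv(as.data.frame(convergence),
                                    path("convergence.tsv")))

    grDevices::png(path("embedding.png"), width = 900, height = 700, res = 120)
    plot_embedding(embedding, meta,
                   main = sprintf("Central structures (stress-1 = %.3f)",
                                  embedding$stress))
    grDevices::dev.off()
    written <- c(written, path("embedding.png"))

    manifest <- list(
      package_version = as.character(utils::packageVersion("loopscape")),
      parameters = config[c("loop", "framework", "atom_names", "cutoff_nm",
                            "top_n", "linkage_threshold_nm", "stride_ps",
                            "seed", "n_restarts")],
      systems = lapply(trajs, function(t)
        list(label = t$label, n_frames = n_frames(t), n_atoms = n_atoms(t))),
      n_clusters = length(clustering$clusters),
      n_meta_clusters = length(unique(meta$groups)),
      mds_stress = embedding$stress,
      plateau = plateau_reached(convergence))
    jsonlite::write_json(manifest, path("manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    written <- c(written, path("manifest.json"))

    log_lines <- c(
      sprintf("loopscape %s", manifest$package_version),
      sprintf("run at %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
      sprintf("seed %d, cutoff %.3g nm, top_n %d, linkage %.3g nm",
              as.integer(config$seed), config$cutoff_nm,
              as.integer(config$top_n), config$linkage_threshold_nm),
      sprintf("systems: %s",
              paste(vapply(trajs, function(t) t$label, ""), collapse = ", ")),
      sprintf("%d frames -> %d clusters -> %d meta-clusters (stress %.4g)",
              nrow(dm$ids), length(clustering$clusters),
              length(unique(meta$groups)), embedding$stress))
    writeLines(log_lines, path("run.log"))
    written <- c(written, path("run.log"))

    invisible(list(dm = dm, clustering = clustering, centers = centers,
                   embedding = embedding, meta = meta,
                   composition = composition, occupancy = occupancy,
                   convergence = convergence, files = written,
                   out_dir = out_dir))
  }, error = on_fail)
}
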