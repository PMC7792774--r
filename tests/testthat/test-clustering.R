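test_that("all-pairs matrix matches the element-wise oracle and keeps origins", {
  set.seed(301)
  tmpl <- make_templates("open_turn_overturn")
  sims <- lapply(c("s1", "s2"), function(lb)
    simulate_system(synth_config(tmpl, matrix(1 / 3, 3, 3), n_frames = 10,
                                 seed = match(lb, c("s1", "s2")), label = lb)))
  fit <- sims[[1]]$framework_atoms; calc <- sims[[1]]$loop_atoms
  dm <- pairwise_matrix(lapply(sims, `[[`, "trajectory"), fit, calc)
  expect_equal(dim(dm$values), c(20L, 20L))
  expect_equal(dm$ids$system, rep(c("s1", "s2"), each = 10))
  expect_equal(diag(dm$values), rep(0, 20))
  expect_lt(max(abs(dm$values - t(dm$values))), 1e-12)
  cc <- concatenate_trajectories(lapply(sims, `[[`, "trajectory"))
  for (i in 1:20) for (j in 1:20) {
    expect_lt(abs(dm$values[i, j] -
                  loop_rmsd(cc$coords[, , i], cc$coords[, , j], fit, calc)),
              1e-9)
  }
})

test_that("duplicated frames give off-diagonal zeros and a one-frame matrix is 0", {
  set.seed(302)
  tmpl <- make_templates("open_turn_overturn")
  sim <- simulate_system(synth_config(tmpl, matrix(1 / 3, 3, 3), n_frames = 3,
                                      seed = 5, label = "x"))
  one <- head_frames(sim$trajectory, 1)
  dm1 <- pairwise_matrix(one, sim$framework_atoms, sim$loop_atoms)
  expect_equal(dm1$values, matrix(0, 1, 1))
  dup <- sim$trajectory
  dup$coords[, , 3] <- dup$coords[, , 1]
  dmd <- pairwise_matrix(dup, sim$framework_atoms, sim$loop_atoms)
  expect_lt(dmd$values[1, 3], 1e-6)
  expect_gt(dmd$values[1, 2], 1e-4)
})

test_that("degenerate cutoffs give all-singleton or single-cluster partitions", {
  set.seed(303)
  v <- random_distance_values(12, max_d = 1)
  v[v < 0.2 & v > 0] <- 0.2
  diag(v) <- 0
  cl_far <- daura_cluster(distance_matrix(v), cutoff_nm = 0.1)
  expect_length(cl_far$clusters, 12L)
  expect_equal(cluster_sizes(cl_far), rep(1L, 12))
  cl_near <- daura_cluster(distance_matrix(v), cutoff_nm = 2)
  expect_length(cl_near$clusters, 1L)
  expect_equal(sort(cl_near$clusters[[1]]$members), 1:12)
})

test_that("neighborhood is strict: a pair exactly at the cutoff stays split", {
  v <- matrix(c(0, 0.15, 0.15, 0), 2, 2)
  cl <- daura_cluster(distance_matrix(v), cutoff_nm = 0.15)
  expect_length(cl$clusters, 2L)
})

test_that("well-separated planted groups are recovered exactly", {
  set.seed(304)
  sizes <- c(20, 17, 8)
  grp <- rep(1:3, sizes)
  n <- sum(sizes)
  v <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n)
    v[i, j] <- if (grp[i] == grp[j]) runif(1, 0, 0.1) else runif(1, 0.4, 0.8)
  v <- (v + t(v)) / 2; diag(v) <- 0
  cl <- daura_cluster(distance_matrix(v), cutoff_nm = 0.15)
  expect_length(cl$clusters, 3L)
  expect_equal(ari(cluster_assignment(cl), grp), 1)
  expect_equal(cluster_sizes(cl), sort(sizes, decreasing = TRUE))
})

test_that("a chain A-B-C inside the cutoff collapses to one cluster centred at B", {
  v <- matrix(c(0, 0.1, 0.2,
                0.1, 0, 0.1,
                0.2, 0.1, 0), 3, 3, byrow = TRUE)
  cl <- daura_cluster(distance_matrix(v), cutoff_nm = 0.15)
  expect_length(cl$clusters, 1L)
  expect_equal(cl$clusters[[1]]$center, 2L)   # most neighbors
  expect_equal(cl$clusters[[1]]$members, 1:3)
})

test_that("greedy clustering equals the naive four-step oracle on random matrices", {
  set.seed(305)
  for (k in 1:20) {
    n <- sample(5:120, 1)
    v <- random_distance_values(n)
    cutoff <- runif(1, 0.1, 0.9)
    cl <- daura_cluster(distance_matrix(v), cutoff)
    ref <- naive_daura(v, cutoff)
    expect_equal(length(cl$clusters), length(ref))
    for (c_i in seq_along(ref)) {
      expect_equal(cl$clusters[[c_i]]$center, ref[[c_i]]$center)
      expect_equal(cl$clusters[[c_i]]$members, ref[[c_i]]$members)
    }
  }
})

test_that("clustering always partitions the frames and is deterministic", {
  set.seed(306)
  for (k in 1:10) {
    n <- sample(10:80, 1)
    dm <- distance_matrix(random_distance_values(n))
    cl <- daura_cluster(dm, 0.3)
    members <- sort(unlist(lapply(cl$clusters, `[[`, "members")))
    expect_equal(members, 1:n)                       # disjoint + exhaustive
    expect_true(all(diff(cluster_sizes(cl)) <= 0))   # non-increasing sizes
    for (c_i in cl$clusters)
      expect_true(all(dm$values[c_i$center, setdiff(c_i$members, c_i$center)]
                      < 0.3))
    cl2 <- daura_cluster(dm, 0.3)
    expect_identical(cluster_assignment(cl), cluster_assignment(cl2))
  }
})

test_that("cluster count is non-increasing in the cutoff", {
  set.seed(307)
  dm <- distance_matrix(random_distance_values(60))
  counts <- vapply(c(0.05, 0.15, 0.5),
                   function(cf) length(daura_cluster(dm, cf)$clusters), 1L)
  expect_true(all(diff(counts) <= 0))
})

test_that("NaN distances are rejected", {
  v <- random_distance_values(4)
  v[1, 2] <- v[2, 1] <- NaN
  expect_error(distance_matrix(v), "NA/NaN")
})

test_that("central-structure selection honours top_n and rank order", {
  set.seed(308)
  sizes <- c(9, 7, 4)
  grp <- rep(1:3, sizes)
  n <- sum(sizes)
  v <- matrix(0.5, n, n)
  for (g in 1:3) v[grp == g, grp == g] <- 0.05
  diag(v) <- 0
  cl <- daura_cluster(distance_matrix(v), 0.15)
  expect_equal(nrow(select_central_structures(cl, 25)), 3L)
  expect_equal(select_central_structures(cl, 2)$cluster_rank, 1:2)
  expect_error(select_central_structures(cl, 0), "top_n")

  # 30 separated singletons -> exactly 25 centres, ranks 1..25
  v30 <- matrix(0.9, 30, 30); diag(v30) <- 0
  cl30 <- daura_cluster(distance_matrix(v30), 0.15)
  ctr <- select_central_structures(cl30, 25)
  expect_equal(nrow(ctr), 25L)
  expect_equal(ctr$cluster_rank, 1:25)
  # a singleton's centre is its only member
  expect_equal(cl30$clusters[[1]]$members, cl30$clusters[[1]]$center)
})
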