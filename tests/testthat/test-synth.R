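test_that("hinge-rotation templates have the closed-form pairwise RMSDs", {
  base <- loop_arc(7, 0.38)
  tmpl <- make_templates("open_turn_overturn", base_loop = base)
  expect_equal(tmpl$coords[[1]], base, tolerance = 1e-12, ignore_attr = TRUE)

  # displacement of a point at distance r from the hinge axis under a
  # rotation by phi is 2 r sin(phi/2)
  axis_r <- abs(base[, 2])                 # hinge along x, arc in xy-plane
  closed_form <- function(phi) sqrt(mean((2 * axis_r * sin(phi / 2))^2))
  expect_equal(tmpl$pairwise_rmsd_nm[1, 2], closed_form(pi / 2),
               tolerance = 1e-10)
  expect_equal(tmpl$pairwise_rmsd_nm[1, 3], closed_form(pi),
               tolerance = 1e-10)
  expect_equal(tmpl$pairwise_rmsd_nm[2, 3], closed_form(pi / 2),
               tolerance = 1e-10)
  # anchors sit on the axis and do not move
  expect_equal(tmpl$coords[[3]][1, ], base[1, ], tolerance = 1e-12,
               ignore_attr = TRUE)

  custom <- make_templates("custom", templates = list(a = base, b = base * 2))
  expect_identical(custom$coords$a, base)
  expect_equal(custom$names, c("a", "b"))

  degenerate <- base
  degenerate[nrow(degenerate), ] <- degenerate[1, ]
  expect_error(make_templates("open_turn_overturn", base_loop = degenerate),
               "degenerate hinge")
})

test_that("the synthetic configuration validates its Markov chain", {
  tmpl <- make_templates("open_turn_overturn")
  bad_rows <- matrix(c(0.5, 0.4, 0.5, 0.5), 2, byrow = TRUE)
  expect_error(synth_config(tmpl$coords[1:2], bad_rows), "sum to 1")
  expect_error(synth_config(tmpl$coords[1:2],
                            matrix(c(1.2, -0.2, 0, 1), 2, byrow = TRUE)),
               "non-negative|sum to 1")
  expect_error(synth_config(tmpl, diag(2)), "K x K")
  cfg <- synth_config(tmpl, diag(3))
  expect_gt(cfg$min_template_rmsd_nm, 2 * cfg$expected_noise_rmsd_nm)
})

test_that("simulation is reproducible and per-system streams are independent", {
  sc1 <- make_study_scenario(seed = 3, n_frames = 50)
  sc2 <- make_study_scenario(seed = 3, n_frames = 50)
  expect_identical(sc1$apo$trajectory$coords, sc2$apo$trajectory$coords)
  expect_identical(sc1$ab2$states, sc2$ab2$states)
  only_apo <- make_study_scenario(seed = 3, n_frames = 50, systems = "apo")
  expect_identical(only_apo$apo$trajectory$coords, sc1$apo$trajectory$coords)
  sc3 <- make_study_scenario(seed = 4, n_frames = 50)
  expect_false(identical(sc1$apo$trajectory$coords, sc3$apo$trajectory$coords))
})

test_that("a single-template system collapses into one dominant cluster", {
  tmpl <- make_templates("open_turn_overturn")
  sim <- simulate_system(synth_config(tmpl$coords[2], matrix(1, 1, 1),
                                      n_frames = 400, seed = 8, label = "k1"))
  expect_true(all(sim$states == 1L))
  dm <- pairwise_matrix(sim$trajectory, sim$framework_atoms, sim$loop_atoms)
  cl <- daura_cluster(dm, 0.15)   # cutoff far above the noise RMSD scale
  expect_gte(cluster_sizes(cl)[1] / 400, 0.99)
})

test_that("sampled transitions are consistent with the configured chain", {
  tmpl <- make_templates("open_turn_overturn")
  P <- matrix(c(0.9, 0.1, 0.3, 0.7), 2, byrow = TRUE)
  cfg <- synth_config(tmpl$coords[1:2], P, n_frames = 4L,
                      noise_sigma_nm = 0.03, seed = 21)
  # state path only; generate a long chain without building coordinates
  set.seed(21)
  s <- loopscape:::sample_markov(P, 12000L, "stationary")
  for (from in 1:2) {
    idx <- which(s[-length(s)] == from)
    obs <- table(factor(s[idx + 1L], levels = 1:2))
    gof <- chisq.test(obs, p = P[from, ])
    expect_gt(gof$p.value, 0.01)
  }
  expect_equal(cfg$n_frames, 4L)
})

test_that("planted stationary occupancy is recovered in label frequencies", {
  sc <- make_study_scenario(seed = 12, n_frames = 2000, systems = "apo")
  freq <- table(sc$apo$state_names) / 2000
  expect_lt(abs(freq[["open"]] - 0.20), 0.03)
  expect_lt(abs(freq[["turned"]] - 0.80), 0.03)
})

test_that("per-frame rigid motions are invisible after framework fitting", {
  tmpl <- make_templates("open_turn_overturn")
  P <- matrix(c(0.8, 0.2, 0.2, 0.8), 2, byrow = TRUE)
  mk <- function(rigid) simulate_system(synth_config(
    tmpl$coords[1:2], P, n_frames = 40, seed = 17,
    rigid_motion_per_frame = rigid, label = "rm"))
  plain <- mk(FALSE); moved <- mk(TRUE)
  expect_identical(plain$states, moved$states)
  # raw coordinates differ wildly ...
  expect_gt(max(abs(plain$trajectory$coords - moved$trajectory$coords)), 0.1)
  # ... but the fitted pairwise loop-RMSD matrix is unchanged
  dm_a <- pairwise_matrix(plain$trajectory, plain$framework_atoms,
                          plain$loop_atoms)
  dm_b <- pairwise_matrix(moved$trajectory, moved$framework_atoms,
                          moved$loop_atoms)
  expect_lt(max(abs(dm_a$values - dm_b$values)), 1e-9)
})

test_that("scenario files round-trip through disk with their labels", {
  sc <- make_study_scenario(seed = 1, n_frames = 5, systems = c("apo", "ab2"))
  out <- withr::local_tempdir()
  files <- write_scenario(sc, out)
  expect_true(file.exists(file.path(out, "apo.pdb")))
  expect_true(file.exists(file.path(out, "labels.tsv")))
  lab <- read.table(file.path(out, "labels.tsv"), header = TRUE, sep = "\t")
  expect_equal(nrow(lab), 10L)
  back <- read_trajectory(file.path(out, "apo.pdb"), label = "apo")
  expect_lt(max(abs(back$coords - sc$apo$trajectory$coords)), 1e-3)
})
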