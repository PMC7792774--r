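test_that("superposition recovers rigid motions and refuses degenerate input", {
  set.seed(201)
  A <- matrix(rnorm(30), 10, 3)

  f0 <- superpose(A, A, 1:10)
  expect_equal(f0$rotation, diag(3), tolerance = 1e-10)
  expect_equal(f0$translation, rep(0, 3), tolerance = 1e-10)
  expect_equal(f0$fit_rmsd_nm, 0, tolerance = 1e-12)

  # 90 degrees about z plus a (1,0,0) nm shift
  Rz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  B <- sweep(A %*% t(Rz), 2, c(-1, 0, 0))
  f <- superpose(A, B, 1:10)
  expect_equal(f$rotation, Rz, tolerance = 1e-9)
  expect_lt(f$fit_rmsd_nm, 1e-10)
  expect_equal(apply_fit(f, A), B, tolerance = 1e-9)

  expect_error(superpose(A, B, 1:2), "at least 3")
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(superpose(line, line, 1:5), "collinear")
})

test_that("superposition matches the quaternion (Horn) oracle on noisy rigid pairs", {
  set.seed(202)
  for (k in 1:100) {
    A <- matrix(rnorm(18), 6, 3)
    B <- random_rigid(A) + matrix(rnorm(18, sd = 0.01), 6, 3)
    f <- superpose(A, B, 1:6)
    h <- horn_transform(A, B, 1:6)
    expect_lt(abs(f$fit_rmsd_nm - h$fit_rmsd), 1e-8)
  }
})

test_that("superposition never returns a reflection for near-planar mirrored sets", {
  set.seed(203)
  for (k in 1:25) {
    A <- cbind(matrix(rnorm(12), 6, 2), rnorm(6, sd = 1e-4))
    B <- A
    B[, 3] <- -B[, 3]   # mirror image; the unconstrained optimum reflects
    f <- superpose(A, B, 1:6)
    expect_equal(det(f$rotation), 1, tolerance = 1e-8)
  }
})

test_that("loop RMSD isolates loop displacement after framework fitting", {
  set.seed(204)
  fr <- matrix(rnorm(60), 20, 3)
  fit <- 1:13; calc <- 14:20
  expect_equal(loop_rmsd(fr, fr, fit, calc), 0, tolerance = 1e-12)

  shifted <- fr
  shifted[calc, 1] <- shifted[calc, 1] + 0.2   # uniform 0.2 nm loop shift
  expect_equal(loop_rmsd(shifted, fr, fit, calc), 0.2, tolerance = 1e-9)
})

test_that("loop RMSD is symmetric, rigid-motion invariant, and matches the oracle", {
  set.seed(205)
  fit <- 1:12; calc <- 13:19
  for (k in 1:50) {
    a <- matrix(rnorm(57), 19, 3)
    b <- matrix(rnorm(57), 19, 3)
    r <- loop_rmsd(a, b, fit, calc)
    expect_lt(abs(r - loop_rmsd(b, a, fit, calc)), 1e-9)
    expect_lt(abs(r - loop_rmsd(random_rigid(a), b, fit, calc)), 1e-9)
    expect_lt(abs(r - oracle_loop_rmsd(a, b, fit, calc)), 1e-10)
  }
})

test_that("RMSD time series is zero at the reference and plateaus per planted state", {
  tmpl <- make_templates("open_turn_overturn")
  two <- make_templates("custom", templates = tmpl$coords[1:2])
  sim <- simulate_system(synth_config(
    two, matrix(c(0.8, 0.2, 0.2, 0.8), 2, byrow = TRUE),
    initial_state = 1L, n_frames = 200, noise_sigma_nm = 0.01, seed = 11))
  ts <- rmsd_timeseries(sim$trajectory, 1L, sim$framework_atoms, sim$loop_atoms)
  expect_equal(ts$rmsd_nm[1], 0)
  expect_equal(ts$time_ps, (0:199) * 10)
  sep <- two$pairwise_rmsd_nm[1, 2]
  same <- sim$states == sim$states[1]
  expect_true(all(ts$rmsd_nm[same] < 0.1))
  expect_true(all(abs(ts$rmsd_nm[!same] - sep) < 0.1))

  cst <- sim$trajectory
  cst$coords <- array(rep(cst$coords[, , 1], 5), dim = c(n_atoms(cst), 3, 5))
  flat <- rmsd_timeseries(cst, 1L, sim$framework_atoms, sim$loop_atoms)
  expect_equal(flat$rmsd_nm, rep(0, 5), tolerance = 1e-12)
})

test_that("RMSF matches the direct-summation oracle and closed forms", {
  set.seed(206)
  # static trajectory -> zero fluctuation
  base <- matrix(rnorm(36), 12, 3)
  static <- trajectory(array(rep(base, 6), dim = c(12, 3, 6)),
                       chain_traj(1:12)$atoms, 10, "static")
  expect_equal(compute_rmsf(static, 1:12, 1:8)$rmsf_nm, rep(0, 12),
               tolerance = 1e-12)

  # one atom alternating xbar +/- a with a fixed framework -> RMSF |a|
  a <- 0.07
  alt <- array(rep(base, 10), dim = c(12, 3, 10))
  alt[12, 1, ] <- base[12, 1] + a * rep(c(1, -1), 5)
  alt_tr <- trajectory(alt, chain_traj(1:12)$atoms, 10, "alt")
  r <- compute_rmsf(alt_tr, 1:12, 1:8)
  expect_equal(r$rmsf_nm[12], a, tolerance = 1e-10)
  expect_equal(r$rmsf_nm[1:8], rep(0, 8), tolerance = 1e-10)

  # random trajectory -> equality with explicit-summation oracle
  noisy <- array(rnorm(12 * 3 * 20, sd = 0.05), dim = c(12, 3, 20)) +
    array(rep(base, 20), dim = c(12, 3, 20))
  ntr <- trajectory(noisy, chain_traj(1:12)$atoms, 10, "noisy")
  expect_equal(compute_rmsf(ntr, 1:12, 1:8)$rmsf_nm,
               oracle_rmsf(ntr, 1:12, 1:8), tolerance = 1e-10)
})

test_that("RMSF of isotropic Gaussian jitter approaches sigma*sqrt(3)", {
  set.seed(207)
  sigma <- 0.02
  nf <- 20000L
  base <- make_framework(10)
  coords <- array(rep(rbind(base, matrix(0, 5, 3)), nf),
                  dim = c(15, 3, nf))
  coords[11:15, , ] <- coords[11:15, , ] +
    array(rnorm(5 * 3 * nf, sd = sigma), dim = c(5, 3, nf))
  tr <- trajectory(coords, chain_traj(1:15)$atoms, 10, "jitter")
  r <- compute_rmsf(tr, 11:15, 1:10)
  expect_equal(mean(r$rmsf_nm), sigma * sqrt(3), tolerance = 0.02)
})

test_that("replicate aggregation defaults to root-mean-square of per-run RMSFs", {
  set.seed(208)
  base <- matrix(rnorm(30), 10, 3)
  mk <- function(sd) {
    co <- array(rep(base, 50), dim = c(10, 3, 50))
    co[10, , ] <- co[10, , ] + matrix(rnorm(150, sd = sd), 3, 50)
    trajectory(co, chain_traj(1:10)$atoms, 10, "rep")
  }
  t1 <- mk(0.02); t2 <- mk(0.08)
  r1 <- compute_rmsf(t1, 10, 1:6)$rmsf_nm
  r2 <- compute_rmsf(t2, 10, 1:6)$rmsf_nm
  both_rms <- compute_rmsf(list(t1, t2), 10, 1:6)$rmsf_nm
  both_mean <- compute_rmsf(list(t1, t2), 10, 1:6, aggregate = "mean")$rmsf_nm
  expect_equal(both_rms, sqrt((r1^2 + r2^2) / 2), tolerance = 1e-12)
  expect_equal(both_mean, (r1 + r2) / 2, tolerance = 1e-12)
  expect_gt(both_rms, both_mean)  # second moment dominates
  expect_error(compute_rmsf(list(), 1, 1:3), "empty")
})
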