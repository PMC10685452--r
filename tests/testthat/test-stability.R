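test_that("Kabsch superposition: identity, rigid recovery, optimality", {
  set.seed(3)
  P <- matrix(rnorm(30), 10, 3)
  s0 <- kabsch_superpose(P, P)
  expect_equal(s0$rotation, diag(3), tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(s0$translation, c(0, 0, 0), tolerance = 1e-10)
  expect_equal(s0$rmsd, 0, tolerance = 1e-10)

  # 90 degree rotation about z plus translation is exactly inverted
  Rz <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  Q <- tcrossprod(P, Rz) + matrix(c(1, -2, 3), 10, 3, byrow = TRUE)
  s <- kabsch_superpose(P, Q)
  expect_equal(s$rmsd, 0, tolerance = 1e-10)
  expect_equal(s$rotation, Rz, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(apply_superposition(P, s), Q, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(det(s$rotation), 1, tolerance = 1e-8)

  # optimal rmsd never exceeds the rmsd of any other rigid placement
  for (i in 1:20) {
    A <- matrix(rnorm(24), 8, 3)
    B <- matrix(rnorm(24), 8, 3)
    opt <- kabsch_superpose(A, B)$rmsd
    Rr <- random_rotation()
    alt <- sqrt(mean(rowSums((tcrossprod(A, Rr) - B)^2)))
    expect_lte(opt, alt + 1e-12)
    expect_lte(opt, sqrt(mean(rowSums((A - B)^2))) + 1e-12)
  }
})

test_that("Kabsch agrees with the quaternion eigen-method oracle", {
  set.seed(8)
  for (i in 1:50) {
    n <- sample(4:40, 1)
    A <- matrix(rnorm(3 * n), n, 3)
    B <- tcrossprod(A, random_rotation()) +
      matrix(rnorm(3, sd = 2), n, 3, byrow = TRUE) +
      matrix(rnorm(3 * n, sd = runif(1, 0.01, 0.3)), n, 3)
    expect_equal(kabsch_superpose(A, B)$rmsd, quaternion_rmsd(A, B),
                 tolerance = 1e-9)
  }
})

test_that("degenerate point sets are rejected", {
  expect_error(kabsch_superpose(matrix(rnorm(6), 2, 3), matrix(rnorm(6), 2, 3)),
               "at least 3")
  line <- cbind(1:5, 2 * (1:5), -(1:5))
  expect_error(kabsch_superpose(line, line), "degenerate")
})

make_protein_traj <- function(coord_list, box = 20) {
  n <- nrow(coord_list[[1]])
  atoms <- data.frame(
    atom_id = seq_len(n), name = "CA", element = "C", molecule_id = 1L,
    molecule_class = "protein", species = "PRO",
    residue_index = seq_len(n), stringsAsFactors = FALSE)
  trajectory(topology(atoms),
             lapply(seq_along(coord_list), function(i)
               frame(i, box, coord_list[[i]])))
}

test_that("RMSF: static and hand-computable cases", {
  ref <- cbind(cos(1:12), sin(1:12), 0.5 * (1:12))
  static <- make_protein_traj(list(ref, ref, ref))
  expect_equal(residue_rmsf(static)$rmsf, rep(0, 12), tolerance = 1e-12)

  # fitting disabled, residue 4 displaced +-0.1 nm about its mean along z
  f2 <- ref
  f2[4, 3] <- f2[4, 3] + 0.2
  tr <- make_protein_traj(list(ref, f2))
  pr <- residue_rmsf(tr, fit_selection = "none")
  want <- rep(0, 12); want[4] <- 0.1
  expect_equal(pr$rmsf, want, tolerance = 1e-12)
})

test_that("RMSF is invariant under global rigid motion of every frame", {
  set.seed(12)
  ref <- cbind(cos(1:15), sin(1:15), 0.45 * (1:15))
  tr <- simulate_protein_fluctuations(ref, sigma = runif(15, 0.02, 0.1),
                                      tau = 3, n_frames = 300, seed = 77)
  base <- residue_rmsf(tr, fit_selection = "heavy")
  moved <- lapply(tr$frames, function(f) {
    R <- random_rotation()
    tcrossprod(f$coords, R) + matrix(rnorm(3, sd = 3), nrow(f$coords), 3,
                                     byrow = TRUE)
  })
  tr2 <- make_protein_traj(moved, box = 50)
  fitted <- residue_rmsf(tr2, fit_selection = "heavy")
  expect_lte(max(abs(fitted$rmsf - base$rmsf)), 1e-6)
})

test_that("RMSF parameter recovery tracks heterogeneous sigma", {
  set.seed(5)
  n_res <- 30
  sig <- runif(n_res, 0.02, 0.15)
  ref <- cbind(2 * cos(1:n_res), 2 * sin(1:n_res), 0.5 * (1:n_res))
  tr <- simulate_protein_fluctuations(ref, sig, tau = 5, n_frames = 6000,
                                      seed = 6)
  pr <- residue_rmsf(tr, fit_selection = "none")
  expect_gte(cor(pr$rmsf, sig, method = "spearman"), 0.99)
})

test_that("delta-RMSF: identity, linearity, antisymmetry, set mismatch", {
  a <- fake_profile(c(0.1, 0.2, 0.3), label = "A")
  expect_equal(delta_rmsf(a, a)$per_residue_delta, rep(0, 3))
  expect_equal(delta_rmsf(a, a)$average_delta, 0)

  b <- fake_profile(c(0.1, 0.2, 0.3) + 0.017, label = "B")
  d <- delta_rmsf(b, a)
  expect_equal(d$per_residue_delta, rep(0.017, 3))
  expect_equal(d$average_delta, 0.017)
  dba <- delta_rmsf(a, b)
  expect_equal(dba$per_residue_delta, -d$per_residue_delta)
  expect_equal(dba$average_delta, -d$average_delta)

  cc <- fake_profile(c(0.1, 0.2), resid = c(1, 4))
  expect_error(delta_rmsf(a, cc), "only in detergent profile: \\{2, 3\\}")
  expect_error(delta_rmsf(a, cc), "only in reference profile: \\{4\\}")
})

test_that("RMSF convergence detects stationarity and regime change", {
  ref <- cbind(cos(1:10), sin(1:10), 0.6 * (1:10))
  tr <- simulate_protein_fluctuations(ref, 0.05, tau = 3, n_frames = 2000,
                                      seed = 14)
  cv <- rmsf_convergence(tr, checkpoint_times = c(500, 1000, 1500, 2000),
                         tolerance = 0.01, fit_selection = "none")
  expect_true(cv$equilibrated)
  expect_length(cv$profiles, 4L)

  # doubling sigma halfway must break convergence below the induced jump
  half1 <- simulate_protein_fluctuations(ref, 0.05, 3, 1000, seed = 15)
  half2 <- simulate_protein_fluctuations(ref, 0.10, 3, 1000, seed = 16)
  co <- c(lapply(half1$frames, `[[`, "coords"),
          lapply(half2$frames, `[[`, "coords"))
  tr2 <- make_protein_traj(co)
  cv2 <- rmsf_convergence(tr2, checkpoint_times = c(1000, 2000),
                          tolerance = 0.005, fit_selection = "none")
  expect_false(cv2$equilibrated)

  expect_error(rmsf_convergence(tr, checkpoint_times = 1000, tolerance = 1),
               "at least 2")
  expect_error(rmsf_convergence(tr, checkpoint_times = c(1000, 9000),
                                tolerance = 1), "beyond")
})
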