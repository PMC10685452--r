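test_that("slab Monte Carlo reproduces the closed-form occupancy", {
  # uniform limit: epsilon = 0 -> h / Lz
  tr0 <- simulate_detergent_membrane(box = 10, slab_halfwidth = 1,
                                     n_lipids = 8, n_detergents = 64,
                                     epsilon = 0, step_size = 1,
                                     n_steps = 3000, sample_every = 10,
                                     seed = 101)
  oc0 <- slab_occupancy(tr0)
  expect_lt(abs(oc0$mean - 0.2), 3 * oc0$se)

  # attractive slab: f_eq = h e^eps / (h e^eps + Lz - h)
  feq <- slab_occupancy_expected(2, 2, 10)
  expect_equal(feq, 2 * exp(2) / (2 * exp(2) + 8))
  tr2 <- simulate_detergent_membrane(box = 10, slab_halfwidth = 1,
                                     n_lipids = 8, n_detergents = 64,
                                     epsilon = 2, step_size = 1,
                                     n_steps = 3000, sample_every = 10,
                                     seed = 102)
  oc2 <- slab_occupancy(tr2)
  expect_lt(abs(oc2$mean - feq), 3 * oc2$se)
})

test_that("slab simulation is reproducible and validates inputs", {
  args <- list(box = 8, slab_halfwidth = 1, n_lipids = 4, n_detergents = 10,
               epsilon = 1, step_size = 0.8, n_steps = 200,
               sample_every = 10, seed = 5)
  a <- do.call(simulate_detergent_membrane, args)
  b <- do.call(simulate_detergent_membrane, args)
  expect_identical(a, b)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_trajectory(a, f1, "xyzext"); write_trajectory(b, f2, "xyzext")
  expect_identical(readLines(f1), readLines(f2))

  expect_error(simulate_detergent_membrane(8, slab_halfwidth = 5, 4, 10, 1),
               "< Lz")
  expect_error(simulate_detergent_membrane(8, 1, 4, n_detergents = 0, 1),
               "n_detergents")
  expect_error(simulate_detergent_membrane(8, 1, 4, 10, 1, step_size = 0),
               "step_size")
})

test_that("equilibrium occupancy is strictly monotone in affinity", {
  eps <- c(0, 1, 2, 3)
  feq <- slab_occupancy_expected(eps, 2, 10)
  expect_true(all(diff(feq) > 0))
  means <- vapply(eps[1:3], function(e) {
    slab_occupancy(simulate_detergent_membrane(
      box = 10, slab_halfwidth = 1, n_lipids = 4, n_detergents = 80,
      epsilon = e, step_size = 1, n_steps = 3000, sample_every = 10,
      seed = 300 + e))$mean
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("OU protein fluctuations match their stationary law", {
  ref <- cbind(cos(1:20), sin(1:20), 0.4 * (1:20))

  # zero-noise limit: all frames identical to the reference
  tr0 <- simulate_protein_fluctuations(ref, sigma = 0, tau = 5,
                                       n_frames = 10, seed = 1)
  expect_true(all(vapply(tr0$frames, function(f)
    max(abs(f$coords - ref)) == 0, logical(1))))

  # stationary RMSF = sigma * sqrt(3), within 2% at 20000 frames
  tr <- simulate_protein_fluctuations(ref, sigma = 0.05, tau = 5,
                                      n_frames = 20000, seed = 2)
  pr <- residue_rmsf(tr, fit_selection = "none")
  expect_equal(pr$rmsf, rep(0.05 * sqrt(3), 20), tolerance = 0.02)

  # lag-1 autocorrelation of coordinates ~ exp(-1/tau)
  a <- exp(-1 / 5)
  z <- vapply(tr$frames, function(f) f$coords[7, 3], numeric(1))
  r1 <- stats::cor(z[-1], z[-length(z)])
  se <- sqrt((1 - a^2) / length(z))
  expect_lt(abs(r1 - a), 3 * se)

  expect_error(simulate_protein_fluctuations(ref, sigma = rep(0.1, 3), tau = 5,
                                             n_frames = 10), "mismatch")
  expect_error(simulate_protein_fluctuations(ref, 0.1, tau = 0, n_frames = 10),
               "tau")
})

test_that("regio placement follows the propensity table", {
  prot <- cbind(0, 0, (1:20) * 1.5)

  # all head mass on residues 1-10 forces every head contact there
  regs <- data.frame(name = c("A", "B"), start = c(1, 11), end = c(10, 20),
                     head = c(1, 0), tail = c(0, 1))
  tr <- place_regio_detergents(prot, regs, n_detergent_particles = 2,
                               contact_distance = 0.6, n_frames = 200,
                               seed = 9)
  cm <- headtail_contact_map(tr, cutoff = 0.6)
  expect_true(all(cm$map$head_occupancy[11:20] == 0))
  expect_true(all(cm$map$tail_occupancy[1:10] == 0))
  expect_gt(sum(cm$map$head_occupancy[1:10]), 0)

  # zero particles: protein-only trajectory
  tr0 <- place_regio_detergents(prot, regs, n_detergent_particles = 0,
                                contact_distance = 0.6, n_frames = 3, seed = 1)
  expect_identical(unique(tr0$topology$atoms$molecule_class), "protein")

  expect_error(place_regio_detergents(prot, regs[0, ], 1, 0.6, 5), "empty")
  regs$head[1] <- 1.4
  expect_error(place_regio_detergents(prot, regs, 1, 0.6, 5), "\\[0, 1\\]")
})

test_that("planted head/tail split is recovered within binomial error", {
  prot <- cbind(0, 0, (1:20) * 1.5)
  regs <- data.frame(name = c("A", "B"), start = c(1, 11), end = c(10, 20),
                     head = c(0.8, 0.2), tail = c(0.2, 0.8))
  n_frames <- 1500
  tr <- place_regio_detergents(prot, regs, n_detergent_particles = 1,
                               contact_distance = 0.6, n_frames = n_frames,
                               seed = 23)
  cm <- headtail_contact_map(tr, cutoff = 0.6)
  share <- sum(cm$map$head_occupancy[1:10]) / sum(cm$map$head_occupancy)
  se <- sqrt(0.8 * 0.2 / n_frames)
  expect_lt(abs(share - 0.8), 3 * se)
})
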