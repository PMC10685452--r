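test_that("constructed-frame invasion fractions are exact", {
  box <- c(10, 10, 10)
  lip <- matrix(c(5, 5, 5), 1, 3)
  # detergents at 0.5, 2.0, 2.0 nm from the lipid
  det <- rbind(c(5.5, 5, 5), c(7, 5, 5), c(3, 5, 5))
  tr <- make_slab_system(det, lip, box)
  inv <- detergent_invasion_fraction(tr, cutoff = 0.6, window = c(0, 0))
  expect_equal(inv$mean_fraction, 100 / 3, tolerance = 1e-12)

  all_in <- make_slab_system(lip + 0.1, lip, box)
  expect_equal(detergent_invasion_fraction(all_in, 0.6, c(0, 0))$mean_fraction, 100)
  none <- make_slab_system(lip + 3, lip, box)
  expect_equal(detergent_invasion_fraction(none, 0.6, c(0, 0))$mean_fraction, 0)
})

test_that("per-frame fractions equal an all-pairs brute-force implementation", {
  set.seed(17)
  box <- c(7, 7, 7)
  for (rep in 1:4) {
    frames <- lapply(1:5, function(i) {
      frame(i, box, matrix(runif(3 * 70, 0, 7), 70, 3))
    })
    atoms <- data.frame(
      atom_id = 1:70, name = "X", element = "C", molecule_id = 1:70,
      molecule_class = c(rep("lipid", 30), rep("detergent", 40)),
      species = c(rep("LIP", 30), rep("DET", 40)), stringsAsFactors = FALSE)
    tr <- trajectory(topology(atoms), frames)
    inv <- detergent_invasion_fraction(tr, cutoff = 0.8, window = c(1, 5))
    want <- vapply(frames, function(f) {
      det <- lapply(31:70, function(i) f$coords[i, , drop = FALSE])
      100 * mean(brute_contact_flags(det, f$coords[1:30, , drop = FALSE],
                                     0.8, box))
    }, numeric(1))
    expect_equal(inv$per_frame$fraction_pct, want, tolerance = 1e-12)
    expect_equal(inv$mean_fraction, mean(want), tolerance = 1e-12)
  }
})

test_that("per-lipid profile: definition cases and brute-force agreement", {
  box <- c(10, 10, 10)
  # 1 lipid, 4 detergents, exactly one in contact -> profile [25]
  lip <- matrix(c(5, 5, 5), 1, 3)
  det <- rbind(c(5.4, 5, 5), c(8, 5, 5), c(2, 5, 5), c(5, 8, 5))
  tr <- make_slab_system(det, lip, box)
  pl <- per_lipid_detergent_profile(tr, 0.6, c(0, 0))
  expect_equal(pl$profile$avg_pct, 25)
  expect_equal(pl$mean_over_lipids, 25)

  # one detergent within reach of both lipids counts toward each
  lip2 <- rbind(c(5, 5, 5), c(5.8, 5, 5))
  det2 <- rbind(c(5.4, 5, 5), c(1, 1, 1))
  tr2 <- make_slab_system(det2, lip2, box)
  pl2 <- per_lipid_detergent_profile(tr2, 0.6, c(0, 0))
  expect_equal(pl2$profile$avg_pct, c(50, 50))

  set.seed(31)
  frames <- lapply(1:4, function(i) frame(i, box, matrix(runif(120, 0, 10), 40, 3)))
  atoms <- data.frame(
    atom_id = 1:40, name = "X", element = "C", molecule_id = 1:40,
    molecule_class = c(rep("lipid", 15), rep("detergent", 25)),
    species = c(rep("LIP", 15), rep("DET", 25)), stringsAsFactors = FALSE)
  tr3 <- trajectory(topology(atoms), frames)
  pl3 <- per_lipid_detergent_profile(tr3, cutoff = 1.1, window = c(1, 4))
  want <- Reduce(`+`, lapply(frames, function(f) {
    m <- brute_contact_matrix(f$coords[16:40, ], 1:25, f$coords[1:15, ], 1:15,
                              1.1, box)
    100 * colSums(m) / 25
  })) / 4
  expect_equal(sort(pl3$profile$avg_pct, decreasing = TRUE),
               sort(want, decreasing = TRUE), tolerance = 1e-12)
  expect_false(is.unsorted(rev(pl3$profile$avg_pct)))
  expect_equal(pl3$mean_over_lipids, mean(want), tolerance = 1e-12)
  expect_equal(pl3$sd_over_lipids, sd(want), tolerance = 1e-12)
})

test_that("invasion fraction is monotone in the cutoff", {
  set.seed(53)
  box <- c(6, 6, 6)
  frames <- lapply(1:3, function(i) frame(i, box, matrix(runif(90, 0, 6), 30, 3)))
  atoms <- data.frame(
    atom_id = 1:30, name = "X", element = "C", molecule_id = 1:30,
    molecule_class = c(rep("lipid", 10), rep("detergent", 20)),
    species = c(rep("LIP", 10), rep("DET", 20)), stringsAsFactors = FALSE)
  tr <- trajectory(topology(atoms), frames)
  cuts <- c(0.3, 0.6, 0.9, 1.2, 1.5)
  fr <- lapply(cuts, function(cc)
    detergent_invasion_fraction(tr, cc, c(1, 3))$per_frame$fraction_pct)
  for (k in seq_along(cuts)[-1]) {
    expect_true(all(fr[[k]] >= fr[[k - 1]]))
  }
})

test_that("invasion fraction is invariant under rigid translation and rewrap", {
  set.seed(67)
  box <- c(8, 8, 8)
  co <- matrix(runif(90, 0, 8), 30, 3)
  atoms <- data.frame(
    atom_id = 1:30, name = "X", element = "C", molecule_id = 1:30,
    molecule_class = c(rep("lipid", 12), rep("detergent", 18)),
    species = c(rep("LIP", 12), rep("DET", 18)), stringsAsFactors = FALSE)
  base <- trajectory(topology(atoms), list(frame(0, box, co)))
  ref <- detergent_invasion_fraction(base, 0.7, c(0, 0))$mean_fraction
  shift <- c(3.21, -5.4, 11.7)
  shifted <- trajectory(topology(atoms),
                        list(frame(0, box, sweep(co, 2, -shift))))
  rewrapped <- trajectory(topology(atoms),
                          list(frame(0, box, (co %% rep(box, each = 30)))))
  expect_equal(detergent_invasion_fraction(shifted, 0.7, c(0, 0))$mean_fraction,
               ref, tolerance = 1e-9)
  expect_equal(detergent_invasion_fraction(rewrapped, 0.7, c(0, 0))$mean_fraction,
               ref, tolerance = 1e-9)
})

test_that("invasion preconditions are enforced", {
  box <- c(10, 10, 10)
  lip <- matrix(c(5, 5, 5), 1, 3)
  tr <- make_slab_system(matrix(c(1, 1, 1), 1, 3), lip, box)
  # no detergent molecules
  atoms <- data.frame(atom_id = 1:2, name = "L", element = "C",
                      molecule_id = 1:2, molecule_class = "lipid",
                      species = "LIP", stringsAsFactors = FALSE)
  lips_only <- trajectory(topology(atoms),
                          list(frame(0, box, matrix(runif(6), 2, 3))))
  expect_error(detergent_invasion_fraction(lips_only, 0.6, c(0, 0)),
               "detergent")
  expect_error(detergent_invasion_fraction(tr, 0.6, window = c(5, 9)), "empty")
  expect_error(detergent_invasion_fraction(tr, cutoff = 6), "minimum-image")
})

test_that("checkpoint convergence follows its windowed-mean definition", {
  times <- 1:100
  const <- checkpoint_convergence(times, rep(4.2, 100), c(30, 60, 90), 0)
  expect_true(const$equilibrated)
  expect_equal(const$checkpoint_values, rep(4.2, 3))

  drift <- checkpoint_convergence(times, times * 0.5, c(30, 60, 90),
                                  tolerance = 10)
  expect_false(drift$equilibrated)
  expect_equal(drift$checkpoint_values, c(mean(1:30), mean(31:60), mean(61:90)) * 0.5)
  expect_equal(drift$max_pairwise_delta, 60 * 0.5)

  expect_error(checkpoint_convergence(times, times, c(50, 150), 1), "beyond")
  expect_error(checkpoint_convergence(times, times, 50, 1), "at least 2")
})

test_that("stationary occupancy series passes the checkpoint test", {
  ok <- 0L
  for (s in 1:10) {
    tr <- simulate_detergent_membrane(box = 10, slab_halfwidth = 1,
                                      n_lipids = 4, n_detergents = 64,
                                      epsilon = 1, step_size = 1,
                                      n_steps = 3000, sample_every = 10,
                                      seed = 700 + s)
    oc <- slab_occupancy(tr)
    rep <- checkpoint_convergence(oc$times, oc$fraction,
                                  checkpoint_times = c(1500, 2250, 3000),
                                  tolerance = 3 * oc$se * sqrt(3))
    ok <- ok + rep$equilibrated
  }
  expect_gte(ok, 9L)
})
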