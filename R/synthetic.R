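# Seeded toy-dynamics generators. Each produces a Trajectory whose
# statistics have a closed-form expectation, so every downstream analysis
# can be checked against an exact oracle rather than against opaque MD.

#' Equilibrium slab occupancy of the square-well membrane model
#'
#' For independent particles in a periodic box with potential U = -epsilon
#' inside a slab of width `h` (and 0 outside), the stationary fraction of
#' particles inside the slab is
#' `f_eq = h e^epsilon / (h e^epsilon + (Lz - h))`.
#'
#' @param epsilon Well depth in kT units (dimensionless).
#' @param slab_width Slab width `h` in nm.
#' @param lz Box extent along z in nm.
#' @return The equilibrium inside-slab fraction.
#' @export
slab_occupancy_expected <- function(epsilon, slab_width, lz) {
  if (any(slab_width >= lz)) stop("slab width must be < Lz", call. = FALSE)
  w <- slab_width * exp(epsilon)
  w / (w + (lz - slab_width))
}

#' Simulate detergent partitioning into a lipid slab
#'
#' Single-particle Metropolis Monte Carlo for `n_detergents` independent
#' particles in the square-well slab potential (U = -epsilon for
#' `|z - z_center| <= h/2`, 0 elsewhere), periodic in all axes. Proposals
#' are uniform displacements in a cube of edge `2 * step_size`; detailed
#' balance holds, so the stationary slab occupancy equals
#' [slab_occupancy_expected()]. Lipid pseudo-atoms are static, placed on two
#' square leaflet grids at `z_center +- h/4`.
#'
#' @param box Periodic box (nm); see [as_box()].
#' @param slab_halfwidth Half-width h/2 of the slab (nm); the slab is
#'   `|z - z_center| <= h/2` with `z_center = Lz/2`.
#' @param n_lipids Number of static lipid pseudo-atoms (split over two
#'   leaflets).
#' @param n_detergents Number of detergent particles (>= 1).
#' @param epsilon Slab well depth in kT units; larger values mean stronger
#'   membrane affinity.
#' @param step_size Maximum per-axis displacement per move (nm).
#' @param n_steps Number of Monte Carlo sweeps.
#' @param sample_every Record a frame every this many sweeps.
#' @param seed Integer seed; the run is fully reproducible.
#' @param species Detergent species label.
#' @return A `"trajectory"` with `lipid` and `detergent` molecules. The slab
#'   geometry and `epsilon` are stored in `attr(, "slab")`.
#' @export
simulate_detergent_membrane <- function(box, slab_halfwidth, n_lipids,
                                        n_detergents, epsilon,
                                        step_size = 0.5, n_steps = 2000L,
                                        sample_every = 10L, seed = 1L,
                                        species = "DET") {
  box <- as_box(box)
  h <- 2 * slab_halfwidth
  if (h <= 0) stop("slab_halfwidth must be positive", call. = FALSE)
  if (h >= box[3]) stop("slab width h must be < Lz", call. = FALSE)
  if (n_detergents < 1L) stop("n_detergents must be >= 1", call. = FALSE)
  if (step_size <= 0) stop("step_size must be positive", call. = FALSE)
  if (sample_every < 1L || n_steps < sample_every) {
    stop("need n_steps >= sample_every >= 1", call. = FALSE)
  }
  set.seed(as.integer(seed))
  zc <- box[3] / 2

  lip <- .leaflet_grid(n_lipids, box, zc, h)
  pos <- cbind(stats::runif(n_detergents, 0, box[1]),
               stats::runif(n_detergents, 0, box[2]),
               stats::runif(n_detergents, 0, box[3]))
  inside <- function(z) abs(z - zc) <= h / 2

  n_rec <- n_steps %/% sample_every
  frames <- vector("list", n_rec)
  rec <- 0L
  in_old <- inside(pos[, 3])
  for (s in seq_len(n_steps)) {
    prop <- pos + matrix(stats::runif(3L * n_detergents, -step_size, step_size),
                         n_detergents, 3L)
    prop <- prop %% rep(box, each = n_detergents)
    in_new <- inside(prop[, 3])
    # dU = -epsilon * (in_new - in_old); accept with min(1, exp(-dU))
    acc <- stats::runif(n_detergents) < exp(epsilon * (in_new - in_old))
    pos[acc, ] <- prop[acc, , drop = FALSE]
    in_old[acc] <- in_new[acc]
    if (s %% sample_every == 0L) {
      rec <- rec + 1L
      frames[[rec]] <- frame(time = s, box = box, coords = rbind(lip, pos))
    }
  }

  n_l <- nrow(lip)
  atoms <- data.frame(
    atom_id = seq_len(n_l + n_detergents),
    name = c(rep("P", n_l), rep("C1", n_detergents)),
    element = "C",
    molecule_id = seq_len(n_l + n_detergents),
    molecule_class = c(rep("lipid", n_l), rep("detergent", n_detergents)),
    species = c(rep("LIP", n_l), rep(species, n_detergents)),
    stringsAsFactors = FALSE
  )
  traj <- trajectory(topology(atoms), frames)
  attr(traj, "slab") <- list(z_center = zc, halfwidth = h / 2, epsilon = epsilon)
  traj
}

# two square leaflet grids at z_center +- h/4; exact placement is arbitrary
.leaflet_grid <- function(n_lipids, box, zc, h) {
  if (n_lipids < 1L) return(matrix(numeric(0), 0, 3))
  n_up <- ceiling(n_lipids / 2)
  one <- function(n, z) {
    if (n < 1L) return(matrix(numeric(0), 0, 3))
    m <- ceiling(sqrt(n))
    g <- expand.grid(i = seq_len(m) - 0.5, j = seq_len(m) - 0.5)[seq_len(n), ]
    cbind(g$i * box[1] / m, g$j * box[2] / m, z)
  }
  rbind(one(n_up, zc + h / 4), one(n_lipids - n_up, zc - h / 4))
}

#' Per-frame and mean slab occupancy of detergent particles
#'
#' @param traj A trajectory from [simulate_detergent_membrane()] (slab
#'   geometry is read from its attributes unless given explicitly).
#' @param z_center,halfwidth Optional slab geometry overrides (nm).
#' @param window Time window `c(t0, t1)`; `NULL` selects the second half.
#' @return A list with `times`, per-frame `fraction`, the window `mean`, and
#'   a block-averaged standard error `se`.
#' @export
slab_occupancy <- function(traj, z_center = NULL, halfwidth = NULL,
                           window = NULL) {
  slab <- attr(traj, "slab")
  z_center <- z_center %||% slab$z_center
  halfwidth <- halfwidth %||% slab$halfwidth
  if (is.null(z_center) || is.null(halfwidth)) {
    stop("slab geometry not available; supply z_center and halfwidth",
         call. = FALSE)
  }
  det <- traj$topology$atoms$molecule_class == "detergent"
  if (!any(det)) stop("trajectory contains no detergent atoms", call. = FALSE)
  frac <- vapply(traj$frames, function(f) {
    mean(abs(f$coords[det, 3] - z_center) <= halfwidth)
  }, numeric(1))
  idx <- window_frames(traj, window)
  list(times = traj_times(traj), fraction = frac,
       mean = mean(frac[idx]), se = block_se(frac[idx]))
}

#' Block-averaged standard error of a correlated series
#'
#' @param x Numeric series.
#' @param n_blocks Number of blocks (default 20, reduced for short series).
#' @return Standard error of the series mean estimated from block means.
#' @export
block_se <- function(x, n_blocks = 20L) {
  n_blocks <- max(2L, min(n_blocks, length(x) %/% 2L))
  blk <- split(x, cut(seq_along(x), n_blocks, labels = FALSE))
  means <- vapply(blk, mean, numeric(1))
  stats::sd(means) / sqrt(length(means))
}

#' Simulate a protein as Ornstein-Uhlenbeck residue fluctuations
#'
#' Each coordinate of each residue pseudo-atom follows the discrete OU
#' update `x <- xbar + a (x - xbar) + sigma_i sqrt(1 - a^2) xi` with
#' `a = exp(-1/tau)` and standard normal `xi`, initialized from the
#' stationary distribution. The stationary per-coordinate standard deviation
#' is `sigma_i`, so the expected RMSF of residue i is `sigma_i * sqrt(3)`.
#'
#' @param reference_coords n-by-3 matrix of residue reference positions (nm).
#' @param sigma Per-residue stationary standard deviation (nm); scalar or
#'   length-n vector, all `>= 0`.
#' @param tau Correlation time in frames (> 0).
#' @param n_frames Number of frames to generate.
#' @param seed Integer seed.
#' @param box Optional box; defaults to the coordinate span plus a 2 nm
#'   margin per side.
#' @param species Protein species label.
#' @return A `"trajectory"` with one protein molecule, one pseudo-atom
#'   (named `CA`) per residue.
#' @export
simulate_protein_fluctuations <- function(reference_coords, sigma, tau,
                                          n_frames, seed = 1L, box = NULL,
                                          species = "PROT") {
  ref <- as.matrix(reference_coords)
  if (ncol(ref) != 3L) stop("reference_coords must be n x 3", call. = FALSE)
  n <- nrow(ref)
  if (length(sigma) == 1L) sigma <- rep(sigma, n)
  if (length(sigma) != n) {
    stop(sprintf("length mismatch: %d sigma values for %d residues",
                 length(sigma), n), call. = FALSE)
  }
  if (any(sigma < 0)) stop("sigma must be >= 0 elementwise", call. = FALSE)
  if (tau <= 0) stop("tau must be > 0", call. = FALSE)
  if (n_frames < 1L) stop("n_frames must be >= 1", call. = FALSE)
  set.seed(as.integer(seed))

  a <- exp(-1 / tau)
  b <- sqrt(1 - a^2)
  sig3 <- rep(sigma, 3L)  # column-major: x block, y block, z block
  prev <- stats::rnorm(3L * n) * sig3
  dev <- matrix(0, n_frames, 3L * n)
  for (t in seq_len(n_frames)) {
    prev <- a * prev + b * sig3 * stats::rnorm(3L * n)
    dev[t, ] <- prev
  }
  if (is.null(box)) {
    span <- apply(ref, 2, function(v) diff(range(v)))
    box <- span + 4 + 8 * max(sigma)
  }
  box <- as_box(box)
  frames <- lapply(seq_len(n_frames), function(t) {
    frame(time = t, box = box,
          coords = ref + matrix(dev[t, ], n, 3L))
  })
  atoms <- data.frame(
    atom_id = seq_len(n), name = "CA", element = "C", molecule_id = 1L,
    molecule_class = "protein", species = species,
    residue_index = seq_len(n), stringsAsFactors = FALSE
  )
  trajectory(topology(atoms), frames)
}

#' Place head/tail detergent particles with regional propensities
#'
#' Per frame, each head (tail) particle selects a residue range with
#' probability equal to that range's head (tail) propensity (leftover
#' probability mass, when the propensities sum to less than 1, places the
#' particle in bulk solvent away from the protein; propensities summing to
#' more than 1 are normalized). Within the chosen range a residue is drawn
#' uniformly and the particle is placed within `contact_distance` of it, so
#' expected per-residue contact occupancies follow directly from the
#' propensity table.
#'
#' @param reference_coords n-by-3 matrix of static protein residue positions
#'   (nm). Residues should be spaced more than `2 * contact_distance` apart
#'   for contacts to be unambiguous.
#' @param regions Data frame with columns `name`, `start`, `end`, `head`,
#'   `tail` (propensities in `[0, 1]`).
#' @param n_detergent_particles Number of particles per role (head and tail).
#' @param contact_distance Placement radius in nm.
#' @param n_frames Number of frames.
#' @param seed Integer seed.
#' @param box Optional box; defaults to the protein span plus margins.
#' @param species Detergent species label.
#' @return A `"trajectory"` with a static protein and role-labeled
#'   single-site detergent molecules.
#' @export
place_regio_detergents <- function(reference_coords, regions,
                                   n_detergent_particles, contact_distance,
                                   n_frames, seed = 1L, box = NULL,
                                   species = "DET") {
  ref <- as.matrix(reference_coords)
  n_res <- nrow(ref)
  regions <- as.data.frame(regions)
  if (!nrow(regions)) stop("empty residue_ranges", call. = FALSE)
  req <- c("start", "end", "head", "tail")
  if (!all(req %in% names(regions))) {
    stop("regions needs columns start, end, head, tail", call. = FALSE)
  }
  if (any(regions$head < 0 | regions$head > 1 |
          regions$tail < 0 | regions$tail > 1)) {
    stop("propensities must lie in [0, 1]", call. = FALSE)
  }
  if (any(regions$start < 1L | regions$end > n_res |
          regions$start > regions$end)) {
    stop("region ranges must lie within residue indices", call. = FALSE)
  }
  if (n_detergent_particles < 0L) stop("n_detergent_particles must be >= 0", call. = FALSE)
  if (n_frames < 1L) stop("n_frames must be >= 1", call. = FALSE)
  set.seed(as.integer(seed))

  if (is.null(box)) {
    span <- apply(ref, 2, function(v) diff(range(v)))
    box <- span + 8 * contact_distance + 2
  }
  box <- as_box(box)
  np <- n_detergent_particles

  draw_positions <- function(props) {
    s <- sum(props)
    p <- if (s > 1) props / s else props
    p_bulk <- max(0, 1 - sum(p))
    choice <- sample.int(nrow(regions) + 1L, np, replace = TRUE,
                         prob = c(p, p_bulk))
    out <- matrix(0, np, 3L)
    for (j in seq_len(np)) {
      if (choice[j] <= nrow(regions)) {
        rg <- regions[choice[j], ]
        res <- if (rg$start == rg$end) rg$start else
          sample(seq.int(rg$start, rg$end), 1L)
        dir <- stats::rnorm(3L)
        dir <- dir / sqrt(sum(dir^2))
        out[j, ] <- ref[res, ] + dir * stats::runif(1, 0, 0.95 * contact_distance)
      } else {
        out[j, ] <- .bulk_point(ref, box, 2 * contact_distance)
      }
    }
    out
  }

  frames <- lapply(seq_len(n_frames), function(t) {
    co <- ref
    if (np > 0L) {
      co <- rbind(co, draw_positions(regions$head), draw_positions(regions$tail))
    }
    frame(time = t, box = box, coords = co)
  })

  atoms <- data.frame(
    atom_id = seq_len(n_res), name = "CA", element = "C", molecule_id = 1L,
    molecule_class = "protein", species = "PROT",
    residue_index = seq_len(n_res), role = "none", stringsAsFactors = FALSE
  )
  if (np > 0L) {
    part <- data.frame(
      atom_id = n_res + seq_len(2L * np),
      name = rep(c("O1", "C2"), each = np),
      element = "C",
      molecule_id = 1L + seq_len(2L * np),
      molecule_class = "detergent",
      species = species,
      residue_index = NA_integer_,
      role = rep(c("head", "tail"), each = np),
      stringsAsFactors = FALSE
    )
    atoms <- rbind(atoms, part)
  }
  trajectory(topology(atoms), frames)
}

# rejection-sample a point at least `clearance` (minimum image) from all
# residues; falls back to the farthest rejected candidate
.bulk_point <- function(ref, box, clearance) {
  best <- NULL
  best_d <- -1
  for (try in 1:200) {
    p <- stats::runif(3) * box
    d2 <- min_image_cross_d2(matrix(p, 1, 3), ref, box)
    dmin <- sqrt(min(d2))
    if (dmin > clearance) return(p)
    if (dmin > best_d) { best_d <- dmin; best <- p }
  }
  best
}
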