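# Independent oracles: deliberately naive implementations kept separate
# from the package's code paths.

# minimum-image distance as an explicit minimum over the 27 image
# translations of the wrapped points
brute_min_image_distance <- function(p, q, box) {
  pw <- p %% box
  qw <- q %% box
  best <- Inf
  for (i in -1:1) for (j in -1:1) for (k in -1:1) {
    d <- pw - (qw + c(i, j, k) * box)
    best <- min(best, sqrt(sum(d * d)))
  }
  best
}

# all-pairs molecule contact flags using the 27-image distance
brute_contact_flags <- function(groupA, groupB, cutoff, box) {
  vapply(groupA, function(mol) {
    for (a in seq_len(nrow(mol))) {
      for (b in seq_len(nrow(groupB))) {
        if (brute_min_image_distance(mol[a, ], groupB[b, ], box) <= cutoff) {
          return(TRUE)
        }
      }
    }
    FALSE
  }, logical(1))
}

# faster all-pairs oracle (still explicit 27 images, vectorized over pairs)
brute_contact_matrix <- function(a_coords, a_group, b_coords, b_group,
                                 cutoff, box) {
  aw <- a_coords %% rep(box, each = nrow(a_coords))
  bw <- b_coords %% rep(box, each = nrow(b_coords))
  d2 <- array(Inf, c(nrow(aw), nrow(bw)))
  for (i in -1:1) for (j in -1:1) for (k in -1:1) {
    sh <- c(i, j, k) * box
    dd <- outer(aw[, 1], bw[, 1] + sh[1], "-")^2 +
      outer(aw[, 2], bw[, 2] + sh[2], "-")^2 +
      outer(aw[, 3], bw[, 3] + sh[3], "-")^2
    d2 <- pmin(d2, dd)
  }
  hit <- d2 <= cutoff^2
  n_a <- max(a_group)
  n_b <- max(b_group)
  m <- matrix(FALSE, n_a, n_b)
  idx <- which(hit, arr.ind = TRUE)
  if (nrow(idx)) m[cbind(a_group[idx[, 1]], b_group[idx[, 2]])] <- TRUE
  m
}

# Horn's quaternion method for optimal superposition RMSD: the largest
# eigenvalue of the 4x4 key matrix gives the optimal (proper) rotation
quaternion_rmsd <- function(mobile, reference) {
  P <- sweep(mobile, 2, colMeans(mobile))
  Q <- sweep(reference, 2, colMeans(reference))
  S <- crossprod(P, Q)
  K <- matrix(c(
    S[1, 1] + S[2, 2] + S[3, 3], S[2, 3] - S[3, 2], S[3, 1] - S[1, 3], S[1, 2] - S[2, 1],
    S[2, 3] - S[3, 2], S[1, 1] - S[2, 2] - S[3, 3], S[1, 2] + S[2, 1], S[3, 1] + S[1, 3],
    S[3, 1] - S[1, 3], S[1, 2] + S[2, 1], -S[1, 1] + S[2, 2] - S[3, 3], S[2, 3] + S[3, 2],
    S[1, 2] - S[2, 1], S[3, 1] + S[1, 3], S[2, 3] + S[3, 2], -S[1, 1] - S[2, 2] + S[3, 3]
  ), 4, 4, byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  n <- nrow(P)
  sqrt(max(0, (sum(P^2) + sum(Q^2) - 2 * lam) / n))
}

random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}
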