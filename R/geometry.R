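#' Minimum-image distance between two points
#'
#' Distance on the torus defined by an orthorhombic periodic box: each
#' Cartesian displacement is wrapped to the nearest periodic image before the
#' Euclidean norm is taken.
#'
#' @param p,q Numeric 3-vectors (nm).
#' @param box Periodic box (see [as_box()]).
#' @return The minimum-image distance in nm.
#' @export
min_image_distance <- function(p, q, box) {
  box <- as_box(box)
  d <- as.numeric(p) - as.numeric(q)
  if (length(d) != 3L) stop("p and q must be 3-vectors", call. = FALSE)
  d <- d - box * round(d / box)
  sqrt(sum(d * d))
}

# Squared minimum-image distances between all rows of a (na x 3) and b (nb x 3).
min_image_cross_d2 <- function(a, b, box) {
  d2 <- matrix(0, nrow(a), nrow(b))
  for (k in 1:3) {
    dk <- outer(a[, k], b[, k], "-")
    dk <- dk - box[k] * round(dk / box[k])
    d2 <- d2 + dk * dk
  }
  d2
}

# Cell-list contact search between group A atoms (with a per-atom molecule
# index) and group B atoms (optionally with a molecule index of their own).
# The cell edge is >= cutoff by construction (n_cells = floor(L / cutoff)),
# so scanning the 27 neighboring cells is sufficient; with fewer than three
# cells per axis the wrapped neighborhood degenerates to all cells, which is
# still correct under the explicit minimum-image distance used per pair.
# Returns per-A-molecule contact flags and, if `pairs`, the unique
# (A molecule, B molecule) contact pairs. The contact boundary is CLOSED
# (distance <= cutoff counts).
cell_contacts <- function(a_coords, a_group, b_coords, b_group = NULL,
                          cutoff, box, pairs = FALSE) {
  box <- as_box(box)
  check_cutoff(cutoff, box)
  if (!nrow(b_coords)) stop("group B is empty", call. = FALSE)
  if (!nrow(a_coords)) stop("group A is empty", call. = FALSE)
  n_a_mol <- max(a_group)
  if (is.null(b_group)) b_group <- rep(1L, nrow(b_coords))

  aw <- a_coords %% rep(box, each = nrow(a_coords))
  bw <- b_coords %% rep(box, each = nrow(b_coords))
  nc <- pmax(1L, as.integer(floor(box / cutoff)))
  edge <- box / nc

  cell_index <- function(w) {
    ci <- matrix(0L, nrow(w), 3L)
    for (k in 1:3) {
      ci[, k] <- pmin(nc[k] - 1L, pmax(0L, as.integer(floor(w[, k] / edge[k]))))
    }
    ci
  }
  cia <- cell_index(aw)
  cib <- cell_index(bw)
  idb <- cib[, 1] + nc[1] * (cib[, 2] + nc[2] * cib[, 3])
  ida <- cia[, 1] + nc[1] * (cia[, 2] + nc[2] * cia[, 3])
  b_cells <- split(seq_len(nrow(bw)), idb)

  offsets <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  flags <- logical(n_a_mol)
  pair_list <- if (pairs) vector("list", 64L) else NULL
  np <- 0L
  cut2 <- cutoff * cutoff

  for (cell in split(seq_len(nrow(aw)), ida)) {
    c3 <- cia[cell[1], ]
    nb <- sweep(offsets, 2L, c3, "+")
    for (k in 1:3) nb[, k] <- nb[, k] %% nc[k]
    neigh <- unique(as.integer(nb[, 1] + nc[1] * (nb[, 2] + nc[2] * nb[, 3])))
    cand <- unlist(b_cells[as.character(neigh)], use.names = FALSE)
    if (is.null(cand) || !length(cand)) next
    d2 <- min_image_cross_d2(aw[cell, , drop = FALSE],
                             bw[cand, , drop = FALSE], box)
    hit <- d2 <= cut2
    any_a <- rowSums(hit) > 0
    flags[a_group[cell[any_a]]] <- TRUE
    if (pairs && any(hit)) {
      idx <- which(hit, arr.ind = TRUE)
      np <- np + 1L
      pair_list[[np]] <- cbind(a_group[cell[idx[, 1]]], b_group[cand[idx[, 2]]])
    }
  }
  out <- list(flags = flags)
  if (pairs) {
    pm <- if (np) unique(do.call(rbind, pair_list[seq_len(np)])) else
      matrix(integer(0), 0, 2)
    colnames(pm) <- c("a_mol", "b_mol")
    out$pairs <- pm
  }
  out
}

#' Flag molecules with any atom within a cutoff of another group
#'
#' For each A-molecule, tests whether ANY of its atoms lies within `cutoff`
#' (minimum image, closed boundary: distance equal to the cutoff counts) of
#' ANY atom of group B. Implemented with a cell list whose cell edge is at
#' least the cutoff.
#'
#' @param groupA List of per-molecule coordinate matrices (each n-by-3, nm).
#' @param groupB Numeric matrix of group-B atom coordinates (nm).
#' @param cutoff Contact cutoff in nm; must be below half the smallest box
#'   extent.
#' @param box Periodic box (see [as_box()]).
#' @return Logical vector, one flag per A-molecule.
#' @export
neighbor_any_within <- function(groupA, groupB, cutoff, box) {
  if (!is.list(groupA) || !length(groupA)) {
    stop("groupA must be a non-empty list of coordinate matrices", call. = FALSE)
  }
  groupA <- lapply(groupA, function(m) {
    m <- as.matrix(m)
    if (!nrow(m) || ncol(m) != 3L) {
      stop("each groupA molecule needs an n x 3 coordinate matrix", call. = FALSE)
    }
    m
  })
  groupB <- as.matrix(groupB)
  if (!nrow(groupB)) stop("group B is empty", call. = FALSE)
  a_group <- rep(seq_along(groupA), vapply(groupA, nrow, integer(1)))
  a_coords <- do.call(rbind, groupA)
  cell_contacts(a_coords, a_group, groupB, cutoff = cutoff, box = box)$flags
}
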