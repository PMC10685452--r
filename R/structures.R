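#' Validate an orthorhombic periodic box
#'
#' Boxes are stored as plain numeric length-3 vectors of edge lengths in nm.
#' Only orthorhombic (rectangular) boxes are supported; triclinic input is
#' rejected at the parsing boundary.
#'
#' @param lengths Numeric vector of three positive edge lengths (nm). A
#'   single value is recycled to a cubic box.
#' @return A validated numeric length-3 vector.
#' @export
as_box <- function(lengths) {
  b <- as.numeric(lengths)
  if (length(b) == 1L) b <- rep(b, 3L)
  if (length(b) != 3L || anyNA(b) || any(!is.finite(b)) || any(b <= 0)) {
    stop("box must be three positive finite edge lengths in nm", call. = FALSE)
  }
  b
}

# cutoff-based queries are only unambiguous below half the smallest extent
check_cutoff <- function(cutoff, box) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L || !is.finite(cutoff) ||
      cutoff <= 0) {
    stop("cutoff must be a single positive finite value (nm)", call. = FALSE)
  }
  if (cutoff >= min(box) / 2) {
    stop(sprintf(
      "cutoff %.4g nm must be < half the smallest box extent (%.4g nm): minimum-image ambiguity",
      cutoff, min(box) / 2
    ), call. = FALSE)
  }
  invisible(cutoff)
}

.molecule_classes <- c("protein", "lipid", "detergent", "solvent", "ion")

#' Guess the element from an atom name
#'
#' Fallback rule used when a format carries no element column: the first
#' alphabetic character of the atom name, uppercased.
#'
#' @param name Character vector of atom names.
#' @return Character vector of one-letter element guesses.
#' @export
infer_element <- function(name) {
  el <- toupper(sub("^[^A-Za-z]*([A-Za-z]).*$", "\\1", name))
  el[!grepl("[A-Za-z]", name)] <- ""
  el
}

is_heavy_element <- function(element) {
  !(toupper(trimws(element)) %in% c("H", "D"))
}

#' Construct an annotated topology
#'
#' A topology is an ordered table of atom records; its row order defines the
#' coordinate order of every frame. Molecules are contiguous runs of a shared
#' `molecule_id`; no bond perception is attempted.
#'
#' @param atoms A data.frame with columns `atom_id`, `name`, `element`,
#'   `molecule_id`, `molecule_class`, `species`, and optionally
#'   `residue_index` (protein only) and `role` (`"head"`/`"tail"`/`"none"`,
#'   detergent only). `is_heavy` is derived from the element.
#' @return An object of class `"topology"`.
#' @export
topology <- function(atoms) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  if (nrow(atoms) == 0L) stop("topology must contain at least one atom", call. = FALSE)
  req <- c("atom_id", "name", "element", "molecule_id", "molecule_class", "species")
  miss <- setdiff(req, names(atoms))
  if (length(miss)) {
    stop("topology is missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!"residue_index" %in% names(atoms)) atoms$residue_index <- NA_integer_
  if (!"role" %in% names(atoms)) atoms$role <- "none"
  atoms$role[is.na(atoms$role)] <- "none"
  atoms$atom_id <- as.integer(atoms$atom_id)
  atoms$molecule_id <- as.integer(atoms$molecule_id)
  atoms$residue_index <- as.integer(atoms$residue_index)

  if (anyDuplicated(atoms$atom_id)) stop("atom_ids must be unique", call. = FALSE)
  if (any(atoms$atom_id < 1L)) stop("atom_ids must be >= 1", call. = FALSE)
  bad <- !(atoms$molecule_class %in% .molecule_classes)
  if (any(bad)) {
    stop("unknown molecule_class: ",
         paste(unique(atoms$molecule_class[bad]), collapse = ", "), call. = FALSE)
  }
  if (!all(atoms$role %in% c("head", "tail", "none"))) {
    stop("role must be one of head, tail, none", call. = FALSE)
  }
  if (any(atoms$role != "none" & atoms$molecule_class != "detergent")) {
    stop("head/tail roles are only valid for detergent atoms", call. = FALSE)
  }
  pr <- atoms$molecule_class == "protein"
  if (any(pr & (is.na(atoms$residue_index) | atoms$residue_index < 1L))) {
    stop("protein atoms require residue_index >= 1", call. = FALSE)
  }
  cls_per_mol <- tapply(atoms$molecule_class, atoms$molecule_id,
                        function(x) length(unique(x)))
  sp_per_mol <- tapply(atoms$species, atoms$molecule_id,
                       function(x) length(unique(x)))
  if (any(cls_per_mol > 1L) || any(sp_per_mol > 1L)) {
    stop("all atoms of one molecule_id must share molecule_class and species",
         call. = FALSE)
  }
  atoms$is_heavy <- is_heavy_element(atoms$element)
  structure(list(atoms = atoms), class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  counts <- table(factor(x$atoms$molecule_class, levels = .molecule_classes))
  cat("topology:", nrow(x$atoms), "atoms,",
      length(unique(x$atoms$molecule_id)), "molecules\n")
  cat("  atoms by class:",
      paste(sprintf("%s=%d", names(counts), as.integer(counts)), collapse = " "),
      "\n")
  invisible(x)
}

#' Number of atoms in a topology
#' @param top A `"topology"` object.
#' @return Integer atom count.
#' @export
n_atoms <- function(top) nrow(top$atoms)

#' Construct a coordinate frame
#'
#' @param time Time stamp in ps.
#' @param box Periodic box (see [as_box()]).
#' @param coords Numeric n-by-3 matrix of coordinates in nm.
#' @return An object of class `"md_frame"`.
#' @export
frame <- function(time, box, coords) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("coords must be an n x 3 matrix", call. = FALSE)
  storage.mode(coords) <- "double"
  if (anyNA(coords) || any(!is.finite(coords))) {
    stop("coordinates must be finite", call. = FALSE)
  }
  structure(list(time = as.numeric(time), box = as_box(box), coords = coords),
            class = "md_frame")
}

#' Construct a trajectory
#'
#' @param topology A `"topology"` object.
#' @param frames List of `"md_frame"` objects with strictly increasing times
#'   and coordinate counts matching the topology.
#' @return An object of class `"trajectory"`.
#' @export
trajectory <- function(topology, frames) {
  if (!inherits(topology, "topology")) stop("topology must be a topology object", call. = FALSE)
  if (!length(frames)) stop("trajectory must contain at least one frame", call. = FALSE)
  na <- n_atoms(topology)
  for (f in frames) {
    if (!inherits(f, "md_frame")) stop("frames must be md_frame objects", call. = FALSE)
    if (nrow(f$coords) != na) {
      stop(sprintf("frame has %d coordinates but topology has %d atoms",
                   nrow(f$coords), na), call. = FALSE)
    }
  }
  times <- vapply(frames, `[[`, numeric(1), "time")
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop("frame times must be strictly increasing", call. = FALSE)
  }
  structure(list(topology = topology, frames = frames), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  times <- traj_times(x)
  cat("trajectory:", length(x$frames), "frames,", n_atoms(x$topology),
      "atoms, t =", sprintf("%g..%g ps", times[1], times[length(times)]), "\n")
  print(x$topology)
  invisible(x)
}

#' Frame times of a trajectory
#' @param traj A `"trajectory"`.
#' @return Numeric vector of frame times (ps).
#' @export
traj_times <- function(traj) vapply(traj$frames, `[[`, numeric(1), "time")

#' Number of frames in a trajectory
#' @param traj A `"trajectory"`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) length(traj$frames)

# Indices of frames inside a closed time window; window = NULL means the
# second half of the trajectory (default production-averaging convention).
window_frames <- function(traj, window = NULL) {
  times <- traj_times(traj)
  if (is.null(window)) {
    mid <- times[1] + (times[length(times)] - times[1]) / 2
    idx <- which(times >= mid)
  } else {
    if (length(window) != 2L || window[2] < window[1]) {
      stop("window must be c(t0, t1) with t1 >= t0", call. = FALSE)
    }
    idx <- which(times >= window[1] & times <= window[2])
  }
  if (!length(idx)) stop("empty time window: no frames selected", call. = FALSE)
  idx
}
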