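# Head/tail regioselectivity: where do detergent hydrophilic head groups
# versus hydrophobic alkyl tail groups contact the protein? Quantified as
# per-residue contact occupancy (fraction of frames with at least one
# role-labeled heavy atom within the cutoff), a deliberately copy-number
# robust statistic.

#' Per-residue head/tail contact occupancy map
#'
#' Per residue and frame, a head (tail) contact occurs iff any head-role
#' (tail-role) detergent heavy atom is within `cutoff` (minimum image,
#' closed boundary) of any of the residue's heavy atoms. Occupancy is the
#' fraction of frames with a contact.
#'
#' @param traj A `"trajectory"` with protein atoms and role-labeled
#'   detergent atoms.
#' @param cutoff Contact cutoff in nm (default 0.6, as for invasion).
#' @return An object of class `"contact_map"`: `map` data frame
#'   (`residue_index`, `head_occupancy`, `tail_occupancy`), `cutoff`,
#'   `n_frames`.
#' @export
headtail_contact_map <- function(traj, cutoff = 0.6) {
  at <- traj$topology$atoms
  prot_rows <- which(at$molecule_class == "protein" & at$is_heavy)
  if (!length(prot_rows)) stop("no protein atoms in trajectory", call. = FALSE)
  head_rows <- which(at$role == "head" & at$is_heavy)
  tail_rows <- which(at$role == "tail" & at$is_heavy)
  if (!length(head_rows) && !length(tail_rows)) {
    stop("no role-labeled detergent atoms (head/tail) in trajectory", call. = FALSE)
  }
  resids <- sort(unique(at$residue_index[prot_rows]))
  res_group <- match(at$residue_index[prot_rows], resids)

  occ <- function(rows) {
    if (!length(rows)) return(rep(0, length(resids)))
    counts <- numeric(length(resids))
    for (f in traj$frames) {
      fl <- cell_contacts(f$coords[prot_rows, , drop = FALSE], res_group,
                          f$coords[rows, , drop = FALSE],
                          cutoff = cutoff, box = f$box)$flags
      counts <- counts + fl
    }
    counts / length(traj$frames)
  }
  structure(list(
    map = data.frame(
      residue_index = resids,
      head_occupancy = occ(head_rows),
      tail_occupancy = occ(tail_rows)
    ),
    cutoff = cutoff,
    n_frames = length(traj$frames)
  ), class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf(
    "head/tail contact map: %d residues, mean head occupancy %.3f, mean tail occupancy %.3f (%d frames)\n",
    nrow(x$map), mean(x$map$head_occupancy), mean(x$map$tail_occupancy),
    x$n_frames))
  invisible(x)
}

#' Summarize a contact map over named residue regions
#'
#' @param map A `"contact_map"` from [headtail_contact_map()].
#' @param regions Data frame with columns `name`, `start`, `end` (inclusive
#'   residue ranges; must be within bounds and non-overlapping). Region
#'   files in the flat config dialect (`name = "TM11"` sections with
#'   `range = [start, end]`) can be loaded with [read_regions()].
#' @return A data frame with per-region mean head and tail occupancy and the
#'   head:tail ratio (`NA` when the tail occupancy is 0, reported as
#'   undefined).
#' @export
region_contact_summary <- function(map, regions) {
  regions <- as.data.frame(regions)
  if (!all(c("name", "start", "end") %in% names(regions))) {
    stop("regions needs columns name, start, end", call. = FALSE)
  }
  resids <- map$map$residue_index
  if (any(regions$start > regions$end)) {
    stop("region ranges must have start <= end", call. = FALSE)
  }
  if (any(regions$start < min(resids) | regions$end > max(resids))) {
    stop("region ranges out of residue index bounds", call. = FALSE)
  }
  covered <- unlist(mapply(seq.int, regions$start, regions$end, SIMPLIFY = FALSE))
  if (anyDuplicated(covered)) {
    stop("overlapping region ranges", call. = FALSE)
  }
  out <- do.call(rbind, lapply(seq_len(nrow(regions)), function(i) {
    sel <- resids >= regions$start[i] & resids <= regions$end[i]
    h <- mean(map$map$head_occupancy[sel])
    t <- mean(map$map$tail_occupancy[sel])
    data.frame(
      name = regions$name[i], start = regions$start[i], end = regions$end[i],
      mean_head_occupancy = h, mean_tail_occupancy = t,
      head_tail_ratio = if (t == 0) NA_real_ else h / t,
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' Read named residue regions from a flat config file
#'
#' Each region is a section with a `range` array, e.g.
#' \preformatted{
#' [TM11]
#' range = [310, 335]
#' head = 0.1   # optional propensities, used by the regio generator
#' tail = 0.7
#' }
#'
#' @param path Path to the regions file.
#' @return A data frame with columns `name`, `start`, `end` and, when
#'   present, `head` and `tail`.
#' @export
read_regions <- function(path) {
  cfg <- read_config(path)
  secs <- Filter(function(x) is.list(x) && !is.null(x$range), cfg)
  if (!length(secs)) stop("no region sections with a range found in ", path, call. = FALSE)
  out <- do.call(rbind, lapply(names(secs), function(nm) {
    rg <- secs[[nm]]$range
    if (length(rg) != 2L) stop("region ", nm, " needs range = [start, end]", call. = FALSE)
    data.frame(name = nm, start = as.integer(rg[1]), end = as.integer(rg[2]),
               head = as.numeric(secs[[nm]]$head %||% NA_real_),
               tail = as.numeric(secs[[nm]]$tail %||% NA_real_),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
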