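# Membrane-invasion statistics: the per-system fraction of detergent
# molecules in heavy-atom contact with any lipid (the Methods-style total),
# the per-lipid ranked profile (the figure-style view), and checkpoint-based
# equilibration assessment. A detergent molecule is "in contact" iff any of
# its heavy atoms is within the cutoff (default 0.6 nm, closed boundary,
# minimum image) of any lipid heavy atom.

# shared per-frame contact machinery; returns per-frame flag vectors or
# detergent x lipid pair matrices
.invasion_frames <- function(traj, cutoff, idx, pairs = FALSE,
                             heavy_only = TRUE) {
  at <- traj$topology$atoms
  keep <- if (heavy_only) at$is_heavy else rep(TRUE, nrow(at))
  det_rows <- which(at$molecule_class == "detergent" & keep)
  lip_rows <- which(at$molecule_class == "lipid" & keep)
  if (!length(det_rows) || !length(unique(at$molecule_id[at$molecule_class == "lipid"]))) {
    stop("trajectory must contain at least one detergent and one lipid molecule",
         call. = FALSE)
  }
  if (!length(lip_rows)) {
    stop("no lipid heavy atoms available for contact analysis", call. = FALSE)
  }
  det_mol <- match(at$molecule_id[det_rows], unique(at$molecule_id[det_rows]))
  lip_mol <- match(at$molecule_id[lip_rows], unique(at$molecule_id[lip_rows]))
  n_det <- max(det_mol)
  n_lip <- max(lip_mol)
  lapply(idx, function(i) {
    f <- traj$frames[[i]]
    res <- cell_contacts(f$coords[det_rows, , drop = FALSE], det_mol,
                         f$coords[lip_rows, , drop = FALSE], lip_mol,
                         cutoff = cutoff, box = f$box, pairs = pairs)
    if (pairs) {
      m <- matrix(FALSE, n_det, n_lip)
      if (nrow(res$pairs)) m[res$pairs] <- TRUE
      m
    } else {
      res$flags
    }
  })
}

#' Total detergent invasion fraction
#'
#' Per frame, the percentage of detergent molecules with at least one heavy
#' atom within `cutoff` of any lipid heavy atom, averaged over the analysis
#' window.
#'
#' @param traj A `"trajectory"` containing detergent and lipid molecules.
#' @param cutoff Contact cutoff in nm (default 0.6, i.e. 6 Angstrom).
#' @param window Time window `c(t0, t1)` for averaging; `NULL` selects the
#'   second half of the trajectory.
#' @param heavy_only Use heavy atoms on the detergent side as well as the
#'   lipid side (default `TRUE`).
#' @return An object of class `"invasion_result"`: per-frame series
#'   (`per_frame`, all frames), `mean_fraction` and `sd_fraction` over the
#'   window (percent), plus `cutoff`, `n_frames_used`.
#' @export
detergent_invasion_fraction <- function(traj, cutoff = 0.6, window = NULL,
                                        heavy_only = TRUE) {
  idx <- window_frames(traj, window)
  all_idx <- seq_len(n_frames(traj))
  flags <- .invasion_frames(traj, cutoff, all_idx, heavy_only = heavy_only)
  frac <- vapply(flags, function(fl) 100 * mean(fl), numeric(1))
  structure(list(
    per_frame = data.frame(time = traj_times(traj), fraction_pct = frac),
    mean_fraction = mean(frac[all_idx %in% idx]),
    sd_fraction = stats::sd(frac[all_idx %in% idx]),
    cutoff = cutoff,
    window_index = idx,
    n_frames_used = length(idx)
  ), class = "invasion_result")
}

#' @export
print.invasion_result <- function(x, ...) {
  cat(sprintf(
    "invasion: %.2f%% +/- %.2f%% of detergent molecules within %.2f nm of lipid (%d frames)\n",
    x$mean_fraction, x$sd_fraction, x$cutoff, x$n_frames_used))
  invisible(x)
}

#' Per-lipid detergent contact profile
#'
#' For each lipid molecule, the time-averaged percentage of detergent
#' molecules with at least one heavy atom within `cutoff` of that lipid's
#' heavy atoms, sorted from highest to lowest. A detergent contacting
#' several lipids counts toward each of them (no exclusive assignment). The
#' summary mean and standard deviation are taken over lipids.
#'
#' @inheritParams detergent_invasion_fraction
#' @return An object of class `"lipid_profile"`: `profile` data frame
#'   (`lipid_molecule_id`, `avg_pct`, `rank`), `mean_over_lipids`,
#'   `sd_over_lipids`, `cutoff`, `n_frames_used`.
#' @export
per_lipid_detergent_profile <- function(traj, cutoff = 0.6, window = NULL,
                                        heavy_only = TRUE) {
  idx <- window_frames(traj, window)
  mats <- .invasion_frames(traj, cutoff, idx, pairs = TRUE,
                           heavy_only = heavy_only)
  n_det <- nrow(mats[[1]])
  # per frame and lipid: % of detergent molecules contacting that lipid
  per_lipid <- Reduce(`+`, lapply(mats, function(m) 100 * colSums(m) / n_det))
  per_lipid <- per_lipid / length(mats)
  at <- traj$topology$atoms
  lip_ids <- unique(at$molecule_id[at$molecule_class == "lipid" & at$is_heavy])
  ord <- order(per_lipid, decreasing = TRUE)
  structure(list(
    profile = data.frame(
      lipid_molecule_id = lip_ids[ord],
      avg_pct = per_lipid[ord],
      rank = seq_along(ord)
    ),
    mean_over_lipids = mean(per_lipid),
    sd_over_lipids = stats::sd(per_lipid),
    cutoff = cutoff,
    n_frames_used = length(idx)
  ), class = "lipid_profile")
}

#' @export
print.lipid_profile <- function(x, ...) {
  cat(sprintf(
    "per-lipid detergent profile: %.2f%% +/- %.2f%% averaged over %d lipids (%d frames)\n",
    x$mean_over_lipids, x$sd_over_lipids, nrow(x$profile), x$n_frames_used))
  invisible(x)
}

#' Checkpoint-based equilibration assessment of a metric series
#'
#' The value at checkpoint t is the mean of the metric over frames in the
#' interval (previous checkpoint, t]; the system is deemed equilibrated when
#' the maximum pairwise difference among the last `k_last` checkpoint values
#' is at most `tolerance`.
#'
#' @param times Frame times of the metric series (ps).
#' @param values Metric values, one per time point.
#' @param checkpoint_times Strictly increasing checkpoint times, all covered
#'   by the series.
#' @param tolerance Equilibration tolerance, same units as the metric.
#' @param k_last Number of trailing checkpoints compared (default 3).
#' @return An object of class `"convergence_report"` with
#'   `checkpoint_times`, `checkpoint_values`, `max_pairwise_delta`,
#'   `equilibrated`, `tolerance`.
#' @export
checkpoint_convergence <- function(times, values, checkpoint_times,
                                   tolerance, k_last = 3L) {
  if (length(times) != length(values)) {
    stop("times and values must have equal length", call. = FALSE)
  }
  ck <- as.numeric(checkpoint_times)
  if (length(ck) < 2L) stop("need at least 2 checkpoints", call. = FALSE)
  if (any(diff(ck) <= 0)) stop("checkpoint times must be strictly increasing", call. = FALSE)
  if (max(ck) > max(times)) {
    stop(sprintf("checkpoint %g is beyond the series end (%g)",
                 max(ck), max(times)), call. = FALSE)
  }
  prev <- c(-Inf, ck[-length(ck)])
  vals <- vapply(seq_along(ck), function(i) {
    sel <- times > prev[i] & times <= ck[i]
    if (!any(sel)) {
      stop(sprintf("no frames in checkpoint interval (%g, %g]", prev[i], ck[i]),
           call. = FALSE)
    }
    mean(values[sel])
  }, numeric(1))
  last <- vals[seq.int(max(1L, length(vals) - k_last + 1L), length(vals))]
  delta <- max(last) - min(last)
  structure(list(
    checkpoint_times = ck,
    checkpoint_values = vals,
    max_pairwise_delta = delta,
    equilibrated = delta <= tolerance,
    tolerance = tolerance
  ), class = "convergence_report")
}

#' @export
print.convergence_report <- function(x, ...) {
  cat("checkpoint convergence:",
      paste(sprintf("%g", x$checkpoint_values), collapse = ", "), "\n")
  cat(sprintf("  max pairwise delta %.4g vs tolerance %.4g -> %s\n",
              x$max_pairwise_delta, x$tolerance,
              if (x$equilibrated) "equilibrated" else "NOT equilibrated"))
  invisible(x)
}
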