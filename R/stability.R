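# Superposition-based per-residue RMSF and delta-RMSF scoring of protein
# structural stabilization, with checkpoint convergence over RMSF profiles.

#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Least-squares optimal rotation and translation mapping `mobile` onto
#' `reference`, reflections excluded by the determinant correction; the
#' returned rotation is always proper (det = +1).
#'
#' @param mobile,reference n-by-3 coordinate matrices (nm), n >= 3.
#' @param weights Optional non-negative per-point weights.
#' @return An object of class `"superposition"` with `rotation` (3x3),
#'   `translation` (3-vector), and the post-fit `rmsd` (nm, weighted when
#'   weights are given).
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  P <- as.matrix(mobile)
  Q <- as.matrix(reference)
  if (ncol(P) != 3L || ncol(Q) != 3L || nrow(P) != nrow(Q)) {
    stop("mobile and reference must be n x 3 matrices of equal size", call. = FALSE)
  }
  n <- nrow(P)
  if (n < 3L) stop("superposition needs at least 3 points", call. = FALSE)
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  if (length(w) != n || any(w < 0) || sum(w) <= 0) {
    stop("weights must be non-negative with positive sum", call. = FALSE)
  }
  w <- w / sum(w)
  cm <- colSums(P * w)
  cr <- colSums(Q * w)
  Pc <- sweep(P, 2L, cm)
  Qc <- sweep(Q, 2L, cr)
  H <- crossprod(Pc * w, Qc)  # 3x3 weighted covariance
  sv <- svd(H)
  scale <- sum(w * rowSums(Pc^2)) + sum(w * rowSums(Qc^2))
  if (sv$d[2] <= 1e-12 * max(sv$d[1], scale, .Machine$double.xmin)) {
    stop("degenerate point set: rank-deficient covariance (collinear or coincident points)",
         call. = FALSE)
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- cr - as.numeric(R %*% cm)
  fitted <- tcrossprod(P, R) + matrix(tr, n, 3L, byrow = TRUE)
  rmsd <- sqrt(sum(w * rowSums((fitted - Q)^2)))
  structure(list(rotation = R, translation = tr, rmsd = rmsd),
            class = "superposition")
}

#' Apply a superposition to coordinates
#'
#' @param coords n-by-3 matrix.
#' @param sup A `"superposition"` from [kabsch_superpose()].
#' @return The transformed n-by-3 matrix.
#' @export
apply_superposition <- function(coords, sup) {
  co <- as.matrix(coords)
  tcrossprod(co, sup$rotation) +
    matrix(sup$translation, nrow(co), 3L, byrow = TRUE)
}

# resolve per-residue representative rows: CA atom when present, otherwise
# all heavy atoms of the residue (their centroid is the representative)
.residue_reps <- function(at, prot_rows, representative) {
  resids <- sort(unique(at$residue_index[prot_rows]))
  reps <- lapply(resids, function(r) {
    rows <- prot_rows[at$residue_index[prot_rows] == r]
    ca <- rows[at$name[rows] == "CA"]
    if (representative == "calpha" || (representative == "auto" && length(ca))) {
      if (!length(ca)) return(NULL)
      ca[1]
    } else {
      heavy <- rows[at$is_heavy[rows]]
      if (!length(heavy)) NULL else heavy
    }
  })
  missing <- resids[vapply(reps, is.null, logical(1))]
  if (length(missing)) {
    stop("residues missing their representative atom: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  list(resids = resids, rows = reps)
}

#' Per-residue root mean square fluctuation
#'
#' Each frame is rigid-body superposed onto a reference using the fit
#' selection, then `RMSF_i = sqrt(mean_t |r_i(t) - <r_i>|^2)` is computed
#' from the residue representative atom positions after fitting, with
#' `<r_i>` the post-fit time mean. With `reference = "mean"` the reference
#' is the iterated mean structure (fit, recompute mean, refit; mean-shift
#' tolerance 1e-6 nm, at most 10 iterations).
#'
#' @param traj A `"trajectory"` containing protein atoms.
#' @param fit_selection Atoms used for superposition: `"heavy"` (all
#'   protein heavy atoms, default), `"calpha"`, or `"none"` (no fitting).
#' @param representative Residue representative rule: `"auto"` (CA when
#'   present, else heavy-atom centroid), `"calpha"` (strict), or
#'   `"centroid"`.
#' @param reference Fluctuation reference: `"mean"` (iterated mean
#'   structure, default), `"first"` frame, or `"external"` (supply
#'   `ref_frame`).
#' @param ref_frame An `"md_frame"` used when `reference = "external"`.
#' @param window Time window; `NULL` uses all frames.
#' @param label Optional species/condition label carried into reports.
#' @return An object of class `"rmsf_profile"`: `residue_index`, `rmsf`
#'   (nm), selection metadata, `n_frames_used`.
#' @export
residue_rmsf <- function(traj, fit_selection = c("heavy", "calpha", "none"),
                         representative = c("auto", "calpha", "centroid"),
                         reference = c("mean", "first", "external"),
                         ref_frame = NULL, window = NULL, label = NULL) {
  fit_selection <- match.arg(fit_selection)
  representative <- match.arg(representative)
  reference <- match.arg(reference)
  at <- traj$topology$atoms
  prot_rows <- which(at$molecule_class == "protein")
  if (!length(prot_rows)) stop("no protein atoms in trajectory", call. = FALSE)
  idx <- if (is.null(window)) seq_len(n_frames(traj)) else window_frames(traj, window)
  if (length(idx) < 2L) stop("RMSF needs a window with at least 2 frames", call. = FALSE)

  fit_rows <- switch(fit_selection,
    heavy = prot_rows[at$is_heavy[prot_rows]],
    calpha = prot_rows[at$name[prot_rows] == "CA"],
    none = integer(0)
  )
  if (fit_selection != "none" && length(fit_rows) < 3L) {
    stop("fit selection must contain at least 3 atoms", call. = FALSE)
  }
  reps <- .residue_reps(at, prot_rows, representative)

  # protein coordinates per frame
  pco <- lapply(idx, function(i) traj$frames[[i]]$coords[prot_rows, , drop = FALSE])
  fit_local <- match(fit_rows, prot_rows)

  if (fit_selection != "none") {
    ref_fit <- switch(reference,
      first = pco[[1]][fit_local, , drop = FALSE],
      external = {
        if (is.null(ref_frame)) stop("reference = 'external' needs ref_frame", call. = FALSE)
        ref_frame$coords[fit_rows, , drop = FALSE]
      },
      mean = pco[[1]][fit_local, , drop = FALSE]  # iterated below
    )
    iterate <- reference == "mean"
    for (it in seq_len(if (iterate) 10L else 1L)) {
      fitted_fit <- lapply(pco, function(co) {
        sup <- kabsch_superpose(co[fit_local, , drop = FALSE], ref_fit)
        apply_superposition(co[fit_local, , drop = FALSE], sup)
      })
      if (!iterate) break
      new_ref <- Reduce(`+`, fitted_fit) / length(fitted_fit)
      shift <- max(abs(new_ref - ref_fit))
      ref_fit <- new_ref
      if (shift < 1e-6) break
    }
    pco <- lapply(pco, function(co) {
      sup <- kabsch_superpose(co[fit_local, , drop = FALSE], ref_fit)
      apply_superposition(co, sup)
    })
  }

  rep_local <- lapply(reps$rows, function(rows) match(rows, prot_rows))
  n_res <- length(reps$resids)
  if (all(lengths(rep_local) == 1L)) {
    # fast path: single representative atom per residue
    rl <- unlist(rep_local)
    M <- vapply(pco, function(co) as.numeric(co[rl, , drop = FALSE]),
                numeric(3L * n_res))  # rows: x block, y block, z block
    D <- M - rowMeans(M)
    S <- rowMeans(D * D)  # per-coordinate variance (biased, as defined)
    rmsf <- sqrt(S[seq_len(n_res)] + S[n_res + seq_len(n_res)] +
                   S[2L * n_res + seq_len(n_res)])
  } else {
    rmsf <- numeric(n_res)
    for (r in seq_len(n_res)) {
      rl <- rep_local[[r]]
      X <- t(vapply(pco, function(co) {
        if (length(rl) == 1L) co[rl, ] else colMeans(co[rl, , drop = FALSE])
      }, numeric(3)))
      mu <- colMeans(X)
      rmsf[r] <- sqrt(mean(rowSums(sweep(X, 2L, mu)^2)))
    }
  }
  structure(list(
    residue_index = reps$resids,
    rmsf = rmsf,
    fit_selection = fit_selection,
    representative = representative,
    reference = reference,
    n_frames_used = length(idx),
    label = label
  ), class = "rmsf_profile")
}

#' @export
print.rmsf_profile <- function(x, ...) {
  cat(sprintf("RMSF profile%s: %d residues, mean %.4f nm (%d frames, fit=%s)\n",
              if (is.null(x$label)) "" else paste0(" [", x$label, "]"),
              length(x$rmsf), mean(x$rmsf), x$n_frames_used, x$fit_selection))
  invisible(x)
}

#' Per-residue and average delta-RMSF between two conditions
#'
#' Residue-wise difference `detergent - reference`; a lower average delta
#' means stronger structural stabilization by the detergent relative to the
#' membrane-equilibrated reference.
#'
#' @param detergent_profile,reference_profile `"rmsf_profile"` objects over
#'   identical residue sets and representative rules.
#' @return An object of class `"delta_rmsf"`: `residue_index`,
#'   `per_residue_delta` (nm), `average_delta` (nm), condition labels.
#' @export
delta_rmsf <- function(detergent_profile, reference_profile) {
  a <- detergent_profile
  b <- reference_profile
  if (!identical(a$representative, b$representative)) {
    stop("profiles use different representative-atom rules", call. = FALSE)
  }
  extra <- setdiff(a$residue_index, b$residue_index)
  missing <- setdiff(b$residue_index, a$residue_index)
  if (length(extra) || length(missing)) {
    stop("mismatched residue sets; only in detergent profile: {",
         paste(extra, collapse = ", "), "}, only in reference profile: {",
         paste(missing, collapse = ", "), "}", call. = FALSE)
  }
  ord <- match(a$residue_index, b$residue_index)
  delta <- a$rmsf - b$rmsf[ord]
  structure(list(
    residue_index = a$residue_index,
    per_residue_delta = delta,
    average_delta = mean(delta),
    label = a$label,
    reference_label = b$label
  ), class = "delta_rmsf")
}

#' @export
print.delta_rmsf <- function(x, ...) {
  cat(sprintf("delta-RMSF%s: average %.4f nm over %d residues\n",
              if (is.null(x$label)) "" else paste0(" [", x$label, "]"),
              x$average_delta, length(x$per_residue_delta)))
  invisible(x)
}

#' RMSF convergence over growing-time checkpoints
#'
#' The RMSF profile is recomputed on all frames up to each checkpoint; the
#' convergence metric at checkpoint k is the maximum over residues of
#' `|profile(t_k) - profile(t_{k-1})|`, and the run is deemed equilibrated
#' when the final pair of profiles agrees within `tolerance`.
#'
#' @inheritParams residue_rmsf
#' @param checkpoint_times Strictly increasing checkpoint times (>= 2).
#' @param tolerance Equilibration tolerance in nm.
#' @param ... Further arguments passed to [residue_rmsf()].
#' @return An object of class `"rmsf_convergence"` with `checkpoint_times`,
#'   `profiles` (list of `"rmsf_profile"`), `deltas` (max abs profile
#'   change per successive pair), `equilibrated`, `tolerance`.
#' @export
rmsf_convergence <- function(traj, checkpoint_times, tolerance, ...) {
  ck <- as.numeric(checkpoint_times)
  if (length(ck) < 2L) stop("need at least 2 checkpoints", call. = FALSE)
  if (any(diff(ck) <= 0)) stop("checkpoint times must be strictly increasing", call. = FALSE)
  times <- traj_times(traj)
  if (max(ck) > max(times)) {
    stop(sprintf("checkpoint %g is beyond the series end (%g)", max(ck),
                 max(times)), call. = FALSE)
  }
  profiles <- lapply(ck, function(t1) {
    residue_rmsf(traj, window = c(times[1], t1), ...)
  })
  deltas <- vapply(seq_along(profiles)[-1], function(k) {
    max(abs(profiles[[k]]$rmsf - profiles[[k - 1]]$rmsf))
  }, numeric(1))
  structure(list(
    checkpoint_times = ck,
    profiles = profiles,
    deltas = deltas,
    equilibrated = deltas[length(deltas)] <= tolerance,
    tolerance = tolerance
  ), class = "rmsf_convergence")
}

#' @export
print.rmsf_convergence <- function(x, ...) {
  cat("RMSF convergence deltas:",
      paste(sprintf("%.4g", x$deltas), collapse = ", "), "nm\n")
  cat(sprintf("  final delta vs tolerance %.4g -> %s\n", x$tolerance,
              if (x$equilibrated) "equilibrated" else "NOT equilibrated"))
  invisible(x)
}
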