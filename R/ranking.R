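# Two-axis classification and combined ranking of screened detergents.
#
# Axis 1 (membrane invasion): mean percentage of detergent molecules in
# lipid contact; a detergent is an "invader" above a percentage threshold
# (default 45). Axis 2 (structural stabilization): average delta-RMSF, lower
# is better; a detergent is a "stabilizer" when its stability rank is within
# the top half of the panel. The combined order is the rank sum, ties broken
# by the better stability rank, then name.

.require_cols <- function(scores, cols) {
  miss <- setdiff(cols, names(scores))
  if (length(miss)) {
    stop("scores is missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  for (cc in cols) {
    bad <- scores$name[is.na(scores[[cc]])]
    if (length(bad)) {
      stop("missing ", cc, " for detergent: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
}

# ranks: 1 = highest invasion %, 1 = lowest avg delta-RMSF; ties share the
# mean of tied ranks. Pre-computed rank columns are honored when present
# (e.g. ranks read off published figures).
.with_ranks <- function(scores) {
  if (!"invasion_rank" %in% names(scores)) {
    scores$invasion_rank <- rank(-scores$invasion_mean, ties.method = "average")
  }
  if (!"stability_rank" %in% names(scores)) {
    scores$stability_rank <- rank(scores$avg_delta_rmsf, ties.method = "average")
  }
  scores
}

#' Classify detergents on the invasion/stabilization axes
#'
#' A detergent is an invader iff its mean invasion percentage exceeds
#' `invasion_threshold`, and a stabilizer iff its stability rank (1 = lowest
#' average delta-RMSF) is at most `ceiling(n/2)`. The four classes are
#' `solubilizer` (both), `invader-only`, `stabilizer-only`, and `poor`
#' (neither).
#'
#' @param scores Data frame with columns `name`, `invasion_mean` (percent)
#'   and `avg_delta_rmsf` (nm); optional pre-computed `invasion_rank` /
#'   `stability_rank` columns are honored.
#' @param invasion_threshold Invasion percentage gate (default 45).
#' @param weak_threshold Annotation-only boundary (default 25): detergents
#'   at or below it are flagged `weak_invader = TRUE` in the output; this is
#'   reporting metadata, not a second classification gate.
#' @return The input with `invasion_rank`, `stability_rank`, `class` and
#'   `weak_invader` columns added.
#' @export
classify_detergents <- function(scores, invasion_threshold = 45,
                                weak_threshold = 25) {
  scores <- as.data.frame(scores)
  if (!nrow(scores)) stop("scores must contain at least one detergent", call. = FALSE)
  .require_cols(scores, c("name", "invasion_mean", "avg_delta_rmsf"))
  if (!is.finite(invasion_threshold)) stop("invasion_threshold must be finite", call. = FALSE)
  scores <- .with_ranks(scores)
  n <- nrow(scores)
  invader <- scores$invasion_mean > invasion_threshold
  stabilizer <- scores$stability_rank <= ceiling(n / 2)
  scores$class <- ifelse(invader & stabilizer, "solubilizer",
                  ifelse(invader, "invader-only",
                  ifelse(stabilizer, "stabilizer-only", "poor")))
  scores$weak_invader <- scores$invasion_mean <= weak_threshold
  scores
}

#' Combined rank order of screened detergents
#'
#' `combined_score = invasion_rank + stability_rank` (lower is better);
#' ties are broken by the better (lower) stability rank, then by name. The
#' returned table is sorted by the combined order and carries the
#' classification columns of [classify_detergents()].
#'
#' @inheritParams classify_detergents
#' @return The classified score table, sorted, with `combined_score` and
#'   `combined_rank` columns.
#' @export
rank_combined <- function(scores, invasion_threshold = 45) {
  scores <- classify_detergents(scores, invasion_threshold)
  scores$combined_score <- scores$invasion_rank + scores$stability_rank
  ord <- order(scores$combined_score, scores$stability_rank, scores$name)
  scores <- scores[ord, , drop = FALSE]
  scores$combined_rank <- seq_len(nrow(scores))
  rownames(scores) <- NULL
  scores
}

#' Write screening reports to a directory
#'
#' Emits a per-detergent summary CSV, per-analysis CSVs (invasion series,
#' per-lipid profiles, RMSF and delta-RMSF profiles, contact maps, region
#' summaries), a run-manifest JSON and a plain-text summary. Output is
#' deterministic: identical inputs give byte-identical files.
#'
#' @param results A list with any of the elements `scores` (classified/
#'   ranked table), `invasion` (named list of `"invasion_result"`),
#'   `per_lipid` (named list of `"lipid_profile"`), `rmsf` (named list of
#'   `"rmsf_profile"`), `delta` (named list of `"delta_rmsf"`),
#'   `contact_map` (named list of `"contact_map"`), `regions` (named list of
#'   region summary data frames), `manifest` (list of run metadata).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
generate_report <- function(results, out_dir) {
  known <- c("scores", "invasion", "per_lipid", "rmsf", "delta",
             "contact_map", "regions")
  if (!is.list(results) || !any(vapply(known, function(k)
    !is.null(results[[k]]), logical(1)))) {
    stop("results must contain at least one analysis result", call. = FALSE)
  }
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir, call. = FALSE)
  paths <- character(0)
  put <- function(df, file) {
    p <- file.path(out_dir, file)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  safe <- function(nm) gsub("[^A-Za-z0-9_.-]", "_", nm)

  if (!is.null(results$scores)) put(results$scores, "detergent_summary.csv")
  for (nm in names(results$invasion %||% list())) {
    put(results$invasion[[nm]]$per_frame, sprintf("invasion_%s.csv", safe(nm)))
  }
  for (nm in names(results$per_lipid %||% list())) {
    put(results$per_lipid[[nm]]$profile, sprintf("per_lipid_%s.csv", safe(nm)))
  }
  for (nm in names(results$rmsf %||% list())) {
    pr <- results$rmsf[[nm]]
    put(data.frame(residue_index = pr$residue_index, rmsf_nm = pr$rmsf),
        sprintf("rmsf_%s.csv", safe(nm)))
  }
  for (nm in names(results$delta %||% list())) {
    d <- results$delta[[nm]]
    put(data.frame(residue_index = d$residue_index, delta_nm = d$per_residue_delta),
        sprintf("delta_rmsf_%s.csv", safe(nm)))
  }
  for (nm in names(results$contact_map %||% list())) {
    put(results$contact_map[[nm]]$map, sprintf("contact_map_%s.csv", safe(nm)))
  }
  for (nm in names(results$regions %||% list())) {
    put(results$regions[[nm]], sprintf("region_summary_%s.csv", safe(nm)))
  }

  manifest <- results$manifest %||% list()
  manifest$software <- list(package = "detscreen",
                            version = as.character(utils::packageVersion("detscreen")))
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(paths, mp)

  sp <- file.path(out_dir, "summary.txt")
  lines <- c("detergent screening summary", "")
  if (!is.null(results$scores)) {
    s <- results$scores
    lines <- c(lines, sprintf(
      "%-10s invasion %6.2f%%  avg dRMSF %8.4f nm  ranks (inv %4.1f, stab %4.1f)  %s",
      s$name, s$invasion_mean, s$avg_delta_rmsf, s$invasion_rank,
      s$stability_rank, s$class))
  }
  writeLines(lines, sp)
  paths <- c(paths, sp)
  invisible(paths)
}
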