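#' Read a flat TOML-style configuration file
#'
#' Parses the minimal dialect used throughout the package for configs,
#' annotation files and region definitions: `key = value` lines, optional
#' `[section]` headers, `#` comments. Values may be quoted strings, numbers,
#' `true`/`false`, or flat arrays `[a, b, c]`.
#'
#' @param path Path to the file.
#' @return A named list; sectioned keys are nested one level deep.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  out <- list()
  section <- NULL
  for (i in seq_along(lines)) {
    ln <- sub("#.*$", "", lines[i])
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    if (grepl("^\\[.+\\]$", ln)) {
      section <- sub("^\\[(.+)\\]$", "\\1", ln)
      if (is.null(out[[section]])) out[[section]] <- list()
      next
    }
    m <- regexpr("=", ln, fixed = TRUE)
    if (m < 0) {
      stop(sprintf("config parse error at line %d: expected key = value", i),
           call. = FALSE)
    }
    key <- trimws(substr(ln, 1L, m - 1L))
    val <- .parse_config_value(trimws(substr(ln, m + 1L, nchar(ln))), i)
    if (is.null(section)) out[[key]] <- val else out[[section]][[key]] <- val
  }
  out
}

.parse_config_value <- function(tok, line) {
  parse_scalar <- function(s) {
    if (grepl('^".*"$', s) || grepl("^'.*'$", s)) return(substr(s, 2L, nchar(s) - 1L))
    if (s %in% c("true", "TRUE")) return(TRUE)
    if (s %in% c("false", "FALSE")) return(FALSE)
    num <- suppressWarnings(as.numeric(s))
    if (!is.na(num)) return(num)
    s
  }
  if (grepl("^\\[.*\\]$", tok)) {
    inner <- trimws(substr(tok, 2L, nchar(tok) - 1L))
    if (!nzchar(inner)) return(list())
    parts <- trimws(strsplit(inner, ",", fixed = TRUE)[[1]])
    vals <- lapply(parts, parse_scalar)
    if (all(vapply(vals, is.numeric, logical(1))) ||
        all(vapply(vals, is.character, logical(1)))) {
      return(unlist(vals))
    }
    return(vals)
  }
  parse_scalar(tok)
}

#' Read a species/role annotation file
#'
#' The annotation file labels molecule species with a class and detergent
#' atoms with head/tail roles, e.g.:
#' \preformatted{
#' [species]
#' DOPC = "lipid"
#' MEGA-9 = "detergent"
#' [roles]
#' MEGA-9:C1 = "tail"
#' MEGA-9:O1 = "head"
#' }
#'
#' @param path Path to the annotation file.
#' @return A list with elements `species` (named character vector of
#'   molecule classes) and `roles` (named character vector keyed by
#'   `"species:atom_name"`).
#' @export
read_annotations <- function(path) {
  cfg <- read_config(path)
  ann <- list(
    species = unlist(cfg$species %||% list()),
    roles = unlist(cfg$roles %||% list())
  )
  validate_annotations(ann)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_annotations <- function(annotations) {
  if (is.null(annotations)) return(list(species = character(0), roles = character(0)))
  if (is.character(annotations) && length(annotations) == 1L) {
    return(read_annotations(annotations))
  }
  sp <- annotations$species %||% character(0)
  rl <- annotations$roles %||% character(0)
  sp <- structure(as.character(sp), names = names(sp))
  rl <- structure(as.character(rl), names = names(rl))
  bad <- !(sp %in% .molecule_classes)
  if (any(bad)) {
    stop("annotation maps species to unknown class: ",
         paste(unique(sp[bad]), collapse = ", "), call. = FALSE)
  }
  if (length(rl) && !all(rl %in% c("head", "tail", "none"))) {
    stop("annotation roles must be head, tail or none", call. = FALSE)
  }
  list(species = sp, roles = rl)
}

# class / role lookup used by all parsers
annotate_atoms <- function(species, name, annotations) {
  ann <- validate_annotations(annotations)
  cls <- unname(ann$species[species])
  unknown <- unique(species[is.na(cls)])
  if (length(unknown)) {
    stop("unknown species without annotation: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  role <- unname(ann$roles[paste0(species, ":", name)])
  role[is.na(role)] <- "none"
  role[cls != "detergent"] <- "none"
  list(class = cls, role = role)
}
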