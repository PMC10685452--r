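# Readers and writers for the three structure/trajectory dialects.
#
# Internal units are nm and ps everywhere; Angstrom coordinates are accepted
# and produced only at the PDB boundary. Only orthorhombic boxes are
# supported; triclinic input raises an explicit unsupported-format error.

#' Read a structure or trajectory file
#'
#' Supports multi-model PDB (Angstrom, converted to nm; CRYST1 read as the
#' box when present), single-frame GRO (read-only), and the package's
#' extended-XYZ dialect (see Details). Molecules are contiguous runs of
#' protein residues (one molecule per chain segment) or single residues for
#' all other classes.
#'
#' @details The extended-XYZ dialect is, per frame: line 1 the atom count,
#' line 2 `time=<ps> box=<Lx>,<Ly>,<Lz> units=nm`, then one line per atom
#' `name x y z` with coordinates in nm printed to 4 decimals. Atom name
#' tokens written by [write_trajectory()] encode
#' `species:molecule_id[:residue_index]:atom_name` so topology round-trips.
#'
#' @param path Path to the file.
#' @param format One of `"pdb"`, `"gro"`, `"xyzext"`.
#' @param annotations Species/role annotation: a list with `species` and
#'   `roles` entries, or a path to an annotation file (see
#'   [read_annotations()]).
#' @return A `"trajectory"` object.
#' @export
read_trajectory <- function(path, format = c("pdb", "gro", "xyzext"),
                            annotations = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  switch(format,
    pdb = .read_pdb(path, annotations),
    gro = .read_gro(path, annotations),
    xyzext = .read_xyzext(path, annotations)
  )
}

#' Parse a structure file into a topology and its first frame
#'
#' @inheritParams read_trajectory
#' @return A list with elements `topology` and `frame` (the first frame).
#' @export
parse_structure <- function(path, format = c("pdb", "gro", "xyzext"),
                            annotations = NULL) {
  traj <- read_trajectory(path, format, annotations)
  list(topology = traj$topology, frame = traj$frames[[1]])
}

.num_field <- function(s, line_no, what) {
  v <- suppressWarnings(as.numeric(trimws(s)))
  if (anyNA(v)) {
    stop(sprintf("parse error at line %d: malformed %s field",
                 line_no[which(is.na(v))[1]], what), call. = FALSE)
  }
  v
}

# Build a topology from per-atom species/name/residue records. Protein
# residues that are contiguous within one chain share a molecule; every
# other residue is its own molecule.
.assemble_topology <- function(species, name, element, chain, resid,
                               annotations) {
  ann <- annotate_atoms(species, name, annotations)
  res_key <- paste(chain, resid, species, sep = "\r")
  new_res <- c(TRUE, res_key[-1] != res_key[-length(res_key)])
  mol_id <- integer(length(species))
  cur <- 0L
  prev_protein_chain <- NA_character_
  for (i in seq_along(species)) {
    if (new_res[i]) {
      if (ann$class[i] == "protein" && identical(chain[i], prev_protein_chain)) {
        # continue the running protein molecule
      } else {
        cur <- cur + 1L
      }
      prev_protein_chain <- if (ann$class[i] == "protein") chain[i] else NA_character_
    }
    mol_id[i] <- cur
  }
  topology(data.frame(
    atom_id = seq_along(species),
    name = name,
    element = element,
    molecule_id = mol_id,
    molecule_class = ann$class,
    species = species,
    residue_index = ifelse(ann$class == "protein", as.integer(resid), NA_integer_),
    role = ann$role,
    stringsAsFactors = FALSE
  ))
}

.read_pdb <- function(path, annotations) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  box <- NULL
  cr <- which(rec == "CRYST1")
  if (length(cr)) {
    ln <- lines[cr[1]]
    abc <- .num_field(c(substr(ln, 7, 15), substr(ln, 16, 24), substr(ln, 25, 33)),
                      rep(cr[1], 3), "CRYST1")
    ang <- .num_field(c(substr(ln, 34, 40), substr(ln, 41, 47), substr(ln, 48, 54)),
                      rep(cr[1], 3), "CRYST1")
    if (any(abs(ang - 90) > 1e-6)) {
      stop("triclinic boxes are unsupported (CRYST1 angles must be 90)",
           call. = FALSE)
    }
    box <- abc / 10  # Angstrom -> nm
  }
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom)) stop("no ATOM/HETATM records in ", path, call. = FALSE)
  model_starts <- which(trimws(rec) == "MODEL")
  if (length(model_starts)) {
    model_ends <- which(trimws(rec) == "ENDMDL")
    if (length(model_ends) != length(model_starts)) {
      stop("unbalanced MODEL/ENDMDL records", call. = FALSE)
    }
    groups <- lapply(seq_along(model_starts), function(i) {
      idx <- which(is_atom & seq_along(lines) > model_starts[i] &
                     seq_along(lines) < model_ends[i])
      idx
    })
  } else {
    groups <- list(which(is_atom))
  }
  counts <- lengths(groups)
  if (length(unique(counts)) != 1L) {
    stop(sprintf("atom count mismatch across models: %s",
                 paste(unique(counts), collapse = " vs ")), call. = FALSE)
  }

  first <- groups[[1]]
  al <- lines[first]
  name <- trimws(substr(al, 13, 16))
  species <- trimws(substr(al, 18, 21))
  chain <- substr(al, 22, 22)
  resid <- as.integer(.num_field(substr(al, 23, 26), first, "residue number"))
  element <- trimws(substr(al, 77, 78))
  element[!nzchar(element)] <- infer_element(name[!nzchar(element)])
  top <- .assemble_topology(species, name, element, chain, resid, annotations)

  frames <- lapply(seq_along(groups), function(i) {
    al <- lines[groups[[i]]]
    x <- .num_field(substr(al, 31, 38), groups[[i]], "x coordinate")
    y <- .num_field(substr(al, 39, 46), groups[[i]], "y coordinate")
    z <- .num_field(substr(al, 47, 54), groups[[i]], "z coordinate")
    co <- cbind(x, y, z) / 10  # Angstrom -> nm
    b <- box
    if (is.null(b)) {
      # no CRYST1: enclose the coordinates with a 1 nm margin per side
      b <- apply(co, 2, function(v) diff(range(v))) + 2
    }
    frame(time = i - 1, box = b, coords = co)
  })
  trajectory(top, frames)
}

.read_gro <- function(path, annotations) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 4L) stop("truncated GRO file", call. = FALSE)
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n)) stop("parse error at line 2: malformed atom count", call. = FALSE)
  if (length(lines) < 3L + n) {
    stop(sprintf("atom count mismatch: declared %d, found %d atom lines",
                 n, length(lines) - 3L), call. = FALSE)
  }
  al <- lines[3:(2 + n)]
  ln_no <- 3:(2 + n)
  resid <- as.integer(.num_field(substr(al, 1, 5), ln_no, "residue number"))
  species <- trimws(substr(al, 6, 10))
  name <- trimws(substr(al, 11, 15))
  x <- .num_field(substr(al, 21, 28), ln_no, "x coordinate")
  y <- .num_field(substr(al, 29, 36), ln_no, "y coordinate")
  z <- .num_field(substr(al, 37, 44), ln_no, "z coordinate")
  bv <- suppressWarnings(as.numeric(strsplit(trimws(lines[3 + n]), "\\s+")[[1]]))
  if (anyNA(bv) || length(bv) < 3L) {
    stop(sprintf("parse error at line %d: malformed box line", 3 + n), call. = FALSE)
  }
  if (length(bv) > 3L && any(abs(bv[-(1:3)]) > 1e-9)) {
    stop("triclinic boxes are unsupported (off-diagonal GRO box vectors)",
         call. = FALSE)
  }
  element <- infer_element(name)
  top <- .assemble_topology(species, name, element, rep("A", n), resid,
                            annotations)
  trajectory(top, list(frame(time = 0, box = bv[1:3], coords = cbind(x, y, z))))
}

.read_xyzext <- function(path, annotations) {
  lines <- readLines(path, warn = FALSE)
  i <- 1L
  frames <- list()
  top <- NULL
  n_expect <- NULL
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1L) {
      stop(sprintf("parse error at line %d: malformed atom count", i), call. = FALSE)
    }
    hdr <- lines[i + 1L]
    tm <- regmatches(hdr, regexec("time=([-0-9.eE+]+)", hdr))[[1]]
    bm <- regmatches(hdr, regexec(
      "box=([-0-9.eE+]+),([-0-9.eE+]+),([-0-9.eE+]+)", hdr))[[1]]
    if (length(tm) != 2L || length(bm) != 4L || !grepl("units=nm", hdr)) {
      stop(sprintf("parse error at line %d: malformed frame header", i + 1L),
           call. = FALSE)
    }
    if (i + 1L + n > length(lines)) {
      stop(sprintf("atom count mismatch: declared %d atoms at line %d but file ends",
                   n, i), call. = FALSE)
    }
    al <- lines[(i + 2L):(i + 1L + n)]
    tok <- strsplit(trimws(al), "\\s+")
    bad <- which(lengths(tok) != 4L)
    if (length(bad)) {
      stop(sprintf("parse error at line %d: expected 'name x y z'",
                   i + 1L + bad[1]), call. = FALSE)
    }
    tok <- do.call(rbind, tok)
    co <- cbind(
      .num_field(tok[, 2], (i + 2L):(i + 1L + n), "x coordinate"),
      .num_field(tok[, 3], (i + 2L):(i + 1L + n), "y coordinate"),
      .num_field(tok[, 4], (i + 2L):(i + 1L + n), "z coordinate")
    )
    if (is.null(top)) {
      n_expect <- n
      top <- .xyzext_topology(tok[, 1], annotations)
    } else if (n != n_expect) {
      stop(sprintf("atom count mismatch: frame at line %d has %d atoms, expected %d",
                   i, n, n_expect), call. = FALSE)
    }
    frames[[length(frames) + 1L]] <- frame(time = as.numeric(tm[2]),
                                           box = as.numeric(bm[2:4]),
                                           coords = co)
    i <- i + 2L + n
  }
  if (is.null(top)) stop("no frames found in ", path, call. = FALSE)
  trajectory(top, frames)
}

# name tokens: "name" | "species:mol:name" | "species:mol:resid:name"
.xyzext_topology <- function(tokens, annotations) {
  parts <- strsplit(tokens, ":", fixed = TRUE)
  np <- lengths(parts)
  if (any(!np %in% c(1L, 3L, 4L))) {
    stop("malformed xyzext atom name token: ",
         tokens[which(!np %in% c(1L, 3L, 4L))[1]], call. = FALSE)
  }
  species <- vapply(parts, function(p) p[1], character(1))
  name <- vapply(parts, function(p) p[length(p)], character(1))
  mol <- vapply(parts, function(p) {
    if (length(p) >= 3L) p[2] else NA_character_
  }, character(1))
  resid <- vapply(parts, function(p) {
    if (length(p) == 4L) p[3] else NA_character_
  }, character(1))
  mol_num <- suppressWarnings(as.integer(mol))
  mol_num[is.na(mol_num)] <- seq_along(tokens)[is.na(mol_num)] + 10000000L
  resid_num <- suppressWarnings(as.integer(resid))
  resid_num[is.na(resid_num)] <- mol_num[is.na(resid_num)]
  .assemble_topology(species, name, infer_element(name),
                     chain = rep("A", length(tokens)),
                     resid = resid_num, annotations = annotations)
}

#' Write a trajectory to disk
#'
#' Output is deterministic and byte-stable for identical input. Multi-model
#' PDB uses `MODEL`/`ENDMDL` records (coordinates converted nm to Angstrom);
#' the extended-XYZ dialect is described in [read_trajectory()].
#'
#' @param traj A `"trajectory"` object.
#' @param path Output file path.
#' @param format One of `"pdb"`, `"xyzext"`.
#' @return Invisibly, `path`.
#' @export
write_trajectory <- function(traj, path, format = c("pdb", "xyzext")) {
  format <- match.arg(format)
  if (!inherits(traj, "trajectory") || !length(traj$frames)) {
    stop("no frames to write", call. = FALSE)
  }
  lines <- switch(format, pdb = .format_pdb(traj), xyzext = .format_xyzext(traj))
  con <- tryCatch(suppressWarnings(file(path, open = "wb")),
                  error = function(e) stop("cannot write to ", path, call. = FALSE))
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

.format_pdb <- function(traj) {
  at <- traj$topology$atoms
  b <- traj$frames[[1]]$box * 10
  resname <- toupper(substr(at$species, 1, 3))
  resseq <- ifelse(at$molecule_class == "protein",
                   at$residue_index, at$molecule_id %% 10000L)
  name4 <- ifelse(nchar(at$name) < 4L, paste0(" ", at$name), at$name)
  out <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                 b[1], b[2], b[3], 90, 90, 90)
  for (i in seq_along(traj$frames)) {
    co <- traj$frames[[i]]$coords * 10
    out <- c(out,
      sprintf("MODEL     %4d", i),
      sprintf("ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
              at$atom_id %% 100000L, name4, resname, resseq %% 10000L,
              co[, 1], co[, 2], co[, 3], 1, 0, toupper(at$element)),
      "ENDMDL")
  }
  c(out, "END")
}

.format_xyzext <- function(traj) {
  at <- traj$topology$atoms
  tok <- ifelse(
    at$molecule_class == "protein",
    sprintf("%s:%d:%d:%s", at$species, at$molecule_id, at$residue_index, at$name),
    sprintf("%s:%d:%s", at$species, at$molecule_id, at$name)
  )
  unlist(lapply(traj$frames, function(f) {
    c(sprintf("%d", nrow(f$coords)),
      sprintf("time=%g box=%.4f,%.4f,%.4f units=nm",
              f$time, f$box[1], f$box[2], f$box[3]),
      sprintf("%s %.4f %.4f %.4f", tok, f$coords[, 1], f$coords[, 2],
              f$coords[, 3]))
  }))
}
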