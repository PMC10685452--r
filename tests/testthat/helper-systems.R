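# Small in-code fixtures shared across test files.

test_annotations <- function() {
  list(
    species = c(LIP = "lipid", DET = "detergent", PRO = "protein",
                SOL = "solvent", NA. = "ion"),
    roles = c("DET:HD" = "head", "DET:TL" = "tail")
  )
}

# single-frame system from explicit single-atom detergent and lipid
# coordinates (one atom per molecule)
make_slab_system <- function(det_pos, lip_pos, box, time = 0,
                             det_species = "DET") {
  det_pos <- as.matrix(det_pos)
  lip_pos <- as.matrix(lip_pos)
  nl <- nrow(lip_pos)
  nd <- nrow(det_pos)
  atoms <- data.frame(
    atom_id = seq_len(nl + nd),
    name = c(rep("L", nl), rep("D", nd)),
    element = "C",
    molecule_id = seq_len(nl + nd),
    molecule_class = c(rep("lipid", nl), rep("detergent", nd)),
    species = c(rep("LIP", nl), rep(det_species, nd)),
    stringsAsFactors = FALSE
  )
  trajectory(topology(atoms),
             list(frame(time, box, rbind(lip_pos, det_pos))))
}

# random multi-atom molecules for contact-search tests
random_molecules <- function(n_mol, max_atoms, box) {
  lapply(seq_len(n_mol), function(i) {
    na <- sample.int(max_atoms, 1)
    matrix(runif(3 * na, -box[1], 2 * box[1]), na, 3)
  })
}

# protein + role-labeled particles from explicit coordinates
make_regio_frame <- function(prot_pos, head_pos, tail_pos, box, time = 0) {
  prot_pos <- as.matrix(prot_pos)
  np <- nrow(prot_pos)
  nh <- if (is.null(head_pos)) 0L else nrow(head_pos <- as.matrix(head_pos))
  nt <- if (is.null(tail_pos)) 0L else nrow(tail_pos <- as.matrix(tail_pos))
  atoms <- data.frame(
    atom_id = seq_len(np + nh + nt),
    name = c(rep("CA", np), rep("HD", nh), rep("TL", nt)),
    element = "C",
    molecule_id = c(rep(1L, np), 1L + seq_len(nh + nt)),
    molecule_class = c(rep("protein", np), rep("detergent", nh + nt)),
    species = c(rep("PRO", np), rep("DET", nh + nt)),
    residue_index = c(seq_len(np), rep(NA_integer_, nh + nt)),
    role = c(rep("none", np), rep("head", nh), rep("tail", nt)),
    stringsAsFactors = FALSE
  )
  co <- prot_pos
  if (nh) co <- rbind(co, head_pos)
  if (nt) co <- rbind(co, tail_pos)
  trajectory(topology(atoms), list(frame(time, box, co)))
}

# fabricate an RMSF profile object for arithmetic tests
fake_profile <- function(rmsf, resid = seq_along(rmsf), label = NULL) {
  structure(list(residue_index = resid, rmsf = rmsf,
                 fit_selection = "none", representative = "auto",
                 reference = "mean", n_frames_used = 2L, label = label),
            class = "rmsf_profile")
}

# panel metrics consistent with the published screening orderings: invasion
# percentages in the >45 / <25 groups with the Fig-1 rank order, delta-RMSF
# values with the Fig-2 stability order (MEGA-9 marginally below LMNG)
published_panel_scores <- function() {
  data.frame(
    name = c("DDM", "BOG", "MEGA-9", "LMNG", "FOS-16", "GDN", "FOS-12", "CHAPS"),
    invasion_mean = c(62, 55, 50, 47, 22, 18, 15, 12),
    avg_delta_rmsf = c(0.080, 0.050, 0.030, 0.031, 0.015, 0.060, 0.012, 0.010),
    stringsAsFactors = FALSE
  )
}
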