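#' Complex models
#'
#' A `complex_model` holds one structure or an ensemble of frames of a
#' domain-peptide complex: an atom table (chain, author residue number,
#' insertion code, residue name, atom name, element) plus a frame-by-3N
#' coordinate matrix in Angstrom, with explicit domain and peptide chain
#' assignments. Chains are never auto-detected: crystal forms with several
#' copies of the peptide (or 1:2 stoichiometry) make guessing unsafe, so the
#' two chains are part of the model's identity.
#'
#' @name complex_model
#' @keywords internal
NULL

.WATER_RESID <- c("HOH", "WAT", "H2O", "DOD", "SOL")

.new_complex_model <- function(atoms, xyz, domain_chain, peptide_chain, source) {
  stopifnot(is.data.frame(atoms), is.matrix(xyz))
  if (nrow(xyz) < 1L)
    stop("a complex_model needs at least one frame", call. = FALSE)
  if (ncol(xyz) != 3L * nrow(atoms))
    stop("coordinate matrix does not match atom count", call. = FALSE)
  if (identical(domain_chain, peptide_chain))
    stop("domain_chain and peptide_chain must differ", call. = FALSE)
  for (ch in c(domain_chain, peptide_chain)) {
    if (!ch %in% atoms$chain)
      stop(sprintf("chain '%s' not present; available chains: %s", ch,
                   paste(sort(unique(atoms$chain)), collapse = ", ")),
           call. = FALSE)
  }
  structure(
    list(atoms = atoms, xyz = xyz,
         domain_chain = domain_chain, peptide_chain = peptide_chain,
         source = source),
    class = "complex_model")
}

#' Number of frames / atoms in a complex model
#'
#' @param model a `complex_model`
#' @return integer count
#' @export
n_frames <- function(model) nrow(model$xyz)

#' @rdname n_frames
#' @export
n_atoms <- function(model) nrow(model$atoms)

#' Coordinates of one frame
#'
#' @param model a `complex_model`
#' @param frame 1-based frame number
#' @return an `n_atoms x 3` matrix (Angstrom)
#' @export
frame_coords <- function(model, frame = 1L) {
  stopifnot(frame >= 1L, frame <= n_frames(model))
  matrix(model$xyz[frame, ], ncol = 3L, byrow = TRUE)
}

#' Atom row indices matching a selection
#'
#' `NULL` arguments match everything. `resno` may be a vector.
#'
#' @param model a `complex_model`
#' @param chain,resno,elety,insert selection filters on the atom table
#' @return integer vector of atom row indices (possibly empty)
#' @export
atom_indices <- function(model, chain = NULL, resno = NULL, elety = NULL,
                         insert = NULL) {
  a <- model$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (!is.null(resno)) keep <- keep & a$resno %in% resno
  if (!is.null(elety)) keep <- keep & a$elety %in% elety
  if (!is.null(insert)) keep <- keep & a$insert %in% insert
  which(keep)
}

# xyz column indices (x,y,z interleaved) for atom row indices
.xyz_cols <- function(idx) {
  as.vector(rbind(3L * idx - 2L, 3L * idx - 1L, 3L * idx))
}

#' Reference to a single residue
#'
#' @param chain chain identifier
#' @param resno author residue number
#' @param resid 3-letter residue name (may be empty when used as a lookup key)
#' @param insert insertion code, `""` when absent
#' @return a `residue_ref`
#' @export
residue_ref <- function(chain, resno, resid = "", insert = "") {
  structure(list(chain = chain, resno = as.integer(resno),
                 resid = resid, insert = insert),
            class = "residue_ref")
}

#' @export
format.residue_ref <- function(x, ...) {
  sprintf("%s %s%d%s", x$resid, x$chain, x$resno,
          if (nzchar(x$insert)) x$insert else "")
}

#' @export
print.residue_ref <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' @export
print.complex_model <- function(x, ...) {
  cat(sprintf("complex_model: %d atoms, %d frame(s)\n", n_atoms(x), n_frames(x)))
  cat(sprintf("  domain chain %s, peptide chain %s\n",
              x$domain_chain, x$peptide_chain))
  cat(sprintf("  source: %s\n", x$source))
  invisible(x)
}

# Resolve altlocs (keep highest occupancy, ties to the earliest altloc id),
# drop waters, keep the two chains of interest.
.clean_atom_table <- function(atom, domain_chain, peptide_chain) {
  atom$insert[is.na(atom$insert)] <- ""
  atom$alt[is.na(atom$alt)] <- ""
  atom$o[is.na(atom$o)] <- 1
  atom <- atom[!atom$resid %in% .WATER_RESID, , drop = FALSE]
  for (ch in c(domain_chain, peptide_chain)) {
    if (!ch %in% atom$chain)
      stop(sprintf("chain '%s' not present; available chains: %s", ch,
                   paste(sort(unique(atom$chain)), collapse = ", ")),
           call. = FALSE)
  }
  atom <- atom[atom$chain %in% c(domain_chain, peptide_chain), , drop = FALSE]
  if (nrow(atom) == 0L) return(atom)
  key <- paste(atom$chain, atom$resno, atom$insert, atom$elety, sep = "\r")
  ord <- order(key, -atom$o, atom$alt)
  atom <- atom[ord, , drop = FALSE]
  atom <- atom[!duplicated(key[ord]), , drop = FALSE]
  # restore file order
  atom[order(as.integer(rownames(atom))), , drop = FALSE]
}

.atoms_from_bio3d <- function(pdb, domain_chain, peptide_chain) {
  atom <- pdb$atom
  atom$row0 <- seq_len(nrow(atom))
  rownames(atom) <- atom$row0
  atom <- .clean_atom_table(atom, domain_chain, peptide_chain)
  if (nrow(atom) == 0L)
    stop("no atoms left after water/altloc filtering", call. = FALSE)
  elesy <- atom$elesy
  guess <- substr(gsub("[^A-Za-z].*$", "", atom$elety), 1L, 1L)
  elesy[is.na(elesy) | !nzchar(trimws(elesy))] <- guess[is.na(elesy) | !nzchar(trimws(elesy))]
  list(
    atoms = data.frame(
      eleno = atom$eleno, elety = atom$elety, resid = atom$resid,
      chain = atom$chain, resno = atom$resno, insert = atom$insert,
      elesy = trimws(elesy), stringsAsFactors = FALSE),
    keep_rows = atom$row0)
}

#' Load a single structure as a complex model
#'
#' Reads a PDB or mmCIF file, keeps the requested domain and peptide chains,
#' removes waters, and resolves alternate locations to the highest-occupancy
#' conformer (ties to altloc 'A'). Hydrogens, when present, are kept: all
#' distance criteria downstream are heavy-atom based, so X-ray structures
#' without hydrogens and ensembles with them are treated uniformly.
#'
#' @param path file path
#' @param format `"pdb"` or `"mmcif"` (default guessed from the extension)
#' @param domain_chain,peptide_chain chain identifiers (explicit, never guessed)
#' @return a single-frame `complex_model`
#' @export
load_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           domain_chain, peptide_chain) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "mmcif") bio3d::read.cif(path, verbose = FALSE,
                                           rm.alt = FALSE)
    else bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE),
    error = function(e) stop(sprintf("cannot parse '%s' as %s: %s",
                                     path, format, conditionMessage(e)),
                             call. = FALSE))
  parsed <- .atoms_from_bio3d(pdb, domain_chain, peptide_chain)
  xyz <- matrix(pdb$xyz[1L, .xyz_cols(parsed$keep_rows)], nrow = 1L)
  .new_complex_model(parsed$atoms, xyz, domain_chain, peptide_chain,
                     sprintf("%s (%s)", path, format))
}

#' Analysis window over ensemble frames
#'
#' Frame indices are 0-based and inclusive, matching trajectory-tool
#' conventions, so `analysis_window(500, 999)` selects the last 500 frames of
#' a 1000-frame ensemble.
#'
#' @param first_frame,last_frame 0-based inclusive frame indices
#' @param stride positive integer stride
#' @return an `analysis_window`
#' @export
analysis_window <- function(first_frame, last_frame, stride = 1L) {
  stopifnot(first_frame >= 0L, last_frame >= first_frame, stride >= 1L)
  structure(list(first_frame = as.integer(first_frame),
                 last_frame = as.integer(last_frame),
                 stride = as.integer(stride)),
            class = "analysis_window")
}

#' Load a conformational ensemble
#'
#' Topology is a PDB file (multi-model allowed); the trajectory is either the
#' models of that file or a separate DCD file with matching atom order. The
#' analysis window restricts and strides the frames (the default keeps all).
#'
#' @param topology PDB file providing the atom table
#' @param trajectory optional DCD trajectory file; when `NULL` the models of
#'   `topology` are the frames
#' @param window optional [analysis_window()]
#' @param domain_chain,peptide_chain chain identifiers
#' @return a multi-frame `complex_model`
#' @export
load_ensemble <- function(topology, trajectory = NULL, window = NULL,
                          domain_chain, peptide_chain) {
  pdb <- bio3d::read.pdb(topology, multi = TRUE, verbose = FALSE,
                         rm.alt = FALSE)
  parsed <- .atoms_from_bio3d(pdb, domain_chain, peptide_chain)
  if (is.null(trajectory)) {
    xyz <- pdb$xyz[, .xyz_cols(parsed$keep_rows), drop = FALSE]
  } else {
    traj <- bio3d::read.dcd(trajectory, verbose = FALSE)
    if (ncol(traj) != ncol(pdb$xyz))
      stop(sprintf("trajectory has %d atoms but topology has %d",
                   ncol(traj) / 3L, ncol(pdb$xyz) / 3L), call. = FALSE)
    xyz <- traj[, .xyz_cols(parsed$keep_rows), drop = FALSE]
  }
  if (!is.null(window)) {
    stopifnot(inherits(window, "analysis_window"))
    if (window$first_frame >= nrow(xyz))
      stop("analysis window starts beyond the last frame", call. = FALSE)
    sel <- seq(window$first_frame, min(window$last_frame, nrow(xyz) - 1L),
               by = window$stride) + 1L
    if (length(sel) == 0L) stop("empty analysis window", call. = FALSE)
    xyz <- xyz[sel, , drop = FALSE]
  }
  .new_complex_model(parsed$atoms, xyz, domain_chain, peptide_chain,
                     sprintf("%s + %s", topology,
                             if (is.null(trajectory)) "models" else trajectory))
}

#' Write a complex model to a (multi-model) PDB file
#'
#' @param model a `complex_model`
#' @param file output path
#' @param frames frame numbers to write (default all)
#' @return `file`, invisibly
#' @export
write_complex_pdb <- function(model, file, frames = seq_len(n_frames(model))) {
  a <- model$atoms
  bio3d::write.pdb(file = file,
                   xyz = model$xyz[frames, , drop = FALSE],
                   resno = a$resno, resid = a$resid, eleno = a$eleno,
                   elety = a$elety, chain = a$chain,
                   insert = ifelse(nzchar(a$insert), a$insert, NA),
                   elesy = a$elesy)
  invisible(file)
}

#' Subset a model to selected frames
#'
#' @param model a `complex_model`
#' @param frames 1-based frame numbers
#' @return a `complex_model` with the selected frames
#' @export
subset_frames <- function(model, frames) {
  stopifnot(all(frames >= 1L), all(frames <= n_frames(model)))
  model$xyz <- model$xyz[frames, , drop = FALSE]
  model
}
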