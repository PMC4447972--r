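# Structure frames: a single coordinate set plus an atom table.
# PDB parsing/writing is delegated to bio3d; this layer adds element
# assignment, heavy-atom flags, and residue bookkeeping.

WATER_RESNAMES <- c("HOH", "TIP3", "TIP", "WAT", "SPC", "OH2", "SOL", "TP3")
ION_RESNAMES <- c("NA", "SOD", "CL", "CLA", "K", "POT", "LI", "LIT",
                  "MG", "CAL", "ZN", "CA2", "CS")

# Map leading characters of an atom name to an element, used when the PDB
# element column is absent. H, 1H..4H prefixes are hydrogens.
infer_element <- function(elety, resid) {
  elety <- toupper(trimws(elety))
  resid <- toupper(trimws(resid))
  n <- length(elety)
  out <- character(n)
  for (i in seq_len(n)) {
    e <- elety[i]
    r <- resid[i]
    # ions: resolve from residue name first (avoids CA = calcium vs C-alpha)
    if (r %in% ION_RESNAMES) {
      out[i] <- switch(r,
        "NA" = , "SOD" = "Na", "CL" = , "CLA" = "Cl", "K" = , "POT" = "K",
        "LI" = , "LIT" = "Li", "MG" = "Mg", "CAL" = , "CA2" = "Ca",
        "ZN" = "Zn", "CS" = "Cs")
      next
    }
    if (grepl("^[1-4]?H", e)) {
      out[i] <- "H"
      next
    }
    first <- substr(gsub("[^A-Z]", "", e), 1, 1)
    out[i] <- switch(first,
      "C" = "C", "N" = "N", "O" = "O", "S" = "S", "P" = "P", "F" = "F",
      NA_character_)
    if (is.na(out[i])) {
      mdain_abort(sprintf("cannot infer element for atom name '%s' (residue %s)",
                          elety[i], resid[i]), "mdain_element_error")
    }
  }
  out
}

#' Construct a structure frame
#'
#' A structure frame holds one coordinate set together with its atom table
#' (names, elements, residue numbering, chain, heavy-atom flag).
#'
#' @param atoms Data frame with columns `elety`, `resid`, `chain`, `resno`
#'   and optionally `element` (inferred from atom names when absent) and
#'   `type` ("ATOM"/"HETATM").
#' @param xyz Numeric matrix, one row per atom, columns x/y/z in Angstrom.
#' @param time_ps Simulation time of the frame in ps (non-negative).
#' @param box Optional orthorhombic box lengths (length-3, Angstrom).
#' @return Object of class `structure_frame`.
#' @export
structure_frame <- function(atoms, xyz, time_ps = 0, box = NULL) {
  stopifnot(is.data.frame(atoms), nrow(atoms) == nrow(xyz), ncol(xyz) == 3)
  if (nrow(atoms) == 0L) mdain_abort("structure has zero atoms", "mdain_io_error")
  if (time_ps < 0) mdain_abort("frame_time must be non-negative", "mdain_value_error")
  if (!all(is.finite(xyz))) mdain_abort("non-finite coordinates", "mdain_value_error")
  if (is.null(atoms$type)) atoms$type <- "ATOM"
  if (is.null(atoms$element) || anyNA(atoms$element)) {
    atoms$element <- infer_element(atoms$elety, atoms$resid)
  }
  if (any(atoms$resno < 1)) {
    mdain_abort("residue indices must be >= 1", "mdain_value_error")
  }
  atoms$is_heavy <- toupper(atoms$element) != "H"
  structure(list(atoms = atoms, xyz = unname(as.matrix(xyz)),
                 time_ps = time_ps, box = box),
            class = "structure_frame")
}

#' @export
print.structure_frame <- function(x, ...) {
  cat(sprintf("<structure_frame> %d atoms, %d residues, t = %g ps\n",
              nrow(x$atoms), nrow(residue_table(x)), x$time_ps))
  invisible(x)
}

#' Load a structure from a PDB file
#'
#' Reads the first model of a PDB file. Elements are taken from the element
#' column when present, otherwise inferred from atom names. Heteroatoms
#' (ions, waters) are retained and flagged via their record `type`.
#'
#' @param path Path to a PDB file.
#' @return A [structure_frame()].
#' @export
load_structure <- function(path) {
  if (!file.exists(path)) mdain_abort(paste("no such file:", path), "mdain_io_error")
  pdb <- tryCatch(bio3d::read.pdb(path),
                  error = function(e) mdain_abort(
                    paste("unreadable PDB:", conditionMessage(e)), "mdain_io_error"))
  at <- pdb$atom
  if (nrow(at) == 0L) mdain_abort("structure has zero atoms", "mdain_io_error")
  element <- at$elesy
  bad <- is.na(element) | trimws(element) == ""
  if (any(bad)) element[bad] <- infer_element(at$elety[bad], at$resid[bad])
  element <- paste0(toupper(substr(element, 1, 1)),
                    tolower(substr(element, 2, 2)))
  atoms <- data.frame(
    elety = at$elety, resid = at$resid,
    chain = ifelse(is.na(at$chain), "A", at$chain),
    resno = at$resno, element = trimws(element), type = at$type,
    stringsAsFactors = FALSE)
  structure_frame(atoms, cbind(at$x, at$y, at$z))
}

#' Write a structure frame to a PDB file
#'
#' @param frame A [structure_frame()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(frame, path) {
  at <- frame$atoms
  bio3d::write.pdb(file = path,
                   type = at$type, elety = at$elety, resid = at$resid,
                   chain = at$chain, resno = at$resno,
                   eleno = seq_len(nrow(at)),
                   elesy = at$element,
                   xyz = as.numeric(t(frame$xyz)))
  invisible(path)
}

#' Residue table of a frame
#'
#' One row per residue with a unique id (`uid`), chain, residue number and
#' 3-letter name, in atom order.
#'
#' @param frame A [structure_frame()].
#' @return Data frame with columns `uid`, `chain`, `resno`, `resid`.
#' @export
residue_table <- function(frame) {
  at <- frame$atoms
  uid <- paste(at$chain, at$resno, sep = ":")
  keep <- !duplicated(uid)
  data.frame(uid = uid[keep], chain = at$chain[keep], resno = at$resno[keep],
             resid = at$resid[keep], stringsAsFactors = FALSE)
}

residue_uids <- function(frame) paste(frame$atoms$chain, frame$atoms$resno, sep = ":")

is_water_atom <- function(atoms) toupper(atoms$resid) %in% WATER_RESNAMES
is_ion_atom <- function(atoms) toupper(atoms$resid) %in% ION_RESNAMES

# Mask of atoms participating in residue-pair analysis: protein-like
# residues only (waters and ions excluded by default).
analysis_mask <- function(frame, include_solvent = FALSE) {
  if (include_solvent) rep(TRUE, nrow(frame$atoms))
  else !(is_water_atom(frame$atoms) | is_ion_atom(frame$atoms))
}

#' Fetch a PDB entry from the RCSB (convenience; needs network)
#'
#' Downloads `<id>.pdb` into `dir`. Never called by the package's analyses
#' or tests; provided so users can pull reference structures such as 2A65.
#'
#' @param id 4-character PDB id.
#' @param dir Destination directory.
#' @return Path to the downloaded file.
#' @export
fetch_pdb <- function(id, dir = ".") {
  dest <- file.path(dir, paste0(tolower(id), ".pdb"))
  utils::download.file(sprintf("https://files.rcsb.org/download/%s.pdb",
                               toupper(id)), dest, quiet = TRUE)
  dest
}
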