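# Geometric hydrogen-bond (polar interaction) detection.
#
# Complements the vdW contact channel, in particular to catch polar changes
# between sequence-local residues (e.g. backbone hydrogen bonds), so NO
# sequence-separation exclusion is applied here. Donor/acceptor typing
# comes from per-residue templates; when hydrogens are present the full
# D-H...A geometry is tested, otherwise a tighter heavy-atom distance is
# used.

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "HSD", "HSE", "HSP", "ILE", "LEU", "LYS", "MET", "PHE", "PRO",
         "SER", "THR", "TRP", "TYR", "VAL")

#' Hydrogen-bond criteria
#'
#' Defaults follow the customary geometric criteria of HBPLUS-style polar
#' interaction detection, with a heavy-only fallback for structures
#' stripped of hydrogens.
#'
#' @param donor_acceptor_max Max donor-acceptor distance, Angstrom (3.9).
#' @param hydrogen_acceptor_max Max hydrogen-acceptor distance, Angstrom (2.5).
#' @param dha_angle_min Min donor-hydrogen-acceptor angle, degrees (90).
#' @param heavy_only_da_max Donor-acceptor cutoff when no hydrogens are
#'   present, Angstrom (3.5).
#' @return Object of class `hbond_criteria`.
#' @export
hbond_criteria <- function(donor_acceptor_max = 3.9,
                           hydrogen_acceptor_max = 2.5,
                           dha_angle_min = 90,
                           heavy_only_da_max = 3.5) {
  stopifnot(donor_acceptor_max > 0, hydrogen_acceptor_max > 0,
            heavy_only_da_max > 0,
            dha_angle_min >= 0, dha_angle_min <= 180)
  structure(list(donor_acceptor_max = donor_acceptor_max,
                 hydrogen_acceptor_max = hydrogen_acceptor_max,
                 dha_angle_min = dha_angle_min,
                 heavy_only_da_max = heavy_only_da_max),
            class = "hbond_criteria")
}

#' Donor/acceptor residue templates
#'
#' Side-chain donor/acceptor atoms per residue type, read from the packaged
#' editable `hbond_templates.tsv`. Backbone typing (amide N donor except in
#' proline; carbonyl O / OXT acceptor) is implicit for standard residues.
#'
#' @return Data frame with columns `resname`, `atom`, `role`.
#' @export
default_hbond_templates <- function() {
  utils::read.delim(system.file("extdata", "hbond_templates.tsv",
                                package = "mdain"),
                    stringsAsFactors = FALSE)
}

# Assign donor/acceptor roles to the (analysis-masked) atoms of a frame.
# Returns list(donors, acceptors): integer indices into frame$atoms.
type_polar_atoms <- function(frame, templates, include_solvent = FALSE) {
  at <- frame$atoms
  sel <- analysis_mask(frame, include_solvent) & at$is_heavy
  resid <- toupper(at$resid)
  known <- resid %in% AA3 | resid %in% toupper(templates$resname)
  unknown_res <- unique(at$resid[sel & !known])
  if (length(unknown_res)) {
    warning(sprintf("no donor/acceptor template for residue type(s): %s; skipped",
                    paste(unknown_res, collapse = ", ")))
  }
  donors <- sel & known &
    ((at$elety == "N" & resid != "PRO" & resid %in% AA3) | FALSE)
  acceptors <- sel & known &
    (at$elety %in% c("O", "OXT") & resid %in% AA3)
  key <- paste(resid, at$elety)
  tpl_d <- paste(toupper(templates$resname[templates$role %in% c("donor", "both")]),
                 templates$atom[templates$role %in% c("donor", "both")])
  tpl_a <- paste(toupper(templates$resname[templates$role %in% c("acceptor", "both")]),
                 templates$atom[templates$role %in% c("acceptor", "both")])
  donors <- donors | (sel & key %in% tpl_d)
  acceptors <- acceptors | (sel & key %in% tpl_a)
  list(donors = which(donors), acceptors = which(acceptors))
}

#' All residue pairs linked by a polar interaction in a frame
#'
#' A pair is reported when any donor-acceptor atom combination between the
#' two residues satisfies the criteria. Hydrogen-aware when the frame
#' contains hydrogens; heavy-only fallback otherwise. No sequence-
#' separation exclusion is applied (this channel exists to detect polar
#' changes between sequence-local residues).
#'
#' @param frame A [structure_frame()].
#' @param criteria An [hbond_criteria()].
#' @param templates Donor/acceptor templates, see
#'   [default_hbond_templates()].
#' @param include_solvent Include waters as partners (default FALSE).
#' @return Data frame of canonical residue pairs.
#' @export
frame_polar_pairs <- function(frame, criteria = hbond_criteria(),
                              templates = default_hbond_templates(),
                              include_solvent = FALSE) {
  empty <- data.frame(chain_a = character(0), resno_a = integer(0),
                      chain_b = character(0), resno_b = integer(0))
  typ <- type_polar_atoms(frame, templates, include_solvent)
  don <- typ$donors; acc <- typ$acceptors
  if (length(don) == 0L || length(acc) == 0L) return(empty)
  at <- frame$atoms
  dxyz <- frame$xyz[don, , drop = FALSE]
  axyz <- frame$xyz[acc, , drop = FALSE]
  dda <- pair_distances(dxyz, axyz, frame$box)
  same_res <- outer(paste(at$chain[don], at$resno[don]),
                    paste(at$chain[acc], at$resno[acc]), "==")
  has_h <- any(!at$is_heavy)
  if (!has_h) {
    ok <- dda <= criteria$heavy_only_da_max & !same_res
  } else {
    # bond hydrogens to their donor heavy atoms (<= 1.25 A)
    hyd <- which(!at$is_heavy)
    ok <- matrix(FALSE, length(don), length(acc))
    if (length(hyd)) {
      hxyz <- frame$xyz[hyd, , drop = FALSE]
      dh <- pair_distances(dxyz, hxyz, frame$box)
      ha <- pair_distances(hxyz, axyz, frame$box)
      within_da <- dda <= criteria$donor_acceptor_max & !same_res
      for (i in seq_along(don)) {
        hs <- which(dh[i, ] <= 1.25)
        if (length(hs) == 0L) {
          # donor lacking an explicit hydrogen: heavy-only test
          ok[i, ] <- dda[i, ] <= criteria$heavy_only_da_max & !same_res[i, ]
          next
        }
        cand <- which(within_da[i, ])
        for (j in cand) {
          for (h in hs) {
            if (ha[h, j] > criteria$hydrogen_acceptor_max) next
            v1 <- dxyz[i, ] - hxyz[h, ]
            v2 <- axyz[j, ] - hxyz[h, ]
            ang <- acos(pmin(1, pmax(-1, sum(v1 * v2) /
                     sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
            if (ang >= criteria$dha_angle_min) { ok[i, j] <- TRUE; break }
          }
        }
      }
    }
  }
  idx <- which(ok, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(empty)
  di <- don[idx[, 1]]; ai <- acc[idx[, 2]]
  dedup_pairs(canonical_pairs(at$chain[di], at$resno[di],
                              at$chain[ai], at$resno[ai]))
}
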