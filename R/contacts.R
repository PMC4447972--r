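# Van der Waals contact detection between residues.
#
# Two residues are in contact in a frame when any two of their heavy atoms
# are closer than the sum of their vdW radii plus a margin (default 0.6 A,
# strict inequality). Pairs closer than `sequence_exclusion` residues along
# the same chain are excluded from this channel, because nearest-neighbour
# vdW contacts are insensitive to conformational rearrangement.

#' Default van der Waals radii (Bondi-style heavy-atom set)
#'
#' Read from the packaged, user-editable `vdw_radii.tsv`. Results depend on
#' this table, so it is shipped explicitly rather than hard-coded.
#'
#' @return Named numeric vector, element -> radius in Angstrom.
#' @export
default_vdw_radii <- function() {
  tab <- utils::read.delim(system.file("extdata", "vdw_radii.tsv",
                                       package = "mdain"),
                           stringsAsFactors = FALSE)
  stats::setNames(tab$radius, tab$element)
}

#' Contact criteria
#'
#' @param vdw_margin Margin added to the radii sum, Angstrom (default 0.6).
#' @param sequence_exclusion Same-chain residue-separation threshold at or
#'   below which contact pairs are excluded (default 4).
#' @param radii Named element -> radius table (Angstrom).
#' @return Object of class `contact_criteria`.
#' @export
contact_criteria <- function(vdw_margin = 0.6, sequence_exclusion = 4,
                             radii = default_vdw_radii()) {
  stopifnot(vdw_margin >= 0, sequence_exclusion >= 0, all(radii > 0))
  structure(list(vdw_margin = vdw_margin,
                 sequence_exclusion = sequence_exclusion,
                 radii = radii),
            class = "contact_criteria")
}

atom_radii <- function(elements, radii) {
  r <- radii[elements]
  if (anyNA(r)) {
    mdain_abort(paste("no vdW radius for element(s):",
                      paste(unique(elements[is.na(r)]), collapse = ", ")),
                "mdain_element_error")
  }
  unname(r)
}

# Canonicalise residue pairs so uid_a < uid_b by (chain, resno).
canonical_pairs <- function(chain_a, resno_a, chain_b, resno_b) {
  swap <- (chain_b < chain_a) | (chain_a == chain_b & resno_b < resno_a)
  data.frame(
    chain_a = ifelse(swap, chain_b, chain_a),
    resno_a = ifelse(swap, resno_b, resno_a),
    chain_b = ifelse(swap, chain_a, chain_b),
    resno_b = ifelse(swap, resno_a, resno_b),
    stringsAsFactors = FALSE)
}

#' Canonical pair keys ("chain:resno--chain:resno") for a pair table
#'
#' @param pairs Data frame with columns `chain_a`, `resno_a`, `chain_b`,
#'   `resno_b`.
#' @return Character vector of pair identifiers.
#' @export
pair_keys <- function(pairs) {
  paste(paste(pairs$chain_a, pairs$resno_a, sep = ":"),
        paste(pairs$chain_b, pairs$resno_b, sep = ":"), sep = "--")
}

dedup_pairs <- function(pairs) {
  if (nrow(pairs) == 0L) return(pairs)
  pairs <- pairs[!duplicated(pair_keys(pairs)), , drop = FALSE]
  pairs[order(pairs$chain_a, pairs$resno_a, pairs$chain_b, pairs$resno_b), ,
        drop = FALSE]
}

#' All residue pairs in vdW contact in a frame
#'
#' @param frame A [structure_frame()].
#' @param criteria A [contact_criteria()].
#' @param include_solvent Include waters/ions as interaction partners
#'   (default FALSE).
#' @return Data frame of canonical residue pairs (`chain_a`, `resno_a`,
#'   `chain_b`, `resno_b`).
#' @export
frame_contact_pairs <- function(frame, criteria = contact_criteria(),
                                include_solvent = FALSE) {
  sel <- which(analysis_mask(frame, include_solvent) & frame$atoms$is_heavy)
  empty <- data.frame(chain_a = character(0), resno_a = integer(0),
                      chain_b = character(0), resno_b = integer(0))
  if (length(sel) < 2) return(empty)
  at <- frame$atoms[sel, ]
  xyz <- frame$xyz[sel, , drop = FALSE]
  r <- atom_radii(at$element, criteria$radii)
  d <- pair_distances(xyz, xyz, frame$box)
  thr <- outer(r, r, "+") + criteria$vdw_margin
  hit <- d < thr
  hit[lower.tri(hit, diag = TRUE)] <- FALSE
  idx <- which(hit, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(empty)
  pa <- at[idx[, 1], ]
  pb <- at[idx[, 2], ]
  keep <- !(pa$chain == pb$chain & abs(pa$resno - pb$resno) <= criteria$sequence_exclusion)
  if (!any(keep)) return(empty)
  dedup_pairs(canonical_pairs(pa$chain[keep], pa$resno[keep],
                              pb$chain[keep], pb$resno[keep]))
}

#' Are two residues in vdW contact?
#'
#' @param frame A [structure_frame()].
#' @param res_a,res_b Residue numbers (single chain) or `"chain:resno"` ids.
#' @param criteria A [contact_criteria()].
#' @return Logical scalar. Same-chain pairs separated by at most
#'   `sequence_exclusion` residues always return FALSE.
#' @export
residues_in_contact <- function(frame, res_a, res_b,
                                criteria = contact_criteria()) {
  uid <- residue_uids(frame)
  resolve <- function(r) {
    key <- if (grepl(":", as.character(r))) as.character(r)
           else paste(frame$atoms$chain[1], r, sep = ":")
    which(uid == key & frame$atoms$is_heavy)
  }
  ia <- resolve(res_a); ib <- resolve(res_b)
  if (length(ia) == 0L || length(ib) == 0L) {
    mdain_abort("residue with zero heavy atoms", "mdain_value_error")
  }
  ca <- frame$atoms$chain[ia[1]]; cb <- frame$atoms$chain[ib[1]]
  na <- frame$atoms$resno[ia[1]]; nb <- frame$atoms$resno[ib[1]]
  if (ca == cb && abs(na - nb) <= criteria$sequence_exclusion) return(FALSE)
  ra <- atom_radii(frame$atoms$element[ia], criteria$radii)
  rb <- atom_radii(frame$atoms$element[ib], criteria$radii)
  d <- pair_distances(frame$xyz[ia, , drop = FALSE],
                      frame$xyz[ib, , drop = FALSE], frame$box)
  any(d < outer(ra, rb, "+") + criteria$vdw_margin)
}

#' Residues with any atom near a set of anchor residues
#'
#' Scans the masked-in frames of an ensemble and returns the residues that
#' come within `distance` of any atom of the anchor residues in any frame
#' (used e.g. to restrict range-filtered interaction lists to the
#' neighbourhood of gating residues).
#'
#' @param ensemble A [condition_ensemble()].
#' @param anchors Residue numbers (single chain) or `"chain:resno"` ids.
#' @param distance Cutoff in Angstrom (default 3).
#' @return Character vector of `"chain:resno"` residue ids (anchors
#'   included).
#' @export
residues_near <- function(ensemble, anchors, distance = 3) {
  found <- character(0)
  for (ri in seq_along(ensemble$replicas)) {
    traj <- ensemble$replicas[[ri]]
    uid <- paste(traj$atoms$chain, traj$atoms$resno, sep = ":")
    akey <- vapply(as.character(anchors), function(r)
      if (grepl(":", r)) r else paste(traj$atoms$chain[1], r, sep = ":"), "")
    ai <- which(uid %in% akey)
    if (length(ai) == 0L) next
    for (k in masked_indices(ensemble)[[ri]]) {
      x <- traj$xyz[, , k, drop = TRUE]
      d <- pair_distances(x, x[ai, , drop = FALSE], traj$box)
      found <- union(found, uid[apply(d <= distance, 1, any)])
    }
  }
  sort(union(found, akey))
}
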