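# Geometric per-frame observables: extracellular-vestibule water counts,
# cation binding-site classification and time traces, chi1 rotamers, and
# conditional occupancy summaries.

#' Region specification for water counting
#'
#' Either the convex hull of the heavy atoms of a set of lining residues,
#' or an explicit cylinder (axis direction, radius, and bounds along the
#' axis measured from an origin).
#'
#' @param mode `"convex_hull"` or `"cylinder"`.
#' @param lining_residues Residue numbers (or `"chain:resno"` ids) whose
#'   heavy atoms define the hull.
#' @param origin Cylinder reference point (3-vector, Angstrom).
#' @param cylinder_axis Cylinder axis direction (3-vector).
#' @param cylinder_radius Cylinder radius, Angstrom.
#' @param z_bounds Interval along the axis, Angstrom.
#' @param water_resnames Residue names recognised as water.
#' @return Object of class `region_spec`.
#' @export
region_spec <- function(mode = c("convex_hull", "cylinder"),
                        lining_residues = NULL,
                        origin = c(0, 0, 0), cylinder_axis = c(0, 0, 1),
                        cylinder_radius = NULL, z_bounds = NULL,
                        water_resnames = WATER_RESNAMES) {
  mode <- match.arg(mode)
  if (mode == "convex_hull" && length(lining_residues) == 0L) {
    mdain_abort("convex_hull mode needs lining residues", "mdain_value_error")
  }
  if (mode == "cylinder" && (is.null(cylinder_radius) || is.null(z_bounds))) {
    mdain_abort("cylinder mode needs radius and z bounds", "mdain_value_error")
  }
  structure(list(mode = mode, lining_residues = lining_residues,
                 origin = origin, cylinder_axis = cylinder_axis,
                 cylinder_radius = cylinder_radius, z_bounds = z_bounds,
                 water_resnames = toupper(water_resnames)),
            class = "region_spec")
}

#' Read a region specification from YAML
#'
#' @param path YAML file mirroring the [region_spec()] fields.
#' @return A `region_spec`.
#' @export
read_region_spec <- function(path) {
  y <- yaml::read_yaml(path)
  region_spec(mode = y$mode,
              lining_residues = y$lining_residues,
              origin = as.numeric(y$origin %||% c(0, 0, 0)),
              cylinder_axis = as.numeric(y$cylinder_axis %||% c(0, 0, 1)),
              cylinder_radius = y$cylinder_radius,
              z_bounds = if (!is.null(y$z_bounds)) as.numeric(y$z_bounds),
              water_resnames = unlist(y$water_resnames %||% WATER_RESNAMES))
}

# LP feasibility test for membership of p in the convex hull of rows of X
# (boundary counts as inside: the region is closed).
in_convex_hull <- function(p, X) {
  n <- nrow(X)
  # shift for conditioning
  ctr <- colMeans(X)
  s <- boot::simplex(a = rep(0, n),
                     A3 = rbind(t(X - matrix(ctr, n, 3, byrow = TRUE)),
                                rep(1, n)),
                     b3 = c(p - ctr, 1))
  s$solved == 1
}

#' Count water molecules inside a region
#'
#' Counts water oxygens inside the convex hull of the lining residues'
#' heavy atoms, or inside the specified cylinder. Points on the region
#' boundary count as inside (closed region).
#'
#' @param frame A [structure_frame()].
#' @param region A [region_spec()].
#' @return Integer count.
#' @export
count_region_waters <- function(frame, region) {
  at <- frame$atoms
  wat <- toupper(at$resid) %in% region$water_resnames &
    toupper(at$element) == "O"
  if (!any(wat)) return(0L)
  wxyz <- frame$xyz[wat, , drop = FALSE]
  if (region$mode == "cylinder") {
    u <- region$cylinder_axis / sqrt(sum(region$cylinder_axis^2))
    rel <- sweep(wxyz, 2, region$origin)
    z <- as.numeric(rel %*% u)
    radial <- sqrt(rowSums((rel - outer(z, u))^2))
    return(sum(z >= region$z_bounds[1] & z <= region$z_bounds[2] &
               radial <= region$cylinder_radius))
  }
  uid <- residue_uids(frame)
  key <- vapply(as.character(region$lining_residues), function(r)
    if (grepl(":", r)) r else paste(at$chain[1], r, sep = ":"), "")
  lin <- which(uid %in% key & at$is_heavy)
  if (length(lin) < 4) mdain_abort("degenerate hull: < 4 lining atoms",
                                   "mdain_value_error")
  X <- frame$xyz[lin, , drop = FALSE]
  if (qr(sweep(X, 2, colMeans(X)))$rank < 3) {
    mdain_abort("degenerate hull: lining atoms are coplanar", "mdain_value_error")
  }
  sum(vapply(seq_len(nrow(wxyz)), function(i) in_convex_hull(wxyz[i, ], X),
             TRUE))
}

#' Cation binding-state thresholds
#'
#' Distances are between the mobile cation near the Na1/Na1' sites and the
#' cation bound in the Na2 site. The default boundaries classify a frame as
#' Na1-bound below 8.3 Angstrom, in transition up to 10.7, and in the Na1'
#' state beyond, so the three states partition the distance axis.
#'
#' @param na1_max Na1/transition boundary, Angstrom (default 8.3).
#' @param transition_max Transition/Na1' boundary, Angstrom (default 10.7).
#' @return Object of class `cation_state_thresholds`.
#' @export
cation_state_thresholds <- function(na1_max = 8.3, transition_max = 10.7) {
  if (!(0 < na1_max && na1_max < transition_max)) {
    mdain_abort("need 0 < na1_max < transition_max", "mdain_value_error")
  }
  structure(list(na1_max = na1_max, transition_max = transition_max),
            class = "cation_state_thresholds")
}

#' Classify a cation position by its distance to the Na2-bound cation
#'
#' @param distance Distance(s) in Angstrom (>= 0); vectorised.
#' @param thresholds A [cation_state_thresholds()].
#' @return Character vector in `{"Na1", "transition", "Na1prime"}`.
#' @export
classify_cation_state <- function(distance, thresholds = cation_state_thresholds()) {
  if (any(distance < 0)) mdain_abort("negative distance", "mdain_value_error")
  ifelse(distance < thresholds$na1_max, "Na1",
         ifelse(distance < thresholds$transition_max, "transition", "Na1prime"))
}

# Resolve an atom selector (named list matching atom-table columns, e.g.
# list(resid = "NA", resno = 600)) to exactly one atom index.
resolve_selector <- function(frame, selector) {
  at <- frame$atoms
  keep <- rep(TRUE, nrow(at))
  for (fld in names(selector)) {
    keep <- keep & (as.character(at[[fld]]) == as.character(selector[[fld]]))
  }
  idx <- which(keep)
  if (length(idx) != 1L) {
    mdain_abort(sprintf("selector resolves to %d atoms (need exactly 1)",
                        length(idx)), "mdain_selector_error")
  }
  idx
}

#' Cation binding-site time trace over an ensemble
#'
#' Per replica: the per-frame distance between the mobile cation and the
#' Na2-bound cation, the classified state, and contiguous same-state
#' segments.
#'
#' @param ensemble A [condition_ensemble()].
#' @param cation_selector,na2_selector Named lists matched against the atom
#'   table (each must resolve to exactly one atom).
#' @param thresholds A [cation_state_thresholds()].
#' @return List (one per replica) of `site_trace` objects with `times`,
#'   `distances`, `states`, `segments`.
#' @export
site_trace <- function(ensemble, cation_selector, na2_selector,
                       thresholds = cation_state_thresholds()) {
  lapply(seq_along(ensemble$replicas), function(ri) {
    traj <- ensemble$replicas[[ri]]
    f1 <- get_frame(traj, 1)
    i <- resolve_selector(f1, cation_selector)
    j <- resolve_selector(f1, na2_selector)
    idx <- masked_indices(ensemble)[[ri]]
    d <- vapply(idx, function(k)
      sqrt(sum((traj$xyz[i, , k] - traj$xyz[j, , k])^2)), 0)
    states <- classify_cation_state(d, thresholds)
    r <- rle(states)
    ends <- cumsum(r$lengths)
    segments <- data.frame(state = r$values,
                           first = c(1, utils::head(ends, -1) + 1),
                           last = ends, stringsAsFactors = FALSE)
    structure(list(times = traj$times_ps[idx], distances = d,
                   states = states, segments = segments),
              class = "site_trace")
  })
}

# gamma heavy atom used as the fourth chi1 atom, per residue type
CHI1_GAMMA <- c(ARG = "CG", ASN = "CG", ASP = "CG", CYS = "SG", GLN = "CG",
                GLU = "CG", HIS = "CG", HSD = "CG", HSE = "CG", ILE = "CG1",
                LEU = "CG", LYS = "CG", MET = "CG", PHE = "CG", PRO = "CG",
                SER = "OG", THR = "OG1", TRP = "CG", TYR = "CG", VAL = "CG1")

#' Side-chain chi1 dihedral of a residue
#'
#' Signed N-CA-CB-gamma torsion in degrees on (-180, 180]; the gamma heavy
#' atom follows the standard per-residue table. Glycine and alanine have no
#' chi1 and signal an error.
#'
#' @param frame A [structure_frame()].
#' @param residue Residue number (single chain) or `"chain:resno"` id.
#' @return Angle in degrees.
#' @export
chi1_angle <- function(frame, residue) {
  uid <- residue_uids(frame)
  key <- if (grepl(":", as.character(residue))) as.character(residue)
         else paste(frame$atoms$chain[1], residue, sep = ":")
  sel <- which(uid == key)
  if (length(sel) == 0L) mdain_abort("residue not found", "mdain_value_error")
  at <- frame$atoms[sel, ]
  resname <- toupper(at$resid[1])
  gamma <- CHI1_GAMMA[resname]
  if (is.na(gamma)) {
    mdain_abort(sprintf("chi1 undefined for residue type %s", resname),
                "mdain_chi1_undefined")
  }
  need <- c("N", "CA", "CB", unname(gamma))
  pos <- lapply(need, function(nm) {
    k <- sel[at$elety == nm]
    if (length(k) == 0L) mdain_abort(
      sprintf("missing atom %s for chi1 of %s", nm, key), "mdain_chi1_undefined")
    frame$xyz[k[1], ]
  })
  dihedral_angle(pos[[1]], pos[[2]], pos[[3]], pos[[4]])
}

#' Rotamer class of a chi1 angle
#'
#' gauche- for chi1 in `[-120, 0)`, gauche+ for `[0, 120)`, trans
#' otherwise.
#'
#' @param chi1 Angle(s) in degrees; vectorised.
#' @return Character vector in `{"gauche_minus", "gauche_plus", "trans"}`.
#' @export
rotamer_label <- function(chi1) {
  if (any(!is.finite(chi1))) mdain_abort("non-finite chi1", "mdain_value_error")
  ifelse(chi1 >= -120 & chi1 < 0, "gauche_minus",
         ifelse(chi1 >= 0 & chi1 < 120, "gauche_plus", "trans"))
}

#' Binding-site occupancy ratio among the most open frames
#'
#' Restricts pooled frames to the top `fraction` by an openness score
#' (e.g. vestibule water count) and reports the ratio of Na1-state to
#' Na1'-state frames, excluding transition frames from both counts. When no
#' Na1' frames fall in the pool the ratio is infinite and the counts are
#' reported alongside.
#'
#' @param openness Per-frame openness scores (pooled across ensembles).
#' @param states Per-frame state labels aligned with `openness`.
#' @param fraction Top quantile to keep (default 0.20).
#' @return List with `ratio`, `n_na1`, `n_na1prime`, `n_pool`.
#' @export
conditional_occupancy <- function(openness, states, fraction = 0.20) {
  stopifnot(length(openness) == length(states), fraction > 0, fraction <= 1)
  n_top <- max(1L, floor(fraction * length(openness)))
  top <- order(openness, decreasing = TRUE)[seq_len(n_top)]
  n1 <- sum(states[top] == "Na1")
  n1p <- sum(states[top] == "Na1prime")
  ratio <- if (n1p == 0L) Inf else n1 / n1p
  list(ratio = ratio, n_na1 = n1, n_na1prime = n1p, n_pool = n_top)
}

#' Write an observable time series as TSV
#'
#' @param times Times in ps.
#' @param value Observable values.
#' @param state Optional per-frame state labels.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_observable_series <- function(times, value, state = NULL, path) {
  df <- data.frame(time_ps = times, value = value)
  if (!is.null(state)) df$state <- state
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
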