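# Trajectories and condition ensembles.
#
# A trajectory is an atom table plus a coordinate array; an ensemble groups
# strided, equilibration-masked replica trajectories under one condition
# (the unit over which interaction frequencies are computed).

#' Construct an in-memory trajectory
#'
#' @param atoms Atom table as in [structure_frame()].
#' @param xyz Numeric array `n_atoms x 3 x n_frames`.
#' @param times_ps Frame times in ps (defaults to `0, dt, 2 dt, ...`).
#' @param box Optional orthorhombic box lengths.
#' @param dt_ps Save interval used to synthesise `times_ps` when absent.
#' @return Object of class `md_trajectory`.
#' @export
md_trajectory <- function(atoms, xyz, times_ps = NULL, box = NULL, dt_ps = 240) {
  stopifnot(length(dim(xyz)) == 3, dim(xyz)[2] == 3)
  nf <- dim(xyz)[3]
  if (is.null(times_ps)) times_ps <- (seq_len(nf) - 1) * dt_ps
  stopifnot(length(times_ps) == nf)
  frame1 <- structure_frame(atoms, xyz[, , 1, drop = TRUE])
  structure(list(atoms = frame1$atoms, xyz = xyz, times_ps = times_ps, box = box),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("<md_trajectory> %d atoms x %d frames\n",
              dim(x$xyz)[1], dim(x$xyz)[3]))
  invisible(x)
}

n_frames <- function(traj) dim(traj$xyz)[3]

#' Extract one frame of a trajectory
#'
#' @param traj An [md_trajectory()].
#' @param i Frame index (1-based).
#' @return A [structure_frame()].
#' @export
get_frame <- function(traj, i) {
  structure_frame(traj$atoms, traj$xyz[, , i, drop = TRUE],
                  time_ps = traj$times_ps[i], box = traj$box)
}

#' Read a trajectory file
#'
#' Supports multi-model PDB (self-topologied) and DCD (requires a PDB
#' topology). The topology atom count must match the trajectory.
#'
#' @param trajectory Path to a `.pdb` (multi-model) or `.dcd` file.
#' @param topology Optional PDB topology (required for DCD).
#' @param dt_ps Save interval in ps used to assign frame times.
#' @return An [md_trajectory()].
#' @export
read_trajectory <- function(trajectory, topology = NULL, dt_ps = 240) {
  ext <- tolower(tools::file_ext(trajectory))
  if (ext == "pdb") {
    pdb <- bio3d::read.pdb(trajectory, multi = TRUE)
    top <- load_structure(if (is.null(topology)) trajectory else topology)
    coords <- as.matrix(pdb$xyz)
    nat <- ncol(coords) / 3
    if (nat != nrow(top$atoms)) {
      mdain_abort("topology atom count does not match trajectory", "mdain_topology_error")
    }
    nf <- nrow(coords)
    xyz <- array(NA_real_, c(nat, 3, nf))
    for (k in seq_len(nf)) xyz[, , k] <- matrix(coords[k, ], ncol = 3, byrow = TRUE)
  } else if (ext == "dcd") {
    if (is.null(topology)) mdain_abort("DCD requires a topology", "mdain_topology_error")
    top <- load_structure(topology)
    coords <- bio3d::read.dcd(trajectory, verbose = FALSE)
    nat <- ncol(coords) / 3
    if (nat != nrow(top$atoms)) {
      mdain_abort("topology atom count does not match trajectory", "mdain_topology_error")
    }
    nf <- nrow(coords)
    xyz <- array(NA_real_, c(nat, 3, nf))
    for (k in seq_len(nf)) xyz[, , k] <- matrix(coords[k, ], ncol = 3, byrow = TRUE)
  } else {
    mdain_abort(paste("unsupported trajectory format:", ext), "mdain_io_error")
  }
  md_trajectory(top$atoms, xyz, dt_ps = dt_ps, box = top$box)
}

#' Write a trajectory as a multi-model PDB
#'
#' @param traj An [md_trajectory()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_pdb <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  for (k in seq_len(n_frames(traj))) {
    writeLines(sprintf("MODEL     %4d", k), con)
    write_structure(get_frame(traj, k), tmp)
    lines <- readLines(tmp)
    writeLines(lines[!grepl("^END", lines)], con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Construct a condition manifest
#'
#' A manifest names one simulated condition (e.g. `"WT.Na.ns"`) and lists
#' its replica trajectories with declared durations.
#'
#' @param condition Condition label (nonempty).
#' @param replicas Data frame with columns `trajectory`, `topology`,
#'   `replica_id`, `length_ns` (and optional `dt_ps`).
#' @return Object of class `condition_manifest`.
#' @export
condition_manifest <- function(condition, replicas) {
  if (!nzchar(condition)) mdain_abort("condition name must be nonempty", "mdain_value_error")
  stopifnot(is.data.frame(replicas), nrow(replicas) >= 1)
  if (is.null(replicas$topology)) replicas$topology <- NA_character_
  if (is.null(replicas$dt_ps)) replicas$dt_ps <- NA_real_
  if (any(replicas$length_ns <= 0)) {
    mdain_abort("declared replica lengths must be > 0", "mdain_value_error")
  }
  structure(list(condition = condition, replicas = replicas),
            class = "condition_manifest")
}

#' Read a condition manifest from YAML
#'
#' Expected layout: `condition: <name>` plus `replicas:` with fields
#' `trajectory`, `topology`, `replica_id`, `length_ns` and optional `dt_ps`.
#'
#' @param path YAML file.
#' @return A [condition_manifest()].
#' @export
read_manifest <- function(path) {
  y <- yaml::read_yaml(path)
  reps <- do.call(rbind, lapply(y$replicas, function(r) {
    data.frame(trajectory = r$trajectory,
               topology = r$topology %||% NA_character_,
               replica_id = r$replica_id,
               length_ns = r$length_ns,
               dt_ps = r$dt_ps %||% NA_real_,
               stringsAsFactors = FALSE)
  }))
  condition_manifest(y$condition, reps)
}

#' Replica and simulated-time totals over manifests
#'
#' Sums replica counts and declared simulation lengths. Accepts either a
#' list of [condition_manifest()] objects or a per-condition summary data
#' frame with columns `n_replicas` and `total_ns` (the bookkeeping form of
#' a printed simulation table).
#'
#' @param manifests List of manifests, or a summary data frame.
#' @return List with `total_replicas` and `total_ns`.
#' @export
manifest_totals <- function(manifests) {
  if (is.data.frame(manifests)) {
    return(list(total_replicas = sum(manifests$n_replicas),
                total_ns = sum(manifests$total_ns)))
  }
  if (length(manifests) == 0L) return(list(total_replicas = 0L, total_ns = 0))
  list(total_replicas = sum(vapply(manifests, function(m) nrow(m$replicas), 0L)),
       total_ns = sum(vapply(manifests, function(m) sum(m$replicas$length_ns), 0)))
}

#' Condition summary for the LeuT simulation set
#'
#' The per-condition replica counts and total simulated times of the ten
#' LeuT MD conditions (wild type and perturbed, with Na+ or Li+, with and
#' without substrate), shipped as a packaged table.
#'
#' @return Data frame with columns `condition`, `n_replicas`, `total_ns`.
#' @export
leut_condition_summary <- function() {
  utils::read.delim(system.file("extdata", "leut_conditions.tsv",
                                package = "mdain"),
                    stringsAsFactors = FALSE)
}

# Subsample frames of a trajectory to a target stride.
stride_trajectory <- function(traj, stride_ps) {
  dt <- if (n_frames(traj) > 1) diff(traj$times_ps[1:2]) else stride_ps
  if (stride_ps < dt - 1e-9) {
    mdain_abort("stride smaller than trajectory save interval", "mdain_value_error")
  }
  k <- stride_ps / dt
  if (abs(k - round(k)) > 1e-6) {
    mdain_abort("stride must be a multiple of the save interval", "mdain_value_error")
  }
  idx <- seq(1, n_frames(traj), by = round(k))
  md_trajectory(traj$atoms, traj$xyz[, , idx, drop = FALSE],
                times_ps = traj$times_ps[idx], box = traj$box)
}

#' Load a condition ensemble
#'
#' Reads every replica of a manifest, subsamples frames to the requested
#' stride and initialises the equilibration mask to all-true.
#'
#' @param manifest A [condition_manifest()].
#' @param stride_ps Sampling interval in ps (default 240).
#' @return Object of class `condition_ensemble`.
#' @export
load_ensemble <- function(manifest, stride_ps = 240) {
  trajs <- lapply(seq_len(nrow(manifest$replicas)), function(i) {
    r <- manifest$replicas[i, ]
    dt <- if (is.na(r$dt_ps)) stride_ps else r$dt_ps
    top <- if (is.na(r$topology)) NULL else r$topology
    stride_trajectory(read_trajectory(r$trajectory, top, dt_ps = dt), stride_ps)
  })
  condition_ensemble(manifest, trajs, stride_ps)
}

#' Construct a condition ensemble from in-memory trajectories
#'
#' @param manifest A [condition_manifest()] or a bare condition label.
#' @param replicas List of [md_trajectory()] objects (already strided).
#' @param stride_ps Sampling interval in ps.
#' @return Object of class `condition_ensemble`.
#' @export
condition_ensemble <- function(manifest, replicas, stride_ps = 240) {
  if (is.character(manifest)) {
    manifest <- condition_manifest(manifest, data.frame(
      trajectory = rep(NA_character_, length(replicas)),
      replica_id = seq_along(replicas),
      length_ns = vapply(replicas, function(t)
        max(1e-6, diff(range(t$times_ps)) / 1000), 0)))
  }
  if (stride_ps <= 0) mdain_abort("stride must be > 0", "mdain_value_error")
  mask <- lapply(replicas, function(t) rep(TRUE, n_frames(t)))
  structure(list(manifest = manifest, condition = manifest$condition,
                 replicas = replicas, stride_ps = stride_ps,
                 equilibrated_mask = mask),
            class = "condition_ensemble")
}

#' @export
print.condition_ensemble <- function(x, ...) {
  cat(sprintf("<condition_ensemble> %s: %d replicas, %s frames (%s masked in)\n",
              x$condition, length(x$replicas),
              sum(vapply(x$replicas, n_frames, 0L)),
              sum(vapply(x$equilibrated_mask, sum, 0L))))
  invisible(x)
}

#' Set the equilibration mask of an ensemble
#'
#' Marks, per replica, which frames belong to the equilibrated trajectory
#' segment used in all frequency computations.
#'
#' `rmsd_plateau` (default): the C-alpha RMSD trace to the mean structure of
#' the final 10% of frames is smoothed with a short running mean; the mask
#' admits frames from the first index after which the smoothed trace stays
#' within `tolerance` (default 1 Angstrom) of its final plateau value. If no
#' such index exists the whole replica is masked out with a warning.
#' `fixed_discard`: drop the first `fraction` of frames. `explicit`:
#' user-supplied inclusive frame-index ranges.
#'
#' @param ensemble A [condition_ensemble()].
#' @param method One of `"rmsd_plateau"`, `"fixed_discard"`, `"explicit"`.
#' @param tolerance Plateau tolerance band in Angstrom.
#' @param fraction Fraction discarded by `fixed_discard`.
#' @param ranges For `explicit`: list (one element per replica) of
#'   two-column matrices / list of `c(first, last)` pairs.
#' @return The ensemble with its mask updated.
#' @export
set_equilibration_mask <- function(ensemble,
                                   method = c("rmsd_plateau", "fixed_discard", "explicit"),
                                   tolerance = 1.0, fraction = 0.25, ranges = NULL) {
  method <- match.arg(method)
  ensemble$equilibrated_mask <- lapply(seq_along(ensemble$replicas), function(ri) {
    traj <- ensemble$replicas[[ri]]
    nf <- n_frames(traj)
    switch(method,
      fixed_discard = {
        drop <- floor(nf * fraction)
        c(rep(FALSE, drop), rep(TRUE, nf - drop))
      },
      explicit = {
        m <- rep(FALSE, nf)
        for (rg in ranges[[ri]]) m[rg[1]:rg[2]] <- TRUE
        m
      },
      rmsd_plateau = {
        idx <- which(traj$atoms$elety == "CA" & traj$atoms$is_heavy)
        if (length(idx) < 3) idx <- which(traj$atoms$is_heavy)
        flat <- t(apply(traj$xyz[idx, , , drop = FALSE], 3, function(m) as.numeric(t(m))))
        tail_n <- max(1, ceiling(0.1 * nf))
        ref_rows <- seq(nf - tail_n + 1, nf)
        inds <- seq_len(ncol(flat))
        fitted <- bio3d::fit.xyz(flat[nf, ], flat,
                                 fixed.inds = inds, mobile.inds = inds)
        ref <- colMeans(fitted[ref_rows, , drop = FALSE])
        r <- bio3d::rmsd(ref, fitted, fit = TRUE)
        w <- min(5, nf)
        sm <- stats::filter(r, rep(1 / w, w), sides = 2)
        sm[is.na(sm)] <- r[is.na(sm)]
        plateau <- mean(sm[ref_rows])
        ok <- abs(sm - plateau) <= tolerance
        # first index after which the trace stays in band
        stays <- rev(cumprod(rev(ok))) == 1
        if (!any(stays)) {
          warning(sprintf("replica %d: RMSD plateau never reached; masked out", ri))
          rep(FALSE, nf)
        } else {
          t0 <- which(stays)[1]
          c(rep(FALSE, t0 - 1), rep(TRUE, nf - t0 + 1))
        }
      })
  })
  ensemble
}

# Iterate over masked-in frames of an ensemble: returns list of per-replica
# integer index vectors.
masked_indices <- function(ensemble) {
  lapply(ensemble$equilibrated_mask, which)
}
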