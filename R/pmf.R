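# Umbrella-sampling bookkeeping and a 1-D WHAM solver with block-error
# estimation. Consumes reaction-coordinate samples produced elsewhere (the
# biased MD itself is out of scope).

KB_KCAL <- 0.0019872041  # Boltzmann constant, kcal/(mol K)

#' Construct an umbrella window
#'
#' @param center Restraint centre on the reaction coordinate z, Angstrom.
#' @param force_constant Harmonic force constant, kcal/(mol A^2) (> 0).
#' @param samples Reaction-coordinate samples, Angstrom.
#' @param equilibration_cut Duration already discarded, ps (metadata).
#' @return Object of class `umbrella_window`.
#' @export
umbrella_window <- function(center, force_constant, samples = numeric(0),
                            equilibration_cut = 0) {
  if (force_constant < 0) mdain_abort("force constant must be >= 0", "mdain_value_error")
  if (length(samples) && !all(is.finite(samples))) {
    mdain_abort("non-finite samples", "mdain_value_error")
  }
  structure(list(center = center, force_constant = force_constant,
                 samples = samples, equilibration_cut = equilibration_cut),
            class = "umbrella_window")
}

#' Regular grid of umbrella windows
#'
#' Centres run from `z_min` to `z_max` inclusive in steps of `spacing`;
#' the spacing must tile the interval exactly.
#'
#' @param z_min,z_max Reaction-coordinate limits, Angstrom.
#' @param spacing Window spacing, Angstrom.
#' @param force_constant Harmonic force constant, kcal/(mol A^2).
#' @return List of [umbrella_window()] objects of length
#'   `round((z_max - z_min)/spacing) + 1`.
#' @export
make_windows <- function(z_min, z_max, spacing, force_constant = 10) {
  stopifnot(z_min < z_max, spacing > 0)
  n <- (z_max - z_min) / spacing
  if (abs(n - round(n)) > 1e-9 * max(1, abs(n))) {
    mdain_abort("window spacing does not tile the interval", "mdain_value_error")
  }
  centers <- z_min + spacing * (0:round(n))
  lapply(centers, umbrella_window, force_constant = force_constant)
}

#' Discard the equilibration segment of a window's samples
#'
#' @param window An [umbrella_window()].
#' @param cut Duration to discard from the start, ps.
#' @param sample_interval Time between consecutive samples, ps.
#' @return The window with the first `cut` ps of samples removed.
#' @export
discard_equilibration <- function(window, cut, sample_interval) {
  stopifnot(cut >= 0, sample_interval > 0)
  n <- length(window$samples)
  drop <- round(cut / sample_interval)
  if (drop >= n) mdain_abort("equilibration cut >= window duration", "mdain_value_error")
  window$samples <- window$samples[(drop + 1):n]
  window$equilibration_cut <- window$equilibration_cut + cut
  window
}

#' WHAM configuration
#'
#' @param temperature Temperature, K (default 310).
#' @param bin_width Histogram bin width, Angstrom (default 0.05).
#' @param tolerance Convergence threshold on window free-energy shifts,
#'   kcal/mol (default 1e-7).
#' @param max_iterations Iteration cap (default 1e5).
#' @param n_blocks Blocks for error estimation (default 3).
#' @return Object of class `wham_config`.
#' @export
wham_config <- function(temperature = 310, bin_width = 0.05,
                        tolerance = 1e-7, max_iterations = 1e5, n_blocks = 3) {
  stopifnot(temperature > 0, tolerance > 0, bin_width > 0, n_blocks >= 2)
  structure(list(temperature = temperature, bin_width = bin_width,
                 tolerance = tolerance, max_iterations = max_iterations,
                 n_blocks = n_blocks),
            class = "wham_config")
}

# Core self-consistent WHAM iteration on pre-binned counts, in log space
# (strongly displaced windows underflow the linear form). counts:
# n_windows x n_bins; grid: bin centres; returns list(free_energy per bin
# [NA where unsampled], shifts f_i, iterations, converged).
wham_core <- function(counts, grid, centers, force_constants, config) {
  kt <- KB_KCAL * config$temperature
  nw <- nrow(counts)
  logc <- -(0.5 * force_constants * (outer(centers, grid, "-"))^2) / kt
  ni <- rowSums(counts)
  mj <- colSums(counts)
  logni <- ifelse(ni > 0, log(ni), -Inf)
  logmj <- ifelse(mj > 0, log(mj), -Inf)
  lse_cols <- function(m) {   # log-sum-exp down each column
    mx <- apply(m, 2, max)
    out <- mx + log(colSums(exp(sweep(m, 2, mx))))
    out[!is.finite(mx)] <- -Inf
    out
  }
  g <- rep(0, nw)             # f_i / kT
  converged <- FALSE
  it <- 0L
  logp <- rep(-Inf, length(grid))
  while (it < config$max_iterations) {
    it <- it + 1L
    logdenom <- lse_cols(logni + g + logc)
    logp <- logmj - logdenom
    gnew <- -lse_cols(t(logc + matrix(logp, nw, length(grid), byrow = TRUE)))
    gnew <- gnew - gnew[1]
    delta <- kt * max(abs(gnew - g))
    g <- gnew
    if (delta < config$tolerance) { converged <- TRUE; break }
  }
  fe <- ifelse(is.finite(logp), -kt * logp, NA_real_)
  list(free_energy = fe, shifts = kt * g, iterations = it,
       converged = converged)
}

bin_counts <- function(samples_list, grid, bin_width) {
  breaks <- c(grid - bin_width / 2, grid[length(grid)] + bin_width / 2)
  t(vapply(samples_list, function(s) {
    s <- s[s >= breaks[1] & s <= breaks[length(breaks)]]
    if (length(s) == 0L) return(numeric(length(grid)))
    as.numeric(table(cut(s, breaks = breaks, include.lowest = TRUE)))
  }, numeric(length(grid))))
}

# Overlap diagnostic: windows sorted by centre must have adjacent sampled
# bin ranges that touch or overlap, otherwise the histogram is disconnected.
check_overlap <- function(counts, centers) {
  ord <- order(centers)
  rng <- lapply(ord, function(i) range(which(counts[i, ] > 0)))
  for (k in seq_len(length(ord) - 1)) {
    if (rng[[k + 1]][1] > rng[[k]][2] + 1) {
      warning(sprintf(
        "disconnected histograms between windows at z = %.3f and %.3f",
        centers[ord[k]], centers[ord[k + 1]]))
    }
  }
}

#' Solve a 1-D WHAM problem
#'
#' Standard self-consistent weighted-histogram iteration over binned
#' samples under harmonic biases U_i(z) = k/2 (z - c_i)^2, converged when
#' the largest change in window free-energy shifts drops below the
#' tolerance. The profile is aligned min-zero by default.
#'
#' @param windows List of [umbrella_window()] objects with samples.
#' @param config A [wham_config()].
#' @param grid_range Optional `c(zmin, zmax)` limiting the reported grid
#'   (default: the sampled range). Samples outside are dropped.
#' @param align `"min_zero"` or `"none"`.
#' @return Object of class `pmf_profile`: `grid`, `free_energy`, `shifts`,
#'   `config`, `converged`, `iterations`.
#' @export
wham_solve <- function(windows, config = wham_config(), grid_range = NULL,
                       align = c("min_zero", "none")) {
  align <- match.arg(align)
  stopifnot(length(windows) >= 1)
  samples_list <- lapply(windows, `[[`, "samples")
  if (any(lengths(samples_list) == 0L)) {
    mdain_abort("every window needs at least one sample", "mdain_value_error")
  }
  if (is.null(grid_range)) grid_range <- range(unlist(samples_list))
  w <- config$bin_width
  ngrid <- max(1L, round(diff(grid_range) / w)) + 1L
  grid <- grid_range[1] + w * (seq_len(ngrid) - 1L)
  centers <- vapply(windows, `[[`, 0, "center")
  ks <- vapply(windows, `[[`, 0, "force_constant")
  counts <- bin_counts(samples_list, grid, w)
  if (length(windows) > 1) check_overlap(counts, centers)
  sol <- wham_core(counts, grid, centers, ks, config)
  if (!sol$converged) {
    warning(sprintf("WHAM did not converge in %d iterations", sol$iterations))
  }
  fe <- sol$free_energy
  if (align == "min_zero" && any(is.finite(fe))) fe <- fe - min(fe, na.rm = TRUE)
  structure(list(grid = grid, free_energy = fe, errors = NULL,
                 shifts = sol$shifts, config = config,
                 converged = sol$converged, iterations = sol$iterations,
                 reference = align),
            class = "pmf_profile")
}

#' @export
print.pmf_profile <- function(x, ...) {
  cat(sprintf("<pmf_profile> %d grid points on [%.2f, %.2f] A, %s\n",
              length(x$grid), min(x$grid), max(x$grid),
              if (x$converged) sprintf("converged in %d iterations", x$iterations)
              else "NOT converged"))
  invisible(x)
}

#' Block errors for a WHAM profile
#'
#' Splits every window's samples into `n_blocks` contiguous blocks, solves
#' WHAM once per block, aligns the block profiles on their common finite
#' support, and reports the standard error across blocks per grid point.
#' `method = "bootstrap"` instead resamples blocks with replacement
#' (Monte-Carlo bootstrap over blocks) and reports the standard deviation
#' of the bootstrap profiles.
#'
#' @param windows List of [umbrella_window()] objects.
#' @param config A [wham_config()].
#' @param n_blocks Number of contiguous blocks (default from config; 3 and
#'   7 are both customary).
#' @param method `"blocks"` or `"bootstrap"`.
#' @param n_boot Bootstrap replicates (default 50).
#' @param grid_range As in [wham_solve()].
#' @return A `pmf_profile` (full-data solution) with `errors` filled in.
#' @export
block_errors <- function(windows, config = wham_config(),
                         n_blocks = config$n_blocks,
                         method = c("blocks", "bootstrap"), n_boot = 50,
                         grid_range = NULL) {
  method <- match.arg(method)
  nsamp <- vapply(windows, function(w) length(w$samples), 0L)
  if (any(nsamp < n_blocks)) {
    mdain_abort("too few samples per window for the requested block count",
                "mdain_value_error")
  }
  if (is.null(grid_range)) {
    grid_range <- range(unlist(lapply(windows, `[[`, "samples")))
  }
  full <- wham_solve(windows, config, grid_range)
  block_of <- function(w, b) {
    n <- length(w$samples)
    edges <- round(seq(0, n, length.out = n_blocks + 1))
    w$samples <- w$samples[(edges[b] + 1):edges[b + 1]]
    w
  }
  solve_blockset <- function(bidx) {
    ws <- lapply(seq_along(windows), function(i) {
      # bootstrap: concatenate a resampled multiset of blocks
      if (length(bidx) > 1) {
        w <- windows[[i]]
        w$samples <- unlist(lapply(bidx, function(b)
          block_of(windows[[i]], b)$samples))
        w
      } else block_of(windows[[i]], bidx)
    })
    suppressWarnings(wham_solve(ws, config, grid_range, align = "none"))
  }
  profiles <- if (method == "blocks") {
    lapply(seq_len(n_blocks), solve_blockset)
  } else {
    lapply(seq_len(n_boot), function(r)
      solve_blockset(sample.int(n_blocks, n_blocks, replace = TRUE)))
  }
  mat <- vapply(profiles, `[[`, numeric(length(full$grid)), "free_energy")
  mat <- matrix(mat, nrow = length(full$grid))
  common <- apply(is.finite(mat), 1, all) & is.finite(full$free_energy)
  common[is.na(common)] <- FALSE
  if (!any(common)) mdain_abort("no common finite support across blocks",
                                "mdain_value_error")
  # common alignment: subtract each profile's mean over the shared support
  mat <- sweep(mat, 2, colMeans(mat[common, , drop = FALSE]))
  errs <- apply(mat, 1, stats::sd)
  if (method == "blocks") errs <- errs / sqrt(n_blocks)
  errs[!common] <- NA_real_
  full$errors <- errs
  full$n_blocks <- n_blocks
  full$error_method <- method
  full
}

#' Write / read umbrella windows in columnar text form
#'
#' `write_umbrella_windows` writes one two-column file (`time_ps`, `z_A`)
#' per window plus a metadata table (`file`, `center`, `force_constant`,
#' `temperature`) compatible with the customary WHAM input layout.
#'
#' @param windows List of [umbrella_window()] objects.
#' @param dir Output directory.
#' @param temperature Temperature recorded in the metadata, K.
#' @param sample_interval Sample spacing used for the time column, ps.
#' @return Path of the metadata file.
#' @export
write_umbrella_windows <- function(windows, dir, temperature = 310,
                                   sample_interval = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- data.frame(file = sprintf("window_%03d.dat", seq_along(windows)),
                     center = vapply(windows, `[[`, 0, "center"),
                     force_constant = vapply(windows, `[[`, 0, "force_constant"),
                     temperature = temperature)
  for (i in seq_along(windows)) {
    s <- windows[[i]]$samples
    utils::write.table(
      data.frame(time_ps = (seq_along(s) - 1) * sample_interval, z_A = s),
      file.path(dir, meta$file[i]), sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
  }
  meta_path <- file.path(dir, "windows.meta")
  utils::write.table(meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta_path
}

#' @rdname write_umbrella_windows
#' @param meta_path Metadata file written by `write_umbrella_windows`.
#' @export
read_umbrella_dataset <- function(meta_path) {
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  dir <- dirname(meta_path)
  lapply(seq_len(nrow(meta)), function(i) {
    dat <- utils::read.table(file.path(dir, meta$file[i]))
    umbrella_window(meta$center[i], meta$force_constant[i], dat[[2]])
  })
}

#' Flat-bottom cylindrical restraint metadata
#'
#' Recorded alongside PMF outputs for provenance (the restraint confines
#' ion dynamics in the xy plane during sampling); no standard-state volume
#' correction is applied to the profile.
#'
#' @param cylinder_radius Radius, Angstrom (default 15).
#' @return Object of class `restraint_spec`.
#' @export
restraint_spec <- function(cylinder_radius = 15) {
  stopifnot(cylinder_radius > 0)
  structure(list(cylinder_radius = cylinder_radius, style = "flat-bottom"),
            class = "restraint_spec")
}
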