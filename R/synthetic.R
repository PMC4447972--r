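# Synthetic-fixture generators with known ground truth: toy structures,
# trajectories with planted interaction-frequency differences and frame
# autocorrelation, exactly-sampled umbrella windows from analytic 1-D
# potentials, and cation distance traces. Fixtures validate code, not
# biology.

# idealised backbone internal coordinates
BB <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
           n_h = 1.000, ca_cb = 1.530, cb_cg = 1.530,
           ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
           ang_ca_c_o = 120.5, ang_c_n_h = 119.0,
           ang_n_ca_cb = 110.5, ang_ca_cb_cg = 114.0)

#' Build an idealised peptide structure
#'
#' Generates a chemically sane backbone (N, HN, CA, C, O) with CB and CG
#' side-chain atoms from standard bond lengths/angles, in either alpha-helix
#' (phi/psi = -57/-47; i,i+4 backbone hydrogen bonds detectable under the
#' default criteria) or extended (phi/psi = -139/135) geometry. Residues
#' are typed LEU so that chi1 (N-CA-CB-CG) is defined.
#'
#' @param n_residues Number of residues (>= 2).
#' @param geometry `"helix"` or `"extended"`.
#' @param seed RNG seed (used only when `jitter_sd > 0`).
#' @param jitter_sd Gaussian coordinate noise, Angstrom (default 0).
#' @param chi1 Side-chain chi1 dihedral applied to every residue, degrees.
#' @return A [structure_frame()].
#' @export
make_toy_structure <- function(n_residues, geometry = c("helix", "extended"),
                               seed = 1, jitter_sd = 0, chi1 = -60) {
  geometry <- match.arg(geometry)
  stopifnot(n_residues >= 2)
  phi <- if (geometry == "helix") -57 else -139
  psi <- if (geometry == "helix") -47 else 135
  omega <- 180
  atoms <- list(); coords <- list()
  add <- function(elety, element, resno, xyz) {
    atoms[[length(atoms) + 1L]] <<- data.frame(
      elety = elety, resid = "LEU", chain = "A", resno = resno,
      element = element, type = "ATOM", stringsAsFactors = FALSE)
    coords[[length(coords) + 1L]] <<- xyz
    xyz
  }
  # seed first residue
  n1 <- add("N", "N", 1L, c(0, 0, 0))
  ca1 <- add("CA", "C", 1L, c(BB$n_ca, 0, 0))
  c1 <- add("C", "C", 1L, place_atom(c(0, -1, 0), n1, ca1, BB$ca_c,
                                     BB$ang_n_ca_c, phi))
  prev <- list(n = n1, ca = ca1, c = c1)
  o_list <- list(); res_atoms <- list(list(n = n1, ca = ca1, c = c1))
  for (i in 2:n_residues) {
    n <- add("N", "N", i, place_atom(prev$n, prev$ca, prev$c, BB$c_n,
                                     BB$ang_ca_c_n, psi))
    ca <- add("CA", "C", i, place_atom(prev$ca, prev$c, n, BB$n_ca,
                                       BB$ang_c_n_ca, omega))
    cc <- add("C", "C", i, place_atom(prev$c, n, ca, BB$ca_c,
                                      BB$ang_n_ca_c, phi))
    # carbonyl O of residue i-1 (anti to the new N across C)
    add("O", "O", i - 1L, carbonyl_o(prev$ca, prev$c, n))
    # amide H of residue i (anti to the carbonyl O, in the peptide plane)
    add("HN", "H", i, amide_h(prev$c, n, ca))
    prev <- list(n = n, ca = ca, c = cc)
    res_atoms[[i]] <- list(n = n, ca = ca, c = cc)
  }
  # terminal carbonyl O
  add("O", "O", n_residues,
      carbonyl_o(prev$ca, prev$c, place_atom(prev$n, prev$ca, prev$c,
                                             BB$c_n, BB$ang_ca_c_n, psi)))
  # side chains: CB off the backbone, CG at the requested chi1
  for (i in seq_len(n_residues)) {
    ra <- res_atoms[[i]]
    cb <- add("CB", "C", i, place_atom(ra$c, ra$n, ra$ca, BB$ca_cb,
                                       BB$ang_n_ca_cb, 123))
    add("CG", "C", i, place_atom(ra$n, ra$ca, cb, BB$cb_cg,
                                 BB$ang_ca_cb_cg, chi1))
  }
  at <- do.call(rbind, atoms)
  xyz <- do.call(rbind, coords)
  ord <- order(at$resno, match(at$elety, c("N", "HN", "CA", "C", "O", "CB", "CG")))
  at <- at[ord, ]; xyz <- xyz[ord, , drop = FALSE]
  if (jitter_sd > 0) {
    set.seed(seed)
    xyz <- xyz + matrix(stats::rnorm(length(xyz), sd = jitter_sd), ncol = 3)
  }
  structure_frame(at, xyz)
}

# carbonyl O: in the Ca-C-N(next) plane, anti to N across C
carbonyl_o <- function(ca, c, n_next) {
  place_atom(ca, n_next, c, BB$c_o, 121, 180)
}

# amide H: in the C(prev)-N-CA plane, roughly anti to CA
amide_h <- function(c_prev, n, ca) {
  place_atom(ca, c_prev, n, BB$n_h, 119, 180)
}

#' Planted interaction model
#'
#' Defines per-condition Bernoulli probabilities for a set of residue
#' pairs, realised as two-state Markov chains: at each frame the pair's
#' state persists with probability `persistence`, otherwise it is redrawn
#' as Bernoulli(p). The stationary frequency equals p and the lag-1
#' autocorrelation equals `persistence`.
#'
#' @param n_residues Number of residues in the toy system.
#' @param pair_probabilities Named list (one element per condition) of data
#'   frames with columns `res_a`, `res_b`, `p`. A residue may appear in at
#'   most one planted pair.
#' @param persistence Markov self-persistence in `[0, 1)`.
#' @param n_frames,n_replicas Frames per replica, replicas per condition.
#' @param seed RNG seed.
#' @return Object of class `planted_interaction_model`.
#' @export
planted_interaction_model <- function(n_residues, pair_probabilities,
                                      persistence = 0, n_frames = 1000,
                                      n_replicas = 3, seed = 1) {
  stopifnot(persistence >= 0, persistence < 1, n_frames >= 1, n_replicas >= 1)
  for (cond in names(pair_probabilities)) {
    pp <- pair_probabilities[[cond]]
    stopifnot(all(pp$p >= 0 & pp$p <= 1))
    res_used <- c(pp$res_a, pp$res_b)
    if (anyDuplicated(res_used)) {
      mdain_abort("a residue may appear in at most one planted pair",
                  "mdain_value_error")
    }
    if (any(res_used > n_residues)) {
      mdain_abort("planted pair outside residue range", "mdain_value_error")
    }
  }
  structure(list(n_residues = n_residues,
                 pair_probabilities = pair_probabilities,
                 persistence = persistence, n_frames = n_frames,
                 n_replicas = n_replicas, seed = seed),
            class = "planted_interaction_model")
}

# One persistent-Bernoulli chain of length n started from stationarity.
simulate_pair_states <- function(p, persistence, n) {
  x <- logical(n)
  x[1] <- stats::runif(1) < p
  if (n > 1) {
    redraw <- stats::runif(n - 1) >= persistence
    fresh <- stats::runif(n - 1) < p
    for (t in 2:n) {
      x[t] <- if (redraw[t - 1]) fresh[t - 1] else x[t - 1]
    }
  }
  x
}

#' Simulate planted per-frame indicators for one condition
#'
#' @param model A [planted_interaction_model()].
#' @param condition Condition name (element of `pair_probabilities`).
#' @return List of per-replica logical matrices (pairs x frames).
#' @export
simulate_pair_indicators <- function(model, condition) {
  pp <- model$pair_probabilities[[condition]]
  lapply(seq_len(model$n_replicas), function(ri) {
    m <- t(vapply(seq_len(nrow(pp)), function(k)
      simulate_pair_states(pp$p[k], model$persistence, model$n_frames),
      logical(model$n_frames)))
    rownames(m) <- paste0("A:", pp$res_a, "--A:", pp$res_b)
    m
  })
}

#' Frequency tables sampled from a planted model
#'
#' Draws per-frame indicator chains for every condition and summarises them
#' as [frequency_table()] objects (the statistical structure the frequency
#' and differencing machinery assumes, without geometric realisation).
#'
#' @param model A [planted_interaction_model()].
#' @param keep_frames Retain per-frame indicators in the tables.
#' @return Named list of [frequency_table()] objects plus the ground-truth
#'   probabilities in `attr(, "truth")`.
#' @export
make_frequency_tables <- function(model, keep_frames = FALSE) {
  set.seed(model$seed)
  out <- lapply(names(model$pair_probabilities), function(cond) {
    pp <- model$pair_probabilities[[cond]]
    ind <- simulate_pair_indicators(model, cond)
    per_replica <- vapply(ind, rowMeans, numeric(nrow(pp)))
    per_replica <- matrix(per_replica, nrow = nrow(pp))
    pairs <- canonical_pairs(rep("A", nrow(pp)), pp$res_a,
                             rep("A", nrow(pp)), pp$res_b)
    frequency_table(cond, pairs, per_replica,
                    n_frames = rep(model$n_frames, model$n_replicas),
                    frames = if (keep_frames) ind else NULL)
  })
  names(out) <- names(model$pair_probabilities)
  attr(out, "truth") <- model$pair_probabilities
  out
}

#' Geometric realisation of a planted interaction model
#'
#' Residues are two-atom (CA, CB) units parked far apart; a planted pair in
#' the "on" state translates its second residue so the CB-CB separation
#' sits 0.5 Angstrom inside the contact threshold, and "off" frames sit at
#' the distant home position, so the contact detector is unambiguous.
#'
#' @param model A [planted_interaction_model()].
#' @return List with `ensembles` (named list of [condition_ensemble()]) and
#'   `truth` (the planted probabilities).
#' @export
make_interaction_trajectory <- function(model) {
  set.seed(model$seed)
  nres <- model$n_residues
  home <- cbind(0, 30 * seq_len(nres), 0)
  base_atoms <- do.call(rbind, lapply(seq_len(nres), function(i) {
    data.frame(elety = c("CA", "CB"), resid = "GLY", chain = "A",
               resno = i, element = "C", type = "ATOM",
               stringsAsFactors = FALSE)
  }))
  contact_sep <- 2 * 1.70 + 0.6 - 0.5       # CB-CB "on" separation
  base_xyz <- matrix(NA_real_, 2 * nres, 3)
  base_xyz[seq(1, 2 * nres, 2), ] <- home                     # CA
  base_xyz[seq(2, 2 * nres, 2), ] <- sweep(home, 2, c(1.7, 0, 0), "+")  # CB
  ensembles <- lapply(names(model$pair_probabilities), function(cond) {
    pp <- model$pair_probabilities[[cond]]
    ind <- simulate_pair_indicators(model, cond)
    trajs <- lapply(ind, function(states) {
      xyz <- array(rep(base_xyz, model$n_frames),
                   c(2 * nres, 3, model$n_frames))
      for (k in seq_len(nrow(pp))) {
        i <- pp$res_a[k]; j <- pp$res_b[k]
        on <- which(states[k, ])
        # translate residue j so CB_j lands contact_sep from CB_i
        target_cb <- home[i, ] + c(1.7 + contact_sep, 0, 0)
        shift <- target_cb - (home[j, ] + c(1.7, 0, 0))
        for (f in on) {
          xyz[2 * j - 1, , f] <- xyz[2 * j - 1, , f] + shift
          xyz[2 * j, , f] <- xyz[2 * j, , f] + shift
        }
      }
      md_trajectory(base_atoms, xyz, dt_ps = 240)
    })
    condition_ensemble(cond, trajs, stride_ps = 240)
  })
  names(ensembles) <- names(model$pair_probabilities)
  list(ensembles = ensembles, truth = model$pair_probabilities)
}

#' Quadratic 1-D potential
#'
#' @param a Coefficient in kcal/(mol A^2): U(z) = a z^2.
#' @return Function with attribute `quadratic_a` (enables closed-form
#'   Gaussian umbrella sampling).
#' @export
quadratic_potential <- function(a) {
  f <- function(z) a * z^2
  attr(f, "quadratic_a") <- a
  f
}

#' Exact samples from biased umbrella-window distributions
#'
#' Draws from p_i(z) proportional to exp(-(U(z) + k/2 (z - c_i)^2) / kT).
#' When U is quadratic (see [quadratic_potential()]) the biased density is
#' an exact Gaussian and is sampled in closed form; otherwise samples are
#' drawn by inverse-CDF lookup on a dense grid of the analytic density.
#'
#' @param potential Function U(z) in kcal/mol.
#' @param windows List of [umbrella_window()] objects (centres and force
#'   constants; samples are filled in).
#' @param temperature Temperature, K.
#' @param n_per_window Samples per window.
#' @param seed RNG seed.
#' @return The windows with `samples` populated.
#' @export
make_umbrella_samples <- function(potential, windows, temperature = 310,
                                  n_per_window = 5000, seed = 1) {
  set.seed(seed)
  kt <- KB_KCAL * temperature
  a <- attr(potential, "quadratic_a")
  lapply(windows, function(w) {
    k <- w$force_constant
    if (!is.null(a)) {
      # U + bias = (a + k/2) z^2 - k c z + const: Gaussian
      prec <- (2 * a + k) / kt
      mu <- (k * w$center) / (2 * a + k)
      w$samples <- stats::rnorm(n_per_window, mu, sqrt(1 / prec))
    } else {
      u <- function(z) potential(z) + 0.5 * k * (z - w$center)^2
      # locate the biased minimum and take a generous bracket
      opt <- stats::optimize(u, c(w$center - 50, w$center + 50))
      zg <- seq(opt$minimum - 25, opt$minimum + 25, length.out = 40001)
      lw <- -(u(zg) - opt$objective) / kt
      dens <- exp(lw - max(lw))
      if (!all(is.finite(dens)) || sum(dens) <= 0) {
        mdain_abort("biased density not integrable on the sampling bracket",
                    "mdain_value_error")
      }
      cdf <- cumsum(dens); cdf <- cdf / cdf[length(cdf)]
      keep <- !duplicated(cdf)
      w$samples <- stats::approx(cdf[keep], zg[keep],
                                 xout = stats::runif(n_per_window),
                                 rule = 2)$y
    }
    w
  })
}

#' Synthetic cation distance trace with known hidden states
#'
#' Distances are drawn around per-state class centres (7.0 / 9.5 / 12.5
#' Angstrom for Na1 / transition / Na1') with Gaussian noise.
#'
#' @param state_sequence Character vector over
#'   `{"Na1", "transition", "Na1prime"}`.
#' @param thresholds A [cation_state_thresholds()] (used to warn when the
#'   noise can cross a class boundary).
#' @param noise_sd Gaussian noise, Angstrom.
#' @param seed RNG seed.
#' @return Numeric distance series, same length as `state_sequence`.
#' @export
make_cation_trace <- function(state_sequence,
                              thresholds = cation_state_thresholds(),
                              noise_sd = 0, seed = 1) {
  centers <- c(Na1 = 7.0, transition = 9.5, Na1prime = 12.5)
  stopifnot(all(state_sequence %in% names(centers)))
  margins <- c(thresholds$na1_max - centers["Na1"],
               min(centers["transition"] - thresholds$na1_max,
                   thresholds$transition_max - centers["transition"]),
               centers["Na1prime"] - thresholds$transition_max)
  if (noise_sd > 0 && any(3 * noise_sd > margins)) {
    warning("noise_sd large enough that distances may cross class bounds")
  }
  set.seed(seed)
  unname(centers[state_sequence]) +
    if (noise_sd > 0) stats::rnorm(length(state_sequence), 0, noise_sd) else 0
}
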