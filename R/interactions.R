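# Pairwise residue interactions: per-frame union of the contact and polar
# channels, per-condition frequency tables over replica ensembles, and
# significance-based differencing between conditions.

#' All interacting residue pairs in a frame
#'
#' A pairwise residue interaction exists when either a vdW contact or a
#' polar interaction is detected between the pair.
#'
#' @param frame A [structure_frame()].
#' @param contact A [contact_criteria()].
#' @param hbond An [hbond_criteria()].
#' @param templates Donor/acceptor templates.
#' @param include_solvent Include waters/ions as partners (default FALSE).
#' @return Data frame of canonical residue pairs.
#' @export
frame_interactions <- function(frame, contact = contact_criteria(),
                               hbond = hbond_criteria(),
                               templates = default_hbond_templates(),
                               include_solvent = FALSE) {
  dedup_pairs(rbind(frame_contact_pairs(frame, contact, include_solvent),
                    frame_polar_pairs(frame, hbond, templates, include_solvent)))
}

#' Construct an interaction frequency table
#'
#' Usually produced by [ensemble_frequencies()]; the constructor is exposed
#' so tables can also be built from externally computed (or simulated)
#' per-replica frequencies.
#'
#' @param condition Condition label.
#' @param pairs Data frame with columns `chain_a`, `resno_a`, `chain_b`,
#'   `resno_b` (one row per residue pair).
#' @param per_replica Numeric matrix, pairs x replicas, of per-replica
#'   interaction frequencies in `[0, 1]`.
#' @param n_frames Masked-in frame counts per replica.
#' @param frames Optional list (per replica) of logical matrices
#'   pairs x frames with the per-frame interaction indicators (needed for
#'   the block-bootstrap differencing method).
#' @return Object of class `interaction_frequency_table`.
#' @export
frequency_table <- function(condition, pairs, per_replica, n_frames,
                            frames = NULL) {
  per_replica <- as.matrix(per_replica)
  stopifnot(nrow(pairs) == nrow(per_replica),
            length(n_frames) == ncol(per_replica),
            all(per_replica >= 0 & per_replica <= 1))
  pairs$pair <- pair_keys(pairs)
  # overall frequency = frame-weighted mean of per-replica frequencies
  w <- n_frames / sum(n_frames)
  pairs$frequency <- as.numeric(per_replica %*% w)
  structure(list(condition = condition, pairs = pairs,
                 per_replica = per_replica, n_frames = n_frames,
                 frames = frames),
            class = "interaction_frequency_table")
}

#' @export
print.interaction_frequency_table <- function(x, ...) {
  cat(sprintf("<interaction_frequency_table> %s: %d pairs, %d replicas (%s frames)\n",
              x$condition, nrow(x$pairs), ncol(x$per_replica),
              paste(x$n_frames, collapse = "+")))
  invisible(x)
}

#' Interaction frequencies over a condition ensemble
#'
#' The frequency of a residue pair is the fraction of masked-in frames in
#' which the pair interacts; per-replica frequencies are retained. Pairs
#' never observed are absent from the table (implicit frequency 0).
#'
#' @param ensemble A [condition_ensemble()].
#' @param contact A [contact_criteria()].
#' @param hbond An [hbond_criteria()].
#' @param templates Donor/acceptor templates.
#' @param keep_frames Retain per-frame indicators (enables the
#'   block-bootstrap differencing method).
#' @param include_solvent Include waters/ions as partners.
#' @return An [frequency_table()].
#' @export
ensemble_frequencies <- function(ensemble, contact = contact_criteria(),
                                 hbond = hbond_criteria(),
                                 templates = default_hbond_templates(),
                                 keep_frames = FALSE,
                                 include_solvent = FALSE) {
  idx <- masked_indices(ensemble)
  if (sum(lengths(idx)) == 0L) {
    mdain_abort("ensemble has no masked-in frames", "mdain_value_error")
  }
  if (any(lengths(idx) == 0L)) {
    mdain_abort("every replica must contribute at least one masked-in frame",
                "mdain_value_error")
  }
  per_rep_sets <- lapply(seq_along(ensemble$replicas), function(ri) {
    traj <- ensemble$replicas[[ri]]
    lapply(idx[[ri]], function(k) {
      pair_keys(frame_interactions(get_frame(traj, k), contact, hbond,
                                   templates, include_solvent))
    })
  })
  all_keys <- sort(unique(unlist(per_rep_sets)))
  nrep <- length(per_rep_sets)
  per_replica <- matrix(0, length(all_keys), nrep)
  frames <- if (keep_frames) vector("list", nrep) else NULL
  for (ri in seq_len(nrep)) {
    sets <- per_rep_sets[[ri]]
    ind <- vapply(sets, function(s) all_keys %in% s,
                  logical(length(all_keys)))
    ind <- matrix(ind, nrow = length(all_keys))
    per_replica[, ri] <- rowMeans(ind)
    if (keep_frames) frames[[ri]] <- ind
  }
  pairs <- parse_pair_keys(all_keys)
  frequency_table(ensemble$condition, pairs, per_replica,
                  n_frames = lengths(idx), frames = frames)
}

parse_pair_keys <- function(keys) {
  if (length(keys) == 0L) {
    return(data.frame(chain_a = character(0), resno_a = integer(0),
                      chain_b = character(0), resno_b = integer(0)))
  }
  halves <- strsplit(keys, "--", fixed = TRUE)
  split1 <- strsplit(vapply(halves, `[`, "", 1), ":", fixed = TRUE)
  split2 <- strsplit(vapply(halves, `[`, "", 2), ":", fixed = TRUE)
  data.frame(chain_a = vapply(split1, `[`, "", 1),
             resno_a = as.integer(vapply(split1, `[`, "", 2)),
             chain_b = vapply(split2, `[`, "", 1),
             resno_b = as.integer(vapply(split2, `[`, "", 2)),
             stringsAsFactors = FALSE)
}

# Align two tables on the union of their pair keys; absent pairs get
# all-zero per-replica frequencies.
align_tables <- function(table_a, table_b) {
  keys <- sort(union(table_a$pairs$pair, table_b$pairs$pair))
  expand <- function(tab) {
    m <- matrix(0, length(keys), ncol(tab$per_replica))
    hit <- match(tab$pairs$pair, keys)
    m[hit, ] <- tab$per_replica
    m
  }
  list(keys = keys, a = expand(table_a), b = expand(table_b))
}

#' Significantly different interaction frequencies between two conditions
#'
#' A residue pair differs significantly between conditions a and b when the
#' difference in its interaction frequencies is statistically significantly
#' different from zero. The default `replica_t` method applies an
#' unequal-variance t test to the per-replica frequencies (replicas as
#' independent units, robust to within-replica frame autocorrelation); the
#' `block_bootstrap` fallback (for single-replica conditions) uses a
#' circular block bootstrap over frames. P values are corrected across all
#' tested pairs by Benjamini-Hochberg; returned edges satisfy q <= alpha.
#'
#' @param table_a,table_b [frequency_table()] objects for the investigated
#'   and reference conditions.
#' @param alpha FDR level (default 0.05).
#' @param method `"replica_t"` or `"block_bootstrap"`.
#' @param block_length Bootstrap block length in frames (default 20).
#' @param n_boot Bootstrap replicates (default 400).
#' @return Data frame of class `differential_edges`: `pair`, residue ids,
#'   `freq_a`, `freq_b`, `delta`, `p_value`, `q_value`, `direction`.
#' @export
differential_pairs <- function(table_a, table_b, alpha = 0.05,
                               method = c("replica_t", "block_bootstrap"),
                               block_length = 20, n_boot = 400) {
  method <- match.arg(method)
  al <- align_tables(table_a, table_b)
  if (length(al$keys) == 0L) return(empty_edges())
  wa <- table_a$n_frames / sum(table_a$n_frames)
  wb <- table_b$n_frames / sum(table_b$n_frames)
  freq_a <- as.numeric(al$a %*% wa)
  freq_b <- as.numeric(al$b %*% wb)
  if (method == "replica_t") {
    if (ncol(al$a) < 2 || ncol(al$b) < 2) {
      mdain_abort("replica_t requires >= 2 replicas per condition; use block_bootstrap",
                  "mdain_value_error")
    }
    p <- vapply(seq_along(al$keys), function(i)
      welch_p(al$a[i, ], al$b[i, ]), 0)
  } else {
    if (is.null(table_a$frames) || is.null(table_b$frames)) {
      mdain_abort("block_bootstrap needs tables built with keep_frames = TRUE",
                  "mdain_value_error")
    }
    p <- block_bootstrap_p(table_a, table_b, al, block_length, n_boot)
  }
  q <- stats::p.adjust(p, method = "BH")
  delta <- freq_a - freq_b
  out <- parse_pair_keys(al$keys)
  out$pair <- al$keys
  out$freq_a <- freq_a
  out$freq_b <- freq_b
  out$delta <- delta
  out$p_value <- p
  out$q_value <- q
  out$direction <- ifelse(delta >= 0, "higher_in_a", "higher_in_b")
  out <- out[q <= alpha & delta != 0, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("differential_edges", "data.frame")
  out
}

empty_edges <- function() {
  out <- data.frame(chain_a = character(0), resno_a = integer(0),
                    chain_b = character(0), resno_b = integer(0),
                    pair = character(0), freq_a = numeric(0),
                    freq_b = numeric(0), delta = numeric(0),
                    p_value = numeric(0), q_value = numeric(0),
                    direction = character(0), stringsAsFactors = FALSE)
  class(out) <- c("differential_edges", "data.frame")
  out
}

# Welch two-sample t test on per-replica frequencies, tolerant of
# zero-variance degenerate cases.
welch_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  d <- mean(x) - mean(y)
  se2 <- stats::var(x) / nx + stats::var(y) / ny
  if (se2 <= 0) return(if (abs(d) < .Machine$double.eps^0.5) 1 else 0)
  tstat <- d / sqrt(se2)
  df <- se2^2 / ((stats::var(x) / nx)^2 / (nx - 1) +
                 (stats::var(y) / ny)^2 / (ny - 1))
  2 * stats::pt(-abs(tstat), df)
}

# Circular block bootstrap over frames, both conditions resampled
# independently; null-centred two-sided p value.
block_bootstrap_p <- function(table_a, table_b, al, block_length, n_boot) {
  resample_freqs <- function(tab, keys) {
    hit <- match(tab$pairs$pair, keys)
    freqs <- matrix(0, length(keys), length(tab$frames))
    for (ri in seq_along(tab$frames)) {
      ind <- tab$frames[[ri]]
      nf <- ncol(ind)
      nb <- ceiling(nf / block_length)
      starts <- sample.int(nf, nb, replace = TRUE)
      pick <- unlist(lapply(starts, function(s)
        ((s - 1 + seq_len(block_length) - 1) %% nf) + 1))[seq_len(nf)]
      freqs[hit, ri] <- rowMeans(ind[, pick, drop = FALSE])
    }
    as.numeric(freqs %*% (tab$n_frames / sum(tab$n_frames)))
  }
  wa <- table_a$n_frames / sum(table_a$n_frames)
  wb <- table_b$n_frames / sum(table_b$n_frames)
  d_obs <- as.numeric(al$a %*% wa) - as.numeric(al$b %*% wb)
  dstar <- replicate(n_boot,
    resample_freqs(table_a, al$keys) - resample_freqs(table_b, al$keys))
  dstar <- matrix(dstar, nrow = length(al$keys))
  exceed <- rowSums(abs(dstar - d_obs) >= abs(d_obs))
  (1 + exceed) / (n_boot + 1)
}

#' Filter pairs by min-max frequency range across conditions
#'
#' Keeps the residue pairs whose interaction frequency range (maximum minus
#' minimum across the given condition tables) is at least `threshold`
#' (default 0.3). Optionally restrict to pairs touching a residue set,
#' e.g. the residues found within 3 Angstrom of gating residues by
#' [residues_near()].
#'
#' @param tables List of [frequency_table()] objects (>= 2).
#' @param threshold Minimum max-min frequency difference (default 0.3,
#'   inclusive).
#' @param restrict_to Optional character vector of `"chain:resno"` residue
#'   ids; only pairs with at least one residue in the set are kept.
#' @return Data frame with pair ids, per-condition frequencies, and the
#'   range, sorted by decreasing range.
#' @export
minmax_range_filter <- function(tables, threshold = 0.3, restrict_to = NULL) {
  stopifnot(length(tables) >= 2)
  keys <- sort(unique(unlist(lapply(tables, function(t) t$pairs$pair))))
  freq <- vapply(tables, function(t) {
    f <- numeric(length(keys))
    f[match(t$pairs$pair, keys)] <- t$pairs$frequency
    f
  }, numeric(length(keys)))
  freq <- matrix(freq, nrow = length(keys))
  colnames(freq) <- vapply(tables, function(t) t$condition, "")
  rng <- apply(freq, 1, max) - apply(freq, 1, min)
  out <- cbind(parse_pair_keys(keys),
               data.frame(pair = keys, stringsAsFactors = FALSE),
               as.data.frame(freq), range = rng)
  keep <- rng >= threshold
  if (!is.null(restrict_to)) {
    ua <- paste(out$chain_a, out$resno_a, sep = ":")
    ub <- paste(out$chain_b, out$resno_b, sep = ":")
    keep <- keep & (ua %in% restrict_to | ub %in% restrict_to)
  }
  out <- out[keep, , drop = FALSE]
  out[order(-out$range), , drop = FALSE]
}

#' Write / read interaction frequency tables as TSV
#'
#' The text form has one row per pair: pair id, residue ids, overall
#' frequency, then one `rep_<id>` column per replica; replica frame counts
#' travel in a `# n_frames:` header comment.
#'
#' @param table An [frequency_table()].
#' @param path Output path.
#' @return `path` (write) or the reconstructed table (read).
#' @export
write_frequency_table <- function(table, path) {
  df <- table$pairs[, c("pair", "chain_a", "resno_a", "chain_b", "resno_b",
                        "frequency")]
  reps <- as.data.frame(table$per_replica)
  names(reps) <- paste0("rep_", seq_len(ncol(reps)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# condition: %s", table$condition),
               sprintf("# n_frames: %s", paste(table$n_frames, collapse = ","))),
             con)
  utils::write.table(cbind(df, reps), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_frequency_table
#' @export
read_frequency_table <- function(path) {
  hdr <- readLines(path, n = 2)
  condition <- sub("^# condition: ", "", hdr[1])
  n_frames <- as.numeric(strsplit(sub("^# n_frames: ", "", hdr[2]), ",")[[1]])
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  repcols <- grep("^rep_", names(df))
  frequency_table(condition,
                  df[, c("chain_a", "resno_a", "chain_b", "resno_b")],
                  as.matrix(df[, repcols, drop = FALSE]), n_frames)
}

#' Write differential edges as TSV
#'
#' @param edges A `differential_edges` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_differential_edges <- function(edges, path) {
  utils::write.table(as.data.frame(edges), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
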