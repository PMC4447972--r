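# Independent brute-force oracles and fixture builders used across tests.
# These deliberately re-derive results by a different route than the
# package implementation (per-pair scans vs global matrix thresholding).

# Random protein-like frame: residues with backbone atom names (plus CB/OG
# for some types) scattered in a box, no hydrogens.
random_frame <- function(n_residues, seed, box_side = 25) {
  set.seed(seed)
  types <- sample(c("GLY", "ALA", "SER"), n_residues, replace = TRUE)
  rows <- list(); coords <- list()
  for (i in seq_len(n_residues)) {
    names_i <- switch(types[i],
      GLY = c("N", "CA", "C", "O"),
      ALA = c("N", "CA", "C", "O", "CB"),
      SER = c("N", "CA", "C", "O", "CB", "OG"))
    center <- runif(3, 0, box_side)
    for (nm in names_i) {
      rows[[length(rows) + 1L]] <- data.frame(
        elety = nm, resid = types[i], chain = "A", resno = i,
        element = substr(nm, 1, 1), type = "ATOM", stringsAsFactors = FALSE)
      coords[[length(coords) + 1L]] <- center + rnorm(3, sd = 1.0)
    }
  }
  structure_frame(do.call(rbind, rows), do.call(rbind, coords))
}

# Brute-force interaction oracle: per residue pair, scan all atom pairs.
# Contact channel: any heavy-atom distance < r_i + r_j + margin, excluding
# same-chain pairs within `seq_excl` residues. Polar channel (heavy-only,
# hydrogens absent): any donor-acceptor distance <= heavy_da, donors =
# backbone N (non-PRO) + SER OG, acceptors = backbone O/OXT + SER OG; no
# sequence exclusion.
brute_force_interactions <- function(frame, margin = 0.6, seq_excl = 4,
                                     heavy_da = 3.5) {
  radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)
  at <- frame$atoms
  res <- unique(at$resno)
  found <- character(0)
  for (ii in seq_along(res)) {
    for (jj in seq_along(res)) {
      if (jj <= ii) next
      a <- res[ii]; b <- res[jj]
      sa <- which(at$resno == a & at$is_heavy)
      sb <- which(at$resno == b & at$is_heavy)
      hit <- FALSE
      if (abs(a - b) > seq_excl) {
        for (u in sa) {
          for (v in sb) {
            d <- sqrt(sum((frame$xyz[u, ] - frame$xyz[v, ])^2))
            if (d < radii[at$element[u]] + radii[at$element[v]] + margin) {
              hit <- TRUE; break
            }
          }
          if (hit) break
        }
      }
      if (!hit) {
        is_donor <- function(k) (at$elety[k] == "N" && at$resid[k] != "PRO") ||
          (at$resid[k] == "SER" && at$elety[k] == "OG")
        is_acc <- function(k) at$elety[k] %in% c("O", "OXT") ||
          (at$resid[k] == "SER" && at$elety[k] == "OG")
        for (u in sa) {
          for (v in sb) {
            du <- is_donor(u) && is_acc(v)
            dv <- is_donor(v) && is_acc(u)
            if (!du && !dv) next
            d <- sqrt(sum((frame$xyz[u, ] - frame$xyz[v, ])^2))
            if (d <= heavy_da) { hit <- TRUE; break }
          }
          if (hit) break
        }
      }
      if (hit) found <- c(found, sprintf("A:%d--A:%d", a, b))
    }
  }
  sort(found)
}

# Expected-value helper: differential-edge data frame row builder for
# network tests.
fake_edge <- function(res_a, res_b, delta, freq_b = 0.4) {
  data.frame(chain_a = "A", resno_a = res_a, chain_b = "A", resno_b = res_b,
             pair = sprintf("A:%d--A:%d", res_a, res_b),
             freq_a = freq_b + delta, freq_b = freq_b, delta = delta,
             p_value = 1e-3, q_value = 4e-3,
             direction = ifelse(delta >= 0, "higher_in_a", "higher_in_b"),
             stringsAsFactors = FALSE)
}

fake_edges <- function(...) {
  out <- do.call(rbind, list(...))
  class(out) <- c("differential_edges", "data.frame")
  out
}

# Minimal hand-written PDB text (fixture builder independent of the
# package's writer).
pdb_line <- function(serial, name, resn, chain, resno, x, y, z, elem,
                     record = "ATOM") {
  sprintf("%-6s%5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          record, serial, name, resn, chain, resno, x, y, z, elem)
}

write_poly_ala_pdb <- function(n_residues, path) {
  lines <- character(0)
  serial <- 0L
  for (i in seq_len(n_residues)) {
    base <- c(3.5 * i, 0, 0)
    offs <- list(N = c(0, 0, 0), CA = c(1.2, 0.5, 0), C = c(2.4, 0, 0),
                 O = c(2.4, -1.2, 0), CB = c(1.2, 1.2, 1.2))
    for (nm in names(offs)) {
      serial <- serial + 1L
      p <- base + offs[[nm]]
      lines <- c(lines, pdb_line(serial, nm, "ALA", "A", i,
                                 p[1], p[2], p[3], substr(nm, 1, 1)))
    }
  }
  writeLines(c(lines, "END"), path)
  path
}
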