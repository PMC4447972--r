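# Subsegment schemes: named residue ranges partitioning a sequence into
# extracellular/middle/intracellular helix thirds, loops and termini.

SCHEME_REGIONS <- c("e", "m", "i", "loop", "terminus")

#' Construct a subsegment scheme
#'
#' @param entries Data frame with columns `name`, `first`, `last`, `region`
#'   (`region` one of e, m, i, loop, terminus; inferred from the name when
#'   absent: trailing e/m/i on TM segments, EL/IL prefixes as loops, NT/CT
#'   as termini).
#' @return Object of class `subsegment_scheme`.
#' @export
subsegment_scheme <- function(entries) {
  stopifnot(is.data.frame(entries), all(c("name", "first", "last") %in% names(entries)))
  if (is.null(entries$region)) {
    entries$region <- vapply(entries$name, infer_region, "")
  }
  if (anyDuplicated(entries$name)) {
    mdain_abort("subsegment names must be unique", "mdain_scheme_error")
  }
  if (!all(entries$region %in% SCHEME_REGIONS)) {
    mdain_abort("unknown region label", "mdain_scheme_error")
  }
  structure(list(entries = entries), class = "subsegment_scheme")
}

infer_region <- function(name) {
  if (grepl("^(EL|IL)", name)) return("loop")
  if (grepl("^(NT|CT)", name)) return("terminus")
  if (grepl("e$", name)) return("e")
  if (grepl("m$", name)) return("m")
  if (grepl("i$", name)) return("i")
  "loop"
}

#' @export
print.subsegment_scheme <- function(x, ...) {
  e <- x$entries
  cat(sprintf("<subsegment_scheme> %d subsegments covering residues %d-%d\n",
              nrow(e), min(e$first), max(e$last)))
  invisible(x)
}

#' Read a subsegment scheme from a TSV file
#'
#' Columns: `name`, `first`, `last`, optionally `region`.
#'
#' @param path TSV file.
#' @return A [subsegment_scheme()].
#' @export
read_scheme <- function(path) {
  subsegment_scheme(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' The default LeuT subsegment scheme
#'
#' The 44 named subsegments of the bacterial transporter LeuT: each TM helix
#' parsed into extracellular (e), middle (m) and intracellular (i) sections,
#' plus extracellular/intracellular loops and the N terminus, jointly
#' covering residues 1-515.
#'
#' @return A [subsegment_scheme()] with 44 entries.
#' @export
leut_default_scheme <- function() {
  read_scheme(system.file("extdata", "leut_subsegments.tsv", package = "mdain"))
}

#' Validate a subsegment scheme against a sequence length
#'
#' Reports gaps, overlaps and out-of-range entries; an empty report means
#' the scheme partitions `1:n_residues` exactly.
#'
#' @param scheme A [subsegment_scheme()].
#' @param n_residues Number of residues the scheme should cover.
#' @return Data frame with columns `kind` (gap/overlap/out_of_range) and
#'   `detail`; zero rows when valid.
#' @export
validate_scheme <- function(scheme, n_residues) {
  e <- scheme$entries
  report <- list()
  covered <- integer(0)
  for (i in seq_len(nrow(e))) {
    rng <- e$first[i]:e$last[i]
    dup <- intersect(rng, covered)
    if (length(dup)) {
      report[[length(report) + 1L]] <- data.frame(
        kind = "overlap",
        detail = sprintf("%s overlaps at residue(s) %s", e$name[i],
                         paste(dup, collapse = ",")))
    }
    out <- rng[rng < 1 | rng > n_residues]
    if (length(out)) {
      report[[length(report) + 1L]] <- data.frame(
        kind = "out_of_range",
        detail = sprintf("%s extends outside 1-%d", e$name[i], n_residues))
    }
    covered <- union(covered, rng)
  }
  missing <- setdiff(seq_len(n_residues), covered)
  if (length(missing)) {
    report[[length(report) + 1L]] <- data.frame(
      kind = "gap",
      detail = sprintf("residues not covered: %s", paste(missing, collapse = ",")))
  }
  if (length(report) == 0L) {
    return(data.frame(kind = character(0), detail = character(0)))
  }
  do.call(rbind, report)
}

#' Map residue numbers to subsegment names
#'
#' @param scheme A [subsegment_scheme()].
#' @param resno Integer vector of residue numbers.
#' @return Character vector of subsegment names (`NA` when uncovered).
#' @export
scheme_lookup <- function(scheme, resno) {
  e <- scheme$entries
  vapply(resno, function(r) {
    hit <- which(e$first <= r & e$last >= r)
    if (length(hit) == 0L) NA_character_ else e$name[hit[1]]
  }, "")
}
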