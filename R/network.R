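# Coarse-grained subsegment networks: project significant residue-pair
# differences onto subsegment pairs and build signed 2-D difference graphs;
# intersect graphs across perturbations to expose shared pathways.

#' Coarse-grain differential residue pairs onto a subsegment scheme
#'
#' One graph edge is drawn per subsegment pair containing at least one
#' significantly different residue pair. The edge sign is `increased` when
#' every member pair is more frequent in the investigated condition than in
#' the reference, `decreased` when every member is less frequent, and
#' `mixed` when both types occur. Pairs with both residues in one
#' subsegment become flagged self-edges.
#'
#' @param edges A `differential_edges` data frame (from
#'   [differential_pairs()]), with `freq_a` from the investigated and
#'   `freq_b` from the reference condition.
#' @param scheme A [subsegment_scheme()].
#' @param investigated,reference Condition labels (metadata).
#' @return Object of class `subsegment_graph`.
#' @export
coarse_grain <- function(edges, scheme, investigated = "a", reference = "b") {
  e <- scheme$entries
  vertices <- data.frame(name = e$name, region = e$region,
                         stringsAsFactors = FALSE)
  # presentational band layout: e on top, m centre, i bottom
  band <- c(e = 2, m = 1, i = 0, loop = 1.5, terminus = -0.5)
  vertices$x <- seq_len(nrow(vertices))
  vertices$y <- unname(band[vertices$region])
  g <- structure(list(vertices = vertices,
                      edges = data.frame(u = character(0), v = character(0),
                                         sign = character(0),
                                         self = logical(0),
                                         stringsAsFactors = FALSE),
                      member_pairs = list(),
                      investigated = investigated, reference = reference,
                      scheme = scheme),
                 class = "subsegment_graph")
  if (nrow(edges) == 0L) return(g)
  sa <- scheme_lookup(scheme, edges$resno_a)
  sb <- scheme_lookup(scheme, edges$resno_b)
  if (anyNA(sa) || anyNA(sb)) {
    bad <- unique(c(edges$resno_a[is.na(sa)], edges$resno_b[is.na(sb)]))
    mdain_abort(paste("residue(s) outside scheme coverage:",
                      paste(bad, collapse = ", ")), "mdain_scheme_error")
  }
  ord <- match(sa, g$vertices$name) > match(sb, g$vertices$name)
  u <- ifelse(ord, sb, sa)
  v <- ifelse(ord, sa, sb)
  key <- paste(u, v, sep = "|")
  grp <- split(seq_len(nrow(edges)), key)
  out <- lapply(names(grp), function(k) {
    rows <- grp[[k]]
    dirs <- edges$delta[rows] > 0
    sign <- if (all(dirs)) "increased" else if (all(!dirs)) "decreased" else "mixed"
    uv <- strsplit(k, "|", fixed = TRUE)[[1]]
    list(edge = data.frame(u = uv[1], v = uv[2], sign = sign,
                           self = uv[1] == uv[2], stringsAsFactors = FALSE),
         members = edges[rows, , drop = FALSE])
  })
  g$edges <- do.call(rbind, lapply(out, `[[`, "edge"))
  g$member_pairs <- lapply(out, `[[`, "members")
  ord2 <- order(g$edges$u, g$edges$v)
  g$edges <- g$edges[ord2, , drop = FALSE]
  rownames(g$edges) <- NULL
  g$member_pairs <- g$member_pairs[ord2]
  g
}

#' @export
print.subsegment_graph <- function(x, ...) {
  cat(sprintf("<subsegment_graph> %s vs %s: %d vertices, %d edges\n",
              x$investigated, x$reference, nrow(x$vertices), nrow(x$edges)))
  invisible(x)
}

edge_keys <- function(g) paste(g$edges$u, g$edges$v, sep = "|")

#' Intersect two subsegment difference graphs
#'
#' Keeps the subsegment pairs significantly different (in either direction)
#' in both inputs — the shared response to two distinct perturbations.
#' Member pairs are concatenated and tagged by source condition.
#'
#' @param g1,g2 [coarse_grain()] graphs over the same scheme.
#' @return A `subsegment_graph` whose edge set is the intersection.
#' @export
graph_intersection <- function(g1, g2) {
  if (!identical(g1$scheme$entries, g2$scheme$entries)) {
    mdain_abort("graphs use different subsegment schemes", "mdain_scheme_error")
  }
  k1 <- edge_keys(g1); k2 <- edge_keys(g2)
  common <- intersect(k1, k2)
  g <- g1
  g$investigated <- paste(g1$investigated, g2$investigated, sep = " & ")
  g$reference <- g1$reference
  sel1 <- match(common, k1); sel2 <- match(common, k2)
  g$edges <- g1$edges[sel1, , drop = FALSE]
  # direction-agnostic intersection: keep both signs in metadata
  g$edges$sign <- ifelse(g1$edges$sign[sel1] == g2$edges$sign[sel2],
                         g1$edges$sign[sel1], "mixed")
  g$member_pairs <- lapply(seq_along(common), function(i) {
    m1 <- g1$member_pairs[[sel1[i]]]
    m2 <- g2$member_pairs[[sel2[i]]]
    m1$source <- g1$investigated
    m2$source <- g2$investigated
    rbind(m1, m2)
  })
  rownames(g$edges) <- NULL
  g
}

as_igraph <- function(graph) {
  ed <- graph$edges[, c("u", "v", "sign", "self")]
  ed$self <- as.integer(ed$self)  # DOT has no boolean attributes
  igraph::graph_from_data_frame(ed, directed = FALSE,
                                vertices = graph$vertices)
}

#' Export a subsegment graph
#'
#' JSON round-trips losslessly through [read_graph_json()]; GraphML and DOT
#' (via igraph) carry `sign` as an edge attribute and `region` as a vertex
#' attribute.
#'
#' @param graph A `subsegment_graph`.
#' @param path Output path.
#' @param format `"json"`, `"graphml"` or `"dot"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(graph, path, format = c("json", "graphml", "dot")) {
  format <- match.arg(format)
  if (format == "json") {
    payload <- list(
      investigated = graph$investigated, reference = graph$reference,
      vertices = graph$vertices, edges = graph$edges,
      member_pairs = stats::setNames(
        lapply(graph$member_pairs, as.data.frame),
        paste0("e", seq_along(graph$member_pairs))),
      scheme = graph$scheme$entries)
    jsonlite::write_json(payload, path, dataframe = "columns", digits = NA,
                         auto_unbox = TRUE)
  } else {
    igraph::write_graph(as_igraph(graph), path, format = format)
  }
  invisible(path)
}

#' Re-import a JSON-exported subsegment graph
#'
#' @param path JSON file written by [export_graph()].
#' @return A `subsegment_graph` equal to the exported one.
#' @export
read_graph_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  g <- structure(list(
    vertices = as.data.frame(p$vertices, stringsAsFactors = FALSE),
    edges = as.data.frame(p$edges, stringsAsFactors = FALSE),
    member_pairs = unname(lapply(p$member_pairs, function(m)
      as.data.frame(m, stringsAsFactors = FALSE))),
    investigated = p$investigated, reference = p$reference,
    scheme = subsegment_scheme(as.data.frame(p$scheme,
                                             stringsAsFactors = FALSE))),
    class = "subsegment_graph")
  if (nrow(g$edges) == 0L) {
    g$edges <- data.frame(u = character(0), v = character(0),
                          sign = character(0), self = logical(0),
                          stringsAsFactors = FALSE)
  }
  g
}

#' All shortest pathways between two subsegments
#'
#' Unweighted hop-count shortest paths in the difference network, returned
#' in deterministic lexicographic order.
#'
#' @param graph A `subsegment_graph`.
#' @param source,target Subsegment names.
#' @return List of character vectors (vertex name sequences); empty when
#'   disconnected.
#' @export
pathway_extract <- function(graph, source, target) {
  if (!source %in% graph$vertices$name || !target %in% graph$vertices$name) {
    mdain_abort("source/target not in graph", "mdain_value_error")
  }
  if (source == target) return(list(source))
  ig <- as_igraph(graph)
  res <- suppressWarnings(
    igraph::all_shortest_paths(ig, from = source, to = target))
  paths <- lapply(res$vpaths, function(p) igraph::V(ig)$name[as.integer(p)])
  if (length(paths) == 0L) return(list())
  paths[order(vapply(paths, paste, "", collapse = " "))]
}

#' Recover the member differential pairs of a graph
#'
#' Expanding every edge's members gives back exactly the differential edge
#' multiset the graph was coarse-grained from.
#'
#' @param graph A `subsegment_graph`.
#' @return A `differential_edges`-shaped data frame.
#' @export
expand_member_pairs <- function(graph) {
  if (length(graph$member_pairs) == 0L) return(empty_edges())
  out <- do.call(rbind, graph$member_pairs)
  rownames(out) <- NULL
  out
}
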