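# Subsegment difference graphs: coarse-graining, intersection, export,
# pathway extraction.

test_that("coarse-graining maps residue pairs to signed subsegment edges", {
  sch <- leut_default_scheme()
  g <- coarse_grain(fake_edges(fake_edge(27, 254, 0.6)), sch,
                    investigated = "Y268A.Na.ns", reference = "WT.Na.ns")
  expect_equal(g$edges$u, "TM1m")
  expect_equal(g$edges$v, "TM6m")
  expect_equal(g$edges$sign, "increased")
  expect_false(g$edges$self)
  # two member pairs with opposite directions -> mixed
  g2 <- coarse_grain(fake_edges(fake_edge(27, 254, 0.6),
                                fake_edge(25, 255, -0.5)), sch)
  expect_equal(g2$edges$sign, "mixed")
  expect_equal(nrow(g2$member_pairs[[1]]), 2)
  # both residues in one subsegment -> flagged self-edge
  g3 <- coarse_grain(fake_edges(fake_edge(250, 261, 0.4)), sch)
  expect_true(g3$edges$self)
  # empty edge list -> vertices only
  g4 <- coarse_grain(fake_edges(fake_edge(27, 254, 0.6))[0, ], sch)
  expect_equal(nrow(g4$edges), 0)
  expect_equal(nrow(g4$vertices), 44)
})

test_that("residues outside the scheme are an error", {
  sch <- leut_default_scheme()
  expect_error(coarse_grain(fake_edges(fake_edge(27, 999, 0.5)), sch),
               class = "mdain_scheme_error")
})

test_that("expanding member pairs recovers the input multiset exactly", {
  sch <- leut_default_scheme()
  edges <- fake_edges(fake_edge(27, 254, 0.6), fake_edge(25, 255, -0.5),
                      fake_edge(268, 361, -0.4), fake_edge(259, 362, -0.7),
                      fake_edge(250, 261, 0.4))
  g <- coarse_grain(edges, sch)
  back <- expand_member_pairs(g)
  expect_setequal(back$pair, edges$pair)
  expect_equal(nrow(back), nrow(edges))
  expect_equal(sum(vapply(g$member_pairs, nrow, 0L)), nrow(edges))
})

test_that("sign flips when investigated and reference are swapped", {
  sch <- leut_default_scheme()
  edges <- fake_edges(fake_edge(27, 254, 0.6), fake_edge(268, 361, -0.4),
                      fake_edge(26, 255, 0.2), fake_edge(25, 256, -0.2))
  flip <- edges
  flip$delta <- -flip$delta
  tmp <- flip$freq_a; flip$freq_a <- flip$freq_b; flip$freq_b <- tmp
  g <- coarse_grain(edges, sch)
  gf <- coarse_grain(flip, sch)
  swap <- c(increased = "decreased", decreased = "increased", mixed = "mixed")
  expect_equal(unname(swap[g$edges$sign]), gf$edges$sign)
})

test_that("graph intersection is commutative, associative, idempotent", {
  sch <- leut_default_scheme()
  g1 <- coarse_grain(fake_edges(fake_edge(27, 254, 0.6),
                                fake_edge(268, 361, -0.4)), sch, "p1", "ref")
  g2 <- coarse_grain(fake_edges(fake_edge(268, 361, 0.5),
                                fake_edge(100, 410, 0.4)), sch, "p2", "ref")
  g3 <- coarse_grain(fake_edges(fake_edge(268, 361, -0.2)), sch, "p3", "ref")
  k <- function(g) sort(paste(g$edges$u, g$edges$v))
  expect_equal(k(graph_intersection(g1, g2)), k(graph_intersection(g2, g1)))
  expect_equal(k(graph_intersection(graph_intersection(g1, g2), g3)),
               k(graph_intersection(g1, graph_intersection(g2, g3))))
  expect_equal(k(graph_intersection(g1, g1)), k(g1))
  # intersection ignores sign but records the members of both sources
  gi <- graph_intersection(g1, g2)
  expect_equal(paste(gi$edges$u, gi$edges$v), "TM6i TM8i")
  expect_setequal(unique(gi$member_pairs[[1]]$source), c("p1", "p2"))
  # disjoint graphs -> vertices only
  g4 <- coarse_grain(fake_edges(fake_edge(5, 100, 0.3)), sch, "p4", "ref")
  expect_equal(nrow(graph_intersection(g1, g4)$edges), 0)
})

test_that("JSON export round-trips; DOT and GraphML are well-formed", {
  sch <- leut_default_scheme()
  g <- coarse_grain(fake_edges(fake_edge(27, 254, 0.6),
                               fake_edge(268, 361, -0.4),
                               fake_edge(100, 410, 0.4)), sch, "p", "ref")
  tdir <- withr::local_tempdir()
  jpath <- file.path(tdir, "g.json")
  export_graph(g, jpath, "json")
  re <- read_graph_json(jpath)
  expect_equal(re$edges, g$edges)
  expect_equal(re$vertices, g$vertices)
  expect_equal(lapply(re$member_pairs, function(m) m$pair),
               lapply(g$member_pairs, function(m) m$pair))
  dpath <- file.path(tdir, "g.dot")
  export_graph(g, dpath, "dot")
  expect_equal(sum(grepl("--", readLines(dpath))), 3)
  gpath <- file.path(tdir, "g.graphml")
  export_graph(g, gpath, "graphml")
  doc <- xml2::read_xml(gpath)   # parses as XML with graphml root
  expect_equal(xml2::xml_name(doc), "graphml")
  expect_error(export_graph(g, file.path(tdir, "g.x"), "xlsx"))
})

test_that("pathway extraction returns ordered shortest paths", {
  sch <- leut_default_scheme()
  # chain: TM6i - TM8i - TM6m - TM1m
  g <- coarse_grain(fake_edges(fake_edge(265, 361, 0.5),
                               fake_edge(361, 255, 0.5),
                               fake_edge(255, 25, 0.5)), sch)
  expect_equal(pathway_extract(g, "TM6i", "TM1m"),
               list(c("TM6i", "TM8i", "TM6m", "TM1m")))
  expect_equal(pathway_extract(g, "TM6i", "TM6i"), list("TM6i"))
  expect_equal(pathway_extract(g, "TM6i", "TM12i"), list())
  expect_error(pathway_extract(g, "TM6i", "nope"), class = "mdain_value_error")
})
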