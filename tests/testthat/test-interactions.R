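# Frequency tables over ensembles and the min-max range filter.

test_that("frequency equals the fraction of masked-in frames with the pair", {
  pp <- list(c1 = data.frame(res_a = 1, res_b = 6, p = 1))
  model <- planted_interaction_model(6, pp, n_frames = 40, n_replicas = 1,
                                     seed = 2)
  ens <- make_interaction_trajectory(model)$ensembles$c1
  tab <- ensemble_frequencies(ens)
  expect_equal(tab$pairs$frequency[tab$pairs$pair == "A:1--A:6"], 1)
  # masking to a subrange recomputes over masked-in frames only
  ens2 <- set_equilibration_mask(ens, "explicit", ranges = list(list(c(21, 40))))
  tab2 <- ensemble_frequencies(ens2)
  expect_equal(tab2$n_frames, 20L)
  expect_equal(tab2$pairs$frequency, 1)
})

test_that("planted probabilities are recovered within binomial error", {
  pp <- list(c1 = data.frame(res_a = 1, res_b = 7, p = 0.7))
  model <- planted_interaction_model(7, pp, n_frames = 2000, n_replicas = 1,
                                     seed = 9)
  ens <- make_interaction_trajectory(model)$ensembles$c1
  tab <- ensemble_frequencies(ens)
  f <- tab$pairs$frequency[tab$pairs$pair == "A:1--A:7"]
  se <- sqrt(0.7 * 0.3 / 2000)
  expect_lt(abs(f - 0.7), 3 * se)
  # never-interacting pairs are absent (implicit zero)
  expect_false("A:2--A:6" %in% tab$pairs$pair)
})

test_that("frequencies are invariant to replica and frame ordering", {
  pp <- list(c1 = data.frame(res_a = 1, res_b = 6, p = 0.5))
  model <- planted_interaction_model(6, pp, n_frames = 60, n_replicas = 2,
                                     seed = 4)
  ens <- make_interaction_trajectory(model)$ensembles$c1
  tab <- ensemble_frequencies(ens)
  # swap replicas
  ens_swap <- ens
  ens_swap$replicas <- rev(ens$replicas)
  ens_swap$equilibrated_mask <- rev(ens$equilibrated_mask)
  tab_swap <- ensemble_frequencies(ens_swap)
  expect_equal(tab_swap$pairs$frequency, tab$pairs$frequency)
  # permute frames within a replica
  perm <- sample(60)
  ens_perm <- ens
  ens_perm$replicas[[1]]$xyz <- ens$replicas[[1]]$xyz[, , perm]
  tab_perm <- ensemble_frequencies(ens_perm)
  expect_equal(tab_perm$pairs$frequency, tab$pairs$frequency)
})

test_that("overall frequency is the frame-weighted mean of replica values", {
  pairs <- data.frame(chain_a = "A", resno_a = 1L, chain_b = "A", resno_b = 9L)
  tab <- frequency_table("x", pairs, per_replica = cbind(0.2, 0.8),
                         n_frames = c(300, 100))
  expect_equal(tab$pairs$frequency, 0.2 * 0.75 + 0.8 * 0.25)
})

test_that("frequency tables round-trip through their TSV form", {
  pairs <- data.frame(chain_a = "A", resno_a = c(1L, 3L),
                      chain_b = "A", resno_b = c(9L, 12L))
  tab <- frequency_table("cond.x", pairs,
                         per_replica = rbind(c(0.25, 0.5), c(0.1, 0.9)),
                         n_frames = c(200, 100))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_frequency_table(tab, path)
  re <- read_frequency_table(path)
  expect_equal(re$condition, "cond.x")
  expect_equal(re$per_replica, tab$per_replica, ignore_attr = TRUE)
  expect_equal(re$n_frames, tab$n_frames)
  expect_equal(re$pairs$frequency, tab$pairs$frequency)
})

test_that("the min-max range filter keeps pairs spanning the threshold", {
  mk_tab <- function(cond, f1, f2) {
    frequency_table(cond,
                    data.frame(chain_a = "A", resno_a = c(1L, 2L),
                               chain_b = "A", resno_b = c(9L, 10L)),
                    per_replica = cbind(c(f1, f2)), n_frames = 100)
  }
  tabs <- list(mk_tab("a", 0.2, 0.5), mk_tab("b", 0.6, 0.7))
  out <- minmax_range_filter(tabs, threshold = 0.3)
  expect_equal(out$pair, "A:1--A:9")          # range 0.4 kept, 0.2 dropped
  expect_equal(out$range, 0.4)
  # boundary: exactly 0.3 is kept (inclusive threshold)
  tabs2 <- list(mk_tab("a", 0.2, 0), mk_tab("b", 0.5, 0))
  expect_equal(minmax_range_filter(tabs2, 0.3)$pair[1], "A:1--A:9")
})

test_that("the range filter agrees with a direct max-min oracle on planted sets", {
  set.seed(31)
  n_pairs <- 10
  pairs <- data.frame(chain_a = "A", resno_a = seq_len(n_pairs) * 2L - 1L,
                      chain_b = "A", resno_b = seq_len(n_pairs) * 2L + 30L)
  freqs <- matrix(runif(n_pairs * 4), n_pairs, 4)
  tabs <- lapply(1:4, function(j)
    frequency_table(paste0("c", j), pairs, cbind(freqs[, j]), n_frames = 50))
  out <- minmax_range_filter(tabs, threshold = 0.3)
  oracle <- apply(freqs, 1, max) - apply(freqs, 1, min)
  expect_setequal(out$pair, pair_keys(pairs)[oracle >= 0.3])
})

test_that("anchor restriction keeps only pairs touching the proximal set", {
  pairs <- data.frame(chain_a = "A", resno_a = c(1L, 2L),
                      chain_b = "A", resno_b = c(9L, 10L))
  tabs <- list(frequency_table("a", pairs, cbind(c(0.1, 0.1)), 100),
               frequency_table("b", pairs, cbind(c(0.9, 0.9)), 100))
  out <- minmax_range_filter(tabs, 0.3, restrict_to = c("A:9"))
  expect_equal(out$pair, "A:1--A:9")
})

test_that("residues_near finds anchor-proximal residues in any frame", {
  pp <- list(c1 = data.frame(res_a = 1, res_b = 6, p = 0.5))
  model <- planted_interaction_model(6, pp, n_frames = 30, n_replicas = 1,
                                     seed = 12)
  ens <- make_interaction_trajectory(model)$ensembles$c1
  near <- residues_near(ens, 1, distance = 5)
  expect_true(all(c("A:1", "A:6") %in% near))   # residue 6 visits residue 1
  expect_false("A:3" %in% near)
})
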