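# Umbrella windows and the WHAM solver.

test_that("window grids tile the interval inclusively", {
  expect_length(make_windows(-1.5, 25.0, 0.25, 10), 107)
  w <- make_windows(0, 1, 0.5, 5)
  expect_equal(vapply(w, `[[`, 0, "center"), c(0, 0.5, 1))
  expect_error(make_windows(0, 1, 0.3, 5), class = "mdain_value_error")
})

test_that("equilibration discarding trims the leading samples", {
  w <- umbrella_window(0, 10, samples = rnorm(2000))
  # 2.0 ns at 1 ps per sample, cut 500 ps -> 1500 samples remain
  trimmed <- discard_equilibration(w, 500, 1)
  expect_length(trimmed$samples, 1500)
  expect_equal(trimmed$samples, w$samples[501:2000])
  expect_equal(discard_equilibration(w, 0, 1)$samples, w$samples)
  expect_error(discard_equilibration(w, 2500, 1), class = "mdain_value_error")
})

test_that("an unbiased uniform window yields a flat profile", {
  set.seed(4)
  w <- umbrella_window(0.5, 0, samples = runif(1e4))
  prof <- wham_solve(list(w), wham_config(bin_width = 0.05),
                     grid_range = c(0.025, 0.975))
  fe <- prof$free_energy[is.finite(prof$free_energy)]
  expect_lt(sqrt(mean((fe - mean(fe))^2)), 0.1)
})

test_that("a single unbiased window reduces WHAM to -kT log(histogram)", {
  set.seed(6)
  w <- umbrella_window(0, 0, samples = rnorm(5e3))
  cfg <- wham_config(bin_width = 0.1)
  prof <- wham_solve(list(w), cfg, grid_range = c(-2, 2), align = "none")
  kt <- 0.0019872041 * cfg$temperature
  breaks <- seq(-2.05, 2.05, by = 0.1)
  counts <- hist(w$samples[w$samples >= -2.05 & w$samples <= 2.05],
                 breaks = breaks, plot = FALSE)$counts
  direct <- ifelse(counts > 0, -kt * log(counts), NA)
  sel <- is.finite(prof$free_energy) & is.finite(direct)
  diffs <- prof$free_energy[sel] - direct[sel]
  expect_lt(max(diffs) - min(diffs), 1e-6)   # equal up to a constant
})

test_that("WHAM recovers a quadratic potential from exact biased samples", {
  wins <- make_windows(-2, 2, 0.2, 10)
  wins <- make_umbrella_samples(quadratic_potential(2), wins, 310, 5000,
                                seed = 42)
  prof <- wham_solve(wins, wham_config(), grid_range = c(-2, 2))
  sel <- prof$grid >= -1.5 & prof$grid <= 1.5 & is.finite(prof$free_energy)
  ana <- 2 * prof$grid[sel]^2
  fe <- prof$free_energy[sel]
  rms <- sqrt(mean(((fe - mean(fe)) - (ana - mean(ana)))^2))
  expect_lt(rms, 0.15)
  expect_true(prof$converged)
})

test_that("WHAM is invariant to window order and to splitting a window", {
  wins <- make_windows(-1, 1, 0.25, 10)
  wins <- make_umbrella_samples(quadratic_potential(1), wins, 310, 2000,
                                seed = 5)
  cfg <- wham_config()
  ref <- wham_solve(wins, cfg, grid_range = c(-1, 1))
  shuf <- wham_solve(rev(wins), cfg, grid_range = c(-1, 1))
  expect_equal(shuf$free_energy, ref$free_energy, tolerance = 1e-5)
  # split the middle window's samples into two half-windows at one centre
  mid <- which(vapply(wins, `[[`, 0, "center") == 0)
  s <- wins[[mid]]$samples
  split_wins <- c(wins[-mid],
                  list(umbrella_window(0, 10, s[1:1000]),
                       umbrella_window(0, 10, s[1001:2000])))
  split_prof <- wham_solve(split_wins, cfg, grid_range = c(-1, 1))
  expect_equal(split_prof$free_energy, ref$free_energy, tolerance = 1e-5)
})

test_that("shifting all window centres translates the profile grid", {
  wins <- make_windows(-1, 1, 0.25, 10)
  wins <- make_umbrella_samples(quadratic_potential(1), wins, 310, 1000,
                                seed = 13)
  cfg <- wham_config()
  ref <- wham_solve(wins, cfg, grid_range = c(-1, 1))
  shifted <- lapply(wins, function(w) {
    w$center <- w$center + 5; w$samples <- w$samples + 5; w
  })
  prof <- wham_solve(shifted, cfg, grid_range = c(4, 6))
  expect_equal(prof$grid, ref$grid + 5)
  sel <- is.finite(ref$free_energy) & is.finite(prof$free_energy)
  expect_equal(prof$free_energy[sel], ref$free_energy[sel], tolerance = 1e-6)
})

test_that("block errors vanish on duplicated data and support 3 and 7 blocks", {
  set.seed(2)
  base <- rnorm(600)
  w <- umbrella_window(0, 0, samples = rep(base, 3))  # 3 identical blocks
  prof <- block_errors(list(w), wham_config(bin_width = 0.2), n_blocks = 3,
                       grid_range = c(-2, 2))
  expect_lt(max(prof$errors, na.rm = TRUE), 1e-10)
  wins <- make_windows(-0.5, 0.5, 0.25, 10)
  wins <- make_umbrella_samples(quadratic_potential(1), wins, 310, 700,
                                seed = 3)
  p7 <- block_errors(wins, wham_config(bin_width = 0.1), n_blocks = 7,
                     grid_range = c(-0.5, 0.5))
  expect_equal(p7$n_blocks, 7)
  expect_true(any(is.finite(p7$errors)))
  pboot <- block_errors(wins, wham_config(bin_width = 0.1), n_blocks = 3,
                        method = "bootstrap", n_boot = 10,
                        grid_range = c(-0.5, 0.5))
  expect_true(any(is.finite(pboot$errors)))
  expect_error(block_errors(list(umbrella_window(0, 1, rnorm(2))),
                            n_blocks = 3),
               class = "mdain_value_error")
})

test_that("block errors shrink like 1/sqrt(N)", {
  sizes <- c(500, 5000, 50000)
  med_err <- vapply(sizes, function(n) {
    set.seed(n)
    w <- umbrella_window(0, 0, samples = rnorm(n))
    prof <- block_errors(list(w), wham_config(bin_width = 0.25), n_blocks = 3,
                         grid_range = c(-1.5, 1.5))
    stats::median(prof$errors, na.rm = TRUE)
  }, 0)
  fit <- stats::lm(log(med_err) ~ log(sizes))
  expect_lt(abs(unname(stats::coef(fit)[2]) + 0.5), 0.1)
  expect_true(all(diff(med_err) < 0))
})

test_that("umbrella windows round-trip through the columnar text layout", {
  wins <- make_umbrella_samples(quadratic_potential(2),
                                make_windows(0, 1, 0.5, 10), 310, 50, seed = 1)
  tdir <- withr::local_tempdir()
  meta <- write_umbrella_windows(wins, tdir)
  back <- read_umbrella_dataset(meta)
  expect_length(back, 3)
  expect_equal(vapply(back, `[[`, 0, "center"), c(0, 0.5, 1))
  expect_equal(back[[2]]$samples, wins[[2]]$samples, tolerance = 1e-6)
})

test_that("non-overlapping windows trigger the disconnection diagnostic", {
  w1 <- umbrella_window(0, 50, samples = rnorm(200, 0, 0.05))
  w2 <- umbrella_window(5, 50, samples = rnorm(200, 5, 0.05))
  expect_warning(wham_solve(list(w1, w2), wham_config(bin_width = 0.1),
                            grid_range = c(-0.5, 5.5)),
                 "disconnected")
})
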