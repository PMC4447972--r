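# Geometric observables: water counts, cation state classification,
# chi1 rotamers, conditional occupancy.

water_frame <- function(wxyz, extra_atoms = NULL, extra_xyz = NULL) {
  n <- nrow(wxyz)
  atoms <- data.frame(elety = "O", resid = "HOH", chain = "W",
                      resno = seq_len(n) + 100L, element = "O",
                      type = "HETATM", stringsAsFactors = FALSE)
  if (!is.null(extra_atoms)) {
    atoms <- rbind(extra_atoms, atoms)
    wxyz <- rbind(extra_xyz, wxyz)
  }
  structure_frame(atoms, wxyz)
}

cube_atoms <- function() {
  data.frame(elety = "CA", resid = "GLY", chain = "A", resno = 1:8,
             element = "C", type = "ATOM", stringsAsFactors = FALSE)
}

test_that("cylinder water counting matches planted geometry", {
  set.seed(10)
  inside <- cbind(runif(10, -2, 2), runif(10, -2, 2), runif(10, 1, 9))
  outside <- rbind(cbind(runif(3, 8, 12), 0, 5),       # radially out
                   cbind(0, 0, c(-3, 12)))             # axially out
  fr <- water_frame(rbind(inside, outside))
  spec <- region_spec("cylinder", cylinder_radius = 4, z_bounds = c(0, 10))
  expect_equal(count_region_waters(fr, spec), 10)
  expect_equal(count_region_waters(water_frame(matrix(c(50, 50, 50), 1)),
                                   spec), 0)
})

test_that("hull water counting is closed and ignores water numbering", {
  cube <- as.matrix(expand.grid(c(0, 10), c(0, 10), c(0, 10)))
  wats <- rbind(c(5, 5, 5), c(0, 0, 0), c(10, 5, 5), c(20, 5, 5))
  fr <- water_frame(wats, cube_atoms(), cube)
  spec <- region_spec("convex_hull", lining_residues = 1:8)
  # centre in; vertex and face points count as inside; far point out
  expect_equal(count_region_waters(fr, spec), 3)
  # relabelling water residues changes nothing
  fr2 <- fr
  fr2$atoms$resno[fr2$atoms$resid == "HOH"] <- c(900L, 901L, 902L, 903L)
  expect_equal(count_region_waters(fr2, spec), 3)
})

test_that("degenerate hulls are rejected", {
  flat <- cbind(c(0, 10, 0, 10), c(0, 0, 10, 10), 0)
  atoms4 <- cube_atoms()[1:4, ]
  fr <- water_frame(matrix(c(5, 5, 0), 1), atoms4, flat)
  spec <- region_spec("convex_hull", lining_residues = 1:4)
  expect_error(count_region_waters(fr, spec), class = "mdain_value_error")
})

test_that("cation states partition the distance axis and are monotone", {
  th <- cation_state_thresholds()
  expect_equal(classify_cation_state(7.0, th), "Na1")     # crystal geometry
  expect_equal(classify_cation_state(9.5, th), "transition")
  expect_equal(classify_cation_state(12.5, th), "Na1prime")
  # boundaries: left-closed on the upper side
  expect_equal(classify_cation_state(c(8.3, 10.7), th),
               c("transition", "Na1prime"))
  grid <- seq(0, 30, by = 0.01)
  states <- classify_cation_state(grid, th)
  expect_true(all(states %in% c("Na1", "transition", "Na1prime")))
  # monotone: state index never decreases with distance
  idx <- match(states, c("Na1", "transition", "Na1prime"))
  expect_true(all(diff(idx) >= 0))
  expect_error(classify_cation_state(-1, th), class = "mdain_value_error")
  expect_error(cation_state_thresholds(11, 10), class = "mdain_value_error")
})

ion_traj <- function(distances) {
  atoms <- data.frame(elety = c("NA", "NA"), resid = c("NA", "NA"),
                      chain = "A", resno = c(601L, 602L),
                      element = c("Na", "Na"), type = "HETATM",
                      stringsAsFactors = FALSE)
  xyz <- array(0, c(2, 3, length(distances)))
  xyz[2, 1, ] <- distances
  md_trajectory(atoms, xyz, dt_ps = 240)
}

test_that("site traces classify per frame and segment contiguous runs", {
  d <- c(7, 7, 12.5, 12.5, 7)
  ens <- condition_ensemble("x", list(ion_traj(d)))
  tr <- site_trace(ens, list(resno = 601), list(resno = 602))[[1]]
  expect_equal(tr$distances, d)
  expect_equal(tr$states, c("Na1", "Na1", "Na1prime", "Na1prime", "Na1"))
  expect_equal(nrow(tr$segments), 3)
  expect_equal(tr$segments$state, c("Na1", "Na1prime", "Na1"))
  # constant trace -> one segment
  tr2 <- site_trace(condition_ensemble("x", list(ion_traj(rep(7, 4)))),
                    list(resno = 601), list(resno = 602))[[1]]
  expect_equal(nrow(tr2$segments), 1)
  # ambiguous selector errors
  expect_error(site_trace(ens, list(resid = "NA"), list(resno = 602)),
               class = "mdain_selector_error")
})

test_that("a hidden-state synthetic trace is recovered by classification", {
  set.seed(3)
  states <- sample(c("Na1", "transition", "Na1prime"), 400, replace = TRUE,
                   prob = c(.5, .2, .3))
  d <- make_cation_trace(states, noise_sd = 0.3, seed = 8)
  recovered <- classify_cation_state(d)
  expect_gte(mean(recovered == states), 0.99)
  # noiseless recovery is exact
  expect_equal(classify_cation_state(make_cation_trace(states)), states)
})

test_that("chi1 reproduces constructed dihedrals and the branch convention", {
  for (target in c(-60, 60, 180, -175, 90.5)) {
    fr <- make_toy_structure(4, "extended", chi1 = target)
    got <- chi1_angle(fr, 2)
    diff <- (got - target + 180) %% 360 - 180
    expect_lt(abs(diff), 1e-6)
  }
  # -180 maps to the +180 branch
  fr <- make_toy_structure(4, "extended", chi1 = -180)
  expect_equal(chi1_angle(fr, 2), 180)
  # alanine (no gamma heavy atom) signals undefined
  ala <- make_toy_structure(4, "extended")
  ala$atoms$resid <- "ALA"
  expect_error(chi1_angle(ala, 2), class = "mdain_chi1_undefined")
})

test_that("chi1 is invariant under rigid rotation and translation", {
  fr <- make_toy_structure(5, "helix", chi1 = -60)
  ref <- chi1_angle(fr, 3)
  set.seed(17)
  for (i in 1:20) {
    rot <- random_rotation()
    moved <- fr
    moved$xyz <- fr$xyz %*% t(rot) + matrix(rnorm(3, sd = 10), nrow(fr$xyz),
                                            3, byrow = TRUE)
    expect_equal(chi1_angle(moved, 3), ref, tolerance = 1e-8)
  }
})

test_that("rotamer labels follow the gauche-/gauche+/trans convention", {
  expect_equal(rotamer_label(c(-60, 60, 180, -179.9, 119.9, 120, -120, 0)),
               c("gauche_minus", "gauche_plus", "trans", "trans",
                 "gauche_plus", "trans", "gauche_minus", "gauche_plus"))
  # composition with chi1 recovers the constructed class
  for (chi in c(-60, 60, 180)) {
    fr <- make_toy_structure(4, "extended", chi1 = chi)
    expect_equal(rotamer_label(chi1_angle(fr, 2)),
                 rotamer_label(chi))
  }
})

test_that("conditional occupancy ratios count Na1 vs Na1prime in the top pool", {
  # planted pool: openness ranks put 30 Na1 + 10 Na1prime + 10 transition on top
  states <- c(rep("Na1", 30), rep("Na1prime", 10), rep("transition", 10),
              rep("Na1prime", 200))
  openness <- c(rep(100, 50), rep(1, 200))
  occ <- conditional_occupancy(openness, states, fraction = 0.2)
  expect_equal(occ$ratio, 3)
  expect_equal(occ$n_na1, 30)
  expect_equal(occ$n_na1prime, 10)
  # all-Na1 pool -> infinite with counts
  occ2 <- conditional_occupancy(rep(1, 30), rep("Na1", 30), fraction = 0.5)
  expect_equal(occ2$ratio, Inf)
  expect_equal(occ2$n_na1prime, 0)
})

test_that("independent openness leaves the occupancy ratio at its marginal", {
  set.seed(9)
  n <- 20000
  states <- sample(c("Na1", "Na1prime"), n, replace = TRUE, prob = c(.6, .4))
  openness <- rnorm(n)   # independent of state
  occ <- conditional_occupancy(openness, states, fraction = 0.2)
  marginal <- 0.6 / 0.4
  se <- sqrt(1.5 * marginal^2 * (1 / (0.2 * n * 0.4)))  # rough delta-method CI
  expect_lt(abs(occ$ratio - marginal), 5 * se + 0.2)
})
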