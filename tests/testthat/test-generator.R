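test_that("stem placement on the cone follows the closed-form geometry", {
  set.seed(1)
  expect_equal(place_stems(1, noise_sd = 0), matrix(c(0, 1, 0), 1, 3))

  d4 <- place_stems(4, half_angle = 30, noise_sd = 0)
  expect_true(all(abs(sqrt(rowSums(d4^2)) - 1) < 1e-12))
  # each at 30 degrees from +y
  expect_equal(acos(d4[, 2]) * 180 / pi, rep(30, 4), tolerance = 1e-9)
  # azimuths 90 degrees apart
  az <- sort(atan2(d4[, 3], d4[, 1]) %% (2 * pi))
  expect_equal(diff(az), rep(pi / 2, 3), tolerance = 1e-9)

  expect_error(place_stems(3, half_angle = 95), "half-angle")
  # noisy stems remain unit vectors
  dn <- place_stems(5, half_angle = 40, noise_sd = 15)
  expect_true(all(abs(sqrt(rowSums(dn^2)) - 1) < 1e-12))
})

test_that("thinning reproduces the target per-bin probabilities", {
  set.seed(2)
  expect_equal(thinned_point_process(0, K = 100, delta = 1), integer(100))
  expect_error(thinned_point_process(0.5, K = 10, delta = 3), "too coarse")

  # lambda == lambda_max: no-op thinning, binomial check over 1e5 bins
  K <- 1e5; lam <- 0.04; delta <- 2
  ev <- thinned_point_process(lam, K, delta)
  p <- lam * delta
  expect_lt(abs(mean(ev) - p), 3 * sqrt(p * (1 - p) / K))

  # step rate: each segment within 3 binomial SE, aggregated replicates
  lam_step <- c(rep(0.08, 50), rep(0.01, 50))
  reps <- 1e4 / 100
  hits <- matrix(0L, reps, 100)
  for (r in seq_len(reps)) hits[r, ] <- thinned_point_process(lam_step, 100, 5)
  for (seg in list(1:50, 51:100)) {
    p <- lam_step[seg[1]] * 5
    n <- reps * length(seg)
    expect_lt(abs(mean(hits[, seg]) - p), 3 * sqrt(p * (1 - p) / n))
  }
})

test_that("bifurcation geometry recovers hand-constructed angles", {
  # soma at (10, 0, 5), stem straight up, bifurcation at (10, 40, 5):
  # primary daughter continues +y (noise 0), secondary along +x
  # (amplitude 90). Toward-axis reference at the bifurcation is the unit
  # vector along (-10, 0, -5); rotating +x clockwise (viewed from the
  # parent base along +y) onto it takes 180 + atan(1/2) degrees.
  nodes <- data.frame(
    id = 1:4, type = c(1, 3, 3, 3),
    x = c(10, 10, 10, 20),
    y = c(0, 40, 50, 40),
    z = c(5, 5, 5, 5),
    radius = 1, parent = c(-1, 1, 2, 2))
  tr <- morph_tree(nodes)
  g <- bifurcation_geometry(tr)
  expect_equal(nrow(g), 1L)
  expect_equal(g$amplitude, 90, tolerance = 1e-9)
  expect_equal(g$noise, 0, tolerance = 1e-9)     # primary collinear
  expect_equal(c(g$x, g$z), c(10, 5))
  expect_equal(g$azimuth, 180 + atan(1 / 2) * 180 / pi, tolerance = 1e-9)

  tab <- measure_angle_tables(tr, xz_bin = 20, angle_bin = 10)
  cell <- which(tab$counts > 0, arr.ind = TRUE)
  expect_equal(unname(tab$counts[cell]), 1L)
  expect_gt(tab$x_edges[cell[1] + 1], 10); expect_lte(tab$x_edges[cell[1]], 10)
  expect_equal(sum(tab$amp[cell[1], cell[2], ]), 1)
  expect_error(measure_angle_tables(make_toy_tree("chain")), "no bifurcations")
})

test_that("symmetric daughters tie-break to the first child in order", {
  s <- 1 / sqrt(2)
  nodes <- data.frame(
    id = 1:4, type = c(1, 3, 3, 3),
    x = c(0, 0, -10 * s, 10 * s),
    y = c(0, 10, 10 + 10 * s, 10 + 10 * s),
    z = 0, radius = 1, parent = c(-1, 1, 2, 2))
  g <- bifurcation_geometry(morph_tree(nodes))
  # both daughters 45 degrees from the parent: primary is child id 3
  expect_equal(g$amplitude, 90, tolerance = 1e-9)
  expect_equal(g$noise, 45, tolerance = 1e-9)
})

test_that("growth respects the boundary and produces valid binary trees", {
  set.seed(3)
  cfg <- generation_config(
    rate = fixture_rate(100L), terminal_lengths = c(250, 300),
    stem_counts = c(1L, 2L), cone_half_angles = 30, tapers = -0.002,
    initial_diams = 2, angles = fixed_angle_table(45, 180), delta = 5)
  for (i in 1:10) {
    tr <- grow(cfg)
    expect_silent(validate_tree(tr))
    L <- attr(tr, "boundary")
    tp <- terminal_paths(tr)
    lens <- vapply(tp, `[[`, 1, "total_pathlength")
    expect_true(all(abs(lens - L) <= cfg$delta + 1e-9))
  }

  # rate 0: single unbranched neurite of the boundary length
  cfg0 <- cfg
  cfg0$rate <- 0; cfg0$stem_counts <- 1L
  cfg0$stem_noise_sd <- 0; cfg0$elong_noise_sd <- 0
  tr0 <- grow(cfg0)
  tp0 <- terminal_paths(tr0)
  expect_length(tp0, 1L)
  expect_true(abs(tp0[[1]]$total_pathlength - attr(tr0, "boundary")) <= 5)
  # all-noise-zero growth is a straight vertical neurite
  expect_true(all(abs(tr0$nodes$x) < 1e-9))
  expect_true(all(abs(tr0$nodes$z) < 1e-9))
  expect_true(all(diff(tr0$nodes$y) > 0))
})

test_that("a degenerate angle table pins generated amplitudes to its bin", {
  set.seed(4)
  cfg <- generation_config(
    rate = rate_curve(rep(0.15, 50), delta = 1 / 50),
    terminal_lengths = 300, stem_counts = 2L, cone_half_angles = 30,
    tapers = -0.002, initial_diams = 2,
    angles = fixed_angle_table(65, 170, angle_bin = 10),
    delta = 5, elong_noise_sd = 0, stem_noise_sd = 0)
  amps <- c()
  for (i in 1:8) {
    tr <- grow(cfg)
    br <- tree_branches(tr)$branch
    if (sum(vapply(br$daughters, length, 1L) == 2L) > 0) {
      amps <- c(amps, bifurcation_geometry(register(tr))$amplitude)
    }
  }
  expect_gt(length(amps), 3)
  # all amplitudes within the sampled 10-degree bin (60, 70), allowing
  # half a bin of numerical/registration slack
  expect_true(all(abs(amps - 65) <= 10))
})

test_that("screening reports reasons and matches an independent recount", {
  cfg <- generation_config(
    rate = fixture_rate(), terminal_lengths = 300, stem_counts = 2L,
    angles = fixed_angle_table(45, 180), delta = 5,
    screen = list(bif_min = 5L, bif_max = 1000L, major_min = 0,
                  major_max = Inf, minor_min = 0, minor_max = Inf))
  y <- make_toy_tree("chain")
  s <- screen(y, cfg)
  expect_false(s$pass)
  expect_true("bifurcation_count" %in% s$reasons)

  set.seed(5)
  cfg$screen$bif_min <- 3L; cfg$screen$bif_max <- 12L
  trees <- lapply(1:60, function(i) grow(cfg))
  got <- vapply(trees, function(t) screen(t, cfg)$pass, TRUE)
  # independent recount: tips - stems for a binary tree
  recount <- vapply(trees, function(t) {
    tp <- length(terminal_paths(t))
    stems <- sum(t$nodes$parent == t$nodes$id[t$nodes$parent == -1L][1])
    nb <- tp - stems
    nb >= 3L && nb <= 12L
  }, TRUE)
  expect_equal(got, recount)
})

test_that("xz rescaling hits its targets and is the identity at them", {
  set.seed(6)
  tr <- register(random_fixture_tree(7, n_bifs_min = 3))
  axes <- dendrogen:::tip_axes(tr)
  same <- rescale_xz(tr, axes[1], axes[2])
  expect_trees_equal(tr, same, tol = 1e-9)
  big <- rescale_xz(tr, 2 * axes[1], 2 * axes[2])
  expect_equal(big$nodes$x, 2 * tr$nodes$x, tolerance = 1e-9)
  expect_equal(big$nodes$z, 2 * tr$nodes$z, tolerance = 1e-9)
  expect_equal(big$nodes$y, tr$nodes$y)
  tgt <- rescale_xz(tr, 80, 40)
  expect_equal(dendrogen:::tip_axes(tgt), c(80, 40), tolerance = 1e-6)
})

test_that("population generation is reproducible and tracks its yield", {
  cfg <- generation_config(
    rate = fixture_rate(), terminal_lengths = c(280, 300, 320),
    stem_counts = c(1L, 2L), angles = fixed_angle_table(45, 180), delta = 5)
  p1 <- generate_population(cfg, 3, seed = 11)
  p2 <- generate_population(cfg, 3, seed = 11)
  expect_identical(p1$trees, p2$trees)
  expect_equal(p1$pass_fraction, 1)
  expect_gte(p1$attempts, 3L)

  # impossible screen aborts with diagnostics
  cfg$screen$bif_min <- 500L
  expect_error(generate_population(cfg, 1, seed = 1), "pass rate")
})
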