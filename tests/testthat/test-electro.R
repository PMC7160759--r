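test_that("proximal current fraction reproduces hand-reduced circuits", {
  # midpoint of an unbranched neurite: equal proximal and distal halves
  chain <- make_toy_tree("chain", n = 4, branch_len = 10)
  expect_equal(proximal_current_fraction(chain, 1, 0.5), 0.5)
  # quarter point: R_prox = 1/4, R_distal = 3/4 of the chain
  expect_equal(proximal_current_fraction(chain, 1, 0.25), 0.75)
  # tip has no distal material
  expect_equal(proximal_current_fraction(chain, 1, 1), 1)

  # unbalanced Y at the bifurcation: stem 1 in series against the two
  # daughters in parallel (1 || 1 = 0.5) -> 0.5 / 1.5
  y <- make_toy_tree("Y")
  br <- tree_branches(y)$branch
  stem <- which(br$order == 0L)
  expect_equal(proximal_current_fraction(y, stem, 1), 1 / 3, tolerance = 1e-12)

  # literal resistance-proportion reading, for sensitivity analysis
  expect_equal(proximal_current_fraction(y, stem, 1, mode = "resistance"),
               2 / 3, tolerance = 1e-12)
  expect_error(proximal_current_fraction(y, 99, 0.5), "not on tree")
})

test_that("fraction is invariant to uniform resistance rescaling", {
  # equal branch lengths: per-um resistances are a uniform multiple of
  # the unit-per-branch ones, so the divider is unchanged
  tr <- make_toy_tree("binary", depth = 3, branch_len = 17)
  br <- tree_branches(tr)$branch
  for (b in seq_along(br$pathlength)) {
    expect_equal(proximal_current_fraction(tr, b, 0.3),
                 proximal_current_fraction(tr, b, 0.3, per_um = TRUE),
                 tolerance = 1e-12)
  }
})

test_that("fraction decreases along the interior of a chain", {
  chain <- make_toy_tree("chain", n = 6, branch_len = 10)
  d <- seq(0.05, 0.95, by = 0.05)
  fr <- vapply(d, function(f) proximal_current_fraction(chain, 1, f), 1)
  expect_true(all(diff(fr) < 0))
  expect_equal(fr, 1 - d, tolerance = 1e-12)  # chain closed form
})

test_that("series/parallel reduction equals the Laplacian oracle", {
  set.seed(9)
  for (seed in 1:10) {
    tr <- random_fixture_tree(600 + seed)
    br <- tree_branches(tr)$branch
    picks <- sample(seq_along(br$pathlength), min(4, length(br$pathlength)))
    for (b in picks) {
      f <- runif(1, 0.05, 0.95)
      expect_equal(proximal_current_fraction(tr, b, f),
                   laplacian_fraction(tr, b, f), tolerance = 1e-9,
                   info = paste("seed", seed, "branch", b))
    }
  }
})

test_that("length-uniform sampling reproduces the chain closed form", {
  chain <- make_toy_tree("chain", n = 5, branch_len = 10)
  set.seed(10)
  s <- sample_current_fractions(chain, 200)
  expect_true(all(s$fraction >= 0 & s$fraction <= 1))
  expect_true(all(s$distance >= 0 & s$distance <= 1))
  expect_equal(s$fraction, 1 - s$distance, tolerance = 1e-9)
  set.seed(11); a <- sample_current_fractions(chain, 5)
  set.seed(11); b <- sample_current_fractions(chain, 5)
  expect_identical(a, b)
})

test_that("quadratic fitting recovers exact and degenerate inputs", {
  d <- seq(0, 1, length.out = 30)
  exact <- data.frame(distance = d, fraction = 0.4 * d^2 - 0.9 * d + 1)
  fit <- fit_quadratic(exact)
  expect_equal(c(fit$a, fit$b, fit$c), c(0.4, -0.9, 1), tolerance = 1e-9)
  expect_equal(fit$r2, 1, tolerance = 1e-9)

  const <- data.frame(distance = d, fraction = rep(0.6, 30))
  cf <- fit_quadratic(const)
  expect_equal(c(cf$a, cf$b, cf$c), c(0, 0, 0.6), tolerance = 1e-9)

  # normal-equations oracle on noisy data
  set.seed(12)
  noisy <- data.frame(distance = runif(80), fraction = runif(80))
  nf <- fit_quadratic(noisy)
  X <- cbind(1, noisy$distance, noisy$distance^2)
  beta <- solve(t(X) %*% X, t(X) %*% noisy$fraction)
  expect_equal(c(nf$c, nf$b, nf$a), drop(beta), tolerance = 1e-9,
               ignore_attr = TRUE)
  # cross-scored r2 of the fit against its own samples equals in-sample r2
  expect_equal(r2_against(nf, noisy), nf$r2, tolerance = 1e-12)
  expect_error(fit_quadratic(data.frame(distance = c(1, 1, 1),
                                        fraction = c(0, 1, 2))), "distinct")
})

test_that("spine weighting multiplies length, density and fraction", {
  chain <- make_toy_tree("chain", n = 10, branch_len = 30)
  prof <- tdl_by_distance(chain, axis = "y", breaks = seq(0, 300, by = 30))
  flat <- structure(list(a = 0, b = 0, c = 1), class = "quad_fit")
  out <- spine_weighted_current(prof, 300, c(2, 2, 2), flat)
  expect_equal(out$spines_per_um, rep(2, 10), tolerance = 1e-9)
  expect_equal(out$current, rep(2, 10), tolerance = 1e-9)

  # doubling one layer's density doubles that segment only; layer 2 is
  # (100, 200], holding the bins with midpoints 105..195
  out2 <- spine_weighted_current(prof, 300, c(2, 4, 2), flat)
  expect_equal(out2$current[4:7], 2 * out$current[4:7], tolerance = 1e-9)
  expect_equal(out2$current[c(1:3, 8:10)], out$current[c(1:3, 8:10)],
               tolerance = 1e-9)

  # element-wise multiplication oracle with a non-trivial fit
  fit <- structure(list(a = -0.5, b = -0.2, c = 1), class = "quad_fit")
  dens <- c(1.5, 2.5, 3.5)
  out3 <- spine_weighted_current(prof, 300, dens, fit)
  mid <- prof$mid
  layer <- findInterval(mid, c(0, 100, 200, 300), rightmost.closed = TRUE)
  manual <- (prof$mass * prof$tdl / 30) * dens[layer] *
    (-0.5 * (mid / 300)^2 - 0.2 * (mid / 300) + 1)
  expect_equal(out3$current, manual, tolerance = 1e-12)

  expect_equal(curve_nrmse(c(0, 1, 2), c(0, 1, 2)), 0)
  expect_equal(curve_nrmse(c(0, 2), c(1, 3)), 0.5)
})
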