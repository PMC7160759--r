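test_that("minimal SWC round trip and structure validation", {
  f <- withr::local_tempfile(fileext = ".swc")
  writeLines(c("# comment",
               "1 1 0 0 0 5 -1",
               "2 3 0 10 0 1 1",
               "3 3 0 20 0 1 2"), f)
  tr <- read_swc(f)
  br <- tree_branches(tr)$branch
  expect_equal(length(br$pathlength), 1L)          # one stem
  expect_equal(sum(vapply(br$daughters, length, 1L) == 2L), 0L)
  expect_equal(br$pathlength, 20)

  # forward reference to an undefined parent is a structure error
  writeLines(c("1 1 0 0 0 5 -1", "2 3 0 10 0 1 7"), f)
  expect_error(read_swc(f), "structure error")
  # malformed line reports its line number
  writeLines(c("1 1 0 0 0 5 -1", "2 3 0 ten 0 1 1"), f)
  expect_error(read_swc(f), "line 2")
  # trifurcation rejected
  nodes <- data.frame(id = 1:5, type = c(1, 3, 3, 3, 3),
                      x = c(0, 0, -1, 0, 1), y = c(0, 1, 2, 2, 2),
                      z = 0, radius = 1, parent = c(-1, 1, 2, 2, 2))
  expect_error(morph_tree(nodes), "non-binary")
})

test_that("SWC write/read round trip is the identity on generated trees", {
  tr <- make_toy_tree("binary", depth = 3, branch_len = 12.5)
  f <- withr::local_tempfile(fileext = ".swc")
  write_swc(tr, f)
  back <- read_swc(f)
  expect_trees_equal(tr, back, tol = 1e-6)
  # second round trip is exact
  f2 <- withr::local_tempfile(fileext = ".swc")
  write_swc(back, f2)
  expect_identical(readLines(f)[-1], readLines(f2)[-1])
})

test_that("write_swc renumbers ids with parents first and both stems on the soma", {
  nodes <- data.frame(id = c(10L, 20L, 30L), type = c(1L, 3L, 3L),
                      x = c(0, 1, -1), y = c(0, 1, 1), z = 0, radius = 1,
                      parent = c(-1L, 10L, 10L))
  tr <- morph_tree(nodes)
  f <- withr::local_tempfile(fileext = ".swc")
  write_swc(tr, f)
  m <- read.table(f)
  expect_equal(m$V1, 1:3)
  expect_equal(m$V7, c(-1L, 1L, 1L))

  soma_only <- morph_tree(data.frame(id = 1L, type = 1L, x = 0, y = 0, z = 0,
                                     radius = 5, parent = -1L))
  write_swc(soma_only, f)
  expect_equal(nrow(read.table(f)), 1L)
})

test_that("terminal path enumeration and pathlength sums", {
  expect_length(terminal_paths(make_toy_tree("Y")), 2L)
  expect_length(terminal_paths(make_toy_tree("binary", depth = 3)), 8L)

  tr <- make_toy_tree("binary", depth = 2, branch_len = 7)
  tp <- terminal_paths(tr)
  expect_length(tp, 4L)
  for (p in tp) {
    expect_equal(p$total_pathlength, 3 * 7, tolerance = 1e-9)
    expect_equal(p$bif_dists, c(7, 14), tolerance = 1e-9)
  }
})

test_that("registration is rigid, idempotent and recovers known rotations", {
  tr <- register(make_reference_population(n = 1, seed = 21)$trees[[1]])
  # idempotence
  tr2 <- register(tr)
  expect_trees_equal(tr, tr2, tol = 1e-9)
  # rigid: pairwise distances preserved under registration of a rotated copy
  rot <- tr
  th <- 90 * pi / 180
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  xyz <- as.matrix(tr$nodes[, c("x", "y", "z")]) %*% t(R)
  rot$nodes$x <- xyz[, 1]; rot$nodes$y <- xyz[, 2]; rot$nodes$z <- xyz[, 3]
  reg <- register(rot)
  i <- seq(1, nrow(tr$nodes), by = 7)
  d0 <- dist(as.matrix(tr$nodes[i, c("x", "y", "z")]))
  d1 <- dist(as.matrix(reg$nodes[i, c("x", "y", "z")]))
  expect_lt(max(abs(d0 - d1)), 1e-6)
  # tip centroid direction restored to +y
  tips <- reg$nodes[reg$nodes$id %in% setdiff(reg$nodes$id, reg$nodes$parent), ]
  units <- as.matrix(tips[, c("x", "y", "z")])
  units <- units / sqrt(rowSums(units^2))
  ctr <- colMeans(units); ctr <- ctr / sqrt(sum(ctr^2))
  expect_equal(unname(ctr[2]), 1, tolerance = 1e-6)

  # straight vertical neurite is unchanged and degenerate input errors
  chain <- make_toy_tree("chain", n = 3)
  expect_trees_equal(register(chain), chain, tol = 1e-9)
  bad <- morph_tree(data.frame(id = 1:2, type = c(1, 3), x = 0, y = 0, z = 0,
                               radius = c(5, 1), parent = c(-1, 1)),
                    validate = FALSE)
  expect_error(register(bad), "degenerate")
})

test_that("point-process encoding follows the half-open bin convention", {
  # path of length 20 with a bifurcation at pathlength 10, delta 5
  s <- 10 / sqrt(2)
  nodes <- data.frame(
    id = 1:5, type = c(1, 3, 3, 3, 3),
    x = c(0, 0, -s, 0, 0), y = c(0, 10, 10 + s, 15, 20), z = 0,
    radius = 1, parent = c(-1, 1, 2, 2, 4))
  tr <- morph_tree(nodes)
  pp <- encode_point_processes(tr, delta = 5, normalize = FALSE)
  # both terminal paths are length 20 with the shared bifurcation at 10
  expect_equal(unname(pp$events),
               rbind(c(0L, 1L, 0L, 1L), c(0L, 1L, 0L, 1L)))

  # unbranched path of length 10: tip only
  pp2 <- encode_point_processes(make_toy_tree("chain", n = 2, branch_len = 5),
                                delta = 5, normalize = FALSE)
  expect_equal(unname(pp2$events[1, ]), c(0L, 1L))

  # symmetric Y: stem 10, daughters 10 -> two identical sequences
  ytree <- make_toy_tree("Y", branch_len = 10)
  pp3 <- encode_point_processes(ytree, delta = 5, normalize = FALSE)
  expect_equal(pp3$R, 2L)
  expect_equal(pp3$N_total, 4L)
  expect_equal(unname(pp3$events), rbind(c(0L, 1L, 0L, 1L), c(0L, 1L, 0L, 1L)))

  # two events in one bin names the offending path
  expect_error(encode_point_processes(ytree, delta = 25, normalize = FALSE),
               "delta too large")
})

test_that("encoding invariants hold over generated populations", {
  pop <- make_reference_population(n = 6, seed = 12)
  pp <- encode_point_processes(pop$trees, bins = 80)
  # every sequence ends in 1 at its tip bin (normalized axis: bin K)
  expect_true(all(pp$events[, pp$K] == 1L))
  expect_true(all(pp$tip_bin == pp$K))
  # per-sequence event count = bifurcations on that path + 1
  paths <- do.call(c, lapply(pop$trees, terminal_paths))
  expect_equal(rowSums(pp$events),
               vapply(paths, function(p) length(p$bif_dists), 1) + 1)
  # recounted path bifurcations at least the number of unique bifurcations
  nuniq <- sum(vapply(pop$trees, function(t) {
    br <- tree_branches(t)$branch
    sum(vapply(br$daughters, length, 1L) == 2L)
  }, 1))
  expect_gte(sum(rowSums(pp$events)) - pp$R, nuniq)
})
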