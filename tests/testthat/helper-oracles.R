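# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: quadrature instead of the recursive filter,
# graph Laplacian solves instead of series/parallel reduction, dense
# polyline sampling instead of the quadratic sphere-crossing count.

# posterior mean of x1 given one bin of Bernoulli observations, by dense
# 1-D grid quadrature over the predictive Gaussian
grid_posterior_k1 <- function(count, n_seq, params, delta, x0, s0,
                              npts = 1e4, span = 10) {
  m <- params$rho * x0
  v <- params$rho^2 * s0 + params$sigma_eps2
  x <- seq(m - span * sqrt(v), m + span * sqrt(v), length.out = npts)
  eta <- params$mu + params$beta * x
  logw <- -(x - m)^2 / (2 * v) + count * eta - n_seq * exp(eta) * delta
  w <- exp(logw - max(logw))
  sum(x * w) / sum(w)
}

# smoothed means for a K=2 problem by dense 2-D grid quadrature of the
# joint posterior p(x1, x2 | n)
grid_posterior_k2 <- function(counts, n_seq, params, delta, x0, s0,
                              npts = 400, span = 8) {
  m1 <- params$rho * x0
  v1 <- params$rho^2 * s0 + params$sigma_eps2
  g1 <- seq(m1 - span * sqrt(v1), m1 + span * sqrt(v1), length.out = npts)
  sd2 <- sqrt(params$sigma_eps2)
  lo2 <- params$rho * min(g1) - span * sd2
  hi2 <- params$rho * max(g1) + span * sd2
  g2 <- seq(lo2, hi2, length.out = npts)
  X1 <- matrix(g1, npts, npts)
  X2 <- matrix(g2, npts, npts, byrow = TRUE)
  e1 <- params$mu + params$beta * X1
  e2 <- params$mu + params$beta * X2
  logw <- -(X1 - m1)^2 / (2 * v1) -
    (X2 - params$rho * X1)^2 / (2 * params$sigma_eps2) +
    counts[1] * e1 - n_seq[1] * exp(e1) * delta +
    counts[2] * e2 - n_seq[2] * exp(e2) * delta
  w <- exp(logw - max(logw))
  c(sum(X1 * w), sum(X2 * w)) / sum(w)
}

# effective resistance between two nodes of a resistor graph by solving
# the grounded Laplacian
laplacian_reff <- function(edges, r, n_nodes, a, b) {
  L <- matrix(0, n_nodes, n_nodes)
  for (e in seq_len(nrow(edges))) {
    i <- edges[e, 1]; j <- edges[e, 2]; g <- 1 / r[e]
    L[i, i] <- L[i, i] + g; L[j, j] <- L[j, j] + g
    L[i, j] <- L[i, j] - g; L[j, i] <- L[j, i] - g
  }
  keep <- setdiff(seq_len(n_nodes), b)
  rhs <- numeric(n_nodes); rhs[a] <- 1
  v <- solve(L[keep, keep], rhs[keep])
  v[match(a, keep)]
}

# proximal current fraction via Laplacian solves: R_prox from the path to
# the soma, R_distal from the distal subtree with all tips tied together
laplacian_fraction <- function(tree, branch, frac) {
  br <- tree_branches(tree)$branch
  nb <- length(br$pathlength)
  # node numbering: 1 = soma junction, branch b's distal junction = b + 1
  parent_node <- function(b) {
    p <- br$parent_branch[b]
    if (is.na(p)) 1L else p + 1L
  }
  # R_prox: series sum on the unique path (plus the split piece)
  r_prox <- frac
  b <- br$parent_branch[branch]
  while (!is.na(b)) { r_prox <- r_prox + 1; b <- br$parent_branch[b] }
  # distal subgraph: remainder of the split branch plus all descendants,
  # tips tied to one supernode
  desc <- c()
  stack <- br$daughters[[branch]]
  while (length(stack)) {
    d <- stack[[1]]; stack <- stack[-1]
    desc <- c(desc, d)
    stack <- c(stack, br$daughters[[d]])
  }
  if (frac >= 1 && !length(desc)) return(1)
  # nodes: 1 = split point P, 2 = branch end junction, descendants map to
  # their own end nodes, supernode = last
  ids <- c(branch, desc)
  node_of <- setNames(seq_along(ids) + 1L, ids)  # end node of each branch
  super <- length(ids) + 2L
  edges <- matrix(0L, 0, 2); r <- numeric(0)
  # split piece: P -> end of `branch`
  edges <- rbind(edges, c(1L, node_of[as.character(branch)]))
  r <- c(r, 1 - frac)
  for (d in desc) {
    from <- node_of[as.character(br$parent_branch[d])]
    edges <- rbind(edges, c(from, node_of[as.character(d)]))
    r <- c(r, 1)
  }
  # tie tip ends to the supernode with zero-ish resistance
  tips <- ids[vapply(ids, function(b) length(br$daughters[[b]]) == 0L, TRUE)]
  for (tp in tips) {
    edges <- rbind(edges, c(node_of[as.character(tp)], super))
    r <- c(r, 1e-12)
  }
  r_dist <- laplacian_reff(edges, r, super, 1L, super)
  r_dist / (r_prox + r_dist)
}

# Sholl crossings by dense sampling of each segment
sholl_oracle <- function(tree, radii, n_sample = 2000) {
  nd <- tree$nodes
  soma <- as.numeric(nd[nd$parent == -1L, c("x", "y", "z")])
  idx <- seq_len(nrow(nd)); names(idx) <- nd$id
  ch <- which(nd$parent != -1L)
  pa <- idx[as.character(nd$parent[ch])]
  counts <- integer(length(radii))
  for (s in seq_along(ch)) {
    p0 <- as.numeric(nd[pa[s], c("x", "y", "z")]) - soma
    p1 <- as.numeric(nd[ch[s], c("x", "y", "z")]) - soma
    t <- seq(0, 1, length.out = n_sample)
    d <- sqrt((p0[1] + t * (p1[1] - p0[1]))^2 +
                (p0[2] + t * (p1[2] - p0[2]))^2 +
                (p0[3] + t * (p1[3] - p0[3]))^2)
    for (ri in seq_along(radii)) {
      # sign changes of d - r along the segment, excluding the far vertex
      sgn <- sign(d - radii[ri])
      counts[ri] <- counts[ri] + sum(sgn[-length(sgn)] != sgn[-1] & sgn[-1] != 0) +
        sum(sgn[-length(sgn)] == 0 & c(sgn[-1] != 0))
    }
  }
  counts
}

# small generated tree for oracle sweeps
random_fixture_tree <- function(seed, n_bifs_min = 1) {
  set.seed(seed)
  cfg <- generation_config(
    rate = rate_curve(rep(0.08, 50), delta = 1 / 50),
    terminal_lengths = runif(20, 150, 250),
    stem_counts = c(1L, 2L), cone_half_angles = 30,
    tapers = -0.002, initial_diams = 2,
    angles = fixed_angle_table(runif(50, 30, 60), runif(50, 0, 360)),
    delta = 5, stem_noise_sd = 8, elong_noise_sd = 4)
  for (i in 1:50) {
    tr <- grow(cfg)
    br <- tree_branches(tr)$branch
    if (sum(vapply(br$daughters, length, 1L) == 2L) >= n_bifs_min) return(tr)
  }
  tr
}

expect_trees_equal <- function(a, b, tol = 1e-9) {
  expect_equal(nrow(a$nodes), nrow(b$nodes))
  expect_equal(as.matrix(a$nodes[, c("x", "y", "z", "radius")]),
               as.matrix(b$nodes[, c("x", "y", "z", "radius")]),
               tolerance = tol, ignore_attr = TRUE)
}
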