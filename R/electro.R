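# resistance of one branch: unit per branch by default, or proportional
# to pathlength in per-um mode
branch_resistance <- function(br, b, per_um) if (per_um) br$pathlength[b] else 1

# equivalent resistance of the subtree rooted at branch b (inclusive),
# collapsing daughters in parallel, all tips tied to a common distal node
subtree_resistance <- function(br, b, per_um) {
  d <- br$daughters[[b]]
  r <- branch_resistance(br, b, per_um)
  if (!length(d)) return(r)
  rd <- vapply(d, function(x) subtree_resistance(br, x, per_um), 1)
  r + 1 / sum(1 / rd)
}

#' Proximal current fraction at a point on the dendritic tree
#'
#' Models each branch as a resistor (identical unit resistance by default)
#' and reduces the morphology around the point by series/parallel
#' combination: R_prox is the series resistance from the point to the
#' soma, and R_distal the equivalent resistance of the subtree distal to
#' the point (daughter subtrees in parallel, dendritic tips tied to a
#' common distal node). The branch containing the point is split
#' proportionally by pathlength. The returned fraction is the current
#' divider R_distal / (R_prox + R_distal): the share of current injected
#' at the point that flows toward the soma. A point at a tip (no distal
#' material) returns 1.
#'
#' @param tree a `morph_tree`.
#' @param branch branch index (into [tree_branches()]).
#' @param frac position along the branch as a fraction of its pathlength,
#'   in [0, 1].
#' @param mode "divider" (default) or "resistance", the literal proximal
#'   resistance share R_prox / (R_prox + R_distal), for sensitivity
#'   analysis.
#' @param per_um resistance proportional to branch pathlength instead of
#'   unit per branch.
#' @return the fraction in [0, 1].
#' @export
proximal_current_fraction <- function(tree, branch, frac,
                                      mode = c("divider", "resistance"),
                                      per_um = FALSE) {
  mode <- match.arg(mode)
  br <- tree_branches(tree)$branch
  if (branch < 1 || branch > length(br$pathlength)) stop("point not on tree: bad branch index")
  if (frac < 0 || frac > 1) stop("point not on tree: frac outside [0, 1]")
  rb <- branch_resistance(br, branch, per_um)
  r_prox <- frac * rb
  b <- br$parent_branch[branch]
  while (!is.na(b)) {
    r_prox <- r_prox + branch_resistance(br, b, per_um)
    b <- br$parent_branch[b]
  }
  d <- br$daughters[[branch]]
  if (!length(d)) {
    if (frac >= 1) return(if (mode == "divider") 1 else {
      if (r_prox == 0) 1 else 0
    })
    r_dist <- (1 - frac) * rb
  } else {
    rd <- vapply(d, function(x) subtree_resistance(br, x, per_um), 1)
    r_dist <- (1 - frac) * rb + 1 / sum(1 / rd)
  }
  if (r_prox == 0) return(if (mode == "divider") 1 else 0)
  if (mode == "divider") r_dist / (r_prox + r_dist) else r_prox / (r_prox + r_dist)
}

#' Sample proximal current fractions across the arbor
#'
#' Draws points uniformly by dendritic length (branch chosen with
#' probability proportional to its pathlength, position uniform within),
#' evaluates the proximal current fraction at each, and reports the
#' pathlength distance from the soma normalized by the morphology's
#' maximum terminal pathlength.
#'
#' @param tree a `morph_tree`.
#' @param n_points number of sample points (>= 1).
#' @param ... passed to [proximal_current_fraction()].
#' @return data.frame with `distance` (normalized, [0, 1]), `fraction`,
#'   `branch`, `frac`.
#' @export
sample_current_fractions <- function(tree, n_points = 100, ...) {
  if (n_points < 1) stop("n_points must be >= 1")
  br <- tree_branches(tree)$branch
  maxlen <- max(vapply(terminal_paths(tree), `[[`, 1, "total_pathlength"))
  bs <- sample.int(length(br$pathlength), n_points, replace = TRUE,
                   prob = br$pathlength)
  fr <- stats::runif(n_points)
  frac_val <- vapply(seq_len(n_points), function(i)
    proximal_current_fraction(tree, bs[i], fr[i], ...), 1)
  dist <- (br$path_from_soma[bs] + fr * br$pathlength[bs]) / maxlen
  data.frame(distance = dist, fraction = frac_val, branch = bs, frac = fr)
}

#' Quadratic regression of current fraction on normalized distance
#'
#' Ordinary least squares fit of fraction = a d^2 + b d + c over pooled
#' population samples.
#'
#' @param samples data.frame with `distance` and `fraction` columns (as
#'   from [sample_current_fractions()], possibly row-bound over trees).
#' @return object of class `quad_fit`: coefficients `a`, `b`, `c` and the
#'   in-sample `r2`.
#' @export
fit_quadratic <- function(samples) {
  if (length(unique(samples$distance)) < 3) stop("need >= 3 distinct distances")
  fit <- stats::lm(fraction ~ I(distance^2) + distance, data = samples)
  co <- stats::coef(fit)
  if (anyNA(co)) stop("rank-deficient quadratic fit")
  ss_tot <- sum((samples$fraction - mean(samples$fraction))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else NA_real_
  structure(list(a = unname(co["I(distance^2)"]), b = unname(co["distance"]),
                 c = unname(co["(Intercept)"]), r2 = r2),
            class = "quad_fit")
}

#' Evaluate a quadratic fit
#' @param fit a `quad_fit`
#' @param d normalized distances
#' @return fitted fractions
#' @export
predict_quadratic <- function(fit, d) fit$a * d^2 + fit$b * d + fit$c

#' Variance in reference samples explained by a fitted curve
#'
#' Cross-scoring r^2: how much of the reference population's
#' fraction-vs-distance samples the given quadratic fit explains.
#'
#' @param fit a `quad_fit` (typically from a generated population).
#' @param samples reference samples (`distance`, `fraction`).
#' @return r^2 (can be negative if the fit is worse than the mean).
#' @export
r2_against <- function(fit, samples) {
  res <- samples$fraction - predict_quadratic(fit, samples$distance)
  1 - sum(res^2) / sum((samples$fraction - mean(samples$fraction))^2)
}

#' Spine-density-weighted relative somatic current profile
#'
#' Multiplies the dendritic length added per um of distance by the
#' per-layer spine density (spines per um of dendrite) to get spines per
#' um of distance, then by the fitted proximal current fraction at that
#' distance to get the relative current reaching the soma under uniform
#' unit-strength inputs.
#'
#' @param profile result of [tdl_by_distance()] (y-axis profile).
#' @param boundary_length soma-to-boundary distance, um, defining the
#'   layers and the distance normalization for the fit.
#' @param spine_densities per-layer spine densities, spines/um.
#' @param fit a `quad_fit` of proximal current fraction vs normalized
#'   distance.
#' @param layer_fractions fractions partitioning (0, 1] into layers.
#' @return data.frame with `distance`, `length_per_um`, `spines_per_um`,
#'   `current`.
#' @export
spine_weighted_current <- function(profile, boundary_length, spine_densities,
                                   fit, layer_fractions = rep(1 / 3, 3)) {
  stopifnot(length(spine_densities) == length(layer_fractions))
  mid <- profile$mid
  len_per_um <- profile$mass * profile$tdl / diff(profile$breaks)
  edges <- boundary_length * cumsum(c(0, layer_fractions))
  layer <- pmin(length(spine_densities),
                pmax(1L, findInterval(mid, edges, rightmost.closed = TRUE)))
  spines <- len_per_um * spine_densities[layer]
  current <- spines * predict_quadratic(fit, mid / boundary_length)
  data.frame(distance = mid, length_per_um = len_per_um,
             spines_per_um = spines, current = current)
}

#' Range-normalized RMSE between two curves on a common grid
#' @param a,b numeric vectors of equal length
#' @return sqrt(mean((a-b)^2)) / diff(range(a))
#' @export
curve_nrmse <- function(a, b) {
  stopifnot(length(a) == length(b))
  sqrt(mean((a - b)^2)) / diff(range(a))
}
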