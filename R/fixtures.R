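#' Construct a rate curve object directly
#'
#' Wraps a known per-bin rate curve in the same container returned by the
#' smoother, so generators and fixtures can run from a ground-truth rate.
#'
#' @param lambda per-bin rates (events per bin), length K.
#' @param delta bin width (defaults to 1/K, the normalized axis).
#' @param normalized whether the axis is the normalized per-path axis.
#' @return a `rate_estimate`.
#' @export
rate_curve <- function(lambda, delta = 1 / length(lambda), normalized = TRUE) {
  stopifnot(all(lambda > 0))
  structure(list(x_smooth = log(lambda), var_smooth = rep(0, length(lambda)),
                 A = rep(0, length(lambda)), lambda = lambda,
                 params = ss_params(0, 0, 1, 1e-6), delta = delta,
                 K = length(lambda), normalized = normalized),
            class = "rate_estimate")
}

#' Default fixture rate: exponential decay
#'
#' lambda(k) = lambda0 * exp(-k / tau) with lambda0 = 0.1 events per bin
#' and tau = K/4, a proximally peaked curve resembling the branching-rate
#' shape of real granule cells without asserting its values.
#'
#' @param K number of bins.
#' @param lambda0 peak per-bin rate.
#' @param tau decay constant in bins.
#' @return a `rate_estimate` on the normalized axis.
#' @export
fixture_rate <- function(K = 100L, lambda0 = 0.1, tau = K / 4) {
  rate_curve(lambda0 * exp(-seq_len(K) / tau), delta = 1 / K, normalized = TRUE)
}

#' Simulate point processes from a known rate
#'
#' R independent binary sequences with per-bin event probability
#' lambda(k) * delta; the final bin of every sequence is forced to 1 (the
#' tip convention used when encoding real morphologies).
#'
#' @param lambda per-um rate vector of length K (events per um).
#' @param R number of sequences.
#' @param delta bin width; lambda * delta must be <= 1 everywhere.
#' @param seed optional RNG seed.
#' @return a `pp_set`.
#' @export
simulate_point_processes <- function(lambda, R, delta = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- lambda * delta
  if (any(p < 0) || any(p > 1)) stop("lambda * delta must lie in [0, 1]")
  K <- length(p)
  ev <- matrix(as.integer(stats::runif(R * K) < rep(p, each = R)), R, K)
  ev[, K] <- 1L
  pp_set(ev, delta = delta, normalized = FALSE)
}

#' Simulate point processes from the state-space model itself
#'
#' Draws one latent AR(1) path x (shared by all sequences), sets the
#' per-bin rate lambda_k = exp(mu + beta * x_k), and simulates R
#' independent Bernoulli(lambda_k * delta) sequences. Used for parameter
#' and rate recovery checks; tips are not forced (this is a raw model
#' draw, not a morphology encoding).
#'
#' @param params an `ss_params`.
#' @param R number of sequences.
#' @param K number of bins.
#' @param delta bin width.
#' @param seed optional RNG seed.
#' @return list with `pp` (a `pp_set`), the latent path `x` and the
#'   realized expected events per bin `lambda` (= exp(mu + beta x) delta).
#' @export
simulate_state_space <- function(params, R, K, delta = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- numeric(K)
  x[1] <- stats::rnorm(1, 0, sqrt(stationary_var(params)))
  for (k in seq_len(K - 1L)) {
    x[k + 1L] <- params$rho * x[k] + stats::rnorm(1, 0, sqrt(params$sigma_eps2))
  }
  lambda <- exp(params$mu + params$beta * x) * delta  # events per bin
  if (any(lambda > 1)) stop("lambda * delta exceeds 1; decrease delta")
  ev <- matrix(as.integer(stats::runif(R * K) < rep(lambda, each = R)), R, K)
  list(pp = pp_set(ev, delta = delta, normalized = FALSE, enforce_tip = FALSE),
       x = x, lambda = lambda)
}

#' Deterministic toy trees
#'
#' Known-geometry trees used across the test suites:
#' \itemize{
#'   \item `chain`: `n` straight segments of `branch_len` um along +y.
#'   \item `Y`: a vertical stem of `branch_len`, then two daughters of
#'     `branch_len` at +-45 degrees in the xy-plane.
#'   \item `binary`: full binary tree of the given `depth`: a vertical
#'     stem then recursive splits, 2^depth tips, (1+2+...+2^depth)
#'     branches each of `branch_len`.
#' }
#'
#' @param kind "chain", "Y" or "binary".
#' @param branch_len branch length, um.
#' @param n number of chain segments (chain only).
#' @param depth tree depth (binary only; <= 8).
#' @param radius compartment radius, um.
#' @return a `morph_tree`.
#' @export
make_toy_tree <- function(kind = c("chain", "Y", "binary"), branch_len = 10,
                          n = 4L, depth = 3L, radius = 0.5) {
  kind <- match.arg(kind)
  soma <- data.frame(id = 1L, type = 1L, x = 0, y = 0, z = 0,
                     radius = max(radius, 1), parent = -1L)
  if (kind == "chain") {
    nodes <- rbind(soma, data.frame(
      id = 1L + seq_len(n), type = 3L, x = 0, y = branch_len * seq_len(n),
      z = 0, radius = radius, parent = seq_len(n)))
    return(morph_tree(nodes))
  }
  if (kind == "Y") {
    s <- branch_len / sqrt(2)
    nodes <- rbind(soma,
      data.frame(id = 2L, type = 3L, x = 0, y = branch_len, z = 0,
                 radius = radius, parent = 1L),
      data.frame(id = 3L, type = 3L, x = -s, y = branch_len + s, z = 0,
                 radius = radius, parent = 2L),
      data.frame(id = 4L, type = 3L, x = s, y = branch_len + s, z = 0,
                 radius = radius, parent = 2L))
    return(morph_tree(nodes))
  }
  if (depth > 8L) stop("binary depth must be <= 8")
  rows <- list(soma)
  nid <- 1L
  # recursive splits alternate between the xy- and zy-planes so deep
  # trees stay non-degenerate
  recurse <- function(parent_id, pos, dir, level) {
    end <- pos + dir * branch_len
    nid <<- nid + 1L
    my <- nid
    rows[[length(rows) + 1L]] <<- data.frame(
      id = my, type = 3L, x = end[1], y = end[2], z = end[3],
      radius = radius, parent = parent_id)
    if (level >= depth) return(invisible(NULL))
    ax <- if (level %% 2L == 0L) c(1, 0, 0) else c(0, 0, 1)
    perp <- unit(ax - sum(ax * dir) * dir)
    a <- 30 * pi / 180
    d1 <- unit(cos(a) * dir + sin(a) * perp)
    d2 <- unit(cos(a) * dir - sin(a) * perp)
    recurse(my, end, d1, level + 1L)
    recurse(my, end, d2, level + 1L)
  }
  recurse(1L, c(0, 0, 0), c(0, 1, 0), 0L)
  morph_tree(do.call(rbind, rows))
}

#' Synthetic reference population with known branching rate
#'
#' Runs the generator from a known (default exponentially decaying) rate
#' curve and fixed empirical distributions to produce a pseudo-"real"
#' population whose rate and angle statistics are known. This stands in
#' for a set of digitized reconstructions in closed-loop
#' estimate-generate-measure tests; it is synthetic and does not mimic
#' any particular archive's morphometric values.
#'
#' @param n population size (default 43).
#' @param rate a `rate_estimate`; default [fixture_rate()] with K = 100.
#' @param seed RNG seed (fixtures regenerate bit-identically from it).
#' @param terminal_lengths,stem_counts,delta overrides of the default
#'   fixture geometry (terminal boundary ~ N(300, 30) um truncated at
#'   200, 1-3 stems, 5 um growth step).
#' @return list with `trees`, the `config` used, and `rate`.
#' @export
make_reference_population <- function(n = 43L, rate = fixture_rate(100L),
                                      seed = 1L, terminal_lengths = NULL,
                                      stem_counts = c(1L, 2L, 2L, 3L),
                                      delta = 5) {
  set.seed(seed)
  if (is.null(terminal_lengths)) {
    terminal_lengths <- pmax(200, stats::rnorm(200, 300, 30))
  }
  angles <- fixed_angle_table(stats::runif(500, 20, 70),
                              stats::runif(500, 0, 360))
  config <- generation_config(
    rate = rate, terminal_lengths = terminal_lengths,
    stem_counts = stem_counts, cone_half_angles = c(20, 30, 40),
    tapers = stats::runif(100, -0.004, -0.001),
    initial_diams = stats::runif(100, 1.5, 3), angles = angles,
    delta = delta, stem_noise_sd = 10, elong_noise_sd = 5)
  trees <- lapply(seq_len(n), function(i) grow(config))
  list(trees = trees, config = config, rate = rate)
}
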