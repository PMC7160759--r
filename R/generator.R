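# --- small vector helpers ------------------------------------------------

unit <- function(v) v / sqrt(sum(v^2))

# right-handed rotation of v about unit axis p by angle (radians)
rotate_about <- function(v, p, angle) {
  v * cos(angle) +
    c(p[2] * v[3] - p[3] * v[2], p[3] * v[1] - p[1] * v[3],
      p[1] * v[2] - p[2] * v[1]) * sin(angle) +
    p * sum(p * v) * (1 - cos(angle))
}

# component of v orthogonal to unit vector p, normalized; NULL if degenerate
perp_unit <- function(v, p) {
  w <- v - sum(v * p) * p
  n <- sqrt(sum(w^2))
  if (n < 1e-9) NULL else w / n
}

# any unit vector orthogonal to p
any_perp <- function(p) {
  w <- if (abs(p[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  unit(w - sum(w * p) * p)
}

# perturb a unit direction by Gaussian angular noise (sd in degrees):
# rotate by N(0, sd) about a uniformly random orthogonal axis
perturb_direction <- function(v, sd_deg) {
  if (sd_deg <= 0) return(v)
  phi <- stats::runif(1, 0, 2 * pi)
  axis <- rotate_about(any_perp(v), v, phi)
  unit(rotate_about(v, axis, stats::rnorm(1, 0, sd_deg * pi / 180)))
}

# --- bifurcation geometry -------------------------------------------------

#' Branch-angle geometry at every bifurcation
#'
#' For each bifurcation of a (registered) tree, computes the bifurcation
#' amplitude (angle between the primary and secondary daughter branch
#' vectors), the azimuth (clockwise angle, viewed along the parent vector
#' from its base, through which the secondary daughter must rotate about
#' the parent vector to point toward the central y-axis), and the
#' orientation noise (angle between the primary daughter and the parent).
#' The primary daughter is the one most parallel to the parent; exact ties
#' go to the first daughter in child order. Branch vectors run from branch
#' start to branch end.
#'
#' @param tree a registered `morph_tree` with at least one bifurcation.
#' @return data.frame with columns `x`, `z` (bifurcation position, um),
#'   `amplitude`, `azimuth`, `noise` (degrees).
#' @export
bifurcation_geometry <- function(tree) {
  br <- tree_branches(tree)$branch
  nd <- tree$nodes
  idx <- seq_len(nrow(nd)); names(idx) <- nd$id
  pos <- function(id) as.numeric(nd[idx[as.character(id)], c("x", "y", "z")])
  bvec <- function(b) {
    ids <- br$node_ids[[b]]
    pos(ids[length(ids)]) - pos(ids[1])
  }
  bifs <- which(vapply(br$daughters, length, 1L) == 2L)
  if (!length(bifs)) stop("tree has no bifurcations")
  out <- vector("list", length(bifs))
  for (j in seq_along(bifs)) {
    b <- bifs[j]
    p <- unit(bvec(b))
    ids <- br$node_ids[[b]]
    at <- pos(ids[length(ids)])
    d <- br$daughters[[b]]
    v1 <- unit(bvec(d[1])); v2 <- unit(bvec(d[2]))
    a1 <- acos(min(1, max(-1, sum(v1 * p))))
    a2 <- acos(min(1, max(-1, sum(v2 * p))))
    if (a2 < a1 - 1e-12) { tmp <- v1; v1 <- v2; v2 <- tmp; a1 <- a2 }
    amplitude <- acos(min(1, max(-1, sum(v1 * v2)))) * 180 / pi
    # azimuth: clockwise (viewed from the parent's base along p) rotation
    # of the secondary daughter onto the direction toward the central axis
    tperp <- perp_unit(c(-at[1], 0, -at[3]), p)
    if (is.null(tperp)) tperp <- any_perp(p)
    dperp <- perp_unit(v2, p)
    if (is.null(dperp)) dperp <- tperp
    cr <- c(dperp[2] * tperp[3] - dperp[3] * tperp[2],
            dperp[3] * tperp[1] - dperp[1] * tperp[3],
            dperp[1] * tperp[2] - dperp[2] * tperp[1])
    phi <- atan2(sum(cr * p), sum(dperp * tperp))  # right-handed d -> t
    azimuth <- (-phi * 180 / pi) %% 360
    out[[j]] <- c(at[1], at[3], amplitude, azimuth, a1 * 180 / pi)
  }
  m <- do.call(rbind, out)
  data.frame(x = m[, 1], z = m[, 2], amplitude = m[, 3], azimuth = m[, 4],
             noise = m[, 5])
}

# --- conditional angle tables --------------------------------------------

norm_hist <- function(values, breaks) {
  h <- graphics::hist(values, breaks = breaks, plot = FALSE)$counts
  if (sum(h) > 0) h / sum(h) else h
}

#' Measure conditional branch-angle tables
#'
#' Builds 2D-binned (x, z) conditional histograms of bifurcation amplitude
#' and azimuth from a set of registered morphologies, with per-x-row and
#' global marginal fallbacks for cells with no observations.
#'
#' @param trees a registered `morph_tree` or list of them.
#' @param xz_bin bin width for the x and z coordinates, um (default 20).
#' @param angle_bin angle bin width in degrees (default 10; amplitude on
#'   0-180, azimuth on 0-360).
#' @return object of class `angle_table`.
#' @export
measure_angle_tables <- function(trees, xz_bin = 20, angle_bin = 10) {
  if (inherits(trees, "morph_tree")) trees <- list(trees)
  geo <- do.call(rbind, lapply(trees, bifurcation_geometry))
  amp_breaks <- seq(0, 180, by = angle_bin)
  azi_breaks <- seq(0, 360, by = angle_bin)
  ex <- range(geo$x); ez <- range(geo$z)
  x_edges <- seq(floor(ex[1] / xz_bin) * xz_bin,
                 ceiling(ex[2] / xz_bin + 1e-9) * xz_bin, by = xz_bin)
  if (length(x_edges) < 2) x_edges <- c(x_edges, x_edges + xz_bin)
  z_edges <- seq(floor(ez[1] / xz_bin) * xz_bin,
                 ceiling(ez[2] / xz_bin + 1e-9) * xz_bin, by = xz_bin)
  if (length(z_edges) < 2) z_edges <- c(z_edges, z_edges + xz_bin)
  nx <- length(x_edges) - 1L; nz <- length(z_edges) - 1L
  ix <- pmin(nx, pmax(1L, findInterval(geo$x, x_edges, rightmost.closed = TRUE)))
  iz <- pmin(nz, pmax(1L, findInterval(geo$z, z_edges, rightmost.closed = TRUE)))
  amp <- array(0, c(nx, nz, length(amp_breaks) - 1L))
  azi <- array(0, c(nx, nz, length(azi_breaks) - 1L))
  counts <- matrix(0L, nx, nz)
  for (i in seq_len(nx)) for (j in seq_len(nz)) {
    sel <- ix == i & iz == j
    counts[i, j] <- sum(sel)
    if (any(sel)) {
      amp[i, j, ] <- norm_hist(geo$amplitude[sel], amp_breaks)
      azi[i, j, ] <- norm_hist(geo$azimuth[sel], azi_breaks)
    }
  }
  amp_row <- t(vapply(seq_len(nx), function(i) {
    sel <- ix == i
    if (any(sel)) norm_hist(geo$amplitude[sel], amp_breaks)
    else rep(0, length(amp_breaks) - 1L)
  }, numeric(length(amp_breaks) - 1L)))
  azi_row <- t(vapply(seq_len(nx), function(i) {
    sel <- ix == i
    if (any(sel)) norm_hist(geo$azimuth[sel], azi_breaks)
    else rep(0, length(azi_breaks) - 1L)
  }, numeric(length(azi_breaks) - 1L)))
  structure(list(x_edges = x_edges, z_edges = z_edges,
                 amp_breaks = amp_breaks, azi_breaks = azi_breaks,
                 amp = amp, azi = azi, counts = counts,
                 amp_row = amp_row, azi_row = azi_row,
                 amp_global = norm_hist(geo$amplitude, amp_breaks),
                 azi_global = norm_hist(geo$azimuth, azi_breaks)),
            class = "angle_table")
}

#' Build a degenerate angle table holding single fixed angles
#'
#' All probability mass is placed in the bins containing `amplitude` and
#' `azimuth`; useful for fixtures with known geometry.
#' @param amplitude,azimuth angles in degrees
#' @param angle_bin bin width, degrees
#' @return an `angle_table`
#' @export
fixed_angle_table <- function(amplitude, azimuth, angle_bin = 10) {
  amp_breaks <- seq(0, 180, by = angle_bin)
  azi_breaks <- seq(0, 360, by = angle_bin)
  amp <- norm_hist(amplitude, amp_breaks)
  azi <- norm_hist(azimuth, azi_breaks)
  structure(list(x_edges = c(-1e6, 1e6), z_edges = c(-1e6, 1e6),
                 amp_breaks = amp_breaks, azi_breaks = azi_breaks,
                 amp = array(amp, c(1, 1, length(amp))),
                 azi = array(azi, c(1, 1, length(azi))),
                 counts = matrix(1L, 1, 1),
                 amp_row = matrix(amp, 1), azi_row = matrix(azi, 1),
                 amp_global = amp, azi_global = azi),
            class = "angle_table")
}

# draw one angle from a normalized histogram (uniform within the bin)
draw_from_hist <- function(mass, breaks) {
  b <- sample.int(length(mass), 1L, prob = mass)
  stats::runif(1, breaks[b], breaks[b + 1L])
}

# sample (amplitude, azimuth) conditioned on bifurcation (x, z);
# fallback: x-row marginal, then global marginal
sample_angles <- function(tab, x, z) {
  nx <- length(tab$x_edges) - 1L; nz <- length(tab$z_edges) - 1L
  i <- pmin(nx, pmax(1L, findInterval(x, tab$x_edges)))
  j <- pmin(nz, pmax(1L, findInterval(z, tab$z_edges)))
  amp_mass <- tab$amp[i, j, ]
  azi_mass <- tab$azi[i, j, ]
  if (sum(amp_mass) == 0) { amp_mass <- tab$amp_row[i, ]; azi_mass <- tab$azi_row[i, ] }
  if (sum(amp_mass) == 0) { amp_mass <- tab$amp_global; azi_mass <- tab$azi_global }
  c(amplitude = draw_from_hist(amp_mass, tab$amp_breaks),
    azimuth = draw_from_hist(azi_mass, tab$azi_breaks))
}

# --- generation configuration --------------------------------------------

#' Generation configuration
#'
#' Bundles the empirical distributions and settings driving morphology
#' generation. Distributions are value vectors sampled with replacement.
#'
#' @param rate a `rate_estimate`, or a single non-negative number for a
#'   constant branching rate in events per um.
#' @param terminal_lengths empirical terminal-pathlength distribution, um;
#'   one draw per morphology sets its anatomical boundary.
#' @param stem_counts empirical number-of-stems distribution.
#' @param cone_half_angles empirical cone half-angle distribution, degrees,
#'   used when a morphology has more than one stem.
#' @param tapers empirical diameter-change-per-um distribution (negative
#'   values shrink the branch).
#' @param initial_diams empirical stem initial-diameter distribution, um.
#' @param angles an `angle_table` for conditional branch-angle sampling.
#' @param delta growth step / bin width, um.
#' @param stem_noise_sd,elong_noise_sd Gaussian angular noise, degrees, on
#'   stem orientation and per elongation step.
#' @param diam_floor minimum diameter, um (never a termination trigger).
#' @param soma_radius soma compartment radius, um.
#' @param screen list with `bif_min`, `bif_max`, `major_min`, `major_max`,
#'   `minor_min`, `minor_max` screening ranges.
#' @param max_compartments hard cap guarding against runaway growth.
#' @return object of class `gen_config`.
#' @export
generation_config <- function(rate, terminal_lengths, stem_counts = 1L,
                              cone_half_angles = 30, tapers = -0.002,
                              initial_diams = 2, angles,
                              delta = 5, stem_noise_sd = 10,
                              elong_noise_sd = 5, diam_floor = 0.1,
                              soma_radius = 5,
                              screen = list(bif_min = 0L, bif_max = .Machine$integer.max,
                                            major_min = 0, major_max = Inf,
                                            minor_min = 0, minor_max = Inf),
                              max_compartments = 1e5) {
  stopifnot(delta > 0, diam_floor > 0, length(terminal_lengths) >= 1,
            length(stem_counts) >= 1)
  structure(list(rate = rate, terminal_lengths = terminal_lengths,
                 stem_counts = stem_counts,
                 cone_half_angles = cone_half_angles, tapers = tapers,
                 initial_diams = initial_diams, angles = angles,
                 delta = delta, stem_noise_sd = stem_noise_sd,
                 elong_noise_sd = elong_noise_sd, diam_floor = diam_floor,
                 soma_radius = soma_radius, screen = screen,
                 max_compartments = max_compartments),
            class = "gen_config")
}

sample_empirical <- function(values) values[sample.int(length(values), 1L)]

#' Draw a terminal boundary pathlength
#' @param config a `gen_config`
#' @return a single draw (um) from the empirical terminal-length
#'   distribution; it sets the anatomical termination boundary of one
#'   generated morphology
#' @export
sample_terminal_length <- function(config) sample_empirical(config$terminal_lengths)

#' Place stem directions on a cone
#'
#' A single stem points straight up (+y); multiple stems are spaced evenly
#' in azimuth (random common phase) on the lateral surface of a cone about
#' +y with the given half-angle. Each direction is then perturbed by
#' Gaussian angular noise.
#'
#' @param n_stems number of stems (>= 1).
#' @param half_angle cone half-angle, degrees; must lie in (0, 90) when
#'   n_stems > 1.
#' @param noise_sd angular noise sd, degrees.
#' @return n_stems x 3 matrix of unit direction vectors.
#' @export
place_stems <- function(n_stems, half_angle = 30, noise_sd = 0) {
  stopifnot(n_stems >= 1)
  if (n_stems == 1L) {
    dirs <- matrix(c(0, 1, 0), 1, 3)
  } else {
    if (half_angle <= 0 || half_angle >= 90) {
      stop("cone half-angle must lie in (0, 90) degrees for multiple stems")
    }
    ha <- half_angle * pi / 180
    phase <- stats::runif(1, 0, 2 * pi)
    az <- phase + 2 * pi * (seq_len(n_stems) - 1L) / n_stems
    dirs <- cbind(sin(ha) * cos(az), rep(cos(ha), n_stems), sin(ha) * sin(az))
  }
  if (noise_sd > 0) {
    for (i in seq_len(n_stems)) dirs[i, ] <- perturb_direction(dirs[i, ], noise_sd)
  }
  dirs
}

#' Simulate an inhomogeneous point process by thinning
#'
#' Generates a homogeneous Bernoulli process at the maximal rate
#' (per-bin event probability lambda_max * delta), then keeps each event
#' with probability lambda(k) / lambda_max, yielding per-bin event
#' probability lambda(k) * delta.
#'
#' @param rate numeric vector of length K (events per um per bin) or a
#'   function of the bin index.
#' @param K number of bins.
#' @param delta bin width, um.
#' @return integer 0/1 vector of length K.
#' @export
thinned_point_process <- function(rate, K, delta) {
  lam <- if (is.function(rate)) vapply(seq_len(K), rate, 1) else rep_len(rate, K)
  if (any(lam < 0)) stop("rate must be non-negative")
  lmax <- max(lam)
  if (lmax == 0) return(integer(K))
  if (lmax * delta > 1) {
    stop("bin too coarse for Bernoulli approximation: max(lambda)*delta = ",
         signif(lmax * delta, 4), " > 1")
  }
  base <- stats::runif(K) < lmax * delta
  keep <- stats::runif(K) < lam / lmax
  as.integer(base & keep)
}

# per-um rate lookup at distance d from the soma, for a morphology whose
# boundary is at pathlength L
rate_lookup <- function(rate, L) {
  if (is.numeric(rate) && length(rate) == 1L) {
    return(function(d) rep_len(rate, length(d)))
  }
  stopifnot(inherits(rate, "rate_estimate"))
  lam <- rate$lambda
  K <- rate$K
  if (isTRUE(rate$normalized)) {
    bin_um <- L / K
    function(d) {
      k <- pmin(K, pmax(1L, ceiling(d / L * K)))
      lam[k] / bin_um
    }
  } else {
    function(d) {
      k <- pmin(K, pmax(1L, ceiling(d / rate$delta)))
      lam[k] / rate$delta
    }
  }
}

#' Grow one morphology
#'
#' Samples a terminal boundary length and a stem count, places stems on a
#' cone, and grows each branch bin-by-bin: direction follows the previous
#' compartment plus Gaussian noise; an event of the branch's thinned point
#' process (indexed by current distance from the soma on the soma-anchored
#' bin grid) triggers a bifurcation whose daughter angles are drawn from
#' the conditional (x, z) angle table; diameter tapers linearly per branch,
#' floored. Every branch terminates when its pathlength from the soma
#' reaches the sampled boundary; the boundary overrides any further
#' branching.
#'
#' The configured rate is interpreted as a terminal-path hazard (the
#' quantity the point-process encoding of a morphology estimates, in
#' which shared bifurcations are recounted once per downstream tip) and
#' is converted internally to the equivalent per-branch hazard
#' h = q / (2 - q), so that encoding the grown population reproduces the
#' configured rate rather than doubling it.
#'
#' @param config a `gen_config`.
#' @param rate_override optional replacement rate (used for the
#'   homogeneous control mode).
#' @return a `morph_tree`, with attributes `boundary` (sampled terminal
#'   length, um) and `n_stems`.
#' @export
grow <- function(config, rate_override = NULL) {
  L <- sample_terminal_length(config)
  n_stems <- as.integer(sample_empirical(config$stem_counts))
  half <- sample_empirical(config$cone_half_angles)
  dirs <- place_stems(n_stems, half, config$stem_noise_sd)
  rate <- if (is.null(rate_override)) config$rate else rate_override
  lookup_raw <- rate_lookup(rate, L)
  delta <- config$delta
  # The estimated rate is a terminal-path bifurcation hazard: encoding
  # every soma-to-tip path recounts a shared bifurcation once per
  # downstream tip, so a per-branch hazard h appears in the paths as
  # q = 2h/(1+h). Growing branches directly at q would double branching
  # on every estimate/generate cycle; invert to the per-branch hazard
  # h = q/(2-q) per growth step. Boundary discard: an event whose
  # daughters could not fit one compartment before the boundary is never
  # scheduled (this also nulls the encoded tip event of the final bin).
  lookup <- function(d) {
    q <- pmin(1, lookup_raw(d) * delta)
    ifelse(d + delta > L, 0, q / (2 - q) / delta)
  }

  rows <- list()
  rows[[1]] <- c(1, 1, 0, 0, 0, config$soma_radius, -1)
  nid <- 1L

  # stack of branches to grow: start position, direction, start distance,
  # start diameter, parent compartment id
  stack <- vector("list", n_stems)
  for (i in seq_len(n_stems)) {
    stack[[i]] <- list(pos = c(0, 0, 0), dir = dirs[i, ],
                       dist = 0, diam = sample_empirical(config$initial_diams),
                       parent = 1L)
  }
  while (length(stack)) {
    brn <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    pos <- brn$pos; dir <- brn$dir; d <- brn$dist
    diam <- brn$diam; parent <- brn$parent
    taper <- sample_empirical(config$tapers)
    m <- floor((L - d) / delta + 1e-9)
    if (m < 1L) m <- 1L  # always emit at least one compartment
    ev <- thinned_point_process(function(j) lookup(d + j * delta), m, delta)
    for (j in seq_len(m)) {
      dir <- perturb_direction(dir, config$elong_noise_sd)
      pos <- pos + dir * delta
      d <- d + delta
      diam <- max(config$diam_floor, diam + taper * delta)
      nid <- nid + 1L
      if (nid > config$max_compartments) {
        stop("growth exceeded max_compartments = ", config$max_compartments)
      }
      rows[[nid]] <- c(nid, 3, pos, diam / 2, parent)
      parent <- nid
      if (ev[j] == 1L && d + delta <= L) {
        # bifurcate: primary continues the parent direction, secondary is
        # rotated away by the sampled amplitude at the sampled azimuth
        ang <- sample_angles(config$angles, pos[1], pos[3])
        p <- dir
        tperp <- perp_unit(c(-pos[1], 0, -pos[3]), p)
        if (is.null(tperp)) tperp <- any_perp(p)
        u <- rotate_about(tperp, p, ang["azimuth"] * pi / 180)
        alpha <- ang["amplitude"] * pi / 180
        sec <- unit(cos(alpha) * p + sin(alpha) * u)
        stack[[length(stack) + 1L]] <- list(pos = pos, dir = p, dist = d,
                                            diam = diam, parent = parent)
        stack[[length(stack) + 1L]] <- list(pos = pos, dir = sec, dist = d,
                                            diam = diam, parent = parent)
        break
      }
    }
  }
  m <- do.call(rbind, rows)
  tree <- morph_tree(data.frame(id = m[, 1], type = m[, 2], x = m[, 3],
                                y = m[, 4], z = m[, 5], radius = m[, 6],
                                parent = m[, 7]))
  attr(tree, "boundary") <- L
  attr(tree, "n_stems") <- n_stems
  tree
}

# ellipse axes (major, minor) of the tip projections onto the xz-plane
tip_axes <- function(tree) {
  nd <- tree$nodes
  tips <- nd[nd$id %in% tip_ids(tree) & nd$parent != -1L, ]
  if (nrow(tips) < 2L) return(c(0, 0))
  el <- enclosing_ellipse(cbind(tips$x, tips$z))
  el$axes
}

#' Screen a generated morphology
#'
#' Pass iff the bifurcation count falls within the configured range and
#' the major/minor axes of the tip-projection ellipse fall within theirs.
#'
#' @param tree a `morph_tree`.
#' @param config a `gen_config` (its `screen` ranges are used).
#' @return list with `pass` (logical) and `reasons` (character vector of
#'   failed checks, empty when passing).
#' @export
screen <- function(tree, config) {
  sc <- config$screen
  br <- tree_branches(tree)$branch
  nbif <- sum(vapply(br$daughters, length, 1L) == 2L)
  axes <- tip_axes(tree)
  reasons <- character(0)
  if (nbif < sc$bif_min || nbif > sc$bif_max) reasons <- c(reasons, "bifurcation_count")
  if (axes[1] < sc$major_min || axes[1] > sc$major_max) reasons <- c(reasons, "major_axis")
  if (axes[2] < sc$minor_min || axes[2] > sc$minor_max) reasons <- c(reasons, "minor_axis")
  list(pass = length(reasons) == 0L, reasons = reasons,
       n_bifurcations = nbif, axes = axes)
}

#' Rescale a morphology in x and z to target ellipse axes
#'
#' Affine scaling of the x and z coordinates only, so that the major and
#' minor axes of the tip-projection ellipse equal the targets; y is
#' untouched. Assumes a registered frame (major axis along x).
#'
#' @param tree a registered `morph_tree`.
#' @param target_major,target_minor target semi-axis lengths, um.
#' @return the rescaled `morph_tree`.
#' @export
rescale_xz <- function(tree, target_major, target_minor) {
  axes <- tip_axes(tree)
  if (any(axes <= 0)) stop("degenerate tip ellipse: cannot rescale")
  nd <- tree$nodes
  nd$x <- nd$x * target_major / axes[1]
  nd$z <- nd$z * target_minor / axes[2]
  out <- morph_tree(nd, validate = FALSE)
  attributes(out)[c("boundary", "n_stems")] <- attributes(tree)[c("boundary", "n_stems")]
  out
}

#' Generate a screened population of morphologies
#'
#' Repeats grow + screen until `n` morphologies pass. In homogeneous mode
#' the branching-rate curve is replaced by its mean over bins (the control
#' comparator). Morphologies failing only the ellipse-axis checks are
#' rescaled to the midpoints of the configured ranges and re-screened.
#'
#' @param config a `gen_config`.
#' @param n number of passing morphologies to return.
#' @param mode "heterogeneous" (default) or "homogeneous".
#' @param seed optional RNG seed for reproducibility.
#' @return list with `trees`, `attempts`, `pass_fraction`, `mode` and (in
#'   homogeneous mode) `rate_constant`, the mean per-um rate used.
#' @export
generate_population <- function(config, n, mode = c("heterogeneous", "homogeneous"),
                                seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  rate_override <- NULL
  rate_constant <- NA_real_
  if (mode == "homogeneous") {
    if (inherits(config$rate, "rate_estimate")) {
      # flatten the curve to its mean over bins, on the same axis
      rate_override <- config$rate
      rate_override$lambda <- rep(mean(config$rate$lambda), config$rate$K)
      rate_constant <- mean(config$rate$lambda) / config$rate$delta
    } else {
      rate_constant <- mean(config$rate)
      rate_override <- rate_constant
    }
  }
  trees <- vector("list", n)
  got <- 0L; attempts <- 0L
  sc <- config$screen
  while (got < n) {
    attempts <- attempts + 1L
    tr <- grow(config, rate_override)
    s <- screen(tr, config)
    if (!s$pass && !("bifurcation_count" %in% s$reasons) &&
        all(tip_axes(tr) > 0) && is.finite(sc$major_max) && is.finite(sc$minor_max)) {
      tr <- rescale_xz(tr, (sc$major_min + sc$major_max) / 2,
                       (sc$minor_min + sc$minor_max) / 2)
      s <- screen(tr, config)
    }
    if (s$pass) { got <- got + 1L; trees[[got]] <- tr }
    if (attempts >= 1000L && got / attempts < 0.01) {
      stop("screening pass rate below 1% after ", attempts,
           " attempts (", got, " passed); check config ranges")
    }
  }
  list(trees = trees, attempts = attempts, pass_fraction = got / attempts,
       mode = mode, rate_constant = rate_constant)
}
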