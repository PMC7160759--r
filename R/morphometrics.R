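assert_registered <- function(tree) {
  soma <- tree$nodes[tree$nodes$parent == -1L, c("x", "y", "z")]
  if (max(abs(as.numeric(soma))) > 1e-6) {
    stop("tree is not registered (soma not at the origin); call register() first")
  }
  invisible(tree)
}

#' Measure the morphometric set of one or more morphologies
#'
#' Computes, per tree: number of bifurcations, total dendritic length
#' (TDL), width (x-extent) and depth (z-extent) of the registered frame,
#' and maximum branch order; pooled over trees: branch pathlengths, branch
#' orders, bifurcation amplitudes and azimuths.
#'
#' @param trees a registered `morph_tree` or list of them.
#' @return object of class `morphometric_set`: `per_tree` data.frame and
#'   pooled value vectors `branch_pathlength`, `branch_order`,
#'   `amplitude`, `azimuth`.
#' @export
measure <- function(trees) {
  if (inherits(trees, "morph_tree")) trees <- list(trees)
  lapply(trees, assert_registered)
  per <- vector("list", length(trees))
  bl <- ord <- amp <- azi <- list()
  for (i in seq_along(trees)) {
    tr <- trees[[i]]
    br <- tree_branches(tr)$branch
    nbif <- sum(vapply(br$daughters, length, 1L) == 2L)
    tdl <- sum(br$pathlength)
    nd <- tr$nodes
    per[[i]] <- data.frame(tree = i, n_bifurcations = nbif, tdl = tdl,
                           width = diff(range(nd$x)), depth = diff(range(nd$z)),
                           max_order = max(br$order), n_stems = sum(br$order == 0L))
    bl[[i]] <- br$pathlength
    ord[[i]] <- br$order
    if (nbif > 0) {
      g <- bifurcation_geometry(tr)
      amp[[i]] <- g$amplitude; azi[[i]] <- g$azimuth
    }
  }
  structure(list(per_tree = do.call(rbind, per),
                 branch_pathlength = unlist(bl), branch_order = unlist(ord),
                 amplitude = unlist(amp), azimuth = unlist(azi)),
            class = "morphometric_set")
}

#' Sholl analysis
#'
#' Counts intersections between the morphology and concentric spheres
#' centred at the soma. Each straight compartment segment contributes the
#' exact number of its geometric crossings of the sphere (0, 1 or 2;
#' tangency counts once); a crossing at a shared vertex is attributed to
#' the downstream segment only.
#'
#' @param tree a `morph_tree` (centred at the soma; registration not
#'   required since the profile is rotation invariant).
#' @param radii increasing vector of sphere radii, um. Default: 10 um
#'   steps from 10 to the maximum tip distance.
#' @return data.frame with `radius` and `crossings`.
#' @export
sholl <- function(tree, radii = NULL) {
  nd <- tree$nodes
  soma <- as.numeric(nd[nd$parent == -1L, c("x", "y", "z")])
  xyz <- sweep(node_xyz(tree), 2, soma)
  idx <- seq_len(nrow(nd)); names(idx) <- nd$id
  ch <- which(nd$parent != -1L)
  pa <- idx[as.character(nd$parent[ch])]
  p0 <- xyz[pa, , drop = FALSE]
  dvec <- xyz[ch, , drop = FALSE] - p0
  a <- rowSums(dvec^2)
  b <- 2 * rowSums(p0 * dvec)
  c0 <- rowSums(p0^2)
  if (is.null(radii)) {
    rmax <- sqrt(max(rowSums(xyz^2)))
    radii <- seq(10, max(10, ceiling(rmax / 10) * 10), by = 10)
  }
  if (is.unsorted(radii)) stop("radii must be increasing")
  crossings <- vapply(radii, function(r) {
    cc <- c0 - r^2
    disc <- b^2 - 4 * a * cc
    n <- integer(length(a))
    ok <- disc >= 0 & a > 0
    sq <- sqrt(pmax(0, disc[ok]))
    t1 <- (-b[ok] - sq) / (2 * a[ok])
    t2 <- (-b[ok] + sq) / (2 * a[ok])
    tang <- disc[ok] < 1e-12 * (a[ok] * r^2 + 1)
    n[ok] <- (t1 >= 0 & t1 < 1) + (!tang & t2 >= 0 & t2 < 1)
    sum(n)
  }, 1L)
  data.frame(radius = radii, crossings = crossings)
}

#' Column-normalized conditional 2D histogram
#'
#' Bins paired (condition, value) samples on a 2D grid and normalizes each
#' condition column to unit mass, yielding the conditional probability
#' mass function of the value given the condition bin.
#'
#' @param condition,value paired sample vectors.
#' @param cond_breaks,value_breaks bin edges.
#' @return list with `table` (rows = value bins, columns = condition
#'   bins), the break vectors, and `empty_cols` flags for condition bins
#'   with no samples (their columns are all zero).
#' @export
conditional_heatmap <- function(condition, value, cond_breaks, value_breaks) {
  stopifnot(length(condition) == length(value), length(condition) >= 1)
  ic <- findInterval(condition, cond_breaks, rightmost.closed = TRUE)
  iv <- findInterval(value, value_breaks, rightmost.closed = TRUE)
  nc <- length(cond_breaks) - 1L; nv <- length(value_breaks) - 1L
  keep <- ic >= 1 & ic <= nc & iv >= 1 & iv <= nv
  tab <- matrix(0, nv, nc)
  for (k in which(keep)) tab[iv[k], ic[k]] <- tab[iv[k], ic[k]] + 1
  colsum <- colSums(tab)
  empty <- colsum == 0
  tab[, !empty] <- sweep(tab[, !empty, drop = FALSE], 2, colsum[!empty], "/")
  list(table = tab, cond_breaks = cond_breaks, value_breaks = value_breaks,
       empty_cols = empty)
}

#' Root-mean-squared error between two binned distributions
#'
#' Both sample vectors are binned on the shared edges and normalized to
#' probability mass per bin; the result is the square root of the mean
#' squared per-bin mass difference.
#'
#' @param a,b numeric sample vectors.
#' @param breaks shared bin edges covering both samples.
#' @return the RMSE (dimensionless).
#' @export
distribution_rmse <- function(a, b, breaks) {
  pa <- norm_hist(a, breaks); pb <- norm_hist(b, breaks)
  sqrt(mean((pa - pb)^2))
}

#' Shared Freedman-Diaconis bin edges for distribution comparison
#' @param reference pooled reference sample defining the binning
#' @param extend range padding fraction (default 5%)
#' @return vector of bin edges spanning the padded reference range
#' @export
fd_breaks <- function(reference, extend = 0.05) {
  r <- range(reference)
  pad <- max(diff(r), 1e-9) * extend
  n <- max(1L, grDevices::nclass.FD(reference))
  seq(r[1] - pad, r[2] + pad, length.out = n + 1L)
}

# apportion segment lengths to bins along an axis coordinate given start
# and end coordinates per segment
apportion_length <- function(c0, c1, len, breaks) {
  nb <- length(breaks) - 1L
  out <- numeric(nb)
  lo <- pmin(c0, c1); hi <- pmax(c0, c1)
  for (s in seq_along(len)) {
    if (hi[s] - lo[s] < 1e-12) {
      b <- findInterval(lo[s], breaks, rightmost.closed = TRUE)
      if (b >= 1 && b <= nb) out[b] <- out[b] + len[s]
      next
    }
    dens <- len[s] / (hi[s] - lo[s])
    b0 <- max(1L, findInterval(lo[s], breaks, rightmost.closed = TRUE))
    b1 <- min(nb, findInterval(hi[s], breaks, rightmost.closed = TRUE))
    if (b1 < b0) next
    for (b in b0:b1) {
      ov <- min(hi[s], breaks[b + 1L]) - max(lo[s], breaks[b])
      if (ov > 0) out[b] <- out[b] + dens * ov
    }
  }
  out
}

#' Dendritic length as a function of distance from the soma
#'
#' Accumulates dendritic length per distance bin (segments apportioned to
#' bins by linear overlap), normalizes to a probability density, and
#' returns the running cumulative distribution.
#'
#' @param trees a registered `morph_tree` or list of them.
#' @param axis "y" (height above the soma) or "pathlength" (arc distance
#'   from the soma).
#' @param breaks bin edges, um; default 20 equal bins over the data range.
#' @return list with `breaks`, `mid`, `mass` (fraction of TDL per bin),
#'   `pdf` (density per um, integrates to 1), `cdf`, and `tdl` (um).
#' @export
tdl_by_distance <- function(trees, axis = c("y", "pathlength"), breaks = NULL) {
  axis <- match.arg(axis)
  if (inherits(trees, "morph_tree")) trees <- list(trees)
  segs <- lapply(trees, tree_segments)
  all <- do.call(rbind, segs)
  if (axis == "y") { c0 <- all$y0; c1 <- all$y1 } else { c0 <- all$d0; c1 <- all$d1 }
  if (is.null(breaks)) {
    breaks <- seq(min(0, c0, c1), max(c0, c1) + 1e-9, length.out = 21L)
  }
  per_bin <- apportion_length(c0, c1, all$len, breaks)
  tdl <- sum(all$len)
  mass <- per_bin / tdl
  list(breaks = breaks, mid = (breaks[-1] + breaks[-length(breaks)]) / 2,
       mass = mass, pdf = mass / diff(breaks), cdf = cumsum(mass), tdl = tdl)
}

#' Dendritic length per anatomical layer
#'
#' Splits the span from the soma (y = 0) to the boundary into layers
#' (default thirds, the molecular-layer convention) and sums the dendritic
#' length falling in each; material above the boundary or below the soma
#' is excluded.
#'
#' @param tree a registered `morph_tree`.
#' @param boundary_length soma-to-boundary distance along y, um.
#' @param layer_fractions positive fractions partitioning (0, 1].
#' @return named numeric vector of per-layer dendritic length, um.
#' @export
tdl_per_layer <- function(tree, boundary_length,
                          layer_fractions = rep(1 / 3, 3)) {
  if (abs(sum(layer_fractions) - 1) > 1e-9) {
    stop("layer_fractions must sum to 1")
  }
  edges <- boundary_length * cumsum(c(0, layer_fractions))
  seg <- tree_segments(tree)
  out <- apportion_length(seg$y0, seg$y1, seg$len, edges)
  names(out) <- paste0("layer", seq_along(out))
  out
}
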