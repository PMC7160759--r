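# rotation matrix taking unit vector a onto unit vector b (Rodrigues)
rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
  c_ <- sum(a * b)
  s <- sqrt(sum(v^2))
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    # opposite vectors: rotate pi about any axis orthogonal to a
    w <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    w <- w - sum(w * a) * a; w <- w / sqrt(sum(w^2))
    return(2 * outer(w, w) - diag(3))
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx * ((1 - c_) / s^2)
}

rotation_about_y <- function(theta) {
  matrix(c(cos(theta), 0, -sin(theta),
           0, 1, 0,
           sin(theta), 0, cos(theta)), 3, 3)
}

#' Minimum-area enclosing ellipse (Khachiyan's algorithm)
#'
#' @param pts n x 2 matrix of points.
#' @param tol convergence tolerance on the barycentric update.
#' @return list with `center` (length 2), `shape` (2 x 2 matrix A such that
#'   the ellipse is (p-c)' A (p-c) <= 1), `axes` (major, minor semi-axis
#'   lengths) and `major_dir` (unit 2-vector of the major axis).
#' @export
enclosing_ellipse <- function(pts, tol = 1e-10) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  if (n < 2L) stop("need at least 2 points for an enclosing ellipse")
  # center and normalize for conditioning; undo at the end
  mid <- colMeans(pts)
  W <- sweep(pts, 2, mid)
  scl <- max(abs(W), 1e-12)
  W <- W / scl
  # rank-deficient or near-collinear clouds: inflate by a sliver so the
  # Khachiyan iteration stays numerically stable
  ev <- eigen(stats::cov(W), symmetric = TRUE, only.values = TRUE)$values
  jitter_needed <- n < 3L || ev[2] < 1e-8 * max(ev[1], 1e-12)
  P <- if (jitter_needed) {
    eps <- 1e-4
    rbind(W + matrix(c(eps, 0), n, 2, byrow = TRUE),
          W - matrix(c(eps, 0), n, 2, byrow = TRUE),
          W + matrix(c(0, eps), n, 2, byrow = TRUE),
          W - matrix(c(0, eps), n, 2, byrow = TRUE))
  } else W
  m <- nrow(P)
  Q <- t(cbind(P, 1))                      # 3 x m lifted points
  u <- rep(1 / m, m)
  for (iter in 1:20000) {
    X <- Q %*% (u * t(Q))                  # 3 x 3
    M <- colSums(Q * solve(X, Q))          # Mahalanobis distances
    j <- which.max(M)
    step <- (M[j] - 3) / (3 * (M[j] - 1))
    if (step < tol) break
    u <- (1 - step) * u
    u[j] <- u[j] + step
  }
  center <- drop(t(P) %*% u)
  S <- t(P) %*% (u * P) - outer(center, center)
  A <- solve(S) / 2                        # (p-c)' A (p-c) <= 1
  e <- eigen(A, symmetric = TRUE)
  axes <- scl / sqrt(e$values)             # back on the original scale
  ord <- order(axes, decreasing = TRUE)
  major_dir <- e$vectors[, ord[1]]
  if (major_dir[1] < 0) major_dir <- -major_dir  # tie-break toward +x half-plane
  list(center = mid + scl * center,
       shape = solve(S) / 2 / scl^2,
       axes = axes[ord], major_dir = major_dir)
}

# measure ellipse axes of tip projections onto the xz-plane
tip_ellipse <- function(tree) {
  nd <- tree$nodes
  tips <- nd[nd$id %in% tip_ids(tree) & nd$parent != -1L, ]
  enclosing_ellipse(cbind(tips$x, tips$z))
}

#' Register a morphology to the standard coordinate frame
#'
#' Translates the soma to the origin, rotates the central axis (the mean of
#' the unit vectors from the soma to each dendritic tip) onto +y, then
#' rotates about y so the major axis of the smallest-area ellipse enclosing
#' the tip projections on the xz-plane lies along x (major axis pointing
#' into the +x half-plane). The transform is rigid, so all pairwise
#' distances are preserved.
#'
#' @param tree a `morph_tree` with at least one terminal compartment.
#' @return the registered `morph_tree`.
#' @export
register <- function(tree) {
  nd <- tree$nodes
  soma <- as.numeric(nd[nd$parent == -1L, c("x", "y", "z")])
  xyz <- sweep(node_xyz(tree), 2, soma)
  tips <- which(nd$id %in% setdiff(nd$id, nd$parent) & nd$parent != -1L)
  if (!length(tips)) stop("tree has no terminals")
  tv <- xyz[tips, , drop = FALSE]
  norms <- sqrt(rowSums(tv^2))
  if (all(norms < 1e-9)) stop("degenerate tree: all tips coincide with the soma")
  units <- tv[norms > 1e-9, , drop = FALSE] / norms[norms > 1e-9]
  axis <- colMeans(units)
  if (sqrt(sum(axis^2)) < 1e-9) {
    stop("degenerate tree: terminal directions cancel, central axis undefined")
  }
  axis <- axis / sqrt(sum(axis^2))
  # snap: an already-aligned axis stays put exactly (idempotence)
  if (acos(min(1, max(-1, axis[2]))) > 1e-8) {
    xyz <- xyz %*% t(rotation_between(axis, c(0, 1, 0)))
  }
  # orient the major axis of the tip-projection ellipse along +x
  proj <- xyz[tips, c(1, 3), drop = FALSE]
  if (nrow(proj) >= 2L && max(dist(proj)) > 1e-9) {
    el <- enclosing_ellipse(proj)
    md <- el$major_dir
    theta <- atan2(md[2], md[1])   # angle of major axis in the xz-plane
    # rotation_about_y(phi) decreases the atan2(z, x) angle by phi, so
    # applying +theta zeroes the major-axis angle
    if (abs(theta) > 1e-8) xyz <- xyz %*% t(rotation_about_y(theta))
  }
  nd$x <- xyz[, 1]; nd$y <- xyz[, 2]; nd$z <- xyz[, 3]
  morph_tree(nd, validate = FALSE)
}
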