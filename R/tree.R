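#' Construct a dendritic tree from a compartment table
#'
#' A `morph_tree` is the package's central container: a rooted tree of point
#' compartments, each with a 3D position (micrometres), a radius and an SWC
#' type code. The soma is the single root compartment (parent `-1`); every
#' other compartment has exactly one parent. After branch decomposition the
#' tree must be binary: any branching node other than the soma has exactly
#' two daughters.
#'
#' @param nodes data.frame with columns `id`, `type`, `x`, `y`, `z`,
#'   `radius`, `parent`. Ids must be unique positive integers; `parent` is
#'   `-1` for the root and otherwise refers to an id appearing earlier in
#'   the table.
#' @param validate logical; run structural validation (default `TRUE`).
#' @return object of class `morph_tree`.
#' @export
morph_tree <- function(nodes, validate = TRUE) {
  required <- c("id", "type", "x", "y", "z", "radius", "parent")
  if (!all(required %in% names(nodes))) {
    stop("nodes must have columns: ", paste(required, collapse = ", "))
  }
  nodes <- as.data.frame(nodes)[, required]
  nodes$id <- as.integer(nodes$id)
  nodes$parent <- as.integer(nodes$parent)
  tree <- structure(list(nodes = nodes), class = "morph_tree")
  if (validate) validate_tree(tree)
  tree
}

#' Validate the structural invariants of a tree
#'
#' Checks id uniqueness, a single root, acyclicity/connectedness (parents
#' precede children after topological ordering), positive radii, and the
#' binary-branching rule (non-soma nodes have at most two daughters).
#'
#' @param tree a `morph_tree`.
#' @return the tree, invisibly; stops with an informative error otherwise.
#' @export
validate_tree <- function(tree) {
  nd <- tree$nodes
  if (anyDuplicated(nd$id)) stop("duplicate compartment ids")
  roots <- which(nd$parent == -1L)
  if (length(roots) != 1L) stop("tree must have exactly one root, found ", length(roots))
  if (any(nd$radius <= 0)) stop("all radii must be positive")
  known <- match(nd$parent, nd$id)
  bad <- which(nd$parent != -1L & (is.na(known) | known >= seq_len(nrow(nd))))
  if (length(bad)) {
    stop("structure error: compartment id ", nd$id[bad[1]],
         " has parent ", nd$parent[bad[1]],
         " that is undefined or defined later (cycle or orphan)")
  }
  # binary rule applies to branch points away from the soma
  tab <- table(nd$parent[nd$parent != -1L])
  root_id <- nd$id[roots]
  nonroot <- tab[names(tab) != as.character(root_id)]
  if (any(nonroot > 2L)) {
    stop("non-binary branching: compartment ", names(nonroot)[which(nonroot > 2L)[1]],
         " has ", max(nonroot), " daughters")
  }
  invisible(tree)
}

#' @export
print.morph_tree <- function(x, ...) {
  b <- tree_branches(x)
  cat(sprintf(
    "morph_tree: %d compartments, %d stems, %d bifurcations, %d tips, TDL %.1f um\n",
    nrow(x$nodes), sum(b$branch$order == 0L),
    sum(vapply(b$branch$daughters, length, 1L) == 2L),
    sum(vapply(b$branch$daughters, length, 1L) == 0L),
    sum(b$branch$pathlength)))
  invisible(x)
}

root_id <- function(tree) tree$nodes$id[tree$nodes$parent == -1L]

children_map <- function(tree) {
  nd <- tree$nodes
  split(nd$id[nd$parent != -1L], factor(nd$parent[nd$parent != -1L], levels = nd$id))
}

node_xyz <- function(tree) as.matrix(tree$nodes[, c("x", "y", "z")])

#' Decompose a tree into unbranched branches
#'
#' A branch runs from the soma or a bifurcation to the next bifurcation or
#' tip. Branch order counts bifurcations between the soma and the branch
#' (stems have order 0). Pathlength is the summed Euclidean length of the
#' member segments; `path_from_soma` is the cumulative pathlength at the
#' branch start.
#'
#' @param tree a `morph_tree`.
#' @return list with `branch`, a data.frame-like list of branch records
#'   (`node_ids`, `parent_branch`, `daughters`, `order`, `pathlength`,
#'   `path_from_soma`, start/end diameters), indexed by branch number.
#' @export
tree_branches <- function(tree) {
  nd <- tree$nodes
  idx <- seq_len(nrow(nd))
  names(idx) <- nd$id
  kids <- children_map(tree)
  root <- root_id(tree)
  xyz <- node_xyz(tree)

  seg_len <- function(a, b) sqrt(sum((xyz[idx[as.character(a)], ] - xyz[idx[as.character(b)], ])^2))

  branches <- list()
  # stack entries: (start node id, parent branch index, order, pathlength so far)
  stack <- lapply(kids[[as.character(root)]], function(cid)
    list(start = cid, from = root, parent = NA_integer_, order = 0L, dist = 0))
  while (length(stack)) {
    fr <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    ids <- fr$from
    cur <- fr$start
    plen <- 0
    repeat {
      plen <- plen + seg_len(ids[length(ids)], cur)
      ids <- c(ids, cur)
      ch <- kids[[as.character(cur)]]
      if (is.null(ch) || length(ch) != 1L) break
      cur <- ch
    }
    bi <- length(branches) + 1L
    ch <- kids[[as.character(cur)]]
    branches[[bi]] <- list(
      node_ids = ids, parent_branch = fr$parent, daughters = integer(0),
      order = fr$order, pathlength = plen, path_from_soma = fr$dist,
      start_diam = 2 * nd$radius[idx[as.character(ids[2])]],
      end_diam = 2 * nd$radius[idx[as.character(cur)]])
    if (!is.na(fr$parent)) {
      branches[[fr$parent]]$daughters <- c(branches[[fr$parent]]$daughters, bi)
    }
    if (length(ch) >= 2L) {
      for (cid in rev(ch)) {
        stack[[length(stack) + 1L]] <- list(start = cid, from = cur,
          parent = bi, order = fr$order + 1L, dist = fr$dist + plen)
      }
    }
  }
  list(branch = list(
    node_ids = lapply(branches, `[[`, "node_ids"),
    parent_branch = vapply(branches, `[[`, 1L, "parent_branch"),
    daughters = lapply(branches, `[[`, "daughters"),
    order = vapply(branches, `[[`, 1L, "order"),
    pathlength = vapply(branches, `[[`, 1, "pathlength"),
    path_from_soma = vapply(branches, `[[`, 1, "path_from_soma"),
    start_diam = vapply(branches, `[[`, 1, "start_diam"),
    end_diam = vapply(branches, `[[`, 1, "end_diam")))
}

#' Enumerate terminal paths
#'
#' A terminal path is the ordered branch sequence from the soma to one
#' dendritic tip; paths through shared branches share those prefixes.
#'
#' @param tree a `morph_tree`.
#' @return list of paths; each has `branches` (branch indices into
#'   [tree_branches()]), `total_pathlength` (um) and `bif_dists`, the
#'   pathlengths from the soma at which the path's bifurcations occur.
#' @export
terminal_paths <- function(tree) {
  br <- tree_branches(tree)$branch
  tips <- which(vapply(br$daughters, length, 1L) == 0L)
  lapply(tips, function(ti) {
    seq <- ti
    while (!is.na(br$parent_branch[seq[1]])) seq <- c(br$parent_branch[seq[1]], seq)
    # bifurcations occur at the ends of non-terminal member branches
    ends <- cumsum(br$pathlength[seq])
    list(branches = seq,
         total_pathlength = ends[length(ends)],
         bif_dists = if (length(seq) > 1L) ends[-length(ends)] else numeric(0))
  })
}

#' Pathlength distances of every compartment from the soma
#' @param tree a `morph_tree`
#' @return numeric vector aligned with `tree$nodes`, soma = 0
#' @export
path_distances <- function(tree) {
  nd <- tree$nodes
  idx <- seq_len(nrow(nd)); names(idx) <- nd$id
  xyz <- node_xyz(tree)
  d <- numeric(nrow(nd))
  for (i in seq_len(nrow(nd))) {
    if (nd$parent[i] == -1L) { d[i] <- 0; next }
    pi <- idx[as.character(nd$parent[i])]
    d[i] <- d[pi] + sqrt(sum((xyz[i, ] - xyz[pi, ])^2))
  }
  d
}

# segment table: one row per parent-child edge, with endpoint coordinates
# and pathlength distances from the soma at both ends
tree_segments <- function(tree) {
  nd <- tree$nodes
  idx <- seq_len(nrow(nd)); names(idx) <- nd$id
  d <- path_distances(tree)
  ch <- which(nd$parent != -1L)
  pa <- idx[as.character(nd$parent[ch])]
  data.frame(
    x0 = nd$x[pa], y0 = nd$y[pa], z0 = nd$z[pa],
    x1 = nd$x[ch], y1 = nd$y[ch], z1 = nd$z[ch],
    d0 = d[pa], d1 = d[ch],
    len = sqrt((nd$x[ch] - nd$x[pa])^2 + (nd$y[ch] - nd$y[pa])^2 +
                 (nd$z[ch] - nd$z[pa])^2))
}

tip_ids <- function(tree) {
  nd <- tree$nodes
  setdiff(nd$id, nd$parent)
}
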