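#' Read an SWC reconstruction file
#'
#' Parses the standard 7-column SWC dialect (id, type, x, y, z, radius,
#' parent), with `#` comment lines. Coordinates and radii are in
#' micrometres; ids are 1-based and the root has parent `-1`. Multi-point
#' somata are not supported: the root must be a single compartment.
#'
#' @param path path to an SWC file.
#' @return a validated [morph_tree()].
#' @export
read_swc <- function(path) {
  if (!file.exists(path)) stop("SWC file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (!length(keep)) stop("no SWC records in ", path)
  rows <- vector("list", length(keep))
  for (j in seq_along(keep)) {
    f <- strsplit(trimws(lines[keep[j]]), "\\s+")[[1]]
    if (length(f) != 7L) {
      stop("malformed SWC line ", keep[j], " in ", path,
           ": expected 7 fields, found ", length(f))
    }
    v <- suppressWarnings(as.numeric(f))
    if (anyNA(v)) stop("malformed SWC line ", keep[j], " in ", path, ": non-numeric field")
    rows[[j]] <- v
  }
  m <- do.call(rbind, rows)
  nodes <- data.frame(id = as.integer(m[, 1]), type = as.integer(m[, 2]),
                      x = m[, 3], y = m[, 4], z = m[, 5],
                      radius = m[, 6], parent = as.integer(m[, 7]))
  morph_tree(nodes)
}

#' Write a tree to an SWC file
#'
#' Compartments are renumbered 1..n in an order in which every parent
#' precedes its children; type codes pass through unmodified.
#'
#' @param tree a `morph_tree`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(tree, path) {
  validate_tree(tree)
  nd <- tree$nodes
  newid <- seq_len(nrow(nd)); names(newid) <- nd$id
  parent <- ifelse(nd$parent == -1L, -1L, newid[as.character(nd$parent)])
  txt <- sprintf("%d %d %.6f %.6f %.6f %.6f %d",
                 newid, nd$type, nd$x, nd$y, nd$z, nd$radius, parent)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# id type x y z radius parent", txt), con)
  invisible(path)
}
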