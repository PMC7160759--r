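#' Encode terminal paths as discretized point processes
#'
#' Each terminal path (soma to tip) is divided into bins of width delta; a
#' bin holds a 1 iff a bifurcation of that path falls inside it. Bins are
#' half-open on the left: bin k covers the pathlength interval
#' ((k-1)*delta, k*delta], so an event at exactly k*delta lands in bin k.
#' The dendritic tip is treated as a bifurcation event and contributes a 1
#' to the final occupied bin of its sequence, so every sequence ends in 1.
#'
#' With `normalize = TRUE` (the default) every path is first rescaled to
#' unit length and the axis is divided into `bins` equal bins, so all
#' sequences share a common length and the tip always falls in the last
#' bin. With `normalize = FALSE` the axis is absolute pathlength in um;
#' sequences of short paths stop contributing beyond their tip bin.
#'
#' @param trees a `morph_tree` or list of them; all terminal paths are
#'   pooled.
#' @param delta bin width in um (absolute axis). Default: half the minimum
#'   inter-event spacing over all paths, floored at 1 um.
#' @param normalize logical; use the normalized per-path axis.
#' @param bins number of bins on the normalized axis (default 100).
#' @return object of class `pp_set`: `events` (R x K 0/1 matrix), `delta`,
#'   `K`, `R`, `N_total`, `tip_bin` (per-sequence index of the final
#'   occupied bin) and `normalized`.
#' @export
encode_point_processes <- function(trees, delta = NULL, normalize = TRUE,
                                   bins = 100L) {
  if (inherits(trees, "morph_tree")) trees <- list(trees)
  paths <- do.call(c, lapply(trees, terminal_paths))
  if (!length(paths)) stop("no terminal paths found")

  ev_pos <- lapply(paths, function(p) sort(c(p$bif_dists, p$total_pathlength)))
  if (normalize) {
    K <- as.integer(bins)
    delta <- 1 / K
    ev_pos <- lapply(seq_along(paths), function(i) ev_pos[[i]] / paths[[i]]$total_pathlength)
  } else {
    if (is.null(delta)) {
      gaps <- unlist(lapply(ev_pos, function(e) diff(c(0, e))))
      delta <- max(1, min(gaps) / 2)
    }
    K <- as.integer(max(ceiling(vapply(paths, `[[`, 1, "total_pathlength") / delta)))
  }

  R <- length(paths)
  events <- matrix(0L, R, K)
  tip_bin <- integer(R)
  for (i in seq_len(R)) {
    b <- pmin(K, pmax(1L, ceiling(ev_pos[[i]] / delta - 1e-12)))
    if (anyDuplicated(b)) {
      stop("delta too large: two events share a bin on terminal path ", i,
           " (inter-event spacing ", signif(min(diff(ev_pos[[i]])), 3), ")")
    }
    events[i, b] <- 1L
    tip_bin[i] <- b[length(b)]
  }
  structure(list(events = events, delta = delta, K = K, R = R,
                 N_total = sum(events), tip_bin = tip_bin,
                 normalized = normalize),
            class = "pp_set")
}

#' Construct a point-process set directly from binary sequences
#'
#' Used by the simulators and tests; applies the same invariants as
#' [encode_point_processes()] (each sequence ends in 1 at its tip bin).
#'
#' @param events R x K matrix of 0/1 event indicators.
#' @param delta bin width.
#' @param tip_bin final occupied bin per sequence; defaults to the last
#'   column for all sequences.
#' @param normalized flag recording the axis convention.
#' @param enforce_tip require a 1 in each sequence's tip bin (the
#'   morphology-encoding convention); disable for raw model simulations.
#' @return a `pp_set`.
#' @export
pp_set <- function(events, delta, tip_bin = NULL, normalized = TRUE,
                   enforce_tip = TRUE) {
  events <- as.matrix(events)
  storage.mode(events) <- "integer"
  if (is.null(tip_bin)) tip_bin <- rep(ncol(events), nrow(events))
  if (enforce_tip &&
      any(events[cbind(seq_len(nrow(events)), tip_bin)] != 1L)) {
    stop("every sequence must end in 1 at its tip bin")
  }
  structure(list(events = events, delta = delta, K = ncol(events),
                 R = nrow(events), N_total = sum(events), tip_bin = tip_bin,
                 normalized = normalized),
            class = "pp_set")
}

#' @export
print.pp_set <- function(x, ...) {
  cat(sprintf("pp_set: R=%d sequences, K=%d bins, delta=%g%s, N=%d events\n",
              x$R, x$K, x$delta, if (x$normalized) " (normalized)" else " um",
              x$N_total))
  invisible(x)
}

# per-bin event counts and number of active (not yet terminated) sequences
pp_sufficient <- function(pp) {
  active <- outer(pp$tip_bin, seq_len(pp$K), `>=`)   # R x K
  list(counts = colSums(pp$events * active),
       n_active = colSums(active))
}
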