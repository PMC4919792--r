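#' @title OPTICS density clustering
#' @description Alternative to the Potts clustering that needs no feature
#'   selection: it orders points by density reachability straight from
#'   Euclidean distances between (by default) the raw aligned waveforms.
#'   Clusters are cut from the reachability profile at `eps`; points that are
#'   not core points at that radius (border samples that do not fully satisfy
#'   the boundary condition) stay unassigned.
#' @name optics
NULL

#' OPTICS clustering with eps-cut extraction
#'
#' @param x an `ss_waveforms`, `ss_features`, or numeric matrix (rows =
#'   points).
#' @param min_samples number of neighbours (excluding the point) within
#'   `eps` required for a core point; also sets the core distance.
#' @param eps cut radius; `NULL` picks twice the median core distance.
#' @return An `ss_clustering` (`method = "optics"`) with attributes
#'   `ordering`, `reachability`, `core_dist`, `eps`.
#' @export
optics_cluster <- function(x, min_samples = 11, eps = NULL) {
  X <- feature_values(x)
  M <- nrow(X)
  if (M < 2) stop_invalid("need at least two points")
  min_samples <- min(as.integer(min_samples), M - 1L)

  dist_to_all <- function(i)
    sqrt(pmax(rowSums(sweep(X, 2, X[i, ])^2), 0))

  core_dist <- numeric(M)
  for (i in seq_len(M)) {
    d <- dist_to_all(i)
    core_dist[i] <- sort(d[-i], partial = min_samples)[min_samples]
  }
  if (is.null(eps)) eps <- 2 * median(core_dist)

  processed <- logical(M)
  reach <- rep(Inf, M)
  ordering <- integer(M)
  pos <- 0L
  seeds <- rep(Inf, M)      # tentative reachability of unprocessed points
  while (pos < M) {
    cand <- which(!processed)
    nxt <- cand[which.min(seeds[cand])]
    if (!is.finite(seeds[nxt])) nxt <- cand[1]  # new density peak / component
    pos <- pos + 1L
    ordering[pos] <- nxt
    reach[nxt] <- seeds[nxt]
    processed[nxt] <- TRUE
    d <- dist_to_all(nxt)
    newreach <- pmax(core_dist[nxt], d)
    upd <- !processed & newreach < seeds
    seeds[upd] <- newreach[upd]
  }

  labels <- integer(M)
  current <- 0L
  for (k in seq_len(M)) {
    p <- ordering[k]
    if (!is.finite(reach[p]) || reach[p] > eps) {
      if (core_dist[p] <= eps) {
        current <- current + 1L
        labels[p] <- current
      }                                    # else: noise
    } else if (core_dist[p] <= eps) {
      labels[p] <- current
    }                                      # non-core border point: unassigned
  }
  # order cluster ids by decreasing size
  if (current > 0) {
    sizes <- table(factor(labels[labels > 0], levels = seq_len(current)))
    remap <- integer(current)
    remap[order(-sizes, seq_len(current))] <- seq_len(current)
    labels[labels > 0] <- remap[labels[labels > 0]]
  }
  out <- cluster_assignment(labels, method = "optics")
  attr(out, "ordering") <- ordering
  attr(out, "reachability") <- reach
  attr(out, "core_dist") <- core_dist
  attr(out, "eps") <- eps
  out
}
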