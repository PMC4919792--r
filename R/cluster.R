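#' @title Super-paramagnetic clustering
#' @description Waveform features are mapped to q-state Potts spins on a
#'   mutual K-nearest-neighbour graph. Interaction strengths decay with
#'   feature distance, so at low temperature the whole graph magnetises (one
#'   cluster), at high temperature spins decorrelate (fragments), and at
#'   intermediate — super-paramagnetic — temperatures dense groups of
#'   waveforms align while weakly coupled groups do not. Clusters are the
#'   connected components of edges whose spin-spin correlation exceeds a
#'   threshold; components below a minimum size stay unassigned (label 0),
#'   which is where overlapping spikes collect.
#' @name cluster
NULL

#' SPC configuration
#'
#' @param q_states number of Potts states (>= 2).
#' @param knn_K neighbourhood size of the mutual K-nearest-neighbour graph.
#' @param temperatures strictly increasing temperature grid.
#' @param sweeps Monte-Carlo (Swendsen-Wang) sweeps averaged per temperature;
#'   one fifth as many extra sweeps are discarded as burn-in.
#' @param correlation_threshold spin-spin correlation above which an edge
#'   links its endpoints into one cluster, in (0, 1).
#' @param min_cluster_size components smaller than this become unassigned.
#' @param seed integer seed for the Monte-Carlo updates.
#' @return list of class `ss_spc_config`.
#' @export
spc_config <- function(q_states = 20, knn_K = 11,
                       temperatures = seq(0, 0.25, by = 0.01),
                       sweeps = 500, correlation_threshold = 0.5,
                       min_cluster_size = 60, seed = 42) {
  if (q_states < 2) stop_invalid("q_states must be >= 2")
  if (is.unsorted(temperatures, strictly = TRUE))
    stop_invalid("temperatures must be strictly increasing")
  if (correlation_threshold <= 0 || correlation_threshold >= 1)
    stop_invalid("correlation_threshold must lie in (0, 1)")
  structure(list(q_states = as.integer(q_states), knn_K = as.integer(knn_K),
                 temperatures = as.numeric(temperatures),
                 sweeps = as.integer(sweeps),
                 correlation_threshold = correlation_threshold,
                 min_cluster_size = as.integer(min_cluster_size),
                 seed = as.integer(seed)),
            class = "ss_spc_config")
}

feature_values <- function(fm) {
  if (inherits(fm, "ss_features")) fm$values
  else if (inherits(fm, "ss_waveforms")) fm$waveforms
  else rbind(fm)
}

# Pairwise Euclidean distances from rows of `x` to rows of `y`, chunked.
row_dists <- function(x, y) {
  d2 <- outer(rowSums(x^2), rowSums(y^2), "+") - 2 * tcrossprod(x, y)
  sqrt(pmax(d2, 0))
}

#' Mutual K-nearest-neighbour graph with edge distances
#'
#' An undirected edge joins `i` and `j` when each lies among the other's `K`
#' nearest points (Euclidean distance in feature space). With
#' `K >= M - 1` this is the complete graph.
#'
#' @param fm an `ss_features`, `ss_waveforms`, or numeric matrix (rows =
#'   points).
#' @param K neighbourhood size.
#' @return list of class `ss_knn_graph`: `edges` (2-column index matrix,
#'   `i < j`), `dist` (edge lengths `e_ij`), `n_nodes`, `K`,
#'   `avg_neighbours` (mean degree, the Potts normalisation constant).
#' @export
knn_distances <- function(fm, K = 11) {
  X <- feature_values(fm)
  M <- nrow(X)
  K <- min(as.integer(K), M - 1L)
  if (M < 2) stop_invalid("need at least two points")
  nn <- matrix(0L, M, K)
  chunk <- max(1L, as.integer(2^22 / max(M, 1)))
  for (s in seq(1, M, by = chunk)) {
    e <- min(M, s + chunk - 1L)
    D <- row_dists(X[s:e, , drop = FALSE], X)
    for (r in seq_len(e - s + 1L)) {
      d <- D[r, ]
      d[s + r - 1L] <- Inf
      nn[s + r - 1L, ] <- order(d)[seq_len(K)]
    }
  }
  pairs <- cbind(rep(seq_len(M), each = K), as.vector(t(nn)))
  keyed <- paste(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
  mutual <- keyed[duplicated(keyed)]          # seen from both endpoints
  if (length(mutual)) {
    parts <- do.call(rbind, strsplit(unique(mutual), " "))
    edges <- cbind(as.integer(parts[, 1]), as.integer(parts[, 2]))
    edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
    ed <- sqrt(rowSums((X[edges[, 1], , drop = FALSE] -
                          X[edges[, 2], , drop = FALSE])^2))
  } else {
    edges <- matrix(integer(0), 0, 2)
    ed <- numeric(0)
  }
  structure(list(edges = edges, dist = ed, n_nodes = M, K = K,
                 avg_neighbours = 2 * nrow(edges) / M),
            class = "ss_knn_graph")
}

#' Potts interaction strengths per edge
#'
#' `J_ij = (1 / Khat) exp(-e_ij^2 / (2 a^2))` with `Khat` the average
#' neighbour count and `a` the average edge length: close pairs couple
#' strongly, distant ones barely.
#'
#' @param graph an `ss_knn_graph`.
#' @param q unused by the formula, kept so configurations travel together.
#' @return numeric vector of `J_ij`, ordered like `graph$edges`.
#' @export
interaction_strengths <- function(graph, q = 20) {
  if (!nrow(graph$edges)) return(numeric(0))
  a <- mean(graph$dist)
  if (a == 0) a <- 1
  (1 / max(graph$avg_neighbours, 1)) * exp(-graph$dist^2 / (2 * a^2))
}

#' Swendsen-Wang sweeps over a temperature grid
#'
#' For each temperature, spins are re-initialised and updated by
#' Swendsen-Wang cluster moves for `sweeps` recorded iterations (plus 20%
#' burn-in); `G_ij` is the post-burn-in frequency of equal endpoint spins.
#' At `T = 0` the exact limit (every connected component a single frozen
#' domain, `G = 1`) is returned analytically.
#'
#' @param graph an `ss_knn_graph`.
#' @param J interaction strengths ([interaction_strengths()]).
#' @param cfg an [spc_config()].
#' @return `n_edges x n_temperatures` matrix of correlations in \[0, 1\],
#'   with attribute `temperatures`.
#' @export
spc_sweep <- function(graph, J = interaction_strengths(graph),
                      cfg = spc_config()) {
  burnin <- max(1L, cfg$sweeps %/% 5L)
  G <- spc_sweep_cpp(graph$n_nodes, graph$edges[, 1] - 1L,
                     graph$edges[, 2] - 1L, J, cfg$q_states,
                     cfg$temperatures, cfg$sweeps, burnin, cfg$seed)
  attr(G, "temperatures") <- cfg$temperatures
  G
}

# Union-find connected components over M nodes given an edge matrix.
edge_components <- function(M, edges) {
  parent <- seq_len(M)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(edges)) {
    for (e in seq_len(nrow(edges))) {
      a <- find(edges[e, 1])
      b <- find(edges[e, 2])
      if (a != b) parent[b] <- a
    }
  }
  vapply(seq_len(M), find, integer(1))
}

#' Cluster assignment container
#'
#' @param labels integer per waveform; 0 marks unassigned (putative overlaps
#'   and outliers), 1..C clusters ordered by decreasing size.
#' @param chosen_temperature temperature the labels were read at (NA when not
#'   applicable).
#' @param method text tag.
#' @export
cluster_assignment <- function(labels, chosen_temperature = NA_real_,
                               method = "manual") {
  labels <- as.integer(labels)
  sizes <- as.integer(table(factor(labels[labels > 0],
                                   levels = seq_len(max(labels, 0)))))
  structure(list(labels = labels, sizes = sizes,
                 chosen_temperature = chosen_temperature, method = method),
            class = "ss_clustering")
}

#' @export
print.ss_clustering <- function(x, ...) {
  cat(sprintf("<ss_clustering (%s): %d clusters [%s], %d unassigned%s>\n",
              x$method, length(x$sizes), paste(x$sizes, collapse = ", "),
              sum(x$labels == 0),
              if (is.na(x$chosen_temperature)) ""
              else sprintf(", T = %g", x$chosen_temperature)))
  invisible(x)
}

#' Read clusters off the spin-spin correlations at one temperature
#'
#' Connected components of edges with `G_ij > correlation_threshold`;
#' components smaller than `min_cluster_size` are folded into the unassigned
#' pool (label 0). Cluster ids are ordered by decreasing size.
#'
#' @param G_t numeric vector of per-edge correlations at the chosen
#'   temperature.
#' @param graph the `ss_knn_graph` the correlations refer to.
#' @param cfg an [spc_config()].
#' @param temperature recorded in the result.
#' @return An `ss_clustering`.
#' @export
extract_clusters <- function(G_t, graph, cfg = spc_config(),
                             temperature = NA_real_) {
  keep <- G_t > cfg$correlation_threshold
  comp <- edge_components(graph$n_nodes, graph$edges[keep, , drop = FALSE])
  tab <- table(comp)
  big <- names(tab)[tab >= cfg$min_cluster_size]
  ord <- big[order(-tab[big], as.integer(big))]
  labels <- integer(graph$n_nodes)
  for (k in seq_along(ord)) labels[comp == as.integer(ord[k])] <- k
  cluster_assignment(labels, chosen_temperature = temperature, method = "spc")
}

#' Choose the working temperature from per-temperature cluster structures
#'
#' Deterministic rule: the number of non-trivial clusters traces out phases
#' along the grid — magnetised (classes still fused), super-paramagnetic
#' (classes split apart), shattered (nothing above the size floor). Genuine
#' spike classes persist over a range of temperatures, whereas accidental
#' agglomerations (typically of overlap waveforms) melt after a single grid
#' step, so only cluster counts observed at two or more adjacent
#' temperatures are considered. Among those, the chosen temperature
#' maximises the cluster count — the super-paramagnetic phase — with ties
#' broken towards the most waveforms assigned (the phase's coolest point,
#' before spins leak into the unassigned pool), then towards the lower
#' temperature. Single-blob data therefore resolves at the lowest grid
#' temperature.
#'
#' @param assignments list of `ss_clustering`, one per grid temperature.
#' @param temperatures the grid.
#' @return list with `index` and `temperature`.
#' @export
select_temperature <- function(assignments, temperatures) {
  n_clusters <- vapply(assignments, function(a) length(a$sizes), integer(1))
  assigned <- vapply(assignments, function(a) sum(a$labels > 0L), integer(1))
  nT <- length(n_clusters)
  persistent <- if (nT == 1) TRUE else
    (c(n_clusters[-1], NA) == n_clusters) |
    (c(NA, n_clusters[-nT]) == n_clusters)
  persistent[is.na(persistent)] <- FALSE
  cand <- if (any(persistent)) which(persistent) else seq_len(nT)
  idx <- cand[order(-n_clusters[cand], -assigned[cand], cand)[1]]
  list(index = idx, temperature = temperatures[idx])
}

#' Super-paramagnetic clustering, end to end
#'
#' @param fm an `ss_features` (or matrix of points).
#' @param cfg an [spc_config()].
#' @return An `ss_clustering` with `chosen_temperature` filled in and
#'   attribute `per_temperature` (list of assignments along the grid).
#' @export
spc_cluster <- function(fm, cfg = spc_config()) {
  graph <- knn_distances(fm, cfg$knn_K)
  J <- interaction_strengths(graph, cfg$q_states)
  G <- spc_sweep(graph, J, cfg)
  per_t <- lapply(seq_along(cfg$temperatures), function(ti)
    extract_clusters(G[, ti], graph, cfg, temperature = cfg$temperatures[ti]))
  pick <- select_temperature(per_t, cfg$temperatures)
  out <- per_t[[pick$index]]
  attr(out, "per_temperature") <- per_t
  attr(out, "graph") <- graph
  out
}
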