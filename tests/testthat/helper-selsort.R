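# Shared fixtures and independent oracles for the test suite. Expensive
# simulations are computed once per run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# 10 s, 3 neurons, default rates; one object per (noise, seed)
fixture_sim <- function(noise = 0.05, seed = 3, seconds = 10) {
  cached(sprintf("sim-%g-%d-%d", noise, seed, seconds), {
    simulate_recording(sim_config(duration = seconds * 24000,
                                  noise_level = noise, seed = seed))
  })
}

fixture_events <- function(noise = 0.05, seed = 3, seconds = 10) {
  cached(sprintf("ev-%g-%d-%d", noise, seed, seconds), {
    detect_spikes(fixture_sim(noise, seed, seconds)$recording)
  })
}

# recall/false positives of an event list against all true spikes
score_events <- function(indices, truth, tol) {
  true_all <- sort(unlist(truth$spike_times))
  hit <- vapply(true_all, function(t) any(abs(indices - t) <= tol), logical(1))
  fp <- vapply(indices, function(t) all(abs(true_all - t) > tol), logical(1))
  list(recall = mean(hit), fp = sum(fp), n_true = length(true_all))
}

# Independent lifting-scheme Haar transform (predict/update steps), full
# depth, for cross-checking the matrix implementation.
lifting_haar <- function(x) {
  out <- numeric(0)
  while (length(x) > 1) {
    odd <- x[seq(1, length(x), by = 2)]
    even <- x[seq(2, length(x), by = 2)]
    d <- (even - odd) / sqrt(2)          # predict
    s <- (odd + even) / sqrt(2)          # update
    out <- c(-d, out)                    # detail sign convention: odd - even
    x <- s
  }
  c(x, out)
}

# Independent maximum-cardinality bipartite matching (augmenting paths) of
# spike times a vs b within +/- tol.
max_matching_oracle <- function(a, b, tol) {
  na <- length(a)
  nb <- length(b)
  if (!na || !nb) return(0L)
  adj <- lapply(seq_len(na), function(i) which(abs(b - a[i]) <= tol))
  match_b <- rep(0L, nb)
  try_kuhn <- function(i, visited) {
    for (j in adj[[i]]) {
      if (!visited[j]) {
        visited[j] <- TRUE
        if (match_b[j] == 0L) {
          match_b[j] <<- i
          return(list(TRUE, visited))
        }
        saved <- match_b[j]
        match_b[j] <<- i
        res <- try_kuhn(saved, visited)
        visited <- res[[2]]
        if (res[[1]]) return(list(TRUE, visited))
        match_b[j] <<- saved
      }
    }
    list(FALSE, visited)
  }
  matched <- 0L
  for (i in seq_len(na)) {
    res <- try_kuhn(i, rep(FALSE, nb))
    if (res[[1]]) matched <- matched + 1L
  }
  matched
}

# Small three-blob Gaussian fixture in feature space
three_blob_points <- function(n_per = 80, sep = 12, sd = 1, seed = 99, d = 4) {
  set.seed(seed)
  centres <- rbind(rep(0, d), c(sep, rep(0, d - 1)), c(0, sep, rep(0, d - 2)))
  X <- do.call(rbind, lapply(1:3, function(k)
    matrix(rnorm(n_per * d, sd = sd), ncol = d) +
      matrix(centres[k, ], n_per, d, byrow = TRUE)))
  list(X = X, labels = rep(1:3, each = n_per))
}

# Compact SPC configuration for tests: coarser grid, fewer sweeps
test_spc_config <- function(...) {
  spc_config(temperatures = seq(0, 0.25, by = 0.025), sweeps = 200,
             min_cluster_size = 20, seed = 42, ...)
}
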