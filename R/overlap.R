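#' @title Template estimation and overlap resolution
#' @description The statistical-estimation stage. Clustered spike times give
#'   per-neuron binary impulse trains; Toeplitz least squares on each train
#'   against the raw voltage yields putative templates (lag axis -L..L, peak
#'   at lag 0). Subtracting the templated spikes leaves a residual whose
#'   autocovariance describes the background noise; the centre column of the
#'   (inverse) noise-covariance Toeplitz matrix is a symmetric, wavelet-like
#'   whitening filter. On the whitened trace, every event the clustering
#'   could not place — including superimposed spikes — is scored per neuron
#'   with a matched-filter log likelihood carrying a Bernoulli firing-rate
#'   prior, and accepted spikes are subtracted so a second neuron can win the
#'   same event (prediction and elimination).
#' @name overlap
NULL

#' Per-neuron binary impulse trains from a cluster assignment
#'
#' Clustered waveforms set their event index to 1 in their neuron's train;
#' unassigned waveforms (label 0) become the matching targets.
#'
#' @param assign an `ss_clustering` over the waveforms.
#' @param events the per-waveform event indices (e.g.
#'   `wf$event_indices`), same length as `assign$labels`.
#' @param duration trace length in samples.
#' @return list of class `ss_impulse_trains`: `trains` (list of sorted index
#'   vectors), `targets` (unassigned event indices), `duration`.
#' @export
build_impulse_trains <- function(assign, events, duration) {
  if (inherits(events, "ss_events")) events <- events$indices
  if (length(events) != length(assign$labels))
    stop_invalid("labels (%d) and events (%d) differ in length",
                 length(assign$labels), length(events))
  n <- length(assign$sizes)
  trains <- lapply(seq_len(n), function(k) sort(events[assign$labels == k]))
  structure(list(trains = trains, targets = sort(events[assign$labels == 0]),
                 duration = as.integer(duration)),
            class = "ss_impulse_trains")
}

# Sparse autocorrelation of a binary train at lags 0..maxlag.
train_autocorr <- function(times, maxlag) {
  r <- numeric(maxlag + 1)
  r[1] <- length(times)
  if (length(times) > 1) {
    for (i in seq_len(length(times) - 1)) {
      gaps <- times[(i + 1):length(times)] - times[i]
      gaps <- gaps[gaps <= maxlag]
      if (length(gaps)) r[gaps + 1] <- r[gaps + 1] + 1
      else next
    }
  }
  r
}

#' Putative templates by Toeplitz least squares
#'
#' For each neuron, solves the normal equations of the regression of the
#' voltage on lagged copies of its impulse train: the Toeplitz matrix of the
#' train's autocorrelation against the train-voltage cross-correlation at
#' lags -L..L, via the pseudo-inverse. With isolated spikes this reduces to
#' the plain spike-triggered average; with overlapping spikes the Toeplitz
#' off-diagonals deconvolve the interference.
#'
#' @param rec an `ss_recording` or numeric trace.
#' @param trains an `ss_impulse_trains` (or plain list of index vectors).
#' @param lags half-width `L`; templates span `2L + 1` samples, peak at lag 0.
#' @return list of class `ss_templates`: `templates` (`N x (2L+1)`),
#'   `lags` (`-L..L`), `spike_rates` (spikes/sample), `filtered_templates`
#'   (`NULL` until re-estimated on a whitened trace).
#' @export
estimate_templates <- function(rec, trains, lags = 30) {
  x <- as_samples(rec)
  duration <- if (inherits(trains, "ss_impulse_trains")) trains$duration else length(x)
  tr <- if (inherits(trains, "ss_impulse_trains")) trains$trains else trains
  L <- as.integer(lags)
  P <- 2L * L + 1L
  N <- length(x)
  W <- matrix(0, length(tr), P)
  for (nn in seq_along(tr)) {
    times <- tr[[nn]]
    if (!length(times)) stop_invalid("neuron %d has no spikes to regress on", nn)
    r_auto <- train_autocorr(times, 2L * L)
    Tm <- toeplitz(r_auto[seq_len(P)])
    r_cross <- vapply(-L:L, function(tau) {
      idx <- times + tau
      ok <- idx >= 1 & idx <= N
      sum(x[idx[ok]])
    }, numeric(1))
    W[nn, ] <- tryCatch(as.numeric(solve(Tm, r_cross)),
                        error = function(e) {
                          warning("singular train autocorrelation; pseudo-inverse solve",
                                  call. = FALSE)
                          as.numeric(MASS::ginv(Tm) %*% r_cross)
                        })
  }
  structure(list(templates = W, lags = -L:L,
                 spike_rates = lengths(tr) / duration,
                 filtered_templates = NULL),
            class = "ss_templates")
}

#' @export
print.ss_templates <- function(x, ...) {
  cat(sprintf("<ss_templates: %d neurons, lags %d..%d, rates %s%s>\n",
              nrow(x$templates), min(x$lags), max(x$lags),
              paste(signif(x$spike_rates, 3), collapse = "/"),
              if (is.null(x$filtered_templates)) "" else ", whitened"))
  invisible(x)
}

#' Residual after removing every clustered spike
#'
#' Subtracts each putative template at its clustered indices; what remains is
#' system noise plus the spikes the clustering could not place (which stay
#' visible as residual peaks — exactly the events the matcher targets).
#'
#' @param rec an `ss_recording` or numeric trace.
#' @param templates an `ss_templates`.
#' @param trains an `ss_impulse_trains` or list of index vectors.
#' @return numeric residual, same length as the input.
#' @export
compute_noise_residual <- function(rec, templates, trains) {
  x <- as_samples(rec)
  tr <- if (inherits(trains, "ss_impulse_trains")) trains$trains else trains
  L <- max(templates$lags)
  for (nn in seq_along(tr)) {
    x <- x - place_template(tr[[nn]], templates$templates[nn, ], L + 1L, length(x))
  }
  x
}

#' Biased sample autocovariance of the residual
#'
#' @param v_delta numeric residual trace.
#' @param m number of lags (0..m-1) to return.
#' @return numeric vector `C(0..m-1)` (biased estimator, divisor `T`).
#' @export
noise_autocovariance <- function(v_delta, m = 61) {
  v_delta <- as_samples(v_delta)
  as.numeric(acf(v_delta, lag.max = m - 1, type = "covariance",
                 demean = TRUE, plot = FALSE)$acf)
}

#' Symmetric noise-shaped filter from the autocovariance
#'
#' Builds the `m x m` Toeplitz matrix of the noise autocovariance `C` and
#' takes its centre column — by default of the (ridge-regularised) inverse
#' matrix square root `C^(-1/2)`, the classical symmetric whitening filter.
#' Filtering the voltage through it decorrelates the background, and because
#' templates are then re-estimated on the filtered trace, the subsequent
#' matched-filter product computes the optimal statistic `w' C^-1 v`.
#' `inverse = FALSE` returns the centre column of the covariance matrix
#' itself. Either way the filter is symmetric by construction, unit L2 norm,
#' and reduces to a unit impulse for white noise.
#'
#' @param autocov autocovariance at lags `0..m-1` ([noise_autocovariance()]).
#' @param m filter length (odd); defaults to `length(autocov)`.
#' @param inverse use the inverse square root of the covariance matrix
#'   (whitening) rather than the covariance matrix itself.
#' @param ridge relative ridge added to the eigenvalues before inversion.
#' @return numeric filter of length `m`.
#' @export
coiflet_filter_from_cov <- function(autocov, m = length(autocov),
                                    inverse = TRUE, ridge = 1e-6) {
  m <- as.integer(m)
  if (m %% 2L == 0L) stop_invalid("filter length m must be odd")
  if (m > length(autocov)) stop_invalid("need autocovariance up to lag m-1")
  Tm <- toeplitz(autocov[seq_len(m)])
  centre <- (m + 1L) %/% 2L
  f <- if (inverse) {
    eg <- eigen(Tm, symmetric = TRUE)
    lam <- pmax(eg$values, ridge * max(abs(eg$values)))
    (eg$vectors %*% ((1 / sqrt(lam)) * t(eg$vectors)))[, centre]
  } else {
    Tm[, centre]
  }
  f / sqrt(sum(f^2))
}

#' Zero-phase filtering of the channel through the noise-shaped filter
#'
#' Linear convolution with the symmetric filter, centred so the output is
#' delay-free and the same length as the input.
#'
#' @param rec an `ss_recording` or numeric trace.
#' @param filter odd-length symmetric filter ([coiflet_filter_from_cov()]).
#' @return numeric filtered trace.
#' @export
whiten <- function(rec, filter) {
  x <- as_samples(rec)
  m <- length(filter)
  N <- length(x)
  nfft <- 2^ceiling(log2(N + m))
  y <- Re(fft(fft(c(x, numeric(nfft - N))) *
                fft(c(filter, numeric(nfft - m))), inverse = TRUE)) / nfft
  centre <- (m + 1L) %/% 2L
  y[centre:(centre + N - 1L)]
}

#' Assign unclustered events to neurons by prediction and elimination
#'
#' At each target index the matched-filter log likelihood
#' `L_n = (w_n' v_win - ||w_n||^2 / 2) / sigma^2 + log(p_n / (1 - p_n))`
#' (Gaussian noise of variance `sigma^2`, Bernoulli firing-rate prior) is
#' evaluated for every neuron over a lag scan around the event. Because a
#' near-synchronous overlap pulls the single-template optimum towards a
#' position between the two true spikes — where greedy subtraction then
#' wrecks the second spike — the matcher also scores every two-neuron joint
#' explanation (the pair likelihood carries the template cross-correlation
#' term at the candidate lag difference) and keeps whichever model wins:
#' no spike, one spike, or an eliminated pair. Accepted templates are
#' subtracted from the working trace before later targets are scored. The
#' lag scan spans up to half a template because coalesced overlap
#' events place the secondary spike several samples off the detected peak.
#' Within-neuron inter-spike intervals below the refractory period are
#' rejected. Scoring is restricted to the supplied target indices — never to
#' arbitrary trace maxima.
#'
#' @param v_tilde whitened trace ([whiten()]).
#' @param templates an `ss_templates`; `filtered_templates` (re-estimated on
#'   the whitened trace) are used when present.
#' @param targets unclustered event indices (numeric or `ss_events`).
#' @param refractory minimum within-neuron inter-spike interval, samples.
#' @param existing_trains clustered per-neuron spike times, honoured by the
#'   refractory rule and included in the output trains.
#' @param lag_search half-width of the lag scan around each target, samples.
#' @param threshold acceptance threshold on the log likelihood.
#' @param noise_var Gaussian noise variance of the whitened trace; estimated
#'   robustly (squared MAD) when `NULL`.
#' @return list of class `ss_sort_result`: `trains` (final per-neuron spike
#'   times), `accepted` (data frame: `event`, `time`, `neuron`, `lag`,
#'   `likelihood`, `pass`), `rejected` (unmatched targets), `likelihoods`
#'   (targets x neurons, max over lags before any elimination), `targets`,
#'   `refractory`.
#' @export
match_unclustered <- function(v_tilde, templates, targets, refractory = 60,
                              existing_trains = NULL, lag_search = 30,
                              threshold = 0, noise_var = NULL) {
  v <- as_samples(v_tilde)
  if (inherits(targets, "ss_events")) targets <- targets$indices
  targets <- sort(as.integer(targets))
  W <- if (!is.null(templates$filtered_templates)) templates$filtered_templates
       else templates$templates
  nN <- if (is.null(W)) 0L else nrow(W)
  trains <- existing_trains %||% replicate(nN, numeric(0), simplify = FALSE)
  if (length(trains) != nN) stop_invalid("existing_trains/template count mismatch")
  if (nN == 0L) {
    return(structure(list(trains = list(), accepted = NULL, rejected = targets,
                          likelihoods = NULL, targets = targets,
                          refractory = refractory),
                     class = "ss_sort_result"))
  }
  if (is.null(noise_var)) {
    noise_var <- (median(abs(v - median(v))) / 0.6745)^2
    if (noise_var == 0) noise_var <- max(var(v), .Machine$double.eps)
  }
  L <- max(templates$lags)
  P <- 2L * L + 1L
  p_n <- pmin(pmax(templates$spike_rates, 1e-12), 1 - 1e-12)
  prior <- log(p_n / (1 - p_n))
  energy <- rowSums(W^2) / 2
  N <- length(v)
  shifts <- -lag_search:lag_search
  nS <- length(shifts)
  acc <- list()
  rej <- integer(0)
  lik1 <- matrix(NA_real_, length(targets), nN)
  new_times <- replicate(nN, numeric(0), simplify = FALSE)

  # template cross-correlations at every lag difference the pair search can
  # produce: xcorr[[n1]][[n2]][d + 2*lag_search + 1] = w_n1' shift(w_n2, d)
  dmax <- 2L * lag_search
  tpl_shift_dot <- function(w1, w2, d) {
    if (d >= 0) sum(w1[(1 + d):P] * w2[seq_len(P - d)])
    else sum(w1[seq_len(P + d)] * w2[(1 - d):P])
  }
  xcorr <- lapply(seq_len(nN), function(n1) lapply(seq_len(nN), function(n2)
    vapply(-dmax:dmax, function(d) tpl_shift_dot(W[n1, ], W[n2, ], d),
           numeric(1))))

  inner_products <- function(t0) {
    out <- matrix(0, nN, nS)
    for (si in seq_len(nS)) {
      idx <- (t0 + shifts[si] - L):(t0 + shifts[si] + L)
      ok <- idx >= 1 & idx <= N
      win <- numeric(P)
      win[ok] <- v[idx[ok]]
      out[, si] <- as.numeric(W %*% win)
    }
    out
  }

  for (ti in seq_along(targets)) {
    t0 <- targets[ti]
    ip <- inner_products(t0)
    L_single <- (ip - energy) / noise_var + prior
    lik1[ti, ] <- apply(L_single, 1, max)
    # a neuron with an existing spike within the refractory span of a
    # candidate time is neglected at that lag
    feasible <- matrix(TRUE, nN, nS)
    for (nn in seq_len(nN)) {
      have <- trains[[nn]]
      if (length(have)) {
        for (si in seq_len(nS)) {
          if (min(abs(have - (t0 + shifts[si]))) < refractory)
            feasible[nn, si] <- FALSE
        }
      }
    }
    L1 <- ifelse(feasible, L_single, -Inf)
    b1 <- which(L1 == max(L1), arr.ind = TRUE)[1, ]
    best1 <- L1[b1[1], b1[2]]

    # best joint two-neuron explanation
    best2 <- -Inf
    pair <- NULL
    if (nN >= 2) {
      for (n1 in seq_len(nN - 1)) {
        for (n2 in (n1 + 1):nN) {
          base <- outer(ip[n1, ], ip[n2, ], "+")
          dmat <- outer(shifts, shifts, function(a, b) b - a)
          cross <- matrix(xcorr[[n1]][[n2]][dmat + dmax + 1L],
                          nrow = nS, ncol = nS)
          Lp <- (base - cross - energy[n1] - energy[n2]) / noise_var +
            prior[n1] + prior[n2]
          Lp[!feasible[n1, ], ] <- -Inf
          Lp[, !feasible[n2, ]] <- -Inf
          bb <- which(Lp == max(Lp), arr.ind = TRUE)[1, ]
          if (Lp[bb[1], bb[2]] > best2) {
            best2 <- Lp[bb[1], bb[2]]
            pair <- c(n1, shifts[bb[1]], n2, shifts[bb[2]])
          }
        }
      }
    }

    accept <- list()
    if (is.finite(best2) && best2 > threshold && best2 > best1) {
      accept <- list(c(pair[1], pair[2], best2, 1L), c(pair[3], pair[4], best2, 2L))
    } else if (is.finite(best1) && best1 > threshold) {
      accept <- list(c(b1[1], shifts[b1[2]], best1, 1L))
    }
    if (!length(accept)) {
      rej <- c(rej, t0)
      next
    }
    for (a in accept) {
      nn <- a[1]
      t_new <- t0 + a[2]
      new_times[[nn]] <- c(new_times[[nn]], t_new)
      trains[[nn]] <- sort(c(trains[[nn]], t_new))
      acc[[length(acc) + 1L]] <- data.frame(event = t0, time = t_new,
                                            neuron = nn, lag = a[2],
                                            likelihood = a[3], pass = a[4])
      idx <- (t_new - L):(t_new + L)
      ok <- idx >= 1 & idx <= N
      v[idx[ok]] <- v[idx[ok]] - W[nn, ok]
    }
  }
  final <- lapply(trains, sort)   # clustered plus newly matched, kept in sync
  structure(list(trains = final,
                 accepted = if (length(acc)) do.call(rbind, acc) else NULL,
                 rejected = rej, likelihoods = lik1, targets = targets,
                 refractory = refractory),
            class = "ss_sort_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ss_sort_result <- function(x, ...) {
  cat(sprintf("<ss_sort_result: %d neurons, %s spikes (%d matched, %d rejected targets)>\n",
              length(x$trains), sum(lengths(x$trains)),
              if (is.null(x$accepted)) 0L else nrow(x$accepted),
              length(x$rejected)))
  invisible(x)
}

#' Sort one channel end to end
#'
#' Composition of the whole chain: detect -> extract -> features -> cluster
#' -> templates -> noise model -> whiten -> re-estimate -> match. Every stage
#' output is retained under `$stages` for audit.
#'
#' @param rec an `ss_recording`.
#' @param detect_cfg a [cob_config()].
#' @param cluster_cfg an [spc_config()] (used when `method = "spc"`).
#' @param method `"spc"` or `"optics"`.
#' @param window,align_index,interp_factor waveform extraction controls
#'   ([extract_waveforms()]); the defaults span one full 2.5 ms template so
#'   the discriminative repolarisation trough stays inside the snippet.
#' @param n_features feature-set size ([select_features()]).
#' @param lags template half-width `L`.
#' @param cov_lags whitening-filter length (odd).
#' @param refractory within-neuron refractory period, samples.
#' @return An `ss_sort_result` with an extra `stages` element
#'   (`events`, `waveforms`, `features`, `assignment`, `impulse_trains`,
#'   `templates`, `noise`) and `n_neurons`.
#' @export
sort_channel <- function(rec, detect_cfg = cob_config(),
                         cluster_cfg = spc_config(),
                         method = c("spc", "optics"),
                         window = 61, align_index = 20, interp_factor = 4,
                         n_features = 10, lags = 40, cov_lags = 61,
                         refractory = 60) {
  method <- match.arg(method)
  x <- as_samples(rec)
  ev <- detect_spikes(rec, detect_cfg)
  wf <- extract_waveforms(rec, ev, window = window, align_index = align_index,
                          interp_factor = interp_factor)
  fm <- build_features(wf, d = n_features)
  assign <- if (method == "spc") spc_cluster(fm, cluster_cfg)
            else optics_cluster(wf, min_samples = cluster_cfg$knn_K)
  it <- build_impulse_trains(assign, wf$event_indices, length(x))
  keep <- lengths(it$trains) > 0
  it$trains <- it$trains[keep]
  tset <- estimate_templates(x, it, lags = lags)
  resid <- compute_noise_residual(x, tset, it)
  autocov <- noise_autocovariance(resid, m = cov_lags)
  nfilter <- coiflet_filter_from_cov(autocov, m = cov_lags)
  vt <- whiten(x, nfilter)
  tset$filtered_templates <- estimate_templates(vt, it, lags = lags)$templates
  noise <- structure(list(residual = resid, autocov = autocov,
                          filter = nfilter), class = "ss_noise_model")
  res <- match_unclustered(vt, tset, it$targets, refractory = refractory,
                           existing_trains = it$trains)
  res$n_neurons <- length(it$trains)
  res$stages <- list(events = ev, waveforms = wf, features = fm,
                     assignment = assign, impulse_trains = it,
                     templates = tset, noise = noise)
  res
}
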