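#' @title Cepstrum-of-bispectrum spike detection
#' @description The channel is modelled as a sparse, positively skewed impulse
#'   sequence filtered through an unknown spike-shaped transfer function plus
#'   Gaussian noise. Because the bispectrum of a Gaussian process vanishes,
#'   the log-bispectrum of the trace isolates the filter: collapsing it to a
#'   one-dimensional log spectrum, taking the minimum-phase cepstrum and
#'   exponentiating reconstructs |F|, whose regularised inverse applied to the
#'   trace concentrates the spike energy back into near-impulses. Stationary
#'   coiflet-wavelet denoising and a robust (MAD-based) threshold then yield
#'   event times.
#' @name detect
NULL

# coif3 analysis low-pass filter (orthonormal, 18 taps); the standard
# published filter bank.
COIF3_DEC_LO <- c(
  -3.459977319727278e-05, -7.0983302506379e-05, 0.0004662169598204029,
  0.0011175187708306303, -0.0025745176881367972, -0.009007976136730624,
  0.015880544863669452, 0.03455502757329774, -0.08230192710629983,
  -0.07179982161915484, 0.42848347637737, 0.7937772226260872,
  0.40517690240911824, -0.06112339000297255, -0.06577191128146936,
  0.023452696142077168, 0.007782596425672746, -0.003793512864380802)

#' Detection configuration
#'
#' @param segment_length bispectrum segment length; a power of two >= 64.
#' @param overlap_fraction segment overlap in \[0, 1).
#' @param taper segment taper; `"hann"` or `"none"`.
#' @param skewness_xi optional skewness of the driving impulse sequence; only
#'   rescales the reconstructed transfer function, never peak positions, and
#'   is estimated from the filtered trace when `NULL`.
#' @param swt_level stationary-wavelet decomposition depth.
#' @param wavelet_order coiflet order (3 supported).
#' @param threshold_k event threshold in multiples of the robust
#'   (median/MAD) SD of the detection trace.
#' @param min_event_gap minimum spacing between detected events, samples.
#'   The inverse-filter response to one spike is a few samples wide, so
#'   successive threshold crossings closer than this are one event; members
#'   of an overlap separated by more than this are reported separately, and
#'   closer collisions are left to the likelihood matcher's elimination step.
#' @param max_segments cap on the number of segments averaged in the
#'   bispectrum (evenly subsampled beyond this).
#' @param tikhonov_eps relative Tikhonov floor used when inverting the
#'   reconstructed transfer function.
#' @param snap_window radius, samples, for snapping a detected index to the
#'   local maximum of the raw trace (spike times mark waveform peaks).
#' @param amp_gate_k amplitude gate: after snapping, events whose raw peak
#'   amplitude falls below `amp_gate_k` robust SDs of the (median-centred)
#'   trace are discarded. The inverse filter is amplitude blind, so without
#'   the gate it happily reports faint multi-unit activity from distant
#'   neurons; the gate is relative, keeping detection invariant to scaling
#'   and offset.
#' @return list of class `ss_cob_config`.
#' @export
cob_config <- function(segment_length = 1024, overlap_fraction = 0.5,
                       taper = c("hann", "none"), skewness_xi = NULL,
                       swt_level = 4, wavelet_order = 3, threshold_k = 4,
                       min_event_gap = 16, max_segments = 128,
                       tikhonov_eps = 1e-3, snap_window = 20, amp_gate_k = 4) {
  taper <- match.arg(taper)
  if (segment_length < 64 || bitwAnd(segment_length, segment_length - 1L) != 0)
    stop_invalid("segment_length must be a power of two >= 64")
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    stop_invalid("overlap_fraction must be in [0, 1)")
  if (wavelet_order != 3) stop_invalid("only coiflet order 3 is provided")
  structure(list(segment_length = as.integer(segment_length),
                 overlap_fraction = overlap_fraction, taper = taper,
                 skewness_xi = skewness_xi, swt_level = as.integer(swt_level),
                 wavelet_order = as.integer(wavelet_order),
                 threshold_k = threshold_k,
                 min_event_gap = as.integer(min_event_gap),
                 max_segments = as.integer(max_segments),
                 tikhonov_eps = tikhonov_eps,
                 snap_window = as.integer(snap_window),
                 amp_gate_k = amp_gate_k),
            class = "ss_cob_config")
}

as_samples <- function(x) {
  if (inherits(x, "ss_recording")) x$samples else as.numeric(x)
}

#' Estimate the bispectrum of a trace
#'
#' Averages the frequency-domain triple product `V(n) V(m) V*(n+m)` over
#' demeaned, tapered, overlapping segments. Frequencies are cyclic DFT bins,
#' so the result is an `L x L` complex matrix symmetric in its two arguments.
#'
#' @param rec an `ss_recording` or numeric trace.
#' @param cfg a [cob_config()].
#' @return Complex matrix with attributes `n_segments`, `segment_length`.
#' @export
estimate_bispectrum <- function(rec, cfg = cob_config()) {
  x <- as_samples(rec)
  L <- cfg$segment_length
  if (length(x) < L)
    stop_invalid("trace (%d samples) shorter than one segment (%d)", length(x), L)
  hop <- max(1L, as.integer(round(L * (1 - cfg$overlap_fraction))))
  starts <- seq(1L, length(x) - L + 1L, by = hop)
  if (length(starts) > cfg$max_segments)
    starts <- starts[unique(round(seq(1, length(starts),
                                      length.out = cfg$max_segments)))]
  win <- if (cfg$taper == "hann")
    0.5 - 0.5 * cos(2 * pi * (seq_len(L) - 1) / (L - 1)) else rep(1, L)
  ii <- (outer(0:(L - 1), 0:(L - 1), "+") %% L) + 1L  # bin index of n+m
  B <- matrix(0 + 0i, L, L)
  for (s in starts) {
    seg <- x[s:(s + L - 1)]
    seg <- (seg - mean(seg)) * win
    V <- fft(seg)
    B <- B + outer(V, V) * Conj(V[ii])
  }
  B <- B / length(starts)
  attr(B, "n_segments") <- length(starts)
  attr(B, "segment_length") <- L
  B
}

# Minimum-phase spectrum from a log-magnitude spectrum via cepstral folding.
min_phase_from_logmag <- function(logF) {
  L <- length(logF)
  ceps <- Re(fft(logF, inverse = TRUE)) / L
  half <- L %/% 2
  fold <- numeric(L)
  fold[1] <- ceps[1]
  fold[2:half] <- 2 * ceps[2:half]
  fold[half + 1] <- ceps[half + 1]
  fft(fold)
}

#' Reconstruct the spike transfer function and inverse-filter the trace
#'
#' Row-averaging the log-magnitude bispectrum recovers the filter's log
#' spectrum up to an additive constant (the triple-product structure makes
#' every row the same log spectrum plus constants). A minimum-phase transfer
#' function is rebuilt through the cepstrum, inverted with a Tikhonov floor,
#' and applied to the trace. The filtered trace is realigned so recovered
#' impulses sit at the template peak position (lag = argmax of the
#' minimum-phase filter's impulse response).
#'
#' @param rec an `ss_recording` or numeric trace.
#' @param cfg a [cob_config()].
#' @return list with `filter` (inverse-filter impulse response), `trace`
#'   (filtered, lag-corrected, same length as input), `transfer` (complex
#'   spectrum of the reconstructed forward filter), `lag` (peak offset), and
#'   `skewness_xi` (estimated skewness of the filtered trace).
#' @export
cob_inverse_filter <- function(rec, cfg = cob_config()) {
  x <- as_samples(rec)
  N <- length(x)
  if (all(x == 0)) {
    warning("all-zero trace; returning the identity filter", call. = FALSE)
    f <- numeric(cfg$segment_length)
    f[1] <- 1
    return(list(filter = f, trace = x, transfer = rep(1 + 0i, cfg$segment_length),
                lag = 0L, skewness_xi = 0))
  }
  B <- estimate_bispectrum(rec, cfg)
  L <- cfg$segment_length
  A <- abs(B)
  A <- pmax(A, max(A) * 1e-10)
  # log|B(n,m)| = const + L(n) + L(m) + L(n+m) with L = log|F|; averaging a
  # row over m leaves L(n) plus a constant (cyclic sums are m-independent).
  # Clamping the dynamic range keeps near-null spectral bins (noise-free or
  # strongly band-limited inputs) from producing a ringing inverse filter.
  logF <- rowMeans(log(A))
  logF <- pmax(logF, max(logF) - 6)
  logF <- logF - mean(logF)
  Fm <- exp(min_phase_from_logmag(logF))
  floor2 <- (cfg$tikhonov_eps * max(Mod(Fm)))^2
  Finv <- Conj(Fm) / (Mod(Fm)^2 + floor2)
  finv <- Re(fft(Finv, inverse = TRUE)) / L
  fwd <- Re(fft(Fm, inverse = TRUE)) / L
  lag <- which.max(abs(fwd[seq_len(L %/% 2)])) - 1L
  # linear convolution of the trace with the inverse filter
  nfft <- 2^ceiling(log2(N + L))
  y <- Re(fft(fft(c(x, numeric(nfft - N))) *
                fft(c(finv, numeric(nfft - L))), inverse = TRUE)) / nfft
  y <- y[seq_len(N)]
  if (lag > 0) y <- c(numeric(lag), y[seq_len(N - lag)])
  xi <- mean(((y - mean(y)) / max(sd(y), .Machine$double.eps))^3)
  if (!is.null(cfg$skewness_xi)) xi <- cfg$skewness_xi
  list(filter = finv, trace = y, transfer = Fm, lag = lag, skewness_xi = xi)
}

# Quadrature mirror high-pass from the low-pass analysis filter.
qmf_highpass <- function(h) {
  n <- length(h)
  rev(h) * (-1)^(seq_len(n) - 1)
}

#' Stationary (undecimated) coiflet wavelet denoising
#'
#' À-trous decomposition implemented exactly in the frequency domain
#' (filters upsampled by `2^(level-1)`), soft thresholding of every detail
#' band at the universal threshold `sigma * sqrt(2 log N)` with `sigma` the
#' MAD estimate from the finest detail band, and the exact least-squares
#' inverse. The trace is reflection-padded internally, so the output length
#' equals the input length.
#'
#' @param x numeric trace (or `ss_recording`).
#' @param cfg a [cob_config()] (fields `swt_level`, `wavelet_order`).
#' @return Denoised numeric trace.
#' @export
swt_denoise <- function(x, cfg = cob_config()) {
  x <- as_samples(x)
  N <- length(x)
  if (N < 2) return(x)
  h <- COIF3_DEC_LO
  g <- qmf_highpass(h)
  level <- cfg$swt_level
  while (level > 1 && length(h) * 2^level > N) {
    level <- level - 1L
  }
  if (level < cfg$swt_level)
    warning(sprintf("trace too short for level %d; using level %d",
                    cfg$swt_level, level), call. = FALSE)
  pad <- min(N - 1, length(h) * 2^level)
  xp <- c(rev(x[seq_len(pad)]), x, rev(x[(N - pad + 1):N]))
  Np <- length(xp)
  H0 <- fft(c(h, numeric(Np - length(h))))
  G0 <- fft(c(g, numeric(Np - length(g))))
  bins <- 0:(Np - 1)
  a <- fft(xp)                       # work in the frequency domain throughout
  details <- vector("list", level)
  Hs <- Gs <- vector("list", level)
  for (j in seq_len(level)) {
    sel <- (bins * 2^(j - 1)) %% Np + 1
    Hs[[j]] <- H0[sel]
    Gs[[j]] <- G0[sel]
    details[[j]] <- a * Gs[[j]]
    a <- a * Hs[[j]]
  }
  d1 <- Re(fft(details[[1]], inverse = TRUE)) / Np
  sigma <- median(abs(d1 - median(d1))) / 0.6745
  thr <- sigma * sqrt(2 * log(Np))
  for (j in seq_len(level)) {
    d <- Re(fft(details[[j]], inverse = TRUE)) / Np
    d <- sign(d) * pmax(abs(d) - thr, 0)
    details[[j]] <- fft(d)
  }
  for (j in rev(seq_len(level))) {
    denom <- Mod(Hs[[j]])^2 + Mod(Gs[[j]])^2
    a <- (a * Conj(Hs[[j]]) + details[[j]] * Conj(Gs[[j]])) / denom
  }
  out <- Re(fft(a, inverse = TRUE)) / Np
  out[(pad + 1):(pad + N)]
}

#' Threshold a detection trace into events
#'
#' Local maxima exceeding `median + threshold_k x MAD-SD`, pruned so that no
#' two retained events are closer than `gap` samples (larger peaks win; ties
#' keep the earlier index).
#'
#' @param x numeric detection trace.
#' @param cfg a [cob_config()].
#' @param gap minimum inter-event spacing, samples.
#' @param source detector name recorded in the result.
#' @return list of class `ss_events` with sorted unique `indices` and `source`.
#' @export
threshold_events <- function(x, cfg = cob_config(), gap = cfg$min_event_gap,
                             source = "threshold") {
  x <- as_samples(x)
  N <- length(x)
  if (N < 3) return(event_index(integer(0), source))
  med <- median(x)
  sdev <- median(abs(x - med)) / 0.6745
  if (sdev == 0) sdev <- sd(x)        # degenerate mostly-zero traces
  thr <- med + cfg$threshold_k * sdev
  core <- x[2:(N - 1)]
  is_peak <- core > x[1:(N - 2)] & core >= x[3:N] & core > thr
  peaks <- which(is_peak) + 1L
  if (!length(peaks)) return(event_index(integer(0), source))
  o <- order(-x[peaks], peaks)
  peaks <- peaks[o]
  kept <- integer(0)
  for (p in peaks) {
    if (!length(kept) || min(abs(kept - p)) >= gap) kept <- c(kept, p)
  }
  event_index(sort(kept), source)
}

#' Construct an EventIndex
#' @param indices sorted sample positions.
#' @param source detector name.
#' @export
event_index <- function(indices, source = "manual") {
  indices <- sort(unique(as.integer(indices)))
  structure(list(indices = indices, source = source), class = "ss_events")
}

#' @export
print.ss_events <- function(x, ...) {
  cat(sprintf("<ss_events: %d events from '%s'>\n", length(x$indices), x$source))
  invisible(x)
}

# Move each index to the local argmax of `x` within +/- w. Stronger
# detections claim their peak first; a detection whose window maximum falls
# within `gap` of an already-claimed peak is the same spike and is dropped.
snap_to_peaks <- function(idx, x, strength, w, gap) {
  if (!length(idx)) return(integer(0))
  N <- length(x)
  o <- order(-strength, idx)
  claimed <- integer(0)
  for (t in idx[o]) {
    lo <- max(1L, t - w)
    hi <- min(N, t + w)
    p <- lo + which.max(x[lo:hi]) - 1L
    if (!length(claimed) || min(abs(claimed - p)) >= gap)
      claimed <- c(claimed, p)
  }
  sort(claimed)
}

#' Detect spikes with the cepstrum-of-bispectrum pipeline
#'
#' Inverse filtering ([cob_inverse_filter()]) followed by stationary-wavelet
#' denoising ([swt_denoise()]), robust thresholding ([threshold_events()]),
#' and snapping of each event to the local raw-trace maximum (spike times mark
#' waveform peaks). Deterministic for a fixed input.
#'
#' @param rec an `ss_recording`.
#' @param cfg a [cob_config()].
#' @return An `ss_events` object (`source = "cob"`).
#' @export
detect_spikes <- function(rec, cfg = cob_config()) {
  x <- as_samples(rec)
  if (!length(x) || all(x == median(x))) return(event_index(integer(0), "cob"))
  x0 <- x - median(x)
  flt <- cob_inverse_filter(x0, cfg)
  y <- swt_denoise(flt$trace, cfg)
  # the inverse filter concentrates spike energy but leaves an oscillatory
  # tail; detection runs on the magnitude and localisation on the raw peaks
  z <- abs(y)
  ev <- threshold_events(z, cfg, gap = cfg$min_event_gap, source = "cob")
  idx <- snap_to_peaks(ev$indices, x0, z[ev$indices], cfg$snap_window,
                       cfg$min_event_gap)
  scale0 <- median(abs(x0)) / 0.6745
  if (scale0 == 0) scale0 <- sd(x0)   # degenerate mostly-zero traces
  gate <- cfg$amp_gate_k * scale0
  idx <- idx[x0[idx] > gate]
  event_index(idx, "cob")
}

#' Hard-threshold baseline detectors
#'
#' Classical amplitude-threshold detection at `k` times one of three channel
#' statistics: the robust background-noise SD (`noise_sd`, median/MAD
#' estimator), the root-mean-square of the channel (`rms`), or the plain
#' channel SD (`channel_sd`). Peak picking and the inter-event gap rule match
#' [detect_spikes()].
#'
#' @param rec an `ss_recording`.
#' @param method one of `"noise_sd"`, `"rms"`, `"channel_sd"`.
#' @param k threshold multiplier.
#' @param cfg a [cob_config()] (gap rule only).
#' @return An `ss_events` object.
#' @export
baseline_detect <- function(rec, method = c("noise_sd", "rms", "channel_sd"),
                            k = 3, cfg = cob_config()) {
  method <- match.arg(method)
  x <- as_samples(rec)
  x <- x - median(x)
  stat <- switch(method,
                 noise_sd = median(abs(x)) / 0.6745,
                 rms = sqrt(mean(x^2)),
                 channel_sd = sd(x))
  N <- length(x)
  if (N < 3) return(event_index(integer(0), method))
  thr <- k * stat
  core <- x[2:(N - 1)]
  is_peak <- core > x[1:(N - 2)] & core >= x[3:N] & core > thr
  peaks <- which(is_peak) + 1L
  if (!length(peaks)) return(event_index(integer(0), method))
  o <- order(-x[peaks], peaks)
  kept <- integer(0)
  for (p in peaks[o]) {
    if (!length(kept) || min(abs(kept - p)) >= cfg$min_event_gap)
      kept <- c(kept, p)
  }
  event_index(sort(kept), method)
}

#' Extract peak-aligned spike waveforms
#'
#' One row per event whose window fits inside the trace. Each row is
#' re-centred on its local maximum (search radius `recentre`), optionally
#' spline-interpolated by `interp_factor` for sub-sample peak alignment and
#' decimated back, so each row's argmax sits at `align_index` (superimposed
#' spikes can place a larger foreign peak inside a window; the row still
#' aligns to its own event's peak). Secondary peaks inside a window never
#' spawn extra rows.
#'
#' @param rec an `ss_recording`.
#' @param events an `ss_events`.
#' @param window snippet length, samples (>= 8); 31 spans ~1.3 ms at 24 kHz.
#' @param align_index 1-based position of the common peak within the window.
#' @param interp_factor integer >= 1; 1 disables interpolation.
#' @param recentre radius, samples, of the peak re-centring search.
#' @return list of class `ss_waveforms`: `waveforms` (`M x window` matrix),
#'   `align_index`, `event_indices` (the retained, re-centred positions),
#'   `interp_factor`, `n_dropped` (events too close to an edge).
#' @export
extract_waveforms <- function(rec, events, window = 31, align_index = 12,
                              interp_factor = 1, recentre = 3) {
  if (window < 8) stop_invalid("window must be >= 8 samples")
  if (align_index >= window || align_index < 1)
    stop_invalid("align_index must lie inside the window")
  x <- as_samples(rec)
  N <- length(x)
  idx <- events$indices
  rows <- list()
  keep_idx <- integer(0)
  dropped <- 0L
  for (t in idx) {
    lo <- max(1L, t - recentre)
    hi <- min(N, t + recentre)
    tc <- lo + which.max(x[lo:hi]) - 1L
    a <- tc - align_index + 1L
    b <- tc + (window - align_index)
    if (a < 1L || b > N) {
      dropped <- dropped + 1L
      next
    }
    if (interp_factor > 1) {
      pad <- 2L
      aa <- max(1L, a - pad)
      bb <- min(N, b + pad)
      fine <- stats::spline(aa:bb, x[aa:bb],
                            n = (bb - aa) * interp_factor + 1)
      pk_rel_lo <- (tc - 1 - aa) * interp_factor + 1
      pk_rel_hi <- (tc + 1 - aa) * interp_factor + 1
      pk <- pk_rel_lo + which.max(fine$y[pk_rel_lo:pk_rel_hi]) - 1L
      take <- pk + (seq_len(window) - align_index) * interp_factor
      if (any(take < 1L | take > length(fine$y))) {
        dropped <- dropped + 1L
        next
      }
      row <- fine$y[take]
    } else {
      row <- x[a:b]
    }
    rows[[length(rows) + 1L]] <- row
    keep_idx <- c(keep_idx, tc)
  }
  wf <- if (length(rows)) do.call(rbind, rows)
  else matrix(numeric(0), nrow = 0, ncol = window)
  structure(list(waveforms = wf, align_index = as.integer(align_index),
                 event_indices = keep_idx,
                 interp_factor = as.integer(interp_factor),
                 n_dropped = dropped),
            class = "ss_waveforms")
}

#' @export
print.ss_waveforms <- function(x, ...) {
  cat(sprintf("<ss_waveforms: %d snippets x %d samples, peak at %d (%d dropped)>\n",
              nrow(x$waveforms), ncol(x$waveforms), x$align_index, x$n_dropped))
  invisible(x)
}
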