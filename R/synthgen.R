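#' @title Synthetic extracellular channels with exact ground truth
#' @description Generative model used throughout the package: each of `N`
#'   neurons owns a distinct biphasic template `w_n` of length `tau` samples
#'   (unit positive peak) and a sparse impulse train `delta_n`; the channel is
#'   the sum of the convolutions plus low-amplitude "neighbour neuron"
#'   activity and additive Gaussian noise whose SD is a stated fraction of
#'   the spike peak amplitude.
#' @name synthgen
NULL

# Run code under a temporary RNG state so simulation seeds do not perturb the
# caller's random stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

#' Construct a Recording object
#'
#' A light container for one voltage channel: finite samples, a positive
#' sampling rate and a text id. Traces rendered by [render_channel()] carry a
#' `components` attribute with the exact signal / neighbour / noise split.
#'
#' @param samples numeric vector of voltages (arbitrary units).
#' @param sampling_rate samples per second (Hz).
#' @param id text label.
#' @return An object of class `ss_recording`.
#' @export
recording <- function(samples, sampling_rate = 24000, id = "trace") {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop_invalid("a recording needs at least 1 sample")
  if (!all(is.finite(samples))) stop_invalid("all samples must be finite")
  assert_scalar_num(sampling_rate, "sampling_rate", min = .Machine$double.eps)
  structure(list(samples = samples, sampling_rate = sampling_rate,
                 id = as.character(id)[1]),
            class = "ss_recording")
}

#' @export
print.ss_recording <- function(x, ...) {
  cat(sprintf("<ss_recording '%s': %d samples @ %g Hz (%.2f s)>\n",
              x$id, length(x$samples), x$sampling_rate,
              length(x$samples) / x$sampling_rate))
  invisible(x)
}

#' Construct a GroundTruth object
#'
#' @param spike_times list of per-neuron sorted spike sample indices (1-based,
#'   marking the template peak sample).
#' @param templates `N x tau` matrix of spike waveforms (one row per neuron),
#'   or `NULL` when unknown (e.g. read from a benchmark file without shapes).
#' @param noise_sigma noise SD in volts (NA when unknown).
#' @param refractory minimum within-neuron inter-spike interval, samples.
#' @return An object of class `ss_ground_truth`.
#' @export
ground_truth <- function(spike_times, templates = NULL, noise_sigma = NA_real_,
                         refractory = 60) {
  stopifnot(is.list(spike_times))
  spike_times <- lapply(spike_times, function(s) as.numeric(sort(s)))
  for (n in seq_along(spike_times)) {
    s <- spike_times[[n]]
    if (anyDuplicated(s)) stop_invalid("neuron %d has duplicated spike times", n)
    if (length(s) > 1 && any(diff(s) < refractory))
      stop_invalid("neuron %d violates the refractory period", n)
  }
  if (!is.null(templates)) {
    pk <- attr(templates, "peak_index")
    templates <- rbind(templates)
    attr(templates, "peak_index") <- pk
    if (nrow(templates) != length(spike_times))
      stop_invalid("need one template per neuron")
  }
  structure(list(n_neurons = length(spike_times), spike_times = spike_times,
                 templates = templates, noise_sigma = noise_sigma,
                 refractory = refractory),
            class = "ss_ground_truth")
}

#' @export
print.ss_ground_truth <- function(x, ...) {
  cat(sprintf("<ss_ground_truth: %d neurons, %s spikes, refractory %d samples>\n",
              x$n_neurons, sum(lengths(x$spike_times)), x$refractory))
  invisible(x)
}

#' Simulation configuration
#'
#' Defaults reproduce the structure of the public single-channel benchmark:
#' three neurons sampled at 24 kHz for 60 s, templates of 60 samples
#' (~2.5 ms), per-sample Bernoulli firing at 7.8e-4 (about 1120 spikes per
#' neuron per minute, so near-coincident spikes from different neurons arise
#' naturally), Gaussian noise at a stated fraction of the unit spike peak, and
#' two faint neighbour neurons.
#'
#' @param duration trace length in samples.
#' @param firing_rates per-neuron spike probabilities per sample; its length
#'   sets the number of neurons.
#' @param noise_level Gaussian noise SD as a fraction of the template peak
#'   amplitude (templates are unit-peak, so this is the noise SD).
#' @param neighbour_amplitude peak amplitude of neighbour-neuron spikes as a
#'   fraction of the main template peak; 0 disables neighbour activity.
#' @param n_neighbours number of faint neighbour neurons.
#' @param tau template length, samples.
#' @param refractory absolute refractory period, samples.
#' @param forced_overlaps number of deliberately injected near-coincident
#'   spike pairs (distinct neurons within one template length).
#' @param sampling_rate Hz.
#' @param seed integer controlling every random draw; fixed seed gives a
#'   bitwise-reproducible recording and ground truth.
#' @return A list of class `ss_sim_config`.
#' @export
sim_config <- function(duration = 60 * 24000,
                       firing_rates = rep(7.8e-4, 3),
                       noise_level = 0.1,
                       neighbour_amplitude = 0.05,
                       n_neighbours = 2,
                       tau = 60,
                       refractory = 60,
                       forced_overlaps = 0,
                       sampling_rate = 24000,
                       seed = 1) {
  if (any(firing_rates < 0)) stop_invalid("firing rates must be >= 0")
  assert_scalar_num(noise_level, "noise_level", min = 0)
  assert_scalar_num(duration, "duration", min = 1)
  structure(list(duration = as.integer(duration),
                 firing_rates = as.numeric(firing_rates),
                 noise_level = noise_level,
                 neighbour_amplitude = neighbour_amplitude,
                 n_neighbours = as.integer(n_neighbours),
                 tau = as.integer(tau), refractory = as.integer(refractory),
                 forced_overlaps = as.integer(forced_overlaps),
                 sampling_rate = sampling_rate,
                 seed = as.integer(seed)),
            class = "ss_sim_config")
}

#' Generate a library of distinct biphasic spike templates
#'
#' Templates are sums of Gaussians (sharp positive peak followed by a wider
#' repolarisation trough, optionally a small pre-depolarisation dip),
#' normalised to unit positive peak placed at a common peak index. Shape
#' parameters are drawn from the seed; candidates too similar to an existing
#' template (|correlation| >= 0.99) are redrawn.
#'
#' @param n number of templates; 0 returns an empty list.
#' @param tau template length in samples (>= 8); ~60 at 24 kHz spans a 2.5 ms
#'   spike.
#' @param seed integer seed.
#' @return An `n x tau` numeric matrix with attribute `peak_index` (common
#'   argmax of every row); `n = 0` gives a 0-row matrix.
#' @export
make_templates <- function(n, tau = 60, seed = 1) {
  if (n == 0) {
    out <- matrix(numeric(0), nrow = 0, ncol = tau)
    attr(out, "peak_index") <- max(8L, round(tau / 3))
    return(out)
  }
  if (tau < 8) stop_invalid("`tau` must be >= 8 samples")
  n <- as.integer(n)
  peak_index <- max(4L, round(tau / 3))
  with_seed(seed, {
    out <- matrix(0, nrow = n, ncol = tau)
    t_ax <- seq_len(tau)
    made <- 0L
    tries <- 0L
    while (made < n) {
      tries <- tries + 1L
      if (tries > 200L * n) stop_invalid("could not draw %d distinct templates", n)
      s1 <- runif(1, 0.04, 0.1) * tau          # depolarisation width (~0.1-0.25 ms)
      trough_amp <- runif(1, 0.25, 0.9)
      gap <- runif(1, 0.12, 0.3) * tau         # peak-to-trough separation
      s2 <- runif(1, 0.1, 0.25) * tau          # repolarisation trough width
      dip_amp <- runif(1, 0, 0.25)
      w <- exp(-((t_ax - peak_index)^2) / (2 * s1^2)) -
        trough_amp * exp(-((t_ax - peak_index - gap)^2) / (2 * s2^2)) -
        dip_amp * exp(-((t_ax - peak_index + 0.12 * tau)^2) / (2 * (0.6 * s1)^2))
      # enforce the common peak sample exactly, then unit peak
      shift <- peak_index - which.max(w)
      if (shift != 0) {
        w <- if (shift > 0) c(rep(0, shift), w[seq_len(tau - shift)])
             else c(w[(1 - shift):tau], rep(0, -shift))
      }
      w <- w / max(w)
      ok <- TRUE
      if (made > 0L) {
        cors <- apply(out[seq_len(made), , drop = FALSE], 1,
                      function(u) suppressWarnings(cor(u, w)))
        if (any(abs(cors) >= 0.95, na.rm = TRUE)) ok <- FALSE
      }
      if (ok) {
        made <- made + 1L
        out[made, ] <- w
      }
    }
    attr(out, "peak_index") <- peak_index
    out
  })
}

# Bernoulli-per-sample spike train thinned by an absolute refractory period.
# Spikes are kept away from the trace edges so a full template always fits.
draw_train <- function(duration, rate, tau, refractory) {
  if (rate <= 0) return(numeric(0))
  lo <- tau + 1
  hi <- duration - tau
  if (hi <= lo) return(numeric(0))
  span <- hi - lo + 1
  k <- rbinom(1, span, rate)
  if (k == 0) return(numeric(0))
  s <- sort(sample.int(span, k)) + lo - 1
  # keep-first refractory thinning
  keep <- numeric(length(s))
  m <- 0L
  last <- -Inf
  for (t in s) {
    if (t - last >= refractory) {
      m <- m + 1L
      keep[m] <- t
      last <- t
    }
  }
  keep[seq_len(m)]
}

#' Generate per-neuron impulse trains with refractory enforcement
#'
#' Each neuron fires as a per-sample Bernoulli process at its configured rate,
#' thinned so that no within-neuron inter-spike interval falls below the
#' refractory period; `forced_overlaps` near-coincident cross-neuron pairs can
#' be injected to stress overlap resolution.
#'
#' @param config an [sim_config()] object.
#' @param templates matrix from [make_templates()]; row count must equal
#'   `length(config$firing_rates)`.
#' @return An `ss_ground_truth` object.
#' @export
generate_ground_truth <- function(config, templates) {
  stopifnot(inherits(config, "ss_sim_config"))
  n <- length(config$firing_rates)
  if (nrow(templates) != n)
    stop_invalid("templates (%d) and firing_rates (%d) disagree", nrow(templates), n)
  if (config$duration <= ncol(templates))
    stop_invalid("duration must exceed the template length")
  rates <- config$firing_rates
  cap <- 1 / config$refractory
  if (any(rates > cap)) {
    warning("firing rate exceeds 1/refractory; clipping", call. = FALSE)
    rates <- pmin(rates, cap)
  }
  with_seed(config$seed, {
    trains <- lapply(rates, draw_train, duration = config$duration,
                     tau = config$tau, refractory = config$refractory)
    if (config$forced_overlaps > 0 && n >= 2) {
      tau <- config$tau
      for (i in seq_len(config$forced_overlaps)) {
        donors <- which(lengths(trains) > 0)
        if (!length(donors)) break
        a <- if (length(donors) == 1) donors else sample(donors, 1)
        b <- sample(setdiff(seq_len(n), a), 1)
        for (try in 1:50) {
          t0 <- sample(trains[[a]], 1)
          lag <- sample(c(-(tau %/% 2):-3, 3:(tau %/% 2)), 1)
          t1 <- t0 + lag
          ok <- t1 > tau && t1 < config$duration - tau &&
            (!length(trains[[b]]) || min(abs(trains[[b]] - t1)) >= config$refractory)
          if (ok) {
            trains[[b]] <- sort(c(trains[[b]], t1))
            break
          }
        }
      }
    }
    ground_truth(trains, templates = templates,
                 noise_sigma = config$noise_level * max(abs(templates)),
                 refractory = config$refractory)
  })
}

# Place template w (peak at peak_index) at each spike time; returns a trace.
place_template <- function(times, w, peak_index, duration) {
  x <- numeric(duration)
  tau <- length(w)
  for (t in times) {
    i0 <- t - peak_index + 1
    idx <- i0:(i0 + tau - 1)
    ok <- idx >= 1 & idx <= duration
    x[idx[ok]] <- x[idx[ok]] + w[ok]
  }
  x
}

#' Render the voltage channel from ground truth
#'
#' Computes `v(t) = sum_n (delta_n * w_n)(t) + neighbour(t) + eta(t)` with
#' `eta` Gaussian of SD `noise_level x` peak template amplitude. The exact
#' decomposition is stored in the result's `components` attribute
#' (`signal`, `neighbour`, `noise`), so the trace is re-derivable as their
#' sum — useful for conservation checks and residual oracles.
#'
#' @param truth an `ss_ground_truth` with templates.
#' @param config the [sim_config()] used (noise, neighbours, seed).
#' @return An `ss_recording`.
#' @export
render_channel <- function(truth, config) {
  stopifnot(inherits(truth, "ss_ground_truth"), inherits(config, "ss_sim_config"))
  duration <- config$duration
  peak_index <- attr(truth$templates, "peak_index")
  if (is.null(peak_index)) peak_index <- max(4L, round(ncol(truth$templates) / 3))
  signal <- numeric(duration)
  for (nn in seq_len(truth$n_neurons))
    signal <- signal + place_template(truth$spike_times[[nn]],
                                      truth$templates[nn, ], peak_index, duration)
  peak_amp <- if (truth$n_neurons > 0) max(abs(truth$templates)) else 1
  neighbour <- numeric(duration)
  if (config$neighbour_amplitude > 0 && config$n_neighbours > 0) {
    neighbour <- with_seed(config$seed + 7919L, {
      nb_templates <- make_templates(config$n_neighbours, config$tau,
                                     seed = config$seed + 104729L)
      nb <- numeric(duration)
      for (k in seq_len(config$n_neighbours)) {
        tr <- draw_train(duration, mean(config$firing_rates), config$tau,
                         config$refractory)
        nb <- nb + place_template(tr, config$neighbour_amplitude * peak_amp *
                                    nb_templates[k, ], peak_index, duration)
      }
      nb
    })
  }
  noise <- if (config$noise_level > 0)
    with_seed(config$seed + 15485863L,
              rnorm(duration, sd = config$noise_level * peak_amp))
  else numeric(duration)
  rec <- recording(signal + neighbour + noise,
                   sampling_rate = config$sampling_rate,
                   id = sprintf("sim-n%d-noise%g-seed%d", truth$n_neurons,
                                config$noise_level, config$seed))
  attr(rec, "components") <- list(signal = signal, neighbour = neighbour,
                                  noise = noise)
  attr(rec, "peak_index") <- peak_index
  rec
}

#' One-call simulation convenience
#'
#' @param config an [sim_config()].
#' @return list with elements `recording`, `truth`, `templates`, `config`.
#' @export
simulate_recording <- function(config = sim_config()) {
  templates <- make_templates(length(config$firing_rates), config$tau,
                              seed = config$seed)
  truth <- generate_ground_truth(config, templates)
  rec <- render_channel(truth, config)
  list(recording = rec, truth = truth, templates = templates, config = config)
}
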