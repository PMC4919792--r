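test_that("bispectrum matches the brute-force triple product and is symmetric", {
  set.seed(1)
  x <- rnorm(64)
  cfg <- cob_config(segment_length = 64, overlap_fraction = 0)
  B <- estimate_bispectrum(x, cfg)

  # independent brute-force loop over V(n) V(m) V*(n+m)
  win <- 0.5 - 0.5 * cos(2 * pi * (0:63) / 63)
  V <- fft((x - mean(x)) * win)
  Bref <- matrix(0 + 0i, 64, 64)
  for (n in 1:64) {
    for (m in 1:64) {
      Bref[n, m] <- V[n] * V[m] * Conj(V[((n - 1 + m - 1) %% 64) + 1])
    }
  }
  expect_lt(max(Mod(B - Bref)), 1e-8 * max(Mod(Bref)))
  expect_lt(max(Mod(B - t(B))), 1e-9)

  set.seed(2)
  B2 <- estimate_bispectrum(rnorm(5000), cob_config(segment_length = 256))
  expect_lt(max(Mod(B2 - t(B2))), 1e-9)

  expect_error(estimate_bispectrum(rnorm(100), cob_config(segment_length = 1024)),
               "shorter")
})

test_that("the bispectrum of a Gaussian process vanishes relative to a skewed one", {
  set.seed(7)
  cfg <- cob_config(segment_length = 64, max_segments = 8192)
  g <- rnorm(2e5)
  e <- rexp(2e5) - 1          # equal power, skewness 2
  ratio <- mean(Mod(estimate_bispectrum(g, cfg))) /
    mean(Mod(estimate_bispectrum(e, cfg)))
  expect_lte(ratio, 0.1)
})

test_that("inverse filtering concentrates spikes and is scale/offset invariant", {
  # noise-free single-neuron render: the 50 strongest recovered impulses sit
  # on the true spike times (the inverse response peaks within the template
  # span of each spike)
  W <- make_templates(1, 60, seed = 4)
  set.seed(10)
  times <- sort(sample(seq(200, 98000, by = 200), 50))
  x <- selsort:::place_template(times, W[1, ], attr(W, "peak_index"), 1e5)
  flt <- cob_inverse_filter(x, cob_config())
  y <- abs(flt$trace)
  top <- order(y, decreasing = TRUE)
  picked <- integer(0)
  for (t in top) {
    if (!length(picked) || min(abs(picked - t)) > 100) picked <- c(picked, t)
    if (length(picked) == length(times)) break
  }
  offs <- vapply(times, function(t) min(abs(picked - t)), numeric(1))
  expect_lte(max(offs), 30)
  # and full detection localises every one to +/-2 samples
  ev_nf <- detect_spikes(recording(x))
  offs2 <- vapply(times, function(t) min(abs(ev_nf$indices - t)), numeric(1))
  expect_lte(max(offs2), 2)

  # unit-impulse transfer function: output reproduces the input sequence
  set.seed(42)
  idx <- sort(sample(200:(2^16 - 200), 150))
  imp <- numeric(2^16)
  imp[idx] <- 1
  flt0 <- cob_inverse_filter(imp, cob_config())
  expect_equal(flt0$lag, 0L)
  expect_gt(cor(imp, flt0$trace), 0.95)

  # amplitude scaling and DC offset change nothing about detected positions
  sim <- fixture_sim(0.1, 3)
  ev <- detect_spikes(sim$recording)
  rec10 <- recording(10 * sim$recording$samples, 24000)
  expect_identical(detect_spikes(rec10)$indices, ev$indices)
  rec_dc <- recording(sim$recording$samples + 3.7, 24000)
  expect_identical(detect_spikes(rec_dc)$indices, ev$indices)

  expect_warning(cob_inverse_filter(numeric(5000), cob_config()), "all-zero")
})

test_that("stationary wavelet denoising preserves structure and suppresses noise", {
  cfg <- cob_config()
  expect_identical(swt_denoise(numeric(4096), cfg), numeric(4096))

  set.seed(3)
  imp <- numeric(8192)
  imp[sample(100:8000, 40)] <- 1
  expect_gt(cor(imp, swt_denoise(imp, cfg)), 0.99)

  # noisy impulses: SD strictly reduced in spike-free regions
  spikes <- numeric(8192)
  spikes[seq(500, 7500, by = 500)] <- 2
  noisy <- spikes + rnorm(8192, sd = 1)
  den <- swt_denoise(noisy, cfg)
  quiet <- setdiff(seq_len(8192), unlist(lapply(which(spikes > 0),
                                                function(t) (t - 30):(t + 30))))
  expect_lt(sd(den[quiet]), sd(noisy[quiet]))

  # over-deep level requested on a short trace
  expect_warning(swt_denoise(rnorm(80), cob_config(swt_level = 4)), "level")
})

test_that("thresholding picks local maxima with the gap rule", {
  cfg <- cob_config()
  expect_length(threshold_events(numeric(1000), cfg)$indices, 0)

  # two peaks 3 samples apart with gap 10: only the larger survives
  x <- numeric(400)
  x[100] <- 5
  x[103] <- 7
  ev <- threshold_events(x, cob_config(threshold_k = 1), gap = 10)
  expect_identical(ev$indices, 103L)

  # tie on equal peaks keeps the earlier index
  x2 <- numeric(400)
  x2[50] <- 4
  x2[57] <- 4
  ev2 <- threshold_events(x2, cob_config(threshold_k = 1), gap = 10)
  expect_identical(ev2$indices, 50L)
})

test_that("CoB detection is accurate on simulated channels and overlaps", {
  # noise 0.05: recall >= 0.95 at +/-2 samples, and perfect on clean renders
  sim <- fixture_sim(0.05, 3)
  ev <- fixture_events(0.05, 3)
  sc <- score_events(ev$indices, sim$truth, tol = 2)
  expect_gte(sc$recall, 0.95)

  # empty input
  expect_length(detect_spikes(recording(numeric(2000)))$indices, 0)

  # near-synchronous overlap: both constituents detected when far enough apart
  W <- make_templates(2, 60, seed = 6)
  pk <- attr(W, "peak_index")
  set.seed(8)
  t1 <- seq(600, 47000, by = 480)
  x <- selsort:::place_template(t1, W[1, ], pk, 48000) +
    selsort:::place_template(c(t1[5] + 25, 24000), W[2, ], pk, 48000) +
    rnorm(48000, sd = 0.05)
  ev2 <- detect_spikes(recording(x))
  expect_true(any(abs(ev2$indices - t1[5]) <= 2))
  expect_true(any(abs(ev2$indices - (t1[5] + 25)) <= 2))
})

test_that("noise-free single-neuron detection is exact", {
  cfg <- sim_config(duration = 3e5, firing_rates = 8e-4, noise_level = 0,
                    neighbour_amplitude = 0, seed = 21)
  sim <- simulate_recording(cfg)
  ev <- detect_spikes(sim$recording)
  sc <- score_events(ev$indices, sim$truth, tol = 2)
  expect_equal(sc$recall, 1)
  expect_equal(sc$fp, 0)
})

test_that("baseline detectors follow hard-threshold behaviour", {
  expect_length(baseline_detect(recording(rep(1, 1000)), "rms")$indices, 0)

  # k -> 0: every strict local maximum above the median is an event
  set.seed(5)
  x <- rnorm(500)
  ev <- baseline_detect(recording(x), "noise_sd", k = 0,
                        cfg = cob_config(min_event_gap = 1))
  xc <- x - median(x)
  core <- xc[2:499]
  n_max <- sum(core > xc[1:498] & core >= xc[3:500] & core > 0)
  expect_equal(length(ev$indices), n_max)
})

test_that("waveform extraction aligns every snippet at the requested peak", {
  # well-separated spikes: alignment is exact on every row
  cfgs <- sim_config(duration = 2e5, firing_rates = 4e-4, noise_level = 0.05,
                     neighbour_amplitude = 0, seed = 23)
  sims <- simulate_recording(cfgs)
  evs <- detect_spikes(sims$recording)
  wf <- extract_waveforms(sims$recording, evs, window = 31, align_index = 12)
  expect_equal(unname(apply(wf$waveforms, 1, which.max)), rep(12, nrow(wf$waveforms)))
  expect_equal(nrow(wf$waveforms), length(evs$indices) - wf$n_dropped)

  # interpolated extraction keeps the alignment invariant
  wf4 <- extract_waveforms(sims$recording, evs, window = 31, align_index = 12,
                           interp_factor = 4)
  expect_equal(unname(apply(wf4$waveforms, 1, which.max)), rep(12, nrow(wf4$waveforms)))

  # on a 3-neuron channel with overlaps, a window can contain a larger
  # foreign peak, but alignment still holds on the vast majority of rows
  sim <- fixture_sim(0.05, 3)
  ev <- fixture_events(0.05, 3)
  wfm <- extract_waveforms(sim$recording, ev, window = 31, align_index = 12)
  expect_gte(mean(apply(wfm$waveforms, 1, which.max) == 12), 0.95)
  expect_equal(nrow(wfm$waveforms), length(ev$indices) - wfm$n_dropped)

  # single noiseless spike: the snippet is the template segment itself
  W <- make_templates(1, 60, seed = 9)
  pk <- attr(W, "peak_index")
  x <- selsort:::place_template(500, W[1, ], pk, 2000)
  wf1 <- extract_waveforms(recording(x), event_index(500), window = 31,
                           align_index = 12)
  expect_equal(as.numeric(wf1$waveforms[1, ]),
               x[(500 - 11):(500 + 19)])

  # events at the very edge are dropped and counted
  wf_edge <- extract_waveforms(recording(x), event_index(c(3, 500, 1998)),
                               window = 31, align_index = 12)
  expect_equal(wf_edge$n_dropped, 2L)
  expect_equal(nrow(wf_edge$waveforms), 1L)
})
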