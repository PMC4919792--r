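# Small hand-built scene: two known templates placed on a short trace with
# isolated "clustered" spikes, used across several tests below.
overlap_scene <- function(noise = 0, seed = 1, lag = 5, n_train = 20) {
  set.seed(seed)
  W <- make_templates(2, 60, seed = seed)
  pk <- attr(W, "peak_index")
  dur <- 24000
  t1 <- seq(400, 400 + (n_train - 1) * 600, by = 600)
  t2 <- t1 + 300
  ta <- 20000
  tb <- ta + lag
  x <- selsort:::place_template(c(t1, ta), W[1, ], pk, dur) +
    selsort:::place_template(c(t2, tb), W[2, ], pk, dur)
  if (noise > 0) x <- x + rnorm(dur, sd = noise)
  list(x = x, W = W, pk = pk, t1 = t1, t2 = t2, ta = ta, tb = tb, dur = dur)
}

test_that("impulse trains partition events into clusters and targets", {
  ev <- c(100L, 220L, 380L, 500L, 620L)
  assign <- cluster_assignment(c(1, 2, 0, 1, 0))
  it <- build_impulse_trains(assign, ev, 1000)
  expect_equal(it$trains, list(c(100, 500), 220))
  expect_equal(it$targets, c(380, 620))
  expect_setequal(c(unlist(it$trains), it$targets), ev)
  expect_equal(sum(lengths(it$trains)), sum(assign$sizes))

  empty <- build_impulse_trains(cluster_assignment(integer(0)), integer(0), 100)
  expect_length(empty$trains, 0)
})

test_that("Toeplitz template estimation matches its oracles", {
  sc <- overlap_scene(noise = 0, seed = 2, n_train = 6)
  # single spike, no noise: template equals the windowed trace segment
  one <- estimate_templates(sc$x, list(sc$t1[1]), lags = 30)
  expect_equal(as.numeric(one$templates[1, ]),
               sc$x[(sc$t1[1] - 30):(sc$t1[1] + 30)], tolerance = 1e-9)

  # isolated spikes: equals the plain spike-triggered average
  est <- estimate_templates(sc$x, list(sc$t1, sc$t2), lags = 30)
  avg <- colMeans(do.call(rbind, lapply(sc$t1, function(t)
    sc$x[(t - 30):(t + 30)])))
  expect_lt(max(abs(est$templates[1, ] - avg)), 1e-6)

  # spike rates are train sums over the duration
  expect_equal(est$spike_rates, lengths(list(sc$t1, sc$t2)) / sc$dur)

  # overlapping spikes: per-neuron normal equations match a dense least
  # squares solve on the same design matrix
  set.seed(4)
  times <- sort(sample(seq(100, 1900, by = 15), 12))
  Wd <- make_templates(1, 60, seed = 5)
  xd <- selsort:::place_template(times, Wd[1, ], attr(Wd, "peak_index"), 2000) +
    rnorm(2000, sd = 0.05)
  L <- 30
  X <- sapply(-L:L, function(tau) {
    d <- numeric(2000)
    ok <- times + tau >= 1 & times + tau <= 2000
    d[times[ok] + tau] <- 1
    d
  })
  w_ls <- qr.solve(X, xd)
  w_tpl <- estimate_templates(xd, list(times), lags = L)$templates[1, ]
  expect_lt(max(abs(w_tpl - w_ls)), 1e-6)
})

test_that("residual, autocovariance and whitening filter behave as specified", {
  sc <- overlap_scene(noise = 0, seed = 3)
  it <- list(sc$t1, sc$t2)
  est <- estimate_templates(sc$x, it, lags = 40)
  # perfect model, no noise: residual vanishes except at the overlap pair
  resid <- compute_noise_residual(sc$x, est, it)
  away <- setdiff(seq_len(sc$dur), (sc$ta - 100):(sc$tb + 100))
  expect_lt(max(abs(resid[away])), 1e-6)
  # unclustered spikes stay visible as residual peaks
  expect_gt(max(abs(resid[(sc$ta - 60):(sc$tb + 60)])), 0.5)
  expect_lte(sum(resid^2), sum(sc$x^2))

  # white-noise autocovariance: lag 0 near sigma^2, others near zero
  set.seed(6)
  wn <- rnorm(1e5, sd = 0.3)
  ac <- noise_autocovariance(wn, m = 20)
  expect_equal(ac[1], 0.09, tolerance = 0.01)
  expect_lt(max(abs(ac[-1])), 3 / sqrt(1e5))

  # AR(1) autocovariance follows phi^k
  ar <- as.numeric(stats::filter(rnorm(1e5), 0.8, method = "recursive"))
  aca <- noise_autocovariance(ar, m = 6)
  expect_equal(aca[-1] / aca[1], 0.8^(1:5), tolerance = 0.05)

  # brute-force double loop oracle on a short trace
  set.seed(8)
  s <- rnorm(500)
  m <- 8
  ref <- vapply(0:(m - 1), function(k)
    sum((s[1:(500 - k)] - mean(s)) * (s[(1 + k):500] - mean(s))) / 500,
    numeric(1))
  expect_equal(noise_autocovariance(s, m), ref, tolerance = 1e-10)

  # white noise: whitening filter is a unit impulse at the centre
  f <- coiflet_filter_from_cov(c(1, rep(0, 30)), m = 31)
  expect_equal(which.max(abs(f)), 16L)
  expect_equal(f[16], 1, tolerance = 1e-4)
  # symmetry, both variants
  fc <- coiflet_filter_from_cov(0.7^(0:30), m = 31)
  expect_equal(fc, rev(fc), tolerance = 1e-12)
  # the non-inverted variant equals the centre column of an explicit
  # Toeplitz matrix, L2-normalised
  ac2 <- 0.6^(0:14)
  fplain <- coiflet_filter_from_cov(ac2, m = 15, inverse = FALSE)
  Tm <- toeplitz(ac2)
  expect_equal(fplain, Tm[, 8] / sqrt(sum(Tm[, 8]^2)), tolerance = 1e-12)
  expect_error(coiflet_filter_from_cov(ac2, m = 14), "odd")
})

test_that("zero-phase whitening preserves length and raises spike SNR in correlated noise", {
  # impulse filter: identity
  x <- rnorm(5000)
  expect_equal(whiten(x, c(0, 0, 1, 0, 0)), x, tolerance = 1e-10)

  # correlated (AR1) noise around known spikes: the template-matched
  # response — what the likelihood matcher consumes — gains SNR after
  # whitening and template re-estimation on the whitened trace
  set.seed(9)
  W <- make_templates(1, 60, seed = 7)
  pk <- attr(W, "peak_index")
  times <- seq(500, 95000, by = 800)
  noise <- as.numeric(stats::filter(rnorm(1e5, sd = 0.1), 0.9,
                                    method = "recursive"))
  sig <- selsort:::place_template(times, W[1, ], pk, 1e5)
  x2 <- sig + noise
  f <- coiflet_filter_from_cov(noise_autocovariance(x2 - sig, 61))
  y <- whiten(x2, f)
  expect_length(y, 1e5)
  w_raw <- estimate_templates(x2, list(times), lags = 40)$templates[1, ]
  w_wht <- estimate_templates(y, list(times), lags = 40)$templates[1, ]
  mf <- function(tr, w) as.numeric(stats::filter(tr, rev(w), sides = 2))
  s_raw <- mf(x2, w_raw)
  s_wht <- mf(y, w_wht)
  quiet <- setdiff(500:99500, unlist(lapply(times, function(t) (t - 80):(t + 80))))
  expect_gt(mean(s_wht[times]) / sd(s_wht[quiet]),
            mean(s_raw[times]) / sd(s_raw[quiet]))
})

test_that("likelihood matching assigns clean windows, overlaps and priors correctly", {
  sc <- overlap_scene(noise = 0.02, seed = 10, lag = 5)
  it <- list(sc$t1, sc$t2)
  tset <- estimate_templates(sc$x, it, lags = 40)

  # noise-free-ish window equal to template 2: neuron 2 wins, residual small
  x1 <- selsort:::place_template(5000, tset$templates[2, ], 41, 10000)
  res1 <- match_unclustered(x1, tset, 5000, refractory = 60, noise_var = 4e-4)
  expect_equal(res1$accepted$neuron, 2)
  expect_equal(res1$accepted$time, 5000)

  # constructed overlap at 5 samples lag: both neurons recovered via the
  # two-spike explanation, residual energy < 5% of window energy
  resid <- compute_noise_residual(sc$x, tset, it)
  f <- coiflet_filter_from_cov(noise_autocovariance(resid, 61))
  vt <- whiten(sc$x, f)
  tset$filtered_templates <- estimate_templates(vt, it, lags = 40)$templates
  res2 <- match_unclustered(vt, tset, sc$ta, refractory = 60,
                            existing_trains = it)
  hit1 <- any(abs(res2$trains[[1]] - sc$ta) <= 3 & !(res2$trains[[1]] %in% sc$t1))
  hit2 <- any(abs(res2$trains[[2]] - sc$tb) <= 3 & !(res2$trains[[2]] %in% sc$t2))
  expect_true(hit1 && hit2)

  # residual energy after removing both accepted templates
  Wf <- tset$filtered_templates
  vres <- vt
  for (r in seq_len(nrow(res2$accepted))) {
    tn <- res2$accepted$time[r]
    nn <- res2$accepted$neuron[r]
    vres[(tn - 40):(tn + 40)] <- vres[(tn - 40):(tn + 40)] - Wf[nn, ]
  }
  win <- (sc$ta - 60):(sc$tb + 60)
  expect_lt(sum(vres[win]^2) / sum(vt[win]^2), 0.05)

  # equal match quality: the Bernoulli prior decides
  Wsame <- rbind(tset$templates[1, ], tset$templates[1, ])
  tset_eq <- structure(list(templates = Wsame, lags = -40:40,
                            spike_rates = c(0.01, 1e-5),
                            filtered_templates = NULL),
                       class = "ss_templates")
  xeq <- selsort:::place_template(5000, Wsame[1, ], 41, 10000)
  reseq <- match_unclustered(xeq, tset_eq, 5000, refractory = 60,
                             noise_var = 1e-4)
  first <- reseq$accepted[reseq$accepted$pass == 1, ]
  expect_equal(first$neuron[1], 1)

  # empty template set rejects all targets
  none <- match_unclustered(rnorm(1000), structure(
    list(templates = NULL, lags = -5:5, spike_rates = numeric(0),
         filtered_templates = NULL), class = "ss_templates"),
    c(100, 200), refractory = 60)
  expect_equal(none$rejected, c(100L, 200L))
})

test_that("matching respects the refractory period and detected indices", {
  sc <- overlap_scene(noise = 0.02, seed = 12, lag = 5)
  it <- list(sc$t1, sc$t2)
  tset <- estimate_templates(sc$x, it, lags = 40)
  # a target within the refractory span of an existing spike of the same
  # neuron cannot be re-assigned to it
  close_target <- sc$t1[3] + 30
  res <- match_unclustered(sc$x, tset, close_target, refractory = 60,
                           existing_trains = it)
  if (!is.null(res$accepted)) {
    expect_true(all(res$accepted$neuron != 1 |
                      abs(res$accepted$time - sc$t1[3]) >= 60))
  }
  for (tr in res$trains) {
    if (length(tr) > 1) expect_gte(min(diff(sort(tr))), 60)
  }
  # accepted events are a subset of the supplied targets
  if (!is.null(res$accepted)) {
    expect_true(all(res$accepted$event %in% close_target))
  }
})

test_that("end-to-end channel sorting recovers the simulated population", {
  sim <- fixture_sim(0.1, 5)
  res <- cached("sort-0.1-5", sort_channel(sim$recording))
  expect_equal(res$n_neurons, 3)
  expect_gt(sum(res$stages$assignment$labels == 0), 0)   # unassigned pool

  # matching only adds to the clustered spikes
  expect_gte(sum(lengths(res$trains)), sum(res$stages$assignment$sizes))

  # final trains honour the refractory period and live inside the trace
  for (tr in res$trains) {
    expect_gte(min(diff(tr)), 60)
    expect_true(all(tr >= 1 & tr <= length(sim$recording$samples)))
  }

  m <- evaluate_sorting(res, sim$truth)
  expect_gte(m$true_sorted / (m$true_sorted + m$missed), 0.9)

  # deterministic given the same input and seed
  res2 <- sort_channel(sim$recording)
  expect_identical(res2$trains, res$trains)
})
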