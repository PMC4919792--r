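#' @title Wavelet features and deviation-from-normality selection
#' @description Every aligned waveform is decomposed with a full orthonormal
#'   Haar transform; for each coefficient position the Kolmogorov-Smirnov
#'   distance between its standardised empirical distribution across
#'   waveforms and the standard normal CDF measures deviation from normality
#'   (a Lilliefors-style statistic: mean and SD are estimated from the data).
#'   Multimodal coefficients — the ones that separate neurons — deviate most,
#'   and the top ten form the clustering feature set. Kernel density curves
#'   per selected feature allow the choice to be cross-checked.
#' @name features
NULL

# One-level orthonormal Haar step on the columns of a row-matrix.
haar_step <- function(m) {
  n <- ncol(m)
  odd <- m[, seq(1, n, by = 2), drop = FALSE]
  even <- m[, seq(2, n, by = 2), drop = FALSE]
  list(approx = (odd + even) / sqrt(2), detail = (odd - even) / sqrt(2))
}

#' Full Haar decomposition of a waveform matrix
#'
#' Rows are zero-padded to the next power of two (norm preserving, so the
#' orthonormal transform satisfies Parseval exactly) and decomposed to full
#' depth. Columns hold, in order, the final approximation coefficient followed
#' by detail coefficients from coarsest to finest.
#'
#' @param wf an `ss_waveforms` or numeric matrix (one waveform per row).
#' @return `M x P` coefficient matrix, `P` the padded power of two.
#' @export
haar_decompose <- function(wf) {
  m <- if (inherits(wf, "ss_waveforms")) wf$waveforms else rbind(wf)
  if (ncol(m) < 4) stop_invalid("waveforms must have length >= 4")
  P <- 2^ceiling(log2(ncol(m)))
  if (P > ncol(m)) m <- cbind(m, matrix(0, nrow(m), P - ncol(m)))
  details <- list()
  while (ncol(m) > 1) {
    st <- haar_step(m)
    details <- c(list(st$detail), details)   # coarsest ends up first
    m <- st$approx
  }
  out <- do.call(cbind, c(list(m), details))
  colnames(out) <- c("a", paste0("d", seq_len(ncol(out) - 1)))
  out
}

#' Kolmogorov-Smirnov deviation-from-normality score per coefficient
#'
#' For each column, the KS distance between the empirical CDF of the
#' standardised values and the standard normal CDF. Zero-variance columns
#' score 0. No p-value is attached: the statistic itself ranks features.
#'
#' @param coeffs coefficient matrix from [haar_decompose()].
#' @return Numeric vector of scores, one per column.
#' @export
ks_deviation_scores <- function(coeffs) {
  apply(coeffs, 2, function(x) {
    s <- sd(x)
    if (!is.finite(s) || s == 0) return(0)
    z <- sort((x - mean(x)) / s)
    n <- length(z)
    p <- pnorm(z)
    max(abs(seq_len(n) / n - p), abs((seq_len(n) - 1) / n - p))
  })
}

#' Select the most non-normal coefficients as the feature set
#'
#' @param coeffs coefficient matrix from [haar_decompose()].
#' @param scores per-coefficient scores ([ks_deviation_scores()]).
#' @param d number of features to keep (10 by default); ties break towards
#'   the lower coefficient index.
#' @return list of class `ss_features`: `values` (`M x d`, columns in
#'   descending score order), `coeff_ids`, `ks_scores`.
#' @export
select_features <- function(coeffs, scores = ks_deviation_scores(coeffs),
                            d = 10) {
  if (length(scores) != ncol(coeffs))
    stop_invalid("scores/coefficient count mismatch")
  d <- min(as.integer(d), ncol(coeffs))
  ord <- order(-scores, seq_along(scores))
  sel <- ord[seq_len(d)]
  structure(list(values = coeffs[, sel, drop = FALSE],
                 coeff_ids = sel, ks_scores = scores[sel]),
            class = "ss_features")
}

#' @export
print.ss_features <- function(x, ...) {
  cat(sprintf("<ss_features: %d waveforms x %d features (KS %.3f .. %.3f)>\n",
              nrow(x$values), ncol(x$values),
              max(x$ks_scores), min(x$ks_scores)))
  invisible(x)
}

#' Per-feature probability density curves
#'
#' Gaussian kernel density per selected feature, bandwidth scaled from the
#' feature's spread (Silverman's rule), renormalised to integrate to one.
#' The number of local maxima is reported so multimodality — the visual
#' signature of a feature that separates clusters — can be checked
#' programmatically as well as by plotting.
#'
#' @param fm an `ss_features` (or numeric matrix).
#' @param n_grid evaluation grid size.
#' @return list of data frames, one per feature, with columns `x`, `density`;
#'   each has attribute `n_modes`. Zero-variance features yield a degenerate
#'   single-point "density" flagged with attribute `degenerate = TRUE`.
#' @export
feature_pdf <- function(fm, n_grid = 512) {
  vals <- if (inherits(fm, "ss_features")) fm$values else rbind(fm)
  if (nrow(vals) < 2) stop_invalid("need at least 2 waveforms for a density")
  lapply(seq_len(ncol(vals)), function(j) {
    x <- vals[, j]
    if (sd(x) == 0) {
      out <- data.frame(x = x[1], density = Inf)
      attr(out, "degenerate") <- TRUE
      attr(out, "n_modes") <- 1L
      return(out)
    }
    den <- density(x, bw = "nrd0", n = n_grid)
    area <- sum(diff(den$x) * (head(den$y, -1) + tail(den$y, -1)) / 2)
    y <- den$y / area
    out <- data.frame(x = den$x, density = y)
    # count interior local maxima carrying real mass (tail ripples excluded)
    dy <- diff(y)
    is_max <- dy[-length(dy)] > 0 & dy[-1] <= 0
    n_modes <- sum(is_max & y[2:(n_grid - 1)] > 0.05 * max(y))
    attr(out, "degenerate") <- FALSE
    attr(out, "n_modes") <- as.integer(max(n_modes, 1L))
    out
  })
}

#' Build the clustering feature set from waveforms in one call
#'
#' @param wf an `ss_waveforms`.
#' @param d number of features (default 10).
#' @return An `ss_features`.
#' @export
build_features <- function(wf, d = 10) {
  coeffs <- haar_decompose(wf)
  select_features(coeffs, ks_deviation_scores(coeffs), d = d)
}
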