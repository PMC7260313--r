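#' Signal energy
#'
#' Sum of squared samples of a discrete signal.
#'
#' @param signal Numeric vector.
#' @return Scalar energy (amplitude^2 x samples).
#' @export
energy <- function(signal) {
  if (length(signal) == 0) stopf("empty signal")
  sum(signal^2)
}

# Amplitude-histogram probabilities over equal-width bins spanning the
# observed range. A constant signal occupies a single bin.
amplitude_histogram <- function(signal, n_bins) {
  if (n_bins < 2) stopf("n_bins must be >= 2")
  rng <- range(signal)
  if (rng[1] == rng[2]) return(1)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  counts <- tabulate(findInterval(signal, breaks, rightmost.closed = TRUE,
                                  all.inside = TRUE), nbins = n_bins)
  p <- counts / sum(counts)
  p[p > 0]
}

#' Shannon entropy of the amplitude distribution
#'
#' `-sum(p * ln p)` over an equal-width amplitude histogram; empty bins
#' contribute nothing. A constant signal has entropy 0.
#'
#' @param signal Numeric vector.
#' @param n_bins Number of histogram bins (default 64).
#' @return Entropy in nats (>= 0).
#' @export
shannon_entropy <- function(signal, n_bins = 64) {
  p <- amplitude_histogram(signal, n_bins)
  -sum(p * log(p))
}

#' Renyi entropy of the amplitude distribution
#'
#' `(1/(1-alpha)) * ln sum(p^alpha)` over the same amplitude histogram as
#' [shannon_entropy()]; approaches the Shannon entropy as `alpha -> 1`.
#'
#' @param signal Numeric vector.
#' @param n_bins Number of histogram bins (default 64).
#' @param alpha Entropy order (> 0, != 1; default 2).
#' @return Entropy in nats (>= 0).
#' @export
renyi_entropy <- function(signal, n_bins = 64, alpha = 2) {
  if (alpha <= 0 || alpha == 1) stopf("alpha must be positive and != 1")
  p <- amplitude_histogram(signal, n_bins)
  log(sum(p^alpha)) / (1 - alpha)
}

#' Normalized spectral entropy over a frequency range
#'
#' The signal is cut into consecutive 1-s windows; in each window the
#' periodogram is restricted to `[f1, f2]`, normalized to a probability
#' distribution, and its Shannon entropy divided by `log` of the number of
#' in-band frequency components, giving a value in `[0, 1]` (0 for a single
#' spectral line, 1 for a flat in-band spectrum). Window values are
#' averaged.
#'
#' @param signal Numeric vector (at least 1 s long).
#' @param sample_rate Hz.
#' @param f1,f2 Frequency range in Hz, `f1 < f2 <=` Nyquist.
#' @return Scalar in `[0, 1]`.
#' @export
spectral_entropy <- function(signal, sample_rate, f1 = 1, f2 = 40) {
  if (!(f1 < f2 && f2 <= sample_rate / 2)) stopf("need f1 < f2 <= Nyquist")
  win <- floor(sample_rate)
  if (length(signal) < win) stopf("signal shorter than one 1-s window")
  n_win <- length(signal) %/% win
  vals <- vapply(seq_len(n_win), function(w) {
    x <- signal[((w - 1) * win + 1):(w * win)]
    pw <- Mod(fft(x))^2
    freqs <- (seq_along(x) - 1) * sample_rate / length(x)
    keep <- freqs >= f1 & freqs <= f2
    nb <- sum(keep)
    p <- pw[keep]
    tot <- sum(p)
    if (tot == 0) stopf("zero in-band power: spectral entropy undefined")
    p <- p[p > 0] / tot
    -sum(p * log(p)) / log(nb)
  }, numeric(1))
  mean(vals)
}

#' Box-counting (capacity) fractal dimension of a signal graph
#'
#' The signal graph is rescaled to the unit square and covered by dyadic
#' grids of side `2^-j`, `j = 2 .. floor(log2 n) - 2`; for each grid the
#' occupied boxes are counted column-wise between the per-column minimum and
#' maximum sample values, and the dimension is the least-squares slope of
#' `log N` against `log(1/eps)`, clipped to `[1, 2]`.
#'
#' @param signal Numeric vector (length >= 64).
#' @return Scalar in `[1, 2]`; 1.0 by convention for a constant signal.
#' @export
box_dimension <- function(signal) {
  n <- length(signal)
  if (n < 64) stopf("need at least 64 samples")
  rng <- range(signal)
  if (rng[1] == rng[2]) return(1.0)
  x <- (signal - rng[1]) / (rng[2] - rng[1])
  t_scaled <- (seq_len(n) - 1) / (n - 1)
  js <- 2:(floor(log2(n)) - 2)
  counts <- vapply(js, function(j) box_count(t_scaled, x, j), numeric(1))
  slope <- stats::coef(stats::lm(log(counts) ~ I(js * log(2))))[2]
  min(max(unname(slope), 1), 2)
}

# Number of occupied eps = 2^-j boxes of the graph (t, x) in [0,1]^2,
# counting per time-column the span between min and max sample values.
box_count <- function(t_scaled, x, j) {
  nb <- 2^j
  col <- pmin(floor(t_scaled * nb), nb - 1)
  row <- pmin(floor(x * nb), nb - 1)
  lo <- tapply(row, col, min)
  hi <- tapply(row, col, max)
  sum(hi - lo + 1)
}

#' Higuchi fractal dimension
#'
#' Average normalized curve lengths `L(k)` over sub-sampled series at delays
#' `k = 1 .. k_max` and offsets `m`, fitted as the least-squares slope of
#' `log L(k)` against `log(1/k)`. Close to 1 for smooth curves and 2 for
#' white noise.
#'
#' @param signal Numeric vector with `length > 2 * k_max`.
#' @param k_max Maximum delay (default 20).
#' @return Scalar fractal dimension.
#' @export
higuchi_fd <- function(signal, k_max = 20) {
  n <- length(signal)
  if (k_max < 2) stopf("k_max must be >= 2")
  if (n <= 2 * k_max) stopf("signal too short for k_max = %d", k_max)
  lk <- vapply(seq_len(k_max), function(k) {
    lm_k <- vapply(seq_len(k), function(m) {
      idx <- seq(m, n, by = k)
      ni <- length(idx) - 1
      if (ni < 1) return(NA_real_)
      (sum(abs(diff(signal[idx]))) * (n - 1) / (ni * k)) / k
    }, numeric(1))
    mean(lm_k, na.rm = TRUE)
  }, numeric(1))
  ks <- seq_len(k_max)
  unname(stats::coef(stats::lm(log(lk) ~ log(1 / ks)))[2])
}

#' Katz fractal dimension
#'
#' `log10(n) / (log10(d/L) + log10(n))` with `L` the waveform length (sum
#' of absolute successive amplitude differences), `d` the maximum absolute
#' excursion from the first sample, and `n` the number of steps — the
#' standard waveform convention, which makes the measure exactly invariant
#' to amplitude scaling. Exactly 1.0 for a monotone straight line.
#'
#' @param signal Numeric vector (length >= 2).
#' @return Scalar >= 1.
#' @export
katz_fd <- function(signal) {
  n_pts <- length(signal)
  if (n_pts < 2) stopf("need at least 2 samples")
  steps <- n_pts - 1
  l <- sum(abs(diff(signal)))
  d <- max(abs(signal - signal[1]))
  if (d == 0 || l == 0) stopf("degenerate waveform: zero extent from first point")
  denom <- log10(d / l) + log10(steps)
  if (denom <= 0) stopf("degenerate waveform: maximal folding (d/L = 1/n)")
  log10(steps) / denom
}

#' Extract all per-channel signal features of an epoch
#'
#' Computes energy, Shannon/spectral/Renyi entropies and box-counting,
#' Higuchi and Katz fractal dimensions for every channel of a band-limited
#' epoch. Spectral entropy is evaluated over the epoch's band edges (or
#' 1-40 Hz for broadband epochs).
#'
#' @param epoch An `eeg_epoch`.
#' @param n_bins Histogram bins for the amplitude entropies (default 64).
#' @param k_max Higuchi delay ceiling (default 20).
#' @param renyi_alpha Renyi order (default 2).
#' @return data.frame with columns `feature`, `channel`, `value`
#'   (7 features x channels rows, deterministically ordered).
#' @export
extract_signal_features <- function(epoch, n_bins = 64, k_max = 20,
                                    renyi_alpha = 2) {
  stopifnot(inherits(epoch, "eeg_epoch"))
  defs <- band_definitions()
  if (epoch$band %in% defs$band) {
    f1 <- defs$low[defs$band == epoch$band]
    f2 <- defs$high[defs$band == epoch$band]
  } else {
    f1 <- 1; f2 <- 40
  }
  feats <- c("energy", "shannon", "spectral", "renyi", "fbd", "hfd", "kfd")
  n_ch <- nrow(epoch$data)
  rows <- lapply(seq_len(n_ch), function(ch) {
    x <- epoch$data[ch, ]
    data.frame(
      feature = feats,
      channel = ch,
      value = c(energy(x),
                shannon_entropy(x, n_bins),
                spectral_entropy(x, epoch$sample_rate, f1, f2),
                renyi_entropy(x, n_bins, renyi_alpha),
                box_dimension(x),
                higuchi_fd(x, k_max),
                katz_fd(x)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(match(out$feature, feats), out$channel), ]
  rownames(out) <- NULL
  out
}
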