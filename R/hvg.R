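#' Horizontal visibility graph of a time series
#'
#' Maps each sample to a node; two samples are connected iff every strictly
#' intermediate sample lies strictly below both endpoints (ties block
#' visibility). Consecutive samples are always connected. Computed with the
#' standard O(n) decreasing-stack sweep.
#'
#' @param signal Numeric vector (length >= 2).
#' @return An `hvg` object: list with `n` and `edges` (2-column integer
#'   matrix, first column < second).
#' @export
horizontal_visibility_graph <- function(signal) {
  n <- length(signal)
  if (n < 2) stopf("need at least 2 samples")
  from <- integer(2L * n)
  to <- integer(2L * n)
  ne <- 0L
  stack <- integer(n)
  top <- 0L
  for (j in seq_len(n)) {
    while (top > 0L && signal[stack[top]] < signal[j]) {
      ne <- ne + 1L; from[ne] <- stack[top]; to[ne] <- j
      top <- top - 1L
    }
    if (top > 0L) {
      ne <- ne + 1L; from[ne] <- stack[top]; to[ne] <- j
      if (signal[stack[top]] == signal[j]) top <- top - 1L
    }
    top <- top + 1L
    stack[top] <- j
  }
  structure(list(n = n, edges = cbind(from = from[seq_len(ne)],
                                      to = to[seq_len(ne)])),
            class = "hvg")
}

#' Degree sequence of a visibility graph
#'
#' Per-node degrees in time order, treated downstream as a derived time
#' series for synchronization estimation.
#'
#' @param adjacency An `hvg` object (from
#'   [horizontal_visibility_graph()]).
#' @return Integer vector of length `n`.
#' @export
degree_sequence <- function(adjacency) {
  stopifnot(inherits(adjacency, "hvg"))
  tabulate(c(adjacency$edges[, 1], adjacency$edges[, 2]),
           nbins = adjacency$n)
}

#' Lagged cross-correlation between two degree sequences
#'
#' Both sequences are standardized to zero mean and unit (population)
#' variance; the normalized cross-correlation `sum(x[t+h] y[t]) / (N - |h|)`
#' is evaluated at all lags `|h| <= max_lag` and the signed value of maximal
#' magnitude is returned (ties broken toward smaller `|h|`, then positive
#' lag), clipped into `[-1, 1]`.
#'
#' @param ds_x,ds_y Equal-length numeric vectors.
#' @param max_lag Maximum lag in samples.
#' @return Scalar in `[-1, 1]`.
#' @export
ds_cross_correlation <- function(ds_x, ds_y, max_lag) {
  n <- length(ds_x)
  if (length(ds_y) != n) stopf("sequences must have equal length")
  sx <- sd_pop(ds_x); sy <- sd_pop(ds_y)
  if (sx == 0 || sy == 0) stopf("constant degree sequence: correlation undefined")
  zx <- (ds_x - mean(ds_x)) / sx
  zy <- (ds_y - mean(ds_y)) / sy
  lags <- 0:max_lag
  cc_pos <- vapply(lags, function(h)
    sum(zx[(1 + h):n] * zy[1:(n - h)]) / (n - h), numeric(1))
  cc_neg <- vapply(lags, function(h)
    sum(zy[(1 + h):n] * zx[1:(n - h)]) / (n - h), numeric(1))
  cc <- c(rbind(cc_pos, cc_neg)) # ordered by |h| then sign (+ first)
  best <- cc[which.max(abs(cc))]
  min(max(best, -1), 1)
}

#' HVG degree-sequence connectivity matrix of an epoch
#'
#' For every channel the HVG degree sequence is computed and standardized;
#' all pairwise lagged cross-correlations (maximal-magnitude signed value
#' over `|h| <= max_lag`) form a symmetric weighted connectivity matrix with
#' unit diagonal. Lagged sums are evaluated for all pairs at once via
#' shifted cross-products.
#'
#' @param epoch An `eeg_epoch`.
#' @param max_lag Maximum lag in samples; default `sample_rate / 8`
#'   (125 ms).
#' @return A `connectivity_matrix`: symmetric channels x channels matrix
#'   with attributes `band` and `subject_id`.
#' @export
build_connectivity <- function(epoch, max_lag = NULL) {
  stopifnot(inherits(epoch, "eeg_epoch"))
  if (is.null(max_lag)) max_lag <- floor(epoch$sample_rate / 8)
  x <- epoch$data
  n_ch <- nrow(x)
  n <- ncol(x)
  z <- matrix(0, n, n_ch)
  for (ch in seq_len(n_ch)) {
    if (sd_pop(x[ch, ]) == 0)
      stopf("channel %d is constant: no visibility structure", ch)
    ds <- degree_sequence(horizontal_visibility_graph(x[ch, ]))
    s <- sd_pop(ds)
    if (s == 0)
      stopf("channel %d has a constant degree sequence", ch)
    z[, ch] <- (ds - mean(ds)) / s
  }
  best <- crossprod(z) / n # lag 0, all pairs
  best_abs <- abs(best)
  for (h in seq_len(max_lag)) {
    m <- crossprod(z[(1 + h):n, , drop = FALSE],
                   z[1:(n - h), , drop = FALSE]) / (n - h)
    # m[i, j] = cc_{ij}(+h); its transpose covers negative lags
    for (cand in list(m, t(m))) {
      upd <- abs(cand) > best_abs
      best[upd] <- cand[upd]
      best_abs[upd] <- abs(cand[upd])
    }
  }
  w <- (best + t(best)) / 2 # numeric symmetrization (max search is symmetric)
  w <- pmin(pmax(w, -1), 1)
  diag(w) <- 1
  structure(w, class = c("connectivity_matrix", "matrix"),
            band = epoch$band, subject_id = epoch$subject_id)
}
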