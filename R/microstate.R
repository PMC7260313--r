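#' Global field power curve
#'
#' Per-sample population standard deviation of the potentials across
#' channels: the instantaneous strength of the scalp field. Local maxima of
#' the GFP curve index the moments of highest topographic signal-to-noise.
#'
#' @param epoch An `eeg_epoch` (>= 2 channels).
#' @return Numeric vector, one non-negative value per sample.
#' @export
gfp <- function(epoch) {
  stopifnot(inherits(epoch, "eeg_epoch"))
  if (nrow(epoch$data) < 2) stopf("GFP needs at least 2 channels")
  x <- epoch$data
  mu <- colMeans(x)
  sqrt(colMeans(sweep(x, 2, mu)^2))
}

# Indices of strict local maxima of v honoring a minimum index distance:
# peaks are visited from highest to lowest and kept greedily.
find_peaks <- function(v, min_distance) {
  n <- length(v)
  if (n < 3) return(integer(0))
  cand <- which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] > v[3:n]) + 1L
  if (length(cand) == 0) return(integer(0))
  cand <- cand[order(v[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (p in cand) {
    if (all(abs(p - kept) >= min_distance)) kept <- c(kept, p)
  }
  sort(kept)
}

#' Extract mean-centered topographies at GFP peaks
#'
#' Finds the strict local maxima of the epoch's GFP curve, honoring a
#' minimum peak distance (default 20 ms); if more than `max_maps` peaks
#' exist, the `max_maps` highest-GFP peaks are kept, ordered by descending
#' GFP. Each returned topography is mean-centered across channels.
#'
#' @param epoch An `eeg_epoch`.
#' @param min_distance Minimum peak separation in ms (default 20).
#' @param max_maps Upper bound on the number of maps (default 500).
#' @return Matrix of topographies (rows = maps, columns = channels) with
#'   attribute `gfp` (the peak GFP values).
#' @export
extract_peak_maps <- function(epoch, min_distance = 20, max_maps = 500) {
  g <- gfp(epoch)
  min_samp <- max(1L, round(min_distance / 1000 * epoch$sample_rate))
  peaks <- find_peaks(g, min_samp)
  if (length(peaks) == 0) stopf("no GFP peaks found (flat GFP curve?)")
  peaks <- peaks[order(g[peaks], decreasing = TRUE)]
  peaks <- head(peaks, max_maps)
  maps <- t(epoch$data[, peaks, drop = FALSE])
  maps <- maps - rowMeans(maps)
  attr(maps, "gfp") <- g[peaks]
  maps
}

# Polarity-invariant assignment: for maps (rows, zero-mean) and prototypes
# (columns of a, unit-norm zero-mean), returns the index of the prototype
# maximizing squared spatial correlation, plus the squared correlations.
assign_maps <- function(maps, a) {
  norms <- sqrt(rowSums(maps^2))
  norms[norms == 0] <- 1
  corr <- (maps / norms) %*% a
  act <- corr^2
  list(labels = max.col(act, ties.method = "first"),
       act = act, corr = corr)
}

# Fix prototype sign deterministically: largest-|.| component positive.
orient_map <- function(v) {
  if (v[which.max(abs(v))] < 0) -v else v
}

#' Polarity-invariant modified K-means clustering of topographies
#'
#' The classic microstate clustering: maps are assigned to the prototype
#' with the largest squared spatial correlation (so a map and its polarity
#' reverse are equivalent), and each prototype is updated as the dominant
#' eigenvector of the outer-product sum (scatter) of its assigned maps.
#' The best of `n_restarts` random initializations by explained variance is
#' returned; an emptied cluster is re-seeded from the worst-fitted map.
#'
#' @param maps Matrix of topographies (rows = maps, columns = channels);
#'   rows are mean-centered internally.
#' @param K Number of clusters (`K <= nrow(maps)`).
#' @param n_restarts Random restarts (default 20).
#' @param tol Relative explained-variance convergence tolerance
#'   (default 1e-6).
#' @param seed Integer seed (restarts are deterministic given it).
#' @param max_iter Iteration cap per restart.
#' @return A `microstate_model`: list with `maps` (channels x K, unit-norm
#'   zero-mean columns), `K`, `labels` (assignment of the training maps),
#'   `explained_variance`, `cv`, `gev`.
#' @export
modified_kmeans <- function(maps, K, n_restarts = 20, tol = 1e-6, seed = 1,
                            max_iter = 100) {
  maps <- as.matrix(maps)
  K <- as.integer(K)
  gfp_w <- attr(maps, "gfp")
  maps <- maps - rowMeans(maps)
  n <- nrow(maps)
  c_ch <- ncol(maps)
  if (n < K) stopf("need at least K maps (have %d, K = %d)", n, K)
  total_ss <- sum(maps^2)

  best <- NULL
  for (r in seq_len(n_restarts)) {
    set.seed(derive_seed(seed, paste0("restart-", r)))
    init <- sample.int(n, K)
    a <- t(maps[init, , drop = FALSE])
    a <- apply(a, 2, function(v) {
      nv <- sqrt(sum(v^2)); if (nv == 0) v + 1 / c_ch else v / nv
    })
    ev_prev <- -Inf
    for (it in seq_len(max_iter)) {
      asg <- assign_maps(maps, a)
      lab <- asg$labels
      # re-seed empty clusters from the worst-fitted map
      for (k in seq_len(K)) {
        if (!any(lab == k)) {
          worst <- which.min(apply(asg$act, 1, max))
          lab[worst] <- k
        }
      }
      for (k in seq_len(K)) {
        mk <- maps[lab == k, , drop = FALSE]
        s <- crossprod(mk)
        a[, k] <- orient_map(eigen(s, symmetric = TRUE)$vectors[, 1])
      }
      asg <- assign_maps(maps, a)
      proj <- asg$corr[cbind(seq_len(n), asg$labels)]^2 * rowSums(maps^2)
      ev <- sum(proj) / total_ss
      if (is.finite(ev_prev) && abs(ev - ev_prev) <= tol * max(ev_prev, 1e-12))
        break
      ev_prev <- ev
    }
    if (is.null(best) || ev > best$explained_variance) {
      best <- list(maps = a, K = K, labels = asg$labels,
                   explained_variance = ev)
    }
  }
  model <- structure(best, class = "microstate_model")
  model$cv <- if (K < c_ch - 1) cv_criterion(maps, model) else NA_real_
  model$gev <- gev(maps, model, gfp_w)
  model
}

#' Cross-validation criterion of a microstate model
#'
#' `CV = sigma2_hat * ((C - 1) / (C - K - 1))^2`, where `sigma2_hat` is the
#' residual-noise variance estimator
#' `sum_n (x_n' x_n - (a_{l_n}' x_n)^2) / (N (C - 1))` under the
#' polarity-invariant assignment. Lower is better; the minimizing `K`
#' balances fit against degrees of freedom.
#'
#' @param maps Matrix of topographies (rows = maps).
#' @param model A `microstate_model`.
#' @return Scalar CV value.
#' @export
cv_criterion <- function(maps, model) {
  maps <- as.matrix(maps)
  maps <- maps - rowMeans(maps)
  n <- nrow(maps)
  c_ch <- ncol(maps)
  if (model$K >= c_ch - 1) stopf("K >= C - 1: degrees of freedom exhausted")
  asg <- assign_maps(maps, model$maps)
  proj <- (maps %*% model$maps)[cbind(seq_len(n), asg$labels)]
  sigma2 <- sum(rowSums(maps^2) - proj^2) / (n * (c_ch - 1))
  sigma2 * ((c_ch - 1) / (c_ch - model$K - 1))^2
}

#' Global explained variance of a microstate model
#'
#' GFP^2-weighted mean of the squared spatial correlation between each map
#' and its assigned prototype; in `[0, 1]`, 1 for a perfect fit.
#'
#' @param maps Matrix of topographies (rows = maps).
#' @param model A `microstate_model`.
#' @param gfp_values Optional per-map GFP weights; defaults to the maps' own
#'   across-channel standard deviation (or the matrix's `gfp` attribute).
#' @return Fraction in `[0, 1]`.
#' @export
gev <- function(maps, model, gfp_values = NULL) {
  maps <- as.matrix(maps)
  if (is.null(gfp_values)) gfp_values <- attr(maps, "gfp")
  maps <- maps - rowMeans(maps)
  if (is.null(gfp_values)) gfp_values <- sqrt(rowMeans(maps^2))
  asg <- assign_maps(maps, model$maps)
  corr2 <- asg$act[cbind(seq_len(nrow(maps)), asg$labels)]
  w <- gfp_values^2
  if (sum(w) == 0) return(0)
  sum(w * corr2) / sum(w)
}

#' Global map dissimilarity between two topographies
#'
#' Euclidean distance between the two GFP-normalized maps divided by
#' `sqrt(C)`: 0 for identical shape at any strength, 2 for opposite
#' polarity, `sqrt(2)` for orthogonal zero-mean maps.
#'
#' @param map_a,map_b Numeric vectors (equal length, non-flat).
#' @return Scalar in `[0, 2]`.
#' @export
gmd <- function(map_a, map_b) {
  if (length(map_a) != length(map_b)) stopf("maps must have equal length")
  c_ch <- length(map_a)
  a <- map_a - mean(map_a)
  b <- map_b - mean(map_b)
  ga <- sqrt(mean(a^2)); gb <- sqrt(mean(b^2))
  if (ga == 0 || gb == 0) stopf("zero-GFP map: dissimilarity undefined")
  sqrt(sum((a / ga - b / gb)^2)) / sqrt(c_ch)
}

#' Back-fit a microstate model to an epoch
#'
#' Labels every sample (or only GFP-peak samples, which are then propagated
#' to the surrounding troughs) with the GMD-nearest prototype — equivalently
#' the prototype of maximal absolute spatial correlation, so labeling is
#' polarity-invariant and amplitude-invariant. Rare zero-GFP samples take
#' the preceding label.
#'
#' @param epoch An `eeg_epoch`.
#' @param model A `microstate_model` (band should match the epoch's).
#' @param at_peaks If `TRUE`, assign labels only at GFP peaks and extend
#'   each label to the surrounding samples (nearest-peak rule); default
#'   `FALSE`, i.e. every sample is fitted.
#' @return A `segmentation`: list with `labels` (per-sample class), and
#'   `segments` (run-length data.frame: class, start, duration in samples
#'   and ms).
#' @export
backfit <- function(epoch, model, at_peaks = FALSE) {
  stopifnot(inherits(epoch, "eeg_epoch"), inherits(model, "microstate_model"))
  x <- sweep(epoch$data, 2, colMeans(epoch$data)) # mean-center each sample
  n <- ncol(x)
  nrm <- sqrt(colSums(x^2))
  ok <- nrm > 0
  corr <- matrix(0, n, model$K)
  corr[ok, ] <- t(x[, ok, drop = FALSE] / rep(nrm[ok], each = nrow(x))) %*%
    model$maps
  labels <- max.col(corr^2, ties.method = "first")
  if (any(!ok)) { # carry previous label over flat samples
    for (i in which(!ok)) labels[i] <- if (i > 1) labels[i - 1] else labels[ok][1]
  }
  if (at_peaks) {
    g <- gfp(epoch)
    peaks <- find_peaks(g, 1L)
    if (length(peaks) > 0) {
      pos <- findInterval(seq_len(n), peaks)
      left <- pmax(pos, 1L)
      right <- pmin(pos + 1L, length(peaks))
      dl <- abs(seq_len(n) - peaks[left])
      dr <- abs(seq_len(n) - peaks[right])
      nearest <- ifelse(dr < dl, peaks[right], peaks[left])
      labels <- labels[nearest]
    }
  }
  new_segmentation(labels, epoch$sample_rate, model$K)
}

new_segmentation <- function(labels, sample_rate, K) {
  seg <- label_runs(labels)
  seg$duration_ms <- seg$length / sample_rate * 1000
  structure(list(labels = labels, segments = seg,
                 sample_rate = sample_rate, K = K),
            class = "segmentation")
}

#' Reject microstate segments shorter than a duration threshold
#'
#' Iteratively dissolves every segment shorter than `threshold` (default
#' 30 ms): each of its samples is relabeled to the most likely class by the
#' GMD measure among the classes of the adjacent segments, which absorbs
#' noise blips into the surrounding runs. Segments are recomputed and the
#' pass repeated until no sub-threshold segment remains or an iteration cap
#' is reached (then a warning is raised and the current state returned).
#'
#' @param seg A `segmentation` from [backfit()].
#' @param model The `microstate_model` used for the fit.
#' @param epoch The fitted `eeg_epoch`.
#' @param threshold Minimum segment duration in ms (default 30).
#' @param max_iter Iteration cap (default twice the initial segment count).
#' @return A smoothed `segmentation`.
#' @export
smooth_segments <- function(seg, model, epoch, threshold = 30,
                            max_iter = NULL) {
  stopifnot(inherits(seg, "segmentation"))
  min_samp <- max(1L, round(threshold / 1000 * epoch$sample_rate))
  x <- sweep(epoch$data, 2, colMeans(epoch$data))
  nrm <- sqrt(colSums(x^2))
  nrm[nrm == 0] <- 1
  corr2 <- (t(x / rep(nrm, each = nrow(x))) %*% model$maps)^2

  labels <- seg$labels
  if (is.null(max_iter)) max_iter <- 2L * nrow(label_runs(labels))
  for (it in seq_len(max_iter)) {
    runs <- label_runs(labels)
    short <- which(runs$length < min_samp)
    if (length(short) == 0 || nrow(runs) == 1)
      return(new_segmentation(labels, seg$sample_rate, seg$K))
    # dissolve the single shortest segment, then re-derive the run table:
    # absorbing a blip merges its neighbors, so later decisions must see
    # the merged structure
    s <- short[which.min(runs$length[short])]
    cand <- unique(c(if (s > 1) runs$class[s - 1],
                     if (s < nrow(runs)) runs$class[s + 1]))
    idx <- runs$start[s]:(runs$start[s] + runs$length[s] - 1L)
    labels[idx] <- cand[max.col(corr2[idx, cand, drop = FALSE],
                                ties.method = "first")]
  }
  warnf("sub-threshold segments remain after smoothing")
  new_segmentation(labels, seg$sample_rate, seg$K)
}

#' Temporal microstate statistics of a segmentation
#'
#' Per microstate class: occurrence (average number of segments per
#' second), duration (mean segment length in ms) and coverage (fraction of
#' samples labeled with the class). Coverage sums to 1 across classes, and
#' `occurrence * duration / 1000` approximates coverage up to epoch-boundary
#' effects. A class that never occurs reports zeros.
#'
#' @param seg A `segmentation`.
#' @param sample_rate Hz (defaults to the segmentation's own rate).
#' @return data.frame with columns `class`, `occurrence`, `duration`,
#'   `coverage`.
#' @export
microstate_features <- function(seg, sample_rate = seg$sample_rate) {
  stopifnot(inherits(seg, "segmentation"))
  n <- length(seg$labels)
  secs <- n / sample_rate
  out <- lapply(seq_len(seg$K), function(k) {
    runs <- seg$segments[seg$segments$class == k, , drop = FALSE]
    data.frame(class = k,
               occurrence = nrow(runs) / secs,
               duration = if (nrow(runs)) mean(runs$duration_ms) else 0,
               coverage = sum(runs$length) / n)
  })
  do.call(rbind, out)
}

#' Fit a global microstate model across subjects, selecting K
#'
#' Pools the GFP-peak topographies of all supplied band-limited epochs,
#' fits a polarity-invariant modified K-means model for every `K` in
#' `K_range`, and returns the model minimizing the cross-validation
#' criterion. The CV and GEV curves over `K_range` are retained for
#' inspection. Set `K_range` to a single value to bypass model selection
#' (e.g. the conventional 3 maps for alpha/beta and 4 for delta/theta).
#'
#' @param epochs List of band-limited `eeg_epoch` objects (one band).
#' @param K_range Integer vector of candidate map counts (default `2:6`).
#' @param n_restarts,tol Passed to [modified_kmeans()].
#' @param min_distance,max_maps Passed to [extract_peak_maps()];
#'   `max_maps` bounds the maps pooled per epoch.
#' @param seed Integer seed.
#' @return The selected `microstate_model`, with `band`, `selection`
#'   (data.frame K/cv/gev) and `K_range` fields added.
#' @export
fit_global_model <- function(epochs, K_range = 2:6, n_restarts = 20,
                             tol = 1e-6, min_distance = 20, max_maps = 500,
                             seed = 1) {
  stopifnot(length(epochs) >= 1)
  band <- epochs[[1]]$band
  pooled <- lapply(epochs, extract_peak_maps, min_distance = min_distance,
                   max_maps = max_maps)
  gfp_w <- unlist(lapply(pooled, attr, "gfp"))
  maps <- do.call(rbind, pooled)
  attr(maps, "gfp") <- gfp_w
  c_ch <- ncol(maps)
  if (any(K_range >= c_ch - 1)) {
    warnf("K_range truncated to K < C - 1 = %d", c_ch - 1)
    K_range <- K_range[K_range < c_ch - 1]
  }
  fits <- lapply(K_range, function(k)
    modified_kmeans(maps, k, n_restarts = n_restarts, tol = tol,
                    seed = derive_seed(seed, paste0("K", k))))
  # the residual-variance estimator behind the CV criterion runs over all
  # EEG time samples, not only the clustered peak maps
  samples <- do.call(rbind, lapply(epochs, function(ep) t(ep$data)))
  cvs <- vapply(fits, function(f) cv_criterion(samples, f), numeric(1))
  gevs <- vapply(fits, function(f) gev(samples, f), numeric(1))
  model <- fits[[which.min(cvs)]]
  model$band <- band
  model$K_range <- K_range
  model$cv <- cvs[which.min(cvs)]
  model$gev <- gevs[which.min(cvs)]
  model$selection <- data.frame(K = K_range, cv = cvs, gev = gevs)
  model
}

#' @export
print.microstate_model <- function(x, ...) {
  cat(sprintf("<microstate_model> K = %d, band = %s, CV = %.4g, GEV = %.3f\n",
              x$K, if (is.null(x$band)) "?" else x$band, x$cv, x$gev))
  invisible(x)
}
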