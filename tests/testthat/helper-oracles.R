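# Independent brute-force oracles and small fixture builders used across the
# suite. Everything here is deliberately naive: the point is independence
# from the implementation paths being checked.

# O(n^2) horizontal-visibility scan straight from the definition.
bf_hvg_edges <- function(x) {
  n <- length(x)
  edges <- NULL
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    visible <- if (j == i + 1) TRUE else
      all(x[(i + 1):(j - 1)] < min(x[i], x[j]))
    if (visible) edges <- rbind(edges, c(i, j))
  }
  edges
}

edge_key <- function(e) paste(e[, 1], e[, 2], sep = "-")

# Exhaustive triple enumeration of the scaled-weight clustering coefficient.
bf_clustering <- function(w) {
  a <- abs(w); diag(a) <- 0
  wt <- a / max(a)
  n <- nrow(a)
  sapply(seq_len(n), function(i) {
    nb <- which(a[i, ] > 0)
    d <- length(nb)
    if (d < 2) return(0)
    s <- 0
    for (j in nb) for (k in nb) if (j != k)
      s <- s + (wt[i, j] * wt[j, k] * wt[k, i])^(1 / 3)
    s / (d * (d - 1))
  })
}

# All simple paths between a pair (recursive DFS); shortest-path counting
# betweenness for tiny weighted graphs with lengths 1/|w|.
bf_betweenness <- function(w) {
  a <- abs(w); diag(a) <- 0
  n <- nrow(a)
  len <- ifelse(a > 0, 1 / a, Inf)
  paths_between <- function(from, to) {
    out <- list()
    walk <- function(path, dist) {
      v <- path[length(path)]
      if (v == to) { out[[length(out) + 1]] <<- list(path = path, dist = dist); return() }
      for (u in which(is.finite(len[v, ]))) if (!(u %in% path))
        walk(c(path, u), dist + len[v, u])
    }
    walk(from, 0)
    out
  }
  b <- numeric(n)
  for (s in 1:(n - 1)) for (t in (s + 1):n) {
    ps <- paths_between(s, t)
    if (length(ps) == 0) next
    dists <- vapply(ps, `[[`, numeric(1), "dist")
    sp <- ps[abs(dists - min(dists)) < 1e-12]
    for (v in setdiff(seq_len(n), c(s, t))) {
      through <- sum(vapply(sp, function(p) v %in% p$path, logical(1)))
      b[v] <- b[v] + through / length(sp)
    }
  }
  b
}

# Power iteration on |w|: independent route to the Perron pair.
bf_power_iteration <- function(w, iters = 5000) {
  a <- abs(w)
  v <- rep(1, nrow(a)) / sqrt(nrow(a))
  lam <- 0
  for (i in seq_len(iters)) {
    nv <- a %*% v
    lam <- sqrt(sum(nv^2))
    if (lam == 0) return(list(lambda = 0, vector = v))
    nv <- as.numeric(nv) / lam
    if (sum(abs(nv - v)) < 1e-13) { v <- nv; break }
    v <- nv
  }
  list(lambda = lam, vector = v)
}

# Naive double-loop dyadic box count over the unit-square-rescaled graph.
bf_box_count <- function(x, j) {
  n <- length(x)
  rng <- range(x)
  xs <- (x - rng[1]) / (rng[2] - rng[1])
  ts <- (seq_len(n) - 1) / (n - 1)
  nb <- 2^j
  total <- 0
  for (col in 0:(nb - 1)) {
    inside <- which(pmin(floor(ts * nb), nb - 1) == col)
    if (length(inside) == 0) next
    rows <- pmin(floor(xs[inside] * nb), nb - 1)
    total <- total + (max(rows) - min(rows) + 1)
  }
  total
}

# Random symmetric weight matrix with unit diagonal.
random_connectivity <- function(n, seed) {
  set.seed(seed)
  w <- matrix(runif(n * n, -1, 1), n)
  w <- (w + t(w)) / 2
  diag(w) <- 1
  w
}

# A band-limited epoch built directly from the generator (no re-filtering):
# the carrier is already confined to the requested band.
planted_beta_epoch <- function(seed, snr = 10, n_templates = 3L) {
  cfg <- generator_config(seed = seed, snr = snr, patient_jitter = 0,
                          n_templates = c(beta = as.integer(n_templates)))
  rec <- simulate_recording(cfg, "EP01", "epilepsy")
  list(epoch = eeg_epoch(rec$data, rec$sample_rate, "beta", "s1", "EP01",
                         "epilepsy"),
       recording = rec)
}

planted_beta_epochs <- function(seed, snr = 10, patients = 2L, epochs = 5L) {
  cfg <- generator_config(seed = seed, snr = snr, patient_jitter = 0,
                          n_templates = c(beta = 3L),
                          patients_per_group = patients,
                          epochs_per_patient = epochs)
  ds <- simulate_dataset(cfg)
  list(epochs = lapply(ds, function(r)
         eeg_epoch(r$data, r$sample_rate, "beta", r$subject_id, r$patient_id,
                   r$group)),
       dataset = ds)
}

# Map model classes onto generator templates by maximal absolute correlation.
match_classes <- function(model, templates) {
  apply(abs(stats::cor(model$maps, templates)), 1, which.max)
}

# Small sine-based recording for filter tests.
sine_recording <- function(freqs, fs = 256, secs = 16) {
  t <- (0:(fs * secs - 1)) / fs
  data <- do.call(rbind, lapply(freqs, function(f) sin(2 * pi * f * t)))
  structure(list(data = data, sample_rate = fs,
                 channel_labels = paste0("Ch", seq_along(freqs)),
                 patient_id = "P1", group = "epilepsy"),
            class = "eeg_recording")
}
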