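#' Configuration for the synthetic EEG generator
#'
#' Bundles and validates the parameters of the synthetic multichannel EEG
#' generator. The defaults emulate the clinical recording geometry the
#' package targets: 27 electrodes sampled at 256 Hz in 16-s epochs, two
#' diagnostic groups of 5 patients with 10 epochs ("subjects") each.
#' Band-limited microstate structure is planted in the delta, theta, alpha
#' and beta bands (4, 4, 3 and 3 quasi-stable topographies respectively);
#' the gamma range carries only background noise.
#'
#' @param n_channels Number of electrodes (default 27).
#' @param sample_rate Sampling rate in Hz (default 256).
#' @param epoch_seconds Epoch duration in seconds (default 16).
#' @param patients_per_group Patients per diagnostic group (default 5).
#' @param epochs_per_patient Epochs ("subjects") per patient (default 10).
#' @param n_templates Named integer vector: planted microstate classes per
#'   band. Default `c(delta = 4, theta = 4, alpha = 3, beta = 3)`.
#' @param mean_state_duration Mean microstate duration in milliseconds
#'   (default 80).
#' @param coverage_shift Perturbation in `[0, 0.5)` of the second group's
#'   beta-band coverage toward its first template; 0 makes the two groups'
#'   generative distributions identical.
#' @param snr Per-channel linear amplitude ratio RMS(template signal) /
#'   RMS(pink-noise background); `Inf` disables the background.
#' @param patient_jitter Standard deviation of a small per-patient
#'   logit-scale coverage perturbation (default 0.02) giving patients an
#'   individual fingerprint, which is what makes the patient-wise
#'   cross-validation split meaningfully stricter than a subject-wise one.
#' @param seed Integer seed; all generator randomness derives from it.
#' @return A validated `generator_config` object (a list).
#' @export
generator_config <- function(n_channels = 27L,
                             sample_rate = 256,
                             epoch_seconds = 16,
                             patients_per_group = 5L,
                             epochs_per_patient = 10L,
                             n_templates = c(delta = 4L, theta = 4L,
                                             alpha = 3L, beta = 3L),
                             mean_state_duration = 80,
                             coverage_shift = 0,
                             snr = 5,
                             patient_jitter = 0.02,
                             seed = 1L) {
  counts <- c(n_channels, patients_per_group, epochs_per_patient, n_templates)
  if (any(counts < 1)) stopf("all counts must be >= 1")
  n_samples <- sample_rate * epoch_seconds
  if (abs(n_samples - round(n_samples)) > 1e-9)
    stopf("sample_rate * epoch_seconds must be an integer")
  if (coverage_shift < 0 || coverage_shift >= 0.5)
    stopf("coverage_shift must lie in [0, 0.5)")
  k_beta <- n_templates[["beta"]]
  if (1 / k_beta + coverage_shift >= 1 ||
      (1 - (1 / k_beta + coverage_shift)) / (k_beta - 1) <= 0)
    stopf("coverage_shift pushes a class probability outside (0,1)")
  if (mean_state_duration / 1000 * sample_rate < 2)
    stopf("mean_state_duration must span at least 2 samples")
  structure(list(
    n_channels = as.integer(n_channels),
    sample_rate = sample_rate,
    epoch_seconds = epoch_seconds,
    n_samples = as.integer(round(n_samples)),
    patients_per_group = as.integer(patients_per_group),
    epochs_per_patient = as.integer(epochs_per_patient),
    n_templates = n_templates,
    mean_state_duration = mean_state_duration,
    coverage_shift = coverage_shift,
    snr = snr,
    patient_jitter = patient_jitter,
    seed = as.integer(seed)
  ), class = "generator_config")
}

#' Draw a set of dissimilar unit-norm scalp topographies
#'
#' Generates `n_templates` random topography vectors over `n_channels`
#' electrodes, each zero-mean across channels and unit Euclidean norm, with
#' every pairwise absolute spatial correlation at most 0.7. These play the
#' role of microstate class maps in the synthetic generator.
#'
#' @param n_templates Number of topographies (>= 2).
#' @param n_channels Number of electrodes (>= 3).
#' @param seed Integer seed.
#' @param max_corr Pairwise absolute-correlation ceiling (default 0.7).
#' @param max_attempts Resampling budget before giving up.
#' @return List of numeric vectors, each zero-mean with unit norm.
#' @export
make_templates <- function(n_templates, n_channels, seed,
                           max_corr = 0.7, max_attempts = 500L) {
  if (n_templates < 2) stopf("n_templates must be >= 2")
  if (n_channels < 3) stopf("n_channels must be >= 3")
  set.seed(seed)
  for (attempt in seq_len(max_attempts)) {
    maps <- lapply(seq_len(n_templates), function(i) {
      v <- rnorm(n_channels)
      v <- v - mean(v)
      v / sqrt(sum(v^2))
    })
    m <- do.call(rbind, maps)
    gram <- m %*% t(m)
    if (max(abs(gram[upper.tri(gram)])) <= max_corr) return(maps)
  }
  stopf("could not draw %d topographies with |corr| <= %.2f in %d attempts",
        n_templates, max_corr, max_attempts)
}

# Solve per-state entry weights and mean durations of the no-self-transition
# semi-Markov process so that its long-run coverage equals `coverage` exactly
# and the entry-weighted mean duration equals `mean_samples`. The planted
# coverage is split between entry rate and duration (sqrt split), with the
# entry share of any state capped at 0.45: in a chain that never
# self-transitions, no state can be entered more than half the time.
solve_state_process <- function(coverage, mean_samples, entry_cap = 0.45) {
  k <- length(coverage)
  p_star <- sqrt(coverage)
  p_star <- p_star / sum(p_star)
  if (max(p_star) > entry_cap) {
    # shrink entry shares toward uniform until the cap binds
    lambda <- (entry_cap - 1 / k) / (max(p_star) - 1 / k)
    p_star <- lambda * p_star + (1 - lambda) / k
  }
  if (k == 2) {
    w <- c(0.5, 0.5)
    p_hat <- c(0.5, 0.5)
  } else {
    # entry weights w with stationary entry shares proportional to p_star:
    # w_i (1 - w_i) = gamma * p_star_i, sum(w) = 1. When no such w exists
    # (shares too skewed for a no-self-transition chain), shrink the target
    # shares toward uniform until it does; the per-state durations absorb
    # the remainder, so long-run coverage is unaffected.
    f <- function(g) sum((1 - sqrt(pmax(0, 1 - 4 * g * p_star))) / 2) - 1
    repeat {
      gamma_max <- (1 - 1e-9) / (4 * max(p_star))
      if (f(gamma_max) >= 0) break
      p_star <- 0.7 * p_star + 0.3 / k
    }
    g <- uniroot(f, c(1e-12, gamma_max), tol = 1e-12)$root
    w <- (1 - sqrt(pmax(0, 1 - 4 * g * p_star))) / 2
    w <- w / sum(w)
    p_hat <- w * (1 - w)
    p_hat <- p_hat / sum(p_hat)
  }
  mean_dur <- mean_samples * coverage / p_hat
  list(entry_weights = w, entry_shares = p_hat,
       mean_durations = pmax(mean_dur, 1))
}

#' Simulate a per-sample microstate label sequence
#'
#' Semi-Markov run-length process: a state is held for a geometric duration,
#' then switches to a different state (no self-transitions). Entry weights
#' and per-state mean durations are solved jointly so the long-run fraction
#' of time each state is active equals `coverage` and the average segment
#' duration equals `mean_duration`.
#'
#' @param n_samples Sequence length in samples.
#' @param n_templates Number of states.
#' @param coverage Probability vector (length `n_templates`, sums to 1):
#'   target long-run fraction of time per state. A zero entry silences that
#'   state (with a warning).
#' @param mean_duration Mean segment duration in milliseconds.
#' @param sample_rate Sampling rate in Hz.
#' @param seed Integer seed.
#' @return Integer vector of length `n_samples` with values in
#'   `1:n_templates`.
#' @export
simulate_label_sequence <- function(n_samples, n_templates, coverage,
                                    mean_duration, sample_rate, seed) {
  if (length(coverage) != n_templates)
    stopf("coverage must have one entry per template")
  if (abs(sum(coverage) - 1) > 1e-8) stopf("coverage must sum to 1")
  mean_samples <- mean_duration / 1000 * sample_rate
  if (mean_samples < 2) stopf("mean_duration must span at least 2 samples")
  set.seed(seed)

  active <- which(coverage > 0)
  if (length(active) < n_templates)
    warnf("states with zero coverage are never emitted: %s",
          paste(setdiff(seq_len(n_templates), active), collapse = ", "))
  if (length(active) == 1) return(rep(active, n_samples))

  proc <- solve_state_process(coverage[active], mean_samples)
  w <- proc$entry_weights
  md <- proc$mean_durations

  labels <- integer(n_samples)
  pos <- 0L
  state <- sample.int(length(active), 1L, prob = proc$entry_shares)
  while (pos < n_samples) {
    dur <- 1L + rgeom(1L, prob = 1 / md[state])
    take <- min(dur, n_samples - pos)
    labels[(pos + 1L):(pos + take)] <- active[state]
    pos <- pos + take
    if (pos >= n_samples) break
    others <- setdiff(seq_along(active), state)
    state <- others[sample.int(length(others), 1L,
                               prob = w[others] / sum(w[others]))]
  }
  labels
}

# Beta-band coverage vector for a group, shifted toward the first template
# for the second group.
group_coverage <- function(k, shift) {
  cov <- rep(1 / k, k)
  if (shift != 0) {
    cov[1] <- cov[1] + shift
    cov[-1] <- cov[-1] - shift / (k - 1)
  }
  cov
}

# Small per-patient multiplicative jitter of a coverage vector.
jitter_coverage <- function(cov, sd, seed) {
  if (sd <= 0) return(cov)
  set.seed(seed)
  j <- cov * exp(rnorm(length(cov), 0, sd))
  j / sum(j)
}

# Band edges used by the generator's per-band carriers.
generator_bands <- function() {
  list(delta = c(1, 4), theta = c(4, 8), alpha = c(9, 13), beta = c(14, 30))
}

# The shared microstate topographies per band for a generator configuration.
generator_templates <- function(config) {
  bands <- names(config$n_templates)
  out <- lapply(bands, function(b) {
    maps <- make_templates(config$n_templates[[b]], config$n_channels,
                           seed = derive_seed(config$seed, paste0("tmpl-", b)))
    do.call(cbind, maps) # channels x K
  })
  names(out) <- bands
  out
}

#' Simulate one synthetic EEG epoch-length recording
#'
#' Builds a 27-channel (by default) recording as a sum over bands of a
#' planted microstate process: in each band the active template topography
#' is modulated by a band-limited noise carrier, and a pink-noise background
#' is added at the configured SNR. The beta-band coverage of group
#' `"pnes"` is shifted toward its first template by `config$coverage_shift`.
#'
#' @param config A [generator_config()].
#' @param patient_id Patient identifier string.
#' @param group `"epilepsy"` or `"pnes"`.
#' @param epoch_index Index of the epoch within the patient (seeds the
#'   epoch's random stream).
#' @param templates Optional pre-computed template list (from
#'   `generator_templates`); supplied by [simulate_dataset()] to avoid
#'   recomputation.
#' @return An `eeg_recording`: list with `data` (channels x samples matrix),
#'   `sample_rate`, `channel_labels`, `patient_id`, `group`, and
#'   `true_labels` (a list of per-band ground-truth label sequences).
#' @export
simulate_recording <- function(config, patient_id, group,
                               epoch_index = 1L, templates = NULL) {
  stopifnot(inherits(config, "generator_config"))
  group <- match.arg(group, c("epilepsy", "pnes"))
  if (is.null(templates)) templates <- generator_templates(config)
  n <- config$n_samples
  fs <- config$sample_rate
  bands <- generator_bands()

  sig <- matrix(0, config$n_channels, n)
  true_labels <- list()
  for (b in names(templates)) {
    k <- ncol(templates[[b]])
    cov <- rep(1 / k, k)
    if (b == "beta" && group == "pnes")
      cov <- group_coverage(k, config$coverage_shift)
    cov <- jitter_coverage(cov, config$patient_jitter,
                           derive_seed(config$seed,
                                       paste0("jit-", b, "-", patient_id)))
    lab <- simulate_label_sequence(
      n, k, cov, config$mean_state_duration, fs,
      seed = derive_seed(config$seed,
                         paste0("lab-", b, "-", patient_id, "-", epoch_index)))
    set.seed(derive_seed(config$seed,
                         paste0("car-", b, "-", patient_id, "-", epoch_index)))
    carrier <- rnorm(n)
    bf <- signal::butter(4, bands[[b]] / (fs / 2), type = "pass")
    carrier <- signal::filtfilt(bf, carrier)
    carrier <- carrier / rms(carrier)
    sig <- sig + templates[[b]][, lab] *
      matrix(carrier, config$n_channels, n, byrow = TRUE)
    true_labels[[b]] <- lab
  }
  sig <- sig * 10 # arbitrary-unit scale (~uV); all features are documented
                  # as amplitude-robust or amplitude-carrying

  if (is.finite(config$snr)) {
    for (ch in seq_len(config$n_channels)) {
      nz <- pink_noise(n, seed = derive_seed(
        config$seed, paste0("noise-", patient_id, "-", epoch_index, "-", ch)))
      sig[ch, ] <- sig[ch, ] + nz * rms(sig[ch, ]) / config$snr
    }
  }

  structure(list(
    data = sig,
    sample_rate = fs,
    channel_labels = if (config$n_channels == 27) EEG_CHANNELS_27 else
      paste0("Ch", seq_len(config$n_channels)),
    patient_id = patient_id,
    group = group,
    epoch_index = as.integer(epoch_index),
    true_labels = true_labels,
    templates = templates
  ), class = "eeg_recording")
}

#' Simulate the full synthetic study dataset
#'
#' Generates `patients_per_group` patients per group, each contributing
#' `epochs_per_patient` epoch-length recordings ("subjects"); at defaults,
#' 100 recordings of 27 channels x 4096 samples.
#'
#' @param config A [generator_config()].
#' @return List of `eeg_recording` objects with `subject_id` fields
#'   `"<patient>_e<epoch>"`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  templates <- generator_templates(config)
  out <- list()
  for (grp in c("epilepsy", "pnes")) {
    for (p in seq_len(config$patients_per_group)) {
      pid <- sprintf("%s%02d", if (grp == "epilepsy") "EP" else "PN", p)
      for (e in seq_len(config$epochs_per_patient)) {
        rec <- simulate_recording(config, pid, grp, epoch_index = e,
                                  templates = templates)
        rec$subject_id <- sprintf("%s_e%02d", pid, e)
        out[[length(out) + 1L]] <- rec
      }
    }
  }
  out
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d ch x %d samples @ %g Hz | patient %s (%s)\n",
              nrow(x$data), ncol(x$data), x$sample_rate,
              x$patient_id, x$group))
  invisible(x)
}
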