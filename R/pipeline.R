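#' Band-decompose a dataset of recordings into per-band epochs
#'
#' Applies the 1-40 Hz broadband conditioning filter, cuts each recording
#' into 16-s epochs (one per epoch-length recording) and band-passes each
#' into the requested sub-bands.
#'
#' @param dataset List of `eeg_recording` objects (e.g. from
#'   [simulate_dataset()]).
#' @param bands Band names (default the four microstate bands).
#' @param epoch_seconds Epoch length in seconds (default 16).
#' @param broadband Apply the 1-40 Hz conditioning filter first (default
#'   TRUE).
#' @return Named list: for each band, a list of band-limited `eeg_epoch`
#'   objects in dataset order.
#' @export
prepare_band_epochs <- function(dataset,
                                bands = c("delta", "theta", "alpha", "beta"),
                                epoch_seconds = 16, broadband = TRUE) {
  out <- stats::setNames(vector("list", length(bands)), bands)
  for (rec in dataset) {
    if (broadband) rec <- broadband_filter(rec, 1, 40)
    for (ep in epochize(rec, epoch_seconds)) {
      bl <- decompose_bands(ep, bands)
      for (b in bands) out[[b]][[length(out[[b]]) + 1L]] <- bl[[b]]
    }
  }
  out
}

epoch_meta <- function(epochs) {
  data.frame(
    subject_id = vapply(epochs, `[[`, "", "subject_id"),
    patient_id = vapply(epochs, `[[`, "", "patient_id"),
    group = vapply(epochs, `[[`, "", "group"),
    stringsAsFactors = FALSE
  )
}

#' Microstate feature table of a dataset
#'
#' Fits one global microstate model per band on the pooled GFP-peak maps of
#' all subjects, back-fits it to every subject's epoch, rejects segments
#' shorter than `smooth_ms`, and tabulates occurrence, duration and
#' coverage per class. Columns are named `"<band>_<family>_<class>"`.
#'
#' @param band_epochs Output of [prepare_band_epochs()].
#' @param K Named integer vector of map counts per band (default the
#'   conventional 3 for alpha/beta and 4 for delta/theta); a band absent
#'   from `K` triggers CV-based selection over `K_range`.
#' @param K_range Candidate map counts when selecting (default `2:6`).
#' @param smooth_ms Minimum segment duration in ms (default 30; 0 disables
#'   smoothing).
#' @param max_maps Peak maps pooled per epoch (default 500).
#' @param seed Integer seed.
#' @return List with `features` (wide feature table) and `models` (the
#'   per-band `microstate_model`s).
#' @export
microstate_feature_table <- function(band_epochs,
                                     K = c(delta = 4L, theta = 4L,
                                           alpha = 3L, beta = 3L),
                                     K_range = 2:6, smooth_ms = 30,
                                     max_maps = 500, seed = 1) {
  feats <- NULL
  models <- list()
  for (b in names(band_epochs)) {
    eps <- band_epochs[[b]]
    kr <- if (b %in% names(K)) K[[b]] else K_range
    model <- fit_global_model(eps, K_range = kr, max_maps = max_maps,
                              seed = derive_seed(seed, paste0("msmod-", b)))
    models[[b]] <- model
    block <- t(vapply(eps, function(ep) {
      seg <- backfit(ep, model)
      if (smooth_ms > 0) seg <- smooth_segments(seg, model, ep,
                                                threshold = smooth_ms)
      mf <- microstate_features(seg)
      stats::setNames(
        c(mf$occurrence, mf$duration, mf$coverage),
        c(paste0(b, "_occurrence_", mf$class),
          paste0(b, "_duration_", mf$class),
          paste0(b, "_coverage_", mf$class)))
    }, numeric(3 * model$K)))
    feats <- if (is.null(feats)) as.data.frame(block) else cbind(feats, block)
  }
  features <- cbind(epoch_meta(band_epochs[[1]]), feats)
  list(features = features, models = models)
}

#' Per-channel signal feature table of a dataset
#'
#' Extracts the seven per-channel signal descriptors for every epoch and
#' band; columns are `"<band>_<feature>_<channel>"`.
#'
#' @param band_epochs Output of [prepare_band_epochs()].
#' @param ... Passed to [extract_signal_features()].
#' @return Wide feature table.
#' @export
signal_feature_table <- function(band_epochs, ...) {
  feats <- NULL
  for (b in names(band_epochs)) {
    block <- t(vapply(band_epochs[[b]], function(ep) {
      sf <- extract_signal_features(ep, ...)
      stats::setNames(sf$value, paste0(b, "_", sf$feature, "_", sf$channel))
    }, numeric(7 * nrow(band_epochs[[b]][[1]]$data))))
    feats <- if (is.null(feats)) as.data.frame(block) else cbind(feats, block)
  }
  cbind(epoch_meta(band_epochs[[1]]), feats)
}

#' Functional-network feature table of a dataset
#'
#' Extracts the HVG degree-sequence connectivity network and its weighted
#' graph measures for every epoch and band; columns are
#' `"<band>_<measure>"`.
#'
#' @param band_epochs Output of [prepare_band_epochs()].
#' @param max_lag Maximum cross-correlation lag (default 125 ms worth of
#'   samples).
#' @return Wide feature table.
#' @export
network_feature_table <- function(band_epochs, max_lag = NULL) {
  feats <- NULL
  for (b in names(band_epochs)) {
    n_ch <- nrow(band_epochs[[b]][[1]]$data)
    block <- t(vapply(band_epochs[[b]], function(ep) {
      v <- extract_network_features(ep, max_lag)
      stats::setNames(v, paste0(b, "_", names(v)))
    }, numeric(4 * n_ch + 3)))
    feats <- if (is.null(feats)) as.data.frame(block) else cbind(feats, block)
  }
  cbind(epoch_meta(band_epochs[[1]]), feats)
}

#' Specify an end-to-end experiment
#'
#' @param feature_family `"signal"`, `"network"` or `"microstate"`.
#' @param bands Band subset (microstate experiments are restricted to
#'   delta/theta/alpha/beta).
#' @param classifiers Classifier names (default [default_classifiers()]).
#' @param config A [generator_config()] (used when no dataset is supplied).
#' @param seed Integer master seed.
#' @param importance Also run the applicable leave-one-out protocols
#'   (default FALSE).
#' @return An `experiment_spec` list.
#' @export
experiment_spec <- function(feature_family = c("microstate", "signal",
                                               "network"),
                            bands = NULL,
                            classifiers = default_classifiers(),
                            config = generator_config(),
                            seed = 1, importance = FALSE) {
  feature_family <- match.arg(feature_family)
  if (is.null(bands))
    bands <- if (feature_family == "microstate")
      c("delta", "theta", "alpha", "beta") else band_definitions()$band
  if (feature_family == "microstate" &&
      !all(bands %in% c("delta", "theta", "alpha", "beta")))
    stopf("microstate analysis is restricted to delta/theta/alpha/beta")
  structure(list(feature_family = feature_family, bands = bands,
                 classifiers = classifiers, config = config, seed = seed,
                 importance = importance),
            class = "experiment_spec")
}

#' Run an end-to-end experiment
#'
#' Simulates (or accepts) a dataset, extracts the requested feature family
#' per band, and evaluates the classifier battery under the patient-wise
#' paired split scheme; optionally adds the leave-one-band-out and (for
#' microstate features) leave-one-feature-out importance tables.
#'
#' @param spec An [experiment_spec()].
#' @param dataset Optional list of `eeg_recording`s; simulated from
#'   `spec$config` when omitted.
#' @param cache_dir Optional directory for content-addressed feature
#'   caching: the feature table is stored under the MD5 of the run manifest
#'   (configuration + seed + experiment settings) and reused bit-identically
#'   when an identical experiment is re-run.
#' @return List with `manifest`, `features`, `results`, `scheme`, plus
#'   `band_importance` / `feature_importance` when requested and `models`
#'   for microstate runs.
#' @export
run_experiment <- function(spec, dataset = NULL, cache_dir = NULL) {
  stopifnot(inherits(spec, "experiment_spec"))
  manifest <- run_manifest(spec$config, spec$seed,
                           extra = list(feature_family = spec$feature_family,
                                        bands = spec$bands,
                                        classifiers = spec$classifiers))
  cache_file <- NULL
  if (!is.null(cache_dir) && is.null(dataset)) {
    dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
    key_file <- tempfile()
    jsonlite::write_json(manifest[c("seed", "config", "settings")], key_file,
                         auto_unbox = TRUE, digits = NA)
    cache_file <- file.path(cache_dir,
                            paste0(unname(tools::md5sum(key_file)),
                                   ".csv"))
    unlink(key_file)
  }
  models <- NULL
  if (!is.null(cache_file) && file.exists(cache_file)) {
    features <- read_feature_table(cache_file)
  } else {
    if (is.null(dataset)) dataset <- simulate_dataset(spec$config)
    band_epochs <- prepare_band_epochs(dataset, spec$bands)
    features <- switch(spec$feature_family,
      microstate = {
        mt <- microstate_feature_table(band_epochs,
                                       seed = derive_seed(spec$seed, "ms"))
        models <- mt$models
        mt$features
      },
      signal = signal_feature_table(band_epochs),
      network = network_feature_table(band_epochs)
    )
    if (!is.null(cache_file)) write_feature_table(features, cache_file)
  }
  scheme <- build_split_scheme(unique(features[, c("patient_id", "group")]))
  results <- run_battery(features, scheme, spec$classifiers, seed = spec$seed)
  out <- list(manifest = manifest, features = features, scheme = scheme,
              results = results, models = models)
  if (isTRUE(spec$importance)) {
    out$band_importance <- leave_one_band_out(features, scheme,
                                              spec$classifiers, spec$seed)
    if (spec$feature_family == "microstate")
      out$feature_importance <- leave_one_feature_out(features, scheme,
                                                      spec$classifiers,
                                                      spec$seed)
  }
  out
}
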