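test_that("GFP is the across-channel population standard deviation", {
  ep <- eeg_epoch(rbind(c(1, 2), c(1, -2)), 256)
  g <- gfp(ep)
  expect_identical(g[1], 0) # all channels equal
  expect_identical(g[2], 2) # mean 0, deviations +-2
  two <- eeg_epoch(rbind(1, -1), 256)
  expect_identical(gfp(two), 1)

  set.seed(8)
  x <- matrix(rnorm(27 * 100), 27)
  oracle <- apply(x, 2, function(v) sqrt(mean((v - mean(v))^2)))
  expect_equal(gfp(eeg_epoch(x, 256)), oracle, tolerance = 1e-12)
})

test_that("peak maps honor distance, truncation and determinism", {
  # single template modulated by a tone: one GFP peak per half-cycle
  tmpl <- make_templates(2, 8, seed = 1)[[1]]
  carrier <- sin(2 * pi * 8 * (0:1023) / 256) # 8 Hz, 4 s -> 64 half-cycles
  ep <- eeg_epoch(outer(tmpl, carrier), 256)
  maps <- extract_peak_maps(ep, min_distance = 4, max_maps = 1000)
  expect_equal(nrow(maps), 64, tolerance = 0.05)

  res <- planted_beta_epoch(seed = 5, snr = 5)
  m10 <- extract_peak_maps(res$epoch, max_maps = 10)
  expect_identical(nrow(m10), 10L)
  expect_true(all(diff(attr(m10, "gfp")) <= 0)) # sorted by GFP descending
  expect_identical(extract_peak_maps(res$epoch), extract_peak_maps(res$epoch))
  expect_error(extract_peak_maps(eeg_epoch(matrix(1, 3, 100), 256)), "peaks")
})

test_that("modified K-means recovers noiseless sign-flipped prototypes", {
  protos <- qr.Q(qr(matrix(rnorm(12 * 3), 12)))[, 1:3] # orthonormal columns
  protos <- apply(protos, 2, function(v) { v <- v - mean(v); v / sqrt(sum(v^2)) })
  set.seed(2)
  signs <- sample(c(-1, 1), 150, replace = TRUE)
  maps <- t(protos[, rep(1:3, each = 50)]) * signs
  fit <- modified_kmeans(maps, 3, n_restarts = 5, seed = 3)
  agreement <- abs(t(fit$maps) %*% protos)
  expect_true(all(apply(agreement, 2, max) >= 0.999))
  expect_equal(fit$explained_variance, 1, tolerance = 1e-9)

  # K = 1: prototype is the dominant eigenvector of the scatter
  one <- modified_kmeans(maps, 1, n_restarts = 2, seed = 3)
  sc <- eigen(crossprod(maps), symmetric = TRUE)$vectors[, 1]
  expect_gt(abs(sum(one$maps[, 1] * sc)), 0.9999)
})

test_that("planted-template recovery from generated beta epochs", {
  res <- planted_beta_epoch(seed = 9, snr = 10)
  maps <- extract_peak_maps(res$epoch)
  fit <- modified_kmeans(maps, 3, n_restarts = 10, seed = 4)
  rc <- abs(stats::cor(fit$maps, res$recording$templates$beta))
  expect_true(all(apply(rc, 2, max) >= 0.95))
  # determinism
  fit2 <- modified_kmeans(maps, 3, n_restarts = 10, seed = 4)
  expect_identical(fit$maps, fit2$maps)
})

test_that("the CV criterion matches its closed-form evaluation", {
  set.seed(6)
  maps <- matrix(rnorm(6 * 8), 6)
  maps <- maps - rowMeans(maps)
  fit <- modified_kmeans(maps, 2, n_restarts = 5, seed = 1)
  # brute force: polarity-invariant assignment, residual variance, penalty
  a <- fit$maps; c_ch <- 8; n <- 6
  lab <- apply(maps, 1, function(x) {
    cr <- abs(apply(a, 2, function(p) sum(p * x) /
                      sqrt(sum(p^2) * sum(x^2))))
    which.max(cr)
  })
  sigma2 <- sum(vapply(1:n, function(i)
    sum(maps[i, ]^2) - sum(a[, lab[i]] * maps[i, ])^2, numeric(1))) /
    (n * (c_ch - 1))
  expect_equal(cv_criterion(maps, fit), sigma2 * ((c_ch - 1) / (c_ch - 3))^2,
               tolerance = 1e-12)

  # perfect fit: maps equal to prototypes -> zero residual
  pure <- t(fit$maps)
  expect_equal(cv_criterion(pure, fit), 0, tolerance = 1e-12)
  expect_error(cv_criterion(maps, structure(list(maps = matrix(0, 8, 7),
                                                 K = 7),
                                            class = "microstate_model")),
               "degrees of freedom")
})

test_that("GEV is the GFP^2-weighted squared-correlation fraction", {
  protos <- make_templates(2, 10, seed = 3)
  fit <- structure(list(maps = cbind(protos[[1]], protos[[2]]), K = 2L),
                   class = "microstate_model")
  pure <- rbind(3 * protos[[1]], -2 * protos[[2]], 0.5 * protos[[1]])
  expect_equal(gev(pure, fit), 1, tolerance = 1e-12)

  set.seed(14)
  maps <- matrix(rnorm(20 * 10), 20)
  maps <- maps - rowMeans(maps)
  g <- sqrt(rowMeans(maps^2))
  corr2 <- sapply(1:20, function(i) {
    max(sapply(1:2, function(k) {
      p <- fit$maps[, k]; x <- maps[i, ]
      (sum(p * x) / sqrt(sum(p^2) * sum(x^2)))^2
    }))
  })
  expect_equal(gev(maps, fit), sum(g^2 * corr2) / sum(g^2),
               tolerance = 1e-12)
})

test_that("GMD obeys its strength-invariant identities", {
  set.seed(4)
  v <- rnorm(27)
  expect_equal(gmd(v, 5.3 * v), 0, tolerance = 1e-12)
  expect_equal(gmd(v, -v), 2, tolerance = 1e-12)
  v0 <- v - mean(v)
  w <- rnorm(27); w0 <- w - mean(w)
  w0 <- w0 - sum(w0 * v0) / sum(v0^2) * v0 # orthogonal, zero-mean
  expect_equal(gmd(v0, w0), sqrt(2), tolerance = 1e-12)
  expect_error(gmd(v, rep(1, 27)), "zero-GFP")

  # pseudo-metric behaviour on a random battery
  for (s in 1:10) {
    set.seed(s)
    a <- rnorm(12); b <- rnorm(12); c <- rnorm(12)
    expect_equal(gmd(a, b), gmd(b, a), tolerance = 1e-12)
    expect_lte(gmd(a, c), gmd(a, b) + gmd(b, c) + 1e-12)
  }
})

test_that("back-fitting labels by polarity-invariant similarity", {
  protos <- make_templates(3, 9, seed = 5)
  a <- cbind(protos[[1]], protos[[2]], protos[[3]])
  model <- structure(list(maps = a, K = 3L), class = "microstate_model")
  carrier <- sin(2 * pi * 10 * (1:512) / 256) + 1.2
  ep2 <- eeg_epoch(outer(protos[[2]], carrier), 256)
  seg <- backfit(ep2, model)
  expect_true(all(seg$labels == 2))

  # amplitude scaling leaves labels unchanged
  res <- planted_beta_epoch(seed = 3, snr = 5)
  maps <- extract_peak_maps(res$epoch)
  fit <- modified_kmeans(maps, 3, n_restarts = 5, seed = 1)
  s1 <- backfit(res$epoch, fit)
  scaled <- res$epoch; scaled$data <- 0.01 * scaled$data
  expect_identical(s1$labels, backfit(scaled, fit)$labels)

  # segments tile the epoch exactly
  expect_identical(sum(s1$segments$length), ncol(res$epoch$data))
  expect_true(all(diff(s1$segments$start) == head(s1$segments$length, -1)))
})

test_that("noiseless back-fitting recovers the planted sequence", {
  res <- planted_beta_epoch(seed = 21, snr = Inf)
  maps <- extract_peak_maps(res$epoch)
  fit <- modified_kmeans(maps, 3, n_restarts = 10, seed = 2)
  cls <- match_classes(fit, res$recording$templates$beta)
  seg <- backfit(res$epoch, fit)
  acc <- mean(cls[seg$labels] == res$recording$true_labels$beta)
  expect_gte(acc, 0.95)
})

test_that("segment smoothing removes blips and denoises labels", {
  # no sub-threshold segments -> identity
  protos <- make_templates(2, 8, seed = 2)
  model <- structure(list(maps = cbind(protos[[1]], protos[[2]]), K = 2L),
                     class = "microstate_model")
  lab <- rep(c(1L, 2L), each = 128)
  ep <- eeg_epoch(sapply(lab, function(l) protos[[l]] * 4), 256)
  seg <- backfit(ep, model)
  expect_identical(smooth_segments(seg, model, ep, 30)$labels, seg$labels)

  # an isolated blip is absorbed and the runs merge (segment count -2)
  mix <- sapply(seq_len(100), function(i)
    if (i == 50) 0.8 * protos[[2]] + 0.6 * protos[[1]] else protos[[1]])
  ep_blip <- eeg_epoch(mix * 5, 256, "beta")
  seg_blip <- backfit(ep_blip, model)
  expect_identical(nrow(seg_blip$segments), 3L)
  sm <- smooth_segments(seg_blip, model, ep_blip, 30)
  expect_identical(nrow(sm$segments), 1L)
  expect_true(all(sm$labels == 1))
  expect_true(all(sm$segments$length >=
                    round(30 / 1000 * 256)))

  # denoising: accuracy improves after 30-ms smoothing under noise
  res <- planted_beta_epoch(seed = 1, snr = 2)
  maps <- extract_peak_maps(res$epoch)
  fit <- modified_kmeans(maps, 3, n_restarts = 10, seed = 2)
  cls <- match_classes(fit, res$recording$templates$beta)
  seg_n <- backfit(res$epoch, fit)
  sm_n <- smooth_segments(seg_n, fit, res$epoch, 30)
  truth <- res$recording$true_labels$beta
  acc_pre <- mean(cls[seg_n$labels] == truth)
  acc_post <- mean(cls[sm_n$labels] == truth)
  expect_gte(acc_post, acc_pre)
})

test_that("temporal statistics follow their definitions", {
  lab <- c(rep(1L, 128), rep(2L, 128)) # 1 s at 256 Hz
  seg <- eegmicronet:::new_segmentation(lab, 256, 2L)
  mf <- microstate_features(seg)
  expect_equal(mf$coverage, c(0.5, 0.5))
  expect_equal(mf$occurrence, c(1, 1))
  expect_equal(mf$duration, c(500, 500))

  seg1 <- eegmicronet:::new_segmentation(rep(2L, 4096), 256, 3L)
  mf1 <- microstate_features(seg1)
  expect_equal(mf1$coverage, c(0, 1, 0))
  expect_equal(mf1$occurrence[2], 1 / 16)
  expect_equal(mf1$duration[c(1, 3)], c(0, 0))
  expect_equal(sum(mf1$coverage), 1)

  # occurrence x duration ~ coverage (boundary tolerance)
  res <- planted_beta_epoch(seed = 2, snr = 5)
  maps <- extract_peak_maps(res$epoch)
  fit <- modified_kmeans(maps, 3, n_restarts = 5, seed = 1)
  mf2 <- microstate_features(backfit(res$epoch, fit))
  expect_equal(sum(mf2$coverage), 1, tolerance = 1e-12)
  expect_true(all(abs(mf2$occurrence * mf2$duration / 1000 - mf2$coverage)
                  <= 0.02))
})

test_that("planted coverage is recovered from pooled epochs", {
  set <- planted_beta_epochs(seed = 33, snr = 10, patients = 1, epochs = 10)
  model <- fit_global_model(set$epochs, K_range = 3, n_restarts = 10,
                            seed = 5)
  cls <- match_classes(model, set$dataset[[1]]$templates$beta)
  cov_est <- rep(0, 3)
  for (ep in set$epochs) {
    mf <- microstate_features(backfit(ep, model))
    cov_est[cls] <- cov_est[cls] + mf$coverage / length(set$epochs)
  }
  expect_true(all(abs(cov_est - 1 / 3) < 0.05))
})

test_that("global model selection recovers the planted map count", {
  set <- planted_beta_epochs(seed = 17, snr = 10)
  model <- fit_global_model(set$epochs, K_range = 2:6, n_restarts = 10,
                            seed = 7)
  expect_identical(model$K, 3L)
  expect_identical(model$selection$K[which.min(model$selection$cv)], 3L)
  # same seed -> identical model
  model2 <- fit_global_model(set$epochs, K_range = 2:6, n_restarts = 10,
                             seed = 7)
  expect_identical(model$maps, model2$maps)
  # bypassing selection pins the conventional K
  m3 <- fit_global_model(set$epochs, K_range = 3, n_restarts = 5, seed = 7)
  expect_identical(m3$K, 3L)
})

test_that("the segmentation pipeline is polarity invariant end to end", {
  res <- planted_beta_epoch(seed = 12, snr = 5)
  maps <- extract_peak_maps(res$epoch)
  fit <- modified_kmeans(maps, 3, n_restarts = 5, seed = 3)
  neg <- res$epoch; neg$data <- -neg$data

  seg_pos <- backfit(res$epoch, fit)
  seg_neg <- backfit(neg, fit)
  expect_identical(seg_pos$labels, seg_neg$labels)
  expect_equal(cv_criterion(t(res$epoch$data), fit),
               cv_criterion(t(neg$data), fit), tolerance = 1e-12)
  expect_equal(gev(t(res$epoch$data), fit), gev(t(neg$data), fit),
               tolerance = 1e-12)
  sm_pos <- smooth_segments(seg_pos, fit, res$epoch, 30)
  sm_neg <- smooth_segments(seg_neg, fit, neg, 30)
  expect_identical(sm_pos$labels, sm_neg$labels)
  expect_identical(microstate_features(sm_pos), microstate_features(sm_neg))
})
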