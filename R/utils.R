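# Internal helpers shared across modules.

# Population standard deviation (denominator n, not n-1).
sd_pop <- function(x) {
  sqrt(mean((x - mean(x))^2))
}

# Root mean square.
rms <- function(x) sqrt(mean(x^2))

# Spatial (Pearson) correlation between two topographies.
spatial_corr <- function(a, b) {
  a <- a - mean(a)
  b <- b - mean(b)
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("spatial correlation undefined for a flat map")
  sum(a * b) / (na * nb)
}

# Derive a child seed from a base seed and a string tag; stays below 2^31.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(paste0(tag)) * seq_along(utf8ToInt(paste0(tag))))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483629)
}

# Pink (1/f) noise of length n with unit RMS, generated by spectral shaping.
pink_noise <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  white <- rnorm(n)
  spec <- fft(white)
  k <- seq_len(n) - 1
  f <- pmin(k, n - k) # two-sided frequency index
  scale <- ifelse(f == 0, 0, 1 / sqrt(f))
  x <- Re(fft(spec * scale, inverse = TRUE)) / n
  x / rms(x)
}

# Run-length encoding of an integer label vector into a segment table.
label_runs <- function(labels) {
  r <- rle(as.integer(labels))
  ends <- cumsum(r$lengths)
  data.frame(
    class = r$values,
    start = ends - r$lengths + 1L,
    length = r$lengths
  )
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
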