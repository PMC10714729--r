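# Independent oracles and small scene builders shared across tests.

# Exhaustive minimiser of the Li minimum cross-entropy criterion over all
# 256-bin candidate thresholds, written directly from the criterion
# definition (independent of the package's fixed-point iteration).
# Returns the CE curve, the set of minimising cut bins (there can be a
# plateau when inter-mode bins are empty) and the histogram geometry.
liExhaustive <- function(values, bins = 256L) {
  v <- as.numeric(values)
  mn <- min(v); mx <- max(v)
  w <- (mx - mn) / bins
  idx <- pmin(bins, floor((v - mn) / w) + 1L)
  cnt <- tabulate(idx, nbins = bins)
  x <- (seq_len(bins) - 0.5) * w + w           # shifted-positive centers
  ce <- rep(NA_real_, bins - 1L)
  for (b in seq_len(bins - 1L)) {
    cb <- sum(cnt[1:b]); ca <- sum(cnt[(b + 1L):bins])
    if (cb == 0 || ca == 0) next
    s1b <- sum(cnt[1:b] * x[1:b])
    s1a <- sum(cnt[(b + 1L):bins] * x[(b + 1L):bins])
    ce[b] <- -(s1b * log(s1b / cb) + s1a * log(s1a / ca))
  }
  mince <- min(ce, na.rm = TRUE)
  minimizers <- which(!is.na(ce) & ce <= mince + abs(mince) * 1e-12)
  list(ce = ce, minimizers = minimizers, mn = mn, w = w)
}

# Cut-bin index of a threshold value on the same 256-bin histogram.
cutBin <- function(thr, oracle, bins = 256L) {
  min(max(floor((thr - oracle$mn) / oracle$w), 1L), bins - 1L)
}

# Welch two-sample t statistic, degrees of freedom and two-sided p-value
# straight from the formulas.
welchOracle <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(statistic = t, df = df, p.value = 2 * pt(-abs(t), df))
}

# A two-species layered scene on a small grid: A occupies slices
# 0..(split-1), B occupies split..(top-1), full lateral extent.
twoLayerSpec <- function(dim = c(10L, 16L, 16L), split = 4L, top = 8L,
                         seed = 1L, species = c("A", "B")) {
  geom <- list(
    list(list(type = "layer", zlo = 0, zhi = split - 1L)),
    list(list(type = "layer", zlo = split, zhi = top - 1L)))
  names(geom) <- species
  sceneSpec(dim, geom, exclusive = TRUE, seed = seed)
}

# Wrap a logical array for quantification.
asMask <- function(arr, channel) binaryMask(arr, channel)

# Render a two-channel single-label control pair and estimate k, at the
# given noise level; returns the estimated matrix.
estimateK <- function(k, noiseSd, seed = 42L, dim = c(32, 64, 64),
                      brightnessSdLog = 0.2, background = 8) {
  m <- imagingModel(c("A", "B"), brightness = 200,
                    brightnessSdLog = brightnessSdLog,
                    background = background, mixing = k,
                    psfSigma = c(0, 1, 1), noiseSd = noiseSd, seed = seed)
  controls <- renderControls(c("A", "B"), m, dim = dim, seed = seed)
  coefficients(buildCrosstalkMatrix(controls))
}
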