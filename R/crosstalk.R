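## Crosstalk (spectral bleed-through) estimation and correction.
##
## For each ordered dye pair the bleed-through coefficient is estimated
## from a single-label control stack as the mode of the per-voxel ratio
## I_unpopulated / I_populated, then mixed-species stacks are corrected by
## subtracting the bled-through fraction of every other channel (or by
## solving the full linear mixing system).

#' Histogram of per-voxel bleed-through ratios from a single-label control
#'
#' The control stack contains one labelled organism only: the
#' \code{populated} channel carries its true signal while the
#' \code{unpopulated} channel records only bleed-through (plus background
#' and noise).  Ratios are computed over the calibration foreground — the
#' voxels where the populated channel exceeds its own Li threshold — since
#' unrestricted division is dominated by background 0/0 noise.  Both
#' channels are background-corrected beforehand by subtracting their
#' median intensity outside the foreground, so a constant detector offset
#' does not bias the ratio.  Ratios outside \code{range} are discarded
#' (clamping them would pile noise-driven negative ratios into the first
#' bin and bias the mode toward zero); the rest are binned into
#' \code{bins} equal-width bins.
#'
#' @param control a single-label [MultiChannelStack-class].
#' @param populated label of the channel carrying the organism's signal.
#' @param unpopulated label of the channel receiving bleed-through.
#' @param range clip range for ratios (default \code{c(0, 1.5)}).
#' @param bins number of histogram bins (default 256).
#' @param sigma blur sigma used for the foreground segmentation.
#' @param minSeparation noise guard for the foreground segmentation.
#' @return A [RatioDistribution-class].
#' @export
ratioDistribution <- function(control, populated, unpopulated,
                              range = c(0, 1.5), bins = 256L,
                              sigma = c(0, 1, 1), minSeparation = 5) {
  stopifnot(is(control, "MultiChannelStack"))
  if (identical(populated, unpopulated))
    stopf("populated and unpopulated channels must differ")
  ipop <- getChannel(control, populated)
  iunp <- getChannel(control, unpopulated)
  fgMask <- withCallingHandlers(
    segmentChannel(control, populated, sigma = sigma,
                   minSeparation = minSeparation),
    warning = function(w) invokeRestart("muffleWarning"))
  fg <- maskArray(fgMask)
  if (!any(fg))
    stopf("no calibration signal: channel '%s' segments to an empty mask",
          populated)
  bgPop <- if (all(fg)) 0 else median(ipop[!fg])
  bgUnp <- if (all(fg)) 0 else median(iunp[!fg])
  den <- ipop[fg] - bgPop
  num <- iunp[fg] - bgUnp
  keep <- den > 0
  if (!any(keep))
    stopf("no calibration signal: all foreground denominators are <= 0")
  r <- num[keep] / den[keep]
  # restrict to the configured range by discarding, not clamping: noise
  # pushes a sizeable mass of ratios below 0 at low crosstalk, and
  # clamping would pile that mass into the first bin and drag the mode
  # to zero
  r <- r[r >= range[1L] & r <= range[2L]]
  if (length(r) == 0L)
    stopf("no calibration signal: all ratios fall outside [%g, %g]",
          range[1L], range[2L])
  w <- (range[2L] - range[1L]) / bins
  idx <- pmin(bins, floor((r - range[1L]) / w) + 1L)
  counts <- tabulate(idx, nbins = bins)
  new("RatioDistribution",
      breaks = seq(range[1L], range[2L], length.out = bins + 1L),
      counts = as.numeric(counts), nVoxels = sum(counts),
      sourceChannel = populated, targetChannel = unpopulated)
}

#' Crosstalk coefficient: the mode of a ratio distribution
#'
#' Returns the center of the highest-count histogram bin.  Equal maxima
#' resolve to the lowest such bin.  The mode — not the largest observed
#' ratio — is used because the extreme ratio is an unbounded noise
#' statistic.
#'
#' @param dist a [RatioDistribution-class] with at least one occupied bin.
#' @return The coefficient (a bin center), accurate to half a bin width.
#' @export
crosstalkCoefficient <- function(dist) {
  stopifnot(is(dist, "RatioDistribution"))
  if (sum(dist@counts) == 0) stopf("empty ratio distribution")
  i <- which.max(dist@counts)            # which.max takes the first maximum
  (dist@breaks[i] + dist@breaks[i + 1L]) / 2
}

#' Build the full crosstalk matrix from single-label controls
#'
#' For every ordered channel pair (i, j), i != j, the coefficient
#' k[i -> j] is estimated from the control stack in which channel i is the
#' only populated one.  The diagonal is 1 by definition.
#'
#' @param controls named list of [MultiChannelStack-class]: element
#'   \code{controls[[lab]]} is the control in which channel \code{lab}
#'   carries the only organism.  One control per channel is required.
#' @param range,bins,sigma,minSeparation forwarded to
#'   [ratioDistribution()].
#' @return A [CrosstalkMatrix-class] (rows = source, columns = target).
#' @export
buildCrosstalkMatrix <- function(controls, range = c(0, 1.5), bins = 256L,
                                 sigma = c(0, 1, 1), minSeparation = 5) {
  if (length(controls) == 0L) stopf("no control stacks supplied")
  labels <- channelLabels(controls[[1L]])
  missing <- setdiff(labels, names(controls))
  if (length(missing) > 0L)
    stopf("missing control stack for channel(s): %s",
          paste(missing, collapse = ", "))
  k <- diag(length(labels))
  dimnames(k) <- list(labels, labels)
  for (src in labels) {
    ctl <- controls[[src]]
    if (!identical(channelLabels(ctl), labels))
      stopf("control for '%s' has mismatched channel labels", src)
    for (tgt in setdiff(labels, src)) {
      d <- ratioDistribution(ctl, populated = src, unpopulated = tgt,
                             range = range, bins = bins, sigma = sigma,
                             minSeparation = minSeparation)
      k[src, tgt] <- crosstalkCoefficient(d)
    }
  }
  CrosstalkMatrix(k)
}

#' Correct a stack for fluorescence crosstalk
#'
#' Subtractive correction (the default, matching pairwise-coefficient
#' calibration) replaces each channel j by
#' \deqn{I'_j = \max(0,\; I_j - \sum_{i \ne j} k_{ij} I_i)}
#' per voxel.  \code{method = "unmix"} instead solves the full linear
#' mixing system per voxel (observed = t(k) \%*\% true) and clamps
#' negatives to zero; the two agree to first order when all off-diagonal
#' coefficients are small.
#'
#' @param stack a [MultiChannelStack-class].
#' @param k a [CrosstalkMatrix-class] whose labels match the stack's
#'   channels.
#' @param method \code{"subtractive"} (default) or \code{"unmix"}.
#' @return A corrected [MultiChannelStack-class] of identical shape and
#'   labels; intensities are never negative.
#' @export
correctStack <- function(stack, k, method = c("subtractive", "unmix")) {
  method <- match.arg(method)
  stopifnot(is(stack, "MultiChannelStack"), is(k, "CrosstalkMatrix"))
  km <- coefficients(k)
  labels <- channelLabels(stack)
  if (!setequal(rownames(km), labels))
    stopf("crosstalk matrix labels do not match the stack's channels")
  km <- km[labels, labels, drop = FALSE]
  a <- stack@intensities
  d <- dim(a)
  nc <- d[1L]
  flat <- matrix(a, nrow = nc)         # channels x voxels
  if (method == "subtractive") {
    off <- km; diag(off) <- 0
    corrected <- flat - t(off) %*% flat
  } else {
    if (abs(det(km)) < 1e-12)
      stopf("singular mixing matrix: cannot unmix")
    corrected <- solve(t(km), flat)
  }
  corrected[corrected < 0] <- 0
  MultiChannelStack(array(corrected, d), labels, stack@voxelSize)
}
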