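## Segmentation: Gaussian blur followed by automated Li minimum
## cross-entropy thresholding, one global threshold per channel per stack.

#' Separable 3D Gaussian blur with reflective boundaries
#'
#' Convolves a 3D array with a normalised, separable Gaussian kernel
#' (truncated at 4 sigma) along each axis whose sigma is positive.
#' Boundaries are handled by symmetric reflection, so a constant array is
#' mapped to itself and total mass is conserved away from clipping.
#' \code{sigma = c(0, 0, 0)} is the identity.
#'
#' @param channel 3D numeric array (Z, Y, X).
#' @param sigma numeric (sz, sy, sx), non-negative, in voxel units.
#' @return Blurred array of the same shape.
#' @export
gaussianBlur <- function(channel, sigma = c(0, 1, 1)) {
  stopifnot(length(dim(channel)) == 3L)
  if (length(sigma) != 3L || any(sigma < 0) || any(!is.finite(sigma)))
    stopf("sigma must be three non-negative finite numbers")
  out <- channel
  d <- dim(channel)
  for (ax in 1:3) {
    s <- sigma[ax]
    if (s == 0) next
    r <- as.integer(ceiling(4 * s))
    w <- dnorm(seq(-r, r), sd = s)
    w <- w / sum(w)
    acc <- array(0, d)
    n <- d[ax]
    for (o in seq(-r, r)) {
      idx <- reflectIndex(seq_len(n) + o, n)
      shifted <- switch(ax,
        out[idx, , , drop = FALSE],
        out[, idx, , drop = FALSE],
        out[, , idx, drop = FALSE])
      acc <- acc + w[o + r + 1L] * shifted
    }
    out <- acc
  }
  out
}

# Shared histogram scaffold for Li thresholding: 256 equal-width bins over
# the observed min-max range, bin centers shifted to a strictly positive
# axis (the cross-entropy criterion takes logarithms of intensity means).
liHistogram <- function(values, bins = 256L) {
  v <- as.numeric(values)
  v <- v[is.finite(v)]
  if (length(v) < 2L) stopf("degenerate histogram: need at least 2 values")
  mn <- min(v); mx <- max(v)
  if (mx <= mn) stopf("degenerate histogram: constant input")
  w <- (mx - mn) / bins
  idx <- pmin(bins, floor((v - mn) / w) + 1L)
  counts <- tabulate(idx, nbins = bins)
  centers <- mn + (seq_len(bins) - 0.5) * w
  # shift so the smallest center sits at one bin width above zero
  list(counts = counts, centers = centers, shifted = centers - mn + w,
       width = w, offset = mn - w)
}

#' Li minimum cross-entropy threshold
#'
#' Automatic threshold selection by Li's minimum cross-entropy rule,
#' computed on a 256-bin histogram of the input scaled to its own min--max
#' range.  Starting from the overall mean, the Li--Tam fixed-point
#' iteration
#' \deqn{t_{n+1} = \frac{\mu_b(t_n) - \mu_a(t_n)}
#'                      {\ln \mu_b(t_n) - \ln \mu_a(t_n)}}
#' (with \eqn{\mu_b}, \eqn{\mu_a} the mean intensities below and above
#' \eqn{t_n}) is run until the update falls below half a gray level, then
#' the threshold is mapped back to the original intensity units.  The
#' iterate is evaluated on intensities shifted to a strictly positive
#' range, which also makes the result shift-equivariant.  Ties and
#' plateaus resolve toward the lower threshold because bins at the
#' threshold count as background.
#'
#' @param values numeric vector or array of intensities with at least two
#'   distinct values; constant input is an error ("degenerate histogram").
#' @param bins histogram bins (default 256).
#' @param tol convergence tolerance in gray levels (default 0.5).
#' @param maxIter iteration cap (default 100; convergence is typically
#'   reached in well under 20).
#' @return The threshold, in the input's intensity units; voxels strictly
#'   above it are foreground.
#' @references Li & Lee (1993) Minimum cross entropy thresholding;
#'   Li & Tam (1998) An iterative algorithm for minimum cross entropy
#'   thresholding.
#' @export
liThreshold <- function(values, bins = 256L, tol = 0.5, maxIter = 100L) {
  h <- liHistogram(values, bins)
  x <- h$shifted
  cnt <- as.numeric(h$counts)
  t_cur <- weighted.mean(x, cnt)
  for (it in seq_len(maxIter)) {
    below <- x <= t_cur
    m0b <- sum(cnt[below]);  m0a <- sum(cnt[!below])
    if (m0b == 0 || m0a == 0) break   # all mass on one side: stop at t_cur
    mub <- sum(cnt[below] * x[below]) / m0b
    mua <- sum(cnt[!below] * x[!below]) / m0a
    t_new <- (mub - mua) / (log(mub) - log(mua))
    if (abs(t_new - t_cur) < tol * h$width) {
      t_cur <- t_new
      break
    }
    t_cur <- t_new
  }
  t_cur + h$offset
}

#' Segment one channel by blur + Li thresholding
#'
#' Applies [gaussianBlur()] to the selected channel, computes one global
#' [liThreshold()] over the whole 3D blurred channel, and returns the
#' voxels above the threshold as a [BinaryMask-class].
#'
#' Two guards keep batch runs alive on channels without real signal (for
#' instance a species that has been completely outcompeted):
#' \itemize{
#'   \item a constant channel has no threshold; an empty mask is returned
#'     with a warning;
#'   \item after thresholding, the contrast between foreground and
#'     background means is measured in units of the background SD; when it
#'     falls below \code{minSeparation} the channel is treated as
#'     containing only noise and an empty mask is returned with a warning.
#'     Any channel whose foreground is a few-fold brighter than background
#'     clears this bar easily, while a pure-noise channel thresholded
#'     inside its own noise band (contrast about 2.7 background SDs for
#'     Gaussian noise) does not.
#' }
#'
#' @param stack a crosstalk-corrected [MultiChannelStack-class].
#' @param label channel to segment.
#' @param sigma blur sigma (sz, sy, sx); the default blurs in-plane only.
#' @param minSeparation contrast floor in background-SD units (default 5);
#'   set to 0 to disable the noise guard.
#' @param bins,tol forwarded to [liThreshold()].
#' @param perSlice threshold each z slice independently instead of
#'   globally (default FALSE: one threshold per channel per stack, since
#'   thresholding precedes the per-slice bookkeeping).  In per-slice mode
#'   the recorded threshold is the median of the slice thresholds and
#'   degenerate slices contribute empty mask planes.
#' @return A [BinaryMask-class]; its \code{threshold} slot is \code{NA}
#'   when a guard fired and the mask is empty.
#' @export
segmentChannel <- function(stack, label, sigma = c(0, 1, 1),
                           minSeparation = 5, bins = 256L, tol = 0.5,
                           perSlice = FALSE) {
  stopifnot(is(stack, "MultiChannelStack"))
  ch <- getChannel(stack, label)
  emptyMask <- function() new("BinaryMask",
    mask = array(FALSE, dim(ch)), channel = label,
    threshold = NA_real_, sigma = as.numeric(sigma),
    voxelSize = stack@voxelSize)
  if (max(ch) <= min(ch)) {
    warnf("channel '%s' is constant; returning an empty mask", label)
    return(emptyMask())
  }
  blurred <- gaussianBlur(ch, sigma)
  if (max(blurred) <= min(blurred)) {
    warnf("channel '%s' is constant after blurring; returning an empty mask",
          label)
    return(emptyMask())
  }
  if (perSlice) {
    m <- array(FALSE, dim(blurred))
    thrs <- rep(NA_real_, dim(blurred)[1L])
    for (zi in seq_len(dim(blurred)[1L])) {
      sl <- blurred[zi, , ]
      if (max(sl) <= min(sl)) next
      thrs[zi] <- liThreshold(sl, bins = bins, tol = tol)
      m[zi, , ] <- sl > thrs[zi]
    }
    thr <- median(thrs, na.rm = TRUE)
  } else {
    thr <- liThreshold(blurred, bins = bins, tol = tol)
    m <- blurred > thr
  }
  if (!any(m) || all(m)) {
    warnf("channel '%s': threshold separates nothing; returning an empty mask",
          label)
    return(emptyMask())
  }
  if (minSeparation > 0) {
    bg <- blurred[!m]
    sdbg <- sd(bg)
    if (sdbg > 0) {
      sep <- (mean(blurred[m]) - mean(bg)) / sdbg
      if (sep < minSeparation) {
        warnf(paste0("channel '%s': foreground/background separation %.2f ",
                     "below %.2f background SDs; treating as signal-free"),
              label, sep, minSeparation)
        return(emptyMask())
      }
    }
  }
  new("BinaryMask", mask = m, channel = label, threshold = thr,
      sigma = as.numeric(sigma), voxelSize = stack@voxelSize)
}

#' Segment every channel of a stack
#'
#' @param stack a [MultiChannelStack-class].
#' @param ... forwarded to [segmentChannel()].
#' @return Named list of [BinaryMask-class], one per channel.
#' @export
segmentStack <- function(stack, ...) {
  masks <- lapply(stack@channelLabels, function(lb)
    segmentChannel(stack, lb, ...))
  names(masks) <- stack@channelLabels
  masks
}
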