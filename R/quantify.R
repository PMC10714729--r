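## Biovolume quantification: per-z-slice and total occupied-volume
## fractions, species composition shares, replicate statistics, volume
## comparisons and layer-order descriptors.

#' Wrap a logical occupancy array as a BinaryMask
#'
#' Convenience constructor for quantifying masks that did not come from
#' [segmentChannel()] — ground-truth occupancies of synthetic scenes, or
#' masks imported from other tools.
#'
#' @param mask logical (Z, Y, X) array, substratum at slice 1.
#' @param channel channel label.
#' @param voxelSize (dz, dy, dx) in micrometres.
#' @return A [BinaryMask-class] with \code{NA} threshold and zero sigma.
#' @export
binaryMask <- function(mask, channel, voxelSize = c(1, 1, 1)) {
  new("BinaryMask", mask = mask, channel = as.character(channel),
      threshold = NA_real_, sigma = c(0, 0, 0),
      voxelSize = as.numeric(voxelSize))
}

#' Per-z-slice biovolume profile of a binary mask
#'
#' Counts occupied voxels per z slice and in total, and normalises by the
#' voxel count of a slice and of the whole stack respectively.  Counting
#' is exact, so the per-slice counts always sum to the total count.
#'
#' @param mask a [BinaryMask-class].
#' @param voxelSize optional (dz, dy, dx) override in micrometres;
#'   defaults to the mask's own voxel size.
#' @return A [SliceProfile-class].
#' @export
sliceProfile <- function(mask, voxelSize = NULL) {
  stopifnot(is(mask, "BinaryMask"))
  m <- mask@mask
  d <- dim(m)
  if (any(d == 0L)) stopf("mask has a zero-sized dimension")
  vs <- if (is.null(voxelSize)) mask@voxelSize else as.numeric(voxelSize)
  perSlice <- apply(m, 1L, sum)
  sliceVox <- d[2L] * d[3L]
  total <- sum(perSlice)
  new("SliceProfile", channel = mask@channel,
      sliceFraction = perSlice / sliceVox,
      totalFraction = total / (d[1L] * sliceVox),
      occupiedVoxels = as.numeric(total),
      physicalVolume = total * prod(vs),
      voxelSize = vs)
}

#' Species composition shares from per-channel masks
#'
#' Each channel's share is its occupied voxel count divided by the sum of
#' occupied counts over all channels, in percent — the "cell ratio"
#' reported per species combination and time point.  Channels segmented
#' independently may overlap; each channel counts its own voxels and the
#' overlap fraction (multiply-claimed voxels over the union) is reported
#' for auditing.  When every channel is empty, shares are all 0 and the
#' summary is flagged degenerate.
#'
#' @param masks list of [BinaryMask-class] sharing one shape (typically
#'   from [segmentStack()]).
#' @return A [CompositionSummary-class].
#' @export
composition <- function(masks) {
  stopifnot(length(masks) >= 1L)
  for (m in masks) stopifnot(is(m, "BinaryMask"))
  labels <- vapply(masks, function(m) m@channel, character(1L))
  d <- dim(masks[[1L]]@mask)
  for (m in masks)
    if (!all(dim(m@mask) == d))
      stopf("masks have mismatched shapes")
  counts <- vapply(masks, function(m) sum(m@mask), numeric(1L))
  names(counts) <- labels
  total <- sum(counts)
  claimed <- Reduce(`+`, lapply(masks, function(m) as.integer(m@mask)))
  union <- sum(claimed > 0L)
  overlap <- if (union > 0) sum(claimed > 1L) / union else 0
  if (total == 0) {
    sh <- counts * 0
    return(new("CompositionSummary", shares = sh, counts = counts,
               overlapFraction = 0, degenerate = TRUE))
  }
  new("CompositionSummary", shares = 100 * counts / total, counts = counts,
      overlapFraction = overlap, degenerate = FALSE)
}

#' Average biovolume profiles over replicate samples
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) of
#' the per-slice and total fractions across replicates of one condition;
#' the study design this mirrors images three positions per condition.
#'
#' @param profiles list of >= 2 [SliceProfile-class] for the same channel
#'   with matching slice counts.
#' @return A [ReplicateSummary-class].
#' @export
averageReplicates <- function(profiles) {
  n <- length(profiles)
  if (n < 2L) stopf("need at least 2 replicate profiles (got %d)", n)
  for (p in profiles) stopifnot(is(p, "SliceProfile"))
  ch <- unique(vapply(profiles, function(p) p@channel, character(1L)))
  if (length(ch) != 1L)
    stopf("replicate profiles mix channels: %s", paste(ch, collapse = ", "))
  nz <- unique(vapply(profiles, function(p) length(p@sliceFraction),
                      integer(1L)))
  if (length(nz) != 1L)
    stopf("replicate profiles have mismatched slice counts")
  sliceMat <- vapply(profiles, function(p) p@sliceFraction, numeric(nz))
  sliceMat <- matrix(sliceMat, nrow = nz)   # slices x replicates
  totals <- vapply(profiles, function(p) p@totalFraction, numeric(1L))
  new("ReplicateSummary", channel = ch,
      meanSlice = rowMeans(sliceMat),
      sdSlice = apply(sliceMat, 1L, sd),
      meanTotal = mean(totals), sdTotal = sd(totals),
      n = as.integer(n))
}

#' Compare total biovolumes of two groups (Welch's t-test)
#'
#' Two-sided Welch two-sample t-test on total biovolume fractions (or any
#' per-replicate totals) of two conditions.
#'
#' @param groupA,groupB numeric vectors of per-replicate totals, each of
#'   length >= 2; at least one group must have nonzero variance.
#' @return List with \code{statistic} (Welch t), \code{df}
#'   (Welch--Satterthwaite degrees of freedom) and \code{p.value}
#'   (two-sided).
#' @export
compareVolumes <- function(groupA, groupB) {
  if (length(groupA) < 2L || length(groupB) < 2L)
    stopf("each group needs at least 2 replicates")
  if (sd(groupA) == 0 && sd(groupB) == 0) {
    if (isTRUE(all.equal(mean(groupA), mean(groupB))))
      return(list(statistic = 0, df = length(groupA) + length(groupB) - 2,
                  p.value = 1))
    stopf("both groups have zero variance; the t statistic is undefined")
  }
  tt <- t.test(groupA, groupB, var.equal = FALSE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p.value = tt$p.value)
}

#' Layer-order descriptors for a set of channel masks
#'
#' Describes the vertical arrangement of the segmented species: for each
#' non-empty channel the occupancy-weighted mean z (0-based, substratum =
#' 0) and the shares of its occupancy falling in the bottom, middle and
#' top thirds of the occupied z-extent (the slices between the lowest and
#' highest slice occupied by any channel, so empty headspace above the
#' biofilm does not dilute the shares); channels are ordered by mean z
#' (bottom first).  A channel is flagged \code{sandwich} when its bottom-third and
#' top-third shares both exceed its mid-third share — the operational
#' version of a species colonising bottom and top layers around another.
#'
#' @param masks list of [BinaryMask-class] sharing one shape, at least one
#'   of them non-empty.
#' @param minEdgeShare optional extra stringency: both edge shares must
#'   also exceed this floor for the sandwich flag (default 0).
#' @return \code{data.frame} with columns \code{channel}, \code{meanZ},
#'   \code{bottomShare}, \code{midShare}, \code{topShare},
#'   \code{sandwich}, ordered bottom-most channel first.  Empty channels
#'   are omitted.
#' @export
layerOrder <- function(masks, minEdgeShare = 0) {
  stopifnot(length(masks) >= 1L)
  d <- dim(masks[[1L]]@mask)
  for (m in masks)
    if (!all(dim(m@mask) == d)) stopf("masks have mismatched shapes")
  nz <- d[1L]
  anySlice <- Reduce(`|`, lapply(masks, function(m) apply(m@mask, 1L, any)))
  if (!any(anySlice)) stopf("all masks are empty")
  zlo <- which(anySlice)[1L]
  zhi <- rev(which(anySlice))[1L]
  ext <- zhi - zlo + 1L
  third <- rep(NA_integer_, nz)
  third[zlo:zhi] <- floor(3 * (seq_len(ext) - 1L) / ext)   # 0, 1, 2
  rows <- lapply(masks, function(m) {
    perSlice <- apply(m@mask, 1L, sum)
    tot <- sum(perSlice)
    if (tot == 0) return(NULL)
    z0 <- seq_len(nz) - 1L
    byThird <- vapply(0:2, function(t3)
      sum(perSlice[which(third == t3)]) / tot, numeric(1L))
    data.frame(channel = m@channel,
               meanZ = sum(perSlice * z0) / tot,
               bottomShare = byThird[1L], midShare = byThird[2L],
               topShare = byThird[3L],
               sandwich = byThird[1L] > byThird[2L] &&
                          byThird[3L] > byThird[2L] &&
                          byThird[1L] > minEdgeShare &&
                          byThird[3L] > minEdgeShare,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (length(rows) == 0L) stopf("all masks are empty")
  out <- do.call(rbind, rows)
  out <- out[order(out$meanZ), , drop = FALSE]
  rownames(out) <- NULL
  out
}
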