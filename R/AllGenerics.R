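#' @name accessors
#' @title Accessors for biofilmq classes
#'
#' @description Slot access for the package's S4 containers:
#' \code{intensities()}, \code{channelLabels()} and \code{voxelSize()} for
#' [MultiChannelStack-class]; \code{getChannel()} extracts one channel as a
#' 3D (Z, Y, X) array; \code{coefficients()} returns the numeric matrix of
#' a [CrosstalkMatrix-class]; \code{maskArray()} the logical array of a
#' [BinaryMask-class]; \code{shares()} the percent shares of a
#' [CompositionSummary-class] or [SceneGroundTruth-class];
#' \code{occupancyMasks()} the truth masks of a scene.
#'
#' @param x an object of the matching class.
#' @param label a channel label.
#' @return The slot value; see Description.
NULL

#' @rdname accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))
#' @rdname accessors
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))
#' @rdname accessors
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))
#' @rdname accessors
#' @export
setGeneric("getChannel", function(x, label) standardGeneric("getChannel"))
#' @rdname accessors
#' @export
setGeneric("coefficients")
#' @rdname accessors
#' @export
setGeneric("maskArray", function(x) standardGeneric("maskArray"))
#' @rdname accessors
#' @export
setGeneric("shares", function(x) standardGeneric("shares"))
#' @rdname accessors
#' @export
setGeneric("occupancyMasks", function(x) standardGeneric("occupancyMasks"))

#' @rdname accessors
setMethod("intensities", "MultiChannelStack", function(x) x@intensities)

#' @rdname accessors
setMethod("channelLabels", "MultiChannelStack", function(x) x@channelLabels)

#' @rdname accessors
setMethod("voxelSize", "MultiChannelStack", function(x) x@voxelSize)

#' @rdname accessors
setMethod("getChannel", "MultiChannelStack", function(x, label) {
  i <- match(label, x@channelLabels)
  if (is.na(i)) stopf("unknown channel label '%s'", label)
  a <- x@intensities[i, , , , drop = FALSE]
  dim(a) <- dim(x@intensities)[2:4]
  a
})

#' @rdname accessors
#' @param object a [CrosstalkMatrix-class] (for \code{coefficients}).
#' @param ... ignored.
setMethod("coefficients", "CrosstalkMatrix",
          function(object, ...) object@coefficients)

#' @rdname accessors
setMethod("maskArray", "BinaryMask", function(x) x@mask)

#' @rdname accessors
setMethod("shares", "CompositionSummary", function(x) x@shares)

#' @rdname accessors
setMethod("shares", "SceneGroundTruth", function(x) x@shares)

#' @rdname accessors
setMethod("occupancyMasks", "SceneGroundTruth", function(x) x@masks)

setMethod("show", "MultiChannelStack", function(object) {
  d <- dim(object@intensities)
  cat(sprintf("MultiChannelStack: %d channel(s) [%s], Z=%d Y=%d X=%d\n",
              d[1], paste(object@channelLabels, collapse = ", "),
              d[2], d[3], d[4]))
  cat(sprintf("  voxel size (dz, dy, dx) um: %s; intensity range [%g, %g]\n",
              paste(signif(object@voxelSize, 4), collapse = ", "),
              min(object@intensities), max(object@intensities)))
})

setMethod("show", "CrosstalkMatrix", function(object) {
  cat("CrosstalkMatrix (row = source, column = target):\n")
  print(round(object@coefficients, 4))
})

setMethod("show", "BinaryMask", function(object) {
  d <- dim(object@mask)
  cat(sprintf(
    "BinaryMask '%s': Z=%d Y=%d X=%d, %d occupied voxel(s), threshold %s\n",
    object@channel, d[1], d[2], d[3], sum(object@mask),
    ifelse(is.na(object@threshold), "NA (degenerate channel)",
           signif(object@threshold, 5))))
})

setMethod("show", "SliceProfile", function(object) {
  cat(sprintf(
    "SliceProfile '%s': %d slices, total fraction %.4f, %g voxels (%.1f um^3)\n",
    object@channel, length(object@sliceFraction), object@totalFraction,
    object@occupiedVoxels, object@physicalVolume))
})

setMethod("show", "CompositionSummary", function(object) {
  cat("CompositionSummary (percent of segmented biovolume):\n")
  print(round(object@shares, 2))
  if (object@degenerate) cat("  [all channels empty]\n")
  else if (object@overlapFraction > 0)
    cat(sprintf("  overlap fraction: %.4f\n", object@overlapFraction))
})

setMethod("show", "ReplicateSummary", function(object) {
  cat(sprintf(
    "ReplicateSummary '%s': n=%d, total %.4f +/- %.4f over %d slices\n",
    object@channel, object@n, object@meanTotal, object@sdTotal,
    length(object@meanSlice)))
})

setMethod("show", "SceneGroundTruth", function(object) {
  cat(sprintf("SceneGroundTruth: %s on grid Z=%d Y=%d X=%d (seed %d)\n",
              paste(names(object@masks), collapse = " + "),
              object@dim[1], object@dim[2], object@dim[3], object@seed))
  cat("  true shares (%):\n")
  print(round(object@shares, 3))
})
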