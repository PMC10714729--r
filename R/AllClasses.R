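#' MultiChannelStack: a multichannel confocal z-stack
#'
#' Container for a 4D fluorescence intensity array with axes
#' (channel, z, y, x).  The z axis ascends from the substratum: slice
#' \code{z = 1} is the attachment surface at the bottom of the biofilm and
#' the last slice is the biofilm top.  Intensities are stored as reals but
#' are expected to live in a native detector range (e.g. 0--255 or
#' 0--65535); the package never rescales them, because crosstalk ratios are
#' only meaningful when both channels share one intensity scale.
#'
#' @slot intensities 4D numeric array, shape (C, Z, Y, X), finite and >= 0.
#' @slot channelLabels character vector of C unique fluorophore/species
#'   labels naming the channels.
#' @slot voxelSize numeric (dz, dy, dx) voxel edge lengths in micrometres.
#'
#' @seealso [MultiChannelStack()] for the validating constructor,
#'   [readStack()] / [writeStack()] for TIFF I/O.
#' @export
setClass("MultiChannelStack",
  representation(
    intensities   = "array",
    channelLabels = "character",
    voxelSize     = "numeric"
  )
)

setValidity("MultiChannelStack", function(object) {
  a <- object@intensities
  if (length(dim(a)) != 4L)
    return("intensities must be a 4D array (C, Z, Y, X)")
  if (any(dim(a) < 1L))
    return("all stack dimensions must be >= 1")
  if (!all(is.finite(a)))
    return("intensities must all be finite")
  if (any(a < 0))
    return("intensities must be non-negative")
  if (length(object@channelLabels) != dim(a)[1L])
    return("length(channelLabels) must equal the number of channels")
  if (anyDuplicated(object@channelLabels))
    return("channel labels must be unique")
  if (length(object@voxelSize) != 3L || any(!is.finite(object@voxelSize)) ||
      any(object@voxelSize <= 0))
    return("voxelSize must be three strictly positive numbers (dz, dy, dx)")
  TRUE
})

#' Construct a MultiChannelStack
#'
#' @param intensities 4D numeric array with axes (C, Z, Y, X); z slice 1 is
#'   the substratum.
#' @param channelLabels character vector of unique channel labels, one per
#'   channel.
#' @param voxelSize numeric (dz, dy, dx) in micrometres.
#' @return A validated [MultiChannelStack-class] object.
#' @examples
#' a <- array(runif(2 * 3 * 4 * 4, 0, 255), c(2, 3, 4, 4))
#' MultiChannelStack(a, c("K279a", "PAO1"))
#' @export
MultiChannelStack <- function(intensities, channelLabels,
                              voxelSize = c(1, 1, 1)) {
  new("MultiChannelStack",
      intensities   = intensities,
      channelLabels = as.character(channelLabels),
      voxelSize     = as.numeric(voxelSize))
}

#' ExperimentConfig: settings shared across a pipeline run
#'
#' Bundles the conventions an analysis run needs: the channel map, the
#' on-disk axis order of TIFF pages, the blur sigma, crosstalk options and
#' the histogram settings for ratio distributions.
#'
#' @slot channels character, channel labels in page order.
#' @slot axisOrder either \code{"CZYX"} (pages grouped by channel, z fastest
#'   within a channel) or \code{"ZCYX"} (pages grouped by z slice, channel
#'   fastest).
#' @slot nz declared number of z slices; \code{NA} means infer from the page
#'   count.
#' @slot voxelSize numeric (dz, dy, dx) in micrometres.
#' @slot blurSigma numeric (sz, sy, sx) Gaussian blur sigma in voxels.
#' @slot crosstalkMethod \code{"subtractive"} or \code{"unmix"}.
#' @slot ratioRange numeric length 2, the clip range for bleed-through
#'   ratios.
#' @slot ratioBins number of equal-width histogram bins over ratioRange.
#' @slot minSeparation minimum contrast, in units of background SD, that a
#'   thresholded channel must show before its mask is accepted (see
#'   [segmentChannel()]).
#' @slot seed integer seed forwarded to stochastic steps.
#' @export
setClass("ExperimentConfig",
  representation(
    channels        = "character",
    axisOrder       = "character",
    nz              = "integer",
    voxelSize       = "numeric",
    blurSigma       = "numeric",
    crosstalkMethod = "character",
    ratioRange      = "numeric",
    ratioBins       = "integer",
    minSeparation   = "numeric",
    seed            = "integer"
  )
)

setValidity("ExperimentConfig", function(object) {
  if (length(object@channels) < 1L || anyDuplicated(object@channels))
    return("channels must be a non-empty set of unique labels")
  if (!object@axisOrder %in% c("CZYX", "ZCYX"))
    return("axisOrder must be 'CZYX' or 'ZCYX'")
  if (length(object@blurSigma) != 3L || any(object@blurSigma < 0))
    return("blurSigma must be three non-negative numbers (sz, sy, sx)")
  if (!object@crosstalkMethod %in% c("subtractive", "unmix"))
    return("crosstalkMethod must be 'subtractive' or 'unmix'")
  if (length(object@ratioRange) != 2L ||
      object@ratioRange[1L] >= object@ratioRange[2L])
    return("ratioRange must be an increasing pair")
  if (object@ratioBins < 2L)
    return("ratioBins must be >= 2")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    return("voxelSize must be three strictly positive numbers")
  TRUE
})

#' Construct an ExperimentConfig
#'
#' @param channels character vector of channel labels in on-disk page order.
#' @param axisOrder \code{"CZYX"} (default) or \code{"ZCYX"}.
#' @param nz declared z-slice count, or \code{NA} to infer it.
#' @param voxelSize (dz, dy, dx) in micrometres.
#' @param blurSigma (sz, sy, sx) blur sigma in voxels; the default blurs
#'   in-plane only because confocal z sampling is much coarser than xy.
#' @param crosstalkMethod \code{"subtractive"} (default) or \code{"unmix"}.
#' @param ratioRange clip range for bleed-through ratios.
#' @param ratioBins histogram bins over \code{ratioRange}.
#' @param minSeparation contrast floor for accepting a segmentation mask.
#' @param seed integer seed.
#' @return An [ExperimentConfig-class] object.
#' @export
experimentConfig <- function(channels,
                             axisOrder = "CZYX",
                             nz = NA_integer_,
                             voxelSize = c(1, 1, 1),
                             blurSigma = c(0, 1, 1),
                             crosstalkMethod = "subtractive",
                             ratioRange = c(0, 1.5),
                             ratioBins = 256L,
                             minSeparation = 5,
                             seed = 1L) {
  new("ExperimentConfig",
      channels = as.character(channels), axisOrder = axisOrder,
      nz = as.integer(nz), voxelSize = as.numeric(voxelSize),
      blurSigma = as.numeric(blurSigma), crosstalkMethod = crosstalkMethod,
      ratioRange = as.numeric(ratioRange), ratioBins = as.integer(ratioBins),
      minSeparation = as.numeric(minSeparation), seed = as.integer(seed))
}

#' RatioDistribution: histogram of per-voxel bleed-through ratios
#'
#' Histogram of the per-voxel ratio (unpopulated-channel intensity) /
#' (populated-channel intensity) over the calibration foreground of a
#' single-label control stack.  Its mode is the crosstalk coefficient.
#'
#' @slot breaks strictly increasing bin edges over the ratio axis.
#' @slot counts non-negative bin counts; \code{sum(counts) == nVoxels}.
#' @slot nVoxels number of foreground voxels that entered the histogram.
#' @slot sourceChannel populated (signal-bearing) channel label.
#' @slot targetChannel unpopulated channel receiving the bleed-through.
#' @seealso [ratioDistribution()], [crosstalkCoefficient()]
#' @export
setClass("RatioDistribution",
  representation(
    breaks        = "numeric",
    counts        = "numeric",
    nVoxels       = "numeric",
    sourceChannel = "character",
    targetChannel = "character"
  )
)

setValidity("RatioDistribution", function(object) {
  if (length(object@breaks) != length(object@counts) + 1L)
    return("breaks must have one more element than counts")
  if (any(diff(object@breaks) <= 0))
    return("breaks must be strictly increasing")
  if (any(object@counts < 0))
    return("counts must be non-negative")
  if (abs(sum(object@counts) - object@nVoxels) > 1e-9)
    return("nVoxels must equal sum(counts)")
  TRUE
})

#' CrosstalkMatrix: linear bleed-through coefficients between channels
#'
#' Square matrix k with \code{k[i, j]} the fraction of channel-i signal that
#' appears in channel j; the diagonal is fixed at 1.  Row and column names
#' carry the channel labels (rows = source, columns = target).
#'
#' @slot coefficients numeric C x C matrix with unit diagonal and
#'   non-negative off-diagonal entries.
#' @seealso [buildCrosstalkMatrix()], [correctStack()]
#' @export
setClass("CrosstalkMatrix", representation(coefficients = "matrix"))

setValidity("CrosstalkMatrix", function(object) {
  k <- object@coefficients
  if (nrow(k) != ncol(k)) return("coefficient matrix must be square")
  if (is.null(rownames(k)) || is.null(colnames(k)) ||
      !identical(rownames(k), colnames(k)))
    return("rows and columns must carry identical channel labels")
  if (any(abs(diag(k) - 1) > 1e-12)) return("diagonal must equal 1")
  if (any(k < 0)) return("coefficients must be non-negative")
  TRUE
})

#' Construct a CrosstalkMatrix
#'
#' @param coefficients square numeric matrix, unit diagonal, labelled rows
#'   (source channels) and columns (target channels).
#' @return A [CrosstalkMatrix-class] object.
#' @examples
#' k <- diag(2); dimnames(k) <- rep(list(c("A", "B")), 2)
#' k["A", "B"] <- 0.05
#' CrosstalkMatrix(k)
#' @export
CrosstalkMatrix <- function(coefficients) {
  new("CrosstalkMatrix", coefficients = coefficients)
}

#' BinaryMask: per-channel 3D occupancy after segmentation
#'
#' @slot mask logical array, shape (Z, Y, X); TRUE marks voxels assigned to
#'   the channel's organism.
#' @slot channel channel label the mask was derived from.
#' @slot threshold intensity threshold applied to the blurred channel;
#'   \code{NA} when the channel was degenerate and an empty mask was
#'   returned.
#' @slot sigma blur sigma (sz, sy, sx) used before thresholding.
#' @slot voxelSize (dz, dy, dx) in micrometres, inherited from the stack.
#' @seealso [segmentChannel()], [sliceProfile()]
#' @export
setClass("BinaryMask",
  representation(
    mask      = "array",
    channel   = "character",
    threshold = "numeric",
    sigma     = "numeric",
    voxelSize = "numeric"
  )
)

setValidity("BinaryMask", function(object) {
  if (!is.logical(object@mask) || length(dim(object@mask)) != 3L)
    return("mask must be a 3D logical array (Z, Y, X)")
  if (length(object@sigma) != 3L || any(object@sigma < 0))
    return("sigma must be three non-negative numbers")
  TRUE
})

#' SliceProfile: per-z-slice biovolume of one channel
#'
#' The thresholded voxel volumes of one channel summed per z slice and in
#' total, normalised to the volume of a z slice and of the whole stack
#' respectively.
#'
#' @slot channel channel label.
#' @slot sliceFraction numeric of length Z; occupied voxels in slice z over
#'   total voxels in slice z, substratum first.
#' @slot totalFraction occupied voxels over total voxels of the stack.
#' @slot occupiedVoxels total occupied voxel count.
#' @slot physicalVolume occupied volume in cubic micrometres
#'   (count x dz x dy x dx).
#' @slot voxelSize (dz, dy, dx) in micrometres.
#' @export
setClass("SliceProfile",
  representation(
    channel        = "character",
    sliceFraction  = "numeric",
    totalFraction  = "numeric",
    occupiedVoxels = "numeric",
    physicalVolume = "numeric",
    voxelSize      = "numeric"
  )
)

setValidity("SliceProfile", function(object) {
  f <- object@sliceFraction
  if (any(f < -1e-12) || any(f > 1 + 1e-12))
    return("slice fractions must lie in [0, 1]")
  if (object@totalFraction < -1e-12 || object@totalFraction > 1 + 1e-12)
    return("total fraction must lie in [0, 1]")
  TRUE
})

#' CompositionSummary: species shares of the segmented biovolume
#'
#' Per-channel share of the total segmented biovolume, in percent: a
#' channel's occupied voxel count divided by the sum over all channels,
#' times 100.  This is the "cell ratio" reported per species combination
#' and time point.  Channels may overlap after independent per-channel
#' segmentation; every channel counts its own voxels and the overlap
#' fraction is reported so the double counting can be audited.
#'
#' @slot shares named numeric, percent per channel; sums to 100 unless all
#'   channels are empty.
#' @slot counts named numeric, occupied voxels per channel.
#' @slot overlapFraction voxels claimed by more than one channel, as a
#'   fraction of the union of all claimed voxels (0 when nothing overlaps).
#' @slot degenerate TRUE when every channel was empty; shares are then all 0.
#' @seealso [composition()]
#' @export
setClass("CompositionSummary",
  representation(
    shares          = "numeric",
    counts          = "numeric",
    overlapFraction = "numeric",
    degenerate      = "logical"
  )
)

setValidity("CompositionSummary", function(object) {
  if (!identical(names(object@shares), names(object@counts)))
    return("shares and counts must carry the same channel names")
  if (!object@degenerate && abs(sum(object@shares) - 100) > 1e-9)
    return("shares must sum to 100% in the non-degenerate case")
  if (any(object@shares < -1e-12) || any(object@shares > 100 + 1e-12))
    return("each share must lie in [0, 100]")
  TRUE
})

#' ReplicateSummary: mean and SD of biovolume profiles over replicates
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) of
#' per-slice and total biovolume fractions over replicate samples of one
#' condition and channel.
#'
#' @slot channel channel label.
#' @slot meanSlice,sdSlice per-slice mean and SD, length Z.
#' @slot meanTotal,sdTotal mean and SD of the total fraction.
#' @slot n number of replicates (>= 2).
#' @seealso [averageReplicates()]
#' @export
setClass("ReplicateSummary",
  representation(
    channel   = "character",
    meanSlice = "numeric",
    sdSlice   = "numeric",
    meanTotal = "numeric",
    sdTotal   = "numeric",
    n         = "integer"
  )
)

setValidity("ReplicateSummary", function(object) {
  if (object@n < 2L) return("replicate summaries need n >= 2")
  if (any(object@sdSlice < 0) || object@sdTotal < 0)
    return("standard deviations must be non-negative")
  if (length(object@meanSlice) != length(object@sdSlice))
    return("meanSlice and sdSlice must have equal length")
  TRUE
})

#' SceneSpec: geometric description of a synthetic biofilm scene
#'
#' Describes species occupancy on a voxel grid through geometry primitives.
#' Supported primitives (each a named list with a \code{type} field):
#' \describe{
#'   \item{\code{layer}}{\code{zlo}, \code{zhi} (0-based, inclusive slice
#'     range), \code{density} in (0, 1]; density < 1 scatters voxels
#'     uniformly at random within the slab.}
#'   \item{\code{slab}}{like layer plus \code{ylo}, \code{yhi},
#'     \code{xlo}, \code{xhi} lateral bounds (0-based, inclusive).}
#'   \item{\code{band}}{\code{zlo} plus an exact voxel count
#'     \code{nVoxels}, filled deterministically in raster order from slice
#'     \code{zlo} upward; used when a preset must hit an exact composition
#'     share.}
#'   \item{\code{microcolonies}}{\code{n} spheres of radius \code{radius}
#'     (voxels) at random centres within \code{zlo..zhi}.}
#'   \item{\code{hypha}}{\code{n} persistent-random-walk tubes of radius
#'     \code{radius} and \code{length} steps growing from the substratum.}
#'   \item{\code{satellite}}{attaches this species to the surface of a
#'     \code{host} species' occupancy with probability \code{prob} per
#'     surface-adjacent voxel (models cells attaching to hyphae).}
#' }
#' With \code{exclusive = TRUE} (the default) species occupancies are
#' pairwise disjoint: deterministic primitives of different species must not
#' collide (it is an error), and random primitives skip occupied voxels.
#'
#' @slot dim integer (Z, Y, X) grid size.
#' @slot species character species/channel labels.
#' @slot geometry named list (one entry per species) of primitive lists.
#' @slot exclusive logical, enforce disjoint occupancy.
#' @slot seed integer seed for the random primitives.
#' @seealso [sceneSpec()], [makeScene()], [biofilmPreset()]
#' @export
setClass("SceneSpec",
  representation(
    dim       = "integer",
    species   = "character",
    geometry  = "list",
    exclusive = "logical",
    seed      = "integer"
  )
)

setValidity("SceneSpec", function(object) {
  if (length(object@dim) != 3L || any(object@dim < 1L))
    return("dim must be three positive integers (Z, Y, X)")
  if (anyDuplicated(object@species))
    return("species labels must be unique")
  if (!identical(sort(names(object@geometry)), sort(object@species)))
    return("geometry must have exactly one entry per species")
  TRUE
})

#' Construct a SceneSpec
#'
#' @param dim integer (Z, Y, X).
#' @param geometry named list of per-species primitive lists; names define
#'   the species labels and channel order.  See [SceneSpec-class] for the
#'   primitive vocabulary.
#' @param exclusive enforce pairwise disjoint occupancy (default TRUE).
#' @param seed integer seed for random primitives.
#' @return A [SceneSpec-class] object.
#' @examples
#' sceneSpec(c(10, 16, 16), list(
#'   K279a = list(list(type = "layer", zlo = 0, zhi = 3)),
#'   PAO1  = list(list(type = "layer", zlo = 4, zhi = 7))))
#' @export
sceneSpec <- function(dim, geometry, exclusive = TRUE, seed = 1L) {
  new("SceneSpec", dim = as.integer(dim), species = names(geometry),
      geometry = geometry, exclusive = isTRUE(exclusive),
      seed = as.integer(seed))
}

#' ImagingModel: forward model from occupancy to recorded intensities
#'
#' The rendering chain is: per-voxel fluorophore signal (lognormal
#' brightness on occupied voxels), linear channel mixing by the true
#' crosstalk matrix, PSF-like Gaussian blur, background offset, additive
#' Gaussian read noise (optionally Poisson shot noise), and clipping at 0.
#' Mixing precedes the blur because fluorophore emission mixes at
#' detection while the blur is an optical point-spread effect.
#'
#' @slot brightness named numeric, mean foreground intensity per species.
#' @slot brightnessSdLog lognormal sigma (log scale) of per-voxel
#'   brightness, mimicking expression heterogeneity.
#' @slot background constant offset added to every voxel after mixing.
#' @slot mixing true crosstalk matrix (source x target, unit diagonal).
#' @slot psfSigma Gaussian blur sigma (sz, sy, sx) in voxels.
#' @slot noiseSd additive Gaussian noise SD.
#' @slot shotNoise logical; when TRUE, Poisson noise replaces each voxel's
#'   pre-readout intensity by a Poisson draw of that mean.
#' @slot seed integer seed for the render.
#' @seealso [imagingModel()], [renderScene()]
#' @export
setClass("ImagingModel",
  representation(
    brightness      = "numeric",
    brightnessSdLog = "numeric",
    background      = "numeric",
    mixing          = "matrix",
    psfSigma        = "numeric",
    noiseSd         = "numeric",
    shotNoise       = "logical",
    seed            = "integer"
  )
)

setValidity("ImagingModel", function(object) {
  if (is.null(names(object@brightness)))
    return("brightness must be named by species")
  if (any(object@brightness <= object@background))
    return("brightness must exceed the background")
  if (object@background < 0) return("background must be >= 0")
  if (any(object@mixing < 0)) return("mixing coefficients must be >= 0")
  if (any(abs(diag(object@mixing) - 1) > 1e-12))
    return("mixing diagonal must equal 1")
  if (length(object@psfSigma) != 3L || any(object@psfSigma < 0))
    return("psfSigma must be three non-negative numbers")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  TRUE
})

#' Construct an ImagingModel
#'
#' @param species species labels (channel order).
#' @param brightness mean foreground intensity per species; recycled.
#' @param brightnessSdLog lognormal sigma of per-voxel brightness.
#' @param background constant offset.
#' @param mixing true crosstalk matrix, or a single off-diagonal value
#'   applied to every ordered pair.
#' @param psfSigma blur sigma (sz, sy, sx) in voxels.
#' @param noiseSd additive Gaussian noise SD.
#' @param shotNoise add Poisson shot noise (default FALSE).
#' @param seed integer seed.
#' @return An [ImagingModel-class] object.
#' @export
imagingModel <- function(species, brightness = 200, brightnessSdLog = 0.2,
                         background = 8, mixing = 0, psfSigma = c(0, 1, 1),
                         noiseSd = 0, shotNoise = FALSE, seed = 1L) {
  nc <- length(species)
  b <- rep_len(as.numeric(brightness), nc)
  names(b) <- species
  if (is.matrix(mixing)) {
    k <- mixing
    if (is.null(rownames(k))) dimnames(k) <- list(species, species)
  } else {
    k <- matrix(as.numeric(mixing), nc, nc,
                dimnames = list(species, species))
    diag(k) <- 1
  }
  new("ImagingModel", brightness = b,
      brightnessSdLog = as.numeric(brightnessSdLog),
      background = as.numeric(background), mixing = k,
      psfSigma = as.numeric(psfSigma), noiseSd = as.numeric(noiseSd),
      shotNoise = isTRUE(shotNoise), seed = as.integer(seed))
}

#' SceneGroundTruth: reference occupancy and composition of a scene
#'
#' Output of [makeScene()]: the per-species occupancy masks together with
#' exact per-slice profiles and composition shares computed by direct voxel
#' counting, so every downstream stage has an oracle.
#'
#' @slot masks named list of logical (Z, Y, X) arrays, one per species.
#' @slot shares named numeric, true composition shares in percent
#'   (all 0 when no species occupies any voxel).
#' @slot sliceFraction numeric matrix (species x Z) of true per-slice
#'   occupied fractions.
#' @slot dim integer (Z, Y, X).
#' @slot seed the seed the scene was generated with.
#' @export
setClass("SceneGroundTruth",
  representation(
    masks         = "list",
    shares        = "numeric",
    sliceFraction = "matrix",
    dim           = "integer",
    seed          = "integer"
  )
)

setValidity("SceneGroundTruth", function(object) {
  if (!identical(names(object@masks), names(object@shares)))
    return("masks and shares must carry the same species names")
  tot <- sum(object@shares)
  if (tot > 0 && abs(tot - 100) > 1e-9)
    return("non-degenerate shares must sum to 100%")
  TRUE
})
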