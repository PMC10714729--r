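## TIFF I/O for multichannel z-stacks.
##
## On disk a stack is a multi-page TIFF of Y x X pages.  The page ordering
## is declared in the config: "CZYX" stores all z slices of channel 1, then
## all of channel 2, ...; "ZCYX" interleaves channels within each z slice.
## Pages are 16-bit grayscale, so intensities must be integers in
## 0..65535 — the native range of the detectors this pipeline targets.
## Reading is exact (no rescaling), which makes write/read a strict
## round trip.

#' Read a multichannel z-stack from a multi-page TIFF
#'
#' Pages are reassembled into a (C, Z, Y, X) array according to the axis
#' order declared in \code{config}; the z axis ascends from the substratum.
#' Intensities are returned exactly as stored (no rescaling).
#'
#' @param path path to a multi-page TIFF written by [writeStack()] or any
#'   16-bit/8-bit grayscale multi-page TIFF with the declared layout.
#' @param config an [ExperimentConfig-class]; its \code{channels},
#'   \code{axisOrder}, \code{nz} and \code{voxelSize} are used.
#' @return A [MultiChannelStack-class].
#' @seealso [writeStack()]
#' @export
readStack <- function(path, config) {
  if (!file.exists(path)) stopf("stack file not found: %s", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  nc <- length(config@channels)
  np <- length(pages)
  nz <- config@nz
  if (is.na(nz)) {
    if (np %% nc != 0L)
      stopf("layout mismatch: %d page(s) cannot split into %d channel(s)",
            np, nc)
    nz <- np %/% nc
  } else if (np != nc * nz) {
    stopf("layout mismatch: %d page(s) but declared C=%d x Z=%d = %d",
          np, nc, nz, nc * nz)
  }
  pg <- pages[[1L]]
  if (length(dim(pg)) != 2L)
    stopf("expected single-sample grayscale pages, got %d samples per pixel",
          if (length(dim(pg)) == 3L) dim(pg)[3L] else NA_integer_)
  ny <- nrow(pg); nx <- ncol(pg)
  a <- array(0, c(nc, nz, ny, nx))
  for (p in seq_len(np)) {
    m <- pages[[p]]
    if (!all(dim(m) == c(ny, nx)))
      stopf("page %d has size %dx%d, expected %dx%d",
            p, nrow(m), ncol(m), ny, nx)
    if (config@axisOrder == "CZYX") {
      ci <- (p - 1L) %/% nz + 1L
      zi <- (p - 1L) %% nz + 1L
    } else {                         # ZCYX: channel varies fastest
      zi <- (p - 1L) %/% nc + 1L
      ci <- (p - 1L) %% nc + 1L
    }
    a[ci, zi, , ] <- m
  }
  if (any(a < 0) || any(!is.finite(a)))
    stopf("stack contains negative or non-numeric pixel values")
  MultiChannelStack(a, config@channels, config@voxelSize)
}

#' Write a multichannel z-stack to a multi-page TIFF
#'
#' Intensities must be integer-valued in 0..65535 (native detector range);
#' pages are written as 16-bit grayscale so that
#' \code{readStack(writeStack(s))} reproduces \code{s} exactly.
#'
#' @param stack a [MultiChannelStack-class] with integer-valued
#'   intensities in 0..65535.
#' @param path output file path.
#' @param axisOrder page ordering on disk, \code{"CZYX"} (default) or
#'   \code{"ZCYX"}.
#' @return \code{path}, invisibly.
#' @seealso [readStack()]
#' @export
writeStack <- function(stack, path, axisOrder = "CZYX") {
  stopifnot(is(stack, "MultiChannelStack"))
  a <- stack@intensities
  if (max(a) > 65535)
    stopf("intensities exceed the 16-bit range (max %g)", max(a))
  if (max(abs(a - round(a))) > 1e-6)
    stopf("intensities must be integer-valued for 16-bit TIFF storage; %s",
          "round or quantise before writing")
  d <- dim(a)
  pages <- vector("list", d[1L] * d[2L])
  p <- 0L
  if (axisOrder == "CZYX") {
    for (ci in seq_len(d[1L])) for (zi in seq_len(d[2L])) {
      p <- p + 1L
      pages[[p]] <- matrix(round(a[ci, zi, , ]) / 65535, d[3L], d[4L])
    }
  } else if (axisOrder == "ZCYX") {
    for (zi in seq_len(d[2L])) for (ci in seq_len(d[1L])) {
      p <- p + 1L
      pages[[p]] <- matrix(round(a[ci, zi, , ]) / 65535, d[3L], d[4L])
    }
  } else stopf("unknown axis order '%s'", axisOrder)
  ok <- try(tiff::writeTIFF(pages, path, bits.per.sample = 16L,
                            reduce = FALSE), silent = TRUE)
  if (inherits(ok, "try-error"))
    stopf("cannot write TIFF to '%s'", path)
  invisible(path)
}

#' Write a binary mask as an 8-bit multi-page TIFF (0/255)
#'
#' @param mask a [BinaryMask-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeMask <- function(mask, path) {
  stopifnot(is(mask, "BinaryMask"))
  d <- dim(mask@mask)
  pages <- lapply(seq_len(d[1L]), function(zi)
    matrix(ifelse(mask@mask[zi, , ], 1, 0), d[2L], d[3L]))
  tiff::writeTIFF(pages, path, bits.per.sample = 8L, reduce = FALSE)
  invisible(path)
}

#' Read an experiment configuration from YAML
#'
#' Recognised keys mirror the [experimentConfig()] arguments:
#' \code{channels}, \code{axis_order}, \code{nz}, \code{voxel_size},
#' \code{blur_sigma}, \code{crosstalk_method}, \code{ratio_range},
#' \code{ratio_bins}, \code{min_separation}, \code{seed}.  Missing keys
#' fall back to the constructor defaults.
#'
#' @param path path to a YAML file.
#' @return An [ExperimentConfig-class].
#' @export
readExperimentConfig <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  y <- yaml::read_yaml(path)
  if (is.null(y$channels)) stopf("config must declare 'channels'")
  args <- list(channels = unlist(y$channels))
  take <- function(key, name) if (!is.null(y[[key]])) args[[name]] <<-
      unlist(y[[key]])
  take("axis_order", "axisOrder");   take("nz", "nz")
  take("voxel_size", "voxelSize");   take("blur_sigma", "blurSigma")
  take("crosstalk_method", "crosstalkMethod")
  take("ratio_range", "ratioRange"); take("ratio_bins", "ratioBins")
  take("min_separation", "minSeparation"); take("seed", "seed")
  do.call(experimentConfig, args)
}
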