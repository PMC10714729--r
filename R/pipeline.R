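## Batch pipeline: calibrate -> correct -> segment -> quantify -> average,
## over a manifest of conditions with replicate stacks, with CSV/JSON
## outputs.  Conditions are processed independently: one failing condition
## is reported and the batch continues, failing the run only at the end.

#' Read a run manifest from YAML
#'
#' Layout:
#' \preformatted{
#' channels: [K279a, PAO1]
#' controls: {K279a: controls/k279a.tif, PAO1: controls/pao1.tif}
#' conditions:
#'   - name: dual_24h
#'     time: 24h
#'     replicates: {r1: stacks/r1.tif, r2: stacks/r2.tif, r3: stacks/r3.tif}
#' seed: 1
#' }
#' Paths are resolved relative to the manifest file.  Replicate IDs must
#' be unique within a condition; all referenced files must exist.
#'
#' @param path path to the manifest YAML.
#' @return A manifest list (fields \code{channels}, \code{controls},
#'   \code{conditions}, \code{seed}).
#' @export
readRunManifest <- function(path) {
  if (!file.exists(path)) stopf("manifest not found: %s", path)
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(grepl("^/", p), p, file.path(base, p))
  if (!is.null(y$controls)) y$controls <- lapply(y$controls, resolve)
  for (i in seq_along(y$conditions)) {
    reps <- y$conditions[[i]]$replicates
    if (anyDuplicated(names(reps)))
      stopf("condition '%s': duplicate replicate IDs",
            y$conditions[[i]]$name)
    y$conditions[[i]]$replicates <- lapply(reps, resolve)
  }
  y
}

checkManifestFiles <- function(manifest) {
  paths <- c(unlist(manifest$controls),
             unlist(lapply(manifest$conditions, `[[`, "replicates")))
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0L)
    stopf("manifest references missing file(s): %s",
          paste(missing, collapse = ", "))
  invisible(TRUE)
}

#' Package version string
#'
#' @return The semantic version of the installed package, as character.
#' @export
versionInfo <- function() {
  as.character(packageVersion("biofilmq"))
}

#' Run the full quantification pipeline over a manifest
#'
#' Executes, per condition and replicate: crosstalk correction (with
#' coefficients calibrated once from the manifest's single-label
#' controls, or supplied precomputed), blur + Li segmentation of every
#' channel, per-slice and total biovolume profiles, and composition
#' shares; then replicate mean/SD per condition and channel.  Writes
#' \code{profiles.csv}, \code{composition.csv}, \code{slice_summary.csv},
#' \code{total_summary.csv}, \code{crosstalk.csv} and a JSON
#' \code{report.json} (versions, seeds, thresholds, crosstalk matrix,
#' overlap fractions, warnings) into \code{outputDir}.  A failing
#' condition is recorded and the remaining conditions still run; the
#' function then raises an error naming the failures.
#'
#' @param manifest a manifest list from [readRunManifest()] or built in
#'   code (same fields).
#' @param config an [ExperimentConfig-class].
#' @param outputDir output directory, created if needed.
#' @param crosstalk optional precomputed [CrosstalkMatrix-class]; when
#'   supplied the manifest needs no \code{controls}.
#' @return The run report, invisibly (also written as JSON).
#' @export
runPipeline <- function(manifest, config, outputDir,
                        crosstalk = NULL) {
  stopifnot(is(config, "ExperimentConfig"))
  checkManifestFiles(manifest)
  dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
  warningsLog <- character(0)
  noteWarning <- function(where, w) {
    warningsLog <<- c(warningsLog, sprintf("[%s] %s", where,
                                           conditionMessage(w)))
    invokeRestart("muffleWarning")
  }

  if (is.null(crosstalk)) {
    if (is.null(manifest$controls))
      stopf("manifest has no controls and no crosstalk matrix was supplied")
    controls <- lapply(manifest$controls, readStack, config = config)
    crosstalk <- withCallingHandlers(
      buildCrosstalkMatrix(controls, range = config@ratioRange,
                           bins = config@ratioBins,
                           sigma = config@blurSigma,
                           minSeparation = config@minSeparation),
      warning = function(w) noteWarning("calibrate", w))
  }
  km <- coefficients(crosstalk)
  write.csv(km, file.path(outputDir, "crosstalk.csv"))

  profRows <- list(); compRows <- list()
  sliceRows <- list(); totalRows <- list()
  thresholds <- list(); overlaps <- list()
  failures <- character(0)

  for (cond in manifest$conditions) {
    cname <- cond$name
    res <- try({
      repProfiles <- list()   # channel -> list of SliceProfile
      for (rid in names(cond$replicates)) {
        stk <- readStack(cond$replicates[[rid]], config)
        corr <- correctStack(stk, crosstalk,
                             method = config@crosstalkMethod)
        masks <- withCallingHandlers(
          segmentStack(corr, sigma = config@blurSigma,
                       minSeparation = config@minSeparation),
          warning = function(w)
            noteWarning(sprintf("%s/%s", cname, rid), w))
        comp <- composition(masks)
        overlaps[[sprintf("%s/%s", cname, rid)]] <- comp@overlapFraction
        for (lb in names(masks)) {
          thresholds[[sprintf("%s/%s/%s", cname, rid, lb)]] <-
            masks[[lb]]@threshold
          prof <- sliceProfile(masks[[lb]])
          repProfiles[[lb]] <- c(repProfiles[[lb]], list(prof))
          profRows[[length(profRows) + 1L]] <- data.frame(
            condition = cname, replicate = rid, channel = lb,
            z = seq_along(prof@sliceFraction) - 1L,
            fraction = prof@sliceFraction, stringsAsFactors = FALSE)
          compRows[[length(compRows) + 1L]] <- data.frame(
            condition = cname, replicate = rid, channel = lb,
            voxels = comp@counts[[lb]], share = comp@shares[[lb]],
            stringsAsFactors = FALSE)
        }
      }
      if (length(cond$replicates) >= 2L) {
        for (lb in names(repProfiles)) {
          rs <- averageReplicates(repProfiles[[lb]])
          sliceRows[[length(sliceRows) + 1L]] <- data.frame(
            condition = cname, channel = lb,
            z = seq_along(rs@meanSlice) - 1L,
            mean = rs@meanSlice, sd = rs@sdSlice,
            stringsAsFactors = FALSE)
          totalRows[[length(totalRows) + 1L]] <- data.frame(
            condition = cname, channel = lb, mean = rs@meanTotal,
            sd = rs@sdTotal, n = rs@n, stringsAsFactors = FALSE)
        }
      }
      NULL
    }, silent = TRUE)
    if (inherits(res, "try-error"))
      failures <- c(failures, sprintf("%s: %s", cname,
                                      attr(res, "condition")$message))
  }

  writeTable <- function(rows, file) {
    if (length(rows) > 0L)
      write.csv(do.call(rbind, rows), file.path(outputDir, file),
                row.names = FALSE)
  }
  writeTable(profRows,  "profiles.csv")
  writeTable(compRows,  "composition.csv")
  writeTable(sliceRows, "slice_summary.csv")
  writeTable(totalRows, "total_summary.csv")

  report <- list(
    tool = "biofilmq", version = versionInfo(),
    seed = manifest$seed,
    config = list(channels = config@channels,
                  axisOrder = config@axisOrder,
                  blurSigma = config@blurSigma,
                  crosstalkMethod = config@crosstalkMethod,
                  ratioRange = config@ratioRange,
                  ratioBins = config@ratioBins,
                  minSeparation = config@minSeparation),
    crosstalk = as.data.frame(km),
    thresholds = thresholds,
    overlapFractions = overlaps,
    warnings = warningsLog,
    failures = failures)
  jsonlite::write_json(report, file.path(outputDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (length(failures) > 0L)
    stopf("pipeline finished with failing condition(s):\n  %s",
          paste(failures, collapse = "\n  "))
  invisible(report)
}

#' Simulate a preset condition to disk, with manifest
#'
#' Generates \code{nReplicates} realisations of a [biofilmPreset()] scene
#' (replicate i uses scene seed \code{seed + 10 i} and render seed
#' \code{seed + 10 i + 5}, mimicking different imaged positions of one
#' condition), renders single-label calibration controls under the same
#' imaging model, writes everything as 16-bit TIFF plus the ground-truth
#' composition CSV, and emits a manifest YAML that [runPipeline()] can
#' consume directly.
#'
#' @param name preset name, see [biofilmPreset()].
#' @param outputDir directory to populate.
#' @param nReplicates replicates per condition (default 3).
#' @param seed base seed (default: the preset's documented seed).
#' @param controlDim grid for the calibration controls.
#' @return Path to the written manifest YAML, invisibly.
#' @export
simulateCondition <- function(name, outputDir, nReplicates = 3L,
                              seed = NULL, controlDim = c(32, 64, 64)) {
  preset <- biofilmPreset(name, seed = seed)
  seed <- preset$spec@seed
  dir.create(file.path(outputDir, "stacks"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(outputDir, "controls"), showWarnings = FALSE)
  species <- preset$spec@species
  truthRows <- list()
  repPaths <- list()
  for (i in seq_len(nReplicates)) {
    spec <- preset$spec
    spec@seed <- as.integer(seed + 10L * i)
    model <- preset$model
    model@seed <- as.integer(seed + 10L * i + 5L)
    truth <- makeScene(spec)
    stk <- quantizeStack(renderScene(truth, model)$stack)
    rid <- sprintf("r%d", i)
    p <- file.path("stacks", sprintf("%s_%s.tif", name, rid))
    writeStack(stk, file.path(outputDir, p))
    repPaths[[rid]] <- p
    truthRows[[i]] <- data.frame(condition = name, replicate = rid,
                                 channel = species,
                                 trueShare = as.numeric(truth@shares),
                                 stringsAsFactors = FALSE)
  }
  controls <- renderControls(species, preset$model, dim = controlDim,
                             seed = seed + 900L)
  ctlPaths <- list()
  for (lb in species) {
    p <- file.path("controls", sprintf("control_%s.tif", lb))
    writeStack(quantizeStack(controls[[lb]]), file.path(outputDir, p))
    ctlPaths[[lb]] <- p
  }
  write.csv(do.call(rbind, truthRows),
            file.path(outputDir, "truth_shares.csv"), row.names = FALSE)
  manifest <- list(channels = as.list(species), controls = ctlPaths,
                   conditions = list(list(name = name, time = name,
                                          replicates = repPaths)),
                   seed = seed)
  mpath <- file.path(outputDir, "manifest.yaml")
  yaml::write_yaml(manifest, mpath)
  invisible(mpath)
}
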