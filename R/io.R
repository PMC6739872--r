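# File interfaces: volumes as NIfTI-1 (RNifti), every table as TSV with a
# header, pipeline configuration as YAML.

#' Read / write NIfTI volumes
#'
#' Thin wrappers around RNifti. `writeVolume` stores 3D or 4D arrays with an
#' isotropic voxel size (and TR in the 4th pixdim for 4D data);
#' `readVolume` returns the data with its voxel dimensions and xform.
#' Round-trips preserve values exactly (data are written as float64).
#'
#' @param data numeric 3D or 4D array.
#' @param path file path (`.nii` / `.nii.gz`).
#' @param voxelSizeMm isotropic voxel edge, mm.
#' @param trSeconds repetition time stored for 4D series.
#' @param expectedDim optional dim check; mismatch is an error.
#' @return `readVolume`: list with `data`, `voxelDims`, `affine`.
#' @export
writeVolume <- function(data, path, voxelSizeMm = 3, trSeconds = NULL) {
  im <- RNifti::asNifti(data)
  nd <- length(dim(data))
  pd <- rep(voxelSizeMm, min(nd, 3L))
  if (nd == 4L) pd <- c(pd, if (is.null(trSeconds)) 1 else trSeconds)
  RNifti::pixdim(im) <- pd
  RNifti::writeNifti(im, path)
  invisible(path)
}

#' @rdname writeVolume
#' @export
readVolume <- function(path, expectedDim = NULL) {
  im <- RNifti::readNifti(path)
  d <- dim(im)
  if (!is.null(expectedDim) && !identical(as.integer(d), as.integer(expectedDim)))
    stop(sprintf("volume %s has dim %s, expected %s", path,
                 paste(d, collapse = "x"), paste(expectedDim, collapse = "x")))
  list(data = array(as.vector(im), dim(im)), voxelDims = RNifti::pixdim(im),
       affine = RNifti::xform(im))
}

writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

readTsv <- function(path, comment = "") {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = comment,
                    stringsAsFactors = FALSE)
}

#' Read / write paradigm timing tables
#'
#' Tab-separated block table with header; acquisition metadata (TR, volumes
#' per run, runs) travels in `#key=value` comment lines.
#'
#' @param paradigm a [Paradigm].
#' @param path TSV path.
#' @return `readParadigm` returns a [Paradigm].
#' @export
writeParadigm <- function(paradigm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#tr_seconds=%g", paradigm@trSeconds),
               sprintf("#volumes_per_run=%d", paradigm@volumesPerRun),
               sprintf("#n_runs=%d", paradigm@nRuns)), con)
  utils::write.table(paradigm@blocks, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeParadigm
#' @export
readParadigm <- function(path) {
  hdr <- readLines(path, n = 10L)
  meta <- hdr[startsWith(hdr, "#")]
  getMeta <- function(key) {
    ln <- meta[startsWith(meta, paste0("#", key, "="))]
    if (!length(ln)) stop(sprintf("paradigm file lacks #%s= metadata", key))
    as.numeric(sub(".*=", "", ln[1]))
  }
  blocks <- readTsv(path, comment = "#")
  new("Paradigm", blocks = blocks, trSeconds = getMeta("tr_seconds"),
      volumesPerRun = as.integer(getMeta("volumes_per_run")),
      nRuns = as.integer(getMeta("n_runs")))
}

#' Read / write ratings tables
#'
#' Two TSVs: one for location-level ratings, one for scale-level ratings.
#'
#' @param ratings a [RatingsTable].
#' @param locationPath,scalePath TSV paths.
#' @return `readRatings` returns a [RatingsTable].
#' @export
writeRatings <- function(ratings, locationPath, scalePath) {
  writeTsv(ratings@locationRatings, locationPath)
  writeTsv(ratings@scaleRatings, scalePath)
  invisible(c(locationPath, scalePath))
}

#' @rdname writeRatings
#' @export
readRatings <- function(locationPath, scalePath) {
  new("RatingsTable", locationRatings = readTsv(locationPath),
      scaleRatings = readTsv(scalePath), bounds = c(1, 7))
}

#' Read / write geographic stimulus tables
#'
#' TSV with columns scale, location, item, lat, lon.
#'
#' @param stimuli a [GeoStimulusSet].
#' @param path TSV path.
#' @return `readGeoStimuli` returns a [GeoStimulusSet].
#' @export
writeGeoStimuli <- function(stimuli, path) {
  writeTsv(geoEntries(stimuli), path)
}

#' @rdname writeGeoStimuli
#' @export
readGeoStimuli <- function(path) {
  new("GeoStimulusSet", entries = readTsv(path))
}

#' Write a voxel tuning table as TSV
#'
#' @param tuning a [VoxelTuning].
#' @param path TSV path.
#' @export
writeTuningTable <- function(tuning, path) {
  writeTsv(tuningFits(tuning), path)
}

#' Default pipeline configuration
#'
#' All tunable parameters of the end-to-end synthetic demo pipeline with
#' their defaults: the study's acquisition geometry (TR 2.5 s, 3 mm voxels,
#' 24 blocks/run), its statistical thresholds (voxelwise FDR 0.01,
#' r-squared gate 0.7, 1000 permutations, region FDR 0.05) and the
#' simulation parameters.
#'
#' @return named list understood by [runFullPipeline()].
#' @export
defaultPipelineConfig <- function() {
  list(
    seed = 1,
    n_subjects = 8,
    n_runs = 2,
    blocks_per_run = 24,
    tr_seconds = 2.5,
    grid = c(20L, 40L, 20L),
    voxel_size_mm = 3,
    axis = 2L,
    amplitude = 1,
    width = 1,
    center_jitter_sd = 0.3,
    subject_slope_jitter_sd = 0.1,
    noise = list(ar = c(0.3, 0.2), innovation_sd = 10, drift_amplitude = 5,
                 drift_period_seconds = 128, baseline = 1000),
    min_intensity = 100,
    ar_method = "pooled",
    highpass_cycles = 0,
    alpha_voxel = 0.01,
    r2_gate = 0.7,
    n_perm = 1000,
    cluster_min = 5,
    connectivity = 6,
    q_regions = 0.05,
    era_volumes = 10,
    geo = list(locations_per_scale = 2, items_per_location = 8,
               dispersion_km = c(0.5, 10, 500, 5000)),
    ratings_targets = c(familiarity = -0.72, emotion = 0, difficulty = 0.39,
                        firstPerson = -0.81, thirdPerson = 0.80,
                        mapStrategy = 0.80),
    output_dir = NULL
  )
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML configuration, fills unset fields from
#' [defaultPipelineConfig()] and validates every threshold; referenced paths
#' must exist at load time.
#'
#' @param path YAML file path, or a named list to validate directly.
#' @return validated configuration list.
#' @export
readPipelineConfig <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  def <- defaultPipelineConfig()
  unknown <- setdiff(names(cfg), names(def))
  if (length(unknown))
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  for (k in names(def)) if (is.null(cfg[[k]])) cfg[[k]] <- def[[k]]
  for (k in c("noise", "geo"))
    for (kk in names(def[[k]]))
      if (is.null(cfg[[k]][[kk]])) cfg[[k]][[kk]] <- def[[k]][[kk]]
  stopIf <- function(cond, msg) if (cond) stop("invalid config: ", msg)
  stopIf(cfg$n_perm < 1, "n_perm must be >= 1")
  stopIf(cfg$alpha_voxel <= 0 || cfg$alpha_voxel >= 1,
         "alpha_voxel must be in (0, 1)")
  stopIf(cfg$q_regions <= 0 || cfg$q_regions >= 1,
         "q_regions must be in (0, 1)")
  stopIf(cfg$r2_gate <= 0 || cfg$r2_gate >= 1, "r2_gate must be in (0, 1)")
  stopIf(cfg$cluster_min < 1, "cluster_min must be >= 1")
  stopIf(cfg$n_subjects < 2, "n_subjects must be >= 2")
  stopIf(cfg$blocks_per_run %% 6 != 0, "blocks_per_run must be divisible by 6")
  stopIf(!cfg$connectivity %in% c(6, 18, 26), "connectivity must be 6/18/26")
  stopIf(!cfg$ar_method %in% c("pooled", "voxel"),
         "ar_method must be 'pooled' or 'voxel'")
  if (!is.null(cfg$output_dir) && !dir.exists(dirname(cfg$output_dir)))
    stop("invalid config: parent of output_dir does not exist")
  cfg$grid <- as.integer(cfg$grid)
  cfg
}
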