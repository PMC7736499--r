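# Plain-format readers/writers for the analysis inputs and outputs.
# Images (linescans, frame stacks, voxel masks) travel as TIFF; tables as
# CSV; generator truths and run records as JSON sidecars.

need_tiff <- function() {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF input/output")
}

#' Read a linescan from a single-page TIFF
#'
#' @param path TIFF file (rows = lines/time, columns = positions).
#' @param line_period Line period, ms.
#' @param pixel_pitch Pixel pitch, um.
#' @export
read_linescan_tiff <- function(path, line_period, pixel_pitch) {
  need_tiff()
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  linescan(img, line_period, pixel_pitch)
}

#' Write a linescan to TIFF
#'
#' @param scan A [linescan()].
#' @param path Output file.
#' @export
write_linescan_tiff <- function(scan, path) {
  need_tiff()
  m <- scan$intensity
  m <- m / max(m, 1)  # TIFF float payload in [0,1]
  tiff::writeTIFF(m, path, bits.per.sample = 32L)
  invisible(path)
}

#' Read a voxel mask from a multi-page TIFF
#'
#' Pages are z-planes; nonzero pixels are occupied.
#'
#' @param path TIFF file.
#' @param pitch Voxel pitch, nm.
#' @param centroids Optional PSD centroids (nm).
#' @export
read_mask_tiff <- function(path, pitch, centroids = NULL) {
  need_tiff()
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  occ <- array(FALSE, c(dim(pages[[1]])[1:2], length(pages)))
  for (k in seq_along(pages)) {
    pg <- pages[[k]]
    if (length(dim(pg)) == 3) pg <- pg[, , 1]
    occ[, , k] <- pg > 0
  }
  voxel_mask(occ, pitch, centroids)
}

#' Write a voxel mask to a multi-page TIFF
#'
#' @param mask A [voxel_mask()].
#' @param path Output file.
#' @export
write_mask_tiff <- function(mask, path) {
  need_tiff()
  pages <- lapply(seq_len(dim(mask$occupancy)[3]), function(k) {
    m <- mask$occupancy[, , k] * 1
    storage.mode(m) <- "double"
    m
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' Read a 3D localization table (ThunderSTORM-compatible CSV)
#'
#' Expects columns `x [nm]`, `y [nm]`, `z [nm]` (or bare `x`, `y`, `z`) and
#' `channel`; an optional `synapse` column is carried through.
#'
#' @param path CSV file.
#' @export
read_localizations_csv <- function(path) {
  d <- read.csv(path, check.names = FALSE)
  names(d) <- sub("\\s*\\[nm\\]$", "", names(d))
  req <- c("x", "y", "z", "channel")
  if (!all(req %in% names(d)))
    stop("input error: localization CSV needs columns x, y, z, channel")
  localization_set(d$x, d$y, d$z, d$channel, synapse = d$synapse)
}

#' Write a localization table as CSV
#'
#' @param locs A [localization_set()].
#' @param path Output file.
#' @export
write_localizations_csv <- function(locs, path) {
  d <- as.data.frame(locs)
  names(d)[1:3] <- c("x [nm]", "y [nm]", "z [nm]")
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Read an EPSC series from CSV (columns trial, pathway, phase, amplitude_pA)
#' @param path CSV file.
#' @export
read_epsc_csv <- function(path) {
  d <- read.csv(path)
  req <- c("trial", "pathway", "phase", "amplitude_pA")
  if (!all(req %in% names(d)))
    stop("input error: EPSC CSV needs columns ", paste(req, collapse = ", "))
  epsc_series(d$trial, d$amplitude_pA, d$pathway, d$phase)
}

#' Write an EPSC series to CSV
#' @param series An [epsc_series()].
#' @param path Output file.
#' @export
write_epsc_csv <- function(series, path) {
  d <- data.frame(trial = series$trial, pathway = series$pathway,
                  phase = series$phase, amplitude_pA = series$amplitude)
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Write a dataset with its generator-truth JSON sidecar
#'
#' Writes the data with the supplied writer and the `"truth"` attribute (plus
#' any extra metadata) to `<path>.json`.
#'
#' @param x Generated object carrying a `"truth"` attribute.
#' @param path Output file for the data.
#' @param writer Function `(x, path)` used for the data payload.
#' @param extra Optional extra metadata list.
#' @export
write_with_truth <- function(x, path, writer, extra = list()) {
  writer(x, path)
  meta <- c(attr(x, "truth"), extra)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Export a scenario-comparison table to CSV
#'
#' @param comparison A `papsim_comparison`.
#' @param path Output file.
#' @export
write_comparison_csv <- function(comparison, path) {
  write.csv(comparison$table, path, row.names = FALSE)
  invisible(path)
}

#' Record of one command/pipeline invocation
#'
#' @param command Command name.
#' @param config Configuration list (hashed into the record).
#' @param seed Seed(s) used.
#' @param outputs Output paths.
#' @export
run_record <- function(command, config = list(), seed = NA, outputs = character(0)) {
  key <- utf8ToInt(paste(deparse(config), collapse = ""))
  list(command = command,
       config_hash = sprintf("%08x", sum(key * seq_along(key)) %% 2^28),
       seed = seed,
       package_version = as.character(utils::packageVersion("papsim")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       outputs = outputs)
}
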