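#' Write FRAP traces to CSV
#'
#' Long format with columns `trace_id`, `time_s`, `phase`, `roi_mean`,
#' `cell_mean` (one row per frame).
#'
#' @param traces List of [frap_trace()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_frap_traces <- function(traces, path) {
  rows <- lapply(traces, function(tr) {
    data.frame(trace_id = tr$trace_id, time_s = tr$times, phase = tr$phase,
               roi_mean = tr$roi_values, cell_mean = tr$cell_values,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read FRAP traces from CSV
#'
#' @param path CSV with columns `trace_id`, `time_s`, `phase`, `roi_mean`,
#'   `cell_mean`.
#' @return List of [frap_trace()] objects, in order of first appearance.
#' @export
read_frap_traces <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("trace_id", "time_s", "phase", "roi_mean", "cell_mean")
  if (!all(need %in% names(d)))
    stop_data(paste("trace CSV must contain columns:",
                    paste(need, collapse = ", ")))
  ids <- unique(d$trace_id)
  lapply(ids, function(id) {
    s <- d[d$trace_id == id, ]
    s <- s[order(s$time_s), ]
    frap_trace(id, s$time_s, s$roi_mean, s$cell_mean, s$phase)
  })
}

# Intensities are stored as 16-bit-range floats; TIFF encoding maps
# [0, 65535] AU onto the writer's [0, 1] unit scale.
TIFF_SCALE <- 65535

#' Write a simulated junction image set to TIFF + CSV
#'
#' One TIFF per channel (`protein.tif`, `marker.tif`), an integer label-mask
#' TIFF (`mask.tif`), and the ground-truth table as `truth.csv`.
#'
#' @param sim A `sim_junction_result` from [simulate_junction_images()].
#' @param dir Output directory (created if absent).
#' @return Named character vector of the files written, invisibly.
#' @export
write_junction_images <- function(sim, dir) {
  if (!inherits(sim, "sim_junction_result"))
    stop_data("`sim` must be a sim_junction_result")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(protein = file.path(dir, "protein.tif"),
             marker = file.path(dir, "marker.tif"),
             mask = file.path(dir, "mask.tif"),
             truth = file.path(dir, "truth.csv"))
  tiff::writeTIFF(pmax(sim$protein, 0) / TIFF_SCALE, paths["protein"],
                  bits.per.sample = 32)
  tiff::writeTIFF(pmax(sim$marker, 0) / TIFF_SCALE, paths["marker"],
                  bits.per.sample = 32)
  tiff::writeTIFF(sim$mask / TIFF_SCALE, paths["mask"], bits.per.sample = 32)
  utils::write.csv(sim$truth, paths["truth"], row.names = FALSE)
  invisible(paths)
}

#' Read a junction image channel or label mask from TIFF
#'
#' @param path TIFF written by [write_junction_images()].
#' @param mask If `TRUE`, round back to integer labels.
#' @return Numeric (or integer) matrix in AU.
#' @export
read_junction_tiff <- function(path, mask = FALSE) {
  if (!file.exists(path)) stop_config(sprintf("file not found: %s", path))
  m <- tiff::readTIFF(path) * TIFF_SCALE
  if (mask) m <- matrix(as.integer(round(m)), nrow(m), ncol(m))
  m
}
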