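#' Measure per-pixel junction intensities from a labelled image
#'
#' Computes, for every labelled junction, the mean channel intensity per
#' pixel. Working per pixel calibrates junctions of different size/area onto
#' a common scale: a 30-pixel and a 10-pixel junction of the same brightness
#' report the same value.
#'
#' @param image Numeric matrix, one channel.
#' @param mask Integer matrix of the same dimensions; positive integers label
#'   junctions, 0 is background.
#' @param image_id Optional identifier recorded on every output row (used
#'   when pooling junctions across images).
#' @return Data frame with one row per label: `junction_id`, `pixel_count`,
#'   `mean_intensity`, `image_id`, and `marker_status` (initialized to
#'   `"unset"`).
#' @seealso [classify_by_marker()], [normalize_relative()]
#' @export
measure_junctions <- function(image, mask, image_id = "image_1") {
  if (!is.matrix(image) || !is.numeric(image))
    stop_data("`image` must be a numeric matrix")
  if (!is.matrix(mask)) stop_data("`mask` must be an integer matrix")
  if (!all(dim(image) == dim(mask)))
    stop_data("image and mask dimensions differ")
  labels <- mask[mask > 0]
  if (length(labels) == 0L) stop_data("mask contains no junction labels")
  if (any(labels != round(labels)))
    stop_data("mask labels must be positive integers")
  f <- factor(labels)
  sums <- tapply(image[mask > 0], f, sum)
  counts <- tapply(rep(1L, length(labels)), f, sum)
  data.frame(
    junction_id = as.integer(levels(f)),
    pixel_count = as.integer(counts),
    mean_intensity = as.numeric(sums / counts),
    image_id = image_id,
    marker_status = "unset",
    stringsAsFactors = FALSE
  )
}

#' Classify junctions by marker-channel intensity
#'
#' A junction is marker-positive when its per-pixel marker mean exceeds the
#' threshold; ties (exactly equal) are negative. In the mixed-population
#' assay this separates junctions between marker-expressing cells from
#' junctions of the unlabelled reference population.
#'
#' @param records Data frame from [measure_junctions()] (protein channel).
#' @param marker_means Either a numeric vector of per-pixel marker means
#'   aligned with `records`, or a data frame from [measure_junctions()] run
#'   on the marker channel (matched by `junction_id` and `image_id`).
#' @param threshold Marker intensity threshold (AU). See
#'   [suggest_marker_threshold()] for a data-driven default.
#' @return `records` with `marker_status` set to `"positive"`/`"negative"`
#'   and a `marker_mean` column appended.
#' @export
classify_by_marker <- function(records, marker_means, threshold) {
  if (!is.data.frame(records) || !all(c("junction_id") %in% names(records)))
    stop_data("`records` must be a junction record data frame")
  if (!is_number(threshold)) stop_data("`threshold` must be a single number")
  if (is.data.frame(marker_means)) {
    key_rec <- paste(records$image_id, records$junction_id)
    key_mar <- paste(marker_means$image_id, marker_means$junction_id)
    idx <- match(key_rec, key_mar)
    if (anyNA(idx))
      stop_data("marker measurement missing for one or more junctions")
    mm <- marker_means$mean_intensity[idx]
  } else {
    if (length(marker_means) != nrow(records))
      stop_data("need one marker mean per junction record")
    mm <- as.numeric(marker_means)
  }
  if (anyNA(mm)) stop_data("marker means contain missing values")
  records$marker_mean <- mm
  records$marker_status <- ifelse(mm > threshold, "positive", "negative")
  records
}

#' Data-driven marker threshold from the image background
#'
#' Background mean plus five background standard deviations of the marker
#' channel, estimated over the mask's background pixels.
#'
#' @param marker Marker-channel matrix.
#' @param mask Label mask (0 = background).
#' @param k Number of standard deviations above background (default 5).
#' @return Threshold intensity (AU).
#' @export
suggest_marker_threshold <- function(marker, mask, k = 5) {
  if (!all(dim(marker) == dim(mask)))
    stop_data("marker and mask dimensions differ")
  bg <- marker[mask == 0]
  if (length(bg) < 2L) stop_data("not enough background pixels")
  mean(bg) + k * stats::sd(bg)
}

#' Normalize junction intensities to the marker-negative reference population
#'
#' Divides every junction's per-pixel mean by the mean over marker-negative
#' junctions, so the reference population averages exactly 1 and
#' marker-positive junctions read as fold-differences from it. Records are
#' pooled across images before normalization.
#'
#' @param records Data frame with `mean_intensity` and `marker_status` set
#'   (at least one `"negative"` record).
#' @return `records` with a `relative_intensity` column.
#' @export
normalize_relative <- function(records) {
  if (!is.data.frame(records) ||
      !all(c("mean_intensity", "marker_status") %in% names(records)))
    stop_data("`records` must carry mean_intensity and marker_status")
  neg <- records$marker_status == "negative"
  if (!any(neg)) stop_data("no marker-negative (reference) junctions")
  ref <- mean(records$mean_intensity[neg])
  if (ref <= 0) stop_data("reference population mean must be positive")
  records$relative_intensity <- records$mean_intensity / ref
  records
}

#' Densitometry relative to loading control and control condition
#'
#' Each band is divided by its loading control; ratios are then expressed as
#' a percentage of the mean control-condition ratio, so the control averages
#' exactly 100%.
#'
#' @param band_values Band intensities (AU).
#' @param loading_values Loading-control intensities (AU, > 0), same length.
#' @param condition Condition label per band.
#' @param control Label of the control condition.
#' @return Data frame: `condition`, `band_value`, `loading_value`, `ratio`,
#'   `percent_of_control`.
#' @examples
#' densitometry_relative(c(50, 75), c(100, 100),
#'                       c("parental", "treated"), "parental")
#' @export
densitometry_relative <- function(band_values, loading_values, condition,
                                  control) {
  n <- length(band_values)
  if (length(loading_values) != n || length(condition) != n)
    stop_data("band, loading and condition vectors must have equal length")
  if (any(!is.finite(loading_values)) || any(loading_values <= 0))
    stop_data("loading-control values must be positive")
  if (!control %in% condition)
    stop_data(sprintf("control condition '%s' not present", control))
  ratio <- band_values / loading_values
  ctrl_ratio <- mean(ratio[condition == control])
  if (ctrl_ratio <= 0) stop_data("control ratio must be positive")
  data.frame(
    condition = as.character(condition),
    band_value = band_values, loading_value = loading_values,
    ratio = ratio, percent_of_control = 100 * ratio / ctrl_ratio,
    stringsAsFactors = FALSE
  )
}

#' Convenience junction mask from an intensity percentile
#'
#' Thresholds the protein channel at an intensity percentile and labels
#' connected runs. A rough stand-in for externally supplied segmentation,
#' intended for exploration only; quantitative use expects a curated label
#' mask.
#'
#' @param image Numeric matrix.
#' @param percentile Quantile of image intensity used as threshold
#'   (default 0.99).
#' @return Integer label mask (4-connected components, row-major scan).
#' @export
threshold_junction_mask <- function(image, percentile = 0.99) {
  if (!is.matrix(image)) stop_data("`image` must be a matrix")
  thr <- stats::quantile(image, percentile, names = FALSE)
  fg <- image > thr
  mask <- matrix(0L, nrow(image), ncol(image))
  lab <- 0L
  # two-pass-free flood fill; images here are small fields of view
  for (i in seq_len(nrow(image))) for (j in seq_len(ncol(image))) {
    if (fg[i, j] && mask[i, j] == 0L) {
      lab <- lab + 1L
      stack <- list(c(i, j))
      while (length(stack) > 0L) {
        p <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        if (p[1] < 1 || p[2] < 1 || p[1] > nrow(image) || p[2] > ncol(image))
          next
        if (!fg[p[1], p[2]] || mask[p[1], p[2]] != 0L) next
        mask[p[1], p[2]] <- lab
        stack <- c(stack, list(p + c(1L, 0L), p - c(1L, 0L),
                               p + c(0L, 1L), p - c(0L, 1L)))
      }
    }
  }
  mask
}
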