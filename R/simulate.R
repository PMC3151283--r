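#' Simulate FRAP traces with known ground truth
#'
#' Generates `n_traces` bleach-ROI / whole-cell time series following the
#' single-exponential recovery model. For post-bleach frames at time `t`
#' (t = 0 at the first post-bleach frame) the ideal ROI signal is
#' `I(t) = I_post + M * (I_pre - I_post) * (1 - exp(-tau * t))` with
#' `I_post = bleach_depth * I_pre`; pre-bleach frames sit at `I_pre`. The
#' whole-cell signal is `I_pre * exp(-photofade_rate * (t - t_first))` over
#' the full schedule, and the observed ROI is the ideal value multiplied by
#' the same relative fading factor. Both channels then receive multiplicative
#' Gaussian noise with standard deviation `noise_sd_frac` times the ideal
#' (faded) value, or Poisson counts if `noise_model = "poisson"`.
#'
#' @param config A [sim_frap_config()].
#' @return A list of class `sim_frap_result` with elements `traces` (list of
#'   [frap_trace()] objects), `truth` (data frame of per-trace ground truth:
#'   `trace_id`, `tau`, `mobile_fraction`, `bleach_depth`, `prebleach_mean`),
#'   and `config` (the input configuration).
#' @examples
#' sim <- simulate_frap_traces(sim_frap_config(n_traces = 2, seed = 7))
#' sim$truth
#' @export
simulate_frap_traces <- function(config) {
  if (!inherits(config, "sim_frap_config"))
    stop_config("`config` must be a sim_frap_config object")
  sched <- config$schedule
  pre <- sched$phase == "prebleach"
  if (!any(pre)) stop_config("schedule has no prebleach frames")
  t_first <- sched$time_s[1]
  post_t <- sched$time_s - sched$time_s[which(!pre)[1]]  # 0 at first postbleach

  i_pre <- config$prebleach_mean
  i_post <- config$bleach_depth * i_pre
  m <- config$mobile_fraction_true

  ideal_roi <- ifelse(pre, i_pre,
                      i_post + m * (i_pre - i_post) * (1 - exp(-config$tau_true * post_t)))
  fade <- exp(-config$photofade_rate * (sched$time_s - t_first))
  ideal_cell <- i_pre * fade
  faded_roi <- ideal_roi * fade

  nf <- nrow(sched)
  traces <- with_seed(config$seed, {
    lapply(seq_len(config$n_traces), function(i) {
      if (config$noise_model == "poisson") {
        roi <- as.numeric(stats::rpois(nf, faded_roi))
        cell <- as.numeric(stats::rpois(nf, ideal_cell))
      } else {
        roi <- faded_roi * (1 + stats::rnorm(nf, 0, config$noise_sd_frac))
        cell <- ideal_cell * (1 + stats::rnorm(nf, 0, config$noise_sd_frac))
      }
      frap_trace(
        trace_id = sprintf("trace_%02d", i),
        times = sched$time_s, roi_values = roi, cell_values = cell,
        phase = sched$phase
      )
    })
  })

  truth <- data.frame(
    trace_id = vapply(traces, `[[`, "", "trace_id"),
    tau = config$tau_true,
    mobile_fraction = m,
    bleach_depth = config$bleach_depth,
    prebleach_mean = i_pre,
    stringsAsFactors = FALSE
  )
  structure(list(traces = traces, truth = truth, config = config),
            class = "sim_frap_result")
}

# Pixel coordinates (matrix indices) of one straight junction segment placed
# inside a placement cell whose top-left corner is (r0, c0). Orientation in
# {horizontal, vertical, diag_down, diag_up}; width 1 or 2 px; length `len`.
segment_pixels <- function(r0, c0, orientation, width, len) {
  k <- seq_len(len) - 1L
  base <- switch(orientation,
    horizontal = cbind(r0 + 6L, c0 + 2L + k),
    vertical   = cbind(r0 + 2L + k, c0 + 6L),
    diag_down  = cbind(r0 + 2L + k, c0 + 2L + k),
    diag_up    = cbind(r0 + 2L + len - 1L - k, c0 + 2L + k)
  )
  px <- base
  if (width == 2L) {
    off <- if (orientation == "horizontal") c(1L, 0L) else c(0L, 1L)
    px <- rbind(base, sweep(base, 2L, off, "+"))
  }
  unique(px)
}

#' Simulate a two-channel junction image with label mask and ground truth
#'
#' Renders marker-positive and marker-negative junctions as thin straight
#' segments (1-2 px wide, mixed orientations) on a background, producing a
#' junction-protein channel, a marker channel (elevated only on
#' marker-positive junctions), an integer label mask (0 = background, one
#' positive id per junction), and a ground-truth table. Junctions are placed
#' on a non-overlapping grid; additive Gaussian noise is applied per pixel to
#' both channels.
#'
#' @param config A [sim_junction_config()].
#' @return A list of class `sim_junction_result` with elements `protein`,
#'   `marker` (numeric matrices), `mask` (integer matrix), `truth` (data
#'   frame: `junction_id`, `marker_status`, `true_mean`, `pixel_count`), and
#'   `config`.
#' @examples
#' sim <- simulate_junction_images(sim_junction_config(
#'   image_size = c(96, 96), n_junctions_pos = 3, n_junctions_neg = 3,
#'   noise_sd = 0, seed = 2))
#' sim$truth
#' @export
simulate_junction_images <- function(config) {
  if (!inherits(config, "sim_junction_config"))
    stop_config("`config` must be a sim_junction_config object")
  nr <- config$image_size[1]; nc <- config$image_size[2]
  cell <- 16L   # placement cell: 11 px segment + margins; guarantees no overlap
  len <- 11L
  grid_r <- nr %/% cell; grid_c <- nc %/% cell
  n_total <- config$n_junctions_pos + config$n_junctions_neg
  if (n_total > grid_r * grid_c)
    stop_config(sprintf(
      "cannot place %d non-overlapping junctions in a %dx%d image (capacity %d)",
      n_total, nr, nc, grid_r * grid_c))

  res <- with_seed(config$seed, {
    slots <- sample.int(grid_r * grid_c, n_total)
    orientations <- sample(c("horizontal", "vertical", "diag_down", "diag_up"),
                           n_total, replace = TRUE)
    widths <- sample(1:2, n_total, replace = TRUE)
    status <- c(rep("positive", config$n_junctions_pos),
                rep("negative", config$n_junctions_neg))
    status <- sample(status)  # interleave populations across the field

    protein <- matrix(config$background, nr, nc)
    marker <- matrix(config$background, nr, nc)
    mask <- matrix(0L, nr, nc)
    pixel_count <- integer(n_total)
    for (j in seq_len(n_total)) {
      slot <- slots[j] - 1L
      r0 <- (slot %/% grid_c) * cell + 1L
      c0 <- (slot %% grid_c) * cell + 1L
      px <- segment_pixels(r0, c0, orientations[j], widths[j], len)
      pixel_count[j] <- nrow(px)
      protein[px] <- if (status[j] == "positive")
        config$junction_intensity_pos else config$junction_intensity_neg
      if (status[j] == "positive") marker[px] <- config$marker_intensity_pos
      mask[px] <- j
    }
    if (config$noise_sd > 0) {
      protein <- protein + matrix(stats::rnorm(nr * nc, 0, config$noise_sd), nr, nc)
      marker <- marker + matrix(stats::rnorm(nr * nc, 0, config$noise_sd), nr, nc)
    }
    list(protein = protein, marker = marker, mask = mask,
         status = status, pixel_count = pixel_count)
  })

  truth <- data.frame(
    junction_id = seq_len(n_total),
    marker_status = res$status,
    true_mean = ifelse(res$status == "positive",
                       config$junction_intensity_pos,
                       config$junction_intensity_neg),
    pixel_count = res$pixel_count,
    stringsAsFactors = FALSE
  )
  structure(
    list(protein = res$protein, marker = res$marker, mask = res$mask,
         truth = truth, config = config),
    class = "sim_junction_result"
  )
}

#' Simulate a balanced two-factor assay replicate table
#'
#' Replicate values are the configured cell mean plus additive Gaussian
#' noise, in the long format used by [anova_two_way()].
#'
#' @param config A [sim_assay_config()].
#' @return A list of class `sim_assay_result` with `table` (data frame:
#'   `factorA`, `factorB`, `replicate`, `value`), `truth` (the cell-mean
#'   matrix), and `config`.
#' @examples
#' cm <- matrix(c(1, 1, 2, 2), 2, dimnames = list(c("MCF7", "FLCARMCF7"),
#'                                                c("basal", "Ad5")))
#' simulate_assay_table(sim_assay_config(cm, n_replicates = 2, noise_sd = 0))$table
#' @export
simulate_assay_table <- function(config) {
  if (!inherits(config, "sim_assay_config"))
    stop_config("`config` must be a sim_assay_config object")
  cm <- config$cell_means
  grid <- expand.grid(factorA = rownames(cm), factorB = colnames(cm),
                      replicate = seq_len(config$n_replicates),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  means <- cm[cbind(grid$factorA, grid$factorB)]
  values <- with_seed(config$seed,
                      means + stats::rnorm(nrow(grid), 0, config$noise_sd))
  tab <- data.frame(grid, value = values, stringsAsFactors = FALSE)
  structure(list(table = tab, truth = cm, config = config),
            class = "sim_assay_result")
}
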