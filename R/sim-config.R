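#' Default FRAP acquisition schedule
#'
#' Frame times for a junctional FRAP experiment: three pre-bleach frames taken
#' every 10 s, then post-bleach frames immediately after the bleach (t = 0 s),
#' at 5 s, and every 15 s thereafter out to 5 minutes. Time zero is the first
#' post-bleach frame; pre-bleach times are negative.
#'
#' @param prebleach_times Numeric vector of pre-bleach frame times in seconds
#'   (negative, strictly increasing).
#' @param postbleach_times Numeric vector of post-bleach frame times in seconds
#'   (non-negative, strictly increasing).
#' @return A data frame with columns `time_s` (seconds) and `phase`
#'   (`"prebleach"` or `"postbleach"`).
#' @examples
#' head(default_frap_schedule())
#' @export
default_frap_schedule <- function(prebleach_times = c(-30, -20, -10),
                                  postbleach_times = c(0, 5, seq(15, 300, by = 15))) {
  data.frame(
    time_s = c(prebleach_times, postbleach_times),
    phase = rep(c("prebleach", "postbleach"),
                c(length(prebleach_times), length(postbleach_times))),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic FRAP trace generator
#'
#' Ground-truth parameters of the single-exponential recovery model used to
#' simulate bleach-ROI and whole-cell time series. The ideal bleach-ROI signal
#' recovers as `I(t) = I_post + M * (I_pre - I_post) * (1 - exp(-tau * t))`
#' with `I_post = bleach_depth * I_pre`; both channels fade multiplicatively
#' at `photofade_rate` from the first acquired frame, and observations carry
#' multiplicative Gaussian noise.
#'
#' @param prebleach_mean Pre-bleach ROI intensity `I_pre`, arbitrary units (AU).
#' @param bleach_depth Fraction of pre-bleach intensity remaining at the first
#'   post-bleach frame, in `[0, 1)`.
#' @param mobile_fraction_true True mobile fraction `M`, in `[0, 1]`.
#' @param tau_true Recovery rate constant, per second (> 0).
#' @param photofade_rate Whole-cell acquisition fading rate, per second (>= 0).
#' @param noise_sd_frac Multiplicative noise standard deviation as a fraction
#'   of the ideal intensity (>= 0).
#' @param schedule Acquisition schedule data frame (`time_s`, `phase`), as from
#'   [default_frap_schedule()]. Needs at least 3 pre-bleach and 5 post-bleach
#'   frames, times strictly increasing within each phase.
#' @param n_traces Number of traces (cells) to simulate.
#' @param noise_model `"gaussian"` (multiplicative, default) or `"poisson"`
#'   (counts with the ideal intensity as the expectation).
#' @param seed Integer RNG seed; identical seeds give bit-identical output.
#' @return An object of class `sim_frap_config`.
#' @seealso [simulate_frap_traces()]
#' @export
sim_frap_config <- function(prebleach_mean = 1000,
                            bleach_depth = 0.2,
                            mobile_fraction_true = 0.5,
                            tau_true = 0.05,
                            photofade_rate = 0.002,
                            noise_sd_frac = 0.02,
                            schedule = default_frap_schedule(),
                            n_traces = 12,
                            noise_model = c("gaussian", "poisson"),
                            seed = 1L) {
  noise_model <- match.arg(noise_model)
  if (!is_number(prebleach_mean) || prebleach_mean <= 0)
    stop_config("`prebleach_mean` must be a positive number")
  if (!is_number(bleach_depth) || bleach_depth < 0 || bleach_depth >= 1)
    stop_config("`bleach_depth` must lie in [0, 1)")
  if (!is_number(mobile_fraction_true) ||
      mobile_fraction_true < 0 || mobile_fraction_true > 1)
    stop_config("`mobile_fraction_true` must lie in [0, 1]")
  if (!is_number(tau_true) || tau_true <= 0)
    stop_config("`tau_true` must be > 0")
  if (!is_number(photofade_rate) || photofade_rate < 0)
    stop_config("`photofade_rate` must be >= 0")
  if (!is_number(noise_sd_frac) || noise_sd_frac < 0)
    stop_config("`noise_sd_frac` must be >= 0")
  if (!is_count(n_traces)) stop_config("`n_traces` must be a positive integer")
  if (!is_count(seed, min = -.Machine$integer.max))
    stop_config("`seed` must be an integer")
  validate_schedule(schedule)

  structure(
    list(
      prebleach_mean = prebleach_mean, bleach_depth = bleach_depth,
      mobile_fraction_true = mobile_fraction_true, tau_true = tau_true,
      photofade_rate = photofade_rate, noise_sd_frac = noise_sd_frac,
      schedule = schedule, n_traces = as.integer(n_traces),
      noise_model = noise_model, seed = as.integer(seed)
    ),
    class = "sim_frap_config"
  )
}

validate_schedule <- function(schedule) {
  if (!is.data.frame(schedule) ||
      !all(c("time_s", "phase") %in% names(schedule)))
    stop_config("`schedule` must be a data frame with columns time_s, phase")
  if (!all(schedule$phase %in% c("prebleach", "postbleach")))
    stop_config("schedule phase labels must be 'prebleach' or 'postbleach'")
  pre <- schedule$time_s[schedule$phase == "prebleach"]
  post <- schedule$time_s[schedule$phase == "postbleach"]
  if (length(pre) < 3L)
    stop_config("schedule must contain at least 3 prebleach frames")
  if (length(post) < 5L)
    stop_config("schedule must contain at least 5 postbleach frames")
  if (any(diff(pre) <= 0) || any(diff(post) <= 0))
    stop_config("schedule times must be strictly increasing within phase")
  if (any(pre >= 0) || any(post < 0) || post[1] != 0)
    stop_config("prebleach times must be negative; postbleach start at t = 0")
  invisible(schedule)
}

#' Configuration for the synthetic junction image generator
#'
#' Describes a two-channel field of view containing two junction populations:
#' marker-positive junctions (cells expressing the fluorescent marker) and
#' marker-negative reference junctions. Junctions are rendered as thin
#' (1-2 px) straight segments with a configured per-pixel mean intensity in
#' the junction-protein channel; the marker channel is elevated only on
#' marker-positive junctions.
#'
#' @param image_size Integer vector `c(rows, cols)` in pixels.
#' @param n_junctions_pos,n_junctions_neg Number of marker-positive and
#'   marker-negative junctions (at least one negative junction is required:
#'   it is the normalization reference population).
#' @param junction_intensity_pos,junction_intensity_neg Per-pixel mean
#'   intensity (AU) of the junction-protein channel on each population.
#' @param marker_intensity_pos Per-pixel marker-channel intensity (AU) on
#'   marker-positive junctions.
#' @param background Background intensity (AU), both channels.
#' @param noise_sd Additive Gaussian noise standard deviation (AU).
#' @param seed Integer RNG seed.
#' @return An object of class `sim_junction_config`.
#' @seealso [simulate_junction_images()]
#' @export
sim_junction_config <- function(image_size = c(256L, 256L),
                                n_junctions_pos = 15L,
                                n_junctions_neg = 15L,
                                junction_intensity_pos = 4,
                                junction_intensity_neg = 8,
                                marker_intensity_pos = 8,
                                background = 1,
                                noise_sd = 0.2,
                                seed = 1L) {
  if (length(image_size) != 2L || !all(vapply(image_size, is_count, TRUE)))
    stop_config("`image_size` must be two positive integers (rows, cols)")
  if (!is_count(n_junctions_pos, min = 0L))
    stop_config("`n_junctions_pos` must be a non-negative integer")
  if (!is_count(n_junctions_neg, min = 1L))
    stop_config("`n_junctions_neg` must be >= 1 (reference population)")
  for (nm in c("junction_intensity_pos", "junction_intensity_neg",
               "marker_intensity_pos", "background", "noise_sd")) {
    v <- get(nm)
    if (!is_number(v) || v < 0) stop_config(sprintf("`%s` must be >= 0", nm))
  }
  structure(
    list(
      image_size = as.integer(image_size),
      n_junctions_pos = as.integer(n_junctions_pos),
      n_junctions_neg = as.integer(n_junctions_neg),
      junction_intensity_pos = junction_intensity_pos,
      junction_intensity_neg = junction_intensity_neg,
      marker_intensity_pos = marker_intensity_pos,
      background = background, noise_sd = noise_sd, seed = as.integer(seed)
    ),
    class = "sim_junction_config"
  )
}

#' Configuration for the synthetic assay replicate-table generator
#'
#' A balanced two-factor design (e.g., cell line x treatment) with a known
#' mean per cell and additive Gaussian replicate noise, emulating
#' permeability, adhesion, and flow-cytometry MFI replicate tables.
#'
#' @param cell_means Numeric matrix of cell means (AU); rows are levels of
#'   factor A, columns levels of factor B; `dimnames` supply the level labels.
#' @param n_replicates Replicates per cell (>= 2, balanced).
#' @param noise_sd Additive Gaussian noise standard deviation (AU).
#' @param seed Integer RNG seed.
#' @return An object of class `sim_assay_config`.
#' @seealso [simulate_assay_table()]
#' @export
sim_assay_config <- function(cell_means, n_replicates = 4L, noise_sd = 1,
                             seed = 1L) {
  if (!is.matrix(cell_means) || !is.numeric(cell_means) ||
      any(!is.finite(cell_means)))
    stop_config("`cell_means` must be a finite numeric matrix")
  if (!is_count(n_replicates, min = 2L))
    stop_config("`n_replicates` must be an integer >= 2 (balanced design)")
  if (!is_number(noise_sd) || noise_sd < 0)
    stop_config("`noise_sd` must be >= 0")
  if (is.null(rownames(cell_means)))
    rownames(cell_means) <- paste0("A", seq_len(nrow(cell_means)))
  if (is.null(colnames(cell_means)))
    colnames(cell_means) <- paste0("B", seq_len(ncol(cell_means)))
  structure(
    list(cell_means = cell_means, n_replicates = as.integer(n_replicates),
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "sim_assay_config"
  )
}
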