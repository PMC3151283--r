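#' Construct a FRAP trace
#'
#' One cell's bleach-ROI and whole-cell time series. Time zero is the first
#' post-bleach frame; pre-bleach frames carry negative times. The whole-cell
#' channel tracks acquisition photofading and drives [correct_photofading()].
#'
#' @param trace_id Identifier.
#' @param times Frame times in seconds, strictly increasing.
#' @param roi_values Mean intensity of the bleached region per frame (AU).
#' @param cell_values Whole-cell mean intensity per frame (AU).
#' @param phase Per-frame label, `"prebleach"` or `"postbleach"`.
#' @param roi_um Side length of the square bleach region in micrometres
#'   (metadata only; 4 um in the junctional assay this models).
#' @return An object of class `frap_trace`.
#' @export
frap_trace <- function(trace_id, times, roi_values, cell_values, phase,
                       roi_um = 4) {
  n <- length(times)
  if (length(roi_values) != n || length(cell_values) != n ||
      length(phase) != n)
    stop_data("times, roi_values, cell_values and phase must have equal length")
  if (!all(phase %in% c("prebleach", "postbleach")))
    stop_data("phase labels must be 'prebleach' or 'postbleach'")
  if (any(diff(times) <= 0))
    stop_data("times must be strictly increasing")
  structure(
    list(trace_id = as.character(trace_id), times = as.numeric(times),
         roi_values = as.numeric(roi_values),
         cell_values = as.numeric(cell_values),
         phase = as.character(phase), roi_um = roi_um),
    class = "frap_trace"
  )
}

#' @export
print.frap_trace <- function(x, ...) {
  cat(sprintf("<frap_trace %s: %d frames (%d prebleach), t = %g..%g s>\n",
              x$trace_id, length(x$times), sum(x$phase == "prebleach"),
              min(x$times), max(x$times)))
  invisible(x)
}

#' Correct a FRAP trace for acquisition photofading
#'
#' Repeated imaging bleaches the whole cell; the ROI signal therefore decays
#' even without exchange. The whole-cell channel measures that fading
#' directly, so each ROI value is divided by the whole-cell signal expressed
#' relative to its pre-bleach mean:
#' `corrected[i] = roi[i] / (cell[i] / mean(prebleach cell))`.
#' After correction the whole-cell channel is set to its constant pre-bleach
#' mean (bookkeeping: the fading it recorded has been applied).
#'
#' @param trace A [frap_trace()]; `cell_values` must be strictly positive and
#'   at least one pre-bleach frame present.
#' @return A `frap_trace` with corrected `roi_values`.
#' @export
correct_photofading <- function(trace) {
  if (!inherits(trace, "frap_trace")) stop_data("`trace` must be a frap_trace")
  if (any(trace$cell_values <= 0))
    stop_data("whole-cell intensities must be strictly positive")
  pre <- trace$phase == "prebleach"
  if (!any(pre)) stop_data("trace has no prebleach frames")
  cell_ref <- mean(trace$cell_values[pre])
  corrected <- trace$roi_values / (trace$cell_values / cell_ref)
  frap_trace(trace$trace_id, trace$times, corrected,
             rep(cell_ref, length(trace$times)), trace$phase, trace$roi_um)
}

#' Normalize a FRAP trace to its pre-bleach intensity
#'
#' Converts intensities to percent of the mean pre-bleach ROI intensity, so
#' the pre-bleach level is 100 by construction and fitted plateaus read
#' directly as percent recovery.
#'
#' @param trace A [frap_trace()] with at least one pre-bleach frame and a
#'   positive pre-bleach mean.
#' @return A `frap_trace` in percent units (pre-bleach ROI mean = 100).
#' @export
normalize_to_prebleach <- function(trace) {
  if (!inherits(trace, "frap_trace")) stop_data("`trace` must be a frap_trace")
  pre <- trace$phase == "prebleach"
  if (!any(pre)) stop_data("trace has no prebleach frames")
  ref <- mean(trace$roi_values[pre])
  if (ref <= 0) stop_data("prebleach ROI mean must be positive")
  frap_trace(trace$trace_id, trace$times,
             trace$roi_values * (100 / ref),
             trace$cell_values * (100 / ref),
             trace$phase, trace$roi_um)
}

# Initial values for the bounded single-exponential fit. The half-recovery
# crossing time seeds tau; a 20 s half-life (tau ~ 0.035/s) is the fallback
# when the trace never crosses mid-recovery.
exp_fit_start <- function(t, y) {
  i0 <- y[1]
  p <- mean(utils::tail(y, 3))
  half <- (i0 + p) / 2
  cross <- which(y >= half & t > 0)
  tau <- if (p > i0 && length(cross) > 0) log(2) / t[cross[1]] else 0.05
  tau <- min(max(tau, 1e-4), 5)
  list(P = min(max(p, 0), 200), I0 = min(max(i0, 0), 200), tau = tau)
}

#' Fit a single-exponential recovery to a normalized FRAP trace
#'
#' Least-squares fit of `I(t) = P - (P - I0) * exp(-tau * t)` over the
#' post-bleach frames only (`t >= 0`), with free parameters `P` (plateau,
#' percent of pre-bleach), `I0` (intensity immediately post-bleach) and `tau`
#' (recovery rate, per second). Fitting uses Levenberg-Marquardt with box
#' bounds `tau` in `[1e-5, 10]` per second and `P`, `I0` in `[0, 200]`
#' percent. The fit is flagged non-converged (`converged = FALSE`) when the
#' optimizer fails, `tau` lands on a bound, the recovery amplitude `P - I0`
#' is negligible (tau unidentifiable), or `P < I0`.
#'
#' @param trace A pre-bleach-normalized [frap_trace()] (percent units) with
#'   at least 3 post-bleach frames.
#' @param convention Mobile-fraction convention passed to
#'   [compute_fractions()]: `"full_scale"` (default) or
#'   `"percent_of_prebleach"`.
#' @param plateau `"fitted"` (default) uses the fitted asymptote `P`;
#'   `"empirical"` uses the mean of the last 3 post-bleach frames.
#' @return An object of class `frap_fit`: `tau`, `post_bleach_pct`,
#'   `plateau_pct`, `t_half`, `mobile_pct`, `immobile_pct`, `rss`,
#'   `converged`, `n_points`, `trace_id`.
#' @examples
#' sim <- simulate_frap_traces(sim_frap_config(noise_sd_frac = 0, n_traces = 1))
#' tr <- normalize_to_prebleach(correct_photofading(sim$traces[[1]]))
#' fit_single_exponential(tr)
#' @export
fit_single_exponential <- function(trace,
                                   convention = c("full_scale",
                                                  "percent_of_prebleach"),
                                   plateau = c("fitted", "empirical")) {
  if (!inherits(trace, "frap_trace")) stop_data("`trace` must be a frap_trace")
  convention <- match.arg(convention)
  plateau <- match.arg(plateau)
  post <- trace$phase == "postbleach"
  if (sum(post) < 3L)
    stop_data("at least 3 postbleach frames are required for fitting")
  t <- trace$times[post]
  y <- trace$roi_values[post]
  t <- t - t[1]

  start <- exp_fit_start(t, y)
  lower <- c(P = 0, I0 = 0, tau = 1e-5)
  upper <- c(P = 200, I0 = 200, tau = 10)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ P - (P - I0) * exp(-tau * t),
      start = start, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                           ptol = 1e-12)
    ),
    error = function(e) NULL
  )

  if (is.null(fit)) {
    cf <- unlist(start)
    converged <- FALSE
    rss <- sum((y - (cf["P"] - (cf["P"] - cf["I0"]) * exp(-cf["tau"] * t)))^2)
  } else {
    cf <- stats::coef(fit)
    rss <- sum(stats::residuals(fit)^2)
    amplitude <- cf["P"] - cf["I0"]
    at_bound <- cf["tau"] <= lower["tau"] * (1 + 1e-6) ||
      cf["tau"] >= upper["tau"] * (1 - 1e-6)
    converged <- !at_bound && amplitude > 1e-2
  }

  plateau_pct <- if (plateau == "empirical") mean(utils::tail(y, 3)) else
    unname(cf["P"])
  out <- structure(
    list(trace_id = trace$trace_id,
         tau = unname(cf["tau"]),
         post_bleach_pct = unname(cf["I0"]),
         plateau_pct = plateau_pct,
         t_half = NA_real_, mobile_pct = NA_real_, immobile_pct = NA_real_,
         rss = rss, converged = converged, n_points = length(y),
         convention = convention),
    class = "frap_fit"
  )
  if (out$tau > 0) out$t_half <- compute_half_life(out$tau)
  if (converged && out$post_bleach_pct < 100) {
    fr <- compute_fractions(out, convention)
    out$mobile_pct <- fr[["mobile_pct"]]
    out$immobile_pct <- fr[["immobile_pct"]]
  }
  out
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf(
    "<frap_fit %s: tau = %.4g /s, t1/2 = %.3g s, plateau = %.3g%%, mobile = %.3g%%%s>\n",
    x$trace_id, x$tau, x$t_half, x$plateau_pct, x$mobile_pct,
    if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' Recovery half-life from the exponential rate
#'
#' The time at which half of the recoverable fluorescence has returned:
#' `t_half = ln(0.5) / (-tau)`, i.e. `ln(2) / tau`.
#'
#' @param tau Recovery rate constant, per second (> 0).
#' @return Half-life in seconds.
#' @examples
#' compute_half_life(log(2))  # 1 s
#' @export
compute_half_life <- function(tau) {
  if (!is.numeric(tau) || any(!is.finite(tau)) || any(tau <= 0))
    stop_data("`tau` must be > 0")
  log(0.5) / (-tau)
}

#' Mobile and immobile fractions from a recovery fit
#'
#' The mobile fraction is the percentage recovery at plateau; the immobile
#' fraction is its complement (they always sum to 100). Two conventions:
#' `"full_scale"` (default, standard FRAP practice) rescales recovery to the
#' bleached amplitude, `mobile = 100 * (plateau - post) / (100 - post)`;
#' `"percent_of_prebleach"` reads the plateau percentage literally,
#' `mobile = plateau`.
#'
#' @param fit A [frap_fit()] (normalized units: pre-bleach = 100).
#' @param convention `"full_scale"` or `"percent_of_prebleach"`.
#' @return Named numeric vector `c(mobile_pct, immobile_pct)`.
#' @examples
#' f <- structure(list(plateau_pct = 60, post_bleach_pct = 20),
#'                class = "frap_fit")
#' compute_fractions(f)  # mobile 50, immobile 50
#' @export
compute_fractions <- function(fit, convention = c("full_scale",
                                                  "percent_of_prebleach")) {
  convention <- match.arg(convention)
  p <- fit$plateau_pct
  i0 <- fit$post_bleach_pct
  if (!is_number(p) || !is_number(i0))
    stop_data("fit must carry numeric plateau_pct and post_bleach_pct")
  if (i0 >= 100)
    stop_data("post-bleach intensity >= pre-bleach level: no bleach occurred")
  mobile <- if (convention == "full_scale") 100 * (p - i0) / (100 - i0) else p
  c(mobile_pct = mobile, immobile_pct = 100 - mobile)
}

#' Analyze a FRAP experiment: per-trace fits and per-condition summaries
#'
#' Runs the full quantification per trace - photofading correction,
#' pre-bleach normalization, single-exponential fit, half-life, and
#' mobile/immobile fractions - then pools converged traces per condition and
#' reports mean and standard error (SEM) of `t_half`, `mobile_pct` and
#' `immobile_pct`. Non-converged traces are excluded from summaries but
#' retained in the per-trace table. A warning is raised for conditions with
#' fewer than 12 converged cells, the customary minimum pooled per condition.
#'
#' @param traces List of [frap_trace()] objects.
#' @param conditions Character vector of condition labels, one per trace.
#' @param convention,plateau Passed to [fit_single_exponential()].
#' @return A list of class `frap_experiment` with `fits` (one row per trace:
#'   id, condition, parameters, diagnostics) and `summary` (one row per
#'   condition x metric: `condition`, `metric`, `mean`, `sem`, `n_cells`).
#' @examples
#' sim <- simulate_frap_traces(sim_frap_config(n_traces = 12, seed = 3))
#' res <- analyze_frap_experiment(sim$traces, rep("basal", 12))
#' res$summary
#' @export
analyze_frap_experiment <- function(traces, conditions,
                                    convention = c("full_scale",
                                                   "percent_of_prebleach"),
                                    plateau = c("fitted", "empirical")) {
  convention <- match.arg(convention)
  plateau <- match.arg(plateau)
  if (length(traces) == 0L) stop_data("no traces supplied")
  if (length(conditions) != length(traces))
    stop_data("`conditions` must supply one label per trace")
  if (any(is.na(conditions) | !nzchar(conditions)))
    stop_data("every trace must carry a non-empty condition label")

  fits <- lapply(traces, function(tr) {
    fit_single_exponential(
      normalize_to_prebleach(correct_photofading(tr)),
      convention = convention, plateau = plateau)
  })
  fit_tab <- data.frame(
    trace_id = vapply(fits, `[[`, "", "trace_id"),
    condition = as.character(conditions),
    tau = vapply(fits, `[[`, 0, "tau"),
    t_half = vapply(fits, `[[`, 0, "t_half"),
    post_bleach_pct = vapply(fits, `[[`, 0, "post_bleach_pct"),
    plateau_pct = vapply(fits, `[[`, 0, "plateau_pct"),
    mobile_pct = vapply(fits, `[[`, 0, "mobile_pct"),
    immobile_pct = vapply(fits, `[[`, 0, "immobile_pct"),
    rss = vapply(fits, `[[`, 0, "rss"),
    n_points = vapply(fits, `[[`, 0L, "n_points"),
    converged = vapply(fits, `[[`, TRUE, "converged"),
    stringsAsFactors = FALSE
  )

  metrics <- c("t_half", "mobile_pct", "immobile_pct")
  rows <- list()
  for (cond in unique(fit_tab$condition)) {
    sub <- fit_tab[fit_tab$condition == cond & fit_tab$converged, ]
    if (nrow(sub) == 0L)
      stop_data(sprintf("condition '%s' has no converged traces", cond))
    if (nrow(sub) < 12L)
      warning(sprintf("condition '%s' pools only %d converged cells (< 12)",
                      cond, nrow(sub)), call. = FALSE)
    for (m in metrics) {
      v <- sub[[m]]
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cond, metric = m, mean = mean(v),
        sem = if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else NA_real_,
        n_cells = nrow(sub), stringsAsFactors = FALSE)
    }
  }
  structure(list(fits = fit_tab, summary = do.call(rbind, rows),
                 convention = convention),
            class = "frap_experiment")
}

#' @export
print.frap_experiment <- function(x, ...) {
  cat(sprintf("<frap_experiment: %d traces, %d condition(s), convention = %s>\n",
              nrow(x$fits), length(unique(x$fits$condition)), x$convention))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
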