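test_that("photofading correction is the identity for a constant whole-cell signal", {
  tr <- make_ideal_trace()
  out <- correct_photofading(tr)
  expect_equal(out$roi_values, tr$roi_values)
})

test_that("photofading correction rejects non-positive whole-cell values", {
  tr <- make_ideal_trace()
  tr$cell_values[5] <- 0
  expect_error(correct_photofading(tr), class = "frapkit_data_error")
  tr2 <- make_ideal_trace()
  tr2$phase <- rep("postbleach", length(tr2$phase))
  tr2$times <- seq_along(tr2$times) - 1  # keep t = 0 start
  expect_error(correct_photofading(tr2), "prebleach",
               class = "frapkit_data_error")
})

test_that("correction of a faded synthetic trace restores the ideal shape", {
  cfg <- sim_frap_config(photofade_rate = 0.002, noise_sd_frac = 0,
                         mobile_fraction_true = 0.7, n_traces = 1, seed = 1)
  cfg0 <- sim_frap_config(photofade_rate = 0, noise_sd_frac = 0,
                          mobile_fraction_true = 0.7, n_traces = 1, seed = 1)
  faded <- simulate_frap_traces(cfg)$traces[[1]]
  ideal <- simulate_frap_traces(cfg0)$traces[[1]]
  corrected <- correct_photofading(faded)
  # corrected trace is proportional to the unfaded ideal (the constant is
  # the mean pre-bleach fade factor) ...
  ratio <- corrected$roi_values / ideal$roi_values
  expect_equal(ratio, rep(ratio[1], length(ratio)), tolerance = 1e-12)
  # ... and after pre-bleach normalization the two are identical
  expect_equal(normalize_to_prebleach(corrected)$roi_values,
               normalize_to_prebleach(ideal)$roi_values, tolerance = 1e-12)
})

test_that("pre-bleach normalization converts to percent of pre-bleach", {
  sched <- data.frame(time_s = c(-30, -20, -10, 0, 5),
                      phase = rep(c("prebleach", "postbleach"), c(3, 2)))
  tr <- frap_trace("t", sched$time_s, c(200, 200, 200, 100, 150),
                   rep(400, 5), sched$phase)
  out <- normalize_to_prebleach(tr)
  expect_equal(out$roi_values, c(100, 100, 100, 50, 75))
  expect_equal(mean(out$roi_values[out$phase == "prebleach"]), 100)

  tr$phase <- rep("postbleach", 5)
  tr$times <- 0:4
  expect_error(normalize_to_prebleach(tr), class = "frapkit_data_error")
})

test_that("normalized pre-bleach mean is exactly 100 for noisy traces", {
  sim <- simulate_frap_traces(sim_frap_config(noise_sd_frac = 0.1, seed = 8))
  for (tr in sim$traces) {
    out <- normalize_to_prebleach(tr)
    expect_equal(mean(out$roi_values[out$phase == "prebleach"]), 100)
  }
})

test_that("noiseless single-exponential fits recover tau, plateau and post-bleach level", {
  cases <- expand.grid(tau = c(0.01, 0.05, 0.2), m = c(0.3, 0.7, 0.95))
  for (i in seq_len(nrow(cases))) {
    tau <- cases$tau[i]; m <- cases$m[i]
    i0 <- 20; p <- i0 + m * (100 - i0)
    fit <- fit_single_exponential(make_ideal_trace(i0 = i0, plateau = p,
                                                   tau = tau))
    expect_true(fit$converged)
    expect_equal(fit$tau, tau, tolerance = 1e-6)
    expect_equal(fit$plateau_pct, p, tolerance = 1e-6)
    expect_equal(fit$post_bleach_pct, i0, tolerance = 1e-6)
  }
})

test_that("a flat post-bleach trace is flagged non-converged", {
  fit <- fit_single_exponential(make_ideal_trace(i0 = 20, plateau = 20))
  expect_false(fit$converged)
  expect_lt(abs(fit$plateau_pct - fit$post_bleach_pct), 1e-6)
})

test_that("fitting requires at least 3 post-bleach frames", {
  tr <- frap_trace("t", c(-10, 0, 5), c(100, 20, 30), rep(100, 3),
                   c("prebleach", "postbleach", "postbleach"))
  expect_error(fit_single_exponential(tr), class = "frapkit_data_error")
})

test_that("mean fitted tau over 12 noisy traces lands within 5% of truth", {
  sim <- simulate_frap_traces(sim_frap_config(
    tau_true = 0.05, mobile_fraction_true = 0.5, noise_sd_frac = 0.02,
    n_traces = 12, seed = 21))
  taus <- vapply(sim$traces, function(tr) {
    fit_single_exponential(normalize_to_prebleach(correct_photofading(tr)))$tau
  }, 0)
  expect_equal(mean(taus), 0.05, tolerance = 0.05)
})

test_that("half-life follows ln(2)/tau and matches the bisection oracle", {
  expect_equal(compute_half_life(log(2)), 1.0)
  # doubling the rate halves the half-life
  expect_equal(compute_half_life(0.1), 2 * compute_half_life(0.2))
  # independent oracle: bisection solve of exp(-tau t) = 0.5
  for (tau in 10^seq(-4, 1, length.out = 21)) {
    expect_equal(compute_half_life(tau), half_life_bisect(tau),
                 tolerance = 1e-9)
  }
  expect_equal(compute_half_life(0.0231049), 30.0, tolerance = 1e-4)
  expect_error(compute_half_life(0), class = "frapkit_data_error")
  expect_error(compute_half_life(-1), class = "frapkit_data_error")
})

test_that("half-life is strictly decreasing in tau", {
  taus <- sort(10^runif(20, -3, 1))
  expect_true(all(diff(compute_half_life(taus)) < 0))
})

test_that("mobile/immobile fractions follow the declared conventions", {
  f <- structure(list(plateau_pct = 60, post_bleach_pct = 20),
                 class = "frap_fit")
  expect_equal(compute_fractions(f, "full_scale"),
               c(mobile_pct = 50, immobile_pct = 50))
  expect_equal(compute_fractions(f, "percent_of_prebleach"),
               c(mobile_pct = 60, immobile_pct = 40))
  f$plateau_pct <- 20
  expect_equal(compute_fractions(f)[["mobile_pct"]], 0)
  f$plateau_pct <- 100
  expect_equal(compute_fractions(f, "full_scale")[["mobile_pct"]], 100)
  expect_equal(compute_fractions(f, "percent_of_prebleach")[["mobile_pct"]], 100)
  f$post_bleach_pct <- 100
  expect_error(compute_fractions(f), class = "frapkit_data_error")
})

test_that("mobile and immobile percentages always sum to 100", {
  set.seed(31)
  for (i in 1:50) {
    post <- runif(1, 0, 99)
    f <- structure(list(plateau_pct = runif(1, post, 100),
                        post_bleach_pct = post),
                   class = "frap_fit")
    for (conv in c("full_scale", "percent_of_prebleach")) {
      fr <- compute_fractions(f, conv)
      expect_identical(unname(fr[1] + fr[2]), 100)
    }
  }
})

test_that("identical noiseless traces summarize with zero SEM", {
  sim <- simulate_frap_traces(sim_frap_config(noise_sd_frac = 0,
                                              n_traces = 12, seed = 1))
  res <- analyze_frap_experiment(sim$traces, rep("ctrl", 12))
  expect_true(all(res$summary$sem < 1e-9))
  expect_true(all(res$summary$n_cells == 12))
})

test_that("two-condition experiments recover distinct generator truths", {
  a <- simulate_frap_traces(sim_frap_config(mobile_fraction_true = 0.5,
                                            n_traces = 12, seed = 41))
  b <- simulate_frap_traces(sim_frap_config(mobile_fraction_true = 0.9,
                                            n_traces = 12, seed = 42))
  res <- analyze_frap_experiment(c(a$traces, b$traces),
                                 rep(c("clustered", "new_contact"), each = 12))
  s <- res$summary
  m_clustered <- s$mean[s$condition == "clustered" & s$metric == "mobile_pct"]
  m_new <- s$mean[s$condition == "new_contact" & s$metric == "mobile_pct"]
  expect_equal(m_clustered, 50, tolerance = 0.06)
  expect_equal(m_new, 90, tolerance = 0.04)
  t_half <- s$mean[s$metric == "t_half"]
  expect_equal(t_half, rep(log(2) / 0.05, 2), tolerance = 0.1)
})

test_that("non-converged traces are excluded from summaries but reported", {
  sim <- simulate_frap_traces(sim_frap_config(n_traces = 12, seed = 5))
  flat <- make_ideal_trace(i0 = 20, plateau = 20, id = "flat")
  res <- suppressWarnings(
    analyze_frap_experiment(c(sim$traces, list(flat)), rep("cond", 13)))
  expect_equal(nrow(res$fits), 13)
  expect_false(res$fits$converged[res$fits$trace_id == "flat"])
  expect_true(all(res$summary$n_cells == 12))
})

test_that("small conditions trigger the pooling warning", {
  sim <- simulate_frap_traces(sim_frap_config(n_traces = 3, seed = 6))
  expect_warning(analyze_frap_experiment(sim$traces, rep("small", 3)),
                 "< 12")
})

test_that("condition labels are mandatory", {
  sim <- simulate_frap_traces(sim_frap_config(n_traces = 2, seed = 7))
  expect_error(analyze_frap_experiment(sim$traces, c("a", "")),
               class = "frapkit_data_error")
  expect_error(analyze_frap_experiment(list(), character(0)),
               class = "frapkit_data_error")
})
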