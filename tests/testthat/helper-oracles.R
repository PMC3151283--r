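# Independent oracles and small fixture builders shared across tests.

# Bisection solve of exp(-tau * t) = 0.5: independent of the closed form
# used by compute_half_life().
half_life_bisect <- function(tau, iters = 200) {
  lo <- 0
  hi <- 1
  while (exp(-tau * hi) > 0.5) hi <- hi * 2
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (exp(-tau * mid) > 0.5) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Hand-rolled trace: constant pre-bleach at `pre`, then exponential recovery
# sampled on the default schedule, no fading, no noise.
make_ideal_trace <- function(pre = 100, i0 = 20, plateau = 70, tau = 0.05,
                             id = "manual") {
  sched <- default_frap_schedule()
  t_post <- sched$time_s[sched$phase == "postbleach"]
  roi <- c(rep(pre, 3), plateau - (plateau - i0) * exp(-tau * t_post))
  frap_trace(id, sched$time_s, roi, rep(pre, nrow(sched)), sched$phase)
}

# One-way F statistic computed directly (for the permutation oracle; kept
# minimal and separate from anova_one_way's table plumbing).
f_stat_oneway <- function(values, group) {
  f <- factor(group)
  grand <- mean(values)
  means <- tapply(values, f, mean)
  n_g <- as.numeric(table(f))
  ssb <- sum(n_g * (means - grand)^2)
  ssw <- sum((values - means[f])^2)
  (ssb / (nlevels(f) - 1)) / (ssw / (length(values) - nlevels(f)))
}
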