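# Shared simulation helpers for the test suite.

# Two parallel-line arms with additive normal noise; arm b is a true
# `shift`-fold horizontal displacement of arm a (ratio alone/combination
# convention: shift > 1 means arm b needs more dose).
sim_parallel_arms <- function(n_per_dose = 6, doses = c(1, 10^0.5, 10),
                              slope = 40, intercept = 20, sd = 8,
                              shift = 1) {
  d <- rep(doses, each = n_per_dose)
  ea <- intercept + slope * log10(d) + rnorm(length(d), 0, sd)
  eb <- intercept + slope * log10(d / shift) + rnorm(length(d), 0, sd)
  list(dose_a = d, effect_a = pmin(ea, 100),
       dose_b = d, effect_b = pmin(eb, 100))
}

# A valid 15-bin behavior row without the generator.
behavior_row <- function(rat_id, group, cg = 0, ms = 0,
                         bins = c(45, 40, 10, 12, 18, 24, 28, 30, 30, 28,
                                  24, 20, 16, 12, 8)) {
  row <- data.frame(rat_id = rat_id, group = group, cg_dose_mgkg = cg,
                    ms_dose_mgkg = ms, stringsAsFactors = FALSE)
  row[sprintf("bin%02d", 1:15)] <- as.list(bins)
  row
}

# Independent weighted least-squares oracle: normal equations solved
# directly, no lm.
ols_oracle <- function(x, y, w = rep(1, length(x))) {
  X <- cbind(1, x)
  XtWX <- t(X) %*% (w * X)
  beta <- solve(XtWX, t(X) %*% (w * y))
  c(intercept = beta[1], slope = beta[2])
}
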