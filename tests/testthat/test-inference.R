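test_that("constant data give F = 0, p = 1 for every effect", {
  d <- expand.grid(rat = paste0("r", 1:8), time = c("t1", "t2"))
  d$treatment <- ifelse(as.integer(sub("r", "", d$rat)) <= 4, "A", "B")
  d$value <- 5
  res <- two_way_rm_anova(d, value = "value", treatment = "treatment",
                          time = "time", rat = "rat")
  expect_equal(res$F, rep(0, 3))
  expect_equal(res$p, rep(1, 3))
})

test_that("mixed-design ANOVA matches a manual SS decomposition", {
  set.seed(51)
  a_lvl <- c("A", "B"); t_lvl <- c("t1", "t2", "t3"); n <- 4
  d <- expand.grid(rat = 1:(2 * n), time = t_lvl)
  d$treatment <- ifelse(d$rat <= n, "A", "B")
  d$value <- rnorm(nrow(d)) + 2 * (d$treatment == "B") +
    1.5 * (d$time == "t3")
  res <- two_way_rm_anova(d, value = "value", treatment = "treatment",
                          time = "time", rat = "rat")

  # independent sums-of-squares oracle
  y <- d$value; gm <- mean(y)
  m_rat <- tapply(y, d$rat, mean)
  m_trt <- tapply(y, d$treatment, mean)
  m_tim <- tapply(y, d$time, mean)
  m_cell <- tapply(y, interaction(d$treatment, d$time), mean)
  t_k <- length(t_lvl); a_k <- length(a_lvl)
  ss_between <- t_k * sum((m_rat - gm)^2)
  ss_trt <- n * t_k * sum((m_trt - gm)^2)
  ss_rat <- ss_between - ss_trt
  ss_tim <- a_k * n * sum((m_tim - gm)^2)
  ss_cell <- n * sum((m_cell - gm)^2)
  ss_int <- ss_cell - ss_trt - ss_tim
  ss_tot <- sum((y - gm)^2)
  ss_res <- ss_tot - ss_between - ss_tim - ss_int
  df_rat <- a_k * (n - 1)
  df_res <- df_rat * (t_k - 1)
  expect_equal(res$F[res$effect == "treatment"],
               (ss_trt / (a_k - 1)) / (ss_rat / df_rat), tolerance = 1e-10)
  expect_equal(res$F[res$effect == "time"],
               (ss_tim / (t_k - 1)) / (ss_res / df_res), tolerance = 1e-10)
  expect_equal(res$F[res$effect == "treatment:time"],
               (ss_int / ((a_k - 1) * (t_k - 1))) / (ss_res / df_res),
               tolerance = 1e-10)
  expect_equal(res$df_den, c(df_rat, df_res, df_res))
})

test_that("injected treatment effects are detected with growing power", {
  power <- vapply(c(0, 2.5), function(eff) {
    mean(vapply(1:60, function(s) {
      set.seed(5100 + s + 1000 * eff)
      d <- expand.grid(rat = 1:12, time = 1:3)
      d$treatment <- ifelse(d$rat <= 6, "A", "B")
      d$value <- rnorm(nrow(d)) + rep(rnorm(12, sd = 0.5), 3) +
        eff * (d$treatment == "B")
      two_way_rm_anova(d, "value", "treatment", "time", "rat")$p[1] < 0.05
    }, logical(1)))
  }, numeric(1))
  expect_lt(power[1], 0.2)
  expect_gt(power[2], 0.8)
})

test_that("unbalanced designs are rejected explicitly", {
  d <- expand.grid(rat = 1:6, time = c("t1", "t2"))
  d$treatment <- ifelse(d$rat <= 2, "A", "B")  # 2 vs 4 rats
  d$value <- rnorm(nrow(d))
  expect_error(two_way_rm_anova(d, "value", "treatment", "time", "rat"),
               "unsupported design")
  expect_error(two_way_rm_anova(d[-1, ], "value", "treatment", "time",
                                "rat"),
               "unsupported design")
})

test_that("Greenhouse-Geisser correction is off by default, available", {
  set.seed(52)
  d <- expand.grid(rat = 1:8, time = c("t1", "t2", "t3", "t4"))
  d$treatment <- ifelse(d$rat <= 4, "A", "B")
  d$value <- rnorm(nrow(d)) + 0.8 * as.integer(d$time)
  plain <- two_way_rm_anova(d, "value", "treatment", "time", "rat")
  expect_false("p_gg" %in% names(plain))
  gg <- two_way_rm_anova(d, "value", "treatment", "time", "rat",
                         gg_correction = TRUE)
  # reduced df can only enlarge the p of an F > 1 effect (time here)
  expect_gte(gg$p_gg[2], gg$p[2] - 1e-12)
  expect_gte(gg$gg_epsilon[2], 1 / 3)
  expect_lte(gg$gg_epsilon[2], 1)
})

test_that("Tukey HSD matches the reference implementation", {
  set.seed(53)
  v <- c(rnorm(6, 0), rnorm(6, 1), rnorm(6, 3))
  g <- rep(c("a", "b", "c"), each = 6)
  mine <- tukey_hsd(v, g)
  ref <- TukeyHSD(aov(v ~ factor(g)))$`factor(g)`
  expect_equal(-mine$mean_diff, unname(ref[, "diff"]), tolerance = 1e-10)
  expect_equal(mine$p_adj, unname(ref[, "p adj"]), tolerance = 1e-8)
})

test_that("Tukey HSD degenerate and constructed cases", {
  expect_equal(tukey_hsd(c(1, 2, 3, 1, 2, 3),
                         rep(c("a", "b"), each = 3))$mean_diff, 0)
  expect_gt(tukey_hsd(c(1, 2, 3, 1, 2, 3),
                      rep(c("a", "b"), each = 3))$p_adj, 0.99)
  set.seed(54)
  v <- c(rnorm(6), rnorm(6), rnorm(6) + 10)  # one group 10 pooled SDs off
  g <- rep(c("a", "b", "c"), each = 6)
  tk <- tukey_hsd(v, g)
  expect_lt(tk$p_adj[tk$group_a == "a" & tk$group_b == "c"], 0.001)
  expect_error(tukey_hsd(c(1, 2, 3), c("a", "a", "b")), "n >= 2")
})

test_that("relabeling groups permutes but never changes the comparisons", {
  set.seed(55)
  v <- rnorm(18)
  g <- rep(c("a", "b", "c"), each = 6)
  g2 <- c(a = "z", b = "y", c = "x")[g]
  t1 <- tukey_hsd(v, g)
  t2 <- tukey_hsd(v, g2)
  key1 <- sort(round(t1$p_adj, 12))
  key2 <- sort(round(t2$p_adj, 12))
  expect_equal(key1, key2)
  expect_equal(sort(abs(t1$mean_diff)), sort(abs(t2$mean_diff)),
               tolerance = 1e-12)
})
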