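test_that("identical arms are exactly parallel with unit potency ratio", {
  d <- rep(c(1, 5, 25), each = 4)
  set.seed(31)
  e <- 10 + 30 * log10(d) + rnorm(length(d), 0, 5)
  pt <- test_parallelism(d, e, d, e)
  expect_equal(pt$F, 0)
  expect_equal(pt$p, 1)
  rp <- relative_potency(d, e, d, e)
  expect_equal(rp$ratio, 1, tolerance = 1e-10)
  expect_equal(rp$verdict, "additive")
})

test_that("grossly opposed slopes are flagged nonparallel", {
  d <- rep(c(1, 5, 25), each = 4)
  set.seed(32)
  ea <- 10 + 50 * log10(d) + rnorm(length(d), 0, 0.1)
  eb <- 80 - 50 * log10(d) + rnorm(length(d), 0, 0.1)
  pt <- test_parallelism(d, ea, d, eb)
  expect_lt(pt$p, 0.001)
  rp <- relative_potency(d, ea, d, eb)
  expect_equal(rp$verdict, "indeterminate-nonparallel")
  expect_true(is.na(rp$ratio))  # ratio withheld
})

test_that("noise-free unequal slopes report p = 0 with a degeneracy flag", {
  d <- c(1, 5, 25, 1, 5, 25)
  pt <- test_parallelism(d, 10 + 20 * log10(d), d, 10 + 40 * log10(d))
  expect_equal(pt$p, 0)
  expect_true(pt$degenerate_variance)
})

test_that("a noise-free 2x dose shift gives ratio 2 with a point CL", {
  d <- rep(c(1, 10^0.5, 10), each = 4)
  e <- 20 + 40 * log10(d)
  rp <- relative_potency(d, e, d * 2, e)
  expect_equal(rp$ratio, 2, tolerance = 1e-9)
  expect_equal(rp$cl_low, 2, tolerance = 1e-6)
  expect_equal(rp$cl_high, 2, tolerance = 1e-6)
  expect_equal(rp$g, 0, tolerance = 1e-12)
  expect_equal(rp$verdict, "antagonism")  # significant right shift
  expect_true(rp$verdict_significant)
})

test_that("ratio, F and p are equivariant under a common dose rescaling", {
  set.seed(33)
  arms <- sim_parallel_arms(shift = 1.6)
  rp1 <- with(arms, relative_potency(dose_a, effect_a, dose_b, effect_b))
  rp2 <- with(arms, relative_potency(dose_a * 3.7, effect_a,
                                     dose_b * 3.7, effect_b))
  expect_equal(rp2$ratio, rp1$ratio, tolerance = 1e-10)
  expect_equal(rp2$parallelism_F, rp1$parallelism_F, tolerance = 1e-10)
  expect_equal(rp2$cl_low, rp1$cl_low, tolerance = 1e-8)
})

test_that("an imprecise slope yields an unbounded Fieller interval", {
  set.seed(34)
  d <- rep(c(1, 2), each = 3)          # narrow dose span
  ea <- 30 + 5 * log10(d) + rnorm(6, 0, 25)
  eb <- 30 + 5 * log10(d) + rnorm(6, 0, 25)
  rp <- relative_potency(d, ea, d, eb, check_parallelism = FALSE)
  expect_gte(rp$g, 1)
  expect_true(is.na(rp$cl_low) && is.na(rp$cl_high))
  expect_false(rp$significant)
  expect_equal(rp$verdict, "additive")
})

test_that("Fieller limits bracket the point estimate when finite", {
  set.seed(35)
  for (i in 1:20) {
    arms <- sim_parallel_arms(sd = runif(1, 2, 12),
                              shift = 10^runif(1, -0.4, 0.4))
    rp <- with(arms, relative_potency(dose_a, effect_a, dose_b, effect_b,
                                      check_parallelism = FALSE))
    if (!is.na(rp$cl_low)) {
      expect_lte(rp$cl_low, rp$ratio)
      expect_gte(rp$cl_high, rp$ratio)
    }
  }
})

test_that("interaction classification follows the significance rule", {
  # the published phase-1 case: right shift 2.40, CL 0.50-139.12 spans 1
  paper_case <- list(ratio = 2.40, cl_low = 0.50, cl_high = 139.12,
                     significant = FALSE)
  cls <- classify_interaction(paper_case)
  expect_equal(cls$trend, "antagonism")
  expect_false(cls$verdict_significant)
  expect_equal(cls$verdict, "additive")  # shift not statistically significant

  expect_equal(classify_interaction(list(ratio = 1, cl_low = 0.9,
                                         cl_high = 1.1,
                                         significant = FALSE))$verdict,
               "additive")
  left <- classify_interaction(list(ratio = 1 / 3, cl_low = 0.2,
                                    cl_high = 0.6, significant = TRUE))
  expect_equal(left$verdict, "synergy")
  expect_true(left$verdict_significant)
  right <- classify_interaction(list(ratio = 3, cl_low = 1.8, cl_high = 5,
                                     significant = TRUE))
  expect_equal(right$verdict, "antagonism")
})

test_that("the parallel model makes combination ED50 = ratio x alone ED50", {
  expect_equal(combination_ed50(2.40, 2.35), 5.64)
  set.seed(36)
  cfg <- scenario_config(seed = 361, ms_effect = list(phase1 = 0,
                                                      phase2 = 0))
  b <- simulate_dose_response_experiment(cfg, c(1, 10, 30),
                                         fixed_ms_dose = 15)
  rep <- fixed_dose_analysis(b, phase = 2)
  if (!is.na(rep$comparison$ratio)) {
    expect_equal(rep$ed50_combo_parallel,
                 combination_ed50(rep$comparison$ratio,
                                  rep$ed50_alone_parallel),
                 tolerance = 1e-10)
    expect_lt(rep$identity_error, 1e-8)
  }
  aa <- rep$aa
  expect_true(all(c("aa_phase1_pct", "aa_phase2_pct") %in% names(aa)))
  expect_equal(nrow(rep$inhibition), 3)
})

test_that("fixed-dose analysis takes the double-reciprocal route for a
           submaximal alone arm", {
  set.seed(37)
  cfg <- scenario_config(seed = 371, ms_effect = list(phase1 = 0,
                                                      phase2 = 0))
  b <- simulate_dose_response_experiment(cfg, c(1, 5, 10),
                                         fixed_ms_dose = 5)
  rep <- fixed_dose_analysis(b, phase = 1)   # phase-1 Emax ~56% < 60%
  expect_true(rep$submaximal)
  if (!is.null(rep$fit_alone_emax)) {
    expect_equal(rep$fit_alone_emax$method_tag, "emax_rescaled")
    expect_true(rep$fit_alone_emax$ed50 > 0)
  }
  expect_error(fixed_dose_analysis(b[b$cg_dose_mgkg %in% c(0, 1, 5), ],
                                   phase = 1),
               ">= 3")
})
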