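test_that("zero dose and zero noise reproduce the control template", {
  cfg <- scenario_config(seed = 1, noise_cv = 0)
  r <- simulate_rubbing_course(cfg, 0, 0, 1)
  expect_equal(as.numeric(r[sprintf("bin%02d", 1:15)]),
               cfg$control_course)
  expect_equal(r$group, "vehicle")
})

test_that("a 100% phase-2 effect silences bins 4-15", {
  cfg <- scenario_config(seed = 1, noise_cv = 0,
                         ms_effect = list(phase1 = 0, phase2 = 100))
  r <- simulate_rubbing_course(cfg, 0, 15, 1)
  bins <- as.numeric(r[sprintf("bin%02d", 1:15)])
  expect_equal(bins[4:15], rep(0, 12))
  expect_equal(bins[1:3], cfg$control_course[1:3])
})

test_that("the generator is deterministic and stream-stable", {
  cfg <- scenario_config(seed = 99)
  b1 <- simulate_dose_response_experiment(cfg, c(1, 10, 30),
                                          fixed_ms_dose = 15)
  b2 <- simulate_dose_response_experiment(cfg, c(1, 10, 30),
                                          fixed_ms_dose = 15)
  expect_identical(b1, b2)
  # byte-identical CSV on regeneration
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write.csv(b1, f1, row.names = FALSE); write.csv(b2, f2, row.names = FALSE)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  # adding groups never perturbs existing groups' draws
  b3 <- simulate_dose_response_experiment(cfg, c(1, 10, 30),
                                          fixed_ms_dose = 15,
                                          ms_alone_doses = c(5, 15))
  shared <- b3[b3$group %in% unique(b1$group), ]
  rownames(shared) <- NULL
  expect_identical(shared, b1)
  # and the caller's RNG state is untouched
  set.seed(5); before <- rnorm(1)
  set.seed(5); invisible(simulate_rubbing_course(cfg, 1, 0, 1))
  expect_identical(rnorm(1), before)
})

test_that("different seeds give different data", {
  b1 <- simulate_dose_response_experiment(scenario_config(seed = 1),
                                          c(1, 10, 30))
  b2 <- simulate_dose_response_experiment(scenario_config(seed = 2),
                                          c(1, 10, 30))
  expect_false(identical(b1$bin01, b2$bin01))
})

test_that("the effect model is Emax-type for CG, flat for MS", {
  cfg <- scenario_config(seed = 1)
  e <- vapply(c(1, 10, 30), function(d) drug_effect(cfg, d, 0, 2),
              numeric(1))
  expect_true(all(diff(e) > 0))                       # dose-dependent
  expect_equal(drug_effect(cfg, 7, 0, 2), 95.5 / 2)   # half-max at ED50
  expect_equal(drug_effect(cfg, 0, 5, 2),
               drug_effect(cfg, 0, 15, 2))            # dose-independent
  expect_equal(drug_effect(cfg, 0, 5, 1), 0)          # phase-1 MS null
  # inhibit mode with magnitude 1 halves the effective dose
  cfg_i <- scenario_config(seed = 1, interaction_mode = "inhibit",
                           interaction_magnitude = 1)
  expect_equal(drug_effect(cfg_i, 10, 15, 2) -
                 drug_effect(cfg_i, 0, 15, 2),
               drug_effect(cfg, 5, 0, 2))
})

test_that("mast-cell fields respect their invariants and calibration", {
  cfg <- scenario_config(seed = 7)
  mc <- simulate_mastcell_experiment(cfg)
  expect_true(all(mc$degranulated_cells <= mc$total_cells))
  expect_true(all(mc$total_cells >= 0))
  expect_equal(sum(mc$group == "naive"), 3 * cfg$n_per_group)
  # naive calibration over many rats
  fields <- do.call(rbind, lapply(1:80, function(i) {
    simulate_mastcell_sample(scenario_config(seed = i), "naive")
  }))
  expect_equal(mean(fields$total_cells), 212, tolerance = 0.03)
  expect_equal(mean(fields$degranulated_cells), 3, tolerance = 0.15)
})

test_that("zero magnesium inhibition leaves formalin groups exchangeable", {
  cfg <- scenario_config(seed = 3)
  cfg$mastcell$ms_inhibition <- c("5min" = 0, "25min" = 0, "24h" = 0)
  cfg$mastcell$ms_total_potentiation <- c("5min" = 1, "25min" = 1,
                                          "24h" = 1)
  deg <- sapply(1:60, function(i) {
    f <- simulate_mastcell_sample(scenario_config(seed = i + 100,
                                                  mastcell = cfg$mastcell),
                                  "formalin", "25min", 1)
    m <- simulate_mastcell_sample(scenario_config(seed = i + 100,
                                                  mastcell = cfg$mastcell),
                                  "formalin_ms", "25min", 1)
    c(mean(f$degranulated_cells), mean(m$degranulated_cells))
  })
  expect_equal(mean(deg[1, ]), mean(deg[2, ]), tolerance = 0.08)
})

test_that("invalid configurations are rejected", {
  expect_error(scenario_config(n_per_group = 0), "n_per_group")
  expect_error(scenario_config(noise_cv = -0.1), "noise_cv")
  expect_error(scenario_config(control_course = rep(200, 15)), "bin")
  expect_error(scenario_config(
    cg_curve = list(emax_phase1 = 50, emax_phase2 = 90, ed50_phase1 = -1,
                    ed50_phase2 = 7, hill = 1)), "> 0")
  expect_error(scenario_config(
    mastcell = list(naive_total = 212, naive_degran = 3,
                    formalin_degran_multiplier = 0.5)), "multiplier")
})
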