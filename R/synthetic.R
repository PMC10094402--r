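#' Scenario configuration for the synthetic study generator
#'
#' Bundles every tunable of the generator that emulates the study's per-rat
#' data: biphasic face-rubbing time courses under an Emax-type dose-dependent
#' drug (cromoglycate) and a dose-independent low-efficacy adjuvant
#' (magnesium sulfate), and Poisson-like mast-cell fields. Defaults are
#' calibrated to the study's printed summaries: cromoglycate phase-1/phase-2
#' maxima of about 52%/77% at 30 mg/kg with half-maximal doses 2.35/7.0
#' mg/kg, a ~40% dose-independent phase-2 magnesium effect, naive fields of
#' ~212 total and ~3 degranulated mast cells/HRF, a 43.9% formalin-induced
#' total-count reduction at 24 h, and degranulation inhibition of 23%/40% at
#' the 5/25 min time points (absent at 24 h).
#'
#' @param seed Integer seed fixing the entire output stream. Each rat's
#'   draws come from a counter-based sub-stream keyed by (seed, group label,
#'   rat index), so adding a group never perturbs existing groups' draws.
#' @param n_per_group Rats per group (study default 6).
#' @param control_course 15 nonnegative bin means (seconds) of the vehicle +
#'   formalin time course: a phase-1 burst in bins 1--2, quiescence in bin
#'   3, and a phase-2 plateau over bins 4--15. The study prints no numeric
#'   template (figures only); the default is a plausible course with phase
#'   totals of 95 s (phase 1) and 250 s (phase 2).
#' @param noise_cv Coefficient of variation of the per-bin noise.
#' @param noise_model `"lognormal"` (multiplicative, mean-1, right-skewed --
#'   rubbing times are nonnegative and skewed) or `"normal"` (additive, for
#'   ANOVA calibration work).
#' @param cg_curve Cromoglycate effect curve per phase:
#'   `emax_phase1`/`emax_phase2` (percent), `ed50_phase1`/`ed50_phase2`
#'   (half-maximal dose, mg/kg), `hill` (dimensionless).
#' @param ms_effect Dose-independent magnesium effect per phase (percent);
#'   phase 1 defaults to 0 (not significant in the study).
#' @param interaction_mode `"null"`, `"potentiate"` or `"inhibit"`: how a
#'   co-administered adjuvant rescales the effective cromoglycate dose.
#' @param interaction_magnitude Fraction m: `potentiate` multiplies the
#'   effective dose by (1 + m), `inhibit` divides it by (1 + m) (m = 1
#'   halves the potency).
#' @param mastcell Mast-cell field parameters; see the defaults in the
#'   function signature. `ms_inhibition` is the fractional reduction of the
#'   expected degranulated count per HRF by magnesium pretreatment at each
#'   time point.
#' @return Object of class `scenario_config` (a validated list).
#' @export
scenario_config <- function(
    seed = 1L,
    n_per_group = 6L,
    control_course = c(45, 40, 10, 12, 18, 24, 28, 30, 30, 28, 24, 20, 16,
                       12, 8),
    noise_cv = 0.25,
    noise_model = c("lognormal", "normal"),
    cg_curve = list(emax_phase1 = 56.5, emax_phase2 = 95.5,
                    ed50_phase1 = 2.35, ed50_phase2 = 7, hill = 1),
    ms_effect = list(phase1 = 0, phase2 = 40),
    interaction_mode = c("null", "potentiate", "inhibit"),
    interaction_magnitude = 0,
    mastcell = list(
      naive_total = 212,
      naive_degran = 3,
      formalin_degran_multiplier = 8,
      formalin_total_multiplier = c("5min" = 0.85, "25min" = 0.80,
                                    "24h" = 0.561),
      vehicle_total_multiplier = c("5min" = 0.92, "25min" = 0.97,
                                   "24h" = 1),
      vehicle_degran_multiplier = c("5min" = 2, "25min" = 1.2, "24h" = 1.1),
      ms_total_potentiation = c("5min" = 0.90, "25min" = 1, "24h" = 1),
      ms_inhibition = c("5min" = 0.23, "25min" = 0.40, "24h" = 0))) {
  noise_model <- match.arg(noise_model)
  interaction_mode <- match.arg(interaction_mode)
  cfg <- list(seed = as.integer(seed), n_per_group = as.integer(n_per_group),
              control_course = control_course, noise_cv = noise_cv,
              noise_model = noise_model, cg_curve = cg_curve,
              ms_effect = ms_effect, interaction_mode = interaction_mode,
              interaction_magnitude = interaction_magnitude,
              mastcell = mastcell)
  validate_scenario_config(cfg)
  structure(cfg, class = "scenario_config")
}

validate_scenario_config <- function(cfg) {
  stopifnot(length(cfg$seed) == 1L, is.finite(cfg$seed))
  if (cfg$n_per_group < 1L) stop("n_per_group must be >= 1", call. = FALSE)
  validate_bins(cfg$control_course)
  if (!is.numeric(cfg$noise_cv) || cfg$noise_cv < 0) {
    stop("noise_cv must be a nonnegative fraction", call. = FALSE)
  }
  cc <- cfg$cg_curve
  for (f in c("emax_phase1", "emax_phase2", "ed50_phase1", "ed50_phase2",
              "hill")) {
    if (is.null(cc[[f]]) || !is.finite(cc[[f]])) {
      stop("cg_curve$", f, " missing or non-finite", call. = FALSE)
    }
  }
  if (cc$ed50_phase1 <= 0 || cc$ed50_phase2 <= 0 || cc$hill <= 0) {
    stop("cg_curve half-maximal doses and hill must be > 0", call. = FALSE)
  }
  if (any(abs(c(cc$emax_phase1, cc$emax_phase2,
                cfg$ms_effect$phase1, cfg$ms_effect$phase2)) > 100)) {
    stop("effect percents must lie in [-100, 100]", call. = FALSE)
  }
  if (cfg$interaction_magnitude < 0) {
    stop("interaction_magnitude must be >= 0", call. = FALSE)
  }
  mc <- cfg$mastcell
  if (mc$naive_total <= 0 || mc$naive_degran < 0 ||
      mc$naive_degran > mc$naive_total) {
    stop("mastcell naive counts invalid", call. = FALSE)
  }
  if (mc$formalin_degran_multiplier <= 1) {
    stop("formalin_degran_multiplier must be > 1", call. = FALSE)
  }
  invisible(cfg)
}

#' Combined drug effect of a cromoglycate/magnesium treatment
#'
#' Emax-type cromoglycate effect `Emax * d^h / (d^h + ED50^h)` at the
#' phase's parameters, plus the dose-independent magnesium effect when
#' magnesium is present, after rescaling the effective cromoglycate dose per
#' the interaction mode. Capped at 100%.
#'
#' @param config A [scenario_config()].
#' @param cg_dose,ms_dose Doses in mg/kg.
#' @param phase 1 or 2.
#' @return Effect in percent.
#' @export
drug_effect <- function(config, cg_dose, ms_dose, phase) {
  stopifnot(inherits(config, "scenario_config"), phase %in% c(1, 2))
  cc <- config$cg_curve
  emax <- if (phase == 1) cc$emax_phase1 else cc$emax_phase2
  ed50 <- if (phase == 1) cc$ed50_phase1 else cc$ed50_phase2
  d <- cg_dose
  if (d > 0 && ms_dose > 0) {
    m <- config$interaction_magnitude
    d <- switch(config$interaction_mode,
                null = d, potentiate = d * (1 + m), inhibit = d / (1 + m))
  }
  cg <- if (d > 0) emax * d^cc$hill / (d^cc$hill + ed50^cc$hill) else 0
  ms <- if (ms_dose > 0) config$ms_effect[[paste0("phase", phase)]] else 0
  min(cg + ms, 100)
}

#' Simulate one rat's face-rubbing time course
#'
#' Scales the biphasic control template per phase by `(1 - effect/100)` and
#' applies per-bin noise (multiplicative lognormal with the configured CV,
#' or additive normal), truncating to \[0, 180\] s. Deterministic for fixed
#' (seed, group label, rat index).
#'
#' @inheritParams drug_effect
#' @param rat_index Rat counter within the group (1-based).
#' @param group_label Group label; defaults to a canonical label built from
#'   the doses. Part of the sub-stream key.
#' @return One-row behavior data frame (`rat_id`, `group`, `cg_dose_mgkg`,
#'   `ms_dose_mgkg`, `bin01`..`bin15`).
#' @export
simulate_rubbing_course <- function(config, cg_dose, ms_dose, rat_index,
                                    group_label = NULL) {
  stopifnot(inherits(config, "scenario_config"),
            cg_dose >= 0, ms_dose >= 0, rat_index >= 1)
  if (is.null(group_label)) group_label <- dose_group_label(cg_dose, ms_dose)
  e1 <- drug_effect(config, cg_dose, ms_dose, 1)
  e2 <- drug_effect(config, cg_dose, ms_dose, 2)
  scale <- c(rep(max(1 - e1 / 100, 0), 3), rep(max(1 - e2 / 100, 0), 12))
  mu <- config$control_course * scale
  bins <- with_substream(config$seed, group_label, rat_index, {
    cv <- config$noise_cv
    if (cv == 0) {
      mu
    } else if (config$noise_model == "lognormal") {
      s <- sqrt(log(1 + cv^2))
      mu * stats::rlnorm(15, meanlog = -s^2 / 2, sdlog = s)
    } else {
      mu + stats::rnorm(15, 0, cv * mu)
    }
  })
  bins <- pmin(pmax(bins, 0), 180)
  out <- data.frame(rat_id = paste0(group_label, "_r", rat_index),
                    group = group_label, cg_dose_mgkg = cg_dose,
                    ms_dose_mgkg = ms_dose, stringsAsFactors = FALSE)
  out[bin_columns()] <- as.list(round(bins, 6))
  out
}

#' Simulate a full dose-response study layout
#'
#' Vehicle control group, drug-alone groups at each dose, optional
#' combination groups at one fixed adjuvant dose and optional
#' adjuvant-alone groups, `n_per_group` rats each -- a behavior table ready
#' for [phase_summaries()] and [fixed_dose_analysis()].
#'
#' @inheritParams drug_effect
#' @param doses Cromoglycate doses in mg/kg (>= 3 for an interaction run).
#' @param fixed_ms_dose Fixed magnesium dose of the combination arm, or
#'   `NULL` for no combination groups.
#' @param ms_alone_doses Magnesium-alone doses, or `NULL`.
#' @return Behavior data frame, one row per rat.
#' @export
simulate_dose_response_experiment <- function(config, doses,
                                              fixed_ms_dose = NULL,
                                              ms_alone_doses = NULL) {
  stopifnot(inherits(config, "scenario_config"), all(doses > 0))
  arms <- list(c(0, 0))
  for (d in doses) arms <- c(arms, list(c(d, 0)))
  for (m in ms_alone_doses) arms <- c(arms, list(c(0, m)))
  if (!is.null(fixed_ms_dose)) {
    stopifnot(fixed_ms_dose > 0)
    for (d in doses) arms <- c(arms, list(c(d, fixed_ms_dose)))
  }
  rows <- lapply(arms, function(a) {
    do.call(rbind, lapply(seq_len(config$n_per_group), function(i) {
      simulate_rubbing_course(config, a[1], a[2], i)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate one rat's mast-cell fields
#'
#' Three high representative fields: totals Poisson around the group/time
#' mean, degranulated counts binomial within each total at the group/time
#' degranulation rate. Magnesium pretreatment reduces the expected
#' degranulated count per HRF by the configured fraction at each time point,
#' so the measured inhibition I% matches the configured one in expectation.
#' `degranulated <= total` holds by construction.
#'
#' @inheritParams drug_effect
#' @param group One of `"naive"`, `"vehicle"`, `"formalin"`, `"ms"`,
#'   `"formalin_ms"`.
#' @param time_point `"5min"`, `"25min"` or `"24h"` (ignored for naive,
#'   recorded as `"baseline"`).
#' @param rat_index Rat counter within the group x time cell.
#' @return Three-row histology data frame (`rat_id`, `group`, `time_point`,
#'   `field_index`, `total_cells`, `degranulated_cells`).
#' @export
simulate_mastcell_sample <- function(config, group, time_point = "25min",
                                     rat_index = 1) {
  stopifnot(inherits(config, "scenario_config"))
  group <- match.arg(group,
                     c("naive", "vehicle", "formalin", "ms", "formalin_ms"))
  if (group == "naive") {
    time_point <- "baseline"
  } else {
    time_point <- match.arg(time_point, c("5min", "25min", "24h"))
  }
  mm <- mastcell_means(config, group, time_point)
  counts <- with_substream(config$seed,
                           paste0("mc_", group, "_", time_point), rat_index, {
    tot <- stats::rpois(3, mm$total_mean)
    deg <- stats::rbinom(3, tot, min(mm$degran_p, 1))
    list(tot = tot, deg = deg)
  })
  data.frame(rat_id = paste0(group, "_", time_point, "_r", rat_index),
             group = group, time_point = time_point, field_index = 1:3,
             total_cells = counts$tot, degranulated_cells = counts$deg,
             stringsAsFactors = FALSE)
}

#' Simulate the full mast-cell histology layout
#'
#' Naive rats plus every group x time-point cell, `n_per_group` rats each.
#'
#' @inheritParams drug_effect
#' @param groups Treated groups to include.
#' @param time_points Time points to include.
#' @return Histology data frame, three rows (fields) per rat.
#' @export
simulate_mastcell_experiment <- function(
    config,
    groups = c("vehicle", "formalin", "ms", "formalin_ms"),
    time_points = c("5min", "25min", "24h")) {
  stopifnot(inherits(config, "scenario_config"))
  rows <- lapply(seq_len(config$n_per_group), function(i) {
    simulate_mastcell_sample(config, "naive", rat_index = i)
  })
  for (g in groups) {
    for (tp in time_points) {
      for (i in seq_len(config$n_per_group)) {
        rows[[length(rows) + 1L]] <-
          simulate_mastcell_sample(config, g, tp, i)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## expected field means per group x time: total-count mean and the
## per-cell degranulation probability
mastcell_means <- function(config, group, time_point) {
  mc <- config$mastcell
  p0 <- mc$naive_degran / mc$naive_total
  tmul <- function(v) unname(v[[time_point]])
  if (group == "naive") {
    return(list(total_mean = mc$naive_total, degran_p = p0))
  }
  total_f <- mc$naive_total * tmul(mc$formalin_total_multiplier)
  switch(group,
    vehicle = list(
      total_mean = mc$naive_total * tmul(mc$vehicle_total_multiplier),
      degran_p = p0 * tmul(mc$vehicle_degran_multiplier)),
    ms = list(
      total_mean = mc$naive_total * tmul(mc$vehicle_total_multiplier) *
        tmul(mc$ms_total_potentiation),
      degran_p = p0 * tmul(mc$vehicle_degran_multiplier)),
    formalin = list(
      total_mean = total_f,
      degran_p = p0 * mc$formalin_degran_multiplier),
    formalin_ms = {
      total_ms <- total_f * tmul(mc$ms_total_potentiation)
      ## inhibition acts on the expected degranulated count per HRF
      p <- p0 * mc$formalin_degran_multiplier *
        (1 - tmul(mc$ms_inhibition)) * total_f / total_ms
      list(total_mean = total_ms, degran_p = p)
    })
}

## deterministic label for a dose pair
dose_group_label <- function(cg_dose, ms_dose) {
  if (cg_dose == 0 && ms_dose == 0) return("vehicle")
  parts <- character()
  if (cg_dose > 0) parts <- c(parts, paste0("CG", cg_dose))
  if (ms_dose > 0) parts <- c(parts, paste0("MS", ms_dose))
  paste(parts, collapse = "+")
}

## Counter-based sub-stream: every (seed, label, index) triple maps to its
## own RNG seed, so draws for one rat never depend on which other groups
## exist. The caller's RNG state is saved and restored.
with_substream <- function(seed, label, index, expr) {
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 1000003
  sub <- (abs(seed) %% 65011 * 33013 + h * 97 + index) %% 2147483647
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(),
                      inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(sub)
  expr
}
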