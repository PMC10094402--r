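#' Test two log dose-response lines for parallelism
#'
#' Extra-sum-of-squares F-test comparing the separate-slopes model
#' `effect ~ log10(dose) * arm` against the common-slope (parallel) model
#' `effect ~ log10(dose) + arm` on the pooled data. Parallelism is the
#' precondition of the relative potency test: only parallel lines have a
#' dose-scale horizontal displacement.
#'
#' @param dose_a,effect_a Dose-effect points of the first arm (drug alone).
#' @param dose_b,effect_b Dose-effect points of the second arm (combination).
#' @return List with `F`, `p`, `df1` (1), `df2` (pooled residual df), and
#'   `degenerate_variance` (`TRUE` when the full model has ~zero residual
#'   variance but the slopes differ, in which case `p = 0`).
#' @export
test_parallelism <- function(dose_a, effect_a, dose_b, effect_b) {
  d <- pool_arms(dose_a, effect_a, dose_b, effect_b)
  full <- stats::lm(effect ~ x * arm, data = d)
  par <- stats::lm(effect ~ x + arm, data = d)
  rss_full <- sum(stats::resid(full)^2)
  rss_par <- sum(stats::resid(par)^2)
  df2 <- stats::df.residual(full)
  if (df2 < 1L) stop("parallelism test needs pooled residual df >= 1",
                     call. = FALSE)
  delta <- max(rss_par - rss_full, 0)
  eps <- 1e-12 * max(1, sum(d$effect^2))
  degenerate <- FALSE
  if (rss_full <= eps) {
    if (delta <= eps) {           # both arms exactly on parallel lines
      F <- 0; p <- 1
    } else {                      # noise-free but slopes differ
      F <- Inf; p <- 0; degenerate <- TRUE
    }
  } else {
    F <- delta / 1 / (rss_full / df2)
    p <- stats::pf(F, 1, df2, lower.tail = FALSE)
  }
  list(F = F, p = p, df1 = 1L, df2 = df2, degenerate_variance = degenerate)
}

#' Relative potency of two parallel log dose-response lines
#'
#' Fits the common-slope (parallel) model to both arms; the log potency
#' ratio is the horizontal displacement
#' `(intercept_a - intercept_b) / common_slope`, and the ratio is its
#' antilog. Confidence limits come from Fieller's theorem on the
#' intercept-difference / slope ratio using the pooled residual variance and
#' the t quantile at the pooled df; when Fieller's `g >= 1` (the slope is
#' too imprecise) the interval is unbounded and reported as such rather than
#' numerically exploding. The ratio is the factor by which arm-b doses must
#' be multiplied to match arm a: with arm a = drug alone and arm b = the
#' combination, `ratio > 1` means the combination needs MORE drug for equal
#' effect (rightward shift, antagonism trend).
#'
#' @inheritParams test_parallelism
#' @param alpha Two-sided error rate of the confidence limits (default 0.05).
#' @param parallelism_alpha Threshold of the parallelism pretest (default
#'   0.05); below it the verdict is `indeterminate-nonparallel` and the
#'   ratio is withheld.
#' @param check_parallelism If `FALSE`, skip the pretest gate (used e.g. in
#'   coverage simulations of the Fieller interval itself).
#' @return Object of class `potency_comparison`: parallelism F/p, common
#'   slope, intercepts, `log_ratio`, `ratio`, `cl_low`/`cl_high` (ratio
#'   scale; NA when unbounded), `g` (Fieller), `significant` (CL finite and
#'   excluding 1), `trend` (direction of the point shift), `verdict`,
#'   `verdict_significant`, `df`, and the common-slope ED50 of each arm.
#' @export
relative_potency <- function(dose_a, effect_a, dose_b, effect_b,
                             alpha = 0.05, parallelism_alpha = 0.05,
                             check_parallelism = TRUE) {
  par_test <- test_parallelism(dose_a, effect_a, dose_b, effect_b)
  out <- list(parallelism_F = par_test$F, parallelism_p = par_test$p,
              parallelism_df = c(par_test$df1, par_test$df2),
              alpha = alpha, parallelism_alpha = parallelism_alpha)
  class(out) <- "potency_comparison"
  if (check_parallelism && par_test$p < parallelism_alpha) {
    out$verdict <- "indeterminate-nonparallel"
    out$trend <- NA_character_
    out$verdict_significant <- FALSE
    out$significant <- FALSE
    out$ratio <- NA_real_
    out$log_ratio <- NA_real_
    out$cl_low <- NA_real_
    out$cl_high <- NA_real_
    return(out)
  }
  d <- pool_arms(dose_a, effect_a, dose_b, effect_b)
  fit <- stats::lm(effect ~ x + arm, data = d)
  cf <- stats::coef(fit)
  b <- unname(cf["x"])
  if (!is.finite(b) || abs(b) < 1e-12 * max(1, stats::sd(d$effect))) {
    stop("relative potency undefined: common slope is numerically zero",
         call. = FALSE)
  }
  delta <- unname(cf["armb"])        # intercept_b - intercept_a
  dd <- -delta                       # intercept_a - intercept_b
  m <- dd / b                        # log10 potency ratio
  V <- suppressWarnings(stats::vcov(fit))  # zero-residual fits are legal
  v_dd <- V["armb", "armb"]
  v_db <- -V["armb", "x"]
  v_bb <- V["x", "x"]
  df <- stats::df.residual(fit)
  tq <- stats::qt(1 - alpha / 2, df)
  g <- tq^2 * v_bb / b^2
  if (!is.finite(g)) g <- 0
  if (g >= 1) {
    cl_log <- c(NA_real_, NA_real_)  # unbounded interval
  } else {
    disc <- v_dd - 2 * m * v_db + m^2 * v_bb - g * (v_dd - v_db^2 / v_bb)
    disc <- max(disc, 0)
    half <- (tq / b) * sqrt(disc)
    centre <- m - g * v_db / v_bb
    cl_log <- sort(c(centre - half, centre + half) / (1 - g))
  }
  out$common_slope <- b
  out$intercept_a <- unname(cf["(Intercept)"])
  out$intercept_b <- unname(cf["(Intercept)"]) + delta
  out$df <- df
  out$g <- g
  out$log_ratio <- m
  out$ratio <- 10^m
  out$cl_low <- 10^cl_log[1]
  out$cl_high <- 10^cl_log[2]
  out$ed50_a <- 10^((50 - out$intercept_a) / b)
  out$ed50_b <- 10^((50 - out$intercept_b) / b)
  out$significant <- all(is.finite(cl_log)) &&
    (cl_log[1] > 0 || cl_log[2] < 0)
  cls <- classify_interaction(out)
  out$trend <- cls$trend
  out$verdict <- cls$verdict
  out$verdict_significant <- cls$verdict_significant
  out
}

#' Classify a drug-drug interaction from a potency comparison
#'
#' Applies the line-shift rule: a significant leftward shift of the
#' combination curve (combination more potent, ratio < 1) is supra-additive
#' (synergy); a significant rightward shift (ratio > 1) is antagonism; when
#' the 95% confidence limits of the potency ratio overlap 1.0 the shift is
#' not significant and the interaction is classified additive; nonparallel
#' lines are indeterminate. The direction of the point shift is always
#' reported as `trend` regardless of significance (a right-shifted ratio of
#' 2.40 with CL spanning 1 has trend "antagonism" but verdict "additive").
#'
#' @param comparison A `potency_comparison` (or any list with `ratio`,
#'   `cl_low`, `cl_high`, `significant`, and optionally `verdict`
#'   `"indeterminate-nonparallel"`).
#' @return List with `verdict` (one of `synergy`, `additive`, `antagonism`,
#'   `indeterminate-nonparallel`), `trend`, and `verdict_significant`.
#' @export
classify_interaction <- function(comparison) {
  if (identical(comparison$verdict, "indeterminate-nonparallel") ||
      (!is.null(comparison$parallelism_p) &&
       !is.null(comparison$parallelism_alpha) &&
       comparison$parallelism_p < comparison$parallelism_alpha)) {
    return(list(verdict = "indeterminate-nonparallel", trend = NA_character_,
                verdict_significant = FALSE))
  }
  r <- comparison$ratio
  trend <- if (r > 1) "antagonism" else if (r < 1) "synergy" else "additive"
  sig <- isTRUE(comparison$significant)
  verdict <- if (sig) trend else "additive"
  list(verdict = verdict, trend = trend, verdict_significant = sig)
}

#' Combination ED50 implied by the parallel-line model
#'
#' Under the common-slope model the combination curve is the alone curve
#' displaced by the log potency ratio, so
#' `ED50_combination = ratio * ED50_alone` holds exactly.
#'
#' @param ratio Relative potency ratio (alone vs combination direction:
#'   > 1 means the combination needs more drug).
#' @param ed50_alone ED50 of the drug alone, mg/kg.
#' @return Combination ED50 in mg/kg.
#' @examples
#' combination_ed50(2.40, 2.35) # 5.64
#' @export
combination_ed50 <- function(ratio, ed50_alone) {
  stopifnot(is.numeric(ratio), is.numeric(ed50_alone),
            all(ratio > 0), all(ed50_alone > 0))
  ratio * ed50_alone
}

#' Fixed-dose interaction analysis of a behavioral study
#'
#' Runs the full chain on a behavior table containing a vehicle group, a
#' dose-ranged drug-alone arm and a combination arm at one fixed adjuvant
#' dose: per-rat AA% against the vehicle group, per-dose group means and %I,
#' log dose-response fits of both arms (adding the double-reciprocal
#' Emax/ED50 route when the alone arm's maximal mean effect is submaximal,
#' below `submax_threshold`), the parallelism test, the relative potency
#' test with Fieller limits, the interaction classification, and the
#' parallel-model ED50s (whose identity
#' `ED50_combination = ratio * ED50_alone` is checked each run).
#'
#' @param behavior Behavior table (see [phase_summaries()] for the schema)
#'   holding the vehicle group (`cg_dose_mgkg = ms_dose_mgkg = 0`), alone
#'   groups (`cg_dose_mgkg > 0`, `ms_dose_mgkg = 0`) and combination groups
#'   (`cg_dose_mgkg > 0`, `ms_dose_mgkg` equal to one fixed dose).
#' @param phase 1 or 2: which phase's totals to analyse.
#' @param control_group Label of the vehicle group.
#' @param submax_threshold Maximal mean alone-arm effect (percent) below
#'   which the drug is treated as submaximal-efficacy and the
#'   double-reciprocal ED50 is reported (default 60).
#' @param alpha Error rate for the potency confidence limits.
#' @param parallelism_alpha Threshold of the parallelism pretest.
#' @return Object of class `fixed_dose_report`: AA tables, per-dose %I,
#'   arm fits, the `potency_comparison`, parallel-model ED50s and the
#'   identity check, plus accumulated warnings.
#' @export
fixed_dose_analysis <- function(behavior, phase = 2,
                                control_group = "vehicle",
                                submax_threshold = 60,
                                alpha = 0.05, parallelism_alpha = 0.05) {
  stopifnot(phase %in% c(1, 2))
  phases <- phase_summaries(behavior)
  aa <- aa_table(phases, control_group = control_group)
  eff_col <- paste0("aa_phase", phase, "_pct")
  alone <- aa[aa$cg_dose_mgkg > 0 & aa$ms_dose_mgkg == 0, ]
  combo <- aa[aa$cg_dose_mgkg > 0 & aa$ms_dose_mgkg > 0, ]
  if (length(unique(alone$cg_dose_mgkg)) < 3L) {
    stop("fixed-dose analysis needs >= 3 drug-alone doses", call. = FALSE)
  }
  ms_doses <- unique(combo$ms_dose_mgkg)
  if (length(ms_doses) != 1L) {
    stop("combination arm must use one fixed adjuvant dose, found: ",
         paste(ms_doses, collapse = ", "), call. = FALSE)
  }
  notes <- character()
  ## effects are capped at 100 for the line fits (AA cannot exceed 100 by
  ## construction, but guard against degenerate synthetic inputs)
  alone_eff <- pmin(alone[[eff_col]], 100)
  combo_eff <- pmin(combo[[eff_col]], 100)

  ## per-dose group means and %I
  mean_by_dose <- function(dose, eff) {
    ag <- stats::aggregate(eff, list(dose = dose), mean)
    names(ag)[2] <- "mean_aa_pct"
    ag[order(ag$dose), ]
  }
  alone_means <- mean_by_dose(alone$cg_dose_mgkg, alone_eff)
  combo_means <- mean_by_dose(combo$cg_dose_mgkg, combo_eff)
  shared <- intersect(alone_means$dose, combo_means$dose)
  inhibition <- do.call(rbind, lapply(shared, function(d) {
    aw <- alone_means$mean_aa_pct[alone_means$dose == d]
    cw <- combo_means$mean_aa_pct[combo_means$dose == d]
    pi <- if (aw == 0) NA_real_ else percent_inhibition(cw, aw)
    data.frame(cg_dose_mgkg = d, aa_alone_pct = aw, aa_combo_pct = cw,
               inhibition_pct = pi)
  }))

  fit_alone <- fit_log_dose_line(alone$cg_dose_mgkg, alone_eff)
  fit_combo <- fit_log_dose_line(combo$cg_dose_mgkg, combo_eff)

  ## submaximal-efficacy route on the alone arm's group means
  submaximal <- max(alone_means$mean_aa_pct) < submax_threshold
  fit_alone_emax <- NULL
  if (submaximal) {
    fit_alone_emax <- withCallingHandlers(
      try(ed50_submaximal(alone_means$dose, alone_means$mean_aa_pct),
          silent = TRUE),
      warning = function(w) {
        notes <<- c(notes, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    if (inherits(fit_alone_emax, "try-error")) {
      notes <- c(notes, paste("double-reciprocal route failed:",
                              attr(fit_alone_emax, "condition")$message))
      fit_alone_emax <- NULL
    }
  }

  comp <- relative_potency(alone$cg_dose_mgkg, alone_eff,
                           combo$cg_dose_mgkg, combo_eff,
                           alpha = alpha,
                           parallelism_alpha = parallelism_alpha)
  identity_error <- NA_real_
  if (!is.na(comp$ratio)) {
    identity_error <- abs(comp$ed50_b - comp$ratio * comp$ed50_a)
    if (identity_error > 1e-8 * max(1, comp$ed50_a)) {
      notes <- c(notes, "parallel-model ED50 identity violated")
    }
  }
  if (isTRUE(fit_alone$ed50_extrapolated)) {
    notes <- c(notes, "alone-arm ED50 extrapolated beyond the dose range")
  }
  structure(list(
    phase = phase,
    fixed_ms_dose = ms_doses,
    aa = aa,
    alone_means = alone_means,
    combo_means = combo_means,
    inhibition = inhibition,
    fit_alone = fit_alone,
    fit_combo = fit_combo,
    fit_alone_emax = fit_alone_emax,
    submaximal = submaximal,
    comparison = comp,
    ed50_alone_parallel = comp$ed50_a,
    ed50_combo_parallel = comp$ed50_b,
    identity_error = identity_error,
    notes = notes
  ), class = "fixed_dose_report")
}

#' @export
print.fixed_dose_report <- function(x, ...) {
  cat("Fixed-dose interaction analysis, phase", x$phase,
      "(adjuvant", x$fixed_ms_dose, "mg/kg)\n")
  cat("Direction convention: ratio > 1 means the combination needs MORE\n")
  cat("drug for equal effect (rightward shift = antagonism trend).\n\n")
  cat("Per-dose mean AA% and inhibition:\n")
  print(x$inhibition, row.names = FALSE)
  c <- x$comparison
  cat(sprintf("\nParallelism: F = %.3f, p = %.4f\n",
              c$parallelism_F, c$parallelism_p))
  if (identical(c$verdict, "indeterminate-nonparallel")) {
    cat("Lines are not parallel; interaction is not possible to determine.\n")
  } else {
    cat(sprintf("Potency ratio %.3f (CL %.3f-%.3f), common slope %.2f\n",
                c$ratio, c$cl_low, c$cl_high, c$common_slope))
    cat(sprintf("Parallel-model ED50 alone %.3f, combination %.3f mg/kg\n",
                c$ed50_a, c$ed50_b))
    cat(sprintf("Verdict: %s (trend %s, significant: %s)\n",
                c$verdict, c$trend, c$verdict_significant))
  }
  if (length(x$notes)) cat("Notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' @export
print.potency_comparison <- function(x, ...) {
  cat(sprintf("Parallelism: F = %.3f, p = %.4f (df %d, %d)\n",
              x$parallelism_F, x$parallelism_p,
              x$parallelism_df[1], x$parallelism_df[2]))
  if (identical(x$verdict, "indeterminate-nonparallel")) {
    cat("Nonparallel lines: relative potency withheld.\n")
    return(invisible(x))
  }
  cl <- if (is.na(x$cl_low)) "unbounded (Fieller g >= 1)" else
    sprintf("%.3f-%.3f", x$cl_low, x$cl_high)
  cat(sprintf("Potency ratio %.3f (CL %s), log10 ratio %.4f\n",
              x$ratio, cl, x$log_ratio))
  cat(sprintf("Verdict: %s (trend %s, significant: %s)\n",
              x$verdict, x$trend, x$verdict_significant))
  invisible(x)
}

pool_arms <- function(dose_a, effect_a, dose_b, effect_b) {
  check_dose_effect(dose_a, effect_a)
  check_dose_effect(dose_b, effect_b)
  data.frame(
    x = c(log10(dose_a), log10(dose_b)),
    effect = c(effect_a, effect_b),
    arm = factor(rep(c("a", "b"), c(length(dose_a), length(dose_b))),
                 levels = c("a", "b")))
}
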