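#' Run the full study analysis
#'
#' Orchestrates the whole chain on a behavior and a histology table --
#' either supplied as data frames / CSV paths or simulated from the
#' scenario configuration: phase summaries and group tables, per-rat AA%,
#' phase-wise fixed-dose interaction analyses (fits, parallelism, relative
#' potency, verdict, per-dose %I), mast-cell summaries with degranulation
#' inhibition, degranulation-pain correlations, and repeated-measures
#' ANOVA/Tukey tables. Every emitted number comes from an exported package
#' operation; the orchestration layer only arranges them. When `out_dir` is
#' given, tables are written as CSV/JSON together with a run manifest
#' (input hashes, seed, package version, artifact hashes); rerunning with
#' identical inputs reproduces identical artifacts.
#'
#' @param config A [scenario_config()] (used to simulate when no data are
#'   supplied, and recorded in the manifest).
#' @param behavior Behavior data frame or CSV path; `NULL` to simulate a
#'   default interaction layout (doses 1, 10, 30 mg/kg with the combination
#'   arm at 15 mg/kg magnesium plus magnesium-alone groups).
#' @param histology Histology data frame or CSV path; `NULL` to simulate.
#' @param phases Which phases to analyse (subset of `c(1, 2)`).
#' @param alpha Error rate for confidence limits and post hoc flags.
#' @param out_dir Output directory for the report bundle, or `NULL` to only
#'   return the results.
#' @return Invisible list with `phase_summaries`, `group_summary`, `aa`,
#'   `interaction` (one `fixed_dose_report` per phase), `mastcells`,
#'   `degranulation_inhibition`, `correlations`, `anova`, `tukey`,
#'   `warnings`, and `manifest`.
#' @export
run_study <- function(config = scenario_config(), behavior = NULL,
                      histology = NULL, phases = c(1, 2), alpha = 0.05,
                      out_dir = NULL) {
  stopifnot(inherits(config, "scenario_config"), all(phases %in% c(1, 2)))
  input_files <- character()
  if (is.character(behavior)) {
    input_files <- c(input_files, behavior)
    behavior <- read_behavior_csv(behavior)
  }
  if (is.character(histology)) {
    input_files <- c(input_files, histology)
    histology <- read_histology_csv(histology)
  }
  if (is.null(behavior)) {
    behavior <- simulate_dose_response_experiment(
      config, doses = c(1, 10, 30), fixed_ms_dose = 15,
      ms_alone_doses = c(5, 15))
  }
  if (is.null(histology)) {
    histology <- simulate_mastcell_experiment(config)
  }
  rep_b <- validate_behavior(behavior)
  if (nrow(rep_b$errors)) {
    stop("behavior table failed validation (", nrow(rep_b$errors),
         " problem(s)); see validate_behavior()", call. = FALSE)
  }
  rep_h <- validate_histology(histology)
  if (nrow(rep_h$errors)) {
    stop("histology table failed validation (", nrow(rep_h$errors),
         " problem(s)); see validate_histology()", call. = FALSE)
  }

  warn <- character()
  note <- function(...) warn <<- c(warn, paste0(...))

  ph <- phase_summaries(behavior)
  grp <- group_phase_summary(ph)
  aa <- aa_table(ph)

  interaction <- list()
  for (p in phases) {
    rep <- tryCatch(
      fixed_dose_analysis(behavior, phase = p, alpha = alpha),
      error = function(e) {
        note("phase ", p, " interaction analysis skipped: ",
             conditionMessage(e))
        NULL
      })
    if (!is.null(rep)) {
      interaction[[paste0("phase", p)]] <- rep
      warn <- c(warn, rep$notes)
    }
  }

  mast <- mastcell_summaries(histology)
  inhib <- degranulation_table(mast)

  correlations <- correlation_table(mast, ph)

  long <- behavior_long(behavior, unit = "phase")
  anova <- two_way_rm_anova(long, value = "value", treatment = "group",
                            time = "phase", rat = "rat_id")
  tukey <- list(
    phase1 = tukey_hsd(ph$phase1_s, ph$group, alpha = alpha),
    phase2 = tukey_hsd(ph$phase2_s, ph$group, alpha = alpha))

  out <- list(phase_summaries = ph, group_summary = grp, aa = aa,
              interaction = interaction, mastcells = mast,
              degranulation_inhibition = inhib,
              correlations = correlations, anova = anova, tukey = tukey,
              warnings = warn)
  if (!is.null(out_dir)) {
    out$manifest <- write_report_bundle(out, config, input_files, out_dir)
  }
  invisible(out)
}

## mean degranulated counts per group x time and I% of magnesium
## pretreatment vs formalin alone at each time point
degranulation_table <- function(mast) {
  treated <- mast[mast$group != "naive", ]
  if (!nrow(treated)) return(NULL)
  ag <- stats::aggregate(
    cbind(mean_total, mean_degranulated) ~ group + time_point,
    data = treated, FUN = mean)
  names(ag)[3:4] <- c("group_mean_total", "group_mean_degranulated")
  ag$inhibition_pct <- NA_real_
  for (i in which(ag$group == "formalin_ms")) {
    ctrl <- ag$group_mean_degranulated[ag$group == "formalin" &
                                         ag$time_point == ag$time_point[i]]
    if (length(ctrl) == 1 && ctrl > 0) {
      ag$inhibition_pct[i] <-
        degranulation_inhibition(ctrl, ag$group_mean_degranulated[i])
    }
  }
  ag[order(ag$time_point, ag$group), ]
}

## degranulation-pain correlations in the magnesium arm, mirroring the
## study's pairings (5 min degranulation vs phase 1 and 2 pain; 25 min vs
## phase 2), paired by position across the separate cohorts
correlation_table <- function(mast, ph) {
  ms_groups <- unique(ph$group[grepl("MS", ph$group) &
                                 !grepl("CG", ph$group)])
  mc <- mast[mast$group == "formalin_ms", ]
  if (!nrow(mc) || !length(ms_groups)) return(NULL)
  pain <- ph[ph$group == ms_groups[length(ms_groups)], ]
  combos <- list(c("5min", 1), c("5min", 2), c("25min", 2))
  rows <- lapply(combos, function(cb) {
    sub <- mc[mc$time_point == cb[1], ]
    if (nrow(sub) < 3 || nrow(pain) < 3) return(NULL)
    paired <- suppressWarnings(
      pair_degranulation_pain(sub, pain, phase = as.integer(cb[2]),
                              mode = "position"))
    ct <- tryCatch(
      correlate_degranulation_pain(paired$mean_degranulated, paired$pain_s),
      error = function(e) NULL)
    if (is.null(ct)) return(NULL)
    data.frame(degranulation_time = cb[1], pain_phase = as.integer(cb[2]),
               r = ct$r, p = ct$p, n = ct$n, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

## CSV/JSON artifacts plus a manifest listing each with its md5 hash
write_report_bundle <- function(out, config, input_files, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- character()
  emit_csv <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    artifacts <<- c(artifacts, p)
  }
  emit_csv(out$phase_summaries, "phase_summaries.csv")
  emit_csv(out$group_summary, "group_summary.csv")
  emit_csv(out$aa, "aa_per_rat.csv")
  if (!is.null(out$degranulation_inhibition)) {
    emit_csv(out$degranulation_inhibition, "mastcell_inhibition.csv")
  }
  if (!is.null(out$correlations)) {
    emit_csv(out$correlations, "correlations.csv")
  }
  emit_csv(out$anova, "anova.csv")
  emit_csv(out$tukey$phase1, "tukey_phase1.csv")
  emit_csv(out$tukey$phase2, "tukey_phase2.csv")
  report <- lapply(out$interaction, function(rep) {
    c <- rep$comparison
    list(phase = rep$phase, fixed_ms_dose = rep$fixed_ms_dose,
         submaximal = rep$submaximal,
         direction_convention = paste(
           "ratio > 1: the combination needs MORE cromoglycate for equal",
           "effect (rightward shift = antagonism trend)"),
         fit_alone = unclass(rep$fit_alone)[c("slope", "intercept", "ed50",
                                              "method_tag")],
         fit_alone_emax = if (!is.null(rep$fit_alone_emax)) {
           unclass(rep$fit_alone_emax)[c("slope", "intercept", "ed50",
                                         "emax", "method_tag")]
         },
         parallelism = list(F = c$parallelism_F, p = c$parallelism_p),
         ratio = c$ratio, cl = c(c$cl_low, c$cl_high),
         ed50_alone_parallel = rep$ed50_alone_parallel,
         ed50_combo_parallel = rep$ed50_combo_parallel,
         verdict = c$verdict, trend = c$trend,
         verdict_significant = c$verdict_significant,
         inhibition = rep$inhibition, notes = rep$notes)
  })
  pj <- file.path(out_dir, "interaction_report.json")
  jsonlite::write_json(report, pj, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  artifacts <- c(artifacts, pj)
  wj <- file.path(out_dir, "warnings.json")
  jsonlite::write_json(out$warnings, wj, pretty = TRUE)
  artifacts <- c(artifacts, wj)

  manifest <- list(
    package_version = as.character(utils::packageVersion("nocistat")),
    seed = config$seed,
    config = unclass(config),
    inputs = as.list(tools::md5sum(input_files)),
    artifacts = as.list(tools::md5sum(artifacts)))
  mj <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mj, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  manifest
}
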