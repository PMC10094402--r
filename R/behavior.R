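#' Phase totals of a face-rubbing time course
#'
#' The orofacial formalin test records the time spent face rubbing in fifteen
#' 3-minute bins (45 min total). Phase 1 is the acute nociceptive phase
#' (0--9 min, bins 1--3); phase 2 is the inflammatory phase (9--45 min,
#' bins 4--15).
#'
#' @param bins Numeric vector of exactly 15 bin durations in seconds; each bin
#'   must lie in \[0, 180\] (a 3-minute bin cannot exceed 180 s).
#' @return Named list with `phase1_s` (sum of bins 1--3) and `phase2_s`
#'   (sum of bins 4--15), both in seconds.
#' @examples
#' phase_totals(c(10, 5, 3, rep(0, 12)))
#' @export
phase_totals <- function(bins) {
  validate_bins(bins)
  list(phase1_s = sum(bins[1:3]), phase2_s = sum(bins[4:15]))
}

## shared ingestion-time bin validation; rejects (never clips) out-of-range
## values, naming the offending bin
validate_bins <- function(bins) {
  if (!is.numeric(bins) || length(bins) != 15L) {
    stop("a rubbing record needs exactly 15 numeric bins, got ",
         length(bins), call. = FALSE)
  }
  if (anyNA(bins) || any(!is.finite(bins))) {
    stop("non-finite bin duration at bin ",
         paste(which(!is.finite(bins)), collapse = ", "), call. = FALSE)
  }
  bad <- which(bins < 0 | bins > 180)
  if (length(bad)) {
    stop("bin duration out of [0, 180] s at bin ",
         paste(bad, collapse = ", "), " (value ",
         paste(signif(bins[bad], 6), collapse = ", "), ")", call. = FALSE)
  }
  invisible(bins)
}

#' Antinociceptive activity (AA%)
#'
#' Percent reduction of rubbing time relative to the formalin-vehicle control:
#' `AA% = 100 * (control - post_drug) / control`. AA% is 100 for complete
#' suppression and negative when the treatment increases nociception
#' (pro-nociceptive responses are preserved, not truncated at zero).
#'
#' @param control_s Control (vehicle + formalin) rubbing time in seconds;
#'   must be > 0. In this package the concurrent vehicle group's phase mean.
#' @param post_drug_s Post-drug rubbing time in seconds, >= 0.
#' @return AA in percent (vectorised over `post_drug_s`).
#' @examples
#' antinociceptive_activity(150, 90) # 40
#' @export
antinociceptive_activity <- function(control_s, post_drug_s) {
  stopifnot(is.numeric(control_s), is.numeric(post_drug_s))
  if (any(!is.finite(control_s)) || any(control_s <= 0)) {
    stop("AA% undefined: control rubbing time must be > 0", call. = FALSE)
  }
  if (any(!is.finite(post_drug_s)) || any(post_drug_s < 0)) {
    stop("post-drug rubbing time must be finite and >= 0", call. = FALSE)
  }
  100 * (control_s - post_drug_s) / control_s
}

#' Percent inhibition (%I) of an antinociceptive effect
#'
#' Inhibition of one drug's antinociceptive activity by a co-administered
#' adjuvant: `%I = 100 - 100 * aa_with / aa_without`. Zero when the adjuvant
#' changes nothing, 100 when it abolishes the effect, and values above 100
#' (the combination reverses the effect into pro-nociception) are returned,
#' not clamped.
#'
#' @param aa_with_mg AA% of the drug in the presence of the adjuvant.
#' @param aa_without_mg AA% of the drug alone; must be nonzero.
#' @return Inhibition in percent.
#' @examples
#' percent_inhibition(44.2, 66.6) # ~33.6
#' @export
percent_inhibition <- function(aa_with_mg, aa_without_mg) {
  stopifnot(is.numeric(aa_with_mg), is.numeric(aa_without_mg))
  if (any(!is.finite(aa_without_mg)) || any(aa_without_mg == 0)) {
    stop("%I undefined: AA without the adjuvant is zero", call. = FALSE)
  }
  100 - 100 * aa_with_mg / aa_without_mg
}

#' Summary statistics of a group of phase totals
#'
#' @param values Numeric vector of per-rat phase totals (seconds) or AA%.
#' @return List with `n`, `mean`, `sd` (sample SD, `n - 1` denominator;
#'   0 for a singleton).
#' @export
summarize_group <- function(values) {
  if (!is.numeric(values) || length(values) < 1L || anyNA(values)) {
    stop("summarize_group needs a non-empty numeric vector without NAs",
         call. = FALSE)
  }
  s <- if (length(values) == 1L) 0 else stats::sd(values)
  list(n = length(values), mean = mean(values), sd = s)
}

#' Per-rat phase summaries of a behavioral table
#'
#' Validates every record and collapses the 15 bins into phase totals.
#'
#' @param behavior Data frame with columns `rat_id`, `group`, `cg_dose_mgkg`,
#'   `ms_dose_mgkg`, `bin01`..`bin15` (seconds), one row per rat.
#' @return Data frame with one row per rat: `rat_id`, `group`,
#'   `cg_dose_mgkg`, `ms_dose_mgkg`, `phase1_s`, `phase2_s`.
#' @export
phase_summaries <- function(behavior) {
  check_behavior_columns(behavior)
  bins <- as.matrix(behavior[, bin_columns()])
  out <- behavior[, c("rat_id", "group", "cg_dose_mgkg", "ms_dose_mgkg")]
  for (i in seq_len(nrow(bins))) {
    tryCatch(validate_bins(as.numeric(bins[i, ])),
             error = function(e) stop("rat_id ", behavior$rat_id[i], ": ",
                                      conditionMessage(e), call. = FALSE))
  }
  out$phase1_s <- rowSums(bins[, 1:3, drop = FALSE])
  out$phase2_s <- rowSums(bins[, 4:15, drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Group means and SDs per phase
#'
#' @param phases Data frame from [phase_summaries()].
#' @return Data frame with one row per group x phase: `group`, `phase`,
#'   `n`, `mean_s`, `sd_s`.
#' @export
group_phase_summary <- function(phases) {
  stopifnot(all(c("group", "phase1_s", "phase2_s") %in% names(phases)))
  rows <- list()
  for (g in unique(phases$group)) {
    sub <- phases[phases$group == g, ]
    for (ph in 1:2) {
      v <- sub[[paste0("phase", ph, "_s")]]
      s <- summarize_group(v)
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, phase = ph, n = s$n, mean_s = s$mean, sd_s = s$sd,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Per-rat antinociceptive activity against the concurrent vehicle group
#'
#' AA% is computed for each rat and each phase against the mean rubbing time
#' of the vehicle (0.9% NaCl + formalin) group in the same phase --
#' "control rubbing time" exists only as a group quantity.
#'
#' @param phases Data frame from [phase_summaries()].
#' @param control_group Label of the vehicle group (default `"vehicle"`).
#' @return `phases` with columns `aa_phase1_pct`, `aa_phase2_pct` added;
#'   control-group rows keep their own AA (scatter around 0).
#' @export
aa_table <- function(phases, control_group = "vehicle") {
  if (!control_group %in% phases$group) {
    stop("control group '", control_group, "' not present", call. = FALSE)
  }
  ctrl <- phases[phases$group == control_group, ]
  c1 <- mean(ctrl$phase1_s)
  c2 <- mean(ctrl$phase2_s)
  phases$aa_phase1_pct <- antinociceptive_activity(c1, phases$phase1_s)
  phases$aa_phase2_pct <- antinociceptive_activity(c2, phases$phase2_s)
  phases
}

check_behavior_columns <- function(behavior) {
  need <- c("rat_id", "group", "cg_dose_mgkg", "ms_dose_mgkg", bin_columns())
  miss <- setdiff(need, names(behavior))
  if (length(miss)) {
    stop("behavior table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  invisible(behavior)
}

bin_columns <- function() sprintf("bin%02d", 1:15)
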