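#' Read a behavioral CSV
#'
#' One row per rat: `rat_id, group, cg_dose_mgkg, ms_dose_mgkg,
#' bin01..bin15` (seconds). The file is validated on ingestion; errors
#' abort with an itemized report.
#'
#' @param path Path to the CSV file.
#' @return Behavior data frame.
#' @export
read_behavior_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  rep <- validate_behavior(df)
  if (nrow(rep$errors)) {
    stop("invalid behavior table '", path, "':\n",
         paste(sprintf("  row %s: %s", rep$errors$row, rep$errors$problem),
               collapse = "\n"), call. = FALSE)
  }
  df
}

#' Read a histology CSV
#'
#' Three rows (fields) per rat: `rat_id, group, time_point, field_index,
#' total_cells, degranulated_cells`.
#'
#' @param path Path to the CSV file.
#' @return Histology data frame.
#' @export
read_histology_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  rep <- validate_histology(df)
  if (nrow(rep$errors)) {
    stop("invalid histology table '", path, "':\n",
         paste(sprintf("  row %s: %s", rep$errors$row, rep$errors$problem),
               collapse = "\n"), call. = FALSE)
  }
  df
}

#' Validate a behavior table
#'
#' Schema, range and invariant checks: required columns (and no stray bin
#' columns), 15 bins per rat each within \[0, 180\] s, nonnegative finite
#' doses, unique rat ids.
#'
#' @param behavior Data frame to check.
#' @return List with data frames `errors` and `warnings`, each with columns
#'   `row` (0 for table-level problems) and `problem`.
#' @export
validate_behavior <- function(behavior) {
  errors <- list()
  warnings <- list()
  add <- function(store, row, problem) {
    store[[length(store) + 1L]] <- data.frame(row = row, problem = problem,
                                              stringsAsFactors = FALSE)
    store
  }
  need <- c("rat_id", "group", "cg_dose_mgkg", "ms_dose_mgkg", bin_columns())
  miss <- setdiff(need, names(behavior))
  if (length(miss)) {
    errors <- add(errors, 0L,
                  paste("missing column(s):", paste(miss, collapse = ", ")))
  }
  stray <- grep("^bin[0-9]+$", names(behavior), value = TRUE)
  stray <- setdiff(stray, bin_columns())
  if (length(stray)) {
    errors <- add(errors, 0L,
                  paste("unexpected bin column(s):",
                        paste(stray, collapse = ", ")))
  }
  if (!length(miss)) {
    if (anyDuplicated(behavior$rat_id)) {
      errors <- add(errors, 0L, "duplicate rat_id values")
    }
    for (i in seq_len(nrow(behavior))) {
      bins <- suppressWarnings(as.numeric(behavior[i, bin_columns()]))
      msg <- tryCatch({ validate_bins(bins); NULL },
                      error = function(e) conditionMessage(e))
      if (!is.null(msg)) errors <- add(errors, i, msg)
      for (dc in c("cg_dose_mgkg", "ms_dose_mgkg")) {
        dv <- suppressWarnings(as.numeric(behavior[[dc]][i]))
        if (!is.finite(dv) || dv < 0) {
          errors <- add(errors, i, paste(dc, "must be a nonnegative number"))
        }
      }
    }
  }
  list(errors = bind_problems(errors), warnings = bind_problems(warnings))
}

#' Validate a histology table
#'
#' Schema and invariant checks: required columns, field indices forming
#' 1--3 per rat x time point, nonnegative integer counts, degranulated <=
#' total (violations reported with their row index).
#'
#' @param histology Data frame to check.
#' @return List with data frames `errors` and `warnings` (columns `row`,
#'   `problem`).
#' @export
validate_histology <- function(histology) {
  errors <- list()
  add <- function(store, row, problem) {
    store[[length(store) + 1L]] <- data.frame(row = row, problem = problem,
                                              stringsAsFactors = FALSE)
    store
  }
  need <- c("rat_id", "group", "time_point", "field_index", "total_cells",
            "degranulated_cells")
  miss <- setdiff(need, names(histology))
  if (length(miss)) {
    errors <- add(errors, 0L,
                  paste("missing column(s):", paste(miss, collapse = ", ")))
    return(list(errors = bind_problems(errors),
                warnings = bind_problems(list())))
  }
  for (i in seq_len(nrow(histology))) {
    tot <- histology$total_cells[i]
    deg <- histology$degranulated_cells[i]
    if (!is.finite(tot) || tot < 0 || tot != round(tot)) {
      errors <- add(errors, i, "total_cells must be a nonnegative integer")
    }
    if (!is.finite(deg) || deg < 0 || deg != round(deg)) {
      errors <- add(errors, i,
                    "degranulated_cells must be a nonnegative integer")
    }
    if (is.finite(tot) && is.finite(deg) && deg > tot) {
      errors <- add(errors, i, "degranulated_cells exceeds total_cells")
    }
    fi <- histology$field_index[i]
    if (!fi %in% 1:3) {
      errors <- add(errors, i, "field_index must be 1, 2 or 3")
    }
  }
  key <- interaction(histology$rat_id, histology$time_point, drop = TRUE)
  for (k in levels(key)) {
    fi <- sort(histology$field_index[key == k])
    if (!identical(as.integer(fi), 1:3)) {
      errors <- add(errors, 0L,
                    paste0("rat/time '", k, "' does not have fields 1-3"))
    }
  }
  list(errors = bind_problems(errors), warnings = bind_problems(list()))
}

bind_problems <- function(store) {
  if (!length(store)) {
    return(data.frame(row = integer(), problem = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, store)
}

#' Long-format view of a behavior table
#'
#' One row per rat x bin, for the repeated-measures ANOVA
#' ([two_way_rm_anova()] with `time = "bin"`); or per rat x phase with
#' `unit = "phase"` for the cumulative phase comparisons (phase as the
#' within factor).
#'
#' @param behavior Behavior data frame.
#' @param unit `"bin"` (15 levels) or `"phase"` (2 levels).
#' @return Long data frame with `rat_id`, `group`, `bin` or `phase`, and
#'   `value` (seconds).
#' @export
behavior_long <- function(behavior, unit = c("bin", "phase")) {
  unit <- match.arg(unit)
  check_behavior_columns(behavior)
  if (unit == "bin") {
    long <- do.call(rbind, lapply(1:15, function(k) {
      data.frame(rat_id = behavior$rat_id, group = behavior$group, bin = k,
                 value = behavior[[bin_columns()[k]]],
                 stringsAsFactors = FALSE)
    }))
  } else {
    ph <- phase_summaries(behavior)
    long <- rbind(
      data.frame(rat_id = ph$rat_id, group = ph$group, phase = 1,
                 value = ph$phase1_s, stringsAsFactors = FALSE),
      data.frame(rat_id = ph$rat_id, group = ph$group, phase = 2,
                 value = ph$phase2_s, stringsAsFactors = FALSE))
  }
  rownames(long) <- NULL
  long
}
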