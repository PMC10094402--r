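#' Average mast-cell counts over the three high representative fields
#'
#' Counting unit of the histomorphometry: the first three high
#' representative fields (HRF; 400x, 0.95 mm^2) of one section, averaged
#' arithmetically and not rounded.
#'
#' @param total Total mast-cell counts, exactly 3 values, >= 0.
#' @param degranulated Degranulated counts, exactly 3 values, each <= the
#'   matching total.
#' @return List with `mean_total` and `mean_degranulated` (cells/HRF).
#' @export
average_fields <- function(total, degranulated) {
  if (length(total) != 3L || length(degranulated) != 3L) {
    stop("a mast-cell sample needs exactly 3 fields, got ",
         length(total), " and ", length(degranulated), call. = FALSE)
  }
  stopifnot(is.numeric(total), is.numeric(degranulated))
  if (anyNA(total) || anyNA(degranulated) || any(total < 0) ||
      any(degranulated < 0)) {
    stop("mast-cell counts must be nonnegative and non-missing",
         call. = FALSE)
  }
  if (any(degranulated > total)) {
    stop("degranulated count exceeds total in field ",
         paste(which(degranulated > total), collapse = ", "), call. = FALSE)
  }
  list(mean_total = mean(total), mean_degranulated = mean(degranulated))
}

#' Per-rat mast-cell summaries of a histology table
#'
#' @param histology Data frame with columns `rat_id`, `group`, `time_point`,
#'   `field_index` (1--3), `total_cells`, `degranulated_cells`; three rows
#'   (fields) per rat.
#' @return Data frame with one row per rat: `rat_id`, `group`, `time_point`,
#'   `mean_total`, `mean_degranulated` (cells/HRF).
#' @export
mastcell_summaries <- function(histology) {
  need <- c("rat_id", "group", "time_point", "field_index", "total_cells",
            "degranulated_cells")
  miss <- setdiff(need, names(histology))
  if (length(miss)) {
    stop("histology table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  key <- interaction(histology$rat_id, histology$time_point, drop = TRUE)
  rows <- lapply(split(histology, key), function(sub) {
    sub <- sub[order(sub$field_index), ]
    av <- average_fields(sub$total_cells, sub$degranulated_cells)
    data.frame(rat_id = sub$rat_id[1], group = sub$group[1],
               time_point = sub$time_point[1],
               mean_total = av$mean_total,
               mean_degranulated = av$mean_degranulated,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Percent inhibition (I%) of mast-cell degranulation
#'
#' `I% = 100 * (control - treated) / control` on degranulated cells per HRF;
#' negative when the treatment increases degranulation.
#'
#' @param control_degranulated Control degranulated cells/HRF, > 0.
#' @param treated_degranulated Post-treatment degranulated cells/HRF.
#' @return Inhibition in percent.
#' @export
degranulation_inhibition <- function(control_degranulated,
                                     treated_degranulated) {
  stopifnot(is.numeric(control_degranulated),
            is.numeric(treated_degranulated))
  if (any(!is.finite(control_degranulated)) ||
      any(control_degranulated <= 0)) {
    stop("I% undefined: control degranulated count must be > 0",
         call. = FALSE)
  }
  100 * (control_degranulated - treated_degranulated) / control_degranulated
}

#' Pearson correlation between mast-cell degranulation and pain
#'
#' Pearson's r with a two-sided p-value from the t transform with `n - 2`
#' df, as used to relate per-rat degranulated counts to per-rat phase pain
#' times. With the study's group size of n = 6, |r| must exceed ~0.811 for
#' p < 0.05.
#'
#' @param degranulated Per-rat degranulated mast cells/HRF.
#' @param pain_s Per-rat phase pain totals in seconds (same length, >= 3).
#' @return List with `r`, `p`, `n`.
#' @export
correlate_degranulation_pain <- function(degranulated, pain_s) {
  stopifnot(is.numeric(degranulated), is.numeric(pain_s),
            length(degranulated) == length(pain_s))
  if (length(degranulated) < 3L) {
    stop("correlation needs >= 3 paired observations", call. = FALSE)
  }
  if (stats::sd(degranulated) == 0 || stats::sd(pain_s) == 0) {
    stop("correlation undefined: zero variance in one variable",
         call. = FALSE)
  }
  ct <- stats::cor.test(degranulated, pain_s, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(degranulated))
}

#' Pair histology and behavior cohorts for correlation
#'
#' The behavioral and histological measurements come from separate cohorts;
#' rats are paired either by shared id (`"id"`, unmatched rats dropped with
#' a warning) or by within-group position after sorting by id
#' (`"position"`).
#'
#' @param mastcells Per-rat summaries from [mastcell_summaries()], already
#'   filtered to one group and time point.
#' @param phases Per-rat summaries from [phase_summaries()], already
#'   filtered to one group.
#' @param phase 1 or 2: which pain phase to pair.
#' @param mode `"id"` or `"position"`.
#' @return Data frame with `mean_degranulated` and `pain_s` columns, one row
#'   per paired rat.
#' @export
pair_degranulation_pain <- function(mastcells, phases, phase = 2,
                                    mode = c("id", "position")) {
  mode <- match.arg(mode)
  stopifnot(phase %in% c(1, 2))
  pain_col <- paste0("phase", phase, "_s")
  if (mode == "id") {
    shared <- intersect(mastcells$rat_id, phases$rat_id)
    dropped <- length(unique(c(mastcells$rat_id, phases$rat_id))) -
      length(shared)
    if (dropped > 0) {
      warning(dropped, " unmatched rat id(s) excluded from the pairing",
              call. = FALSE)
    }
    m <- mastcells[match(shared, mastcells$rat_id), ]
    p <- phases[match(shared, phases$rat_id), ]
  } else {
    n <- min(nrow(mastcells), nrow(phases))
    if (nrow(mastcells) != nrow(phases)) {
      warning("cohorts of unequal size; pairing the first ", n,
              " rats by position", call. = FALSE)
    }
    m <- mastcells[order(mastcells$rat_id), ][seq_len(n), ]
    p <- phases[order(phases$rat_id), ][seq_len(n), ]
  }
  data.frame(mean_degranulated = m$mean_degranulated,
             pain_s = p[[pain_col]])
}
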