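#' Fit a log dose-response line
#'
#' Ordinary (optionally weighted) least squares of effect on log10(dose) --
#' the linear workhorse of classical parallel-line bioassay. Residual sum of
#' squares and degrees of freedom are kept for downstream pooled-variance
#' tests.
#'
#' @param dose Doses in mg/kg, all > 0.
#' @param effect Effects (AA%), one per dose point; per-rat points or group
#'   means. Effects above 100 are rejected; negative effects are legitimate
#'   (pro-nociceptive) and are kept.
#' @param weight Optional nonnegative weights (e.g. n behind a mean point).
#' @return Object of class `dose_response_fit`: list with `slope` (AA% per
#'   log10 mg/kg), `intercept` (AA% at 1 mg/kg), `residual_ss`, `df`
#'   (n - 2), `ed50` (mg/kg at 50% absolute effect), `emax` (NA for the
#'   direct method), `method_tag` (`"direct"`), `n`, `dose_range`,
#'   `ed50_extrapolated`, `slope_inverted`, and the fitting `data`.
#' @export
fit_log_dose_line <- function(dose, effect, weight = NULL) {
  check_dose_effect(dose, effect)
  if (length(dose) < 3L) {
    stop("insufficient data: need >= 3 dose-effect points", call. = FALSE)
  }
  if (length(unique(dose)) < 2L) {
    stop("rank deficient: all doses identical, no log-dose line exists",
         call. = FALSE)
  }
  if (is.null(weight)) weight <- rep(1, length(dose))
  stopifnot(length(weight) == length(dose), all(weight >= 0))
  x <- log10(dose)
  fit <- stats::lm(effect ~ x, weights = weight)
  cf <- stats::coef(fit)
  out <- structure(list(
    slope = unname(cf["x"]),
    intercept = unname(cf["(Intercept)"]),
    residual_ss = sum(weight * stats::resid(fit)^2),
    df = stats::df.residual(fit),
    emax = NA_real_,
    method_tag = "direct",
    n = length(dose),
    dose_range = range(dose),
    data = data.frame(dose = dose, effect = effect, weight = weight)
  ), class = "dose_response_fit")
  ed <- try(ed50_from_line(out), silent = TRUE)
  out$ed50 <- if (inherits(ed, "try-error")) NA_real_ else ed
  out$ed50_extrapolated <- is.finite(out$ed50) &&
    (out$ed50 < out$dose_range[1] || out$ed50 > out$dose_range[2])
  out$slope_inverted <- out$slope < 0
  out
}

#' Read a dose off a fitted log dose-response line
#'
#' `ED50 = 10^((target_effect - intercept) / slope)`: the dose producing a
#' 50% reduction in time spent in pain-related behavior (or any other target
#' effect level).
#'
#' @param fit A `dose_response_fit`.
#' @param target_effect Target effect in percent (default 50).
#' @return Dose in mg/kg.
#' @export
ed50_from_line <- function(fit, target_effect = 50) {
  stopifnot(inherits(fit, "dose_response_fit") ||
              (is.list(fit) && all(c("slope", "intercept") %in% names(fit))))
  if (!is.finite(fit$slope) || fit$slope == 0) {
    stop("ED50 undefined: slope of the log dose-response line is zero",
         call. = FALSE)
  }
  10^((target_effect - fit$intercept) / fit$slope)
}

#' Estimate Emax by the double-reciprocal method
#'
#' For a drug with a submaximal, dose-dependent effect the asymptotic maximal
#' effect is estimated from a double-reciprocal plot: least squares of `1/E`
#' on `1/D`. Under the hyperbolic model `E = Emax * D / (D + K)` this plot is
#' exactly linear with intercept `1/Emax` and slope `K/Emax`, so both the
#' asymptote and the half-saturation dose are recovered exactly from exact
#' data.
#'
#' @inheritParams fit_log_dose_line
#' @param strict If `TRUE`, any effect <= 0 is an error; otherwise such
#'   points are dropped with a warning (their reciprocal is undefined).
#' @return List with `emax` (percent), `k` (half-saturation dose, mg/kg),
#'   `slope` and `intercept` of the reciprocal regression, and `n_used`.
#' @export
estimate_emax_double_reciprocal <- function(dose, effect, strict = FALSE) {
  check_dose_effect(dose, effect)
  nonpos <- effect <= 0
  if (any(nonpos)) {
    if (strict) {
      stop("reciprocal undefined: effects <= 0 present (strict mode)",
           call. = FALSE)
    }
    warning(sum(nonpos), " point(s) with effect <= 0 dropped from the ",
            "double-reciprocal fit", call. = FALSE)
    dose <- dose[!nonpos]
    effect <- effect[!nonpos]
  }
  if (length(dose) < 3L) {
    stop("insufficient data: need >= 3 positive-effect points for the ",
         "double-reciprocal fit", call. = FALSE)
  }
  rx <- 1 / dose
  ry <- 1 / effect
  fit <- stats::lm(ry ~ rx)
  cf <- stats::coef(fit)
  intc <- unname(cf["(Intercept)"])
  slope <- unname(cf["rx"])
  if (!is.finite(intc) || intc <= 0) {
    stop("no finite asymptote: double-reciprocal intercept <= 0",
         call. = FALSE)
  }
  list(emax = 1 / intc, k = slope / intc, slope = slope, intercept = intc,
       n_used = length(dose))
}

#' ED50 of a submaximal-efficacy drug via the double-reciprocal route
#'
#' Estimates Emax from the double-reciprocal plot, rescales each effect to
#' percent-of-Emax, fits the log-dose line on the rescaled effects (kept for
#' downstream slope comparisons), and reports the ED50 as the dose producing
#' 50% of the estimated Emax -- the half-saturation dose of the fitted
#' hyperbola, `K = slope/intercept` of the reciprocal regression. For data
#' lying exactly on `E = Emax * D / (D + K)` this recovers `K` exactly
#' (a fitted straight line through the rescaled points would not).
#'
#' @inheritParams estimate_emax_double_reciprocal
#' @return A `dose_response_fit` with `method_tag = "emax_rescaled"`, `emax`
#'   set, `ed50 = K`, and slope/intercept/residuals of the rescaled log-dose
#'   line.
#' @export
ed50_submaximal <- function(dose, effect, strict = FALSE) {
  em <- estimate_emax_double_reciprocal(dose, effect, strict = strict)
  keep <- effect > 0
  rescaled <- 100 * effect[keep] / em$emax
  line <- fit_log_dose_line(dose[keep], rescaled)
  line$emax <- em$emax
  line$ed50 <- em$k
  line$ed50_extrapolated <- em$k < min(dose[keep]) || em$k > max(dose[keep])
  line$method_tag <- "emax_rescaled"
  line
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat("Log dose-response fit (", x$method_tag, ")\n", sep = "")
  cat(sprintf("  slope     %8.3f AA%% per log10(mg/kg)\n", x$slope))
  cat(sprintf("  intercept %8.3f AA%% at 1 mg/kg\n", x$intercept))
  if (is.finite(x$emax)) cat(sprintf("  Emax      %8.3f %%\n", x$emax))
  cat(sprintf("  ED50      %8.4f mg/kg%s\n", x$ed50,
              if (isTRUE(x$ed50_extrapolated)) " (extrapolated)" else ""))
  cat(sprintf("  residual SS %.4g on %d df (n = %d)\n",
              x$residual_ss, x$df, x$n))
  invisible(x)
}

check_dose_effect <- function(dose, effect) {
  stopifnot(is.numeric(dose), is.numeric(effect),
            length(dose) == length(effect))
  if (anyNA(dose) || anyNA(effect) || any(!is.finite(dose)) ||
      any(!is.finite(effect))) {
    stop("dose-effect points must be finite", call. = FALSE)
  }
  if (any(dose <= 0)) {
    stop("doses must be > 0 (log dose undefined)", call. = FALSE)
  }
  if (any(effect > 100)) {
    stop("effects above 100% are not valid AA values", call. = FALSE)
  }
  invisible(NULL)
}
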