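#' Two-way repeated-measures ANOVA
#'
#' Mixed-design ANOVA with one between-subjects factor (treatment) and one
#' within-subjects factor (time bin or phase), rats nested in treatment as
#' the error stratum for the within factor -- the design of the behavioral
#' comparisons (balanced, n rats per group, every rat observed at every
#' level of the within factor). Unbalanced designs are rejected explicitly
#' rather than silently approximated. No sphericity correction is applied
#' by default; `gg_correction = TRUE` additionally reports
#' Greenhouse-Geisser-corrected p-values.
#'
#' @param data Long-format data frame.
#' @param value,treatment,time,rat Column names (strings) of the response,
#'   the between factor, the within factor and the subject id.
#' @param gg_correction Also compute Greenhouse-Geisser corrected df and p
#'   for the within-factor terms.
#' @return Data frame with one row per effect (`treatment`, `time`,
#'   `treatment:time`): `F`, `df_num`, `df_den`, `p` (and `p_gg` if
#'   requested). Effects with zero sum of squares report `F = 0`, `p = 1`.
#' @export
two_way_rm_anova <- function(data, value = "value", treatment = "treatment",
                             time = "time", rat = "rat",
                             gg_correction = FALSE) {
  need <- c(value, treatment, time, rat)
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  d <- data.frame(value = data[[value]],
                  treatment = factor(data[[treatment]]),
                  time = factor(data[[time]]),
                  rat = factor(data[[rat]]))
  if (anyNA(d)) stop("missing values are not supported", call. = FALSE)
  ## balance: every rat at every time level, equal rats per treatment
  tab <- table(d$rat, d$time)
  per_trt <- table(unique(d[, c("rat", "treatment")])$treatment)
  if (any(tab != 1L) || length(unique(per_trt)) != 1L) {
    stop("unsupported design: repeated-measures ANOVA here requires a ",
         "balanced layout (each rat once per time level, equal group sizes)",
         call. = FALSE)
  }
  fit <- stats::aov(value ~ treatment * time + Error(rat), data = d)
  sm <- summary(fit)
  pull <- function(stratum, term) {
    tabl <- sm[[stratum]][[1]]
    idx <- match(term, trimws(rownames(tabl)))
    resid_idx <- match("Residuals", trimws(rownames(tabl)))
    ss <- tabl[idx, "Sum Sq"]
    df_num <- tabl[idx, "Df"]
    ss_res <- tabl[resid_idx, "Sum Sq"]
    df_den <- tabl[resid_idx, "Df"]
    if (!is.finite(ss) || ss <= 1e-12 * max(1, sum(d$value^2))) {
      F <- 0; p <- 1
    } else if (ss_res <= 1e-12 * max(1, sum(d$value^2))) {
      F <- Inf; p <- 0
    } else {
      F <- (ss / df_num) / (ss_res / df_den)
      p <- stats::pf(F, df_num, df_den, lower.tail = FALSE)
    }
    data.frame(effect = term, F = F, df_num = df_num, df_den = df_den, p = p,
               stringsAsFactors = FALSE)
  }
  out <- rbind(pull("Error: rat", "treatment"),
               pull("Error: Within", "time"),
               pull("Error: Within", "treatment:time"))
  rownames(out) <- NULL
  if (gg_correction) {
    eps <- gg_epsilon(d)
    out$p_gg <- out$p
    for (i in 2:3) {
      if (out$F[i] > 0 && is.finite(out$F[i])) {
        out$p_gg[i] <- stats::pf(out$F[i], eps * out$df_num[i],
                                 eps * out$df_den[i], lower.tail = FALSE)
      }
    }
    out$gg_epsilon <- c(NA, eps, eps)
  }
  out
}

## Greenhouse-Geisser epsilon from the pooled within-treatment covariance of
## the rat x time matrix
gg_epsilon <- function(d) {
  wide <- stats::reshape(d[, c("rat", "treatment", "time", "value")],
                         idvar = c("rat", "treatment"), timevar = "time",
                         direction = "wide")
  y <- as.matrix(wide[, -(1:2), drop = FALSE])
  covs <- lapply(split(as.data.frame(y), wide$treatment),
                 function(m) stats::cov(as.matrix(m)))
  S <- Reduce(`+`, covs) / length(covs)
  k <- ncol(S)
  sbar <- mean(S)
  dbar <- mean(diag(S))
  eps <- (k^2 * (dbar - sbar)^2) /
    ((k - 1) * (sum(S^2) - 2 * k * sum(rowMeans(S)^2) + k^2 * sbar^2))
  min(max(eps, 1 / (k - 1)), 1)
}

#' Tukey HSD post hoc comparisons
#'
#' All-pairs comparisons with studentized-range adjusted p-values using the
#' pooled within-group variance, as applied after a significant ANOVA.
#'
#' @param values Numeric response vector.
#' @param groups Group labels, same length; >= 2 groups, each with n >= 2.
#' @param alpha Error rate used for the `significant` flag.
#' @return Data frame with one row per unordered pair: `group_a`, `group_b`,
#'   `mean_diff` (a minus b), `q`, `p_adj`, `significant`.
#' @export
tukey_hsd <- function(values, groups, alpha = 0.05) {
  stopifnot(is.numeric(values), length(values) == length(groups))
  g <- factor(groups)
  if (nlevels(g) < 2L) stop("need >= 2 groups", call. = FALSE)
  ns <- table(g)
  if (any(ns < 2L)) {
    stop("every group needs n >= 2 (got n = ", min(ns), ")", call. = FALSE)
  }
  k <- nlevels(g)
  N <- length(values)
  means <- tapply(values, g, mean)
  vars <- tapply(values, g, stats::var)
  s2 <- sum((ns - 1) * vars) / (N - k)
  df <- N - k
  pairs <- utils::combn(levels(g), 2)
  out <- do.call(rbind, apply(pairs, 2, function(pr) {
    a <- pr[1]; b <- pr[2]
    diff <- means[[a]] - means[[b]]
    se <- sqrt(s2 / 2 * (1 / ns[[a]] + 1 / ns[[b]]))
    if (se == 0) {
      q <- if (diff == 0) 0 else Inf
      p <- if (diff == 0) 1 else 0
    } else {
      q <- abs(diff) / se
      p <- stats::ptukey(q, nmeans = k, df = df, lower.tail = FALSE)
    }
    data.frame(group_a = a, group_b = b, mean_diff = diff, q = q, p_adj = p,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out$significant <- out$p_adj < alpha
  out
}
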