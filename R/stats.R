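#' Welch two-sample comparison with Hedges' g
#'
#' Welch's unequal-variance t-test (Welch-Satterthwaite degrees of freedom,
#' two-sided p, 95% CI for the mean difference `mean(x) - mean(y)`) together
#' with the bias-corrected standardized mean difference Hedges' g:
#' `g = J * (mean(x) - mean(y)) / s_pooled` with
#' `J = 1 - 3 / (4 * (nx + ny - 2) - 1)`.  The g confidence interval uses
#' the normal approximation with
#' `SE^2 = (nx + ny) / (nx * ny) + g^2 / (2 * (nx + ny - 2))`.
#' Missing values are dropped per sample and the retained counts reported.
#'
#' @param x,y Numeric samples (at least 2 non-missing values each, positive
#'   variance in at least one).
#' @param conf_level Confidence level, default 0.95.
#' @return A `welch_test` list: `mean_diff`, `ci95`, `t_stat`, `df`,
#'   `p_two_sided`, `hedges_g`, `g_ci95`, `n` (per-group counts).
#' @export
welch_test <- function(x, y, conf_level = 0.95) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  nx <- length(x); ny <- length(y)
  if (nx < 2L || ny < 2L)
    stop("each sample needs at least 2 non-missing values", call. = FALSE)
  if (stats::var(x) == 0 && stats::var(y) == 0 && mean(x) == mean(y)) {
    # identical constant samples: define the null result directly
    tt <- list(statistic = 0, parameter = nx + ny - 2, p.value = 1,
               conf.int = c(0, 0))
  } else {
    if (stats::var(x) == 0 && stats::var(y) == 0)
      stop("both samples have zero variance", call. = FALSE)
    tt <- stats::t.test(x, y, var.equal = FALSE, conf.level = conf_level)
  }
  df2 <- nx + ny - 2
  s_pooled <- sqrt(((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / df2)
  d <- if (s_pooled > 0) (mean(x) - mean(y)) / s_pooled else 0
  J <- 1 - 3 / (4 * df2 - 1)
  g <- J * d
  se_g <- sqrt((nx + ny) / (nx * ny) + g^2 / (2 * df2))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(mean_diff = mean(x) - mean(y),
                 ci95 = as.numeric(tt$conf.int),
                 t_stat = unname(tt$statistic),
                 df = unname(tt$parameter),
                 p_two_sided = unname(tt$p.value),
                 hedges_g = g,
                 g_ci95 = c(g - z * se_g, g + z * se_g),
                 n = c(nx, ny)),
            class = "welch_test")
}

#' 2x2 contingency test with odds ratio
#'
#' Chi-square test without continuity correction by default, switching to
#' Fisher's exact test when any expected cell count is below 5 (or when
#' requested).  The odds ratio is `(a*d)/(b*c)` with the Haldane-Anscombe
#' +0.5 correction applied to all cells when any cell is zero; its 95% CI is
#' the Woolf logit interval.
#'
#' @param tab 2x2 matrix of nonnegative integer counts (rows: group,
#'   columns: outcome).
#' @param method `"auto"` (default), `"chi_square"` or `"fisher"`.
#' @param conf_level Confidence level, default 0.95.
#' @return A `contingency_result` list: `odds_ratio`, `or_ci95`, `p`,
#'   `method`.
#' @export
contingency_test <- function(tab, method = c("auto", "chi_square", "fisher"),
                             conf_level = 0.95) {
  method <- match.arg(method)
  tab <- matrix(as.numeric(tab), 2, 2)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("`tab` must contain nonnegative integer counts", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("contingency table has an all-zero margin", call. = FALSE)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (method == "auto")
    method <- if (any(expected < 5)) "fisher" else "chi_square"
  p <- if (method == "fisher") {
    stats::fisher.test(tab)$p.value
  } else {
    stats::chisq.test(tab, correct = FALSE)$p.value
  }
  cells <- if (any(tab == 0)) tab + 0.5 else tab
  or <- (cells[1, 1] * cells[2, 2]) / (cells[1, 2] * cells[2, 1])
  se <- sqrt(sum(1 / cells))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(odds_ratio = or,
                 or_ci95 = exp(log(or) + c(-z, z) * se),
                 p = p, method = method),
            class = "contingency_result")
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate with Greenwood variance and log-transformed 95%
#' confidence bands, clipped to \[0, 1\].  With no censoring the estimate
#' equals the empirical survival function.
#'
#' @param times Nonnegative follow-up times (days).
#' @param events Event indicators (1 = death/event, 0 = censored).
#' @param conf_level Confidence level, default 0.95.
#' @return A `km_fit` list: `time`, `n_risk`, `n_event`, `surv`, `lower`,
#'   `upper`, `n`, `n_events`.
#' @export
km_fit <- function(times, events, conf_level = 0.95) {
  if (length(times) == 0L)
    stop("empty survival input", call. = FALSE)
  if (any(times < 0)) stop("negative survival time", call. = FALSE)
  if (!all(events %in% c(0, 1)))
    stop("`events` must be binary", call. = FALSE)
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "log", conf.int = conf_level)
  structure(list(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
                 surv = fit$surv,
                 lower = pmax(0, ifelse(is.na(fit$lower), 0, fit$lower)),
                 upper = pmin(1, ifelse(is.na(fit$upper), 1, fit$upper)),
                 n = length(times), n_events = sum(events)),
            class = "km_fit")
}

#' Two-group log-rank test
#'
#' Standard two-group log-rank statistic (1 df) with two-sided p-value.
#' When neither group has any event the test is undefined and `NA` is
#' returned with a warning.
#'
#' @param times_a,events_a,times_b,events_b Per-group survival data.
#' @return List `chi2`, `p`.
#' @export
logrank_test <- function(times_a, events_a, times_b, events_b) {
  if (length(times_a) == 0L || length(times_b) == 0L)
    stop("both groups must be nonempty", call. = FALSE)
  if (sum(events_a) + sum(events_b) == 0) {
    warning("no events in either group; log-rank p is NA")
    return(list(chi2 = NA_real_, p = NA_real_))
  }
  time <- c(times_a, times_b)
  event <- c(events_a, events_b)
  group <- rep(c(0L, 1L), c(length(times_a), length(times_b)))
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  chi2 <- unname(sd$chisq)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Event-rate-ratio hazard ratio
#'
#' Approximates the hazard ratio of group A versus group B as the ratio of
#' event rates: `(dA / TA) / (dB / TB)` with `d` the event count and `T`
#' the summed follow-up time (person-time, the default) or the group size
#' (`person_time = FALSE`, a simple event-proportion ratio).  The 95% CI is
#' `exp(log HR +/- z * sqrt(1/dA + 1/dB))`.  A zero event count in either
#' group gets a +0.5 continuity correction with a warning.
#'
#' @param times_a,events_a,times_b,events_b Per-group survival data.
#' @param person_time Use person-time denominators (default TRUE).
#' @param conf_level Confidence level, default 0.95.
#' @return List `hr`, `ci95`, `d` (event counts), `denom`.
#' @export
event_rate_hr <- function(times_a, events_a, times_b, events_b,
                          person_time = TRUE, conf_level = 0.95) {
  ta <- if (person_time) sum(times_a) else length(times_a)
  tb <- if (person_time) sum(times_b) else length(times_b)
  if (ta <= 0 || tb <= 0)
    stop("both groups need positive follow-up", call. = FALSE)
  da <- sum(events_a); db <- sum(events_b)
  if (da == 0 || db == 0) {
    warning("zero events in a group; +0.5 continuity correction applied")
    da <- da + 0.5; db <- db + 0.5
  }
  hr <- (da / ta) / (db / tb)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(1 / da + 1 / db)
  list(hr = hr, ci95 = exp(log(hr) + c(-z, z) * se),
       d = c(da, db), denom = c(ta, tb))
}

#' Median dichotomization
#'
#' Splits values at the cohort median: `high` when strictly above the
#' median, `low` otherwise (ties at the median go low).  Missing values
#' stay missing.  A constant vector produces an empty `high` group with a
#' warning.
#'
#' @param values Numeric vector with at least 2 non-missing values.
#' @return Factor with levels `c("low", "high")` and attribute `median`.
#' @export
dichotomize_median <- function(values) {
  ok <- !is.na(values)
  if (sum(ok) < 2L)
    stop("need at least 2 non-missing values to dichotomize", call. = FALSE)
  med <- stats::median(values[ok])
  lab <- ifelse(values > med, "high", "low")
  f <- factor(lab, levels = c("low", "high"))
  if (any(table(f) == 0))
    warning("median split produced an empty group (constant values?)")
  attr(f, "median") <- med
  f
}
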