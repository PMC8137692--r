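#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator of the survival function, with the median
#' defined as the smallest observed time `t` with `S(t) <= 0.5` (undefined,
#' `NA`, when the curve never reaches 0.5).
#'
#' @param time Follow-up times (months), `>= 0`.
#' @param event Event indicators, 0 = censored, 1 = event.
#' @return Object of class `km_estimate`: `time`, `surv`, `n_risk`,
#'   `n_event` step-function vectors, `median`, `n`, `n_events`, and the
#'   underlying [survival::survfit] object in `fit`.
#' @examples
#' km <- km_estimate(c(5, 8), c(1, 0))
#' km$surv  # 0.5 at t = 5
#' @export
km_estimate <- function(time, event) {
  check_surv_input(time, event)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  med <- if (any(fit$surv <= 0.5)) min(fit$time[fit$surv <= 0.5]) else NA_real_
  structure(list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
                 n_event = fit$n.event, median = med,
                 n = length(time), n_events = sum(event), fit = fit),
            class = "km_estimate")
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#'
#' @param km A `km_estimate`.
#' @param t Times at which to evaluate `S(t)` (right-continuous step
#'   function, `S(t) = 1` before the first event).
#' @return Numeric vector of survival probabilities.
#' @export
km_surv_at <- function(km, t) {
  vapply(t, function(tt) {
    idx <- km$time <= tt & km$n_event > 0
    if (!any(idx)) 1 else min(km$surv[km$time <= tt])
  }, numeric(1))
}

#' Median follow-up by reverse Kaplan-Meier
#'
#' Standard reverse-KM estimate: censoring is treated as the event.
#'
#' @inheritParams km_estimate
#' @return Median follow-up in the time unit of `time` (`NA` if undefined).
#' @export
median_followup <- function(time, event) {
  km_estimate(time, 1 - event)$median
}

#' Two-group log-rank test
#'
#' @param time,event Follow-up times and event indicators.
#' @param group Two-level grouping (factor, character or logical).
#' @return List with `statistic` (chi-square, 1 df), `p`, `n` per group,
#'   `events` per group, and `flag` (`"no_events"` with `p = NA` when
#'   neither group has any event).
#' @export
logrank_test <- function(time, event, group) {
  check_surv_input(time, event)
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2)
    stop("log-rank test requires exactly two non-empty groups")
  n <- table(group)
  ev <- tapply(event, group, sum)
  if (sum(event) == 0)
    return(list(statistic = NA_real_, p = NA_real_, n = n, events = ev,
                flag = "no_events"))
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  list(statistic = unname(sd$chisq),
       p = pchisq(sd$chisq, df = 1, lower.tail = FALSE),
       n = n, events = ev, flag = NULL)
}

check_surv_input <- function(time, event) {
  stopifnot(length(time) == length(event), length(time) >= 1)
  if (any(is.na(time)) || any(time < 0)) stop("times must be >= 0, non-NA")
  if (!all(event %in% c(0, 1))) stop("event indicators must be 0 or 1")
  invisible(TRUE)
}

#' Cox proportional-hazards fit (continuous or dichotomized covariates)
#'
#' Partial-likelihood Cox regression with the Breslow tie-handling
#' approximation. Covariates may be used as-is or dichotomized at supplied
#' thresholds: a dichotomized covariate is the indicator `value <
#' threshold`, i.e. 1 marks the at-risk (below-threshold) group, so a
#' hazard ratio above 1 means a low marker value is adverse. Records with
#' missing values in any requested covariate are dropped and the drop count
#' reported.
#'
#' @param data A cohort `data.frame`.
#' @param covariates Character vector of covariate column names.
#' @param time_col,event_col Column names of time and event.
#' @param dichotomize Optional named numeric vector of thresholds; names
#'   must be a subset of `covariates`.
#' @return Object of class `cox_fit`: `table` (one row per term: `coef`,
#'   `HR`, `lower95`, `upper95`, `p`), `loglik`, `n`, `n_events`,
#'   `n_dropped`, `flags` (character: may contain `"nonconvergence"`,
#'   `"possible_separation"`), `dichotomize`, and the underlying
#'   [survival::coxph] fit.
#' @export
fit_cox <- function(data, covariates, time_col = "time_months",
                    event_col = "event", dichotomize = NULL) {
  stopifnot(is.data.frame(data), length(covariates) >= 1)
  missing_cols <- setdiff(c(covariates, time_col, event_col), names(data))
  if (length(missing_cols))
    stop("columns not in data: ", paste(missing_cols, collapse = ", "))
  df <- data[, c(time_col, event_col, covariates), drop = FALSE]
  names(df)[1:2] <- c(".time", ".event")
  check_surv_input(df$.time, df$.event)
  if (!is.null(dichotomize)) {
    extra <- setdiff(names(dichotomize), covariates)
    if (length(extra))
      stop("dichotomize names not among covariates: ",
           paste(extra, collapse = ", "))
    for (nm in names(dichotomize))
      df[[nm]] <- as.integer(df[[nm]] < dichotomize[[nm]])
  }
  keep <- complete.cases(df)
  n_dropped <- sum(!keep)
  df <- df[keep, , drop = FALSE]
  if (sum(df$.event) == 0) stop("no events in the data; Cox fit undefined")
  if (any(vapply(df[covariates], function(x)
      length(unique(x[!is.na(x)])) < 2, logical(1))))
    stop("each covariate needs at least two distinct values")

  flags <- character(0)
  form <- as.formula(paste("survival::Surv(.time, .event) ~",
                           paste(sprintf("`%s`", covariates), collapse = "+")))
  fit <- withCallingHandlers(
    survival::coxph(form, data = df, ties = "breslow"),
    warning = function(w) {
      if (grepl("converge|infinite|Loglik", conditionMessage(w)))
        flags <<- union(flags, "nonconvergence")
      invokeRestart("muffleWarning")
    })
  s <- summary(fit)
  tab <- data.frame(term = rownames(s$coefficients),
                    coef = s$coefficients[, "coef"],
                    HR = s$coefficients[, "exp(coef)"],
                    lower95 = s$conf.int[, "lower .95"],
                    upper95 = s$conf.int[, "upper .95"],
                    p = s$coefficients[, "Pr(>|z|)"],
                    row.names = NULL)
  if (any(!is.finite(tab$coef)) ||
      any(abs(tab$coef) > 15, na.rm = TRUE) ||
      any(s$coefficients[, "se(coef)"] > 100, na.rm = TRUE))
    flags <- union(flags, "possible_separation")
  structure(list(table = tab, loglik = fit$loglik[2], n = nrow(df),
                 n_events = sum(df$.event), n_dropped = n_dropped,
                 flags = flags, dichotomize = dichotomize, fit = fit),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Cox fit (Breslow ties): n = %d, events = %d, dropped = %d\n",
              x$n, x$n_events, x$n_dropped))
  tab <- x$table
  tab[-1] <- lapply(tab[-1], signif, digits = digits)
  print(tab, row.names = FALSE)
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.km_estimate <- function(x, ...) {
  cat(sprintf("Kaplan-Meier estimate: n = %d, events = %d, median = %s\n",
              x$n, x$n_events,
              if (is.na(x$median)) "not reached" else format(x$median)))
  invisible(x)
}

#' Plot a Kaplan-Meier curve
#'
#' @param x A `km_estimate`.
#' @param ... Passed to [survival::plot.survfit].
#' @export
plot.km_estimate <- function(x, ...) {
  plot(x$fit, xlab = "time (months)", ylab = "survival probability", ...)
  invisible(x)
}
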