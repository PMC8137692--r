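#' Stepwise (forward-backward) Cox model selection by partial-likelihood p
#'
#' Reproduces a classical clinical model-building workflow: candidate
#' covariates are first screened by univariate Cox regression (keeping those
#' with p < `p_screen`), then a forward-backward stepwise search on the
#' partial likelihood successively includes the candidate with the smallest
#' likelihood-ratio p-value below `p_enter` and removes any included
#' covariate whose removal p-value exceeds `p_remove`, until the model is
#' stable. The procedure is deterministic: ties are broken by the smaller
#' p-value and then by name order.
#'
#' Covariates with more than `max_missing_frac` missing values are excluded
#' from candidacy up front and reported (mirroring the exclusion of
#' variables with too many missing values from multivariate modeling);
#' remaining analysis is complete-case.
#'
#' @param data Cohort `data.frame`.
#' @param candidates Character vector of candidate covariate columns.
#' @param time_col,event_col Time and event column names.
#' @param p_screen Univariate screening level (default 0.05); set to 1 to
#'   skip screening.
#' @param p_enter,p_remove Stepwise entry/removal levels (default 0.05).
#' @param max_missing_frac Maximum tolerated missingness per candidate
#'   (default 0.25).
#' @return Object of class `stepwise_fit`: `fit` (final multivariate
#'   [fit_cox()] result, or `NULL` for an empty model), `selected`,
#'   `screened` (candidates passing univariate screening, with p-values),
#'   `excluded_missing`, `trace` (`data.frame` of steps), and `flag`
#'   (`"empty_model"` when nothing survives).
#' @export
stepwise_select <- function(data, candidates, time_col = "time_months",
                            event_col = "event", p_screen = 0.05,
                            p_enter = 0.05, p_remove = 0.05,
                            max_missing_frac = 0.25) {
  stopifnot(is.data.frame(data), length(candidates) >= 1)
  miss_frac <- vapply(candidates, function(v) mean(is.na(data[[v]])),
                      numeric(1))
  excluded <- candidates[miss_frac > max_missing_frac]
  candidates <- setdiff(candidates, excluded)
  trace <- data.frame(step = character(0), term = character(0),
                      p = numeric(0))
  add_trace <- function(step, term, p)
    trace <<- rbind(trace, data.frame(step = step, term = term, p = p))

  df <- data[, c(time_col, event_col, candidates), drop = FALSE]
  df <- df[complete.cases(df), , drop = FALSE]

  loglik_of <- function(vars) {
    if (!length(vars))
      return(list(ll = null_cox_loglik(df, time_col, event_col), df = 0L))
    fit <- fit_cox(df, vars, time_col = time_col, event_col = event_col)
    list(ll = fit$loglik, df = sum(is.finite(fit$table$coef)))
  }
  lrt_p <- function(vars1, vars0) {
    f1 <- loglik_of(vars1); f0 <- loglik_of(vars0)
    dof <- f1$df - f0$df
    if (dof <= 0) return(1)  # no identifiable new parameter (collinearity)
    pchisq(2 * (f1$ll - f0$ll), df = dof, lower.tail = FALSE)
  }

  # univariate screen (continuous Cox p, per candidate)
  screened_p <- vapply(sort(candidates), function(v) lrt_p(v, character(0)),
                       numeric(1))
  screened <- names(screened_p)[screened_p < p_screen]
  for (v in names(screened_p)) add_trace("screen", v, screened_p[v])

  selected <- character(0)
  if (length(screened)) {
    repeat {
      changed <- FALSE
      # forward step: best remaining candidate
      remaining <- setdiff(screened, selected)
      if (length(remaining)) {
        pv <- vapply(sort(remaining),
                     function(v) lrt_p(c(selected, v), selected), numeric(1))
        best <- names(pv)[order(pv, names(pv))][1]
        if (pv[best] < p_enter) {
          selected <- c(selected, best)
          add_trace("enter", best, pv[best])
          changed <- TRUE
        }
      }
      # backward step: worst included covariate
      if (length(selected)) {
        pv <- vapply(sort(selected),
                     function(v) lrt_p(selected, setdiff(selected, v)),
                     numeric(1))
        worst <- names(pv)[order(-pv, names(pv))][1]
        if (pv[worst] > p_remove) {
          selected <- setdiff(selected, worst)
          add_trace("remove", worst, pv[worst])
          changed <- TRUE
        }
      }
      if (!changed) break
    }
  }

  fit <- if (length(selected))
    fit_cox(df, selected, time_col = time_col, event_col = event_col)
  else NULL
  structure(list(fit = fit, selected = selected,
                 screened = screened_p[screened_p < p_screen],
                 excluded_missing = excluded, trace = trace,
                 flag = if (!length(selected)) "empty_model" else NULL),
            class = "stepwise_fit")
}

# Log partial likelihood of the null (no-covariate) Cox model.
null_cox_loglik <- function(df, time_col, event_col) {
  fit <- survival::coxph(
    as.formula(sprintf("survival::Surv(`%s`, `%s`) ~ 1", time_col, event_col)),
    data = df, ties = "breslow")
  fit$loglik[1]
}

#' @export
print.stepwise_fit <- function(x, ...) {
  cat("stepwise Cox selection\n")
  if (length(x$excluded_missing))
    cat("  excluded (>25% missing):",
        paste(x$excluded_missing, collapse = ", "), "\n")
  cat("  passed univariate screen:",
      if (length(x$screened)) paste(names(x$screened), collapse = ", ")
      else "(none)", "\n")
  if (is.null(x$fit)) {
    cat("  final model: empty\n")
  } else {
    cat("  final model:\n")
    print(x$fit)
  }
  invisible(x)
}
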