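#' Two-group comparison with automatic test choice
#'
#' Implements the classical clinical-table testing rule: qualitative
#' variables are compared by a chi-squared test (no continuity correction;
#' the statistic is the plain `sum((O-E)^2/E)`), switching to Fisher's exact
#' test when any expected cell count is below 5; quantitative variables are
#' compared by Student's t test when both groups pass a Shapiro-Wilk
#' normality check at the 5% level, and by the Wilcoxon-Mann-Whitney test
#' otherwise.
#'
#' @param values Variable to compare: numeric for quantitative, factor /
#'   character / logical for qualitative (or force with `type`).
#' @param group Two-level grouping variable.
#' @param type `"auto"` (default), `"quantitative"` or `"qualitative"`.
#' @param alpha_normality Shapiro-Wilk level gating t vs Wilcoxon.
#' @return List with `test` (name), `statistic` (chi-square, t or W; `NA`
#'   for Fisher), `p`, and `n` per group.
#' @export
compare_groups <- function(values, group,
                           type = c("auto", "quantitative", "qualitative"),
                           alpha_normality = 0.05) {
  type <- match.arg(type)
  keep <- !is.na(values) & !is.na(group)
  values <- values[keep]; group <- droplevels(as.factor(group[keep]))
  if (nlevels(group) != 2 || any(table(group) == 0))
    stop("compare_groups requires exactly two non-empty groups")
  if (type == "auto")
    type <- if (is.numeric(values)) "quantitative" else "qualitative"

  if (type == "qualitative") {
    tab <- table(values, group)
    expected <- suppressWarnings(chisq.test(tab, correct = FALSE)$expected)
    if (any(expected < 5)) {
      ft <- fisher.test(tab)
      return(list(test = "fisher", statistic = NA_real_, p = ft$p.value,
                  n = table(group)))
    }
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    return(list(test = "chi-squared", statistic = unname(ct$statistic),
                p = ct$p.value, n = table(group)))
  }

  a <- values[group == levels(group)[1]]
  b <- values[group == levels(group)[2]]
  normal_ok <- function(x) {
    if (length(unique(x)) < 3 || length(x) < 3 || length(x) > 5000)
      return(FALSE)
    shapiro.test(x)$p.value > alpha_normality
  }
  if (normal_ok(a) && normal_ok(b)) {
    tt <- t.test(a, b, var.equal = TRUE)
    list(test = "student-t", statistic = unname(tt$statistic),
         p = tt$p.value, n = table(group))
  } else {
    wt <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = FALSE))
    list(test = "wilcoxon", statistic = unname(wt$statistic),
         p = wt$p.value, n = table(group))
  }
}

#' Nutritional indices (BMI, weight-loss percentage, Buzby NRI)
#'
#' Computes, per patient: body mass index `BMI = weight / height^2`
#' (kg/m^2); signed weight change `100 * (weight - usual_weight) /
#' usual_weight` (% — negative values are loss); the Buzby Nutritional Risk
#' Index `NRI = 1.519 * albumin + 41.7 * (weight / usual_weight)` (albumin
#' in g/L); and the standard at-risk flags `BMI < 21`,
#' `albumin < 35 g/L`, `NRI < 97.5`.
#'
#' @param weight Current weight, kg (> 0).
#' @param usual_weight Usual (pre-illness) weight, kg (> 0).
#' @param height Height, m (> 0).
#' @param albumin Serum albumin, g/L; `NA` yields `NA` NRI and flag.
#' @return `data.frame` with columns `BMI`, `weight_loss_pct`, `NRI`,
#'   `albumin`, `flag_low_bmi`, `flag_low_albumin`, `flag_low_nri`.
#' @examples
#' nutritional_indices(70, 74, 1.70, 40)
#' @export
nutritional_indices <- function(weight, usual_weight, height,
                                albumin = NA_real_) {
  n <- max(length(weight), length(usual_weight), length(height),
           length(albumin))
  weight <- rep_len(weight, n); usual_weight <- rep_len(usual_weight, n)
  height <- rep_len(height, n); albumin <- rep_len(albumin, n)
  if (any(usual_weight <= 0, na.rm = TRUE))
    stop("usual weight must be > 0")
  if (any(weight <= 0, na.rm = TRUE) || any(height <= 0, na.rm = TRUE))
    stop("weight and height must be > 0")
  bmi <- weight / height^2
  wl <- 100 * (weight - usual_weight) / usual_weight
  nri <- 1.519 * albumin + 41.7 * (weight / usual_weight)
  data.frame(BMI = bmi, weight_loss_pct = wl, NRI = nri, albumin = albumin,
             flag_low_bmi = bmi < 21,
             flag_low_albumin = albumin < 35,
             flag_low_nri = nri < 97.5)
}
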