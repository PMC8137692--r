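#' Specification of a simulated survival cohort
#'
#' Describes a synthetic oncology cohort whose survival follows a
#' proportional-hazards model with known (planted) covariate effects, so
#' that Kaplan-Meier, log-rank, Cox and ROC machinery can be validated
#' against ground truth. Event times are exponential:
#' `T ~ Exp(rate = lambda0 * exp(sum(beta * x)))`, censored by an
#' administrative cut-off and/or an independent exponential censoring time.
#'
#' Demographic columns (sex, height, weight, usual weight, albumin, WHO
#' performance score) are always generated; additional continuous or binary
#' markers (e.g. anthropometric indices) are declared in `markers`, and any
#' numeric generated column may carry a log-hazard-ratio in `betas`.
#'
#' @param n Number of patients (>= 2).
#' @param markers Named list of marker generators; each element is a list
#'   with `dist` in `c("normal", "binary", "lognormal", "uniform")` and the
#'   matching parameters (`mean`/`sd`, `p`, `meanlog`/`sdlog`, `min`/`max`).
#' @param betas Named numeric log-hazard-ratios; names must be marker names
#'   or one of the built-in numeric columns (`who_score`, `weight_kg`, ...).
#' @param lambda0 Baseline hazard rate, events per month (> 0).
#' @param admin_censor_time Administrative censoring time in months
#'   (`Inf` = none).
#' @param censor_rate Rate of an independent exponential censoring process
#'   (0 = none).
#' @param sex_ratio_male Probability a patient is male.
#' @param height_mean_sd Named list `male`/`female` of `c(mean, sd)` for
#'   height in metres.
#' @param weight_mean_sd `c(mean, sd)` of current weight, kg.
#' @param weight_loss_mean_sd `c(mean, sd)` of weight change in percent
#'   (negative = loss); usual weight is derived from it.
#' @param albumin_mean_sd `c(mean, sd)` of serum albumin, g/L.
#' @param albumin_missing_prob Probability an albumin value is missing.
#' @param who0_prob Probability of WHO performance score 0 (vs >= 1).
#' @param progression_rate_mult Hazard multiplier for progression relative
#'   to death (progression-free-survival times).
#' @param seed Integer RNG seed.
#' @return An object of class `cohort_spec`.
#' @seealso [simulate_cohort()]
#' @export
cohort_spec <- function(n,
                        markers = list(),
                        betas = numeric(0),
                        lambda0 = log(2) / 24,
                        admin_censor_time = Inf,
                        censor_rate = 0,
                        sex_ratio_male = 0.785,
                        height_mean_sd = list(male = c(1.75, 0.07),
                                              female = c(1.62, 0.06)),
                        weight_mean_sd = c(70, 12),
                        weight_loss_mean_sd = c(-2, 4),
                        albumin_mean_sd = c(37, 5),
                        albumin_missing_prob = 0,
                        who0_prob = 0.5,
                        progression_rate_mult = 1.5,
                        seed = 1L) {
  spec <- list(n = as.integer(n), markers = markers, betas = betas,
               lambda0 = lambda0, admin_censor_time = admin_censor_time,
               censor_rate = censor_rate, sex_ratio_male = sex_ratio_male,
               height_mean_sd = height_mean_sd,
               weight_mean_sd = weight_mean_sd,
               weight_loss_mean_sd = weight_loss_mean_sd,
               albumin_mean_sd = albumin_mean_sd,
               albumin_missing_prob = albumin_missing_prob,
               who0_prob = who0_prob,
               progression_rate_mult = progression_rate_mult,
               seed = as.integer(seed))
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  if (spec$n < 2) stop("cohort size n must be >= 2")
  if (spec$lambda0 <= 0) stop("baseline hazard lambda0 must be > 0")
  if (spec$admin_censor_time < 0) stop("administrative censoring time < 0")
  if (spec$censor_rate < 0) stop("censoring rate must be >= 0")
  probs <- c(spec$sex_ratio_male, spec$albumin_missing_prob, spec$who0_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  for (nm in names(spec$markers)) {
    m <- spec$markers[[nm]]
    if (!m$dist %in% c("normal", "binary", "lognormal", "uniform"))
      stop("unknown marker distribution for '", nm, "': ", m$dist)
    if (m$dist == "binary" && (m$p < 0 || m$p > 1))
      stop("binary marker prevalence must be in [0, 1]")
  }
  invisible(spec)
}

draw_marker <- function(m, n) {
  switch(m$dist,
    normal = rnorm(n, m$mean, m$sd),
    binary = rbinom(n, 1, m$p),
    lognormal = stats::rlnorm(n, m$meanlog, m$sdlog),
    uniform = runif(n, m$min, m$max))
}

#' Simulate a survival cohort with planted covariate effects
#'
#' @param spec A [cohort_spec()].
#' @return A `data.frame` (one row per patient) with columns `id`, `sex`,
#'   `height_m`, `weight_kg`, `usual_weight_kg`, `albumin_gL`, `who_score`,
#'   one column per marker, `time_months`, `event`,
#'   `progression_time_months`, `progression_event`.
#' @examples
#' sp <- cohort_spec(n = 200, markers = list(trt = list(dist = "binary",
#'   p = 0.5)), betas = c(trt = log(2)), admin_censor_time = 36, seed = 7)
#' head(simulate_cohort(sp))
#' @export
simulate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  set.seed(spec$seed)
  n <- spec$n
  sex <- ifelse(runif(n) < spec$sex_ratio_male, "male", "female")
  height <- numeric(n)
  for (s in c("male", "female")) {
    idx <- sex == s
    pars <- spec$height_mean_sd[[s]]
    height[idx] <- rnorm(sum(idx), pars[1], pars[2])
  }
  weight <- pmax(rnorm(n, spec$weight_mean_sd[1], spec$weight_mean_sd[2]), 30)
  wl_pct <- rnorm(n, spec$weight_loss_mean_sd[1], spec$weight_loss_mean_sd[2])
  usual_weight <- weight / (1 + wl_pct / 100)
  albumin <- rnorm(n, spec$albumin_mean_sd[1], spec$albumin_mean_sd[2])
  if (spec$albumin_missing_prob > 0)
    albumin[runif(n) < spec$albumin_missing_prob] <- NA_real_
  who <- ifelse(runif(n) < spec$who0_prob, 0L, 1L)

  df <- data.frame(id = seq_len(n), sex = sex, height_m = height,
                   weight_kg = weight, usual_weight_kg = usual_weight,
                   albumin_gL = albumin, who_score = who,
                   stringsAsFactors = FALSE)
  for (nm in names(spec$markers))
    df[[nm]] <- draw_marker(spec$markers[[nm]], n)

  lp <- rep(0, n)
  for (nm in names(spec$betas)) {
    if (!nm %in% names(df) || !is.numeric(df[[nm]]))
      stop("beta refers to unknown or non-numeric column: ", nm)
    lp <- lp + spec$betas[[nm]] * df[[nm]]
  }

  draw_times <- function(rate_mult) {
    t_event <- rexp(n, rate = spec$lambda0 * rate_mult * exp(lp))
    t_cens <- rep(spec$admin_censor_time, n)
    if (spec$censor_rate > 0)
      t_cens <- pmin(t_cens, rexp(n, spec$censor_rate))
    list(time = pmin(t_event, t_cens),
         event = as.integer(t_event <= t_cens))
  }
  os <- draw_times(1)
  pfs <- draw_times(spec$progression_rate_mult)
  df$time_months <- os$time
  df$event <- os$event
  df$progression_time_months <- pmin(pfs$time, os$time)
  df$progression_event <- as.integer(pfs$event | (os$event == 1L &
                                                  os$time <= pfs$time))
  df
}
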