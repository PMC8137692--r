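# Independent brute-force / hand-computation oracles. These deliberately
# share no code with the package: plain loops and textbook formulas.

# Exhaustive ROC cut search: loops over every midpoint cut, low marker
# predicts the adverse outcome, first (lowest) maximizer of Youden J wins.
oracle_best_cut <- function(marker, outcome) {
  v <- sort(unique(marker))
  best <- list(j = -Inf, cut = NA, sens = NA, spec = NA)
  if (length(v) < 2) return(best)
  for (i in seq_len(length(v) - 1)) {
    cut <- (v[i] + v[i + 1]) / 2
    tp <- fp <- fn <- tn <- 0
    for (k in seq_along(marker)) {
      pos <- marker[k] < cut
      if (pos && outcome[k] == 1) tp <- tp + 1
      if (pos && outcome[k] == 0) fp <- fp + 1
      if (!pos && outcome[k] == 1) fn <- fn + 1
      if (!pos && outcome[k] == 0) tn <- tn + 1
    }
    sens <- tp / (tp + fn); spec <- tn / (tn + fp)
    if (sens + spec - 1 > best$j + 1e-12)
      best <- list(j = sens + spec - 1, cut = cut, sens = sens, spec = spec)
  }
  best
}

# Textbook two-group log-rank chi-square from the observed-expected table.
oracle_logrank <- function(time, event, g1) {
  ts <- sort(unique(time[event == 1]))
  O1 <- E1 <- V <- 0
  for (t in ts) {
    n <- sum(time >= t); n1 <- sum(time >= t & g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O1 - E1)^2 / V
}

# Two-sided Fisher exact p by exhaustive hypergeometric enumeration.
enum_fisher <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  p_obs <- dhyper(tab[1, 1], m, n, k)
  acc <- 0
  for (a in max(0, k - n):min(k, m)) {
    p <- dhyper(a, m, n, k)
    if (p <= p_obs * (1 + 1e-7)) acc <- acc + p
  }
  acc
}
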