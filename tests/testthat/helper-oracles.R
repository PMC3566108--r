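# Independent oracles used across the suite. These are deliberately
# slow, literal transcriptions of the defining formulas and never call
# the code paths they are meant to check.

# Cox partial log-likelihood for a single covariate, written from the
# definition. `ties` selects the Efron or Breslow correction.
cox_partial_loglik <- function(beta, x, time, event, ties = "efron") {
  ll <- 0
  for (t_ev in sort(unique(time[event == 1]))) {
    at_risk <- which(time >= t_ev)
    dead <- which(time == t_ev & event == 1)
    d <- length(dead)
    risk_sum <- sum(exp(beta * x[at_risk]))
    dead_sum <- sum(exp(beta * x[dead]))
    ll <- ll + beta * sum(x[dead])
    if (ties == "breslow") {
      ll <- ll - d * log(risk_sum)
    } else {
      for (l in seq_len(d) - 1)
        ll <- ll - log(risk_sum - (l / d) * dead_sum)
    }
  }
  ll
}

# Maximizer of the hand-written partial likelihood over beta in [-5, 5].
cox_oracle_beta <- function(x, time, event, ties = "efron") {
  stats::optimize(function(b) cox_partial_loglik(b, x, time, event, ties),
                  interval = c(-5, 5), maximum = TRUE,
                  tol = 1e-9)$maximum
}

# Brute-force UPGMA: clusters as index sets, inter-cluster distance
# recomputed each step as the mean over all cross pairs of the original
# matrix; ties broken by the lexicographically smallest pair.
upgma_oracle_heights <- function(d) {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA)
    best_d <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      dij <- mean(d[clusters[[i]], clusters[[j]]])
      if (dij < best_d - 1e-12) {
        best_d <- dij
        best <- c(i, j)
      }
    }
    heights <- c(heights, best_d)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# Spearman distance the long way: mid-ranks then the Pearson formula.
spearman_oracle <- function(a, b) {
  ra <- rank(a)
  rb <- rank(b)
  1 - sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
}

# Kaplan-Meier product-limit by direct multiplication over event times.
km_oracle <- function(time, event) {
  tt <- sort(unique(time[event == 1]))
  s <- 1
  surv <- numeric(length(tt))
  for (k in seq_along(tt)) {
    n_risk <- sum(time >= tt[k])
    d <- sum(time == tt[k] & event == 1)
    s <- s * (1 - d / n_risk)
    surv[k] <- s
  }
  list(time = tt, surv = surv)
}

# Step-up BH by the definition, for cross-checking bh_adjust.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- pmin(1, n * p[o] / seq_len(n))
  q <- rev(cummin(rev(q)))
  out <- numeric(n)
  out[o] <- q
  out
}
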