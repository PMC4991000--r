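# Independent reference implementations used as oracles. These stay
# deliberately naive (sorting, explicit loops, textbook formulas) and
# never call the package functions they check.

# BH step-up by explicit sort: adjusted_i = min over j with p_j >= p_i
# of p_(j) * n / rank_j, capped at 1.
oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj_sorted <- p[ord] * n / seq_len(n)
  for (i in seq(n - 1, 1, length.out = max(0, n - 1)))
    adj_sorted[i] <- min(adj_sorted[i], adj_sorted[i + 1])
  out <- numeric(n)
  out[ord] <- pmin(1, adj_sorted)
  out
}

# Upper-tail hypergeometric by direct summation of binomial terms.
oracle_hyper_tail <- function(k, K, n, N) {
  kk <- seq(k, min(K, n))
  if (k > min(K, n)) return(0)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# Two-sided Fisher z p-value, coded directly from the transform.
oracle_fisher_p <- function(r, n) {
  z <- 0.5 * log((1 + r) / (1 - r)) * sqrt(n - 3)
  2 * (1 - pnorm(abs(z)))
}

# Pearson correlation from raw definitional sums.
oracle_pcc <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

# Type-7 (linear interpolation) quantile, written out by hand.
oracle_quantile7 <- function(x, p) {
  xs <- sort(x)
  h <- (length(xs) - 1) * p
  lo <- floor(h)
  xs[lo + 1] + (h - lo) * (xs[min(lo + 2, length(xs))] - xs[lo + 1])
}

# Triple-loop co-expression network reference: returns a sorted
# "a|b" edge-key vector for a study, mirroring the published rule
# (|r| cutoff AND Bonferroni Fisher p AND both-endpoint percentile).
oracle_network_edges <- function(study, pcc_cutoff, alpha, q) {
  x <- study$values
  g <- rownames(x)
  ng <- length(g)
  ns <- ncol(x)
  r <- matrix(1, ng, ng)
  for (i in seq_len(ng)) for (j in seq_len(ng))
    if (i != j) r[i, j] <- oracle_pcc(x[i, ], x[j, ])
  npairs <- ng * (ng - 1) / 2
  pass_pct <- matrix(FALSE, ng, ng)
  for (i in seq_len(ng)) {
    vals <- r[i, -i]
    lo <- oracle_quantile7(vals, q)
    hi <- oracle_quantile7(vals, 1 - q)
    for (j in seq_len(ng)) if (j != i)
      pass_pct[i, j] <- r[i, j] >= hi || r[i, j] <= lo
  }
  keys <- character(0)
  for (i in seq_len(ng - 1)) for (j in seq((i + 1), ng)) {
    p <- min(1, oracle_fisher_p(r[i, j], ns) * npairs)
    if (abs(r[i, j]) >= pcc_cutoff && p <= alpha &&
        pass_pct[i, j] && pass_pct[j, i])
      keys <- c(keys, paste(g[i], g[j], sep = "|"))
  }
  sort(keys)
}

# Hand product-limit curve: data frame time/surv over distinct times.
oracle_km <- function(time, event) {
  ts <- sort(unique(time))
  s <- 1
  out <- data.frame(time = ts, surv = NA_real_)
  for (i in seq_along(ts)) {
    at_risk <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event == 1)
    s <- s * (1 - d / at_risk)
    out$surv[i] <- s
  }
  out
}

# Term-by-term log-rank accumulation (O - E with hypergeometric
# variance; groups coded 1/2).
oracle_logrank_chi2 <- function(time, event, group) {
  ts <- sort(unique(time[event == 1]))
  oe <- 0; v <- 0
  for (t in ts) {
    n1 <- sum(time >= t & group == 1)
    n2 <- sum(time >= t & group == 2)
    d1 <- sum(time == t & event == 1 & group == 1)
    d2 <- sum(time == t & event == 1 & group == 2)
    n <- n1 + n2; d <- d1 + d2
    oe <- oe + d1 - d * n1 / n
    if (n > 1)
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  oe^2 / v
}

# Welch two-sample t p-value from the textbook formulas.
oracle_welch_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  v1 <- sum((a - mean(a))^2) / (n1 - 1)
  v2 <- sum((b - mean(b))^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  2 * pt(-abs((mean(a) - mean(b)) / sqrt(se2)), df)
}
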