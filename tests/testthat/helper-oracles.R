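# Independent oracles, deliberately naive implementations.

# Step-up BH by the textbook recipe.
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# P(overlap >= k) by exhaustive enumeration of all draws of size n from a
# universe of size N containing K marked items.
brute_hyper <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  marked <- seq_len(K)
  mean(apply(draws, 2, function(d) sum(d %in% marked) >= k))
}

# Efron-corrected Cox partial log-likelihood for one covariate.
efron_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    D <- which(time == t & event == 1)
    R <- which(time >= t)
    sR <- sum(exp(x[R] * beta))
    sD <- sum(exp(x[D] * beta))
    d <- length(D)
    ll <- ll + sum(x[D]) * beta -
      sum(log(sR - (seq_len(d) - 1) / d * sD))
  }
  ll
}

# Log-rank chi-square from the 2x2 tables at each event time.
brute_logrank <- function(time, event, group) {
  g1 <- group == levels(factor(group))[1]
  O1 <- 0; E1 <- 0; V <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O1 - E1)^2 / V
}

# Hand product-limit estimate at the distinct observed times.
brute_km <- function(time, event) {
  out_t <- sort(unique(time))
  s <- 1
  surv <- numeric(length(out_t))
  for (i in seq_along(out_t)) {
    t <- out_t[i]
    n <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / n)
    surv[i] <- s
  }
  data.frame(time = out_t, surv = surv)
}

# Dense running-sum ES via the public scorer, for a metric vector.
es_of <- function(metric, set, p = 1) {
  gsea_score(rank_genes(metric), metric, set, weight_exponent = p)
}

# Tiny cohort configuration used across tests.
tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(n_genes = 300, n_mirnas = 40, n_pairs = 12,
                   n_normal = 6, n_sets = 8, set_size_range = c(8L, 15L),
                   seed = 42)
  do.call(synthetic_config, utils::modifyList(defaults, args))
}
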