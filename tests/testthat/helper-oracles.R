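# Independent brute-force oracles used to cross-check the analytic
# implementations. Each one recomputes the target quantity by direct
# enumeration or by the published algorithm written out longhand, sharing no
# code with the package internals.

# Two-sided Fisher p by explicit enumeration of all margin-consistent 2x2
# tables, multivariate-hypergeometric pmf from factorials.
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d; n <- r1 + r2
  tab_prob <- function(x) {
    # table (x, r1-x, c1-x, r2-c1+x)
    factorial(r1) * factorial(r2) * factorial(c1) * factorial(c2) /
      (factorial(n) * factorial(x) * factorial(r1 - x) *
         factorial(c1 - x) * factorial(r2 - c1 + x))
  }
  xs <- seq(max(0, c1 - r2), min(r1, c1))
  probs <- vapply(xs, tab_prob, numeric(1))
  p_obs <- tab_prob(a)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exact two-sided Mann-Whitney p by enumerating every assignment of the
# pooled values to group x; U computed by pair counting, not rank sums.
oracle_mw <- function(x, y) {
  pooled <- c(x, y)
  nx <- length(x); n <- length(pooled)
  count_u <- function(xs, ys) {
    sum(outer(xs, ys, function(a, b) (a > b) + 0.5 * (a == b)))
  }
  u_obs <- count_u(x, y)
  mu <- nx * (n - nx) / 2
  combs <- utils::combn(n, nx)
  us <- apply(combs, 2, function(idx) count_u(pooled[idx], pooled[-idx]))
  list(u = u_obs, p = mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9))
}

# TMM factors computed longhand from the published weighted-trimmed-mean
# algorithm: upper-quartile reference choice, double trim, inverse binomial
# variance weights, geometric-mean rescaling.
oracle_tmm <- function(m, trim_m = 0.30, trim_a = 0.05) {
  lib <- colSums(m)
  uq <- apply(m, 2, quantile, p = 0.75) / lib
  ref <- which.min(abs(uq - mean(uq)))
  one_factor <- function(i) {
    obs <- m[, i]; refc <- m[, ref]
    nO <- lib[i]; nR <- lib[ref]
    logR <- log2((obs / nO) / (refc / nR))
    absE <- (log2(obs / nO) + log2(refc / nR)) / 2
    v <- (nO - obs) / nO / obs + (nR - refc) / nR / refc
    fin <- is.finite(logR) & is.finite(absE)
    logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
    if (max(abs(logR)) < 1e-6) return(1)
    n <- length(logR)
    loL <- floor(n * trim_m) + 1; hiL <- n + 1 - loL
    loS <- floor(n * trim_a) + 1; hiS <- n + 1 - loS
    keep <- rank(logR) >= loL & rank(logR) <= hiL &
      rank(absE) >= loS & rank(absE) <= hiS
    f <- sum(logR[keep] / v[keep]) / sum(1 / v[keep])
    if (!is.finite(f)) f <- 0
    2^f
  }
  f <- vapply(seq_len(ncol(m)), one_factor, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(m)
  f
}

# Log-rank chi-square recomputed from an explicit risk-set table built with
# data-frame arithmetic (independent of the package's loop).
oracle_logrank_chi2 <- function(time, event, group) {
  g1 <- sort(unique(group))[1]
  tab <- do.call(rbind, lapply(sort(unique(time[event == 1])), function(u) {
    data.frame(nj = sum(time >= u),
               n1j = sum(time >= u & group == g1),
               dj = sum(time == u & event == 1),
               d1j = sum(time == u & event == 1 & group == g1))
  }))
  o <- sum(tab$d1j)
  e <- sum(tab$dj * tab$n1j / tab$nj)
  keep <- tab$nj > 1
  v <- sum((tab$dj * (tab$n1j / tab$nj) * (1 - tab$n1j / tab$nj) *
              (tab$nj - tab$dj) / (tab$nj - 1))[keep])
  (o - e)^2 / v
}

# AUC of scores for the positive class vs the rest, by rank (equivalent to
# the Mann-Whitney statistic scaled to [0, 1]).
rank_auc <- function(score_pos, score_neg) {
  r <- rank(c(score_pos, score_neg))
  n1 <- length(score_pos)
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * length(score_neg))
}

# Exponential survival times with uniform censoring, for log-rank checks.
sim_surv_groups <- function(n_per_group, hazard_ratio, censor_time = Inf) {
  t1 <- rexp(n_per_group, 1)
  t2 <- rexp(n_per_group, hazard_ratio)
  time <- c(t1, t2)
  event <- as.integer(time <= censor_time)
  time <- pmin(time, censor_time)
  list(time = time, event = event,
       group = rep(c("g1", "g2"), each = n_per_group))
}

# Build a sign-weighted kd_signature directly from a gene/direction tibble.
new_test_signature <- function(genes) {
  kdsig:::new_kd_signature(
    tibble::tibble(gene = genes$gene, weight = as.numeric(sign(genes$direction)),
                   direction = as.integer(sign(genes$direction)),
                   rank = seq_len(nrow(genes))),
    derivation = list(weight_mode = "sign", source = "test fixture"))
}

# Matrix -> expression tibble without touching package internals.
matrix_to_expr_test <- function(m) tibble::as_tibble(m, rownames = "gene")
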