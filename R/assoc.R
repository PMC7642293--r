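# Association statistics implemented from first principles: exact 2x2
# contingency, rank and trend tests, proportion comparison, and the
# product-limit estimator with the log-rank test. Each exact path is checked
# against brute-force enumeration in the test suite.

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' The two-sided p-value is the sum of hypergeometric probabilities, over all
#' tables with the observed margins, that do not exceed the probability of
#' the observed table (with `1e-7` relative slack for floating-point ties —
#' the dominant two-sided convention). The hypergeometric pmf is evaluated in
#' log space via `lgamma`. The reported estimate is the sample odds ratio
#' `ad/bc`, `Inf` when `bc = 0`.
#'
#' @param tab 2x2 integer matrix (rows = phenotype, columns = score class),
#'   or a numeric vector `c(a, b, c, d)` read row-wise.
#' @return One-row tibble: `estimate` (odds ratio), `p.value`, `method`.
#' @export
fisher_exact_2x2 <- function(tab) {
  if (is.matrix(tab)) {
    stopifnot(all(dim(tab) == 2))
    v <- as.vector(t(tab))
  } else {
    stopifnot(length(tab) == 4)
    v <- as.numeric(tab)
  }
  if (any(v < 0) || any(v != floor(v))) abort("counts must be non-negative integers")
  a <- v[1]; b <- v[2]; c_ <- v[3]; d <- v[4]
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_; c2 <- b + d
  if (min(r1, r2, c1, c2) == 0) abort("zero margin: exact test undefined")
  n <- r1 + r2

  lpmf <- function(x) {
    lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(n, c1)
  }
  support <- seq(max(0, c1 - r2), min(r1, c1))
  lp <- lpmf(support)
  lp_obs <- lpmf(a)
  p <- sum(exp(lp)[lp <= lp_obs + log1p(1e-7)])
  or <- if (b * c_ == 0) {
    if (a * d == 0) NaN else Inf
  } else (a * d) / (b * c_)
  tibble(estimate = or, p.value = min(p, 1),
         method = "Fisher exact (two-sided)")
}

#' Mann-Whitney U test
#'
#' U is computed from rank sums with midranks for ties. When the combined
#' sample size is at most `exact_max` and there are no ties, the two-sided
#' p-value is exact, by enumeration of all group labelings (counting
#' labelings whose U is at least as far from the null mean `n_x n_y / 2` as
#' observed). Otherwise a normal approximation with tie-corrected variance
#' and continuity correction is used.
#'
#' @param x,y Numeric vectors (both non-empty).
#' @param exact_max Largest combined size for the exact enumeration path.
#' @return One-row tibble: `statistic` (U for `x`), `p.value`, `method`.
#' @export
mann_whitney_u <- function(x, y, exact_max = 12) {
  if (length(x) == 0 || length(y) == 0) abort("both samples must be non-empty")
  nx <- length(x); ny <- length(y); n <- nx + ny
  pooled <- c(x, y)
  r <- rank(pooled)
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  has_ties <- anyDuplicated(pooled) > 0

  if (n <= exact_max && !has_ties) {
    mu <- nx * ny / 2
    combs <- utils::combn(n, nx)
    us <- colSums(matrix(r[combs], nrow = nx)) - nx * (nx + 1) / 2
    p <- mean(abs(us - mu) >= abs(u - mu) - 1e-9)
    return(tibble(statistic = u, p.value = p,
                  method = "Mann-Whitney U (exact)"))
  }
  ties <- table(pooled)
  mu <- nx * ny / 2
  v <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (v == 0) {
    return(tibble(statistic = u, p.value = 1,
                  method = "Mann-Whitney U (normal approx)"))
  }
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(v)
  tibble(statistic = u, p.value = min(1, 2 * pnorm(-abs(z))),
         method = "Mann-Whitney U (normal approx)")
}

#' Mann-Kendall trend test
#'
#' `S` is the number of concordant minus discordant ordered pairs of the
#' series. For short series (`n <= exact_max`) the two-sided p-value is
#' exact, from the full permutation null of the observed values (counting
#' permutations with `|S| >= |S_obs|`); the normal approximation at such n
#' can be off by more than 0.01, which matters for trend tests on a handful
#' of deciles. For longer series, the null variance is
#' `[n(n-1)(2n+5) - sum_t t(t-1)(2t+5)] / 18` with the sum over tie groups,
#' the z statistic carries a +/-1 continuity correction, and the p-value is
#' two-sided normal.
#'
#' @param series Numeric vector in its natural order (>= 3 values).
#' @param exact_max Largest n for the exact permutation-null path.
#' @return One-row tibble: `statistic` (S), `z`, `p.value`, `method`.
#' @export
mann_kendall <- function(series, exact_max = 8) {
  n <- length(series)
  if (n < 3) abort("need >= 3 values for a trend test")
  pairs <- utils::combn(n, 2)
  kendall_s <- function(x) sum(sign(x[pairs[2, ]] - x[pairs[1, ]]))
  s <- kendall_s(series)
  ties <- table(series)
  v <- (n * (n - 1) * (2 * n + 5) - sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  z <- if (v <= 0 || s == 0) 0 else (s - sign(s)) / sqrt(v)

  if (n <= exact_max) {
    perms <- all_permutations(n)
    vals <- matrix(series[perms], nrow = nrow(perms))
    sp <- numeric(nrow(perms))
    for (j in seq_len(ncol(pairs))) {
      sp <- sp + sign(vals[, pairs[2, j]] - vals[, pairs[1, j]])
    }
    p <- mean(abs(sp) >= abs(s))
    return(tibble(statistic = s, z = z, p.value = p,
                  method = "Mann-Kendall trend (exact)"))
  }
  tibble(statistic = s, z = z, p.value = min(1, 2 * pnorm(-abs(z))),
         method = "Mann-Kendall trend (normal approx)")
}

# all n! permutations of 1:n as a matrix, one per row (n <= 8 or so)
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow = nrow(sub)))
  }))
}

#' Two-tailed two-proportion z-test
#'
#' Pooled-variance score test of `k1/n1` versus `k2/n2`; with
#' `continuity = TRUE` a Yates-style correction of `(1/n1 + 1/n2)/2` is
#' subtracted from the absolute difference. Without correction, `z^2` equals
#' the Pearson chi-square statistic of the corresponding 2x2 table.
#'
#' @param k1,n1,k2,n2 Successes and trials per group (`n > 0`).
#' @param continuity Apply the continuity correction?
#' @return One-row tibble: `statistic` (z), `p.value`, `method`.
#' @export
two_proportion_test <- function(k1, n1, k2, n2, continuity = FALSE) {
  if (n1 <= 0 || n2 <= 0) abort("group sizes must be positive")
  if (k1 < 0 || k1 > n1 || k2 < 0 || k2 > n2) abort("counts must satisfy 0 <= k <= n")
  p1 <- k1 / n1; p2 <- k2 / n2
  pp <- (k1 + k2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  num <- abs(p1 - p2)
  if (continuity) num <- max(0, num - (1 / n1 + 1 / n2) / 2)
  z <- if (se == 0) 0 else sign(p1 - p2) * num / se
  tibble(statistic = z, p.value = min(1, 2 * pnorm(-abs(z))),
         method = paste0("two-proportion z",
                         if (continuity) " (continuity-corrected)" else ""))
}

#' Compare loss-of-heterozygosity fractions of a gene across disease states
#'
#' For one gene, the LOH fraction per state pools hemizygous deletion and
#' copy-number-neutral LOH calls. All state pairs are compared with the
#' two-tailed two-proportion test at level `alpha`. When no sample carries an
#' LOH call the tests are skipped with a message.
#'
#' @param loh Tibble: `gene` column plus one character call column per sample
#'   (values none / hemizygous_deletion / CNNL).
#' @param annotation Tibble with `sample` and `state`.
#' @param gene Gene id to compare.
#' @param alpha Significance level for the `significant` flag.
#' @param continuity Passed to [two_proportion_test()].
#' @return List: `fractions` (tibble `state`, `n`, `n_loh`, `fraction`) and
#'   `tests` (tibble `state1`, `state2`, `statistic`, `p.value`,
#'   `significant`; empty when skipped).
#' @export
loh_state_compare <- function(loh, annotation, gene, alpha = 0.05,
                              continuity = FALSE) {
  if (!gene %in% loh$gene) abort(paste0("gene not present: ", gene))
  calls <- unlist(loh[loh$gene == gene, setdiff(names(loh), "gene")])
  calls <- calls[annotation$sample]
  states <- annotation$state
  if (length(unique(states)) < 2) abort("need >= 2 states")

  frac <- tibble(state = states, loh = calls %in% c("hemizygous_deletion", "CNNL")) |>
    dplyr::group_by(.data$state) |>
    dplyr::summarise(n = dplyr::n(), n_loh = sum(.data$loh),
                     fraction = mean(.data$loh), .groups = "drop")

  if (sum(frac$n_loh) == 0) {
    inform("no LOH call for this gene in any state; tests skipped")
    return(list(fractions = frac,
                tests = tibble(state1 = character(), state2 = character(),
                               statistic = numeric(), p.value = numeric(),
                               significant = logical())))
  }
  pairs <- utils::combn(frac$state, 2)
  tests <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    f1 <- frac[frac$state == pairs[1, j], ]
    f2 <- frac[frac$state == pairs[2, j], ]
    tp <- two_proportion_test(f1$n_loh, f1$n, f2$n_loh, f2$n,
                              continuity = continuity)
    tibble(state1 = pairs[1, j], state2 = pairs[2, j],
           statistic = tp$statistic, p.value = tp$p.value,
           significant = tp$p.value < alpha)
  })
  list(fractions = frac, tests = tests)
}

#' Kaplan-Meier curves and the two-group log-rank test
#'
#' Product-limit survival estimates per group, and a 1-df log-rank chi-square
#' from the observed-versus-expected event counts over the pooled risk sets
#' at each distinct event time (hypergeometric variance term, skipping risk
#' sets of size one).
#'
#' @param time Non-negative follow-up times.
#' @param event Event indicator (1 = event, 0 = censored).
#' @param group Two-level group labels.
#' @return List: `curves` (tibble `group`, `time`, `n_risk`, `n_event`,
#'   `survival`) and `test` (one-row tibble `statistic` (chi-square), `df`,
#'   `p.value`, `method`).
#' @export
km_logrank <- function(time, event, group) {
  if (any(time < 0)) abort("times must be >= 0")
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2) abort("need exactly 2 groups")
  if (any(table(group) == 0)) abort("a group has zero subjects")
  g1 <- levels(group)[1]

  curves <- purrr::map_dfr(levels(group), function(g) {
    tt <- time[group == g]; ee <- event[group == g]
    times <- sort(unique(tt[ee == 1]))
    surv <- 1
    rows <- purrr::map_dfr(times, function(u) {
      n_risk <- sum(tt >= u)
      n_event <- sum(tt == u & ee == 1)
      surv <<- surv * (1 - n_event / n_risk)
      tibble(group = g, time = u, n_risk = n_risk, n_event = n_event,
             survival = surv)
    })
    rows
  })

  etimes <- sort(unique(time[event == 1]))
  o1 <- 0; e1 <- 0; v <- 0
  for (u in etimes) {
    at_risk <- time >= u
    nj <- sum(at_risk)
    n1j <- sum(at_risk & group == g1)
    dj <- sum(time == u & event == 1)
    d1j <- sum(time == u & event == 1 & group == g1)
    o1 <- o1 + d1j
    e1 <- e1 + dj * n1j / nj
    if (nj > 1) {
      v <- v + dj * (n1j / nj) * (1 - n1j / nj) * (nj - dj) / (nj - 1)
    }
  }
  chi2 <- if (v > 0) (o1 - e1)^2 / v else 0
  list(curves = curves,
       test = tibble(statistic = chi2, df = 1,
                     p.value = stats::pchisq(chi2, 1, lower.tail = FALSE),
                     method = "log-rank"))
}

#' Run the cohort association battery on signature scores
#'
#' Given classified scores and a sample annotation, runs the association
#' tests the score is designed to feed: (1) Fisher's exact test on the 2x2
#' table of extreme score class (low/high, mid dropped) versus CRPC phenotype
#' (CRPC-NE vs CRPC-Adeno); (2) Mann-Whitney U on rescaled scores between the
#' lowest and highest observed Gleason grade groups; (3) Mann-Kendall trend
#' of the percentage of high-risk samples (`risk_score > high_risk_cutoff`)
#' across score deciles; (4) if `time`/`event` columns are present, a
#' log-rank test of low versus high score class. Tests whose inputs are
#' absent are skipped.
#'
#' @param scores Tibble from [score_cohort()].
#' @param annotation Tibble with `sample`, `state`, optionally
#'   `gleason_group`, `risk_score`, `time`, `event`.
#' @param high_risk_cutoff Risk-score threshold defining "high risk".
#' @return Tibble: `test`, `statistic`, `p.value`, `n`; the extreme-quartile
#'   2x2 table is attached as attribute `contingency`.
#' @export
associate_scores <- function(scores, annotation, high_risk_cutoff = 0.7) {
  d <- dplyr::inner_join(scores, annotation, by = "sample")
  out <- list()
  tab <- NULL

  cr <- d[d$state %in% c("CRPC-NE", "CRPC-Adeno") & d$class != "mid", ]
  if (length(unique(cr$state)) == 2 && length(unique(as.character(cr$class))) == 2) {
    tab <- table(factor(cr$state, c("CRPC-NE", "CRPC-Adeno")),
                 factor(as.character(cr$class), c("low", "high")))
    fe <- fisher_exact_2x2(unclass(tab))
    out$fisher <- tibble(test = "extreme_quartile_fisher",
                         statistic = fe$estimate, p.value = fe$p.value,
                         n = nrow(cr))
  }

  if ("gleason_group" %in% names(d)) {
    gl <- range(d$gleason_group, na.rm = TRUE)
    if (gl[1] < gl[2]) {
      mw <- mann_whitney_u(d$rescaled_score[d$gleason_group == gl[1]],
                           d$rescaled_score[d$gleason_group == gl[2]])
      out$mw <- tibble(test = "gleason_extremes_mann_whitney",
                       statistic = mw$statistic, p.value = mw$p.value,
                       n = sum(d$gleason_group %in% gl))
    }
  }

  if ("risk_score" %in% names(d) && nrow(d) >= 30) {
    dec <- dplyr::ntile(d$rescaled_score, 10)
    pct <- tibble(decile = dec, high = d$risk_score > high_risk_cutoff) |>
      dplyr::group_by(.data$decile) |>
      dplyr::summarise(pct_high = 100 * mean(.data$high), .groups = "drop") |>
      dplyr::arrange(.data$decile)
    mk <- mann_kendall(pct$pct_high)
    out$mk <- tibble(test = "risk_by_decile_mann_kendall",
                     statistic = mk$statistic, p.value = mk$p.value,
                     n = nrow(d))
  }

  if (all(c("time", "event") %in% names(d))) {
    ext <- d[d$class != "mid", ]
    lr <- km_logrank(ext$time, ext$event, as.character(ext$class))
    out$lr <- tibble(test = "low_vs_high_logrank",
                     statistic = lr$test$statistic, p.value = lr$test$p.value,
                     n = nrow(ext))
  }

  res <- dplyr::bind_rows(out)
  attr(res, "contingency") <- tab
  res
}
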