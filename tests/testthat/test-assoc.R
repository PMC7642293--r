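# Association statistics against enumeration oracles, closed forms, and the
# standard library implementations as independent cross-checks.

test_that("Fisher exact reproduces hand and reference values", {
  flat <- fisher_exact_2x2(matrix(c(3, 3, 3, 3), 2))
  expect_equal(flat$p.value, 1)
  su2c <- fisher_exact_2x2(matrix(c(16, 0, 57, 65), 2, byrow = TRUE))
  expect_equal(su2c$p.value,
               stats::fisher.test(matrix(c(16, 0, 57, 65), 2, byrow = TRUE))$p.value,
               tolerance = 1e-12)
  expect_equal(su2c$estimate, Inf)
  expect_error(fisher_exact_2x2(c(0, 0, 3, 4)), "margin")
})

test_that("Fisher exact agrees with table enumeration on random small tables", {
  set.seed(101)
  for (i in 1:40) {
    v <- rmultinom(1, sample(6:24, 1), prob = runif(4, 0.1, 1))[, 1]
    if (min(v[1] + v[2], v[3] + v[4], v[1] + v[3], v[2] + v[4]) == 0) next
    got <- fisher_exact_2x2(v)$p.value
    expect_equal(got, oracle_fisher_p(v[1], v[2], v[3], v[4]),
                 tolerance = 1e-12)
  }
})

test_that("Fisher exact is symmetric under simultaneous row and column swaps", {
  set.seed(102)
  for (i in 1:10) {
    v <- sample(1:12, 4, replace = TRUE)
    p1 <- fisher_exact_2x2(c(v[1], v[2], v[3], v[4]))$p.value
    p2 <- fisher_exact_2x2(c(v[4], v[3], v[2], v[1]))$p.value
    expect_equal(p1, p2, tolerance = 1e-12)
  }
})

test_that("Mann-Whitney exact path matches complete enumeration", {
  sep <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sep$statistic, 0)
  expect_equal(sep$p.value, 0.1)  # 2 of the 20 labelings are as extreme

  set.seed(103)
  for (i in 1:25) {
    nx <- sample(2:6, 1); ny <- sample(2:6, 1)
    x <- rnorm(nx); y <- rnorm(ny, 0.5)
    got <- mann_whitney_u(x, y)
    orc <- oracle_mw(x, y)
    expect_equal(got$statistic, orc$u)
    expect_equal(got$p.value, orc$p, tolerance = 1e-12)
  }
})

test_that("Mann-Whitney approximation handles ties and matches wilcox.test", {
  x <- c(1, 2, 2, 3, 5, 5, 6, 8, 9, 9)
  y <- c(2, 3, 3, 4, 5, 7, 7, 8, 10, 11)
  got <- mann_whitney_u(x, y)
  ref <- suppressWarnings(stats::wilcox.test(x, y, correct = TRUE, exact = FALSE))
  expect_equal(got$statistic, unname(ref$statistic))
  expect_equal(got$p.value, ref$p.value, tolerance = 1e-10)

  same <- mann_whitney_u(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$statistic, 16 / 2)
  expect_gte(same$p.value, 0.99)
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("Mann-Kendall handles constant, monotone and reversed series", {
  const <- mann_kendall(rep(4, 6))
  expect_equal(const$statistic, 0)
  expect_equal(const$p.value, 1)

  up <- mann_kendall(1:10)
  expect_equal(up$statistic, 45)  # n(n-1)/2, maximal concordance
  expect_lt(up$p.value, 0.001)

  set.seed(104)
  s <- rnorm(8)
  expect_equal(mann_kendall(rev(s))$statistic, -mann_kendall(s)$statistic)
  expect_error(mann_kendall(c(1, 2)), ">= 3")
})

test_that("Mann-Kendall exact p equals the permutation null", {
  set.seed(105)
  for (i in 1:5) {
    s <- rnorm(7)
    got <- mann_kendall(s)
    # Monte-Carlo permutation oracle
    sobs <- got$statistic
    perm_s <- vapply(1:20000, function(j) {
      x <- sample(s)
      sum(vapply(1:6, function(a) sum(sign(x[(a + 1):7] - x[a])), numeric(1)))
    }, numeric(1))
    phat <- mean(abs(perm_s) >= abs(sobs))
    expect_lt(abs(got$p.value - phat),
              2.576 * sqrt(phat * (1 - phat) / 20000) + 1e-9)
  }
})

test_that("two-proportion test matches its closed form and the chi-square identity", {
  eq <- two_proportion_test(30, 60, 15, 30)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p.value, 1)

  hand <- two_proportion_test(50, 100, 25, 100)
  expect_equal(hand$statistic, 0.25 / sqrt(0.375 * 0.625 * 0.02),
               tolerance = 1e-10)
  expect_equal(hand$p.value, 2.607e-4, tolerance = 2e-3)

  set.seed(106)
  for (i in 1:20) {
    n1 <- sample(10:80, 1); n2 <- sample(10:80, 1)
    k1 <- sample(1:(n1 - 1), 1); k2 <- sample(1:(n2 - 1), 1)
    z <- two_proportion_test(k1, n1, k2, n2)$statistic
    chi <- suppressWarnings(
      stats::prop.test(c(k1, k2), c(n1, n2), correct = FALSE))$statistic
    expect_equal(z^2, unname(chi), tolerance = 1e-10)
  }
  expect_error(two_proportion_test(5, 0, 1, 10), "positive")
})

test_that("LOH comparison reports per-state fractions and pairwise tests", {
  states <- rep(c("CRPC-NE", "CRPC-Adeno"), c(56, 245))
  sim <- simulate_loh_calls(states, c("CRPC-NE" = 0.51, "CRPC-Adeno" = 0.30),
                            n_genes = 5, seed = 9)
  cmp <- loh_state_compare(sim$loh, sim$annotation, "g001")
  expect_true(all(cmp$fractions$fraction >= 0 & cmp$fractions$fraction <= 1))
  expect_equal(nrow(cmp$tests), 1)

  none <- simulate_loh_calls(states, c("CRPC-NE" = 0, "CRPC-Adeno" = 0),
                             n_genes = 2, seed = 9)
  expect_message(res <- loh_state_compare(none$loh, none$annotation, "g001"),
                 "skipped")
  expect_equal(nrow(res$tests), 0)
  expect_true(all(res$fractions$fraction == 0))
})

test_that("log-rank agrees with the risk-set oracle and survdiff", {
  # identical groups: observed equals expected exactly
  t0 <- c(2, 4, 6, 8); e0 <- c(1, 1, 0, 1)
  dup <- km_logrank(c(t0, t0), c(e0, e0), rep(c("a", "b"), each = 4))
  expect_equal(dup$test$statistic, 0, tolerance = 1e-12)
  expect_equal(dup$test$p.value, 1, tolerance = 1e-12)

  # 6-subject worked example
  time <- c(1, 3, 4, 2, 5, 7); event <- c(1, 1, 0, 1, 1, 1)
  group <- c("a", "a", "a", "b", "b", "b")
  got <- km_logrank(time, event, group)
  expect_equal(got$test$statistic, oracle_logrank_chi2(time, event, group),
               tolerance = 1e-10)
  ref <- survival::survdiff(survival::Surv(time, event) ~ group)
  expect_equal(got$test$statistic, unname(ref$chisq), tolerance = 1e-10)

  # KM curve: product-limit by hand for group a
  a <- got$curves[got$curves$group == "a", ]
  expect_equal(a$survival, c(1 - 1/3, (1 - 1/3) * (1 - 1/2)))
})

test_that("log-rank has power against a hazard ratio of 3", {
  hits <- vapply(1:30, function(s) {
    set.seed(200 + s)
    d <- sim_surv_groups(100, hazard_ratio = 3)
    km_logrank(d$time, d$event, d$group)$test$p.value < 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("the association battery wires scores to the right tests", {
  sig_genes <- tibble::tibble(gene = paste0("sg", 1:60),
                              direction = rep(c(1, -1), 30))
  sim <- simulate_cohort(c("CRPC-Adeno" = 120, "CRPC-NE" = 60), sig_genes,
                         effect_size_sd = 1.5, n_background_genes = 40,
                         seed = 12)
  sc <- score_cohort(sim$expr, new_test_signature(sig_genes))
  res <- associate_scores(sc, sim$annotation)
  expect_true("extreme_quartile_fisher" %in% res$test)
  expect_lt(res$p.value[res$test == "extreme_quartile_fisher"], 1e-4)
  tab <- attr(res, "contingency")
  expect_equal(sum(tab), 2 * floor(180 / 4))
  # all p-values are probabilities
  expect_true(all(res$p.value >= 0 & res$p.value <= 1))
})
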