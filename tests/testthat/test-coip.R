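# Co-IP quantification: Top3 roll-up, normalization, downshifted imputation,
# enrichment testing, the significance curve, and dimethyl ratio rules.

make_peptides <- function(per_protein) {
  purrr::imap_dfr(per_protein, function(ints, prot) {
    tibble::tibble(protein = prot, peptide = paste0(prot, "_p", seq_along(ints)),
                   condition = "IP", replicate = 1L, intensity = ints)
  })
}

test_that("Top3 sums the three most intense observed peptides", {
  q <- top3_quantify(make_peptides(list(A = c(10, 8, 5, 2), B = c(7, 3))))
  expect_equal(q$intensity[q$protein == "A"], 23)
  expect_equal(q$evidence[q$protein == "A"], 4)
  expect_equal(q$intensity[q$protein == "B"], 10)
  expect_equal(q$evidence[q$protein == "B"], 2)

  allna <- top3_quantify(make_peptides(list(C = c(NA_real_, NA_real_))))
  expect_true(is.na(allna$intensity))
  expect_equal(allna$evidence, 0)
  expect_error(top3_quantify(make_peptides(list(D = -1))), "negative")
})

test_that("Top3 equals a brute-force sort-and-sum oracle on random tables", {
  set.seed(301)
  sim <- simulate_coip_peptides(n_proteins = 40, n_bait_partners = 4,
                                missingness_midpoint = 21, seed = 17)
  got <- top3_quantify(sim$peptides)
  oracle <- aggregate(intensity ~ protein + condition + replicate,
                      data = as.data.frame(sim$peptides),
                      FUN = function(v) sum(sort(v, decreasing = TRUE)[1:min(3, length(v))]),
                      na.action = stats::na.pass)
  merged <- merge(as.data.frame(got), oracle,
                  by = c("protein", "condition", "replicate"))
  obs <- !is.na(merged$intensity.y)
  expect_gt(sum(obs), 0)
  expect_equal(merged$intensity.x[obs], merged$intensity.y[obs],
               tolerance = 1e-12)
  # top3 never exceeds the total peptide sum
  tot <- aggregate(intensity ~ protein + condition + replicate,
                   data = as.data.frame(sim$peptides), FUN = sum,
                   na.rm = TRUE, na.action = stats::na.pass)
  m2 <- merge(as.data.frame(got), tot, by = c("protein", "condition", "replicate"))
  expect_true(all(m2$intensity.x <= m2$intensity.y + 1e-9, na.rm = TRUE))
})

test_that("median alignment equalizes sample medians and respects scaling", {
  set.seed(302)
  sim <- simulate_coip_peptides(n_proteins = 60, n_bait_partners = 5,
                                missingness_midpoint = 20, seed = 23)
  norm1 <- normalize_peptides(sim$peptides)
  meds <- norm1 |>
    dplyr::filter(!is.na(log2_intensity)) |>
    dplyr::group_by(condition, replicate) |>
    dplyr::summarise(m = median(log2_intensity), .groups = "drop")
  expect_lt(diff(range(meds$m)), 1e-9)

  # already aligned data are unchanged
  renorm <- normalize_peptides(dplyr::select(norm1, -log2_intensity))
  expect_equal(renorm$intensity, norm1$intensity, tolerance = 1e-12)

  # a replicate scaled x4 is pulled back onto the common medians: relative to
  # the unscaled solution every normalized value shifts by one global constant
  scaled <- sim$peptides |>
    dplyr::mutate(intensity = intensity *
                    ifelse(condition == "IP" & replicate == 1, 4, 1))
  norm2 <- normalize_peptides(scaled)
  # the scaled replicate's +2 (log2) inflation is removed: relative to the
  # unscaled solution every value shifts by the same constant 2/k coming from
  # the common alignment target (k samples), i.e. the -2 correction has been
  # applied to that replicate
  delta <- norm2$log2_intensity - norm1$log2_intensity
  expect_lt(diff(range(delta, na.rm = TRUE)), 1e-9)
  expect_equal(mean(delta, na.rm = TRUE), 2 / 6, tolerance = 1e-9)

  # missing cells stay missing
  expect_equal(is.na(norm1$intensity), is.na(sim$peptides$intensity))
})

test_that("imputation drops under-evidenced features and is seed-stable", {
  q <- tidyr::expand_grid(protein = c("P1", "P2"),
                          condition = c("IP", "IgG"), replicate = 1:3) |>
    dplyr::mutate(log2_intensity = rep(c(20, 21, NA, 19, NA, 18), 2))
  # P2: one observation per condition after masking -> ineligible
  q$log2_intensity[q$protein == "P2"] <- c(20, NA, NA, 19, NA, NA)
  # pad with fully observed proteins so per-sample moments exist
  pad <- tidyr::expand_grid(protein = paste0("bg", 1:20),
                            condition = c("IP", "IgG"), replicate = 1:3) |>
    dplyr::mutate(log2_intensity = rnorm(dplyr::n(), 20))
  full <- dplyr::bind_rows(q, pad)
  expect_message(imp <- impute_missing(full, level = "protein", seed = 4),
                 "dropped")
  expect_false("P2" %in% imp$protein)
  expect_false(anyNA(imp$log2_intensity))
  imp2 <- suppressMessages(impute_missing(full, level = "protein", seed = 4))
  expect_identical(imp$log2_intensity, imp2$log2_intensity)
  imp3 <- suppressMessages(impute_missing(full, level = "protein", seed = 5))
  expect_false(identical(imp$log2_intensity, imp3$log2_intensity))
})

test_that("imputed draws stay below the per-sample observed mean", {
  set.seed(303)
  n <- 400
  q <- tidyr::expand_grid(protein = paste0("P", 1:n),
                          condition = c("IP", "IgG"), replicate = 1:3) |>
    dplyr::mutate(peptide = paste0(protein, "_p1"),
                  log2_intensity = rnorm(dplyr::n(), 22, 2))
  mask <- q$condition == "IgG" & q$replicate == 3 &
    as.integer(sub("P", "", q$protein)) %% 3 == 0
  q$log2_intensity[mask] <- NA
  imp <- impute_missing(q, level = "peptide", width = 0.3, downshift = 1.8,
                        seed = 6)
  obs_mean <- mean(q$log2_intensity[q$condition == "IgG" & q$replicate == 3],
                   na.rm = TRUE)
  expect_true(all(imp$log2_intensity[imp$imputed] < obs_mean))

  # a sample with fewer than two observed values has no usable distribution
  gone <- q
  gone$log2_intensity[gone$condition == "IgG" & gone$replicate == 3] <- NA
  expect_error(impute_missing(gone, level = "peptide", seed = 6), "IgG_3")
})

test_that("enrichment testing recovers planted partners and flips with labels", {
  sim <- simulate_coip_peptides(n_proteins = 300, n_bait_partners = 15,
                                enrichment_log2 = 3, missingness_midpoint = 20,
                                seed = 31)
  prot <- normalize_peptides(sim$peptides) |>
    top3_quantify() |>
    dplyr::mutate(log2_intensity = log2(intensity))
  imp <- suppressMessages(impute_missing(prot, level = "protein", seed = 31))
  res <- enrichment_test(imp)
  top <- head(dplyr::arrange(res, p_adj), 30)
  expect_gte(sum(top$protein %in% sim$truth$protein), 13)

  flipped <- dplyr::mutate(imp, condition = ifelse(condition == "IP", "IgG", "IP"))
  res_fl <- enrichment_test(flipped)
  expect_equal(res_fl$log2fc, -res$log2fc, tolerance = 1e-12)
})

test_that("enrichment on fully observed data ignores the imputation seed", {
  sim <- simulate_coip_peptides(n_proteins = 100, n_bait_partners = 10,
                                missingness_steepness = 0,
                                missingness_midpoint = -Inf, seed = 37)
  prot <- top3_quantify(normalize_peptides(sim$peptides)) |>
    dplyr::mutate(log2_intensity = log2(intensity))
  r1 <- enrichment_test(impute_missing(prot, level = "protein", seed = 1))
  r2 <- enrichment_test(impute_missing(prot, level = "protein", seed = 99))
  expect_identical(r1$p.value, r2$p.value)
})

test_that("the significance curve gates on fold change and adjusted p", {
  res <- tibble::tibble(protein = paste0("P", 1:5),
                        log2fc = c(1.0, 200, 200, 5, -5),
                        t = 0, p.value = 0,
                        p_adj = c(1e-9, 0.049, 0.051, 1e-9, 1e-3))
  class(res) <- c("kd_enrichment", class(res))
  # fix the curve constant at exactly 1 so the thresholds are known in closed
  # form: -log10(p_adj) >= -log10(0.05) + 1 / (|fc| - 1)
  out <- significance_curve(res, p0 = 0.05, fc0 = 1,
                            s0_mult = 1 / sd(res$log2fc))
  expect_false(out$significant[1])  # |fc| at the asymptote: never significant
  expect_true(out$significant[2])   # very large fc, p_adj just under 0.05
  expect_false(out$significant[3])  # very large fc, p_adj over 0.05
  expect_true(out$significant[5])   # symmetric in the sign of the fold change

  # at fixed p_adj, significance is monotone non-decreasing in |log2fc|
  fcs <- seq(0.5, 6, by = 0.25)
  grid <- tibble::tibble(protein = as.character(seq_along(fcs)), log2fc = fcs,
                         t = 0, p.value = 0, p_adj = 0.01)
  class(grid) <- c("kd_enrichment", class(grid))
  sig_flags <- significance_curve(grid, s0_mult = 0.5)$significant
  expect_true(all(diff(as.integer(sig_flags)) >= 0))
})

test_that("dimethyl ratios follow the published filter and imputation rules", {
  psms <- tibble::tibble(
    protein = c(rep("keep", 8), rep("few", 7), rep("ctl0", 8), rep("lowsn", 8)),
    psm = paste0("m", 1:31),
    sn_heavy = c(rep(10, 8), rep(10, 7), rep(12, 8), c(rep(10, 7), 5)),
    sn_light = c(rep(5, 8), rep(5, 7), rep(0, 8), c(rep(5, 7), 4)))
  r <- dimethyl_ratios(psms, experimental_channel = "heavy")
  expect_false("few" %in% r$protein)    # 7 surviving PSMs: dropped
  expect_false("lowsn" %in% r$protein)  # S/N sum 9 PSM removed -> 7 left
  expect_equal(r$log2_ratio[r$protein == "keep"], log2(80 / 40))
  ctl0 <- r[r$protein == "ctl0", ]
  expect_true(ctl0$control_imputed)
  expect_equal(ctl0$log2_ratio, log2(96))  # control-zero -> denominator 1

  # the arithmetic of the control-zero rule on a minimal table
  tiny <- tibble::tibble(protein = "bait", psm = "m1",
                         sn_heavy = 8, sn_light = 0)
  expect_equal(dimethyl_ratios(tiny, min_psms = 1, min_sn_sum = 0)$log2_ratio, 3)

  # totals equal a brute-force group-by-sum oracle on random tables
  sim <- simulate_dimethyl_psms(n_proteins = 50, n_partners = 5, seed = 41)
  got <- dimethyl_ratios(sim$psms)
  surv <- sim$psms[sim$psms$sn_heavy + sim$psms$sn_light >= 10, ]
  oracle <- aggregate(cbind(sn_heavy, sn_light) ~ protein, data = surv, FUN = sum)
  names(oracle) <- c("protein", "tot_heavy", "tot_light")
  oracle <- oracle[table(surv$protein)[oracle$protein] >= 8, ]
  m <- merge(as.data.frame(got), oracle, by = "protein")
  expect_equal(nrow(m), nrow(got))
  expect_equal(m$sn_experimental, m$tot_heavy)
  expect_equal(m$sn_control, m$tot_light)
})
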