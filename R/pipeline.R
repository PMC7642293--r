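# End-to-end orchestration on synthetic data: simulate -> normalize/test ->
# derive signature -> score cohort -> associate -> co-IP, with every artifact
# written as TSV and a machine-readable JSON summary.

default_pipeline_config <- function() {
  list(
    seed = 1,
    kd = list(n_genes = 2000, n_replicates_per_arm = 3, n_true_de = 400,
              log2fc_magnitude = 2, dispersion = 0.1,
              baseline_log_mean = 6, batch_effect_sd = 0.15),
    de = list(min_logcpm = 1, max_fail_samples = 3),
    signature = list(lfc_threshold = 1.5, fdr_threshold = 0.01,
                     top_n = 419, weight_mode = "sign"),
    cohort = list(n_samples_per_state = c("CRPC-Adeno" = 120, "CRPC-NE" = 60),
                  effect_size_sd = 1.5, noise_sd = 1,
                  n_background_genes = 1000, n_signature_genes = 100),
    coip = list(n_proteins = 800, n_bait_partners = 20, enrichment_log2 = 3,
                n_replicates = 3, missingness_steepness = 1,
                missingness_midpoint = 20,
                impute_width = 0.2, impute_downshift = 2.5),
    dimethyl = list(n_proteins = 300, n_partners = 20, enrichment_log2 = 3),
    loh = list(n_genes = 20,
               fractions = c("CRPC-NE" = 0.51, "CRPC-Adeno" = 0.30),
               n_per_state = c("CRPC-NE" = 56, "CRPC-Adeno" = 245))
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Run the full synthetic analysis pipeline
#'
#' Simulates a knock-down RNA-seq experiment, derives the knock-down
#' signature (low-expression filter, TMM log2-CPM, moderated t, thresholds +
#' top-N), simulates a CRPC cohort carrying the planted signature shift,
#' scores and classifies it, runs the association battery, and runs the co-IP
#' arm (peptide simulation, normalization, Top3, protein-level downshift
#' imputation, moderated enrichment test, significance curve) plus dimethyl
#' ratio quantification and an LOH state comparison. Every stage receives a
#' seed derived deterministically from the global seed and the stage name, so
#' a rerun with the same config reproduces every artifact.
#'
#' @param config Named list overriding entries of the default configuration
#'   (see `kdsig:::default_pipeline_config()`), or a path to a YAML file.
#' @param out_dir Output directory; created if needed. `NULL` skips writing.
#' @return A list of in-memory results: `de`, `signature`, `scores`,
#'   `associations`, `coip`, `dimethyl`, `loh`, `summary` (the content of
#'   `summary.json`). Invisibly when `out_dir` is given.
#' @export
run_end_to_end <- function(config = list(), out_dir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  cfg <- merge_config(default_pipeline_config(), config)
  seed <- cfg$seed

  # knock-down experiment -> differential expression -> signature
  kd <- do.call(simulate_kd_counts, c(cfg$kd, list(seed = derive_seed(seed, "kd"))))
  kept <- filter_low_expression(kd$counts, cfg$de$min_logcpm, cfg$de$max_fail_samples)
  fac <- tmm_factors(kept)
  lc <- log2_cpm(kept, fac)
  de <- moderated_t_test(lc, kd$design$group, kd$design$batch)
  sig <- derive_signature(de, cfg$signature$lfc_threshold,
                          cfg$signature$fdr_threshold, cfg$signature$top_n,
                          cfg$signature$weight_mode)

  # cohort simulation on the derived signature genes, scoring, association
  sig_genes <- head(tidy(sig)[c("gene", "direction")],
                    cfg$cohort$n_signature_genes)
  cohort <- simulate_cohort(
    n_samples_per_state = cfg$cohort$n_samples_per_state,
    signature_genes = sig_genes,
    effect_size_sd = cfg$cohort$effect_size_sd,
    noise_sd = cfg$cohort$noise_sd,
    n_background_genes = cfg$cohort$n_background_genes,
    seed = derive_seed(seed, "cohort"))
  scores <- score_cohort(cohort$expr, sig)
  assoc <- associate_scores(scores, cohort$annotation)

  # co-IP arm: peptides -> normalize -> Top3 -> impute -> enrich -> curve
  coip <- simulate_coip_peptides(
    n_proteins = cfg$coip$n_proteins, n_bait_partners = cfg$coip$n_bait_partners,
    enrichment_log2 = cfg$coip$enrichment_log2, n_replicates = cfg$coip$n_replicates,
    missingness_steepness = cfg$coip$missingness_steepness,
    missingness_midpoint = cfg$coip$missingness_midpoint,
    seed = derive_seed(seed, "coip"))
  normed <- normalize_peptides(coip$peptides)
  prot <- top3_quantify(normed) |>
    dplyr::mutate(log2_intensity = log2(.data$intensity))
  imputed <- impute_missing(prot, level = "protein",
                            width = cfg$coip$impute_width,
                            downshift = cfg$coip$impute_downshift,
                            seed = derive_seed(seed, "impute"))
  enr <- enrichment_test(imputed) |> significance_curve()

  dm <- do.call(simulate_dimethyl_psms,
                c(cfg$dimethyl, list(seed = derive_seed(seed, "dimethyl"))))
  ratios <- dimethyl_ratios(dm$psms, experimental_channel = dm$experimental_channel)

  loh_states <- rep(names(cfg$loh$n_per_state), times = cfg$loh$n_per_state)
  loh <- simulate_loh_calls(loh_states, cfg$loh$fractions, cfg$loh$n_genes,
                            seed = derive_seed(seed, "loh"))
  loh_cmp <- loh_state_compare(loh$loh, loh$annotation, loh$loh$gene[1])

  top_partner_hits <- sum(head(dplyr::arrange(enr, .data$p_adj), 40)$protein
                          %in% coip$truth$protein)
  summary <- list(
    seed = seed,
    n_genes_after_filter = nrow(kept),
    n_de_genes = sum(de$fdr < cfg$signature$fdr_threshold &
                       abs(de$log2fc) >= cfg$signature$lfc_threshold, na.rm = TRUE),
    signature_size = nrow(tidy(sig)),
    associations = as.list(setNames(assoc$p.value, assoc$test)),
    coip_significant = sum(enr$significant),
    coip_partners_in_top40 = top_partner_hits,
    dimethyl_proteins_quantified = nrow(ratios),
    loh_fractions = as.list(setNames(loh_cmp$fractions$fraction,
                                     loh_cmp$fractions$state)),
    loh_p = if (nrow(loh_cmp$tests) > 0) loh_cmp$tests$p.value[1] else NA
  )

  res <- list(de = de, signature = sig, scores = scores, associations = assoc,
              coip = enr, dimethyl = ratios, loh = loh_cmp, summary = summary)
  if (is.null(out_dir)) return(res)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_expression_matrix(kd$counts, file.path(out_dir, "kd_counts.tsv"))
  readr::write_tsv(de, file.path(out_dir, "de_result.tsv"), progress = FALSE)
  write_signature(sig, file.path(out_dir, "signature.tsv"))
  write_expression_matrix(cohort$expr, file.path(out_dir, "cohort_expr.tsv"))
  write_sample_annotation(cohort$annotation, file.path(out_dir, "annotation.tsv"))
  readr::write_tsv(scores, file.path(out_dir, "scores.tsv"), progress = FALSE)
  readr::write_tsv(assoc, file.path(out_dir, "associations.tsv"), progress = FALSE)
  readr::write_tsv(enr, file.path(out_dir, "coip_enrichment.tsv"), progress = FALSE)
  readr::write_tsv(ratios, file.path(out_dir, "dimethyl_ratios.tsv"), progress = FALSE)
  readr::write_tsv(loh_cmp$fractions, file.path(out_dir, "loh_fractions.tsv"),
                   progress = FALSE)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}

#' Reconstruct the published extreme-quartile contingency tables
#'
#' Rebuilds, from the printed counts, the 2x2 tables of score class (low vs
#' high quartile, mid dropped) against CRPC phenotype for the two validation
#' cohorts — SU2C-PCF (16 of 16 CRPC-NE low-score vs 57 of 122 CRPC-Adeno,
#' n = 138) and WCM (8 of 9 CRPC-NE low-score vs 5 of 16 CRPC-Adeno, n = 25)
#' — and reports the two-sided Fisher exact test on each.
#'
#' @param cohort `"su2c"` or `"wcm"`.
#' @return List: `table` (2x2 matrix, rows = phenotype, cols = class) and
#'   `test` (one-row tibble `estimate`, `p.value`, `n`).
#' @export
reproduce_extreme_quartile_table <- function(cohort = c("su2c", "wcm")) {
  cohort <- match.arg(cohort)
  tab <- switch(cohort,
    su2c = matrix(c(16, 0, 57, 65), nrow = 2, byrow = TRUE,
                  dimnames = list(c("CRPC-NE", "CRPC-Adeno"), c("low", "high"))),
    wcm = matrix(c(8, 1, 5, 11), nrow = 2, byrow = TRUE,
                 dimnames = list(c("CRPC-NE", "CRPC-Adeno"), c("low", "high"))))
  fe <- fisher_exact_2x2(tab)
  list(table = tab,
       test = tibble(cohort = cohort, estimate = fe$estimate,
                     p.value = fe$p.value, n = sum(tab)))
}
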