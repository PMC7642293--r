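# Knock-down signature: derivation from a differential-expression table,
# z-score weighted-sum scoring of cohorts, quantile rescaling, and
# extreme-quartile classification.

new_kd_signature <- function(genes, derivation = list()) {
  stopifnot(is.data.frame(genes),
            all(c("gene", "weight", "direction", "rank") %in% names(genes)))
  structure(list(genes = tibble::as_tibble(genes), derivation = derivation),
            class = "kd_signature")
}

#' Derive a knock-down signature from a differential-expression table
#'
#' Keeps genes with `|log2fc| >= lfc_threshold` and `fdr < fdr_threshold`,
#' ranks them by FDR ascending, then `|log2fc|` descending, then gene id
#' (deterministic tie-break), truncates to the top `top_n`, and assigns each
#' gene a weight: the sign of its fold change (`weight_mode = "sign"`, the
#' default minimal reading of a direction-weighted sum) or the fold change
#' itself (`weight_mode = "log2fc"`). The thresholds default to the derivation
#' regime of a SMARCA4 knock-down signature: log fold change 1.5, FDR < 0.01,
#' top 419 genes.
#'
#' @param de Tibble from [moderated_t_test()] (`gene`, `log2fc`, `fdr`, ...).
#' @param lfc_threshold Minimum `|log2fc|` (log2 scale).
#' @param fdr_threshold Maximum FDR (exclusive).
#' @param top_n Maximum number of genes retained.
#' @param weight_mode `"sign"` or `"log2fc"`.
#' @return A `kd_signature`: list with `genes` (tibble `gene`, `weight`,
#'   `direction`, `rank`, `log2fc`, `fdr`) and `derivation` metadata. Errors
#'   if no gene passes, reporting the thresholds.
#' @export
derive_signature <- function(de, lfc_threshold = 1.5, fdr_threshold = 0.01,
                             top_n = 419, weight_mode = c("sign", "log2fc")) {
  weight_mode <- match.arg(weight_mode)
  stopifnot(is.data.frame(de), all(c("gene", "log2fc", "fdr") %in% names(de)))
  if (nrow(de) == 0) abort("empty differential-expression table")

  passing <- de |>
    dplyr::filter(!is.na(.data$fdr),
                  abs(.data$log2fc) >= lfc_threshold,
                  .data$fdr < fdr_threshold)
  if (nrow(passing) == 0) {
    abort(sprintf(
      "no gene passes |log2fc| >= %g and fdr < %g (max |log2fc| = %.3g, min fdr = %.3g)",
      lfc_threshold, fdr_threshold, max(abs(de$log2fc), na.rm = TRUE),
      min(de$fdr, na.rm = TRUE)))
  }
  ranked <- passing |>
    dplyr::arrange(.data$fdr, dplyr::desc(abs(.data$log2fc)), .data$gene) |>
    head(top_n) |>
    dplyr::mutate(
      rank = dplyr::row_number(),
      direction = as.integer(sign(.data$log2fc)),
      weight = if (weight_mode == "sign") as.numeric(.data$direction) else .data$log2fc
    )
  new_kd_signature(
    ranked[c("gene", "weight", "direction", "rank", "log2fc", "fdr")],
    derivation = list(lfc_threshold = lfc_threshold,
                      fdr_threshold = fdr_threshold,
                      top_n = top_n, weight_mode = weight_mode,
                      n_passing = nrow(passing), engine = "moderated_t")
  )
}

#' @export
print.kd_signature <- function(x, ...) {
  cat("<kd_signature> ", nrow(x$genes), " genes (",
      sum(x$genes$direction > 0), " up, ", sum(x$genes$direction < 0),
      " down)\n", sep = "")
  d <- x$derivation
  if (length(d) > 0) {
    cat("derivation:", paste(names(d), unlist(d), sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @describeIn derive_signature Gene-level tibble of the signature.
#' @param x A `kd_signature`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.kd_signature <- function(x, ...) x$genes

#' @describeIn derive_signature One-row tibble of derivation metadata.
#' @exportS3Method generics::glance
glance.kd_signature <- function(x, ...) {
  tibble(n_genes = nrow(x$genes),
         n_up = sum(x$genes$direction > 0),
         n_down = sum(x$genes$direction < 0),
         !!!x$derivation)
}

#' Score cohort samples by a weighted sum of z-scored expression
#'
#' Expression of each signature gene is z-scored across the cohort being
#' scored (mean 0, SD 1 within this cohort — scores are comparable within a
#' cohort, not across platforms), then each sample's raw score is the
#' weight-weighted sum over signature genes. Signature genes absent from the
#' matrix, or with zero variance across samples, are skipped with a message.
#'
#' @param expr Tibble: `gene` column plus numeric sample columns (log scale).
#' @param signature A `kd_signature`.
#' @return Tibble: `sample`, `raw_score`.
#' @export
score_samples <- function(expr, signature) {
  stopifnot(inherits(signature, "kd_signature"))
  m <- expr_to_matrix(expr)
  if (ncol(m) < 2) abort("need >= 2 samples to z-score within the cohort")

  sig <- signature$genes
  present <- sig$gene %in% rownames(m)
  if (!any(present)) abort("no signature gene present in the expression matrix")
  if (any(!present)) {
    inform(paste0(sum(!present), " signature gene(s) absent from matrix; skipped"))
  }
  sub <- m[sig$gene[present], , drop = FALSE]
  w <- sig$weight[present]
  sds <- apply(sub, 1, sd)
  nonconst <- sds > 0
  if (any(!nonconst)) {
    inform(paste0(sum(!nonconst), " zero-variance signature gene(s) skipped"))
  }
  sub <- sub[nonconst, , drop = FALSE]
  w <- w[nonconst]
  z <- (sub - rowMeans(sub)) / apply(sub, 1, sd)
  tibble(sample = colnames(m), raw_score = as.numeric(crossprod(z, w)))
}

#' Rescale scores so the 2.5% and 97.5% quantiles map to -1 and +1
#'
#' Affine rescaling `r = 2 * (s - Q(q_low)) / (Q(q_high) - Q(q_low)) - 1`
#' using type-7 (linear-interpolation) empirical quantiles. Invariant under
#' positive affine transformation of the input; errors when the two quantiles
#' coincide (degenerate, e.g. constant scores).
#'
#' @param scores Numeric vector, or a tibble with a `raw_score` column.
#' @param q_low,q_high Quantile probabilities anchored to -1 and +1.
#' @return Same shape as the input: a numeric vector, or the tibble with a
#'   `rescaled_score` column added.
#' @export
rescale_scores <- function(scores, q_low = 0.025, q_high = 0.975) {
  tab <- NULL
  if (is.data.frame(scores)) {
    tab <- scores
    scores <- tab$raw_score
  }
  qs <- quantile(scores, c(q_low, q_high), type = 7, names = FALSE)
  if (qs[1] == qs[2]) abort("degenerate scores: rescaling quantiles coincide")
  r <- 2 * (scores - qs[1]) / (qs[2] - qs[1]) - 1
  if (is.null(tab)) r else dplyr::mutate(tab, rescaled_score = r)
}

#' Classify samples into extreme score quartiles
#'
#' The `floor(n/4)` samples with the lowest scores are labelled `low`, the
#' `floor(n/4)` with the highest `high`, and the remainder `mid`. Ties at a
#' boundary are broken by sample id (ascending), so the partition is
#' deterministic.
#'
#' @param scores Tibble with `sample` and a score column (`rescaled_score` if
#'   present, else `raw_score`).
#' @return The tibble with a `class` factor column (`low` < `mid` < `high`).
#' @export
classify_quartiles <- function(scores) {
  stopifnot(is.data.frame(scores), "sample" %in% names(scores))
  score_col <- intersect(c("rescaled_score", "raw_score"), names(scores))[1]
  if (is.na(score_col)) abort("scores must have `rescaled_score` or `raw_score`")
  n <- nrow(scores)
  if (n < 4) abort("need >= 4 samples to form quartile classes")
  k <- floor(n / 4)
  ord <- order(scores[[score_col]], scores$sample)
  cls <- rep("mid", n)
  cls[ord[seq_len(k)]] <- "low"
  cls[ord[seq(n - k + 1, n)]] <- "high"
  dplyr::mutate(scores, class = factor(cls, levels = c("low", "mid", "high")))
}

#' Score, rescale and classify a cohort in one call
#'
#' Convenience pipeline: [score_samples()] then [rescale_scores()] then
#' [classify_quartiles()].
#'
#' @inheritParams score_samples
#' @inheritParams rescale_scores
#' @return Tibble: `sample`, `raw_score`, `rescaled_score`, `class`.
#' @export
score_cohort <- function(expr, signature, q_low = 0.025, q_high = 0.975) {
  score_samples(expr, signature) |>
    rescale_scores(q_low = q_low, q_high = q_high) |>
    classify_quartiles()
}
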