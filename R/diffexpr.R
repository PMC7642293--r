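# Count preprocessing and the moderated-t differential expression engine.
# The same engine tests RNA-seq log2-CPM and imputed proteomics log2
# intensities, so signature derivation and co-IP enrichment share one code
# path for effect sizes, moderated statistics and FDR.

#' Filter genes with low counts-per-million
#'
#' Removes a gene when its log2-CPM (pseudo-count 1, raw library sizes) falls
#' below `min_logcpm` in more than `max_fail_samples` samples. The boundary is
#' inclusive: a gene failing in exactly `max_fail_samples` samples is kept.
#'
#' @param counts Tibble with `gene` column plus one count column per sample.
#' @param min_logcpm Log2-CPM threshold below which a sample "fails" a gene.
#' @param max_fail_samples Maximum number of failing samples tolerated.
#' @return The filtered counts tibble, row order preserved.
#' @export
filter_low_expression <- function(counts, min_logcpm = 1, max_fail_samples = 3) {
  m <- expr_to_matrix(counts)
  if (ncol(m) < 1 || nrow(m) < 1) abort("empty count matrix")
  if (any(m < 0)) abort("counts must be non-negative")
  lib <- colSums(m)
  logcpm <- log2(t(t(m) / lib) * 1e6 + 1)
  fails <- rowSums(logcpm < min_logcpm)
  counts[fails <= max_fail_samples, , drop = FALSE]
}

#' TMM normalization factors
#'
#' Weighted trimmed mean of M-values between-sample normalization: the
#' reference is the sample whose upper-quartile count fraction is closest to
#' the mean upper quartile; per sample the factor is `2^` the weighted mean of
#' gene-wise M-values after two-sided trimming (`trim_m` on M, `trim_a` on A)
#' with inverse asymptotic binomial-variance weights; factors are rescaled to
#' geometric mean one. Computed with the reference implementation in
#' \pkg{edgeR}.
#'
#' @param counts Tibble with `gene` column plus count columns.
#' @param trim_m Two-sided trim fraction on M-values.
#' @param trim_a Two-sided trim fraction on A-values.
#' @return Tibble: `sample`, `lib_size`, `tmm_factor`,
#'   `effective_lib_size` (= `lib_size * tmm_factor`).
#' @export
tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  m <- expr_to_matrix(counts)
  if (ncol(m) < 2) abort("need at least 2 samples")
  if (any(colSums(m) == 0)) {
    abort(paste0("degenerate all-zero sample: ",
                 colnames(m)[colSums(m) == 0][1]))
  }
  f <- edgeR::calcNormFactors(m, method = "TMM",
                              logratioTrim = trim_m, sumTrim = trim_a)
  tibble(sample = colnames(m), lib_size = colSums(m), tmm_factor = as.numeric(f),
         effective_lib_size = colSums(m) * as.numeric(f))
}

#' Log2 counts-per-million on TMM-effective library sizes
#'
#' `log2(1e6 * count / effective_lib_size + pseudo)`, where the effective
#' library size is the raw depth times the sample's TMM factor. With
#' `factors = NULL` raw library sizes are used.
#'
#' @param counts Tibble with `gene` column plus count columns.
#' @param factors Output of [tmm_factors()], or `NULL`.
#' @param pseudo Pseudo-count added before the log (default 1, so a zero
#'   count maps to 0).
#' @return Tibble of log2-CPM values, same shape as `counts`.
#' @export
log2_cpm <- function(counts, factors = NULL, pseudo = 1) {
  m <- expr_to_matrix(counts)
  lib <- colSums(m)
  if (!is.null(factors)) {
    if (!all(colnames(m) %in% factors$sample)) abort("factors missing samples")
    fac <- factors$tmm_factor[match(colnames(m), factors$sample)]
    if (any(fac <= 0)) abort("TMM factors must be positive")
    lib <- lib * fac
  }
  matrix_to_expr(log2(t(t(m) / lib) * 1e6 + pseudo))
}

#' Empirical-Bayes moderated two-group t-test
#'
#' Fits a per-feature linear model (group, plus an optional blocking batch
#' factor included in the design matrix), shrinks residual variances toward a
#' pooled prior by empirical Bayes, and reports moderated t statistics with
#' augmented degrees of freedom, two-sided p-values, and Benjamini-Hochberg
#' FDR. The engine is \pkg{limma}'s `lmFit`/`eBayes`. With a single feature
#' there is no information to shrink (prior df 0) and the moderated t equals
#' the ordinary two-sample t. A feature with one group entirely missing is
#' reported with `NA` statistics.
#'
#' The reported `log2fc` is the second group level minus the first (levels in
#' factor order, alphabetical for character input).
#'
#' @param expr Tibble with `gene` (or `protein`) id column plus one numeric
#'   column per sample, on a log scale. `NA` marks missing values.
#' @param groups Character/factor vector, one entry per sample column, with
#'   exactly two levels.
#' @param batch Optional vector of batch labels, one per sample column.
#' @return Tibble: `gene`, `log2fc`, `mean_expr`, `t`, `p`, `fdr`, `df`.
#' @export
moderated_t_test <- function(expr, groups, batch = NULL) {
  id_col <- intersect(c("gene", "protein"), names(expr))[1]
  if (is.na(id_col)) abort("expression table must have a `gene` or `protein` column")
  m <- as.matrix(expr[setdiff(names(expr), id_col)])
  rownames(m) <- expr[[id_col]]

  groups <- droplevels(as.factor(groups))
  if (length(groups) != ncol(m)) abort("`groups` length must match sample columns")
  if (nlevels(groups) != 2) abort("need exactly 2 groups")
  if (any(table(groups) < 2)) abort("need >= 2 samples per group")

  design <- if (is.null(batch)) {
    model.matrix(~groups)
  } else {
    batch <- as.factor(batch)
    if (length(batch) != ncol(m)) abort("`batch` length must match sample columns")
    model.matrix(~groups + batch)
  }
  fit <- limma::lmFit(m, design)
  fit <- limma::eBayes(fit)
  i <- 2L  # the group contrast
  res <- tibble(
    !!id_col := rownames(m),
    log2fc = as.numeric(fit$coefficients[, i]),
    mean_expr = as.numeric(fit$Amean),
    t = as.numeric(fit$t[, i]),
    p = as.numeric(fit$p.value[, i]),
    df = as.numeric(fit$df.total)
  )
  res$fdr <- NA_real_
  ok <- !is.na(res$p)
  res$fdr[ok] <- bh_fdr(res$p[ok])
  res[c(id_col, "log2fc", "mean_expr", "t", "p", "fdr", "df")]
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate control with monotonicity enforcement,
#' order-preserving (a permutation of the input permutes the output the same
#' way). Wraps `stats::p.adjust(method = "BH")`.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_fdr <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

#' Hierarchical clustering of samples on the most variable genes
#'
#' Ranks genes by variance across samples (ties broken lexicographically by
#' gene id, for determinism), keeps the top `n_top_variable`, and clusters
#' samples by Ward linkage on Euclidean distances. If `n_top_variable` is at
#' least the number of genes, all genes are used.
#'
#' @param expr Tibble with `gene` column plus numeric sample columns
#'   (log-scale expression).
#' @param n_top_variable Number of most-variable genes to keep.
#' @param k Number of flat clusters to cut (default 2).
#' @return List: `tree` (an `hclust`), `genes_used` (character vector),
#'   `clusters` (tibble `sample`, `cluster`).
#' @export
cluster_samples <- function(expr, n_top_variable = 500, k = 2) {
  m <- expr_to_matrix(expr)
  if (ncol(m) < 2) abort("need at least 2 samples")
  v <- apply(m, 1, var)
  ord <- order(-v, rownames(m))
  top <- rownames(m)[head(ord, min(n_top_variable, nrow(m)))]
  d <- dist(t(m[top, , drop = FALSE]), method = "euclidean")
  tree <- hclust(d, method = "ward.D2")
  cl <- cutree(tree, k = k)
  list(tree = tree, genes_used = top,
       clusters = tibble(sample = names(cl), cluster = as.integer(cl)))
}
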