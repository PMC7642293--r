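# Co-IP mass-spectrometry quantification: Top3 protein roll-up, peptide
# normalization, Gaussian-downshift imputation of left-censored missing
# values, moderated-t enrichment testing against the IgG control, the
# fold-change-dependent significance curve, and dimethyl-label S/N ratios.

#' Top3 protein quantification
#'
#' Rolls peptides up to proteins per condition/replicate as the sum of the
#' three most intense observed peptides; with fewer than three observed
#' peptides the available ones are summed and the evidence count records how
#' many. A protein is missing in a replicate iff no peptide was observed
#' there.
#'
#' @param peptides Long tibble: `protein`, `peptide`, `condition`,
#'   `replicate`, `intensity` (`NA` = missing).
#' @return Tibble: `protein`, `condition`, `replicate`, `intensity` (Top3
#'   sum, `NA` when nothing observed), `evidence` (number of peptides used).
#' @export
top3_quantify <- function(peptides) {
  stopifnot(all(c("protein", "peptide", "condition", "replicate", "intensity")
                %in% names(peptides)))
  if (nrow(peptides) == 0) abort("empty peptide table")
  if (any(peptides$intensity < 0, na.rm = TRUE)) abort("negative intensity")
  peptides |>
    dplyr::group_by(.data$protein, .data$condition, .data$replicate) |>
    dplyr::summarise(
      evidence = sum(!is.na(.data$intensity)),
      intensity = if (all(is.na(.data$intensity))) NA_real_ else {
        sum(sort(.data$intensity[!is.na(.data$intensity)],
                 decreasing = TRUE)[seq_len(min(3, sum(!is.na(.data$intensity))))])
      },
      .groups = "drop"
    ) |>
    dplyr::select(dplyr::all_of(c("protein", "condition", "replicate",
                                  "intensity", "evidence")))
}

#' Normalize peptide intensities across replicates
#'
#' Log2-transforms intensities and aligns the per-sample (condition x
#' replicate) medians of observed values to their common mean, so all sample
#' medians coincide exactly after normalization — the variance-stabilizing
#' median alignment conventional for label-free peptide data. An
#' inverse-hyperbolic-sine variant is available for data containing zeros.
#' Missing values are untouched.
#'
#' @param peptides Long tibble as in [top3_quantify()].
#' @param method `"log2_median"` (default) or `"asinh_median"`.
#' @return The tibble with `intensity` replaced by its normalized raw-scale
#'   value and a `log2_intensity` column added (`NA` preserved). The
#'   normalization name is attached as attribute `normalization`.
#' @export
normalize_peptides <- function(peptides, method = c("log2_median", "asinh_median")) {
  method <- match.arg(method)
  trans <- if (method == "log2_median") log2 else asinh
  inv <- if (method == "log2_median") function(x) 2^x else sinh
  out <- peptides |>
    dplyr::mutate(sample = paste0(.data$condition, "_", .data$replicate),
                  lg = trans(.data$intensity))
  meds <- out |>
    dplyr::filter(!is.na(.data$lg)) |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(med = median(.data$lg), .groups = "drop")
  if (nrow(meds) < 2) abort("need >= 2 samples with observed values")
  target <- mean(meds$med)
  out <- out |>
    dplyr::left_join(meds, by = "sample") |>
    dplyr::mutate(lg = .data$lg - .data$med + target,
                  intensity = inv(.data$lg)) |>
    dplyr::select(-dplyr::all_of(c("sample", "med")))
  out <- dplyr::rename(out, log2_intensity = "lg")
  if (method == "asinh_median") {
    out$log2_intensity <- log2(out$intensity)
  }
  attr(out, "normalization") <- method
  out
}

#' Impute left-censored missing values from a downshifted Gaussian
#'
#' Works on log2-scale quantifications. A feature is eligible for imputation
#' iff at least one condition has at least `min_evidence` observed values;
#' ineligible features are dropped (with a message). Each eligible missing
#' cell in sample `s` (a condition x replicate column) is drawn from
#' `Normal(mean_s - downshift * sd_s, (width * sd_s)^2)`, where `mean_s` and
#' `sd_s` are computed from the observed values of that sample — the
#' left-censored (missing-not-at-random) model under which low-abundance
#' intensities drop out. Width and downshift are multiples of the per-sample
#' SD; defaults are (0.3, 1.8) at peptide level and (0.2, 2.5) at protein
#' level.
#'
#' @param quant Long tibble with feature id columns (`protein`, optionally
#'   `peptide`), `condition`, `replicate`, and `log2_intensity` (`NA` =
#'   missing).
#' @param level `"peptide"` or `"protein"`; sets default width/downshift.
#' @param width Gaussian SD as a multiple of the sample SD.
#' @param downshift Center offset below the sample mean, in sample SDs.
#' @param min_evidence Observed values required in some condition.
#' @param seed Integer seed; fixed seed gives identical imputations.
#' @return The tibble restricted to eligible features, `log2_intensity`
#'   filled in, plus a logical `imputed` column.
#' @export
impute_missing <- function(quant, level = c("peptide", "protein"),
                           width = NULL, downshift = NULL,
                           min_evidence = 2, seed = 1) {
  level <- match.arg(level)
  width <- width %||% if (level == "peptide") 0.3 else 0.2
  downshift <- downshift %||% if (level == "peptide") 1.8 else 2.5
  stopifnot(all(c("condition", "replicate", "log2_intensity") %in% names(quant)))
  id_cols <- intersect(c("protein", "peptide"), names(quant))
  if (level == "peptide" && !"peptide" %in% id_cols) {
    abort("peptide-level imputation needs a `peptide` column")
  }

  q <- dplyr::mutate(quant,
                     .feature = do.call(paste, c(quant[id_cols], sep = "\r")),
                     .sample = paste0(.data$condition, "_", .data$replicate))

  elig <- q |>
    dplyr::group_by(.data$.feature, .data$condition) |>
    dplyr::summarise(n_obs = sum(!is.na(.data$log2_intensity)), .groups = "drop_last") |>
    dplyr::summarise(eligible = any(.data$n_obs >= min_evidence), .groups = "drop")
  dropped <- elig$.feature[!elig$eligible]
  if (length(dropped) > 0) {
    inform(paste0(length(dropped),
                  " feature(s) without >= ", min_evidence,
                  " observations in any condition dropped before imputation"))
  }
  q <- q[q$.feature %in% elig$.feature[elig$eligible], , drop = FALSE]

  stats_s <- q |>
    dplyr::filter(!is.na(.data$log2_intensity)) |>
    dplyr::group_by(.data$.sample) |>
    dplyr::summarise(mu = mean(.data$log2_intensity),
                     sigma = sd(.data$log2_intensity),
                     n_obs = dplyr::n(), .groups = "drop")
  thin <- setdiff(unique(q$.sample), stats_s$.sample[stats_s$n_obs >= 2])
  if (length(thin) > 0) {
    abort(paste0("sample ", thin[1],
                 " has < 2 observed values; imputation distribution undefined"))
  }

  q <- dplyr::left_join(q, stats_s, by = ".sample")
  miss <- is.na(q$log2_intensity)
  q$imputed <- miss
  with_seed(seed, {
    q$log2_intensity[miss] <- rnorm(sum(miss),
                                    mean = q$mu[miss] - downshift * q$sigma[miss],
                                    sd = width * q$sigma[miss])
  })
  q |> dplyr::select(-dplyr::all_of(c(".feature", ".sample", "mu", "sigma", "n_obs")))
}

#' Test protein enrichment in the IP over the IgG control
#'
#' Reshapes a protein-level log2 quantification to a protein x sample matrix
#' and applies the empirical-Bayes moderated t engine
#' ([moderated_t_test()]), IP versus IgG, with Benjamini-Hochberg adjustment.
#' The reported `log2fc` is mean(IP) - mean(IgG).
#'
#' @param quant Long tibble: `protein`, `condition` (IP / IgG), `replicate`,
#'   `log2_intensity` (finite after imputation).
#' @return A `kd_enrichment` tibble: `protein`, `log2fc`, `t`, `p.value`,
#'   `p_adj`.
#' @export
enrichment_test <- function(quant) {
  stopifnot(all(c("protein", "condition", "replicate", "log2_intensity")
                %in% names(quant)))
  if (!all(unique(quant$condition) %in% c("IP", "IgG"))) {
    abort("conditions must be IP and IgG")
  }
  wide <- quant |>
    dplyr::mutate(sample = paste0(.data$condition, "_", .data$replicate)) |>
    dplyr::select(dplyr::all_of(c("protein", "sample", "log2_intensity"))) |>
    tidyr::pivot_wider(names_from = "sample", values_from = "log2_intensity")
  samples <- setdiff(names(wide), "protein")
  groups <- factor(sub("_.*$", "", samples), levels = c("IgG", "IP"))
  res <- moderated_t_test(wide, groups)
  out <- tibble(protein = res$protein, log2fc = res$log2fc, t = res$t,
                p.value = res$p, p_adj = res$fdr)
  class(out) <- c("kd_enrichment", class(out))
  out
}

#' Flag significant enrichment with a fold-change-dependent p-value curve
#'
#' A protein is significant iff `|log2fc| > fc0` and
#' `-log10(p_adj) >= -log10(p0) + c / (|log2fc| - fc0)`, with
#' `c = s0_mult * sd(log2fc)` over all proteins. The curve makes the maximum
#' admissible adjusted p-value equal `p0` at large fold changes and drives it
#' asymptotically to zero as `|log2fc|` approaches `fc0`, so moderate
#' p-values require large effects. `curve_margin` is the left side minus the
#' right side (`-Inf` when `|log2fc| <= fc0`).
#'
#' @param results A `kd_enrichment` tibble from [enrichment_test()].
#' @param p0 Maximum adjusted p-value at large fold change.
#' @param fc0 Log2 fold-change asymptote.
#' @param s0_mult Curve parameter, in multiples of the overall `sd(log2fc)`.
#' @return `results` with `significant` and `curve_margin` columns.
#' @export
significance_curve <- function(results, p0 = 0.05, fc0 = 1.0, s0_mult = 1.0) {
  if (nrow(results) == 0) {
    return(dplyr::mutate(results, significant = logical(0),
                         curve_margin = numeric(0)))
  }
  cc <- s0_mult * sd(results$log2fc)
  afc <- abs(results$log2fc)
  lhs <- -log10(results$p_adj)
  rhs <- -log10(p0) + ifelse(afc > fc0, cc / (afc - fc0), Inf)
  out <- dplyr::mutate(results,
                       significant = afc > fc0 & lhs >= rhs,
                       curve_margin = lhs - rhs)
  attr(out, "curve") <- list(p0 = p0, fc0 = fc0, s0_mult = s0_mult, c = cc)
  out
}

#' Join two enrichment results into a cross-experiment fold-change table
#'
#' Inner-joins two [enrichment_test()] results by protein (e.g. pulldowns in
#' two cell lines), emitting the two log2 fold changes side by side for a 2D
#' comparison. Proteins must have been quantified in both experiments; the
#' evidence rule (observed in at least two replicates of one condition) is
#' enforced upstream by [impute_missing()] eligibility.
#'
#' @param x,y `kd_enrichment` tibbles.
#' @param suffixes Length-2 character suffixes for the two experiments.
#' @return Tibble: `protein`, `log2fc<suffix>`, `p_adj<suffix>`, and
#'   `significant<suffix>` when present.
#' @export
compare_enrichment <- function(x, y, suffixes = c("_x", "_y")) {
  keep <- intersect(c("protein", "log2fc", "p_adj", "significant"), names(x))
  dplyr::inner_join(x[intersect(keep, names(x))], y[intersect(keep, names(y))],
                    by = "protein", suffix = suffixes)
}

#' Protein log2 ratios from dimethyl-label heavy/light signal-to-noise
#'
#' Applies the canonical dimethyl quantification rules: PSMs with heavy+light
#' S/N sum below `min_sn_sum` are discarded; proteins with fewer than
#' `min_psms` surviving PSMs are dropped; each protein's ratio is the log2 of
#' total experimental-channel S/N over total control-channel S/N. When the
#' control total is zero (the theoretical ideal for a bait-specific partner)
#' a denominator of one is imputed.
#'
#' @param psms Tibble: `protein`, `psm`, `sn_heavy`, `sn_light`.
#' @param experimental_channel Which channel carries the experimental
#'   pulldown (`"heavy"` or `"light"`); the other is the IgG control.
#' @param min_psms Minimum surviving PSMs per protein.
#' @param min_sn_sum Minimum heavy+light S/N per PSM.
#' @return Tibble: `protein`, `n_psms`, `sn_experimental`, `sn_control`,
#'   `control_imputed`, `log2_ratio`.
#' @export
dimethyl_ratios <- function(psms, experimental_channel = c("heavy", "light"),
                            min_psms = 8, min_sn_sum = 10) {
  experimental_channel <- match.arg(experimental_channel)
  stopifnot(all(c("protein", "psm", "sn_heavy", "sn_light") %in% names(psms)))
  if (any(psms$sn_heavy < 0 | psms$sn_light < 0)) abort("S/N must be >= 0")

  exp_col <- paste0("sn_", experimental_channel)
  ctl_col <- if (experimental_channel == "heavy") "sn_light" else "sn_heavy"

  psms |>
    dplyr::filter(.data$sn_heavy + .data$sn_light >= min_sn_sum) |>
    dplyr::group_by(.data$protein) |>
    dplyr::summarise(n_psms = dplyr::n(),
                     sn_experimental = sum(.data[[exp_col]]),
                     sn_control = sum(.data[[ctl_col]]),
                     .groups = "drop") |>
    dplyr::filter(.data$n_psms >= min_psms) |>
    dplyr::mutate(control_imputed = .data$sn_control == 0,
                  log2_ratio = log2(.data$sn_experimental /
                                      dplyr::if_else(.data$control_imputed,
                                                     1, .data$sn_control)))
}
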