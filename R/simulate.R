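#' Simulate a knock-down versus control RNA-seq count experiment
#'
#' Generates negative-binomial gene counts for a two-arm siRNA knock-down
#' design (knock-down vs scrambled control) with a two-level batch factor and
#' a planted set of truly differential genes, mirroring the structure of a
#' cell-line perturbation experiment. Counts are NB with variance
#' `mu + dispersion * mu^2` (mean--dispersion parameterization).
#'
#' Half of the planted genes are up-regulated and half down-regulated in the
#' knock-down arm by `log2fc_magnitude` on the log2 scale. Replicates within
#' each arm are assigned alternately to batches `b1`/`b2`; batch `b2` carries a
#' per-gene multiplicative effect `2^N(0, batch_effect_sd^2)`.
#'
#' @param n_genes Number of genes.
#' @param n_replicates_per_arm Replicates per arm (>= 2).
#' @param n_true_de Number of truly differential genes (<= `n_genes`).
#' @param log2fc_magnitude Absolute planted log2 fold change.
#' @param dispersion NB dispersion (> 0).
#' @param baseline_log_mean Mean of the per-gene log2 baseline expression.
#' @param batch_effect_sd SD (log2 scale) of the per-gene batch effect.
#' @param seed Integer seed; fixed seed gives identical output.
#'
#' @return A list with `counts` (tibble: `gene` + one column per sample),
#'   `design` (tibble: `sample`, `group` in \{control, knockdown\}, `batch`),
#'   and `truth` (tibble: `gene`, `log2fc` for the planted genes).
#' @export
simulate_kd_counts <- function(n_genes = 2000,
                               n_replicates_per_arm = 3,
                               n_true_de = 400,
                               log2fc_magnitude = 2,
                               dispersion = 0.1,
                               baseline_log_mean = 6,
                               batch_effect_sd = 0.15,
                               seed = 1) {
  n_genes <- check_count(n_genes, "n_genes")
  n_replicates_per_arm <- check_count(n_replicates_per_arm, "n_replicates_per_arm", min = 2L)
  n_true_de <- check_count(n_true_de, "n_true_de", min = 0L)
  if (n_true_de > n_genes) abort("`n_true_de` must be <= `n_genes`")
  dispersion <- check_positive(dispersion, "dispersion")
  log2fc_magnitude <- check_nonneg(log2fc_magnitude, "log2fc_magnitude")
  batch_effect_sd <- check_nonneg(batch_effect_sd, "batch_effect_sd")

  with_seed(seed, {
    genes <- sprintf("g%04d", seq_len(n_genes))
    base_log2 <- rnorm(n_genes, baseline_log_mean, 1.5)
    lfc <- numeric(n_genes)
    if (n_true_de > 0) {
      sgn <- rep(c(1, -1), length.out = n_true_de)
      lfc[seq_len(n_true_de)] <- sgn * log2fc_magnitude
    }
    batch_fx <- rnorm(n_genes, 0, batch_effect_sd)

    groups <- rep(c("control", "knockdown"), each = n_replicates_per_arm)
    batches <- rep_len(c("b1", "b2"), 2L * n_replicates_per_arm)
    samples <- paste0(ifelse(groups == "control", "ctrl_", "kd_"),
                      rep(seq_len(n_replicates_per_arm), 2))

    counts <- vapply(seq_along(samples), function(s) {
      mu_log2 <- base_log2 +
        (groups[s] == "knockdown") * lfc +
        (batches[s] == "b2") * batch_fx
      rnbinom(n_genes, mu = 2^mu_log2, size = 1 / dispersion)
    }, numeric(n_genes))
    dimnames(counts) <- list(genes, samples)

    list(
      counts = matrix_to_expr(counts),
      design = tibble(sample = samples, group = groups, batch = batches),
      truth = tibble(gene = genes[seq_len(n_true_de)],
                     log2fc = lfc[seq_len(n_true_de)])
    )
  })
}

#' Simulate a multi-state clinical cohort with a planted signature shift
#'
#' Generates log-scale expression for a cohort spanning the disease states
#' benign, PCa, CRPC-Adeno and CRPC-NE. Each CRPC-NE sample is shifted on the
#' signature genes by `effect_size_sd` within-cohort standard deviations,
#' sign-concordant with each gene's direction, so a direction-weighted score
#' separates CRPC-NE from the other states. The annotation carries an ordinal
#' Gleason grade group (1--5, proportional-odds link on a per-sample latent
#' aggressiveness) and a continuous risk score in (0, 1) derived from the same
#' latent, so trend and rank tests have an honest association to detect.
#'
#' @param n_samples_per_state Named integer vector; names from
#'   `c("benign", "PCa", "CRPC-Adeno", "CRPC-NE")`.
#' @param signature_genes Tibble with columns `gene` and `direction` (+1/-1).
#' @param effect_size_sd Shift applied to CRPC-NE samples on signature genes,
#'   in units of the within-state expression SD (>= 0).
#' @param noise_sd Within-state expression SD.
#' @param n_background_genes Genes carrying no signal.
#' @param seed Integer seed.
#'
#' @return List with `expr` (log-scale tibble, `gene` + sample columns),
#'   `annotation` (tibble: `sample`, `state`, `gleason_group`, `risk_score`)
#'   and `truth` (list: `state_of_sample`, `latent_aggressiveness`,
#'   `shifted_genes`).
#' @export
simulate_cohort <- function(n_samples_per_state = c("CRPC-Adeno" = 120, "CRPC-NE" = 60),
                            signature_genes,
                            effect_size_sd = 1.5,
                            noise_sd = 1,
                            n_background_genes = 1000,
                            seed = 1) {
  if (is.null(names(n_samples_per_state))) {
    abort("`n_samples_per_state` must be a named vector of state counts")
  }
  check_states(names(n_samples_per_state))
  effect_size_sd <- check_nonneg(effect_size_sd, "effect_size_sd")
  noise_sd <- check_positive(noise_sd, "noise_sd")
  n_background_genes <- check_count(n_background_genes, "n_background_genes", min = 0L)
  stopifnot(is.data.frame(signature_genes),
            all(c("gene", "direction") %in% names(signature_genes)))
  if (any(n_samples_per_state < 0)) abort("negative sample counts")

  with_seed(seed, {
    states <- rep(names(n_samples_per_state), times = n_samples_per_state)
    n <- length(states)
    samples <- sprintf("s%03d", seq_len(n))

    sig <- tibble(gene = as.character(signature_genes$gene),
                  direction = sign(signature_genes$direction))
    bg_genes <- if (n_background_genes > 0) {
      sprintf("bg%04d", seq_len(n_background_genes))
    } else character()
    genes <- c(sig$gene, bg_genes)

    base <- rnorm(length(genes), 0, 1)
    expr <- base + matrix(rnorm(length(genes) * n, 0, noise_sd),
                          nrow = length(genes))
    is_ne <- states == "CRPC-NE"
    if (any(is_ne) && nrow(sig) > 0) {
      shift <- sig$direction * effect_size_sd * noise_sd
      expr[seq_len(nrow(sig)), is_ne] <- expr[seq_len(nrow(sig)), is_ne] + shift
    }
    dimnames(expr) <- list(genes, samples)

    # latent aggressiveness rises along the disease-state ordering
    severity <- c("benign" = -1.5, "PCa" = -0.5,
                  "CRPC-Adeno" = 0.5, "CRPC-NE" = 1.5)
    latent <- severity[states] + rnorm(n, 0, 1)
    cutpoints <- c(-2, -0.75, 0.75, 2)
    gleason <- 1L + vapply(latent, function(a) {
      sum(a + stats::rlogis(length(cutpoints)) > cutpoints)
    }, integer(1))
    risk <- plogis(latent)

    list(
      expr = matrix_to_expr(expr),
      annotation = tibble(sample = samples, state = states,
                          gleason_group = gleason, risk_score = risk),
      truth = list(state_of_sample = setNames(states, samples),
                   latent_aggressiveness = setNames(latent, samples),
                   shifted_genes = sig)
    )
  })
}

#' Simulate a bait--prey co-IP peptide intensity table with MNAR dropout
#'
#' Generates log-normal peptide intensities for an immunoprecipitation (IP)
#' versus IgG isotype-control design. A planted set of bait-partner proteins
#' is enriched by `enrichment_log2` (log2 units) in the IP condition. Each
#' intensity is independently set missing with probability
#' `plogis(-missingness_steepness * (log2(I) - missingness_midpoint))`, i.e.
#' dropout probability strictly decreases with intensity (missing not at
#' random, the left-censoring regime downshifted imputation assumes). A
#' midpoint of `-Inf` disables missingness entirely.
#'
#' @param n_proteins Total proteins.
#' @param n_bait_partners Number of enriched partner proteins (<= `n_proteins`).
#' @param enrichment_log2 Planted IP enrichment, log2 units.
#' @param n_replicates Replicates per condition.
#' @param missingness_steepness Logistic slope of dropout vs log2 intensity.
#' @param missingness_midpoint Log2 intensity at 50% dropout (`-Inf` for none).
#' @param peptides_per_protein Length-2 integer range of peptides per protein.
#' @param base_log2_intensity Mean log2 intensity of protein baselines.
#' @param seed Integer seed.
#'
#' @return List with `peptides` (tibble: `protein`, `peptide`, `condition`
#'   in \{IP, IgG\}, `replicate`, `intensity` with `NA` for missing) and
#'   `truth` (tibble of partner proteins).
#' @export
simulate_coip_peptides <- function(n_proteins = 800,
                                   n_bait_partners = 20,
                                   enrichment_log2 = 3,
                                   n_replicates = 3,
                                   missingness_steepness = 1,
                                   missingness_midpoint = 20,
                                   peptides_per_protein = c(2L, 8L),
                                   base_log2_intensity = 24,
                                   seed = 1) {
  n_proteins <- check_count(n_proteins, "n_proteins")
  n_bait_partners <- check_count(n_bait_partners, "n_bait_partners", min = 0L)
  if (n_bait_partners > n_proteins) abort("`n_bait_partners` must be <= `n_proteins`")
  n_replicates <- check_count(n_replicates, "n_replicates", min = 2L)
  if (missingness_steepness < 0) abort("`missingness_steepness` must be >= 0")
  stopifnot(length(peptides_per_protein) == 2)

  with_seed(seed, {
    proteins <- sprintf("P%04d", seq_len(n_proteins))
    partners <- proteins[seq_len(n_bait_partners)]
    n_pep <- sample(seq(peptides_per_protein[1], peptides_per_protein[2]),
                    n_proteins, replace = TRUE)

    prot_base <- rnorm(n_proteins, base_log2_intensity, 2)
    tab <- tidyr::expand_grid(
      idx = seq_len(n_proteins),
      condition = c("IP", "IgG"),
      replicate = seq_len(n_replicates)
    )
    rows <- purrr::pmap(tab, function(idx, condition, replicate) {
      k <- n_pep[idx]
      pep_off <- rnorm(k, 0, 1)  # same peptide ids across replicates, fresh noise
      log2i <- prot_base[idx] + pep_off +
        (condition == "IP" && proteins[idx] %in% partners) * enrichment_log2 +
        rnorm(k, 0, 0.5)
      tibble(protein = proteins[idx],
             peptide = paste0(proteins[idx], "_pep", seq_len(k)),
             condition = condition, replicate = replicate,
             intensity = 2^log2i)
    })
    peptides <- dplyr::bind_rows(rows)

    p_drop <- if (is.infinite(missingness_midpoint) && missingness_midpoint < 0) {
      rep(0, nrow(peptides))
    } else {
      plogis(-missingness_steepness *
               (log2(peptides$intensity) - missingness_midpoint))
    }
    drop <- runif(nrow(peptides)) < p_drop
    peptides$intensity[drop] <- NA_real_

    list(peptides = peptides, truth = tibble(protein = partners))
  })
}

#' Simulate a dimethyl-label PSM table with heavy/light signal-to-noise
#'
#' Generates peptide-spectrum matches (PSMs) with gamma-distributed heavy and
#' light channel signal-to-noise (S/N), emulating a reductive-dimethylation
#' co-IP in which one channel carries the experimental pulldown and the other
#' the IgG control. Partner proteins receive `enrichment_log2` extra signal in
#' the experimental channel. To exercise downstream filters, a fraction of
#' proteins is given fewer than `min_psms_planted` PSMs, a fraction of PSMs is
#' scaled to a heavy+light S/N sum below 10, and `n_control_absent` partner
#' proteins have all control-channel S/N set to zero.
#'
#' @param n_proteins Total proteins.
#' @param n_partners Enriched partner proteins.
#' @param enrichment_log2 Log2 enrichment of partners in the experimental channel.
#' @param psms_per_protein Length-2 range of PSMs per protein.
#' @param sn_shape,sn_scale Gamma shape/scale of baseline channel S/N.
#' @param frac_low_psm Fraction of proteins forced below `min_psms_planted` PSMs.
#' @param min_psms_planted PSM count threshold the low-PSM proteins fall under.
#' @param frac_low_sn Fraction of PSMs scaled to an S/N sum below 10.
#' @param n_control_absent Partner proteins with all-zero control S/N.
#' @param experimental_channel `"heavy"` or `"light"`.
#' @param seed Integer seed.
#'
#' @return List with `psms` (tibble: `protein`, `psm`, `sn_heavy`, `sn_light`),
#'   `experimental_channel`, and `truth` (list: `partners`,
#'   `control_absent`, `low_psm_proteins`).
#' @export
simulate_dimethyl_psms <- function(n_proteins = 300,
                                   n_partners = 20,
                                   enrichment_log2 = 3,
                                   psms_per_protein = c(10L, 30L),
                                   sn_shape = 2,
                                   sn_scale = 20,
                                   frac_low_psm = 0.1,
                                   min_psms_planted = 8,
                                   frac_low_sn = 0.05,
                                   n_control_absent = 2,
                                   experimental_channel = c("heavy", "light"),
                                   seed = 1) {
  n_proteins <- check_count(n_proteins, "n_proteins")
  n_partners <- check_count(n_partners, "n_partners", min = 0L)
  if (n_partners > n_proteins) abort("`n_partners` must be <= `n_proteins`")
  experimental_channel <- match.arg(experimental_channel)

  with_seed(seed, {
    proteins <- sprintf("Q%04d", seq_len(n_proteins))
    partners <- proteins[seq_len(n_partners)]
    n_low_psm <- floor(frac_low_psm * n_proteins)
    low_psm <- if (n_low_psm > 0) {
      sample(setdiff(proteins, partners), n_low_psm)
    } else character()
    control_absent <- head(partners, n_control_absent)

    n_psm <- sample(seq(psms_per_protein[1], psms_per_protein[2]),
                    n_proteins, replace = TRUE)
    n_psm[proteins %in% low_psm] <- sample(seq_len(max(1, min_psms_planted - 1)),
                                           sum(proteins %in% low_psm),
                                           replace = TRUE)

    psms <- purrr::map2_dfr(proteins, n_psm, function(p, k) {
      exp_sn <- rgamma(k, sn_shape, scale = sn_scale) *
        if (p %in% partners) 2^enrichment_log2 else 1
      ctl_sn <- if (p %in% control_absent) rep(0, k) else rgamma(k, sn_shape, scale = sn_scale)
      tibble(protein = p, psm = paste0(p, "_psm", seq_len(k)),
             sn_exp = exp_sn, sn_ctl = ctl_sn)
    })

    # plant PSMs whose heavy+light sum falls below the canonical S/N filter
    n_low_sn <- floor(frac_low_sn * nrow(psms))
    if (n_low_sn > 0) {
      idx <- sample(nrow(psms), n_low_sn)
      tot <- psms$sn_exp[idx] + psms$sn_ctl[idx]
      f <- runif(n_low_sn, 1, 9.5) / pmax(tot, 1e-9)
      psms$sn_exp[idx] <- psms$sn_exp[idx] * f
      psms$sn_ctl[idx] <- psms$sn_ctl[idx] * f
    }

    if (experimental_channel == "heavy") {
      out <- tibble(protein = psms$protein, psm = psms$psm,
                    sn_heavy = psms$sn_exp, sn_light = psms$sn_ctl)
    } else {
      out <- tibble(protein = psms$protein, psm = psms$psm,
                    sn_heavy = psms$sn_ctl, sn_light = psms$sn_exp)
    }
    list(psms = out,
         experimental_channel = experimental_channel,
         truth = list(partners = partners, control_absent = control_absent,
                      low_psm_proteins = low_psm))
  })
}

#' Simulate per-gene loss-of-heterozygosity calls across disease states
#'
#' For each sample, every gene independently receives a loss-of-heterozygosity
#' call with the planted probability of the sample's disease state; LOH calls
#' are split evenly between hemizygous deletion and copy-number-neutral LOH
#' (CNNL), the two categories a two-proportion enrichment test pools.
#'
#' @param states Character vector, one disease state per sample.
#' @param per_state_fractions Named numeric vector of LOH probabilities in
#'   `[0, 1]`, one entry per state present in `states`.
#' @param n_genes Number of genes.
#' @param seed Integer seed.
#'
#' @return List with `loh` (tibble: `gene` + one character column per sample,
#'   values in \{none, hemizygous_deletion, CNNL\}), `annotation` (tibble:
#'   `sample`, `state`) and `truth` (the planted fractions).
#' @export
simulate_loh_calls <- function(states, per_state_fractions, n_genes = 50, seed = 1) {
  check_states(states)
  missing_frac <- setdiff(unique(states), names(per_state_fractions))
  if (length(missing_frac) > 0) {
    abort(paste0("no planted fraction for state(s): ",
                 paste(missing_frac, collapse = ", ")))
  }
  if (any(per_state_fractions < 0 | per_state_fractions > 1)) {
    abort("fractions must lie in [0, 1]")
  }
  n_genes <- check_count(n_genes, "n_genes")

  with_seed(seed, {
    genes <- sprintf("g%03d", seq_len(n_genes))
    samples <- sprintf("s%03d", seq_along(states))
    calls <- vapply(seq_along(states), function(s) {
      p <- per_state_fractions[[states[s]]]
      loh <- runif(n_genes) < p
      type <- ifelse(runif(n_genes) < 0.5, "hemizygous_deletion", "CNNL")
      ifelse(loh, type, "none")
    }, character(n_genes))
    calls <- matrix(calls, nrow = n_genes, dimnames = list(genes, samples))
    list(
      loh = tibble::as_tibble(calls, rownames = "gene"),
      annotation = tibble(sample = samples, state = states),
      truth = list(per_state_fractions = per_state_fractions)
    )
  })
}
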