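# Readers and writers for the plain-text (TSV, UTF-8, header row) tables the
# pipeline exchanges. All readers validate shape and identifiers up front and
# name the offending row/column in their error messages.

#' Read a gene-by-sample expression or count matrix from TSV
#'
#' The first column must be named `gene`; every other column is one sample.
#' Windows (`\r\n`) line endings are accepted. Duplicate gene or sample ids,
#' ragged rows, and non-numeric cells are rejected with an error naming the
#' culprit.
#'
#' @param path Path to a tab-separated file with a header row.
#' @return A tibble with a `gene` column and numeric sample columns, rows in
#'   file order.
#' @export
read_expression_matrix <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (!"gene" %in% names(raw)) abort("expression file must have a `gene` column")
  if (anyDuplicated(names(raw))) {
    abort(paste0("duplicate sample id: ", names(raw)[duplicated(names(raw))][1]))
  }
  if (anyDuplicated(raw$gene)) {
    abort(paste0("duplicate gene id: ", raw$gene[duplicated(raw$gene)][1]))
  }
  prob <- readr::problems(raw)
  if (nrow(prob) > 0) {
    abort(paste0("ragged or malformed row ", prob$row[1], " in ", path))
  }
  for (col in setdiff(names(raw), "gene")) {
    vals <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(vals) & !is.na(raw[[col]]))
    if (length(bad) > 0) {
      abort(paste0("non-numeric value in column `", col, "`, row ", bad[1],
                   " (gene ", raw$gene[bad[1]], ")"))
    }
    raw[[col]] <- vals
  }
  raw
}

#' Write a gene-by-sample matrix as TSV
#'
#' Inverse of [read_expression_matrix()]; round-trips integer counts exactly
#' and reals to full double precision.
#'
#' @param expr Tibble with `gene` column plus numeric sample columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(expr, path) {
  expr_to_matrix(expr)  # validates
  readr::write_tsv(expr, path, progress = FALSE)
  invisible(path)
}

#' Read a per-sample annotation table
#'
#' Requires columns `sample` and `state` (states limited to benign, PCa,
#' CRPC-Adeno, CRPC-NE); optional columns `gleason_group` (ordinal 1--5),
#' `risk_score`, `event` (0/1) and `time` (>= 0). Optional columns that are
#' absent from the file stay absent (they are never zero-filled).
#'
#' @param path Path to a TSV file.
#' @return A tibble, one row per sample.
#' @export
read_sample_annotation <- function(path) {
  ann <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  if (!all(c("sample", "state") %in% names(ann))) {
    abort("annotation must have `sample` and `state` columns")
  }
  check_states(ann$state)
  if (anyDuplicated(ann$sample)) {
    abort(paste0("duplicate sample id: ", ann$sample[duplicated(ann$sample)][1]))
  }
  if ("gleason_group" %in% names(ann)) {
    g <- ann$gleason_group
    if (any(!is.na(g) & (g < 1 | g > 5 | g != floor(g)))) {
      abort("`gleason_group` must be ordinal 1-5")
    }
  }
  if ("time" %in% names(ann) && any(ann$time < 0, na.rm = TRUE)) {
    abort("`time` must be >= 0")
  }
  ann
}

#' Write a per-sample annotation table as TSV
#' @param annotation Tibble with `sample` and `state` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_annotation <- function(annotation, path) {
  check_states(annotation$state)
  readr::write_tsv(annotation, path, progress = FALSE)
  invisible(path)
}

#' Read a signature model from TSV
#'
#' The file is tab-separated with columns `gene`, `weight`, `direction`,
#' `rank`, preceded by `#`-prefixed `key: value` metadata lines recording how
#' the signature was derived (thresholds, top-N, weight mode).
#'
#' @param path Path to a signature TSV.
#' @return A `kd_signature` object (see [derive_signature()]).
#' @export
read_signature <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  meta_lines <- lines[startsWith(lines, "#")]
  meta <- list()
  for (l in meta_lines) {
    kv <- stringr::str_match(l, "^#\\s*([^:]+):\\s*(.*)$")
    if (!is.na(kv[1, 2])) {
      val <- kv[1, 3]
      num <- suppressWarnings(as.numeric(val))
      meta[[stringr::str_trim(kv[1, 2])]] <- if (!is.na(num)) num else val
    }
  }
  body <- readr::read_tsv(I(lines[!startsWith(lines, "#")]),
                          col_types = readr::cols(
                            gene = readr::col_character(),
                            weight = readr::col_double(),
                            direction = readr::col_integer(),
                            rank = readr::col_integer()
                          ), progress = FALSE)
  if (anyDuplicated(body$gene)) {
    abort(paste0("duplicate gene in signature: ",
                 body$gene[duplicated(body$gene)][1]))
  }
  bad <- body$weight != 0 & body$direction != sign(body$weight)
  if (any(bad)) {
    abort(paste0("direction disagrees with sign(weight) for gene ",
                 body$gene[which(bad)[1]]))
  }
  new_kd_signature(body, derivation = meta)
}

#' Write a signature model as TSV with a commented metadata header
#' @param signature A `kd_signature` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signature <- function(signature, path) {
  stopifnot(inherits(signature, "kd_signature"))
  meta <- signature$derivation
  hdr <- purrr::imap_chr(meta, ~ paste0("# ", .y, ": ", .x))
  body <- readr::format_tsv(signature$genes[c("gene", "weight", "direction", "rank")])
  readr::write_lines(c(hdr, strsplit(body, "\n", fixed = TRUE)[[1]]), path)
  invisible(path)
}

#' Read a MaxQuant-style wide quantification table into long format
#'
#' Accepts the wide dialect with one row per protein (or peptide) and one
#' `"<prefix> <sample>"` column per sample, e.g. `LFQ intensity IP_1`. Zero
#' and empty intensity cells are read as missing (`NA`), never as numeric
#' zero — the convention of the source format, where 0 encodes "not
#' quantified".
#'
#' @param path Path to the TSV file.
#' @param design Tibble with columns `sample`, `condition`, `replicate`
#'   mapping each sample column onto the experimental design.
#' @param id_col Name of the identifier column (default `"Protein IDs"`).
#' @param intensity_prefix Column prefix before the sample name.
#' @param peptide_col Optional peptide id column to carry through.
#' @return A long tibble: `protein` (and `peptide` if requested), `condition`,
#'   `replicate`, `intensity` (`NA` when missing).
#' @export
read_quant_table <- function(path, design,
                             id_col = "Protein IDs",
                             intensity_prefix = "LFQ intensity",
                             peptide_col = NULL) {
  stopifnot(all(c("sample", "condition", "replicate") %in% names(design)))
  wide <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  if (!id_col %in% names(wide)) {
    abort(paste0("id column `", id_col, "` absent from ", path))
  }
  wanted <- paste(intensity_prefix, design$sample)
  missing_cols <- setdiff(wanted, names(wide))
  if (length(missing_cols) > 0) {
    abort(paste0("design column `", missing_cols[1], "` absent from file"))
  }
  keep <- c(id_col, peptide_col, wanted)
  long <- wide[keep] |>
    tidyr::pivot_longer(dplyr::all_of(wanted),
                        names_to = "sample", values_to = "intensity") |>
    dplyr::mutate(sample = stringr::str_remove(
      .data$sample, paste0("^", stringr::fixed(paste0(intensity_prefix, " "))))) |>
    dplyr::left_join(design, by = "sample") |>
    dplyr::mutate(intensity = dplyr::if_else(
      !is.na(.data$intensity) & .data$intensity == 0,
      NA_real_, as.numeric(.data$intensity)))
  out <- dplyr::rename(long, protein = dplyr::all_of(id_col))
  if (!is.null(peptide_col)) out <- dplyr::rename(out, peptide = dplyr::all_of(peptide_col))
  cols <- c("protein", if (!is.null(peptide_col)) "peptide",
            "condition", "replicate", "intensity")
  out[cols]
}

#' Write a long quantification table in the wide MaxQuant-style dialect
#'
#' Missing intensities are written as 0 per the source convention, so the
#' table round-trips through [read_quant_table()].
#'
#' @param quant Long tibble with `protein`, optional `peptide`, `condition`,
#'   `replicate`, `intensity`.
#' @param path Output path.
#' @param intensity_prefix Column prefix to use.
#' @return `path`, invisibly.
#' @export
write_quant_table <- function(quant, path, intensity_prefix = "LFQ intensity") {
  has_pep <- "peptide" %in% names(quant)
  wide <- quant |>
    dplyr::mutate(col = paste(intensity_prefix,
                              paste0(.data$condition, "_", .data$replicate)),
                  intensity = dplyr::coalesce(.data$intensity, 0)) |>
    dplyr::select(dplyr::all_of(c("protein", if (has_pep) "peptide", "col", "intensity"))) |>
    tidyr::pivot_wider(names_from = "col", values_from = "intensity",
                       values_fill = 0)
  names(wide)[names(wide) == "protein"] <- "Protein IDs"
  if (has_pep) names(wide)[names(wide) == "peptide"] <- "Sequence"
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}

#' Read / write a pipeline configuration (YAML-compatible key-value file)
#'
#' @param path Path to the YAML file.
#' @return `read_pipeline_config()`: a named list. `write_pipeline_config()`:
#'   `path`, invisibly.
#' @export
read_pipeline_config <- function(path) {
  yaml::read_yaml(path)
}

#' @rdname read_pipeline_config
#' @param config Named list of stage-block parameters.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
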