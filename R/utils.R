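# Internal helpers shared across modules.

# Expression tables are tibbles with a `gene` id column followed by one
# numeric column per sample. These two helpers convert to/from the matrix
# form the numerical code works on, preserving ids and order.
expr_to_matrix <- function(expr) {
  stopifnot(is.data.frame(expr))
  if (!"gene" %in% names(expr)) {
    abort("expression table must have a `gene` column")
  }
  if (anyDuplicated(expr$gene)) {
    dup <- expr$gene[duplicated(expr$gene)][1]
    abort(paste0("duplicate gene id: ", dup))
  }
  m <- as.matrix(expr[setdiff(names(expr), "gene")])
  if (!is.numeric(m)) abort("expression values must be numeric")
  rownames(m) <- expr$gene
  m
}

matrix_to_expr <- function(m) {
  tibble::as_tibble(m, rownames = "gene")
}

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1 || is.na(x) || x < min || x != floor(x)) {
    abort(paste0("`", name, "` must be a single integer >= ", min))
  }
  as.integer(x)
}

check_positive <- function(x, name) {
  if (length(x) != 1 || is.na(x) || x <= 0) {
    abort(paste0("`", name, "` must be a single positive number"))
  }
  as.numeric(x)
}

check_nonneg <- function(x, name) {
  if (length(x) != 1 || is.na(x) || x < 0) {
    abort(paste0("`", name, "` must be a single non-negative number"))
  }
  as.numeric(x)
}

# States a cohort annotation may carry, in disease-progression order.
cohort_states <- function() c("benign", "PCa", "CRPC-Adeno", "CRPC-NE")

check_states <- function(states) {
  bad <- setdiff(states, cohort_states())
  if (length(bad) > 0) {
    abort(paste0("unknown state label(s): ", paste(bad, collapse = ", ")))
  }
  invisible(states)
}

# Deterministic per-stage seed from a global seed and a stage name: a small
# multiplicative string hash folded into [0, 2^31 - 2]. Documented so runs
# are reproducible stage by stage, independent of stage order.
derive_seed <- function(seed, stage) {
  stopifnot(length(seed) == 1, !is.na(seed))
  h <- as.double(seed %% 2147483647L)
  for (code in utf8ToInt(stage)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
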