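# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG state when `seed` is given, without
# disturbing the caller's RNG stream; with seed = NULL the global stream is
# used (and advanced) as usual.
with_seed_or_global <- function(seed, expr) {
  if (is.null(seed)) {
    expr
  } else {
    withr::with_seed(as.integer(seed), expr)
  }
}

# Deterministic per-stage seed: master seed plus the sum of the stage name's
# UTF-8 code points. Adding a stage never perturbs another stage's stream.
stage_seed <- function(seed, stage) {
  offset <- sum(utf8ToInt(stage))
  as.integer((as.numeric(seed) + offset) %% .Machine$integer.max)
}

# Smallest p-value we ever report; avoids log/qnorm underflow downstream.
P_FLOOR <- 1e-300

floor_p <- function(p) pmin(pmax(p, P_FLOOR), 1)

# Signed z-score from a two-sided p-value.
z_from_p <- function(p, sign_of) {
  sign(sign_of) * qnorm(p / 2, lower.tail = FALSE)
}

check_fraction <- function(x, name, open_low = FALSE, open_high = FALSE) {
  ok <- is.numeric(x) && length(x) == 1 && is.finite(x) &&
    (if (open_low) x > 0 else x >= 0) &&
    (if (open_high) x < 1 else x <= 1)
  if (!ok) {
    abort(sprintf("`%s` must be a fraction in %s0, 1%s, got %s",
                  name, if (open_low) "(" else "[",
                  if (open_high) ")" else "]", format(x)))
  }
  invisible(x)
}

# Convert an OTU tibble (sample_id + one numeric column per OTU) to a matrix
# with sample_id as rownames.
otu_matrix <- function(tbl) {
  stopifnot(is.data.frame(tbl), "sample_id" %in% names(tbl))
  m <- as.matrix(tbl[setdiff(names(tbl), "sample_id")])
  rownames(m) <- tbl$sample_id
  storage.mode(m) <- "double"
  m
}

# Inverse of otu_matrix().
matrix_to_tbl <- function(m) {
  out <- as_tibble(m)
  tibble(sample_id = rownames(m)) |> dplyr::bind_cols(out)
}

# Abundance tables downstream of filter_otus() are deliberately NOT
# renormalized, so rows may sum to less than 1; only cell-level validity is
# checked here.
validate_abundance <- function(tbl) {
  if (!is.data.frame(tbl) || names(tbl)[1] != "sample_id") {
    abort("abundance table must be a data frame whose first column is `sample_id`")
  }
  if (anyDuplicated(tbl$sample_id)) abort("duplicate sample ids")
  if (ncol(tbl) > 1) {
    m <- otu_matrix(tbl)
    if (any(!is.finite(m)) || any(m < 0) || any(m > 1)) {
      abort("relative abundances must be fractions in [0, 1]")
    }
  }
  invisible(tbl)
}

align_samples <- function(tbl, pheno) {
  if (!setequal(tbl$sample_id, pheno$sample_id)) {
    missing_a <- setdiff(pheno$sample_id, tbl$sample_id)
    missing_b <- setdiff(tbl$sample_id, pheno$sample_id)
    abort(paste0(
      "sample sets of the abundance table and phenotype frame differ",
      if (length(missing_a)) paste0("; absent from table: ",
                                    paste(head(missing_a, 5), collapse = ", ")),
      if (length(missing_b)) paste0("; absent from phenotype: ",
                                    paste(head(missing_b, 5), collapse = ", "))
    ))
  }
  pheno[match(tbl$sample_id, pheno$sample_id), ]
}
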