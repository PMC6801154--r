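# Small fixture builders shared across test files.

# Random count tibble with the canonical layout.
rand_counts <- function(n, m, lambda = 20, seed = NULL) {
  gen <- function() {
    cnt <- matrix(rpois(n * m, lambda), n, m)
    dimnames(cnt) <- list(sprintf("s%02d", seq_len(n)),
                          sprintf("OTU%03d", seq_len(m)))
    dplyr::bind_cols(tibble::tibble(sample_id = rownames(cnt)),
                     tibble::as_tibble(cnt))
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# Random relative-abundance tibble (rows sum to 1) with optional zeros.
rand_rel <- function(n, m, zero_frac = 0.3, seed = NULL) {
  gen <- function() {
    a <- matrix(rexp(n * m), n, m)
    a[matrix(runif(n * m) < zero_frac, n, m)] <- 0
    a[rowSums(a) == 0, 1] <- 1
    a <- a / rowSums(a)
    dimnames(a) <- list(sprintf("s%02d", seq_len(n)),
                        sprintf("OTU%03d", seq_len(m)))
    dplyr::bind_cols(tibble::tibble(sample_id = rownames(a)),
                     tibble::as_tibble(a))
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# Phenotype tibble already carrying adjusted values (centered).
pheno_adj <- function(y, ids = sprintf("s%02d", seq_along(y))) {
  tibble::tibble(sample_id = ids, phenotype_adj = y - mean(y))
}

# Rand index between two partitions.
rand_index <- function(a, b) {
  n <- length(a)
  same_a <- outer(a, a, "==")[upper.tri(diag(n))]
  same_b <- outer(b, b, "==")[upper.tri(diag(n))]
  mean(same_a == same_b)
}

write_tsv_fixture <- function(lines) {
  tf <- tempfile(fileext = ".tsv")
  writeLines(lines, tf)
  tf
}
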