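#' Rarefy an OTU count table to a fixed library size
#'
#' Subsamples each sample's tags without replacement (multivariate
#' hypergeometric) down to `depth`, the standard way of equalizing library
#' size before comparing samples. Samples whose library is already exactly
#' `depth` are returned unchanged; samples with fewer tags than `depth` are
#' dropped with a warning.
#'
#' @param table OTU count tibble (samples as rows).
#' @param depth Positive integer target library size (e.g. 40000).
#' @param seed Optional integer; fixes the subsampling so repeated calls are
#'   bit-identical.
#' @return A rarefied count tibble; every row sums exactly to `depth`.
#' @export
rarefy <- function(table, depth, seed = NULL) {
  validate_otu_table(table, "counts")
  if (!is.numeric(depth) || length(depth) != 1 || depth <= 0 || depth != round(depth)) {
    abort("`depth` must be a positive integer")
  }
  m <- otu_matrix(table)
  totals <- rowSums(m)
  keep <- totals >= depth
  if (any(!keep)) {
    warn(sprintf("dropping %d sample(s) below depth %d: %s",
                 sum(!keep), depth,
                 paste(rownames(m)[!keep], collapse = ", ")))
    m <- m[keep, , drop = FALSE]
    totals <- totals[keep]
  }
  if (nrow(m) == 0) abort("no samples at or above the rarefaction depth")
  with_seed_or_global(seed, {
    for (i in seq_len(nrow(m))) {
      if (totals[i] == depth) next
      m[i, ] <- mv_hypergeom(m[i, ], depth)
    }
  })
  storage.mode(m) <- "integer"
  matrix_to_tbl(m)
}

# Draw from the multivariate hypergeometric: `k` tags sampled without
# replacement from an urn with `counts[j]` tags of category j.
mv_hypergeom <- function(counts, k) {
  out <- numeric(length(counts))
  remaining <- sum(counts)
  for (j in seq_along(counts)) {
    if (k <= 0) break
    cj <- counts[j]
    x <- rhyper(1, m = cj, n = remaining - cj, k = k)
    out[j] <- x
    k <- k - x
    remaining <- remaining - cj
  }
  out
}

#' Convert counts to relative abundances
#'
#' Divides each sample's counts by its library size so rows sum to one.
#'
#' @param table OTU count tibble.
#' @return Relative-abundance tibble (same shape, fractions in \[0, 1\]).
#' @export
to_relative <- function(table) {
  validate_otu_table(table, "counts")
  m <- otu_matrix(table)
  rs <- rowSums(m)
  if (any(rs == 0)) {
    abort(sprintf("all-zero sample(s): %s",
                  paste(rownames(m)[rs == 0], collapse = ", ")))
  }
  matrix_to_tbl(m / rs)
}

#' Filter OTUs by mean abundance and prevalence
#'
#' Retains OTUs whose mean relative abundance across all samples is at least
#' `min_mean_abundance` (default 0.05%) and which are detected
#' (abundance > 0) in at least a fraction `min_prevalence` of samples
#' (default 5%). Both thresholds are inclusive. Abundances are not
#' renormalized after filtering, so retained values keep their original
#' meaning as fractions of the whole community.
#'
#' @param rel Relative-abundance tibble.
#' @param min_mean_abundance Minimum mean relative abundance, in \[0, 1\].
#' @param min_prevalence Minimum detection fraction, in \[0, 1\].
#' @param abundance_stat Summary used for the abundance rule: `"mean"`
#'   (default, the common microbiome-QC convention) or `"max"`.
#' @return A list with `table` (the filtered tibble) and `report`, a list
#'   with fields `n_input_otus`, `n_removed_abundance`, `n_removed_prevalence`,
#'   `n_retained` and `removed_ids`. An OTU failing both rules is counted
#'   once, under the abundance rule.
#' @export
filter_otus <- function(rel, min_mean_abundance = 5e-4, min_prevalence = 0.05,
                        abundance_stat = c("mean", "max")) {
  abundance_stat <- match.arg(abundance_stat)
  check_fraction(min_mean_abundance, "min_mean_abundance")
  check_fraction(min_prevalence, "min_prevalence")
  validate_otu_table(rel, "relative")
  m <- otu_matrix(rel)
  stat <- if (abundance_stat == "mean") colMeans(m) else apply(m, 2, max)
  prev <- colMeans(m > 0)
  fail_ab <- stat < min_mean_abundance
  fail_prev <- prev < min_prevalence
  removed <- fail_ab | fail_prev
  report <- list(
    n_input_otus = ncol(m),
    n_removed_abundance = sum(fail_ab),
    n_removed_prevalence = sum(fail_prev & !fail_ab),
    n_retained = sum(!removed),
    removed_ids = colnames(m)[removed]
  )
  keep_cols <- c("sample_id", colnames(m)[!removed])
  list(table = rel[keep_cols], report = report)
}

#' Residualize the phenotype on sex and cage
#'
#' Fits an ordinary least-squares model of the raw phenotype on sex and cage
#' (both as fixed categorical effects) and stores the residuals in a
#' `phenotype_adj` column. All downstream association tests use these
#' residuals, so sex and cage effects never masquerade as microbial signal.
#' Terms with a single level are dropped (degenerating to centering when
#' neither covariate varies); cages with one sample get residual zero by
#' construction.
#'
#' @param pheno Metadata tibble as returned by [read_metadata()].
#' @return The input tibble with a `phenotype_adj` column; residuals have
#'   mean zero and are orthogonal to every design column.
#' @export
adjust_phenotype <- function(pheno) {
  stopifnot(all(c("sample_id", "phenotype_raw") %in% names(pheno)))
  if (any(!is.finite(pheno$phenotype_raw))) abort("phenotype_raw must be finite")
  terms <- character(0)
  if ("sex" %in% names(pheno) && length(unique(pheno$sex)) > 1) {
    terms <- c(terms, "factor(sex)")
  }
  if ("cage" %in% names(pheno) && length(unique(pheno$cage)) > 1) {
    terms <- c(terms, "factor(cage)")
  }
  rhs <- if (length(terms) == 0) "1" else paste(terms, collapse = " + ")
  fit <- lm(stats::as.formula(paste("phenotype_raw ~", rhs)), data = pheno)
  if (any(is.na(stats::coef(fit)))) {
    warn("collinear covariate design; redundant columns dropped")
  }
  dplyr::mutate(pheno, phenotype_adj = unname(residuals(fit)))
}
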