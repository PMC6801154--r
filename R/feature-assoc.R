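#' Spearman screen of a feature table against the phenotype
#'
#' Generic rank-correlation screen for per-sample feature tables such as
#' predicted KEGG Orthology (KO) or pathway relative abundances. Each
#' feature is correlated with the covariate-adjusted phenotype using
#' Spearman's rho with average-rank tie handling and an asymptotic two-sided
#' p-value; q-values are Benjamini-Hochberg across all testable features.
#' A feature is called significant when `q < q_threshold` and
#' `|rho| > r_threshold` (defaults follow the common screen: q < 0.05,
#' |rho| > 0.3). Constant features cannot be ranked against anything and are
#' excluded with a message.
#'
#' @param features Tibble with `sample_id` plus one numeric column per
#'   feature (samples as rows).
#' @param pheno Phenotype tibble containing `sample_id` and `phenotype_adj`.
#' @param r_threshold Minimum |rho| for the significant subset.
#' @param q_threshold Maximum q for the significant subset.
#' @return A list with `all` (tibble: `feature_id`, `rho`, `p`, `q`,
#'   `direction`, `significant`) and `significant` (the filtered subset).
#' @export
spearman_scan <- function(features, pheno, r_threshold = 0.3, q_threshold = 0.05) {
  check_fraction(r_threshold, "r_threshold")
  check_fraction(q_threshold, "q_threshold")
  if (names(features)[1] != "sample_id") {
    abort("feature table must have `sample_id` as its first column")
  }
  pheno <- align_samples(features, pheno)
  if (!"phenotype_adj" %in% names(pheno)) {
    abort("phenotype must be adjusted first; run adjust_phenotype()")
  }
  m <- otu_matrix(features)
  y <- pheno$phenotype_adj
  constant <- apply(m, 2, function(x) length(unique(x)) < 2)
  if (any(constant)) {
    inform(sprintf("excluding %d constant feature(s): %s", sum(constant),
                   paste(head(colnames(m)[constant], 5), collapse = ", ")))
    m <- m[, !constant, drop = FALSE]
  }
  res <- purrr::map_dfr(seq_len(ncol(m)), function(j) {
    ct <- suppressWarnings(cor.test(m[, j], y, method = "spearman",
                                    exact = FALSE))
    tibble(feature_id = colnames(m)[j],
           rho = unname(ct$estimate), p = ct$p.value)
  })
  res$q <- p.adjust(res$p, method = "BH")
  res$direction <- sign(res$rho)
  res$significant <- res$q < q_threshold & abs(res$rho) > r_threshold
  list(all = res, significant = dplyr::filter(res, .data$significant))
}
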