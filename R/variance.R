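#' Split samples into discovery and validation sets
#'
#' Random disjoint, exhaustive 80/20 (by default) split used by the
#' cross-validated variance-explained analysis. Discovery size is
#' `round(fraction_discovery * n)`.
#'
#' @param sample_ids Character vector of sample ids (>= 10).
#' @param fraction_discovery Fraction assigned to discovery, in (0, 1).
#' @param seed Optional integer.
#' @return A list with `discovery` and `validation` id vectors.
#' @export
cv_split <- function(sample_ids, fraction_discovery = 0.8, seed = NULL) {
  if (fraction_discovery <= 0 || fraction_discovery >= 1) {
    abort("`fraction_discovery` must be in (0, 1)")
  }
  n <- length(sample_ids)
  if (n < 10) abort("need at least 10 samples to split")
  n_disc <- round(fraction_discovery * n)
  disc <- with_seed_or_global(seed, sample(sample_ids, n_disc))
  list(discovery = disc, validation = setdiff(sample_ids, disc))
}

#' Additive microbiome prediction for held-out samples
#'
#' Predicts each validation sample's microbiome contribution to the
#' phenotype as `r_m = sum_j (beta1_j * b_j + beta2_j * q_j)`, summing over
#' the OTUs selected in the discovery set. `b_j` is the presence indicator
#' in the validation sample and `q_j` the log relative abundance
#' standardized with the discovery-set location and scale (`q_mu`, `q_sd`
#' from the discovery scan), taken as 0 when the OTU is absent. Undefined
#' component effect sizes contribute 0, so no information leaks from the
#' validation samples.
#'
#' @param rel Validation relative-abundance tibble.
#' @param selected Rows of a [two_part_scan()] result (fit on discovery
#'   samples only) for the selected OTUs.
#' @param literal If `TRUE`, uses the sum `beta1 + b_j + beta2 * q_j`
#'   verbatim instead of `beta1 * b_j + beta2 * q_j`; the two differ only by
#'   a per-sample shift plus a rescaling of the binary term, so validation
#'   R-squared is essentially unchanged. Kept for auditability.
#' @return A tibble with `sample_id` and `r_m` (phenotype units).
#' @export
additive_predict <- function(rel, selected, literal = FALSE) {
  missing <- setdiff(selected$otu_id, names(rel))
  if (length(missing) > 0) {
    abort(sprintf("selected OTU(s) absent from validation table: %s",
                  paste(head(missing, 5), collapse = ", ")))
  }
  if (nrow(selected) == 0) {
    return(tibble(sample_id = rel$sample_id, r_m = 0))
  }
  m <- otu_matrix(rel[c("sample_id", selected$otu_id)])
  B <- (m > 0) * 1
  beta1 <- ifelse(is.na(selected$beta1), 0, selected$beta1)
  beta2 <- ifelse(is.na(selected$beta2), 0, selected$beta2)
  q_mu <- ifelse(is.na(selected$q_mu), 0, selected$q_mu)
  q_sd <- ifelse(is.na(selected$q_sd) | selected$q_sd == 0, 1, selected$q_sd)
  L <- ifelse(B > 0, log(pmax(m, .Machine$double.xmin)), 0)
  Q <- (sweep(L, 2, q_mu, "-") / rep(q_sd, each = nrow(m))) * B
  r_m <- if (literal) {
    sum(beta1) + rowSums(B) + as.vector(Q %*% beta2)
  } else {
    as.vector(B %*% beta1 + Q %*% beta2)
  }
  tibble(sample_id = rel$sample_id, r_m = r_m)
}

#' Microbiome-explained phenotypic variance by cross-validation
#'
#' Repeats an 80/20 discovery/validation split `n_repeats` times. In each
#' repeat the two-part scan runs on the discovery samples alone; at each
#' p-value threshold the OTUs with `p_final <= threshold` are selected and
#' their discovery effect sizes drive [additive_predict()] on the held-out
#' validation samples. The explained variance is the squared Pearson
#' correlation between the additive prediction and the adjusted phenotype
#' over validation samples (0 when the prediction is constant). Reported
#' per threshold: mean and SD of validation R-squared and the mean number
#' of selected OTUs.
#'
#' @param rel Relative-abundance tibble (all samples).
#' @param pheno Phenotype tibble with `phenotype_adj`.
#' @param thresholds Increasing p-value cutoffs (defaults span 1e-5 to 0.1).
#' @param n_repeats Number of cross-validation repeats (reference analysis:
#'   100).
#' @param fraction_discovery Discovery fraction per split.
#' @param min_group,min_present,transform Passed to [two_part_scan()].
#' @param seed Optional integer; each repeat draws its split from this
#'   stream.
#' @return An object of class `variance_curve`: list with `summary`
#'   (per-threshold tibble), `repeats` (long per-repeat tibble), `n_repeats`,
#'   `thresholds`. Has [tidy()], [glance()] and [autoplot()] methods.
#' @export
explained_variance <- function(rel, pheno,
                               thresholds = c(1e-5, 1e-4, 1e-3, 1e-2, 0.05, 0.1),
                               n_repeats = 100, fraction_discovery = 0.8,
                               min_group = 5, min_present = 10,
                               transform = "log", seed = NULL) {
  validate_abundance(rel)
  pheno <- align_samples(rel, pheno)
  if (!"phenotype_adj" %in% names(pheno)) {
    abort("phenotype must be adjusted first; run adjust_phenotype()")
  }
  thresholds <- sort(thresholds)
  n <- nrow(rel)
  if (round((1 - fraction_discovery) * n) < 5) {
    abort("validation set would have fewer than 5 samples")
  }
  run <- function() {
    purrr::map_dfr(seq_len(n_repeats), function(rep_i) {
      split <- cv_split(rel$sample_id, fraction_discovery)
      disc_idx <- rel$sample_id %in% split$discovery
      scan <- two_part_scan(rel[disc_idx, ], pheno[disc_idx, ],
                            min_group = min_group, min_present = min_present,
                            transform = transform)
      rel_val <- rel[!disc_idx, ]
      y_val <- pheno$phenotype_adj[!disc_idx]
      purrr::map_dfr(thresholds, function(th) {
        sel <- dplyr::filter(scan, !is.na(.data$p_final), .data$p_final <= th)
        pred <- additive_predict(rel_val, sel)
        r2 <- if (sd(pred$r_m) == 0 || sd(y_val) == 0) 0 else
          cor(pred$r_m, y_val)^2
        tibble(repeat_id = rep_i, threshold = th,
               n_otus = nrow(sel), R2 = r2)
      })
    })
  }
  repeats <- with_seed_or_global(seed, run())
  summary <- repeats |>
    dplyr::group_by(.data$threshold) |>
    dplyr::summarise(mean_R2 = mean(.data$R2), sd_R2 = sd(.data$R2),
                     mean_n_otus = mean(.data$n_otus), .groups = "drop")
  structure(list(summary = summary, repeats = repeats,
                 n_repeats = n_repeats, thresholds = thresholds),
            class = "variance_curve")
}
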