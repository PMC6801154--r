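#' Build a block basis-correlation matrix
#'
#' Convenience constructor for simulation configs: OTUs inside a block share
#' correlation `r_within`, blocks are mutually uncorrelated, and OTUs outside
#' every block are independent.
#'
#' @param n_otus Total number of OTUs.
#' @param blocks List of integer index vectors, one per block.
#' @param r_within Within-block correlation (scalar or one value per block).
#' @return An `n_otus` x `n_otus` correlation matrix.
#' @export
block_correlation <- function(n_otus, blocks, r_within) {
  r_within <- rep(r_within, length.out = length(blocks))
  S <- diag(n_otus)
  for (i in seq_along(blocks)) {
    idx <- blocks[[i]]
    S[idx, idx] <- r_within[i]
    diag(S)[idx] <- 1
  }
  S
}

#' Simulate an OTU count table, metadata and phenotype with known truth
#'
#' Emulates a rarefied 16S profile of a weaning cohort: per sample,
#' log-basis abundances are drawn from a multivariate normal with a
#' configurable correlation structure, exponentiated, masked by per-OTU
#' Bernoulli presence indicators (structural zeros, so presence/absence is
#' meaningful ground truth for the binary component), closed to fractions,
#' and counted multinomially at a fixed library depth — mirroring a table
#' rarefied to `depth` tags. The phenotype (weight in grams) is
#' `grand_mean + sex effect + cage intercept + planted OTU effects + noise`,
#' where a planted effect contributes `beta1 * presence` and
#' `beta2 * standardized log basis abundance` (0 when absent). Defaults
#' mirror the study design this package targets: 135 animals in 90 cages of
#' 1-2, libraries of 40,000 tags, a male-female weight gap and
#' between-cage variation of a few tens of grams.
#'
#' @param n_samples,n_otus Cohort and panel size.
#' @param depth Library size after rarefaction (tags per sample).
#' @param basis_cor Basis correlation matrix (`n_otus` square, positive
#'   definite) or `NULL` for independence; see [block_correlation()].
#' @param log_mean,log_sd Per-OTU location/scale of log basis abundance;
#'   scalars are recycled, `log_mean = NULL` draws locations from
#'   Normal(0, 2) to give a realistic spread of mean abundances.
#' @param presence_prob Per-OTU structural presence probability in (0, 1\];
#'   scalar recycled, or `NULL` to draw Uniform(0.2, 1) per OTU.
#' @param n_cages Number of cages; samples are dealt round-robin so cages
#'   hold 1 or 2 animals.
#' @param sex_effect Male minus female weight difference (g).
#' @param cage_sd SD of cage random intercepts (g).
#' @param noise_sd SD of residual noise (g).
#' @param grand_mean Mean weaning weight (g).
#' @param effects Tibble/data frame with columns `otu` (index), `beta1` (g
#'   per presence) and `beta2` (g per SD of log abundance); `NULL` for none.
#' @param presence_groups Optional list of OTU index vectors; OTUs within a
#'   group share a single per-sample presence draw (at the first member's
#'   `presence_prob`), emulating co-occurring guilds whose members are
#'   detected together. OTUs outside any group keep independent masks.
#' @param seed Optional integer; the whole draw is deterministic given it.
#' @return A list with `counts` (count tibble; every row sums to `depth`),
#'   `metadata` (tibble: `sample_id`, `sex`, `cage`, `phenotype_raw`) and
#'   `truth` (list of every planted parameter, including the per-sample
#'   microbiome contribution `g` and presence masks).
#' @export
simulate_microbiome <- function(n_samples = 135, n_otus = 800, depth = 40000,
                                basis_cor = NULL, log_mean = NULL, log_sd = 1,
                                presence_prob = NULL, n_cages = 90,
                                sex_effect = 30, cage_sd = 40, noise_sd = 50,
                                grand_mean = 500, effects = NULL,
                                presence_groups = NULL, seed = NULL) {
  if (depth <= 0) abort("`depth` must be positive")
  if (!is.null(basis_cor)) {
    stopifnot(nrow(basis_cor) == n_otus, ncol(basis_cor) == n_otus)
    ev <- eigen(basis_cor, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-10) abort("`basis_cor` must be positive definite")
  }
  with_seed_or_global(seed, {
    otu_ids <- sprintf("OTU%04d", seq_len(n_otus))
    sample_ids <- sprintf("S%03d", seq_len(n_samples))
    if (is.null(log_mean)) log_mean <- rnorm(n_otus, 0, 2)
    log_mean <- rep(log_mean, length.out = n_otus)
    log_sd <- rep(log_sd, length.out = n_otus)
    if (is.null(presence_prob)) presence_prob <- runif(n_otus, 0.2, 1)
    presence_prob <- rep(presence_prob, length.out = n_otus)
    if (any(presence_prob <= 0 | presence_prob > 1)) {
      abort("presence probabilities must be in (0, 1]")
    }

    Z <- if (is.null(basis_cor)) {
      matrix(rnorm(n_samples * n_otus), n_samples, n_otus)
    } else {
      MASS::mvrnorm(n_samples, mu = rep(0, n_otus), Sigma = basis_cor)
    }
    Lb <- sweep(sweep(Z, 2, log_sd, "*"), 2, log_mean, "+")
    X <- exp(Lb)
    mask <- matrix(rbinom(n_samples * n_otus, 1, rep(presence_prob, each = n_samples)),
                   n_samples, n_otus)
    if (!is.null(presence_groups)) {
      for (grp in presence_groups) {
        shared <- rbinom(n_samples, 1, presence_prob[grp[1]])
        mask[, grp] <- shared
      }
    }
    empty <- rowSums(mask) == 0
    if (any(empty)) mask[empty, which.max(presence_prob)] <- 1
    Xm <- X * mask
    fracs <- Xm / rowSums(Xm)
    counts <- t(apply(fracs, 1, function(p) rmultinom(1, depth, p)[, 1]))
    dimnames(counts) <- list(sample_ids, otu_ids)

    # host covariates: round-robin cage assignment, interleaved sexes
    cage <- sprintf("C%03d", rep_len(seq_len(n_cages), n_samples))
    n_male <- ceiling(n_samples * 70 / 135)
    sex <- c(rep("male", n_male), rep("female", n_samples - n_male))
    cage_int <- rnorm(n_cages, 0, cage_sd)

    g <- numeric(n_samples)
    truth_effects <- NULL
    if (!is.null(effects) && nrow(effects) > 0) {
      truth_effects <- as_tibble(effects)
      for (i in seq_len(nrow(truth_effects))) {
        j <- truth_effects$otu[i]
        b <- mask[, j]
        q <- numeric(n_samples)
        present <- b > 0
        if (sum(present) > 1) {
          lj <- Lb[present, j]
          q[present] <- (lj - mean(lj)) / sd(lj)
        }
        g <- g + truth_effects$beta1[i] * b + truth_effects$beta2[i] * q
      }
      truth_effects$otu_id <- otu_ids[truth_effects$otu]
    }
    pheno <- grand_mean + sex_effect * (sex == "male") +
      cage_int[match(cage, sprintf("C%03d", seq_len(n_cages)))] + g +
      rnorm(n_samples, 0, noise_sd)

    list(
      counts = matrix_to_tbl(counts),
      metadata = tibble(sample_id = sample_ids, sex = sex, cage = cage,
                        phenotype_raw = pheno),
      truth = list(log_mean = log_mean, log_sd = log_sd,
                   presence_prob = presence_prob, basis_cor = basis_cor,
                   effects = truth_effects, g = g,
                   cage_intercepts = cage_int, sex_effect = sex_effect,
                   cage_sd = cage_sd, noise_sd = noise_sd,
                   grand_mean = grand_mean, mask = mask, log_basis = Lb)
    )
  })
}

#' Simulate a functional-feature table with target phenotype correlations
#'
#' Generates samples x features tables mimicking predicted KO or pathway
#' relative abundances for exercising [spearman_scan()]. Features are drawn
#' through a Gaussian copula against the adjusted phenotype's ranks so a
#' requested Spearman correlation is achieved approximately (the Pearson
#' correlation of the underlying normals is `2 sin(pi * rho / 6)`); features
#' without a requested effect are independent noise.
#'
#' @param pheno Phenotype tibble with `phenotype_adj` (run
#'   [adjust_phenotype()] first).
#' @param n_features Number of features.
#' @param effects Tibble/data frame with columns `feature` (index) and `rho`
#'   (target Spearman, |rho| < 1); `NULL` for all-null features.
#' @param seed Optional integer.
#' @return A tibble with `sample_id` plus `n_features` numeric columns
#'   (`K0001`, ...).
#' @export
simulate_features <- function(pheno, n_features, effects = NULL, seed = NULL) {
  if (!"phenotype_adj" %in% names(pheno)) {
    abort("phenotype must be adjusted first; run adjust_phenotype()")
  }
  n <- nrow(pheno)
  with_seed_or_global(seed, {
    z_ph <- qnorm((rank(pheno$phenotype_adj, ties.method = "average") - 0.5) / n)
    F <- matrix(rnorm(n * n_features), n, n_features)
    if (!is.null(effects) && nrow(effects) > 0) {
      if (any(abs(effects$rho) >= 1)) abort("|rho| targets must be < 1")
      for (i in seq_len(nrow(effects))) {
        j <- effects$feature[i]
        rp <- 2 * sin(pi * effects$rho[i] / 6)
        F[, j] <- rp * z_ph + sqrt(1 - rp^2) * rnorm(n)
      }
    }
    colnames(F) <- sprintf("K%04d", seq_len(n_features))
    dplyr::bind_cols(tibble(sample_id = pheno$sample_id), as_tibble(F))
  })
}
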