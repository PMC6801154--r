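#' Binary (presence/absence) component of the two-part model
#'
#' Ordinary least-squares fit of the adjusted phenotype on a presence
#' indicator, equivalent to a pooled-variance two-sample t-test between
#' carriers and non-carriers. The slope `beta1` is the phenotype difference
#' attributable to carrying the taxon, in phenotype units.
#'
#' @param presence Numeric/logical vector of per-sample presence indicators
#'   (abundance > 0).
#' @param pheno_adj Covariate-adjusted phenotype, same length.
#' @param min_group Minimum size of both the present and absent groups;
#'   below it the component is undefined (returned as `NULL`).
#' @return A list `(beta1, se1, z1, p_binary)`, or `NULL` when undefined.
#'   `z1` is the signed normal quantile matching the two-sided p.
#' @export
binary_component <- function(presence, pheno_adj, min_group = 5) {
  x <- as.numeric(presence > 0)
  stats <- simple_ols(x, pheno_adj)
  n1 <- sum(x > 0)
  if (min(n1, length(x) - n1) < min_group || is.null(stats)) return(NULL)
  list(beta1 = stats$beta, se1 = stats$se, z1 = z_from_p(stats$p, stats$beta),
       p_binary = stats$p)
}

#' Quantitative (abundance-among-carriers) component of the two-part model
#'
#' Restricted to samples where the taxon was detected, regresses the adjusted
#' phenotype on the transformed abundance. The default transform is the
#' natural log of relative abundance, standardized to mean 0 / sd 1 within
#' the carrier subset, so `beta2` is in phenotype units per SD of log
#' abundance; a rank-based inverse-normal transform is also available.
#'
#' @param abundance Per-sample relative abundances.
#' @param pheno_adj Covariate-adjusted phenotype, same length.
#' @param min_present Minimum number of carrier samples; below it the
#'   component is undefined.
#' @param transform `"log"` (default) or `"rank_invnorm"`.
#' @return A list `(beta2, se2, z2, p_quant)`, or `NULL` when undefined
#'   (too few carriers, or zero variance of the transformed abundance).
#' @export
quant_component <- function(abundance, pheno_adj, min_present = 10,
                            transform = c("log", "rank_invnorm")) {
  transform <- match.arg(transform)
  present <- abundance > 0
  if (sum(present) < max(min_present, 3)) return(NULL)
  a <- abundance[present]
  y <- pheno_adj[present]
  q <- transform_abundance(a, transform)
  if (is.null(q)) return(NULL)
  stats <- simple_ols(q, y)
  if (is.null(stats)) return(NULL)
  list(beta2 = stats$beta, se2 = stats$se, z2 = z_from_p(stats$p, stats$beta),
       p_quant = stats$p)
}

transform_abundance <- function(a, transform) {
  if (transform == "log") {
    l <- log(a)
    s <- sd(l)
    if (!is.finite(s) || s == 0) return(NULL)
    (l - mean(l)) / s
  } else {
    r <- qnorm((rank(a) - 0.5) / length(a))
    s <- sd(r)
    if (!is.finite(s) || s == 0) return(NULL)
    (r - mean(r)) / s
  }
}

#' Unweighted-Z meta-analysis of the two components
#'
#' Combines the binary and quantitative signed z-scores as
#' `z_meta = (z1 + z2) / sqrt(2)`, with a two-sided normal p-value. Defined
#' only when both components are.
#'
#' @param z1,z2 Signed z-scores from the two components.
#' @return A list `(z_meta, p_meta)`, or `NULL` when either z is missing.
#' @export
meta_component <- function(z1, z2) {
  if (is.null(z1) || is.null(z2) || is.na(z1) || is.na(z2)) return(NULL)
  z <- (z1 + z2) / sqrt(2)
  list(z_meta = z, p_meta = floor_p(2 * pnorm(abs(z), lower.tail = FALSE)))
}

# Closed-form simple linear regression y ~ 1 + x. Returns NULL on a
# degenerate design (constant x or y, or n < 3).
simple_ols <- function(x, y) {
  n <- length(x)
  if (n < 3) return(NULL)
  sxx <- sum(x^2) - sum(x)^2 / n
  syy <- sum(y^2) - sum(y)^2 / n
  if (sxx <= 0 || syy <= 0) return(NULL)
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  beta <- sxy / sxx
  sse <- max(syy - beta * sxy, 0)
  df <- n - 2
  s2 <- sse / df
  se <- sqrt(s2 / sxx)
  tval <- if (se > 0) beta / se else sign(beta) * Inf
  p <- floor_p(2 * pt(abs(tval), df, lower.tail = FALSE))
  list(beta = beta, se = se, t = tval, p = p, df = df)
}

# Precompute the abundance-side quantities of the two-part scan once; they
# do not depend on the phenotype, so permutation rounds reuse them.
tp_prepare <- function(m, min_group, min_present, transform) {
  n <- nrow(m)
  P <- (m > 0) * 1
  n_p <- unname(colSums(P))
  L <- ifelse(P > 0, log(pmax(m, .Machine$double.xmin)), 0)
  mu <- ifelse(n_p > 0, unname(colSums(L)) / pmax(n_p, 1), NA_real_)
  ss <- unname(colSums(L^2)) - n_p * mu^2
  q_var <- ifelse(n_p > 1, pmax(ss, 0) / (n_p - 1), NA_real_)
  q_sd <- sqrt(q_var)
  if (transform == "log") {
    ok_sd <- is.finite(q_sd) & q_sd > 0
    Q <- sweep(L, 2, ifelse(ok_sd, mu, 0), "-") * P
    Q <- sweep(Q, 2, ifelse(ok_sd, q_sd, 1), "/")
    Q[, !ok_sd] <- 0
  } else {
    Q <- matrix(0, n, ncol(m))
    ok_sd <- rep(FALSE, ncol(m))
    for (j in seq_len(ncol(m))) {
      if (n_p[j] < 2) next
      idx <- which(P[, j] > 0)
      qj <- transform_abundance(m[idx, j], transform)
      if (is.null(qj)) next
      Q[idx, j] <- qj
      ok_sd[j] <- TRUE
    }
  }
  list(P = P, Q = Q, n = n, n_p = n_p, n0 = n - n_p,
       q_mu = mu, q_sd = q_sd, ok_sd = ok_sd,
       bin_ok = pmin(n_p, n - n_p) >= min_group,
       quant_ok = ok_sd & n_p >= max(min_present, 3))
}

# Vectorized two-part statistics for one phenotype vector.
tp_stats <- function(prep, y) {
  n <- prep$n
  n_p <- prep$n_p
  sy <- sum(y)
  syy_tot <- sum(y^2) - sy^2 / n

  # binary: OLS on the presence indicator
  sxy_b <- as.vector(crossprod(prep$P, y)) - n_p * sy / n
  sxx_b <- n_p * prep$n0 / n
  bin_ok <- prep$bin_ok & sxx_b > 0 & syy_tot > 0
  beta1 <- ifelse(bin_ok, sxy_b / sxx_b, NA_real_)
  sse_b <- pmax(syy_tot - beta1 * sxy_b, 0)
  se1 <- ifelse(bin_ok, sqrt((sse_b / (n - 2)) / sxx_b), NA_real_)
  t1 <- ifelse(bin_ok & se1 > 0, beta1 / se1, ifelse(bin_ok, sign(beta1) * Inf, NA_real_))
  p1 <- ifelse(bin_ok, floor_p(2 * pt(abs(t1), n - 2, lower.tail = FALSE)), NA_real_)
  z1 <- ifelse(bin_ok, z_from_p(p1, beta1), NA_real_)

  # quantitative: OLS on standardized transformed abundance among carriers;
  # carrier columns of Q have mean 0 and sum of squares n_p - 1
  sy_p <- as.vector(crossprod(prep$P, y))
  syy_p <- as.vector(crossprod(prep$P, y^2)) - ifelse(n_p > 0, sy_p^2 / pmax(n_p, 1), 0)
  sxy_q <- as.vector(crossprod(prep$Q, y))
  sxx_q <- n_p - 1
  quant_ok <- prep$quant_ok & syy_p > 0
  beta2 <- ifelse(quant_ok, sxy_q / sxx_q, NA_real_)
  sse_q <- pmax(syy_p - beta2 * sxy_q, 0)
  se2 <- ifelse(quant_ok, sqrt((sse_q / (n_p - 2)) / sxx_q), NA_real_)
  t2 <- ifelse(quant_ok & se2 > 0, beta2 / se2, ifelse(quant_ok, sign(beta2) * Inf, NA_real_))
  p2 <- ifelse(quant_ok, floor_p(2 * pt(abs(t2), n_p - 2, lower.tail = FALSE)), NA_real_)
  z2 <- ifelse(quant_ok, z_from_p(p2, beta2), NA_real_)

  meta_ok <- bin_ok & quant_ok
  z_meta <- ifelse(meta_ok, (z1 + z2) / sqrt(2), NA_real_)
  p_meta <- ifelse(meta_ok, floor_p(2 * pnorm(abs(z_meta), lower.tail = FALSE)), NA_real_)

  p_final <- pmin(ifelse(is.na(p1), Inf, p1),
                  ifelse(is.na(p2), Inf, p2),
                  ifelse(is.na(p_meta), Inf, p_meta))
  p_final[!is.finite(p_final)] <- NA_real_

  direction <- rep(NA_real_, length(p_final))
  use_bin <- !is.na(p_final) & !is.na(p1) & p1 <= p_final
  use_quant <- !is.na(p_final) & !is.na(p2) & p2 <= p_final & !use_bin
  use_meta <- !is.na(p_final) & !use_bin & !use_quant
  direction[use_bin] <- sign(beta1[use_bin])
  direction[use_quant] <- sign(beta2[use_quant])
  direction[use_meta] <- sign(z_meta[use_meta])

  list(beta1 = beta1, se1 = se1, z1 = z1, p_binary = p1,
       beta2 = beta2, se2 = se2, z2 = z2, p_quant = p2,
       z_meta = z_meta, p_meta = p_meta, p_final = p_final,
       direction = direction)
}

#' Two-part association scan across all OTUs
#'
#' Runs the two-part model (binary component, quantitative component,
#' unweighted-Z meta-analysis) for every OTU against the covariate-adjusted
#' phenotype, and sets each OTU's final p-value to the minimum over its
#' defined components. The min-P combination is anticonservative under the
#' null, which is why downstream significance uses [permutation_fdr()]
#' rather than the nominal p-values.
#'
#' @param rel Relative-abundance tibble (samples as rows).
#' @param pheno Phenotype tibble containing `sample_id` and `phenotype_adj`
#'   (see [adjust_phenotype()]).
#' @param min_group Minimum group size for the binary component.
#' @param min_present Minimum carrier count for the quantitative component.
#' @param transform Abundance transform for the quantitative component.
#' @return A tibble with one row per OTU: carrier counts, per-component
#'   effect sizes (`beta1`, `beta2`), standard errors, z-scores and p-values,
#'   the meta-analysis statistics, `p_final`, the dominant-component
#'   `direction`, and the carrier log-abundance location/scale
#'   (`q_mu`, `q_sd`) frozen for later prediction. Undefined components are
#'   `NA`.
#' @export
two_part_scan <- function(rel, pheno, min_group = 5, min_present = 10,
                          transform = c("log", "rank_invnorm")) {
  transform <- match.arg(transform)
  validate_abundance(rel)
  pheno <- align_samples(rel, pheno)
  if (!"phenotype_adj" %in% names(pheno)) {
    abort("phenotype must be adjusted first; run adjust_phenotype()")
  }
  m <- otu_matrix(rel)
  prep <- tp_prepare(m, min_group, min_present, transform)
  st <- tp_stats(prep, pheno$phenotype_adj)
  out <- tibble(
    otu_id = colnames(m),
    n_present = as.integer(prep$n_p),
    presence_fraction = prep$n_p / prep$n,
    beta1 = st$beta1, se1 = st$se1, z1 = st$z1, p_binary = st$p_binary,
    beta2 = st$beta2, se2 = st$se2, z2 = st$z2, p_quant = st$p_quant,
    q_mu = ifelse(prep$quant_ok, prep$q_mu, NA_real_),
    q_sd = ifelse(prep$quant_ok, prep$q_sd, NA_real_),
    z_meta = st$z_meta, p_meta = st$p_meta, p_final = st$p_final,
    direction = st$direction
  )
  attr(out, "tp_params") <- list(min_group = min_group,
                                 min_present = min_present,
                                 transform = transform,
                                 n_samples = prep$n)
  out
}

#' Permutation-based FDR for the two-part scan
#'
#' Estimates q-values by rerunning the full two-part scan on phenotype
#' vectors permuted across samples (which preserves the correlation
#' structure among OTUs). For an observed final p-value t, the FDR estimate
#' is the average number of null p-values at or below t per permutation,
#' divided by the observed count at or below t; q-values are the step-up
#' monotonization of that ratio, capped at 1. OTUs whose two-part model was
#' undefined (never tested) get q = 1.
#'
#' @param scan Result of [two_part_scan()].
#' @param rel,pheno The inputs the scan was computed from.
#' @param n_perm Number of permutations (>= 100; the reference analysis used
#'   1000).
#' @param seed Optional integer for reproducible permutations.
#' @return The scan tibble with a `q_value` column appended.
#' @export
permutation_fdr <- function(scan, rel, pheno, n_perm = 1000, seed = NULL) {
  if (n_perm < 100) abort("`n_perm` must be at least 100")
  params <- attr(scan, "tp_params")
  if (is.null(params)) abort("`scan` must come from two_part_scan()")
  pheno <- align_samples(rel, pheno)
  m <- otu_matrix(rel)
  prep <- tp_prepare(m, params$min_group, params$min_present, params$transform)
  y <- pheno$phenotype_adj

  null_p <- with_seed_or_global(seed, {
    vapply(seq_len(n_perm), function(b) {
      tp_stats(prep, sample(y))$p_final
    }, numeric(ncol(m)))
  })

  obs <- scan$p_final
  q <- rep(1, length(obs))
  tested <- which(!is.na(obs))
  if (length(tested) > 0) {
    null_sorted <- sort(null_p[!is.na(null_p)])
    obs_t <- obs[tested]
    ord <- order(obs_t)
    t_sorted <- obs_t[ord]
    v <- findInterval(t_sorted, null_sorted) / n_perm
    r <- findInterval(t_sorted, t_sorted)  # #{observed <= t}
    fdr <- v / pmax(r, 1)
    q_sorted <- pmin(rev(cummin(rev(fdr))), 1)
    q[tested[ord]] <- q_sorted
  }
  out <- dplyr::mutate(scan, q_value = q)
  attr(out, "tp_params") <- params
  out
}
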