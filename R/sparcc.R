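#' SparCC compositional correlation
#'
#' Estimates correlations among taxa from count data while accounting for
#' the compositional (closed-sum) nature of sequencing profiles, following
#' the sparse correlations for compositional data algorithm. Each inner
#' repetition draws per-sample Dirichlet fractions (counts plus a
#' pseudocount of 1), forms the matrix of log-ratio variances
#' `t_ij = Var(log(x_i/x_j))`, solves the sparsity-assuming linear system
#' for basis variances, and converts them to correlations
#' `r_ij = (w_i + w_j - t_ij) / (2 sqrt(w_i w_j))`. The single most strongly
#' correlated pair above `exclude_threshold` is iteratively removed from the
#' basis estimation and the system re-solved, up to `n_exclude_iter` times.
#' The reported matrix is the element-wise median over inner repetitions.
#'
#' @param counts OTU count tibble (samples as rows), typically restricted to
#'   the taxa of interest; at least 4 taxa are required (the basis-variance
#'   system is underdetermined below that).
#' @param n_inner Number of Dirichlet resampling repetitions.
#' @param n_exclude_iter Maximum strongly-correlated-pair exclusions.
#' @param exclude_threshold Absolute correlation above which a pair may be
#'   excluded from basis estimation.
#' @param seed Optional integer for reproducibility.
#' @return A symmetric correlation matrix with unit diagonal, entries
#'   clipped to \[-1, 1\], dimnames = OTU ids.
#' @export
sparcc <- function(counts, n_inner = 20, n_exclude_iter = 20,
                   exclude_threshold = 0.1, seed = NULL) {
  validate_otu_table(counts, "counts")
  m <- otu_matrix(counts)
  if (ncol(m) < 4) abort("SparCC needs at least 4 OTUs")
  with_seed_or_global(seed, sparcc_core(m, n_inner, n_exclude_iter, exclude_threshold))
}

sparcc_core <- function(m, n_inner, n_exclude_iter, exclude_threshold) {
  p <- ncol(m)
  reps <- array(NA_real_, dim = c(p, p, n_inner))
  for (it in seq_len(n_inner)) {
    f <- dirichlet_fractions(m + 1)
    reps[, , it] <- sparcc_once(log(f), n_exclude_iter, exclude_threshold)
  }
  r <- apply(reps, c(1, 2), median)
  r <- (r + t(r)) / 2
  diag(r) <- 1
  dimnames(r) <- list(colnames(m), colnames(m))
  r
}

# One Dirichlet draw per sample: gamma variates normalized within rows.
dirichlet_fractions <- function(alpha) {
  g <- matrix(rgamma(length(alpha), shape = alpha), nrow = nrow(alpha))
  g / rowSums(g)
}

# One SparCC estimate from a matrix of per-sample log fractions.
sparcc_once <- function(L, n_exclude_iter, exclude_threshold) {
  p <- ncol(L)
  C <- stats::cov(L)
  v <- diag(C)
  Tm <- outer(v, v, "+") - 2 * C       # log-ratio variances
  A <- matrix(1, p, p) - diag(p)       # pairs still used for basis estimation
  r <- solve_basis(Tm, A)
  for (k in seq_len(n_exclude_iter)) {
    ra <- abs(r) * A
    diag(ra) <- 0
    mx <- max(ra)
    if (mx <= exclude_threshold) break
    idx <- which(ra == mx, arr.ind = TRUE)[1, ]
    A[idx[1], idx[2]] <- A[idx[2], idx[1]] <- 0
    if (any(rowSums(A) < 2)) break     # system would degenerate
    r <- solve_basis(Tm, A)
  }
  r
}

# Solve the basis-variance linear system restricted to included pairs A,
# then convert basis variances to correlations.
solve_basis <- function(Tm, A) {
  M <- diag(rowSums(A)) + A
  b <- rowSums(Tm * A)
  w <- tryCatch(solve(M, b), error = function(e) rep(mean(diag(Tm)), nrow(Tm)))
  if (any(w <= 0)) {
    warn("non-positive basis variance encountered; clipped")
    w <- pmax(w, .Machine$double.eps)
  }
  r <- (outer(w, w, "+") - Tm) / (2 * sqrt(outer(w, w)))
  r <- pmin(pmax(r, -1), 1)
  diag(r) <- 1
  r
}

#' Bootstrap pseudo-p-values for SparCC correlations
#'
#' Destroys all inter-OTU correlation (while keeping each OTU's marginal
#' count distribution) by independently shuffling each OTU's counts across
#' samples, re-estimates the SparCC matrix on each shuffled dataset, and
#' reports the two-sided add-one pseudo-p
#' `(1 + #\{|r_boot| >= |r_obs|\}) / (1 + n_boot)` per pair. The smallest
#' attainable value is `1/(n_boot + 1)`.
#'
#' @param counts The count tibble `r_obs` was estimated from.
#' @param r_obs Observed SparCC matrix from [sparcc()] on the same counts.
#' @param n_boot Number of bootstrap datasets (>= 50).
#' @param n_inner,n_exclude_iter,exclude_threshold Passed through to the
#'   SparCC core; keep them equal to those used for `r_obs`.
#' @param seed Optional integer.
#' @return A symmetric matrix of pseudo-p-values in (0, 1\].
#' @export
sparcc_bootstrap_p <- function(counts, r_obs, n_boot = 100, n_inner = 20,
                               n_exclude_iter = 20, exclude_threshold = 0.1,
                               seed = NULL) {
  if (n_boot < 50) abort("`n_boot` must be at least 50")
  validate_otu_table(counts, "counts")
  m <- otu_matrix(counts)
  stopifnot(identical(dim(r_obs), c(ncol(m), ncol(m))))
  with_seed_or_global(seed, {
    exceed <- matrix(0, ncol(m), ncol(m))
    for (b in seq_len(n_boot)) {
      mb <- apply(m, 2, sample)
      rb <- sparcc_core(mb, n_inner, n_exclude_iter, exclude_threshold)
      exceed <- exceed + (abs(rb) >= abs(r_obs))
    }
    p <- (1 + exceed) / (1 + n_boot)
    dimnames(p) <- dimnames(r_obs)
    p
  })
}

#' Filter a correlation matrix into a co-abundance edge list
#'
#' Keeps the pairs with pseudo-p strictly below `p_threshold` and absolute
#' correlation strictly above `r_threshold`; self-edges are never emitted.
#'
#' @param r Symmetric correlation matrix.
#' @param p Symmetric pseudo-p matrix aligned with `r`.
#' @param r_threshold,p_threshold Retention thresholds (defaults |r| > 0.4,
#'   p < 0.05).
#' @return A tibble with columns `otu_a`, `otu_b`, `r`, `p`, one row per
#'   retained unordered pair (ids sorted within a row).
#' @export
build_network <- function(r, p, r_threshold = 0.4, p_threshold = 0.05) {
  stopifnot(identical(dim(r), dim(p)))
  ids <- colnames(r)
  ut <- upper.tri(r)
  keep <- ut & p < p_threshold & abs(r) > r_threshold
  idx <- which(keep, arr.ind = TRUE)
  a <- ids[idx[, 1]]
  b <- ids[idx[, 2]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  out <- tibble(otu_a = a, otu_b = b,
                r = r[keep], p = p[keep])
  dplyr::arrange(out, .data$otu_a, .data$otu_b)
}

#' Cluster taxa into co-abundance groups
#'
#' Converts the SparCC correlation matrix to the distance
#' `d_ij = (1 - r_ij) / 2` (mapping r in \[-1, 1\] to \[0, 1\]) and cuts a
#' Ward-linkage dendrogram into `k` groups. Group labels are renumbered so
#' that CAG 1 contains the lexicographically smallest OTU id, making labels
#' deterministic.
#'
#' @param r Symmetric correlation matrix with OTU ids as dimnames.
#' @param k Number of co-abundance groups (default 2).
#' @return A tibble with columns `otu_id` and `cag` (integer labels 1..k).
#' @export
cluster_cags <- function(r, k = 2) {
  if (k > ncol(r)) abort("`k` cannot exceed the number of OTUs")
  d <- as.dist((1 - r) / 2)
  hc <- hclust(d, method = "ward.D2")
  raw <- cutree(hc, k = k)
  ids <- colnames(r)
  first_id <- vapply(seq_len(k), function(g) min(ids[raw == g]), character(1))
  new_of_old <- rank(first_id)  # group with the smallest id becomes CAG 1
  tibble(otu_id = ids, cag = as.integer(new_of_old[raw]))
}

#' PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance: the pseudo-F statistic
#' compares between-group to within-group sums of squared distances,
#' `F = (SS_between/(k-1)) / (SS_within/(n-k))`, where the total sum of
#' squares is `sum_{i<j} d_ij^2 / n` and within-group terms are computed
#' analogously per group. Significance comes from permuting group labels.
#'
#' @param d Symmetric distance matrix (zero diagonal) or `dist` object.
#' @param labels Group label per observation; every group needs >= 2 members.
#' @param n_perm Number of label permutations (default 999).
#' @param seed Optional integer.
#' @return A list `(pseudo_F, p_value, n_perm)`; `p_value` uses the add-one
#'   estimator so its minimum is `1/(n_perm + 1)`.
#' @export
permanova <- function(d, labels, n_perm = 999, seed = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  stopifnot(length(labels) == n)
  if (any(table(labels) < 2)) abort("every group must have at least 2 members")
  d2 <- d^2
  f_obs <- permanova_f(d2, labels)
  if (!is.finite(f_obs)) abort("pseudo-F undefined (no within-group variation?)")
  f_perm <- with_seed_or_global(seed, {
    vapply(seq_len(n_perm), function(b) permanova_f(d2, sample(labels)),
           numeric(1))
  })
  p <- (1 + sum(f_perm >= f_obs)) / (1 + n_perm)
  list(pseudo_F = f_obs, p_value = p, n_perm = n_perm)
}

permanova_f <- function(d2, labels) {
  n <- nrow(d2)
  k <- length(unique(labels))
  ss_tot <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (g in unique(labels)) {
    idx <- labels == g
    dg <- d2[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(dg[upper.tri(dg)]) / sum(idx)
  }
  ss_between <- ss_tot - ss_within
  if (ss_within <= 0) {
    if (ss_between <= 0) return(NaN)
    return(Inf)
  }
  (ss_between / (k - 1)) / (ss_within / (n - k))
}

#' Associate co-abundance group abundances with the phenotype
#'
#' Per-sample CAG abundance is the sum of member OTUs' relative abundances
#' (the mean would be a monotone rescaling, leaving Spearman's rho
#' unchanged). Each CAG is tested against the adjusted phenotype with
#' Spearman's rank correlation; q-values are Benjamini-Hochberg across CAGs.
#'
#' @param rel Relative-abundance tibble covering the clustered OTUs.
#' @param cag_labels Tibble from [cluster_cags()].
#' @param pheno Phenotype tibble with `phenotype_adj`.
#' @return A tibble with one row per CAG: `cag`, `n_otus`, `rho`, `p`, `q`.
#'   The per-sample abundances are attached as attribute `"abundance"`.
#' @export
cag_phenotype_assoc <- function(rel, cag_labels, pheno) {
  missing <- setdiff(cag_labels$otu_id, names(rel))
  if (length(missing) > 0) {
    abort(sprintf("OTU(s) in cag_labels absent from table: %s",
                  paste(head(missing, 5), collapse = ", ")))
  }
  pheno <- align_samples(rel, pheno)
  m <- otu_matrix(rel)
  cags <- sort(unique(cag_labels$cag))
  ab <- vapply(cags, function(g) {
    rowSums(m[, cag_labels$otu_id[cag_labels$cag == g], drop = FALSE])
  }, numeric(nrow(m)))
  colnames(ab) <- paste0("CAG", cags)
  res <- purrr::map_dfr(seq_along(cags), function(i) {
    ct <- suppressWarnings(cor.test(ab[, i], pheno$phenotype_adj,
                                    method = "spearman", exact = FALSE))
    tibble(cag = cags[i],
           n_otus = sum(cag_labels$cag == cags[i]),
           rho = unname(ct$estimate), p = ct$p.value)
  })
  res$q <- p.adjust(res$p, method = "BH")
  attr(res, "abundance") <- dplyr::bind_cols(tibble(sample_id = rownames(m)),
                                             as_tibble(ab))
  res
}

#' Build the full co-abundance network for a set of associated taxa
#'
#' Orchestrates [sparcc()], [sparcc_bootstrap_p()], [build_network()],
#' [cluster_cags()], [permanova()] (on the `(1-r)/2` distances, validating
#' the clustering) and [cag_phenotype_assoc()] into one result object.
#'
#' @param counts Count tibble restricted to the taxa of interest (>= 4).
#' @param rel Relative-abundance tibble covering the same taxa (used for CAG
#'   abundances); pass `NULL` to skip the CAG-phenotype association.
#' @param pheno Phenotype tibble with `phenotype_adj`, or `NULL`.
#' @param r_threshold,p_threshold Edge retention thresholds.
#' @param k Number of co-abundance groups.
#' @param n_boot Bootstrap datasets for pseudo-p-values.
#' @param n_inner,n_exclude_iter,exclude_threshold SparCC parameters.
#' @param n_perm_permanova Label permutations for the PERMANOVA check.
#' @param seed Optional integer seeding all stages.
#' @return An object of class `co_network`: list with `otu_ids`, `r`, `p`,
#'   `edges`, `cag_labels`, `permanova`, `cag_assoc`. Has [tidy()],
#'   [glance()] and [autoplot()] methods.
#' @export
co_abundance_network <- function(counts, rel = NULL, pheno = NULL,
                                 r_threshold = 0.4, p_threshold = 0.05,
                                 k = 2, n_boot = 100, n_inner = 20,
                                 n_exclude_iter = 20, exclude_threshold = 0.1,
                                 n_perm_permanova = 999, seed = NULL) {
  seeds <- if (is.null(seed)) list(NULL, NULL, NULL) else
    lapply(c("sparcc", "bootstrap", "permanova"), function(s) stage_seed(seed, s))
  r <- sparcc(counts, n_inner, n_exclude_iter, exclude_threshold, seed = seeds[[1]])
  p <- sparcc_bootstrap_p(counts, r, n_boot, n_inner, n_exclude_iter,
                          exclude_threshold, seed = seeds[[2]])
  edges <- build_network(r, p, r_threshold, p_threshold)
  labels <- cluster_cags(r, k)
  perm <- permanova((1 - r) / 2, labels$cag[match(colnames(r), labels$otu_id)],
                    n_perm = n_perm_permanova, seed = seeds[[3]])
  assoc <- if (!is.null(rel) && !is.null(pheno)) {
    cag_phenotype_assoc(rel[c("sample_id", intersect(names(rel), labels$otu_id))],
                        labels, pheno)
  }
  structure(list(otu_ids = colnames(r), r = r, p = p, edges = edges,
                 cag_labels = labels, permanova = perm, cag_assoc = assoc,
                 params = list(r_threshold = r_threshold,
                               p_threshold = p_threshold, k = k,
                               n_boot = n_boot, n_inner = n_inner)),
            class = "co_network")
}

#' Export a co-abundance edge list to GraphML
#'
#' Writes the retained edges for import into an external network viewer.
#' Requires the `igraph` package.
#'
#' @param edges Edge tibble from [build_network()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_graphml <- function(edges, path) {
  if (!requireNamespace("igraph", quietly = TRUE)) {
    abort("GraphML export requires the `igraph` package")
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
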