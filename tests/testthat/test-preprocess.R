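test_that("rarefaction preserves depth exactly and is seed-deterministic", {
  tbl <- rand_counts(8, 30, lambda = 60, seed = 21)
  out <- rarefy(tbl, depth = 1000, seed = 1)
  expect_true(all(rowSums(microtrait::validate_otu_table(out)[-1]) == 1000))
  expect_equal(rarefy(tbl, depth = 1000, seed = 1), out)

  # a sample already at depth is returned unchanged
  one <- tibble::tibble(sample_id = "s1", A = 39990L, B = 10L)
  expect_equal(rarefy(one, 40000), one)
  solo <- tibble::tibble(sample_id = "s1", A = 40000L)
  expect_equal(rarefy(solo, 40000), solo)

  # shallow samples are dropped with a warning
  mix <- tibble::tibble(sample_id = c("deep", "shallow"),
                        A = c(500L, 10L), B = c(600L, 5L))
  expect_warning(res <- rarefy(mix, 100, seed = 2), "shallow")
  expect_equal(res$sample_id, "deep")
  expect_error(rarefy(mix, 0), "positive")
})

test_that("rarefaction subsampling matches hypergeometric moments", {
  # {A:6000, B:4000} at depth 1000: E[A] = 600,
  # Var[A] = 1000 * 0.6 * 0.4 * (9000/9999) = 216.02
  tbl <- tibble::tibble(sample_id = "s1", A = 6000L, B = 4000L)
  draws <- withr::with_seed(5, {
    vapply(seq_len(4000), function(i) rarefy(tbl, 1000)$A, integer(1))
  })
  expect_equal(mean(draws), 600, tolerance = 0.005)
  expect_equal(var(draws), 1000 * 0.6 * 0.4 * (9000 / 9999), tolerance = 0.08)
})

test_that("relative-abundance conversion divides by library size", {
  tbl <- tibble::tibble(sample_id = c("a", "b"),
                        X = c(5L, 1L), Y = c(5L, 0L), Z = c(0L, 3L))
  rel <- to_relative(tbl)
  expect_equal(unlist(rel[1, -1], use.names = FALSE), c(0.5, 0.5, 0))
  expect_equal(unlist(rel[2, -1], use.names = FALSE), c(0.25, 0, 0.75))

  zero <- tibble::tibble(sample_id = c("ok", "empty"), X = c(2L, 0L))
  expect_error(to_relative(zero), "empty")

  # after rarefaction every denominator is the depth, so rows sum to 1
  rel2 <- to_relative(rarefy(rand_counts(6, 20, lambda = 80, seed = 3), 800, seed = 4))
  expect_true(all(abs(rowSums(rel2[-1]) - 1) < 1e-9))
})

test_that("OTU filtering applies inclusive mean-abundance and prevalence rules", {
  # prevalence 4/100 < 5% -> removed even with high abundance
  n <- 100
  a <- matrix(0, n, 2)
  a[1:4, 1] <- 0.5
  a[, 2] <- 1 - a[, 1]
  rel <- dplyr::bind_cols(tibble::tibble(sample_id = sprintf("s%03d", 1:n)),
                          tibble::as_tibble(`colnames<-`(a, c("rare", "common"))))
  res <- filter_otus(rel)
  expect_equal(names(res$table), c("sample_id", "common"))
  expect_equal(res$report$n_removed_prevalence, 1)

  # mean abundance exactly at the threshold is retained (inclusive >=)
  b <- cbind(rep(5e-4, 40), rep(1 - 5e-4, 40))
  rel2 <- dplyr::bind_cols(tibble::tibble(sample_id = sprintf("s%02d", 1:40)),
                           tibble::as_tibble(`colnames<-`(b, c("edge", "big"))))
  res2 <- filter_otus(rel2)
  expect_true("edge" %in% names(res2$table))
})

test_that("filtering equals a brute-force per-OTU scan and accounts removals", {
  rel <- rand_rel(50, 60, zero_frac = 0.6, seed = 31)
  res <- filter_otus(rel, min_mean_abundance = 0.01, min_prevalence = 0.3)
  m <- as.matrix(rel[-1])
  keep_oracle <- vapply(seq_len(ncol(m)), function(j) {
    mean(m[, j]) >= 0.01 && mean(m[, j] > 0) >= 0.3
  }, logical(1))
  expect_equal(setdiff(names(res$table), "sample_id"),
               colnames(m)[keep_oracle])
  rpt <- res$report
  expect_equal(rpt$n_retained, rpt$n_input_otus - length(rpt$removed_ids))
  expect_equal(rpt$n_removed_abundance + rpt$n_removed_prevalence,
               length(rpt$removed_ids))
})

test_that("phenotype residualization removes sex and cage effects", {
  # intercept-only design degenerates to centering
  md <- tibble::tibble(sample_id = sprintf("s%d", 1:4), sex = "male",
                       cage = "c1", phenotype_raw = c(10, 20, 30, 40))
  expect_equal(adjust_phenotype(md)$phenotype_adj, c(-15, -5, 5, 15))

  # per-cage centering when only cage varies
  md2 <- tibble::tibble(sample_id = sprintf("s%d", 1:4), sex = "female",
                        cage = c("A", "A", "B", "B"),
                        phenotype_raw = c(100, 120, 200, 220))
  expect_equal(adjust_phenotype(md2)$phenotype_adj, c(-10, 10, -10, 10))

  # residuals are mean-zero and orthogonal to the design
  md3 <- withr::with_seed(7, tibble::tibble(
    sample_id = sprintf("s%02d", 1:60),
    sex = sample(c("male", "female"), 60, replace = TRUE),
    cage = sample(sprintf("c%d", 1:6), 60, replace = TRUE),
    phenotype_raw = rnorm(60, 500, 50)))
  adj <- adjust_phenotype(md3)
  expect_lt(abs(mean(adj$phenotype_adj)), 1e-6)
  X <- model.matrix(~ factor(sex) + factor(cage), data = md3)
  expect_lt(max(abs(crossprod(X, adj$phenotype_adj))), 1e-6)

  # invariant to the categorical reference level
  md3b <- dplyr::mutate(md3, cage = factor(cage, levels = rev(sort(unique(cage)))))
  expect_equal(adjust_phenotype(md3b)$phenotype_adj, adj$phenotype_adj,
               tolerance = 1e-8)

  # a singleton cage gets residual zero by construction
  md4 <- tibble::tibble(sample_id = sprintf("s%d", 1:5), sex = "male",
                        cage = c("A", "A", "A", "A", "lone"),
                        phenotype_raw = c(9, 11, 10, 10, 99))
  expect_equal(adjust_phenotype(md4)$phenotype_adj[5], 0)
})

test_that("a planted sex effect is recovered by the residualization fit", {
  est <- withr::with_seed(19, {
    vapply(1:50, function(i) {
      md <- tibble::tibble(
        sample_id = sprintf("s%02d", 1:80),
        sex = rep(c("male", "female"), 40),
        cage = rep(sprintf("c%d", 1:8), each = 10),
        phenotype_raw = 500 + 50 * (sex == "male") + rnorm(80, 0, 30))
      coef(lm(phenotype_raw ~ factor(sex) + factor(cage), md))[["factor(sex)male"]]
    }, numeric(1))
  })
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 50), 3 * se + 1e-9)
})
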