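test_that("binary component handles degenerate and textbook cases", {
  # all-present: no absent group, undefined
  expect_null(binary_component(rep(1, 20), rnorm(20)))
  # two clean groups of two: slope is the mean difference
  res <- binary_component(c(0, 0, 1, 1), c(-1, -1, 1, 1), min_group = 2)
  expect_equal(res$beta1, 2)
  expect_lt(res$p_binary, 1e-10)  # zero residual variance -> floored p
  # constant phenotype is undefined
  expect_null(binary_component(c(0, 1, 0, 1, 0, 1), rep(3, 6), min_group = 3))
})

test_that("quantitative component transforms and fits among carriers only", {
  # constant abundance among carriers -> zero variance -> undefined
  ab <- c(rep(0.1, 12), rep(0, 4))
  expect_null(quant_component(ab, rnorm(16), min_present = 10))
  # noise-free linear relation recovers the slope exactly with floored p
  a <- exp(rnorm(20, -4, 1))
  q <- (log(a) - mean(log(a))) / sd(log(a))
  res <- quant_component(a, 3.5 * q, min_present = 10)
  expect_equal(res$beta2, 3.5, tolerance = 1e-12)
  expect_equal(res$p_quant, 1e-300)
})

test_that("components agree with independent regression oracles", {
  withr::with_seed(61, {
    for (i in 1:20) {
      n <- 60
      pres <- rbinom(n, 1, 0.5)
      if (min(sum(pres), n - sum(pres)) < 5) next
      y <- rnorm(n)
      res <- binary_component(pres, y)
      # pooled-variance two-sample t-test is the same model
      tt <- t.test(y[pres == 1], y[pres == 0], var.equal = TRUE)
      expect_equal(res$beta1, unname(diff(rev(tt$estimate))), tolerance = 1e-10)
      expect_equal(res$p_binary, tt$p.value, tolerance = 1e-10)

      ab <- ifelse(pres == 1, exp(rnorm(n, -5, 1)), 0)
      resq <- quant_component(ab, y, min_present = 5)
      keep <- ab > 0
      q <- scale(log(ab[keep]))[, 1]  # same mean-0 / sd-1 standardization
      fit <- summary(lm(y[keep] ~ q))
      expect_equal(resq$beta2, unname(coef(fit)[2, 1]), tolerance = 1e-10)
      expect_equal(resq$p_quant, unname(coef(fit)[2, 4]), tolerance = 1e-10)
    }
  })
})

test_that("unweighted-Z meta-analysis follows the normal combination rule", {
  z <- 1.3
  expect_equal(meta_component(z, z)$z_meta, sqrt(2) * z)
  m0 <- meta_component(1.7, -1.7)
  expect_equal(m0$z_meta, 0)
  expect_equal(m0$p_meta, 1)
  m <- meta_component(1.96, 0)
  expect_equal(m$z_meta, 1.96 / sqrt(2), tolerance = 1e-12)
  expect_equal(m$p_meta, 2 * pnorm(1.96 / sqrt(2), lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(m$p_meta, 0.16577, tolerance = 1e-4)
  expect_null(meta_component(NULL, 1))
})

test_that("z-from-p inversion round-trips across the full range", {
  p <- 10^seq(-10, 0, length.out = 40)
  p <- p[p < 1]
  z <- abs(microtrait:::z_from_p(p, 1))
  back <- 2 * pnorm(z, lower.tail = FALSE)
  expect_equal(back, p, tolerance = 1e-8)
})

test_that("the vectorized scan equals the per-OTU component functions", {
  rel <- rand_rel(50, 25, zero_frac = 0.35, seed = 41)
  ph <- pheno_adj(withr::with_seed(42, rnorm(50, 0, 2)), rel$sample_id)
  scan <- two_part_scan(rel, ph, min_group = 5, min_present = 8)
  for (j in seq_len(25)) {
    a <- rel[[j + 1]]
    row <- scan[j, ]
    b <- binary_component(as.numeric(a > 0), ph$phenotype_adj, min_group = 5)
    q <- quant_component(a, ph$phenotype_adj, min_present = 8)
    if (is.null(b)) {
      expect_true(is.na(row$p_binary))
    } else {
      expect_equal(row$beta1, b$beta1, tolerance = 1e-10)
      expect_equal(row$p_binary, b$p_binary, tolerance = 1e-10)
      expect_equal(row$z1, b$z1, tolerance = 1e-8)
    }
    if (is.null(q)) {
      expect_true(is.na(row$p_quant))
    } else {
      expect_equal(row$beta2, q$beta2, tolerance = 1e-10)
      expect_equal(row$p_quant, q$p_quant, tolerance = 1e-10)
    }
    if (!is.null(b) && !is.null(q)) {
      mm <- meta_component(b$z1, q$z2)
      expect_equal(row$z_meta, mm$z_meta, tolerance = 1e-8)
    }
    comps <- c(row$p_binary, row$p_quant, row$p_meta)
    if (all(is.na(comps))) {
      expect_true(is.na(row$p_final))
    } else {
      expect_equal(row$p_final, min(comps, na.rm = TRUE))
    }
  }
})

test_that("an OTU detected in every sample is tested by the quantitative part only", {
  rel <- rand_rel(40, 6, zero_frac = 0, seed = 43)
  ph <- pheno_adj(withr::with_seed(44, rnorm(40)), rel$sample_id)
  scan <- two_part_scan(rel, ph)
  expect_true(all(is.na(scan$p_binary)))
  expect_true(all(is.na(scan$p_meta)))
  expect_equal(scan$p_final, scan$p_quant)
})

test_that("min-P final p-values are anticonservative under the null", {
  sim <- simulate_microbiome(n_samples = 120, n_otus = 400, depth = 5000,
                             n_cages = 12, seed = 51)
  ph <- adjust_phenotype(sim$metadata)
  scan <- two_part_scan(to_relative(sim$counts), ph)
  expect_gt(mean(scan$p_final < 0.05, na.rm = TRUE), 0.05)
})

test_that("permutation FDR ranks a planted spike above 99 null OTUs", {
  rel <- rand_rel(100, 100, zero_frac = 0.3, seed = 71)
  y <- withr::with_seed(72, {
    a <- rel$OTU001
    q <- ifelse(a > 0, log(a), 0)
    5 * (a > 0) + 2 * scale(q)[, 1] + rnorm(100, 0, 1)
  })
  ph <- pheno_adj(y, rel$sample_id)
  scan <- two_part_scan(rel, ph)
  res <- permutation_fdr(scan, rel, ph, n_perm = 150, seed = 73)
  expect_lt(res$q_value[res$otu_id == "OTU001"], 0.05)
  # q is monotone non-decreasing in p_final
  ord <- order(res$p_final)
  q_sorted <- res$q_value[ord][!is.na(res$p_final[ord])]
  expect_true(all(diff(q_sorted) >= -1e-12))
  # deterministic given the seed
  res2 <- permutation_fdr(scan, rel, ph, n_perm = 150, seed = 73)
  expect_equal(res2$q_value, res$q_value)
  expect_error(permutation_fdr(scan, rel, ph, n_perm = 50), "at least 100")
})

test_that("untestable OTUs saturate at q = 1", {
  rel <- rand_rel(30, 8, zero_frac = 0.2, seed = 81)
  ph <- pheno_adj(rep(0, 30), rel$sample_id)  # constant phenotype
  scan <- two_part_scan(rel, ph)
  expect_true(all(is.na(scan$p_final)))
  res <- permutation_fdr(scan, rel, ph, n_perm = 100, seed = 82)
  expect_true(all(res$q_value == 1))
})

test_that("a planted strong binary effect is detected with high power", {
  # presence in half the samples, +2 SD phenotype shift, n = 135
  hits <- withr::with_seed(91, {
    vapply(1:60, function(i) {
      pres <- rbinom(135, 1, 0.5)
      y <- 2 * pres + rnorm(135)
      b <- binary_component(pres, y - mean(y))
      !is.null(b) && b$p_binary < 1e-4
    }, logical(1))
  })
  expect_gte(mean(hits), 0.9)
})
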