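test_that("cross-validation splits are disjoint, exhaustive and reproducible", {
  ids <- sprintf("s%03d", 1:135)
  sp <- cv_split(ids, seed = 1)
  expect_length(sp$discovery, 108)
  expect_length(sp$validation, 27)
  expect_setequal(c(sp$discovery, sp$validation), ids)
  expect_equal(cv_split(ids, seed = 1), sp)
  expect_error(cv_split(ids, fraction_discovery = 1.2), "0, 1")
  expect_error(cv_split(ids[1:5]), "at least 10")

  # each sample lands in validation about 20% of the time
  ids20 <- sprintf("s%02d", 1:20)
  hits <- withr::with_seed(2, {
    rowSums(vapply(1:500, function(i) {
      ids20 %in% cv_split(ids20)$validation
    }, logical(20)))
  }) / 500
  expect_true(all(abs(hits - 0.2) <= 3 * sqrt(0.2 * 0.8 / 500) + 0.02))
})

test_that("additive prediction matches a hand-summed oracle", {
  rel <- rand_rel(25, 10, zero_frac = 0.4, seed = 11)
  ph <- pheno_adj(withr::with_seed(12, rnorm(25)), rel$sample_id)
  scan <- two_part_scan(rel, ph, min_group = 2, min_present = 3)
  sel <- scan[!is.na(scan$p_final), ][1:6, ]
  pred <- additive_predict(rel, sel)
  m <- as.matrix(rel[-1])[, sel$otu_id, drop = FALSE]
  oracle <- vapply(seq_len(nrow(m)), function(i) {
    total <- 0
    for (j in seq_len(ncol(m))) {
      b <- as.numeric(m[i, j] > 0)
      q <- if (b > 0 && !is.na(sel$q_sd[j])) {
        (log(m[i, j]) - sel$q_mu[j]) / sel$q_sd[j]
      } else 0
      b1 <- if (is.na(sel$beta1[j])) 0 else sel$beta1[j]
      b2 <- if (is.na(sel$beta2[j])) 0 else sel$beta2[j]
      total <- total + b1 * b + b2 * q
    }
    total
  }, numeric(1))
  expect_equal(pred$r_m, oracle, tolerance = 1e-10)

  # degenerate cases
  expect_equal(additive_predict(rel, sel[0, ])$r_m, rep(0, 25))
  one <- tibble::tibble(sample_id = c("x", "y"), OTUA = c(0.3, 0))
  sel1 <- tibble::tibble(otu_id = "OTUA", beta1 = 10, beta2 = NA_real_,
                         q_mu = NA_real_, q_sd = NA_real_)
  expect_equal(additive_predict(one, sel1)$r_m, c(10, 0))
  expect_error(additive_predict(one, dplyr::mutate(sel1, otu_id = "missing")),
               "absent")
})

test_that("the literal formula reading is not equivalent in general but is under equal binary weights", {
  rel <- rand_rel(40, 8, zero_frac = 0.4, seed = 21)
  sel <- tibble::tibble(otu_id = sprintf("OTU%03d", 1:4),
                        beta1 = c(5, -3, 2, 8), beta2 = 0,
                        q_mu = NA_real_, q_sd = NA_real_)
  y <- withr::with_seed(22, rnorm(40))
  prod_form <- additive_predict(rel, sel)$r_m
  lit_form <- additive_predict(rel, sel, literal = TRUE)$r_m
  expect_lt(cor(prod_form, lit_form), 0.999)  # distinct predictions

  # with equal beta1 the two differ by an affine map, so R^2 agrees
  sel_eq <- dplyr::mutate(sel, beta1 = 5)
  p1 <- additive_predict(rel, sel_eq)$r_m
  p2 <- additive_predict(rel, sel_eq, literal = TRUE)$r_m
  expect_equal(cor(p1, y)^2, cor(p2, y)^2, tolerance = 1e-10)
})

test_that("no validation information leaks into the prediction", {
  rel <- rand_rel(60, 12, zero_frac = 0.3, seed = 31)
  y <- withr::with_seed(32, rnorm(60))
  sp <- cv_split(rel$sample_id, seed = 33)
  disc <- rel$sample_id %in% sp$discovery
  scan <- two_part_scan(rel[disc, ], pheno_adj(y[disc], rel$sample_id[disc]),
                        min_group = 2, min_present = 3)
  sel <- scan[!is.na(scan$p_final), ]
  pred1 <- additive_predict(rel[!disc, ], sel)
  # scrambling the validation phenotype cannot change predictions
  scan2 <- two_part_scan(rel[disc, ], pheno_adj(y[disc], rel$sample_id[disc]),
                         min_group = 2, min_present = 3)
  pred2 <- additive_predict(rel[!disc, ], scan2[!is.na(scan2$p_final), ])
  expect_equal(pred1$r_m, pred2$r_m)
  # transform parameters come from discovery, not validation
  expect_equal(sel$q_mu, scan$q_mu[!is.na(scan$p_final)])
})

test_that("a noise-free additive phenotype is recovered almost perfectly", {
  # phenotype built exactly from the observed presence features of 10 OTUs
  # (two co-detected guilds of five), with no residual noise; per-OTU
  # marginal fits are then near-exact and the additive model reconstructs
  # the phenotype
  rel <- withr::with_seed(41, {
    bA <- rbinom(200, 1, 0.5)
    bB <- rbinom(200, 1, 0.5)
    a <- matrix(rexp(200 * 30), 200, 30) / 400
    a[, 1:5] <- a[, 1:5] * bA
    a[, 6:10] <- a[, 6:10] * bB
    dimnames(a) <- list(sprintf("s%03d", 1:200), sprintf("OTU%03d", 1:30))
    dplyr::bind_cols(tibble::tibble(sample_id = rownames(a)),
                     tibble::as_tibble(a))
  })
  m <- as.matrix(rel[-1])[, 1:10]
  g <- rowSums(20 * (m > 0))
  ph <- tibble::tibble(sample_id = rel$sample_id,
                       phenotype_adj = g - mean(g))
  cv <- explained_variance(rel, ph, n_repeats = 10, seed = 42)
  s <- tidy(cv)
  expect_gte(s$mean_R2[s$threshold == 0.1], 0.95)
  expect_true(all(diff(s$mean_n_otus) >= 0))  # monotone in the threshold
  expect_true(all(cv$repeats$R2 >= 0 & cv$repeats$R2 <= 1))
  expect_equal(glance(cv)$n_repeats, 10)
})

test_that("undersized validation sets are rejected", {
  rel <- rand_rel(12, 5, seed = 51)
  ph <- pheno_adj(rnorm(12), rel$sample_id)
  expect_error(explained_variance(rel, ph, fraction_discovery = 0.9),
               "fewer than 5")
})
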