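#' Default pipeline parameters
#'
#' Returns the full parameter list for [run_pipeline()] with the defaults
#' used throughout the package (rarefaction to 40,000 tags; mean relative
#' abundance >= 0.05% and prevalence >= 5% filters; 1000 phenotype
#' permutations with FDR 0.05; SparCC edges at |r| > 0.4 and p < 0.05 with
#' 100 bootstraps; k = 2 CAGs validated by 999-permutation PERMANOVA;
#' Spearman screen at |rho| > 0.3, q < 0.05; 100 repeats of 80/20
#' cross-validation over thresholds 1e-5 ... 0.1). Override any element via
#' `...`.
#'
#' @param ... Named overrides of the defaults.
#' @return A named list of parameters.
#' @export
pipeline_params <- function(...) {
  defaults <- list(
    depth = 40000,
    min_mean_abundance = 5e-4,
    min_prevalence = 0.05,
    min_group = 5,
    min_present = 10,
    transform = "log",
    n_perm = 1000,
    fdr = 0.05,
    r_threshold = 0.4,
    p_threshold = 0.05,
    k = 2,
    n_boot = 100,
    n_inner = 20,
    n_exclude_iter = 20,
    exclude_threshold = 0.1,
    permanova_n_perm = 999,
    spearman_r = 0.3,
    spearman_q = 0.05,
    cv_thresholds = c(1e-5, 1e-4, 1e-3, 1e-2, 0.05, 0.1),
    cv_repeats = 100,
    fraction_discovery = 0.8
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0) {
    abort(sprintf("unknown parameter(s): %s", paste(unknown, collapse = ", ")))
  }
  modifyList(defaults, overrides)
}

#' Run the full microbiome-phenotype pipeline
#'
#' Executes preprocess (rarefy, relative abundance, OTU filter, phenotype
#' residualization) -> two-part association with permutation FDR ->
#' SparCC co-abundance network and CAGs (when at least 4 OTUs are
#' FDR-significant) -> Spearman feature screen (when a feature table is
#' given) -> cross-validated variance explained, writing every result table
#' plus a manifest of stage counts to `out_dir`. All randomness derives from
#' `seed` through fixed per-stage substreams, so a rerun with the same
#' inputs and seed writes byte-identical result files. Stage timings go to
#' `log.txt` only, which is the one file excluded from that guarantee.
#'
#' @param otu OTU count tibble or path to a TSV readable by
#'   [read_otu_table()].
#' @param metadata Metadata tibble or path readable by [read_metadata()].
#' @param out_dir Output directory (created if needed).
#' @param features Optional feature tibble or TSV path (samples as rows).
#' @param taxonomy Optional taxonomy tibble or TSV path; joined onto the
#'   significant-OTU table.
#' @param params Parameter list from [pipeline_params()].
#' @param seed Master integer seed.
#' @return Invisibly, a list with all in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(otu, metadata, out_dir, features = NULL,
                         taxonomy = NULL, params = pipeline_params(),
                         seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "log.txt")
  cat("", file = log_path)
  log_line <- function(...) {
    cat(sprintf(...), "\n", sep = "", file = log_path, append = TRUE)
  }
  timed <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)))
    })
    log_line("[%s] %.2fs", stage, proc.time()[["elapsed"]] - t0)
    out
  }

  if (is.character(otu)) otu <- read_otu_table(otu)
  if (is.character(metadata)) metadata <- read_metadata(metadata)
  if (is.character(features)) {
    features <- readr::read_tsv(features, show_col_types = FALSE)
    names(features)[1] <- "sample_id"
  }
  if (is.character(taxonomy)) taxonomy <- read_taxonomy(taxonomy)

  # sample set = intersection of table and metadata
  common <- intersect(otu$sample_id, metadata$sample_id)
  dropped <- setdiff(union(otu$sample_id, metadata$sample_id), common)
  if (length(dropped) > 0) {
    warn(sprintf("dropping %d sample(s) absent from table or metadata: %s",
                 length(dropped), paste(head(dropped, 10), collapse = ", ")))
    log_line("dropped samples: %s", paste(dropped, collapse = ", "))
  }
  otu <- otu[otu$sample_id %in% common, ]
  metadata <- metadata[metadata$sample_id %in% common, ]

  manifest <- list(n_samples_input = length(common))

  pre <- timed("preprocess", {
    rarefied <- rarefy(otu, params$depth, seed = stage_seed(seed, "rarefy"))
    rel_full <- to_relative(rarefied)
    flt <- filter_otus(rel_full, params$min_mean_abundance, params$min_prevalence)
    list(rarefied = rarefied, rel = flt$table, report = flt$report)
  })
  metadata <- metadata[metadata$sample_id %in% pre$rel$sample_id, ]
  pheno <- timed("adjust_phenotype", adjust_phenotype(metadata))
  manifest$n_samples_analyzed <- nrow(pre$rel)
  manifest$n_otus_input <- pre$report$n_input_otus
  manifest$n_otus_retained <- pre$report$n_retained

  scan <- timed("two_part_scan",
                two_part_scan(pre$rel, pheno, params$min_group,
                              params$min_present, params$transform))
  scan <- timed("permutation_fdr",
                permutation_fdr(scan, pre$rel, pheno, params$n_perm,
                                seed = stage_seed(seed, "permutation_fdr")))
  sig <- dplyr::filter(scan, .data$q_value < params$fdr)
  manifest$n_otus_significant <- nrow(sig)
  manifest$n_otus_positive <- sum(sig$direction > 0, na.rm = TRUE)
  manifest$n_otus_negative <- sum(sig$direction < 0, na.rm = TRUE)

  network <- NULL
  if (nrow(sig) >= 4) {
    network <- timed("co_abundance_network", {
      counts_sig <- pre$rarefied[c("sample_id", sig$otu_id)]
      co_abundance_network(counts_sig, rel = pre$rel, pheno = pheno,
                           r_threshold = params$r_threshold,
                           p_threshold = params$p_threshold, k = params$k,
                           n_boot = params$n_boot, n_inner = params$n_inner,
                           n_exclude_iter = params$n_exclude_iter,
                           exclude_threshold = params$exclude_threshold,
                           n_perm_permanova = params$permanova_n_perm,
                           seed = stage_seed(seed, "network"))
    })
    manifest$n_edges <- nrow(network$edges)
    manifest$n_cags <- length(unique(network$cag_labels$cag))
    manifest$permanova_p <- network$permanova$p_value
  } else {
    log_line("network skipped: %d significant OTU(s) < 4", nrow(sig))
    manifest$network_skipped <- TRUE
  }

  feat <- NULL
  if (!is.null(features)) {
    feat <- timed("spearman_scan",
                  spearman_scan(features[features$sample_id %in% pheno$sample_id, ],
                                pheno, params$spearman_r, params$spearman_q))
    manifest$n_features_significant <- nrow(feat$significant)
  }

  curve <- timed("explained_variance",
                 explained_variance(pre$rel, pheno,
                                    thresholds = params$cv_thresholds,
                                    n_repeats = params$cv_repeats,
                                    fraction_discovery = params$fraction_discovery,
                                    min_group = params$min_group,
                                    min_present = params$min_present,
                                    transform = params$transform,
                                    seed = stage_seed(seed, "variance")))
  manifest$variance_curve <- setNames(as.list(curve$summary$mean_R2),
                                      format(curve$summary$threshold,
                                             scientific = TRUE))

  timed("write_outputs", {
    jsonlite::write_json(pre$report, file.path(out_dir, "filter_report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    readr::write_tsv(pheno, file.path(out_dir, "phenotype_adjusted.tsv"))
    readr::write_tsv(scan, file.path(out_dir, "twopart_results.tsv"))
    sig_out <- sig
    if (!is.null(taxonomy)) {
      sig_out <- dplyr::left_join(sig_out, taxonomy, by = "otu_id")
    }
    readr::write_tsv(sig_out, file.path(out_dir, "significant_otus.tsv"))
    if (!is.null(network)) {
      readr::write_tsv(network$edges, file.path(out_dir, "network_edges.tsv"))
      readr::write_tsv(network$cag_labels, file.path(out_dir, "cag_membership.tsv"))
      if (!is.null(network$cag_assoc)) {
        readr::write_tsv(network$cag_assoc, file.path(out_dir, "cag_assoc.tsv"))
      }
      jsonlite::write_json(network$permanova, file.path(out_dir, "permanova.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
    }
    if (!is.null(feat)) {
      readr::write_tsv(feat$all, file.path(out_dir, "feature_assoc.tsv"))
    }
    readr::write_tsv(curve$summary, file.path(out_dir, "variance_curve.tsv"))
    readr::write_tsv(curve$repeats, file.path(out_dir, "variance_repeats.tsv"))
    yaml::write_yaml(c(params, list(seed = seed)),
                     file.path(out_dir, "params.yaml"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  })

  invisible(list(rel = pre$rel, report = pre$report, pheno = pheno,
                 scan = scan, significant = sig, network = network,
                 features = feat, variance = curve, manifest = manifest))
}
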