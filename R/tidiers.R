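#' Tidy a co-abundance network
#'
#' Returns the retained edge list as a tibble.
#'
#' @param x A `co_network` object.
#' @param ... Unused.
#' @return Tibble with `otu_a`, `otu_b`, `r`, `p`.
#' @export
tidy.co_network <- function(x, ...) x$edges

#' One-row summary of a co-abundance network
#'
#' @param x A `co_network` object.
#' @param ... Unused.
#' @return Tibble with node/edge/CAG counts and the PERMANOVA validation of
#'   the clustering.
#' @export
glance.co_network <- function(x, ...) {
  tibble(n_otus = length(x$otu_ids),
         n_edges = nrow(x$edges),
         n_cags = length(unique(x$cag_labels$cag)),
         permanova_F = x$permanova$pseudo_F,
         permanova_p = x$permanova$p_value)
}

#' @export
print.co_network <- function(x, ...) {
  cat(sprintf("Co-abundance network: %d OTUs, %d edges (|r| > %.2g, p < %.2g), %d CAGs\n",
              length(x$otu_ids), nrow(x$edges), x$params$r_threshold,
              x$params$p_threshold, length(unique(x$cag_labels$cag))))
  cat(sprintf("PERMANOVA: pseudo-F = %.3f, p = %.4g (%d permutations)\n",
              x$permanova$pseudo_F, x$permanova$p_value, x$permanova$n_perm))
  if (!is.null(x$cag_assoc)) {
    cat("CAG-phenotype association:\n")
    print(x$cag_assoc)
  }
  invisible(x)
}

#' Tidy a variance-explained curve
#'
#' @param x A `variance_curve` object.
#' @param ... Unused.
#' @return Per-threshold tibble with `threshold`, `mean_R2`, `sd_R2`,
#'   `mean_n_otus`.
#' @export
tidy.variance_curve <- function(x, ...) x$summary

#' One-row summary of a variance-explained curve
#'
#' @param x A `variance_curve` object.
#' @param ... Unused.
#' @return Tibble with the number of repeats and the largest mean validation
#'   R-squared with its threshold.
#' @export
glance.variance_curve <- function(x, ...) {
  i <- which.max(x$summary$mean_R2)
  tibble(n_repeats = x$n_repeats,
         n_thresholds = nrow(x$summary),
         best_threshold = x$summary$threshold[i],
         best_mean_R2 = x$summary$mean_R2[i])
}

#' @export
print.variance_curve <- function(x, ...) {
  cat(sprintf("Microbiome-explained variance over %d CV repeats (80/20 splits)\n",
              x$n_repeats))
  print(x$summary)
  invisible(x)
}
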