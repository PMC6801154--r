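#' Read an OTU count table from a tab-delimited file
#'
#' Reads a samples x OTUs table of sequence tag counts. The file must be
#' UTF-8, tab-delimited, with one header row and the identifiers in the first
#' column. Input may be oriented either way; the returned tibble always has
#' samples as rows, which is the canonical orientation every downstream
#' function assumes.
#'
#' @param path Path to a TSV file.
#' @param orientation Either `"samples_as_rows"` (default; first column holds
#'   sample ids) or `"otus_as_rows"` (first column holds OTU ids; the table is
#'   transposed on read).
#' @return A tibble with a `sample_id` character column followed by one
#'   integer column per OTU. Input ordering of samples and OTUs is preserved.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("sample_id\tOTU1\tOTU2", "s1\t5\t0", "s2\t2\t7"), tf)
#' read_otu_table(tf)
#' @export
read_otu_table <- function(path, orientation = c("samples_as_rows", "otus_as_rows")) {
  orientation <- match.arg(orientation)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(raw) < 1) abort("empty table")
  ids <- raw[[1]]
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate identifiers in first column: %s",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  other <- names(raw)[-1]
  if (anyDuplicated(other)) {
    abort(sprintf("duplicate identifiers in header: %s",
                  paste(unique(other[duplicated(other)]), collapse = ", ")))
  }
  cells <- as.matrix(raw[-1])
  num <- suppressWarnings(matrix(as.numeric(cells), nrow = nrow(cells)))
  bad <- which(is.na(num) | num < 0 | num != round(num), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "non-integer or negative count at row '%s', column '%s' (value '%s')",
      ids[bad[1, 1]], other[bad[1, 2]], cells[bad[1, 1], bad[1, 2]]))
  }
  storage.mode(num) <- "integer"
  rownames(num) <- ids
  colnames(num) <- other
  if (orientation == "otus_as_rows") num <- t(num)
  out <- as_tibble(num)
  dplyr::bind_cols(tibble(sample_id = rownames(num)), out)
}

#' Write an OTU count table to a tab-delimited file
#'
#' Writes in the canonical samples-as-rows orientation;
#' `read_otu_table(write_otu_table(x, f))` reproduces `x` exactly.
#'
#' @param table Tibble as returned by [read_otu_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(table, path) {
  validate_otu_table(table)
  readr::write_tsv(table, path, progress = FALSE)
  invisible(path)
}

#' Validate an OTU table tibble
#'
#' Checks the invariants of the in-memory representation: a `sample_id`
#' column of unique strings, unique OTU column names, and cells that are
#' non-negative integers (`kind = "counts"`) or fractions in \[0, 1\] with
#' rows summing to 1 (`kind = "relative"`).
#'
#' @param table Tibble to check.
#' @param kind `"counts"` or `"relative"`.
#' @return `table`, invisibly; aborts with an informative message otherwise.
#' @export
validate_otu_table <- function(table, kind = c("counts", "relative")) {
  kind <- match.arg(kind)
  if (!is.data.frame(table) || names(table)[1] != "sample_id") {
    abort("OTU table must be a data frame whose first column is `sample_id`")
  }
  if (anyDuplicated(table$sample_id)) abort("duplicate sample ids")
  if (anyDuplicated(names(table))) abort("duplicate OTU ids")
  if (ncol(table) > 1) {
    m <- otu_matrix(table)
    if (any(!is.finite(m))) abort("non-finite abundance values")
    if (any(m < 0)) abort("negative abundance values")
    if (kind == "counts" && any(m != round(m))) abort("counts must be integers")
    if (kind == "relative") {
      rs <- rowSums(m)
      off <- which(abs(rs - 1) > 1e-9)
      if (length(off) > 0) {
        abort(sprintf("relative-abundance rows must sum to 1; sample '%s' sums to %.12f",
                      table$sample_id[off[1]], rs[off[1]]))
      }
    }
  }
  invisible(table)
}

#' Read a sample metadata sheet
#'
#' Expects columns `sample_id`, `sex`, `cage` and `weight` (case-insensitive,
#' any order; extra columns are kept). Sex values are normalized to
#' `"male"`/`"female"` from `{M, F, male, female}` in any letter case. The
#' weight column is renamed `phenotype_raw`; the covariate-adjusted
#' `phenotype_adj` column only appears after [adjust_phenotype()].
#'
#' @param path Path to a TSV file.
#' @return A tibble with one record per sample.
#' @export
read_metadata <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  nm <- tolower(names(raw))
  need <- c("sample_id", "sex", "cage", "weight")
  missing <- setdiff(need, nm)
  if (length(missing) > 0) {
    abort(sprintf("metadata is missing required column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  names(raw) <- nm
  sex_map <- c(m = "male", f = "female", male = "male", female = "female")
  sex <- unname(sex_map[tolower(raw$sex)])
  if (anyNA(sex)) {
    abort(sprintf("unrecognized sex value(s): %s",
                  paste(unique(raw$sex[is.na(sex)]), collapse = ", ")))
  }
  weight <- suppressWarnings(as.numeric(raw$weight))
  if (any(is.na(weight) | !is.finite(weight))) {
    abort(sprintf("missing or non-numeric weight for sample(s): %s",
                  paste(raw$sample_id[is.na(weight) | !is.finite(weight)],
                        collapse = ", ")))
  }
  if (anyDuplicated(raw$sample_id)) abort("duplicate sample ids in metadata")
  tibble(sample_id = raw$sample_id, sex = sex, cage = raw$cage,
         phenotype_raw = weight)
}

#' Read a taxonomy map
#'
#' Two-column TSV mapping OTU id to a semicolon-delimited lineage string
#' (lineages may be truncated at any rank).
#'
#' @param path Path to a TSV file with columns `otu_id` and `lineage`.
#' @return A tibble with columns `otu_id`, `lineage`.
#' @export
read_taxonomy <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(raw) < 2) abort("taxonomy file needs two columns: otu_id, lineage")
  out <- tibble(otu_id = raw[[1]], lineage = raw[[2]])
  if (anyDuplicated(out$otu_id)) abort("duplicate otu ids in taxonomy map")
  out
}

#' Read an OTU table from a BIOM file
#'
#' Convenience reader for BIOM-format tables (dense or sparse payloads;
#' sparse data are expanded to dense). Requires the `biomformat` package.
#'
#' @param path Path to a BIOM file.
#' @return A tibble in the canonical samples-as-rows orientation.
#' @export
read_biom_table <- function(path) {
  if (!requireNamespace("biomformat", quietly = TRUE)) {
    abort("reading BIOM files requires the `biomformat` package")
  }
  b <- biomformat::read_biom(path)
  m <- as(biomformat::biom_data(b), "matrix")  # OTUs x samples in BIOM
  m <- t(m)
  if (any(m < 0) || any(m != round(m))) abort("BIOM payload is not integer counts")
  storage.mode(m) <- "integer"
  dplyr::bind_cols(tibble(sample_id = rownames(m)), as_tibble(m))
}
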