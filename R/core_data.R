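#' Construct an abundance table
#'
#' The central container of the pipeline: a samples x metabolites matrix of
#' non-negative ion intensities from a GC-TOF-MS profiling run, with one
#' genotype label per sample. Missing measurements are stored as \code{NA},
#' never as zero.
#'
#' @param values numeric matrix, samples in rows, metabolites in columns.
#'   Entries must be non-negative or \code{NA}.
#' @param sample_ids character vector of unique sample labels, one per row.
#' @param genotypes character vector of genotype labels, one per sample.
#' @param metabolite_names character vector of unique metabolite names, one
#'   per column. Leading/trailing whitespace is trimmed; matching elsewhere in
#'   the pipeline is exact after trimming (no fuzzy aliasing).
#' @return An object of class \code{abundance_table}: a list with elements
#'   \code{values}, \code{sample_ids}, \code{genotypes},
#'   \code{metabolite_names}.
#' @export
abundance_table <- function(values, sample_ids, genotypes, metabolite_names) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  sample_ids <- as.character(sample_ids)
  genotypes <- as.character(genotypes)
  metabolite_names <- trimws(as.character(metabolite_names))

  if (nrow(values) != length(sample_ids))
    stop("values has ", nrow(values), " rows but ", length(sample_ids),
         " sample ids were given")
  if (ncol(values) != length(metabolite_names))
    stop("values has ", ncol(values), " columns but ",
         length(metabolite_names), " metabolite names were given")
  if (length(genotypes) != length(sample_ids))
    stop("need exactly one genotype label per sample")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  dup <- metabolite_names[duplicated(metabolite_names)]
  if (length(dup))
    stop("duplicate metabolite names: ", paste(unique(dup), collapse = ", "))
  if (any(values < 0, na.rm = TRUE))
    stop("negative intensities are not allowed")

  dimnames(values) <- list(sample_ids, metabolite_names)
  structure(
    list(values = values, sample_ids = sample_ids, genotypes = genotypes,
         metabolite_names = metabolite_names),
    class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat("abundance_table: ", length(x$sample_ids), " samples x ",
      length(x$metabolite_names), " metabolites\n", sep = "")
  tab <- table(x$genotypes)
  cat("genotypes: ",
      paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
            collapse = ", "), "\n", sep = "")
  cat("missing cells: ", sum(is.na(x$values)), "\n", sep = "")
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$values)

# Internal: rows of `table` belonging to one genotype, error if too few for
# group statistics.
group_rows <- function(table, genotype, min_n = 1L) {
  idx <- which(table$genotypes == genotype)
  if (length(idx) == 0L)
    stop("genotype not present in table: ", genotype)
  if (length(idx) < min_n)
    stop("genotype ", genotype, " has ", length(idx),
         " samples; at least ", min_n, " required")
  idx
}

# Internal: subset metabolite columns, preserving order and class.
subset_metabolites <- function(table, keep) {
  abundance_table(table$values[, keep, drop = FALSE], table$sample_ids,
                  table$genotypes, table$metabolite_names[keep])
}

#' Read an abundance table from delimited text
#'
#' Expects a header row of metabolite names, the first column holding sample
#' ids, and one row per sample. Empty cells and the literal strings
#' \code{NA}/\code{nan} become missing values.
#'
#' @param path path to a CSV (or TSV, see \code{sep}) file.
#' @param genotype_map named character vector (or 2-column data frame with
#'   columns sample, genotype) mapping every sample id in the file to its
#'   genotype.
#' @param sep field separator; \code{","} by default.
#' @return An \code{\link{abundance_table}}.
#' @export
read_abundance_table <- function(path, genotype_map, sep = ",") {
  if (is.data.frame(genotype_map)) {
    if (ncol(genotype_map) < 2)
      stop("genotype_map data frame needs columns sample, genotype")
    genotype_map <- stats::setNames(as.character(genotype_map[[2]]),
                                    as.character(genotype_map[[1]]))
  }
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, na.strings = c("", "NA", "nan"),
                          comment.char = "")
  if (ncol(df) < 2)
    stop("file has no metabolite columns: ", path)
  sample_ids <- trimws(as.character(df[[1]]))
  values <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  metabolite_names <- trimws(colnames(df)[-1])
  dup <- unique(metabolite_names[duplicated(metabolite_names)])
  if (length(dup))
    stop("duplicate metabolite column(s): ", paste(dup, collapse = ", "))
  unknown <- setdiff(sample_ids, names(genotype_map))
  if (length(unknown))
    stop("sample(s) missing from genotype_map: ",
         paste(unknown, collapse = ", "))
  abundance_table(values, sample_ids,
                  unname(genotype_map[sample_ids]), metabolite_names)
}

#' Write an abundance table to delimited text
#'
#' Inverse of \code{\link{read_abundance_table}}; missing cells are written
#' as empty fields.
#'
#' @param table an \code{\link{abundance_table}}.
#' @param path output file path.
#' @param sep field separator.
#' @return \code{path}, invisibly.
#' @export
write_abundance_table <- function(table, path, sep = ",") {
  df <- data.frame(sample = table$sample_ids, check.names = FALSE,
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(table$values, check.names = FALSE))
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = TRUE,
                     na = "")
  invisible(path)
}

#' Presence filter: report a metabolite only if detected in every study group
#'
#' Retains a metabolite iff, in every genotype group, the fraction of
#' non-missing samples is at least \code{min_fraction}. The conventional
#' reporting rule for GC-TOF-MS panels is detection in at least 80% of the
#' samples per study group, applied before any statistics.
#'
#' @param table an \code{\link{abundance_table}}.
#' @param min_fraction minimum per-group fraction of non-missing samples, in
#'   (0, 1]. Default 0.8.
#' @return A filtered \code{abundance_table} with the surviving metabolites in
#'   their original order.
#' @export
presence_filter <- function(table, min_fraction = 0.8) {
  stopifnot(is.numeric(min_fraction), length(min_fraction) == 1L)
  if (min_fraction <= 0 || min_fraction > 1)
    stop("min_fraction must be in (0, 1], got ", min_fraction)
  groups <- unique(table$genotypes)
  present <- vapply(groups, function(g) {
    rows <- table$values[table$genotypes == g, , drop = FALSE]
    colMeans(!is.na(rows)) >= min_fraction
  }, logical(length(table$metabolite_names)))
  keep <- rowSums(!as.matrix(present)) == 0L
  if (!any(keep))
    stop("no metabolite passes the ", min_fraction,
         " presence threshold in every group")
  subset_metabolites(table, which(keep))
}

#' Total ion chromatogram (mTIC) normalization
#'
#' Divides each sample's intensities by that sample's summed signal over all
#' (identified) metabolites, removing per-sample loading and instrument
#' drift. With \code{rescale = "mean"} (default) the fractions are multiplied
#' back by the cohort mean of per-sample totals so values stay on the
#' original intensity magnitude. After normalization every sample has an
#' identical metabolite total.
#'
#' @param table an \code{\link{abundance_table}}; should already be
#'   presence-filtered and imputed (missing cells are ignored in the totals).
#' @param rescale \code{"mean"} (cohort-mean rescale, default) or
#'   \code{"none"} (pure fractions summing to 1 per sample).
#' @return A normalized \code{abundance_table}.
#' @export
normalize_tic <- function(table, rescale = c("mean", "none")) {
  rescale <- match.arg(rescale)
  totals <- rowSums(table$values, na.rm = TRUE)
  bad <- table$sample_ids[totals <= 0]
  if (length(bad))
    stop("sample(s) with non-positive total signal: ",
         paste(bad, collapse = ", "))
  scale_to <- if (rescale == "mean") mean(totals) else 1
  values <- table$values / totals * scale_to
  abundance_table(values, table$sample_ids, table$genotypes,
                  table$metabolite_names)
}

#' Half-minimum imputation of residual missing values
#'
#' Replaces each missing cell by half the minimum observed intensity of that
#' metabolite across all samples — the standard left-censoring surrogate for
#' below-detection-limit values in metabolomics. Intended to run after
#' \code{\link{presence_filter}} (so no metabolite is mostly missing) and
#' before \code{\link{normalize_tic}}.
#'
#' @param table an \code{\link{abundance_table}}.
#' @return An \code{abundance_table} with no missing entries. Tables without
#'   missing cells are returned unchanged.
#' @export
impute_missing <- function(table) {
  if (!anyNA(table$values)) return(table)
  values <- table$values
  for (j in seq_len(ncol(values))) {
    miss <- is.na(values[, j])
    if (!any(miss)) next
    if (all(miss))
      stop("metabolite entirely missing, cannot impute: ",
           table$metabolite_names[j])
    values[miss, j] <- min(values[, j], na.rm = TRUE) / 2
  }
  abundance_table(values, table$sample_ids, table$genotypes,
                  table$metabolite_names)
}
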