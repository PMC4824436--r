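#' Label a differential comparison for cross-genotype analysis
#'
#' Wraps a differential result table with the comparison's label and its
#' orientation, i.e. whether the test group is the gene-deficient condition.
#' Orientation matters: consensus calling compares directions across
#' comparisons, which is only meaningful when every comparison points the
#' same way (deficient over proficient).
#'
#' @param label comparison label, e.g. \code{"hom_vs_wt"}.
#' @param results a data frame from \code{\link{compare_groups}}.
#' @param alpha significance threshold used to derive the significant set;
#'   default 0.05.
#' @param test_is_deficient logical; \code{TRUE} when the test group is the
#'   gene-deficient condition.
#' @return A list of class \code{comparison_set}: \code{label},
#'   \code{results}, \code{alpha}, \code{test_is_deficient},
#'   \code{significant} (data frame \code{metabolite}, \code{direction},
#'   \code{p_value}).
#' @export
comparison_set <- function(label, results, alpha = 0.05,
                           test_is_deficient = NA) {
  sig <- results[results$p_value < alpha,
                 c("metabolite", "direction", "p_value"), drop = FALSE]
  rownames(sig) <- NULL
  structure(list(label = label, results = results, alpha = alpha,
                 test_is_deficient = test_is_deficient, significant = sig),
            class = "comparison_set")
}

#' Allele-discordance ratio between two mutant alleles
#'
#' When two independent loss-of-function alleles of the same gene are
#' compared head to head, metabolites that differ significantly between them
#' reflect allele-specific (or systematic) effects rather than loss of the
#' gene. The ratio of such discordant metabolites to the panel size is
#' reported; a ratio at or below the test's own false-positive rate
#' (100*alpha %) is consistent with systematic error rather than genuine
#' isoform differences.
#'
#' @param results either a differential data frame from
#'   \code{\link{compare_groups}} for the allele-vs-allele comparison, or
#'   directly the count of significantly different metabolites.
#' @param panel_size total number of metabolites in the panel (defaults to
#'   \code{nrow(results)} when \code{results} is a data frame).
#' @param alpha significance threshold; default 0.05.
#' @return A list: \code{n_discordant}, \code{panel_size},
#'   \code{percentage} (rounded to 1 decimal), \code{within_systematic_error}
#'   (\code{percentage <= 100 * alpha}).
#' @export
allele_discordance <- function(results, panel_size = NULL, alpha = 0.05) {
  if (is.data.frame(results)) {
    n <- sum(results$p_value < alpha)
    if (is.null(panel_size)) panel_size <- nrow(results)
  } else {
    n <- as.integer(results)
    if (is.null(panel_size)) stop("panel_size required when a count is given")
  }
  stopifnot(panel_size > 0, n >= 0, n <= panel_size)
  pct <- round(100 * n / panel_size, 1)
  list(n_discordant = n, panel_size = panel_size, percentage = pct,
       within_systematic_error = pct <= 100 * alpha)
}

#' Allele-specific and shared significant sets
#'
#' Partitions the union of two comparisons' significant metabolites into the
#' sets unique to each comparison and the shared set — the Venn view of
#' allele-specific metabolite changes.
#'
#' @param cmp_a,cmp_b \code{\link{comparison_set}} objects over the same
#'   metabolite panel.
#' @return A list \code{only_a}, \code{only_b}, \code{shared} (character
#'   vectors, sorted) plus \code{counts} (named integer vector).
#' @export
allele_specific_sets <- function(cmp_a, cmp_b) {
  pa <- sort(cmp_a$results$metabolite)
  pb <- sort(cmp_b$results$metabolite)
  if (!identical(pa, pb))
    stop("comparisons cover different metabolite panels")
  sa <- cmp_a$significant$metabolite
  sb <- cmp_b$significant$metabolite
  out <- list(only_a = sort(setdiff(sa, sb)),
              only_b = sort(setdiff(sb, sa)),
              shared = sort(intersect(sa, sb)))
  out$counts <- c(only_a = length(out$only_a), only_b = length(out$only_b),
                  shared = length(out$shared))
  out
}

#' Direction-consistent consensus call across genetic settings
#'
#' A metabolite is called a consensus target when it is significantly
#' changed in both comparisons (e.g. null-mutant vs wild type, and
#' GAL4-driver mutant vs its rescue strain) with the same direction of
#' change. Both comparisons must be oriented with the gene-deficient
#' condition as the test group; otherwise "same direction" is meaningless.
#'
#' @param cmp_mut_vs_wt,cmp_gal4_vs_rescue \code{\link{comparison_set}}
#'   objects with \code{test_is_deficient = TRUE}.
#' @return A data frame sorted by combined evidence (sum of -log10 p over
#'   the two comparisons, descending; ties by name): \code{metabolite},
#'   \code{direction}, \code{p_a}, \code{p_b}, \code{evidence}.
#' @export
consensus_call <- function(cmp_mut_vs_wt, cmp_gal4_vs_rescue) {
  for (cmp in list(cmp_mut_vs_wt, cmp_gal4_vs_rescue))
    if (!isTRUE(cmp$test_is_deficient))
      stop("comparison '", cmp$label, "' is not oriented with the ",
           "deficient condition as test group (set test_is_deficient)")
  a <- cmp_mut_vs_wt$significant
  b <- cmp_gal4_vs_rescue$significant
  shared <- merge(a, b, by = "metabolite", suffixes = c("_a", "_b"))
  hit <- shared[shared$direction_a == shared$direction_b, , drop = FALSE]
  out <- data.frame(metabolite = hit$metabolite,
                    direction = hit$direction_a,
                    p_a = hit$p_value_a,
                    p_b = hit$p_value_b,
                    evidence = -log10(hit$p_value_a) - log10(hit$p_value_b),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$evidence, out$metabolite), , drop = FALSE]
  rownames(out) <- NULL
  out
}
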