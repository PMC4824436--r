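#' Pavlidis template matching against a gene-dosage template
#'
#' Scores each metabolite's profile across an ordered genotype series by
#' Pearson correlation with a template vector (one value per genotype in the
#' series, e.g. \code{c(1, 0.5, 0)} for a monotone dosage-dependent decrease
#' across WT -> het -> hom). By default the correlation is computed over
#' replicate-level values, with the template value broadcast to every
#' replicate of its genotype; this gives the significance test its n-2
#' degrees of freedom over all replicates, mirroring how template matching
#' is applied in expression-analysis suites. \code{level = "means"} instead
#' correlates the per-genotype means with the template.
#'
#' A metabolite is \code{matched} only when its correlation is positive and
#' significant: anti-correlated profiles are captured by matching the
#' reversed template, so the up- and down-template matches are mutually
#' exclusive by construction.
#'
#' @param table an \code{\link{abundance_table}} with no missing values.
#' @param genotype_order ordered genotype labels (length >= 3), each present
#'   in the table.
#' @param template numeric template, one value per genotype in
#'   \code{genotype_order}; must be non-constant. Correlation is invariant
#'   to affine rescaling of the template.
#' @param threshold significance threshold on the correlation p-value;
#'   default 0.05.
#' @param level \code{"replicates"} (default) or \code{"means"}.
#' @return A data frame, one row per metabolite in input order:
#'   \code{metabolite}, \code{r} (Pearson correlation), \code{p_value}
#'   (two-sided, t-distribution with n-2 df), \code{matched},
#'   \code{degenerate} (TRUE for constant profiles, where r is undefined and
#'   the metabolite is reported unmatched).
#' @export
match_template <- function(table, genotype_order, template, threshold = 0.05,
                           level = c("replicates", "means")) {
  level <- match.arg(level)
  if (length(genotype_order) < 3)
    stop("genotype_order must list at least 3 genotypes")
  if (length(template) != length(genotype_order))
    stop("template length ", length(template), " != ",
         length(genotype_order), " genotypes")
  if (stats::sd(template) == 0) stop("template must be non-constant")
  if (anyNA(table$values))
    stop("table contains missing values; impute before template matching")
  rows <- lapply(genotype_order, function(g) group_rows(table, g))

  if (level == "replicates") {
    idx <- unlist(rows)
    tmpl <- rep(template, times = lengths(rows))
  } else {
    idx <- NULL
    tmpl <- template
  }

  res <- lapply(seq_along(table$metabolite_names), function(j) {
    y <- if (level == "replicates") table$values[idx, j]
         else vapply(rows, function(ii) mean(table$values[ii, j]), 0)
    if (stats::sd(y) == 0)
      return(c(r = NA_real_, p = NA_real_, degenerate = 1))
    ct <- stats::cor.test(y, tmpl, method = "pearson",
                          alternative = "two.sided")
    c(r = unname(ct$estimate), p = ct$p.value, degenerate = 0)
  })
  res <- do.call(rbind, res)
  out <- data.frame(
    metabolite = table$metabolite_names,
    r = res[, "r"],
    p_value = res[, "p"],
    matched = !is.na(res[, "r"]) & res[, "r"] > 0 &
      res[, "p"] < threshold,
    degenerate = res[, "degenerate"] == 1,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Report the matched gene-dosage clusters
#'
#' Collates the up- and down-template matches into two named clusters with
#' members sorted by correlation, strongest first. The two clusters cannot
#' overlap: a profile cannot be positively correlated with both a template
#' and its reversal.
#'
#' @param matches_up,matches_down data frames from
#'   \code{\link{match_template}} run with the monotone-up and monotone-down
#'   templates over the same table.
#' @return A list of two data frames, \code{dosage_up} and
#'   \code{dosage_down}, each with columns \code{metabolite}, \code{r},
#'   \code{p_value}, plus member counts \code{n_up}, \code{n_down}.
#' @export
dosage_report <- function(matches_up, matches_down) {
  pick <- function(m) {
    sel <- m[m$matched, c("metabolite", "r", "p_value"), drop = FALSE]
    sel <- sel[order(-sel$r, sel$metabolite), , drop = FALSE]
    rownames(sel) <- NULL
    sel
  }
  up <- pick(matches_up)
  down <- pick(matches_down)
  both <- intersect(up$metabolite, down$metabolite)
  if (length(both))
    stop("metabolite(s) matched both opposing templates (should be ",
         "impossible): ", paste(both, collapse = ", "))
  list(dosage_up = up, dosage_down = down,
       n_up = nrow(up), n_down = nrow(down))
}
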