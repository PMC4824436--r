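#' Two-group differential abundance (Student's t-test + fold change)
#'
#' Compares a test genotype against a reference genotype for every
#' metabolite. The p-value comes from a two-sided pooled-variance Student's
#' t-test (the classic form; set \code{welch = TRUE} for the unequal-variance
#' variant) and the fold change is the ratio of arithmetic group means,
#' test over reference — so fold change > 1 means up in the test group.
#'
#' @param table an \code{\link{abundance_table}}, normalized and imputed (no
#'   missing values).
#' @param test,reference genotype labels; each must have at least 2
#'   replicates.
#' @param alpha significance threshold for the \code{significant} flag;
#'   default 0.05 (raw p, no multiple-testing correction — an auxiliary
#'   Benjamini-Hochberg column \code{p_adj_bh} is provided but never drives
#'   the calls).
#' @param welch use Welch's unequal-variance t-test instead of the pooled
#'   form. Default \code{FALSE}.
#' @return A data frame with one row per metabolite, in input order:
#'   \code{metabolite}, \code{p_value}, \code{fold_change},
#'   \code{direction} ("up"/"down"), \code{significant}, \code{p_adj_bh},
#'   plus group means \code{mean_test}, \code{mean_reference}. When both
#'   groups are constant with equal means, p = 1 by convention.
#' @export
compare_groups <- function(table, test, reference, alpha = 0.05,
                           welch = FALSE) {
  if (anyNA(table$values))
    stop("table contains missing values; impute before group comparison")
  it <- group_rows(table, test, min_n = 2L)
  ir <- group_rows(table, reference, min_n = 2L)
  res <- lapply(seq_along(table$metabolite_names), function(j) {
    x <- table$values[it, j]
    y <- table$values[ir, j]
    my <- mean(y)
    if (my == 0)
      stop("zero reference mean for metabolite ", table$metabolite_names[j])
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      p <- if (mean(x) == my) 1 else 0
    } else {
      p <- stats::t.test(x, y, var.equal = !welch)$p.value
    }
    c(p = p, fc = mean(x) / my, mt = mean(x), mr = my)
  })
  res <- do.call(rbind, res)
  out <- data.frame(
    metabolite = table$metabolite_names,
    p_value = res[, "p"],
    fold_change = res[, "fc"],
    direction = ifelse(res[, "fc"] > 1, "up", "down"),
    significant = res[, "p"] < alpha,
    p_adj_bh = stats::p.adjust(res[, "p"], method = "BH"),
    mean_test = res[, "mt"],
    mean_reference = res[, "mr"],
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Count significant metabolites and their directions
#'
#' @param results a differential data frame from \code{\link{compare_groups}}
#'   (or any data frame with \code{p_value} and \code{fold_change} columns).
#' @param alpha significance threshold; default 0.05.
#' @return A list \code{n_sig}, \code{n_up}, \code{n_down} with
#'   \code{n_sig = n_up + n_down}.
#' @export
summarize_filter <- function(results, alpha = 0.05) {
  stopifnot(nrow(results) > 0)
  sig <- results$p_value < alpha
  list(n_sig = sum(sig),
       n_up = sum(sig & results$fold_change > 1),
       n_down = sum(sig & results$fold_change < 1))
}

#' Rank the extremes of a differential table
#'
#' Deterministic report of the largest and smallest fold changes and the
#' smallest p-values. All orderings break ties alphabetically by metabolite
#' name.
#'
#' @param results a differential data frame (see
#'   \code{\link{summarize_filter}}).
#' @param n_top number of rows per ranking; default 5.
#' @return A list of three data frames: \code{top_fold_change} (descending
#'   fold change), \code{bottom_fold_change} (ascending), \code{top_p}
#'   (ascending p-value).
#' @export
rank_extremes <- function(results, n_top = 5) {
  stopifnot(nrow(results) > 0)
  take <- function(ord) {
    out <- results[ord, c("metabolite", "p_value", "fold_change"),
                   drop = FALSE]
    rownames(out) <- NULL
    utils::head(out, n_top)
  }
  list(
    top_fold_change = take(order(-results$fold_change, results$metabolite)),
    bottom_fold_change = take(order(results$fold_change, results$metabolite)),
    top_p = take(order(results$p_value, results$metabolite)))
}

#' Load the published trpA1-vs-wild-type differential table fixture
#'
#' The package ships the 46-row table of metabolites significantly changed
#' (Student's t-test, p < 0.05) in the trpA1 null mutant relative to wild
#' type, with fold changes computed as mutant mean over wild-type mean, as a
#' plain-text fixture. Several p-values were published rounded to three
#' decimals as \code{0.000}; these are left-censored at display resolution
#' and stored here as 5e-4 with \code{p_censored = TRUE}, so that exact
#' scientific-notation entries (down to 2.1e-08) rank below them, consistent
#' with the published ranking of most-significant metabolites.
#'
#' @param path fixture path; defaults to the copy installed with the
#'   package.
#' @return A data frame with columns \code{metabolite}, \code{p_value},
#'   \code{p_censored}, \code{fold_change}, \code{direction},
#'   \code{significant}.
#' @export
read_published_differential <- function(path = system.file(
    "extdata", "trpa1_vs_wt_differential.csv", package = "metabodose",
    mustWork = TRUE)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(p_value = "character"))
  censored <- trimws(df$p_value) == "0.000"
  p <- ifelse(censored, 5e-4, suppressWarnings(as.numeric(df$p_value)))
  if (anyNA(p)) stop("unparseable p-value in fixture: ",
                     paste(df$p_value[is.na(p)], collapse = ", "))
  data.frame(metabolite = trimws(df$metabolite),
             p_value = p,
             p_censored = censored,
             fold_change = df$fold_change,
             direction = ifelse(df$fold_change > 1, "up", "down"),
             significant = p < 0.05,
             stringsAsFactors = FALSE)
}
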