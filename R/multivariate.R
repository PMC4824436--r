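#' Principal component analysis of an abundance table
#'
#' Unsupervised projection of the samples x metabolites matrix via singular
#' value decomposition. The default scaling is autoscaling (centre to zero
#' mean, scale to unit variance per metabolite), the usual choice for
#' metabolomics panels whose intensities span orders of magnitude;
#' \code{scaling = "center"} gives covariance PCA.
#'
#' Component signs follow a deterministic convention: within each component
#' the loading of largest magnitude is made positive.
#'
#' @param table an \code{\link{abundance_table}} with no missing values, at
#'   least 2 samples and 2 metabolites.
#' @param scaling \code{"autoscale"} (default) or \code{"center"}.
#' @return A list of class \code{pca_result}:
#'   \code{scores} (samples x components), \code{loadings}
#'   (metabolites x components), \code{variance_fraction} (per-component
#'   fraction of total variance, non-increasing), \code{genotypes}.
#' @export
run_pca <- function(table, scaling = c("autoscale", "center")) {
  scaling <- match.arg(scaling)
  x <- table$values
  if (anyNA(x)) stop("table contains missing values; impute before PCA")
  if (nrow(x) < 2 || ncol(x) < 2)
    stop("PCA needs at least 2 samples and 2 metabolites")
  if (scaling == "autoscale") {
    sds <- apply(x, 2, stats::sd)
    zero <- table$metabolite_names[sds == 0]
    if (length(zero))
      stop("zero-variance metabolite(s) under autoscaling: ",
           paste(zero, collapse = ", "))
  }
  fit <- stats::prcomp(x, center = TRUE, scale. = (scaling == "autoscale"))
  # sign convention: largest-magnitude loading positive per component
  for (k in seq_len(ncol(fit$rotation))) {
    lead <- which.max(abs(fit$rotation[, k]))
    if (fit$rotation[lead, k] < 0) {
      fit$rotation[, k] <- -fit$rotation[, k]
      fit$x[, k] <- -fit$x[, k]
    }
  }
  structure(
    list(scores = fit$x, loadings = fit$rotation,
         variance_fraction = fit$sdev^2 / sum(fit$sdev^2),
         genotypes = table$genotypes),
    class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  k <- min(5L, length(x$variance_fraction))
  cat("pca_result: ", nrow(x$scores), " samples, ",
      length(x$variance_fraction), " components\n", sep = "")
  cat("variance explained: ",
      paste(sprintf("PC%d %.1f%%", seq_len(k),
                    100 * x$variance_fraction[seq_len(k)]), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

# Internal: Spearman dissimilarity (1 - rank correlation, midranks for ties)
# between rows of `m`; errors on constant rows, where rank correlation is
# undefined.
spearman_dissimilarity <- function(m, item_names) {
  const <- apply(m, 1, function(v) stats::sd(v) == 0)
  if (any(const))
    stop("constant profile(s), Spearman correlation undefined: ",
         paste(item_names[const], collapse = ", "))
  stats::as.dist(1 - stats::cor(t(m), method = "spearman"))
}

#' Hierarchical clustering with Spearman distance and average linkage
#'
#' Clusters samples or metabolites using the dissimilarity
#' d = 1 - Spearman rank correlation (midranks for ties) under average
#' (UPGMA) linkage — the standard heatmap companion view for genotype-series
#' metabolomics. Because Spearman depends only on ranks, any monotone
#' transform of the intensities leaves the dendrogram unchanged.
#'
#' @param table an \code{\link{abundance_table}} with no missing values.
#' @param axis cluster \code{"samples"} (default) or \code{"metabolites"}.
#' @return An object of class \code{hclust} with attributes \code{metric}
#'   (\code{"spearman"}) and \code{linkage} (\code{"average"}).
#' @export
cluster_hca <- function(table, axis = c("samples", "metabolites")) {
  axis <- match.arg(axis)
  if (anyNA(table$values))
    stop("table contains missing values; impute before clustering")
  m <- if (axis == "samples") table$values else t(table$values)
  items <- if (axis == "samples") table$sample_ids else table$metabolite_names
  if (nrow(m) < 3)
    stop("need at least 3 ", axis, " to cluster")
  d <- spearman_dissimilarity(m, items)
  hc <- stats::hclust(d, method = "average")
  attr(hc, "metric") <- "spearman"
  attr(hc, "linkage") <- "average"
  hc
}

#' Export a dendrogram as Newick text
#'
#' Writes the clustering tree with merge heights as branch lengths, readable
#' by any phylogenetic/dendrogram viewer.
#'
#' @param hc an \code{hclust} object (e.g. from \code{\link{cluster_hca}}).
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_dendrogram_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
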