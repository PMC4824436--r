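#' Default pipeline configuration
#'
#' Returns the configuration list consumed by \code{\link{run_pipeline}},
#' optionally overridden by a YAML file and/or named arguments. With no
#' abundance path the pipeline runs on a synthetic table generated by
#' \code{\link{generate_abundance}} under \code{sim} (see
#' \code{\link{sim_config}}).
#'
#' @param yaml optional YAML file whose keys override the defaults.
#' @param ... named overrides applied after the YAML.
#' @return A named list: paths (\code{abundance}, \code{genotype_map},
#'   \code{annotation}, \code{reaction_pairs}, \code{out_dir}), thresholds
#'   (\code{alpha}, \code{presence_fraction}, \code{tanimoto_threshold},
#'   \code{ptm_threshold}), \code{scaling}, \code{genotype_order},
#'   \code{templates} (\code{up}, \code{down}), \code{comparisons} (list of
#'   \code{label}/\code{test}/\code{reference}/\code{test_is_deficient}),
#'   \code{consensus_pair} (two comparison labels), \code{sim}, \code{seed}.
#' @export
pipeline_config <- function(yaml = NULL, ...) {
  cfg <- list(
    abundance = NULL, genotype_map = NULL, annotation = NULL,
    reaction_pairs = NULL, out_dir = "results",
    alpha = 0.05, presence_fraction = 0.8, tanimoto_threshold = 0.7,
    ptm_threshold = 0.05, scaling = "autoscale", tic_rescale = "mean",
    genotype_order = c("WT", "het", "hom"),
    templates = list(down = c(1, 0.5, 0), up = c(0, 0.5, 1)),
    comparisons = list(
      list(label = "hom_vs_wt", test = "hom", reference = "WT",
           test_is_deficient = TRUE),
      list(label = "gal4_vs_wt", test = "gal4", reference = "WT",
           test_is_deficient = TRUE),
      list(label = "gal4_vs_rescue", test = "gal4", reference = "rescue",
           test_is_deficient = TRUE),
      list(label = "hom_vs_gal4", test = "hom", reference = "gal4",
           test_is_deficient = NA)),
    consensus_pair = c("hom_vs_wt", "gal4_vs_rescue"),
    sim = list(), seed = 1L)
  if (!is.null(yaml)) {
    over <- yaml::read_yaml(yaml)
    cfg[names(over)] <- over
  }
  dots <- list(...)
  cfg[names(dots)] <- dots
  for (p in c("abundance", "genotype_map", "annotation", "reaction_pairs"))
    if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]]))
      stop("configured ", p, " file does not exist: ", cfg[[p]])
  stopifnot(cfg$alpha > 0, cfg$alpha < 1,
            cfg$presence_fraction > 0, cfg$presence_fraction <= 1,
            cfg$tanimoto_threshold > 0, cfg$tanimoto_threshold <= 1)
  cfg
}

#' Run the full genotype-series metabolomics pipeline
#'
#' Executes, in order: data loading (or synthetic generation), presence
#' filtering, half-minimum imputation, mTIC normalization, differential
#' abundance for every configured genotype pair, PCA and hierarchical
#' clustering, Pavlidis template matching against the monotone dosage
#' templates, two-layer network assembly (when annotations are configured),
#' and cross-genotype consensus calling. Every stage output is written under
#' \code{out_dir} together with a manifest (config, file hashes, seed), so a
#' rerun with the same inputs and seed is bit-identical for all
#' deterministic stages.
#'
#' @param config a configuration list from \code{\link{pipeline_config}}.
#' @return The manifest, invisibly: a list with \code{outputs} (named file
#'   paths), \code{md5} (their checksums), \code{config}, and the key stage
#'   summaries (\code{filter_counts}, \code{dosage_counts},
#'   \code{n_consensus}).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  emit <- function(name, path) outputs[[name]] <<- path

  # -- stage: core data ------------------------------------------------
  if (is.null(config$abundance)) {
    sim <- do.call(sim_config, c(config$sim, list(seed = config$seed)))
    gen <- generate_abundance(sim)
    table <- gen$table
    truth_path <- file.path(out_dir, "truth.json")
    write_truth(gen$truth, truth_path)
    emit("truth", truth_path)
  } else {
    gm <- utils::read.csv(config$genotype_map, stringsAsFactors = FALSE)
    table <- read_abundance_table(config$abundance, gm)
  }
  table <- presence_filter(table, config$presence_fraction)
  table <- impute_missing(table)
  table <- normalize_tic(table, config$tic_rescale)
  norm_path <- file.path(out_dir, "normalized_abundance.csv")
  write_abundance_table(table, norm_path)
  emit("normalized", norm_path)

  # -- stage: differential --------------------------------------------
  diffs <- list()
  for (cmp in config$comparisons) {
    res <- compare_groups(table, cmp$test, cmp$reference,
                          alpha = config$alpha)
    diffs[[cmp$label]] <- res
    p <- file.path(out_dir, paste0("differential_", cmp$label, ".tsv"))
    utils::write.table(res, p, sep = "\t", row.names = FALSE, quote = FALSE)
    emit(paste0("differential_", cmp$label), p)
  }
  first <- diffs[[config$comparisons[[1]]$label]]
  counts <- summarize_filter(first, config$alpha)
  counts_path <- file.path(out_dir, "filter_counts.json")
  jsonlite::write_json(counts, counts_path, auto_unbox = TRUE)
  emit("filter_counts", counts_path)

  # -- stage: multivariate --------------------------------------------
  pca <- run_pca(table, config$scaling)
  scores <- data.frame(sample = rownames(pca$scores),
                       genotype = pca$genotypes, pca$scores[, 1:2],
                       check.names = FALSE)
  p <- file.path(out_dir, "pca_scores.tsv")
  utils::write.table(scores, p, sep = "\t", row.names = FALSE, quote = FALSE)
  emit("pca_scores", p)
  hca <- cluster_hca(table, "samples")
  p <- file.path(out_dir, "hca_samples.nwk")
  write_dendrogram_newick(hca, p)
  emit("hca_samples", p)

  # -- stage: dosage template matching --------------------------------
  ord <- config$genotype_order
  m_up <- match_template(table, ord, config$templates$up,
                         config$ptm_threshold)
  m_down <- match_template(table, ord, config$templates$down,
                           config$ptm_threshold)
  report <- dosage_report(m_up, m_down)
  p <- file.path(out_dir, "dosage_clusters.json")
  jsonlite::write_json(report, p, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  emit("dosage_clusters", p)

  # -- stage: chemical / biochemical network --------------------------
  if (!is.null(config$annotation)) {
    ann <- read_annotations(config$annotation)
    sim_layer <- build_similarity_layer(ann, config$tanimoto_threshold)
    rx_layer <- if (!is.null(config$reaction_pairs))
      build_reaction_layer(config$reaction_pairs, ann$name)
    else data.frame(from = character(0), to = character(0))
    # every cohort metabolite is a node; annotations only gate edges
    net_nodes <- first$metabolite
    g <- assemble_network(
      sim_layer[sim_layer$from %in% net_nodes &
                  sim_layer$to %in% net_nodes, , drop = FALSE],
      rx_layer[rx_layer$from %in% net_nodes &
                 rx_layer$to %in% net_nodes, , drop = FALSE],
      first, nodes = net_nodes)
    sif <- file.path(out_dir, "network.sif")
    attrs <- file.path(out_dir, "network_nodes.tsv")
    gml <- file.path(out_dir, "network.graphml")
    write_network_sif(g, sif, attrs)
    write_network_graphml(g, gml)
    emit("network_sif", sif); emit("network_nodes", attrs)
    emit("network_graphml", gml)
  }

  # -- stage: consensus ------------------------------------------------
  pair <- config$consensus_pair
  n_consensus <- NA_integer_
  if (all(pair %in% names(diffs))) {
    cmp_a <- comparison_set(pair[1], diffs[[pair[1]]], config$alpha,
                            test_is_deficient = TRUE)
    cmp_b <- comparison_set(pair[2], diffs[[pair[2]]], config$alpha,
                            test_is_deficient = TRUE)
    cons <- consensus_call(cmp_a, cmp_b)
    n_consensus <- nrow(cons)
    p <- file.path(out_dir, "consensus.tsv")
    utils::write.table(cons, p, sep = "\t", row.names = FALSE, quote = FALSE)
    emit("consensus", p)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("metabodose")),
    seed = config$seed,
    config = config[setdiff(names(config), "out_dir")],
    outputs = as.list(outputs),
    md5 = as.list(tools::md5sum(unlist(outputs))),
    filter_counts = counts,
    dosage_counts = list(n_up = report$n_up, n_down = report$n_down),
    n_consensus = n_consensus,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(manifest)
}

#' Replicate the published differential-table summaries from the fixture
#'
#' Recomputes, from the packaged 46-row differential table alone: the
#' significant/up/down counts, the fold-change and p-value extremes, and the
#' styled network node table (size from |log2 FC|, red/blue colour by
#' direction for significant metabolites).
#'
#' @param fixture differential fixture data frame; defaults to
#'   \code{\link{read_published_differential}()}.
#' @param alpha significance threshold; default 0.05.
#' @return A list: \code{counts} (from \code{\link{summarize_filter}}),
#'   \code{extremes} (from \code{\link{rank_extremes}}), \code{node_table}
#'   (data frame name, fold_change, p_value, node_size, node_color).
#' @export
replicate_table1 <- function(fixture = read_published_differential(),
                             alpha = 0.05) {
  counts <- summarize_filter(fixture, alpha)
  extremes <- rank_extremes(fixture)
  g <- assemble_network(
    similarity = data.frame(from = character(0), to = character(0),
                            score = numeric(0)),
    reaction = data.frame(from = character(0), to = character(0)),
    differential = fixture)
  node_table <- data.frame(name = igraph::V(g)$name,
                           fold_change = igraph::V(g)$fold_change,
                           p_value = igraph::V(g)$p_value,
                           node_size = igraph::V(g)$node_size,
                           node_color = igraph::V(g)$node_color,
                           stringsAsFactors = FALSE)
  list(counts = counts, extremes = extremes, node_table = node_table)
}
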