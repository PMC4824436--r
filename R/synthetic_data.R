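#' Simulation configuration for the genotype-series study design
#'
#' Describes a synthetic GC-TOF-MS metabolite profiling experiment over an
#' ordered genotype series (wild type, heterozygote, homozygous mutant,
#' rescue, GAL4-driver mutant) with planted effect structure:
#' \describe{
#'   \item{dosage}{metabolites whose abundance changes monotonically with
#'     gene dosage across WT -> het -> hom; the heterozygote carries half the
#'     homozygote effect on the log2 scale (linear-in-log dosage).}
#'   \item{consensus}{metabolites altered concordantly in both
#'     TRPA1-deficient backgrounds (hom and gal4) relative to WT, and
#'     restored to the WT mean in the rescue genotype.}
#'   \item{marker}{one metabolite with a very large fold change in every
#'     mutant-background genotype, emulating the eye-pigment xanthurenic-acid
#'     artifact of mini-white marker insertions.}
#' }
#' All remaining metabolites are null (identical group means).
#'
#' @param n_metabolites panel size; default 109 identified metabolites.
#' @param replicates_per_genotype biological replicates per genotype;
#'   default 6.
#' @param genotypes ordered genotype labels; default
#'   \code{c("WT","het","hom","rescue","gal4")}.
#' @param baseline_log_mean,baseline_log_sd natural-log mean and sd of the
#'   lognormal draw of per-metabolite baseline abundances (arbitrary ion
#'   counts). Defaults 10 and 1.0 give right-skewed intensities spanning
#'   two to three orders of magnitude while keeping the identified-compound
#'   total spread across the panel — the regime in which mTIC normalization
#'   is appropriate (no single compound dominates the summed signal).
#' @param cv multiplicative noise coefficient of variation on the natural
#'   scale; default 0.2. \code{cv = 0} yields noise-free tables equal to the
#'   true means.
#' @param planted_dosage_down,planted_dosage_up integer metabolite indices
#'   (1-based) with monotone decrease / increase across WT -> het -> hom.
#'   Defaults mirror the observed dosage clusters: 17 down, 9 up.
#' @param planted_consensus named numeric vector: indices with a concordant
#'   hom + gal4 effect, values giving the signed per-metabolite log2 effect.
#'   Default: two down, one up at the configured effect size (emulating
#'   methionine / ornithine / glucose-6-phosphate).
#' @param marker_index,marker_log2 index and log2 effect of the marker
#'   metabolite; \code{marker_index = NA} disables it. Default log2 effect
#'   4.7 (~26-fold).
#' @param effect_size_log2 magnitude of the homozygote dosage effect in log2
#'   units; default 1.
#' @param missing_rate fraction of cells masked missing completely at
#'   random; default 0 (no missingness).
#' @param seed integer random seed consumed by \code{\link{generate_abundance}}.
#' @return A \code{sim_config} list, validated (planted sets pairwise
#'   disjoint, indices in range, effects finite and nonzero).
#' @export
sim_config <- function(n_metabolites = 109,
                       replicates_per_genotype = 6,
                       genotypes = c("WT", "het", "hom", "rescue", "gal4"),
                       baseline_log_mean = 10,
                       baseline_log_sd = 1.0,
                       cv = 0.2,
                       planted_dosage_down = 1:17,
                       planted_dosage_up = 18:26,
                       planted_consensus = c("27" = -1, "28" = -1, "29" = 1),
                       marker_index = 30,
                       marker_log2 = 4.7,
                       effect_size_log2 = 1,
                       missing_rate = 0,
                       seed = 1L) {
  cfg <- list(
    n_metabolites = as.integer(n_metabolites),
    replicates_per_genotype = as.integer(replicates_per_genotype),
    genotypes = as.character(genotypes),
    baseline_log_mean = baseline_log_mean,
    baseline_log_sd = baseline_log_sd,
    cv = cv,
    planted_dosage_down = as.integer(planted_dosage_down),
    planted_dosage_up = as.integer(planted_dosage_up),
    planted_consensus = planted_consensus,
    marker_index = if (length(marker_index) && !is.na(marker_index[1]))
      as.integer(marker_index[1]) else NA_integer_,
    marker_log2 = marker_log2,
    effect_size_log2 = effect_size_log2,
    missing_rate = missing_rate,
    seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_metabolites >= 1, cfg$replicates_per_genotype >= 2,
            length(cfg$genotypes) >= 1, cfg$cv >= 0,
            cfg$missing_rate >= 0, cfg$missing_rate < 1)
  cons_idx <- as.integer(names(cfg$planted_consensus))
  sets <- list(down = cfg$planted_dosage_down, up = cfg$planted_dosage_up,
               consensus = cons_idx,
               marker = if (is.na(cfg$marker_index)) integer(0) else cfg$marker_index)
  all_idx <- unlist(sets, use.names = FALSE)
  if (length(all_idx) && (min(all_idx) < 1 || max(all_idx) > cfg$n_metabolites))
    stop("planted metabolite index out of range 1..", cfg$n_metabolites)
  if (anyDuplicated(all_idx))
    stop("planted sets must be pairwise disjoint; overlapping index: ",
         paste(unique(all_idx[duplicated(all_idx)]), collapse = ", "))
  effects <- c(if (length(sets$down)) -cfg$effect_size_log2,
               if (length(sets$up)) cfg$effect_size_log2,
               cfg$planted_consensus,
               if (!is.na(cfg$marker_index)) cfg$marker_log2)
  if (length(effects) && any(!is.finite(effects) | effects == 0))
    stop("planted effect sizes must be finite and nonzero")
  invisible(cfg)
}

# Internal: n_metabolites x n_genotypes matrix of true log2 effects relative
# to baseline. Dosage effects scale linearly in log2 with gene dosage
# (WT 0, het 1/2, hom 1); consensus effects hit hom and gal4 with rescue at
# baseline; the marker hits every non-WT genotype.
true_log2_effects <- function(cfg) {
  eff <- matrix(0, cfg$n_metabolites, length(cfg$genotypes),
                dimnames = list(NULL, cfg$genotypes))
  dosage_frac <- c(WT = 0, het = 0.5, hom = 1)
  for (g in intersect(names(dosage_frac), cfg$genotypes)) {
    eff[cfg$planted_dosage_down, g] <- -cfg$effect_size_log2 * dosage_frac[[g]]
    eff[cfg$planted_dosage_up, g] <- cfg$effect_size_log2 * dosage_frac[[g]]
  }
  cons_idx <- as.integer(names(cfg$planted_consensus))
  for (g in intersect(c("hom", "gal4"), cfg$genotypes))
    eff[cons_idx, g] <- unname(cfg$planted_consensus)
  if (!is.na(cfg$marker_index)) {
    mutants <- setdiff(cfg$genotypes, "WT")
    eff[cfg$marker_index, mutants] <- cfg$marker_log2
  }
  eff
}

#' Generate a synthetic abundance table with known ground truth
#'
#' Draws per-metabolite baselines from a lognormal distribution, applies the
#' planted log2 effects of the configuration, and adds multiplicative
#' lognormal noise with coefficient of variation \code{cv}, mean-preserving
#' (so the expected value of every cell equals its true group mean; with
#' \code{cv = 0} the table equals the truth exactly). The same seed always
#' reproduces the same table bit for bit.
#'
#' @param config a \code{\link{sim_config}}.
#' @return A list with elements
#'   \describe{
#'     \item{table}{an \code{\link{abundance_table}} of strictly positive
#'       intensities (missing cells only if \code{missing_rate > 0}),
#'       samples named \code{<genotype>_<replicate>}, metabolites
#'       \code{met001 ...}.}
#'     \item{truth}{data frame with one row per metabolite: \code{metabolite},
#'       \code{class} (\code{null}, \code{dosage_down}, \code{dosage_up},
#'       \code{consensus_down}, \code{consensus_up}, \code{marker}),
#'       \code{log2_effect} (the homozygote-vs-WT effect), and one
#'       \code{mean_<genotype>} column per genotype with the true group
#'       mean.}
#'   }
#' @export
generate_abundance <- function(config) {
  cfg <- validate_sim_config(config)
  set.seed(cfg$seed)
  n_gt <- length(cfg$genotypes)
  n_rep <- cfg$replicates_per_genotype
  n_samp <- n_gt * n_rep
  m <- cfg$n_metabolites

  baseline <- exp(stats::rnorm(m, cfg$baseline_log_mean, cfg$baseline_log_sd))
  # the marker emulates an eye-pigment artifact: a trace compound whose
  # fold change is huge but whose absolute signal stays minor, so it cannot
  # dominate the identified-compound total that mTIC normalization divides by
  if (!is.na(cfg$marker_index))
    baseline[cfg$marker_index] <-
      exp(cfg$baseline_log_mean - 2 * cfg$baseline_log_sd)
  eff <- true_log2_effects(cfg)
  true_means <- baseline * 2^eff          # m x n_gt

  genotypes <- rep(cfg$genotypes, each = n_rep)
  sample_ids <- paste(genotypes, rep(seq_len(n_rep), times = n_gt), sep = "_")
  mu <- t(true_means[, genotypes, drop = FALSE])   # n_samp x m

  if (cfg$cv > 0) {
    sdlog <- sqrt(log(1 + cfg$cv^2))
    noise <- matrix(stats::rlnorm(n_samp * m, -sdlog^2 / 2, sdlog), n_samp, m)
    values <- mu * noise
  } else {
    values <- mu
  }
  if (cfg$missing_rate > 0) {
    mask <- matrix(stats::runif(n_samp * m) < cfg$missing_rate, n_samp, m)
    values[mask] <- NA_real_
  }

  met_names <- sprintf("met%03d", seq_len(m))
  cls <- rep("null", m)
  cls[cfg$planted_dosage_down] <- "dosage_down"
  cls[cfg$planted_dosage_up] <- "dosage_up"
  cons_idx <- as.integer(names(cfg$planted_consensus))
  cls[cons_idx] <- ifelse(cfg$planted_consensus < 0,
                          "consensus_down", "consensus_up")
  if (!is.na(cfg$marker_index)) cls[cfg$marker_index] <- "marker"

  hom_eff <- if ("hom" %in% cfg$genotypes) eff[, "hom"] else rep(0, m)
  truth <- data.frame(metabolite = met_names, class = cls,
                      log2_effect = hom_eff, stringsAsFactors = FALSE)
  for (g in cfg$genotypes) truth[[paste0("mean_", g)]] <- true_means[, g]

  list(table = abundance_table(values, sample_ids, genotypes, met_names),
       truth = truth)
}

#' Write the ground-truth record of a simulation as JSON
#'
#' Sidecar emission so downstream tests can compare calls against truth
#' without reaching into generator internals.
#'
#' @param truth the \code{truth} data frame from
#'   \code{\link{generate_abundance}}.
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, dataframe = "rows", digits = NA)
  invisible(path)
}
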