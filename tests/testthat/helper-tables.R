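# Small in-code fixtures shared across test files.

# Tiny abundance table from a matrix given row-wise by genotype.
make_table <- function(values, genotypes, metabolites = NULL) {
  values <- as.matrix(values)
  if (is.null(metabolites))
    metabolites <- sprintf("m%02d", seq_len(ncol(values)))
  abundance_table(values,
                  sample_ids = paste0("s", seq_len(nrow(values))),
                  genotypes = genotypes,
                  metabolite_names = metabolites)
}

# Random positive table: n_per replicates for each genotype label.
random_table <- function(genotypes, n_per, n_met, seed = 1) {
  set.seed(seed)
  gts <- rep(genotypes, each = n_per)
  make_table(matrix(rlnorm(length(gts) * n_met, 3, 0.5),
                    nrow = length(gts)), gts)
}

# Random logical fingerprint with at least one bit set.
random_fingerprint <- function(n_bits = 64, density = 0.3) {
  repeat {
    fp <- runif(n_bits) < density
    if (any(fp)) return(fp)
  }
}

# Naive O(n^3) average-linkage (UPGMA) agglomeration over a dissimilarity
# matrix; returns the sorted merge heights. Independent of stats::hclust.
naive_average_linkage_heights <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  sizes <- rep(1, n)
  active <- seq_len(n)
  heights <- numeric(0)
  while (length(active) > 1) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(active)) for (j in seq_along(active)) {
      if (i < j && d[active[i], active[j]] < best_d) {
        best_d <- d[active[i], active[j]]; best <- c(active[i], active[j])
      }
    }
    a <- best[1]; b <- best[2]
    heights <- c(heights, best_d)
    # average-linkage update: merged cluster stored in slot a
    for (k in setdiff(active, c(a, b))) {
      d[a, k] <- d[k, a] <-
        (sizes[a] * d[a, k] + sizes[b] * d[b, k]) / (sizes[a] + sizes[b])
    }
    sizes[a] <- sizes[a] + sizes[b]
    active <- setdiff(active, b)
  }
  sort(heights)
}

# Pooled-variance two-sided Student t-test p-value, written out longhand.
pooled_t_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  2 * pt(-abs(tstat), df = nx + ny - 2)
}
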