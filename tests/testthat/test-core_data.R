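test_that("reading a delimited table records empty cells as missing", {
  csv <- tempfile(fileext = ".csv")
  writeLines(c("sample,Methionine,Ornithine",
               "s1,10,3",
               "s2,,4",
               "s3,12,5"), csv)
  tab <- read_abundance_table(csv, c(s1 = "WT", s2 = "WT", s3 = "hom"))
  expect_equal(dim(tab), c(3L, 2L))
  expect_equal(sum(is.na(tab$values)), 1L)
  expect_true(is.na(tab$values["s2", "Methionine"]))
  expect_identical(tab$genotypes, c("WT", "WT", "hom"))
})

test_that("duplicate metabolite columns and unmapped samples are hard errors", {
  csv <- tempfile(fileext = ".csv")
  writeLines(c("sample,Methionine,Methionine", "s1,1,2"), csv)
  expect_error(read_abundance_table(csv, c(s1 = "WT")), "Methionine")
  csv2 <- tempfile(fileext = ".csv")
  writeLines(c("sample,Methionine", "s1,1", "s9,2"), csv2)
  expect_error(read_abundance_table(csv2, c(s1 = "WT")), "s9")
})

test_that("generator output round-trips through write/read identically", {
  gen <- generate_abundance(sim_config(
    n_metabolites = 12, seed = 5, missing_rate = 0.1,
    planted_dosage_down = 1:2, planted_dosage_up = 3,
    planted_consensus = c("4" = -1), marker_index = 5))
  path <- tempfile(fileext = ".csv")
  write_abundance_table(gen$table, path)
  back <- read_abundance_table(
    path, stats::setNames(gen$table$genotypes, gen$table$sample_ids))
  expect_equal(back$values, gen$table$values)
  expect_identical(back$metabolite_names, gen$table$metabolite_names)
  expect_identical(back$genotypes, gen$table$genotypes)
})

test_that("presence filter applies the per-group detection rule", {
  # m1: 5/6 present in both groups (0.833 >= 0.8) -> retained
  # m2: 4/6 in group A (0.667 < 0.8) -> dropped
  # m3: complete -> retained
  v <- matrix(rlnorm(36, 3, 0.2), nrow = 12, ncol = 3)
  v[1, 1] <- NA; v[7, 1] <- NA          # one missing per group in m1
  v[1:2, 2] <- NA                       # two missing in group A for m2
  tab <- make_table(v, rep(c("A", "B"), each = 6))
  kept <- presence_filter(tab, 0.8)
  expect_identical(kept$metabolite_names, c("m01", "m03"))

  # boundary: min_fraction = 1 drops anything with any missing cell
  strict <- presence_filter(tab, 1.0)
  expect_identical(strict$metabolite_names, "m03")

  # idempotence
  expect_equal(presence_filter(kept, 0.8), kept)

  # all-dropped is an explicit error, not an empty table
  v2 <- matrix(1, 4, 1); v2[1:3, 1] <- NA
  expect_error(presence_filter(make_table(v2, rep("A", 4)), 0.8),
               "no metabolite")
  expect_error(presence_filter(tab, 1.5), "min_fraction")
})

test_that("mTIC normalization equalizes totals and keeps structure", {
  tab <- make_table(rbind(c(40, 60), c(120, 80)), c("A", "A"))
  norm <- normalize_tic(tab)
  # totals 100 and 200 -> both become the cohort mean 150
  expect_equal(unname(rowSums(norm$values)), c(150, 150))

  # single-sample table is unchanged (its total equals the mean total)
  one <- make_table(matrix(c(3, 7), 1), "A")
  expect_equal(normalize_tic(one)$values, one$values)

  # brute-force: every sample total equals mean of raw totals, rel tol 1e-9
  tab2 <- random_table(c("A", "B"), 3, 10, seed = 7)
  norm2 <- normalize_tic(tab2)
  expect_equal(unname(rowSums(norm2$values)),
               rep(mean(rowSums(tab2$values)), 6), tolerance = 1e-9)

  # rescale = "none" gives per-sample fractions summing to 1
  expect_equal(unname(rowSums(normalize_tic(tab2, "none")$values)),
               rep(1, 6))
  zero <- make_table(rbind(c(1, 2), c(0, 0)), c("A", "A"))
  expect_error(normalize_tic(zero), "s2")
})

test_that("normalization is scale-invariant and preserves within-sample ratios", {
  tab <- random_table(c("A", "B"), 3, 8, seed = 11)
  scaled <- tab
  scaled$values[2, ] <- scaled$values[2, ] * 37.5   # rescale one sample
  # per-sample fractions are exactly invariant to sample-specific scaling
  expect_equal(normalize_tic(scaled, "none")$values,
               normalize_tic(tab, "none")$values, tolerance = 1e-12)
  # mean-rescale differs only by one global constant (the cohort mean moved)
  ratio <- normalize_tic(scaled)$values / normalize_tic(tab)$values
  expect_lt(diff(range(ratio)), 1e-9)

  norm <- normalize_tic(tab)
  for (i in seq_len(nrow(tab$values)))
    expect_equal(norm$values[i, ] / norm$values[i, 1],
                 tab$values[i, ] / tab$values[i, 1])
})

test_that("half-minimum imputation fills exactly the missing cells", {
  v <- rbind(c(10, 5), c(NA, 6), c(40, 7))
  tab <- make_table(v, c("A", "A", "A"))
  imp <- impute_missing(tab)
  expect_equal(unname(imp$values[2, 1]), 5)   # half of observed min 10
  expect_false(anyNA(imp$values))

  # tables without missing cells come back identical
  full <- random_table("A", 4, 5, seed = 2)
  expect_identical(impute_missing(full), full)

  # brute-force check of all imputed values on a randomly masked table
  set.seed(8)
  v2 <- matrix(rlnorm(60, 2, 1), 6, 10)
  mask <- matrix(runif(60) < 0.1, 6, 10)
  mask[1, ] <- FALSE                          # keep every column observed
  v2m <- v2; v2m[mask] <- NA
  imp2 <- impute_missing(make_table(v2m, rep("A", 6)))
  mins <- apply(v2m, 2, min, na.rm = TRUE)
  for (j in 1:10)
    expect_equal(unname(imp2$values[mask[, j], j]),
                 rep(mins[j] / 2, sum(mask[, j])))

  all_missing <- make_table(matrix(NA_real_, 3, 1), rep("A", 3))
  expect_error(impute_missing(all_missing), "entirely missing")
})
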