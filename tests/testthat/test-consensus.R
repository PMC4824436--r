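fake_results <- function(names, sig = character(0), dir_up = character(0)) {
  data.frame(metabolite = names,
             p_value = ifelse(names %in% sig, 0.01, 0.5),
             fold_change = ifelse(names %in% dir_up, 2, 0.5),
             direction = ifelse(names %in% dir_up, "up", "down"),
             significant = names %in% sig,
             stringsAsFactors = FALSE)
}

test_that("allele discordance reports the ratio and the error-range verdict", {
  r <- allele_discordance(3, 109, 0.05)
  expect_equal(r$percentage, 2.8)
  expect_true(r$within_systematic_error)
  expect_equal(allele_discordance(0, 109)$percentage, 0)
  expect_true(allele_discordance(0, 109)$within_systematic_error)
  r6 <- allele_discordance(6, 109, 0.05)
  expect_equal(r6$percentage, 5.5)
  expect_false(r6$within_systematic_error)
  # data-frame input counts significant rows itself
  df <- fake_results(sprintf("m%d", 1:10), sig = c("m1", "m2"))
  rd <- allele_discordance(df)
  expect_equal(rd$n_discordant, 2)
  expect_equal(rd$panel_size, 10)
})

test_that("allele-specific sets partition the union of significant names", {
  panel <- c("m1", "m2", "m3", "m4")
  a <- comparison_set("a", fake_results(panel, sig = c("m1", "m2")))
  b <- comparison_set("b", fake_results(panel, sig = c("m2", "m3")))
  s <- allele_specific_sets(a, b)
  expect_identical(s$only_a, "m1")
  expect_identical(s$only_b, "m3")
  expect_identical(s$shared, "m2")
  expect_equal(unname(s$counts["only_a"] + s$counts["shared"]), 2)
  same <- allele_specific_sets(a, a)
  expect_length(same$only_a, 0)
  expect_length(same$only_b, 0)
  c_other <- comparison_set("c", fake_results(c(panel, "m5"), sig = "m1"))
  expect_error(allele_specific_sets(a, c_other), "panels")
})

test_that("consensus requires shared significance with matching direction", {
  panel <- c("m1", "m2", "m3")
  a <- comparison_set("mut_vs_wt",
                      fake_results(panel, sig = c("m1", "m2"), dir_up = "m2"),
                      test_is_deficient = TRUE)
  b_same <- comparison_set("gal4_vs_rescue",
                           fake_results(panel, sig = c("m1", "m3")),
                           test_is_deficient = TRUE)
  called <- consensus_call(a, b_same)
  expect_identical(called$metabolite, "m1")   # down in both
  expect_identical(called$direction, "down")

  # significant in both but opposite directions: not called
  b_flip <- comparison_set("gal4_vs_rescue",
                           fake_results(panel, sig = "m1", dir_up = "m1"),
                           test_is_deficient = TRUE)
  expect_equal(nrow(consensus_call(a, b_flip)), 0)

  # unoriented comparisons are refused
  b_unoriented <- comparison_set("gal4_vs_rescue",
                                 fake_results(panel, sig = "m1"))
  expect_error(consensus_call(a, b_unoriented), "oriented")
})

test_that("consensus calls are a subset of the shared significant set", {
  gen <- generate_abundance(sim_config(seed = 61))
  tab <- normalize_tic(impute_missing(presence_filter(gen$table)))
  a <- comparison_set("hom_vs_wt", compare_groups(tab, "hom", "WT"),
                      test_is_deficient = TRUE)
  b <- comparison_set("gal4_vs_rescue",
                      compare_groups(tab, "gal4", "rescue"),
                      test_is_deficient = TRUE)
  called <- consensus_call(a, b)
  shared <- allele_specific_sets(a, b)$shared
  expect_true(all(called$metabolite %in% shared))
  expect_true(all(diff(called$evidence) <= 1e-12))  # sorted by evidence
})

test_that("planted consensus class is recovered and direction-sensitive", {
  hits <- vapply(1:12, function(s) {
    gen <- generate_abundance(sim_config(seed = 200 + s))
    tab <- normalize_tic(impute_missing(presence_filter(gen$table)))
    a <- comparison_set("hom_vs_wt", compare_groups(tab, "hom", "WT"),
                        test_is_deficient = TRUE)
    b <- comparison_set("gal4_vs_rescue",
                        compare_groups(tab, "gal4", "rescue"),
                        test_is_deficient = TRUE)
    called <- consensus_call(a, b)$metabolite
    planted <- gen$truth$metabolite[grepl("consensus", gen$truth$class)]
    all(planted %in% called)
  }, TRUE)
  expect_gt(mean(hits), 0.5)

  # flipping one comparison's orientation empties single-direction plants
  gen <- generate_abundance(sim_config(
    planted_consensus = c("27" = -1, "28" = -1, "29" = -1), seed = 62))
  tab <- normalize_tic(impute_missing(presence_filter(gen$table)))
  a <- comparison_set("hom_vs_wt", compare_groups(tab, "hom", "WT"),
                      test_is_deficient = TRUE)
  b_rev <- comparison_set("rescue_vs_gal4",
                          compare_groups(tab, "rescue", "gal4"),
                          test_is_deficient = TRUE)  # wrong way round
  planted <- gen$truth$metabolite[grepl("consensus", gen$truth$class)]
  called_rev <- consensus_call(a, b_rev)$metabolite
  expect_length(intersect(called_rev, planted), 0)
})
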