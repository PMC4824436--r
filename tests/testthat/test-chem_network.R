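bits <- function(set, n = 16) { v <- rep(FALSE, n); v[set] <- TRUE; v }

fake_annotations <- function(fps, names = sprintf("M%02d", seq_along(fps))) {
  out <- data.frame(name = names, compound_id = NA, pathway_tag = NA,
                    provenance = "given", stringsAsFactors = FALSE)
  out$fingerprint <- fps
  class(out) <- c("metabolite_annotation", "data.frame")
  out
}

test_that("Tanimoto score follows |intersection| / |union|", {
  expect_equal(tanimoto(bits(1:5), bits(1:5)), 1)
  expect_equal(tanimoto(bits(1:3), bits(4:6)), 0)
  expect_equal(tanimoto(bits(1:3), bits(2:4)), 0.5)
  expect_equal(tanimoto(bits(1:3), bits(2:4)), tanimoto(bits(2:4), bits(1:3)))
  expect_error(tanimoto(bits(1:3), bits(1:3, n = 8)), "bit lengths")
  expect_error(tanimoto(rep(FALSE, 4), rep(FALSE, 4)), "empty")
})

test_that("similarity layer equals exhaustive all-pairs evaluation", {
  set.seed(51)
  for (rep in 1:5) {
    fps <- replicate(8, random_fingerprint(32, 0.4), simplify = FALSE)
    ann <- fake_annotations(fps)
    thr <- 0.4
    layer <- build_similarity_layer(ann, thr)
    brute <- 0
    for (i in 1:7) for (j in (i + 1):8) {
      s <- tanimoto(fps[[i]], fps[[j]])
      if (s >= thr) {
        brute <- brute + 1
        row <- layer[layer$from == ann$name[i] & layer$to == ann$name[j], ]
        expect_equal(row$score, s)
      }
    }
    expect_equal(nrow(layer), brute)
  }
})

test_that("similarity edges shrink as the threshold rises", {
  set.seed(52)
  fps <- replicate(12, random_fingerprint(24, 0.5), simplify = FALSE)
  ann <- fake_annotations(fps)
  counts <- vapply(c(0.2, 0.4, 0.6, 0.8, 1.0),
                   function(t) nrow(build_similarity_layer(ann, t)), 0)
  expect_true(all(diff(counts) <= 0))
  # threshold 1 keeps only bit-identical structures
  ann2 <- fake_annotations(list(bits(1:4), bits(1:4), bits(2:5)))
  exact <- build_similarity_layer(ann2, 1.0)
  expect_equal(nrow(exact), 1)
  expect_identical(c(exact$from, exact$to), c("M01", "M02"))
  expect_error(build_similarity_layer(ann2, 0), "threshold")
})

test_that("metabolites without structure are kept as nodes, not edges", {
  ann <- fake_annotations(list(bits(1:4), NULL, bits(1:4)),
                          names = c("A", "NoStruct", "B"))
  expect_warning(layer <- build_similarity_layer(ann, 0.7), "NoStruct")
  expect_false("NoStruct" %in% c(layer$from, layer$to))
})

test_that("the packaged annotation fixture parses into uniform fingerprints", {
  ann <- read_annotations(system.file("extdata",
                                      "metabolite_annotations_demo.csv",
                                      package = "metabodose"))
  expect_true(all(lengths(ann$fingerprint) == 1024))
  expect_true(all(ann$provenance == "given"))
  # chemically near-identical long-chain fatty acids exceed the 0.7 cut-off
  fp <- setNames(ann$fingerprint, ann$name)
  expect_gte(tanimoto(fp[["Stearic acid"]], fp[["Arachidic acid"]]), 0.7)
  expect_lt(tanimoto(fp[["Stearic acid"]], fp[["Guanine"]]), 0.7)
})

test_that("reaction layer filters, normalizes and deduplicates pairs", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("# comment", "B\tA", "A\tB", "A\tZ", "C\tA", ""), f)
  suppressMessages(layer <- build_reaction_layer(f, c("A", "B", "C")))
  expect_equal(layer, data.frame(from = c("A", "A"), to = c("B", "C")))
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("A\tB\tC"), bad)
  expect_error(build_reaction_layer(bad, c("A", "B")), "line 1")
})

test_that("the packaged reaction-pair fixture keeps only cohort pairs", {
  fx <- read_published_differential()
  suppressMessages(layer <- build_reaction_layer(
    system.file("extdata", "reaction_pairs_demo.tsv",
                package = "metabodose"),
    fx$metabolite))
  expect_true(all(layer$from %in% fx$metabolite))
  expect_true(all(layer$to %in% fx$metabolite))
  expect_true(any(layer$from == "Fumaric acid" & layer$to == "Malate"))
  # S-Adenosylmethionine and Putrescine are outside the cohort
  expect_false(any(grepl("Adenosylmethionine|Putrescine",
                         c(layer$from, layer$to))))
})

test_that("assembled network styles nodes by the differential result", {
  fx <- read_published_differential()
  rep1 <- replicate_table1(fx)
  nt <- rep1$node_table
  xa <- nt[nt$name == "Xanthurenic acid", ]
  expect_identical(xa$node_color, "red")
  expect_equal(xa$node_size, max(nt$node_size))
  expect_identical(nt$node_color[nt$name == "Methionine"], "blue")
  # a non-significant node carries no colour
  d <- rbind(fx, data.frame(metabolite = "Quiet", p_value = 0.2,
                            p_censored = FALSE, fold_change = 1.1,
                            direction = "up", significant = FALSE))
  g <- assemble_network(
    data.frame(from = character(0), to = character(0), score = numeric(0)),
    data.frame(from = character(0), to = character(0)), d)
  expect_true(is.na(igraph::V(g)$node_color[igraph::V(g)$name == "Quiet"]))
  expect_error(assemble_network(
    data.frame(from = "Ghost", to = "Quiet", score = 0.8),
    data.frame(from = character(0), to = character(0)), d),
    "Ghost")
})

test_that("a pair linked in both layers keeps two tagged parallel edges", {
  d <- data.frame(metabolite = c("A", "B"), p_value = c(0.01, 0.3),
                  fold_change = c(2, 1.1),
                  significant = c(TRUE, FALSE))
  g <- assemble_network(
    data.frame(from = "A", to = "B", score = 0.9),
    data.frame(from = "A", to = "B"), d)
  expect_equal(igraph::ecount(g), 2)
  expect_setequal(igraph::E(g)$layer, c("similarity", "reaction_pair"))
})

test_that("SIF and GraphML exports round-trip to the identical network", {
  d <- data.frame(metabolite = c("A", "B", "C", "Lonely"),
                  p_value = c(0.01, 0.3, 0.001, 0.5),
                  fold_change = c(2, 1.1, 0.4, 1),
                  significant = c(TRUE, FALSE, TRUE, FALSE))
  g <- assemble_network(
    data.frame(from = c("A", "B"), to = c("B", "C"), score = c(0.8, 0.75)),
    data.frame(from = "A", to = "B"), d)
  sif <- tempfile(fileext = ".sif"); at <- tempfile(fileext = ".tsv")
  write_network_sif(g, sif, at)
  scores <- c("A|B" = 0.8, "B|C" = 0.75)
  g2 <- read_network_sif(sif, at, similarity_scores = scores)
  expect_setequal(igraph::V(g2)$name, igraph::V(g)$name)
  key <- function(gr) sort(paste(igraph::as_edgelist(gr)[, 1],
                                 igraph::E(gr)$layer,
                                 igraph::as_edgelist(gr)[, 2]))
  expect_identical(key(g2), key(g))
  for (a in c("fold_change", "p_value", "node_size"))
    expect_equal(igraph::vertex_attr(g2, a)[match(igraph::V(g)$name,
                                                  igraph::V(g2)$name)],
                 igraph::vertex_attr(g, a), tolerance = 1e-9)

  gml <- tempfile(fileext = ".graphml")
  write_network_graphml(g, gml)
  g3 <- read_network_graphml(gml)
  expect_identical(key(g3), key(g))
  expect_equal(sort(igraph::E(g3)$score), sort(igraph::E(g)$score))
})
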