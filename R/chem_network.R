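#' Read a metabolite annotation table
#'
#' CSV with columns \code{name}, \code{compound_id}, \code{smiles},
#' \code{fingerprint} (hex-encoded bit string), \code{pathway_tag};
#' \code{smiles} and \code{fingerprint} are mutually exclusive per row.
#' Precomputed fingerprints are the canonical path: published similarity
#' networks were built from database-side structure clustering whose bit
#' sets cannot be regenerated offline, so shipping the bits themselves keeps
#' edge sets reproducible. Rows carrying only SMILES are fingerprinted with
#' a substructure fingerprint via the optional ChemmineOB backend.
#'
#' @param path CSV path.
#' @param n_bits fingerprint length in bits used when hex strings are
#'   decoded or SMILES are fingerprinted; default 1024.
#' @return A data frame of class \code{metabolite_annotation} with columns
#'   \code{name}, \code{compound_id}, \code{pathway_tag}, \code{provenance}
#'   ("given" or "computed-from-SMILES"), and a list-column
#'   \code{fingerprint} of logical bit vectors (NULL where no structure is
#'   available).
#' @export
read_annotations <- function(path, n_bits = 1024) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"), colClasses = "character")
  need <- c("name", "smiles", "fingerprint")
  missing_cols <- setdiff(need, colnames(df))
  if (length(missing_cols))
    stop("annotation table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  df$name <- trimws(df$name)
  if (anyDuplicated(df$name))
    stop("duplicate annotation name(s): ",
         paste(unique(df$name[duplicated(df$name)]), collapse = ", "))
  both <- !is.na(df$smiles) & !is.na(df$fingerprint)
  if (any(both))
    stop("smiles and fingerprint are mutually exclusive; both given for: ",
         paste(df$name[both], collapse = ", "))

  fp <- vector("list", nrow(df))
  provenance <- rep(NA_character_, nrow(df))
  for (i in seq_len(nrow(df))) {
    if (!is.na(df$fingerprint[i])) {
      fp[[i]] <- parse_fingerprint_hex(df$fingerprint[i], n_bits)
      provenance[i] <- "given"
    } else if (!is.na(df$smiles[i])) {
      fp[[i]] <- fingerprint_from_smiles(df$smiles[i], n_bits)
      provenance[i] <- "computed-from-SMILES"
    }
  }
  lens <- unique(lengths(fp[!vapply(fp, is.null, TRUE)]))
  if (length(lens) > 1)
    stop("fingerprint bit lengths differ across metabolites: ",
         paste(lens, collapse = ", "))
  out <- data.frame(
    name = df$name,
    compound_id = if ("compound_id" %in% colnames(df)) df$compound_id
                  else NA_character_,
    pathway_tag = if ("pathway_tag" %in% colnames(df)) df$pathway_tag
                  else NA_character_,
    provenance = provenance,
    stringsAsFactors = FALSE)
  out$fingerprint <- fp
  class(out) <- c("metabolite_annotation", "data.frame")
  out
}

# Internal: hex string -> logical bit vector of length n_bits (big-endian
# within each hex digit).
parse_fingerprint_hex <- function(hex, n_bits) {
  hex <- gsub("\\s", "", tolower(hex))
  if (!grepl("^[0-9a-f]+$", hex)) stop("invalid hex fingerprint: ", hex)
  digits <- strtoi(strsplit(hex, "")[[1]], base = 16L)
  bits <- as.logical(t(vapply(digits,
                              function(d) bitwAnd(d, c(8L, 4L, 2L, 1L)) > 0,
                              logical(4))))
  if (length(bits) < n_bits) bits <- c(bits, rep(FALSE, n_bits - length(bits)))
  if (length(bits) > n_bits) {
    if (any(bits[(n_bits + 1):length(bits)]))
      stop("hex fingerprint longer than ", n_bits, " bits")
    bits <- bits[seq_len(n_bits)]
  }
  if (!any(bits)) stop("fingerprint has no bits set")
  bits
}

# Internal: substructure fingerprint from SMILES via ChemmineOB (optional).
fingerprint_from_smiles <- function(smiles, n_bits) {
  if (!requireNamespace("ChemmineOB", quietly = TRUE))
    stop("fingerprinting SMILES requires the ChemmineOB package; supply ",
         "precomputed hex fingerprints instead")
  fp <- ChemmineOB::fingerprint_OB(
    ChemmineOB::forEachMol("SMILES", smiles, identity), "FP2")
  bits <- as.logical(fp[1, ])
  if (length(bits) >= n_bits) bits <- bits[seq_len(n_bits)]
  else bits <- c(bits, rep(FALSE, n_bits - length(bits)))
  if (!any(bits)) stop("empty fingerprint computed from SMILES: ", smiles)
  bits
}

#' Tanimoto similarity of two binary fingerprints
#'
#' \eqn{|a \cap b| / |a \cup b|} over set bits: the standard chemical
#' similarity score for substructure fingerprints. Symmetric, in [0, 1];
#' note it does not satisfy the triangle inequality.
#'
#' @param a,b logical bit vectors of identical length, each with at least
#'   one bit set.
#' @return Similarity score in [0, 1].
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b))
    stop("fingerprints have different bit lengths: ", length(a), " vs ",
         length(b))
  union <- sum(a | b)
  if (union == 0) stop("both fingerprints empty; Tanimoto undefined")
  sum(a & b) / union
}

#' Build the chemical-similarity edge layer
#'
#' Evaluates pairwise Tanimoto similarity between all fingerprinted
#' metabolites and keeps pairs at or above the threshold. The conventional
#' cut-off for substructure-fingerprint similarity networks is 0.7.
#' Metabolites without a structure are skipped (with a warning) but remain
#' valid network nodes.
#'
#' @param annotations a \code{metabolite_annotation} data frame from
#'   \code{\link{read_annotations}}.
#' @param threshold similarity cut-off in (0, 1]; default 0.7.
#' @return A data frame of edges \code{from}, \code{to} (alphabetical within
#'   each pair), \code{score}, sorted by \code{from}, \code{to}.
#' @export
build_similarity_layer <- function(annotations, threshold = 0.7) {
  if (threshold <= 0 || threshold > 1)
    stop("threshold must be in (0, 1], got ", threshold)
  has_fp <- !vapply(annotations$fingerprint, is.null, TRUE)
  if (any(!has_fp))
    warning("no structure for metabolite(s), excluded from similarity ",
            "layer: ", paste(annotations$name[!has_fp], collapse = ", "))
  names <- annotations$name[has_fp]
  fps <- annotations$fingerprint[has_fp]
  n <- length(names)
  from <- character(0); to <- character(0); score <- numeric(0)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        s <- tanimoto(fps[[i]], fps[[j]])
        if (s >= threshold) {
          pair <- sort(c(names[i], names[j]))
          from <- c(from, pair[1]); to <- c(to, pair[2])
          score <- c(score, s)
        }
      }
    }
  }
  out <- data.frame(from = from, to = to, score = score,
                    stringsAsFactors = FALSE)
  out <- out[order(out$from, out$to), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the biochemical reaction-pair edge layer
#'
#' Reads a plain edge list (two tab- or comma-separated metabolite names per
#' line, \code{#} comments allowed) of substrate-product pairs connected by
#' one enzymatic reaction, keeps pairs whose both endpoints belong to the
#' cohort, and normalizes order/duplicates.
#'
#' @param pairs_file path to the edge list.
#' @param node_names character vector of cohort metabolite names.
#' @return A data frame of edges \code{from}, \code{to} (alphabetical within
#'   pair, deduplicated), sorted.
#' @export
build_reaction_layer <- function(pairs_file, node_names) {
  lines <- readLines(pairs_file, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  from <- character(0); to <- character(0)
  node_names <- trimws(node_names)
  for (k in idx) {
    fields <- trimws(strsplit(lines[k], "[\t,]")[[1]])
    fields <- fields[fields != ""]
    if (length(fields) != 2)
      stop("malformed reaction-pair line ", k, ": expected 2 names, got ",
           length(fields))
    if (!all(fields %in% node_names)) {
      message("reaction pair dropped (endpoint not in cohort): ",
              paste(fields, collapse = " -- "))
      next
    }
    if (fields[1] == fields[2]) next  # self-pairs carry no edge
    pair <- sort(fields)
    from <- c(from, pair[1]); to <- c(to, pair[2])
  }
  out <- unique(data.frame(from = from, to = to, stringsAsFactors = FALSE))
  out <- out[order(out$from, out$to), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble the two-layer metabolic network with differential styling
#'
#' Merges the chemical-similarity and reaction-pair layers into one graph
#' whose edges carry a \code{layer} tag (a metabolite pair may carry both,
#' as two parallel tagged edges). Node style encodes the differential
#' result: node size grows affinely with |log2 fold change| (clipped to
#' [\code{min_size}, \code{max_size}]), and colour is assigned only to
#' significant metabolites — red for up, blue for down.
#'
#' @param similarity edge data frame from \code{\link{build_similarity_layer}}.
#' @param reaction edge data frame from \code{\link{build_reaction_layer}}.
#' @param differential data frame with \code{metabolite}, \code{p_value},
#'   \code{fold_change}, \code{significant} covering every node.
#' @param nodes node name vector; defaults to \code{differential$metabolite}.
#' @param min_size,max_size node size range for the affine |log2 FC| map.
#' @param log2fc_cap |log2 FC| mapped to \code{max_size}; default 5.
#' @return An \code{igraph} graph with node attributes \code{fold_change},
#'   \code{p_value}, \code{significant}, \code{node_size}, \code{node_color}
#'   (\code{NA} for non-significant nodes) and edge attributes \code{layer},
#'   \code{score}. Graph attribute \code{fingerprint_scheme} records
#'   provenance when given.
#' @export
assemble_network <- function(similarity, reaction, differential,
                             nodes = differential$metabolite,
                             min_size = 10, max_size = 60, log2fc_cap = 5) {
  nodes <- trimws(nodes)
  missing_nodes <- setdiff(nodes, differential$metabolite)
  if (length(missing_nodes))
    stop("node(s) missing from differential results: ",
         paste(missing_nodes, collapse = ", "))
  edge_nodes <- unique(c(similarity$from, similarity$to,
                         reaction$from, reaction$to))
  stray <- setdiff(edge_nodes, nodes)
  if (length(stray))
    stop("edge endpoint(s) not in node set: ", paste(stray, collapse = ", "))

  edges <- rbind(
    if (nrow(similarity))
      data.frame(from = similarity$from, to = similarity$to,
                 layer = "similarity", score = similarity$score,
                 stringsAsFactors = FALSE),
    if (nrow(reaction))
      data.frame(from = reaction$from, to = reaction$to,
                 layer = "reaction_pair", score = NA_real_,
                 stringsAsFactors = FALSE))
  d <- differential[match(nodes, differential$metabolite), , drop = FALSE]
  abs_l2 <- pmin(abs(log2(d$fold_change)), log2fc_cap)
  vertices <- data.frame(
    name = nodes,
    fold_change = d$fold_change,
    p_value = d$p_value,
    significant = d$significant,
    node_size = min_size + (max_size - min_size) * abs_l2 / log2fc_cap,
    node_color = ifelse(!d$significant, NA_character_,
                        ifelse(d$fold_change > 1, "red", "blue")),
    stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    if (is.null(edges)) data.frame(from = character(0), to = character(0),
                                   layer = character(0), score = numeric(0))
    else edges,
    directed = FALSE, vertices = vertices)
  g
}

#' Export a metabolic network as SIF plus a node attribute table
#'
#' SIF (Simple Interaction Format): one \code{node<TAB>layer<TAB>node} line
#' per tagged edge, the convention for typed interactions in Cytoscape. The
#' companion attribute table (TSV: name, fold_change, p_value, significant,
#' node_size, node_color) carries the differential styling.
#'
#' @param graph an \code{igraph} network from \code{\link{assemble_network}}.
#' @param sif_path,attr_path output file paths; pass \code{NULL} to skip
#'   either file.
#' @return \code{sif_path}, invisibly.
#' @export
write_network_sif <- function(graph, sif_path, attr_path = NULL) {
  el <- igraph::as_edgelist(graph)
  layer <- igraph::edge_attr(graph, "layer")
  if (!is.null(sif_path)) {
    lines <- if (nrow(el)) paste(el[, 1], layer, el[, 2], sep = "\t")
             else character(0)
    # isolated nodes appear as single-column SIF lines so they survive
    connected <- unique(c(el[, 1], el[, 2]))
    isolated <- setdiff(igraph::V(graph)$name, connected)
    writeLines(c(lines, isolated), sif_path)
  }
  if (!is.null(attr_path)) {
    at <- data.frame(name = igraph::V(graph)$name,
                     fold_change = igraph::V(graph)$fold_change,
                     p_value = igraph::V(graph)$p_value,
                     significant = igraph::V(graph)$significant,
                     node_size = igraph::V(graph)$node_size,
                     node_color = igraph::V(graph)$node_color,
                     stringsAsFactors = FALSE)
    utils::write.table(at, attr_path, sep = "\t", row.names = FALSE,
                       quote = FALSE, na = "")
  }
  invisible(sif_path)
}

#' Re-import a SIF + attribute table pair written by
#' \code{\link{write_network_sif}}
#'
#' @param sif_path,attr_path the two files.
#' @param similarity_scores optional named numeric vector
#'   (\code{"from|to"} -> score) restoring similarity edge scores, which SIF
#'   itself cannot carry.
#' @return An \code{igraph} network equivalent to the exported one.
#' @export
read_network_sif <- function(sif_path, attr_path,
                             similarity_scores = NULL) {
  lines <- readLines(sif_path, warn = FALSE)
  lines <- lines[lines != ""]
  parts <- strsplit(lines, "\t")
  n_fields <- lengths(parts)
  if (any(!n_fields %in% c(1L, 3L)))
    stop("malformed SIF line(s): ",
         paste(which(!n_fields %in% c(1L, 3L)), collapse = ", "))
  edges <- do.call(rbind, lapply(parts[n_fields == 3L], function(p)
    data.frame(from = p[1], to = p[3], layer = p[2],
               stringsAsFactors = FALSE)))
  at <- utils::read.table(attr_path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, na.strings = "",
                          quote = "", comment.char = "")
  if (is.null(edges))
    edges <- data.frame(from = character(0), to = character(0),
                        layer = character(0), stringsAsFactors = FALSE)
  edges$score <- NA_real_
  if (!is.null(similarity_scores)) {
    key <- paste(edges$from, edges$to, sep = "|")
    hit <- edges$layer == "similarity" & key %in% names(similarity_scores)
    edges$score[hit] <- similarity_scores[key[hit]]
  }
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = at)
}

#' Export a metabolic network as GraphML with all attributes inline
#'
#' @param graph an \code{igraph} network.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_network_graphml <- function(graph, path) {
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}

#' Re-import a GraphML network
#'
#' @param path GraphML file written by \code{\link{write_network_graphml}}.
#' @return An \code{igraph} network.
#' @export
read_network_graphml <- function(path) {
  igraph::read_graph(path, format = "graphml")
}
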