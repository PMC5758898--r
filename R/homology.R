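# All-against-all protein similarity graph.  Edge weights are local-alignment
# bitscores (not e-values), which avoids numerical underflow and folds in the
# length of the homologous region.

# Ungapped Karlin-Altschul constants for BLOSUM62 (standard published values).
KA_LAMBDA <- 0.267
KA_K <- 0.041

#' Local-alignment bitscore and e-value for a protein pair
#'
#' Smith-Waterman local alignment under BLOSUM62 with affine gap costs
#' (open 11, extend 1; a gap of length L costs 11 + L).  The raw score S is
#' converted to bits as `(lambda * S - ln K)/ln 2` with lambda = 0.267,
#' K = 0.041, and the e-value is `m * n * 2^-bits` for sequence lengths
#' m and n.
#'
#' @param a,b amino-acid sequences (non-empty strings).
#' @return list with `bitscore` and `evalue`.
#' @export
pairwise_bitscore <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) fatal("empty protein sequence")
  raw <- sw_raw_score_cpp(a, b)
  bits <- (KA_LAMBDA * raw - log(KA_K)) / log(2)
  list(bitscore = bits, evalue = nchar(a) * nchar(b) * 2^(-bits))
}

similarity_graph <- function(nodes, edges) {
  stopifnot(all(c("gene_a", "gene_b", "bitscore", "evalue") %in% names(edges)))
  swap <- edges$gene_a > edges$gene_b
  tmp <- edges$gene_a[swap]
  edges$gene_a[swap] <- edges$gene_b[swap]
  edges$gene_b[swap] <- tmp
  edges <- edges[edges$gene_a != edges$gene_b, , drop = FALSE]
  edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = sort(nodes), edges = edges), class = "similarity_graph")
}

#' @export
print.similarity_graph <- function(x, ...) {
  cat(sprintf("<similarity_graph> %d genes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Build the all-against-all similarity graph
#'
#' Candidate pairs are found by exact k-mer seeding (k = 5, two seeds
#' required) and scored by Smith-Waterman ([pairwise_bitscore()]); pairs with
#' e-value at most `evalue_cutoff` become edges.  The `external` backend
#' instead ingests the 12-column tabular output of a similarity search tool
#' (query, subject, %id, length, mismatches, gapopens, qstart, qend, sstart,
#' send, evalue, bitscore); when a pair was hit in both directions the
#' maximum bitscore is kept.
#'
#' @param genomes list of [strain_genome] objects (or a combined gene table).
#' @param evalue_cutoff significance cutoff (default 0.001).
#' @param backend `"internal"` or `"external"`.
#' @param hits_path tabular hits file, required for the external backend.
#' @return a `similarity_graph`.
#' @export
build_graph <- function(genomes, evalue_cutoff = 0.001,
                        backend = c("internal", "external"), hits_path = NULL) {
  backend <- match.arg(backend)
  genes <- if (inherits(genomes, "gene_table")) genomes else combined_gene_table(genomes)
  if (!nrow(genes)) fatal("no genes to compare")
  if (backend == "external") {
    if (is.null(hits_path) || !file.exists(hits_path %||% ""))
      fatal(paste("external backend needs a tabular hits file with columns:",
                  "query, subject, pident, length, mismatches, gapopens,",
                  "qstart, qend, sstart, send, evalue, bitscore"))
    return(graph_from_hits(hits_path, genes, evalue_cutoff))
  }
  ids <- sort(genes$gene_id)
  aa <- genes$aa_seq[match(ids, genes$gene_id)]
  # small inputs (e.g. the representative level of divide-and-conquer) are
  # searched exhaustively: no seeding heuristic can lose a pair there
  if (length(ids) <= 800) {
    cand <- t(combn(seq_along(ids), 2))
    return(similarity_graph(ids, score_candidate_pairs(aa, ids, cand, evalue_cutoff)))
  }
  # tier 1: exact 5-mer two-hit seeding (fast; catches closely and
  # moderately related pairs)
  cand <- kmer_candidate_pairs_cpp(aa, k = 5L, min_hits = 2L)
  edges <- score_candidate_pairs(aa, ids, cand, evalue_cutoff)
  # tier 2: sensitivity ladder for diverged homologs — compare connected-
  # component representatives under reduced-alphabet seeds, then score all
  # cross pairs of components whose representatives hit
  edges2 <- rescue_distant_components(aa, ids, edges, evalue_cutoff)
  edges <- unique(rbind(edges, edges2))
  # tier 3: densify — within every connected component, score the pairs the
  # seeding missed, so cluster-internal edge density reflects actual
  # similarity rather than seed sensitivity
  edges3 <- densify_components(aa, ids, edges, evalue_cutoff)
  edges <- unique(rbind(edges, edges3))
  similarity_graph(ids, edges)
}

densify_components <- function(aa, ids, edges, evalue_cutoff, max_comp = 400) {
  empty <- edges[0, ]
  if (!nrow(edges)) return(empty)
  g <- igraph::graph_from_data_frame(edges[, 1:2], directed = FALSE,
                                     vertices = ids)
  comp <- igraph::components(g)$membership[ids]
  have <- paste(pmin(edges$gene_a, edges$gene_b),
                pmax(edges$gene_a, edges$gene_b))
  idx_of <- setNames(seq_along(ids), ids)
  todo <- list()
  for (members in split(ids, comp)) {
    n <- length(members)
    if (n < 3 || n > max_comp) next
    pairs <- t(combn(sort(members), 2))
    miss <- !(paste(pairs[, 1], pairs[, 2]) %in% have)
    if (any(miss))
      todo[[length(todo) + 1]] <- cbind(idx_of[pairs[miss, 1]],
                                        idx_of[pairs[miss, 2]])
  }
  if (!length(todo)) return(empty)
  score_candidate_pairs(aa, ids, do.call(rbind, todo), evalue_cutoff)
}

score_candidate_pairs <- function(aa, ids, cand, evalue_cutoff) {
  if (!nrow(cand))
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      bitscore = numeric(0), evalue = numeric(0)))
  # banded scoring: the seed-driven search explores a 48-diagonal corridor
  # around the length-difference diagonal (cannot exceed the full score)
  raw <- sw_raw_scores_pairs_cpp(aa, cand[, 1], cand[, 2], band = 48L)
  bits <- (KA_LAMBDA * raw - log(KA_K)) / log(2)
  ev <- nchar(aa)[cand[, 1]] * nchar(aa)[cand[, 2]] * 2^(-bits)
  keep <- ev <= evalue_cutoff
  data.frame(gene_a = ids[cand[keep, 1]], gene_b = ids[cand[keep, 2]],
             bitscore = bits[keep], evalue = ev[keep], stringsAsFactors = FALSE)
}

rescue_distant_components <- function(aa, ids, edges, evalue_cutoff) {
  empty <- edges[0, ]
  g <- igraph::graph_from_data_frame(edges[, 1:2], directed = FALSE,
                                     vertices = ids)
  comp <- igraph::components(g)$membership[ids]
  ncomp <- max(comp)
  if (ncomp < 2) return(empty)
  # representative = longest member (ties: smallest id; ids are sorted)
  rep_idx <- vapply(split(seq_along(ids), comp), function(ii)
    ii[which.max(nchar(aa)[ii])], integer(1))
  rcand <- kmer_candidate_pairs_cpp(aa[rep_idx], k = 6L, min_hits = 1L,
                                    reduced = TRUE)
  if (!nrow(rcand)) return(empty)
  rraw <- sw_raw_scores_pairs_cpp(aa[rep_idx], rcand[, 1], rcand[, 2], band = 48L)
  rbits <- (KA_LAMBDA * rraw - log(KA_K)) / log(2)
  rev_ <- nchar(aa)[rep_idx[rcand[, 1]]] * nchar(aa)[rep_idx[rcand[, 2]]] * 2^(-rbits)
  hit <- which(rev_ <= evalue_cutoff)
  if (!length(hit)) return(empty)
  by_comp <- split(seq_along(ids), comp)
  cross <- do.call(rbind, lapply(hit, function(h) {
    A <- by_comp[[rcand[h, 1]]]; B <- by_comp[[rcand[h, 2]]]
    as.matrix(expand.grid(A, B))
  }))
  score_candidate_pairs(aa, ids, cross, evalue_cutoff)
}

graph_from_hits <- function(path, genes, evalue_cutoff) {
  h <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(h) < 12)
    fatal("hits file must have 12 tab-separated columns (found %d)", ncol(h))
  names(h)[c(1, 2, 11, 12)] <- c("query", "subject", "evalue", "bitscore")
  h <- h[h$evalue <= evalue_cutoff & h$query != h$subject, , drop = FALSE]
  a <- pmin(h$query, h$subject); b <- pmax(h$query, h$subject)
  key <- paste(a, b, sep = "\r")
  best <- tapply(seq_along(key), key, function(i) i[which.max(h$bitscore[i])])
  idx <- as.integer(best)
  edges <- data.frame(gene_a = a[idx], gene_b = b[idx],
                      bitscore = h$bitscore[idx], evalue = h$evalue[idx],
                      stringsAsFactors = FALSE)
  similarity_graph(sort(genes$gene_id), edges)
}

#' Export a similarity graph as an ABC edge list
#'
#' `gene_a<TAB>gene_b<TAB>bitscore`, the standard input of graph clustering
#' tools.
#'
#' @param graph a `similarity_graph`.
#' @param path output file.
#' @export
export_abc <- function(graph, path) {
  write.table(graph$edges[, c("gene_a", "gene_b", "bitscore")], path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
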