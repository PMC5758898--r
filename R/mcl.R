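# Markov Clustering of the similarity graph, and the divide-and-conquer
# strategy that keeps all-against-all clustering tractable for large strain
# collections.

#' Markov Clustering (MCL)
#'
#' Standard MCL on the weighted similarity graph: the column-stochastic
#' transition matrix (with a self-loop on every node weighted by its maximum
#' incident edge weight) is alternately squared (expansion) and taken to an
#' elementwise power with column renormalization (inflation), pruning
#' entries below `prune`, until the matrix changes by less than 1e-8 or
#' `max_iter` iterations.  Clusters are the connected attractor systems of
#' the limit matrix; every node is assigned to exactly one cluster, ties
#' resolved towards the cluster holding the largest attractor mass and then
#' the smallest cluster label.
#'
#' @param graph a `similarity_graph` from [build_graph()].
#' @param inflation inflation exponent (> 1; default 1.5, deliberately
#'   coarse: paralogs are separated later by tree-based post-processing).
#' @param max_iter iteration cap.
#' @param prune entries below this are zeroed each iteration.
#' @return list of clusters, each a character vector of gene ids.
#' @export
mcl <- function(graph, inflation = 1.5, max_iter = 200, prune = 1e-5) {
  if (inflation <= 1) fatal("inflation must be > 1")
  nodes <- graph$nodes
  n <- length(nodes)
  e <- graph$edges
  ia <- match(e$gene_a, nodes); ib <- match(e$gene_b, nodes)
  A <- Matrix::sparseMatrix(i = c(ia, ib), j = c(ib, ia),
                            x = rep(e$bitscore, 2), dims = c(n, n))
  loop <- apply_max_incident(A, n)
  M <- A + Matrix::Diagonal(n, loop)
  M <- normalize_cols(M)
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M
    M2@x <- M2@x^inflation
    M2 <- normalize_cols(M2)
    M2 <- as(M2, "CsparseMatrix")
    M2@x[M2@x < prune] <- 0
    M2 <- normalize_cols(Matrix::drop0(M2))
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < 1e-8) break
  }
  interpret_mcl(M, nodes)
}

apply_max_incident <- function(A, n) {
  mx <- numeric(n)
  if (length(A@x)) {
    T <- as(A, "TsparseMatrix")
    for (k in seq_along(T@x)) {
      j <- T@j[k] + 1L
      if (T@x[k] > mx[j]) mx[j] <- T@x[k]
    }
  }
  mx[mx == 0] <- 1
  mx
}

normalize_cols <- function(M) {
  cs <- Matrix::colSums(M)
  cs[cs == 0] <- 1
  M %*% Matrix::Diagonal(length(cs), 1 / cs)
}

interpret_mcl <- function(M, nodes) {
  n <- length(nodes)
  d <- Matrix::diag(M)
  attractors <- which(d > 0)
  if (!length(attractors)) attractors <- seq_len(n)
  S <- M + Matrix::t(M)
  sub <- S[attractors, attractors, drop = FALSE]
  g <- igraph::graph_from_adjacency_matrix(sub > 0, mode = "undirected")
  comp <- igraph::components(g)$membership
  nsys <- max(comp)
  # attractor mass of each node in each system
  mass <- matrix(0, nsys, n)
  Ma <- M[attractors, , drop = FALSE]
  for (s in seq_len(nsys)) {
    rows <- which(comp == s)
    mass[s, ] <- Matrix::colSums(Ma[rows, , drop = FALSE])
  }
  assign <- apply(mass, 2, function(col) {
    if (all(col == 0)) return(NA_integer_)
    which(col == max(col))[1]   # ties: smallest system index
  })
  out <- split(nodes, assign)
  orphans <- nodes[is.na(assign)]
  out <- c(unname(out), as.list(orphans))
  canonical_clusters(out)
}

canonical_clusters <- function(clusters) {
  clusters <- lapply(clusters, function(x) sort(unique(x)))
  clusters <- clusters[order(-vapply(clusters, length, integer(1)),
                             vapply(clusters, `[`, character(1), 1))]
  names(clusters) <- sprintf("C%05d", seq_along(clusters))
  clusters
}

#' Per-cluster summary statistics
#'
#' @param clusters list of character vectors of gene ids.
#' @param genes gene table.
#' @param strains character vector of all strain ids in the dataset.
#' @return data.frame with per-cluster size, strain representation, mean
#'   nucleotide length and the core / single-copy / duplicated flags.
#' @export
cluster_info <- function(clusters, genes, strains = unique(genes$strain_id)) {
  st <- strain_of(genes$gene_id, genes)
  len <- setNames(nchar(genes$nt_seq), genes$gene_id)
  rows <- lapply(seq_along(clusters), function(i) {
    m <- clusters[[i]]
    cs <- table(st[m])
    data.frame(cluster_id = names(clusters)[i] %||% as.character(i),
               n_members = length(m),
               n_strains = length(cs),
               mean_length = mean(len[m]),
               is_core = all(strains %in% names(cs)),
               is_single_copy = all(cs == 1),
               duplicated = any(cs > 1),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-strain copy numbers of one cluster
#' @param members gene ids of one cluster.
#' @param genes gene table.
#' @return named integer vector strain_id -> copy number.
#' @export
strain_counts <- function(members, genes) {
  tab <- table(strain_of(members, genes))
  setNames(as.integer(tab), names(tab))
}

#' Cluster genomes with the divide-and-conquer strategy
#'
#' Strains are partitioned (sorted by strain id, then chunked) into batches
#' of at most `batch_size`; each batch is clustered with
#' [build_graph()] + [mcl()]; each batch cluster is reduced to a
#' representative sequence (the longest member, ties towards the smallest
#' gene id); the representatives of a batch form one pseudo-genome; the
#' pseudo-genomes are clustered the same way (recursively while more than
#' `batch_size` remain), and final clusters are the unions of the member
#' sets of co-clustered representatives.
#'
#' @param genomes list of [strain_genome] objects.
#' @param batch_size batch size (default 50).
#' @param evalue_cutoff,inflation passed to [build_graph()] / [mcl()].
#' @return list of clusters (character vectors of gene ids).
#' @export
divide_and_conquer <- function(genomes, batch_size = 50,
                               evalue_cutoff = 0.001, inflation = 1.5) {
  units <- lapply(genomes, function(g) as.data.frame(g$genes))
  names(units) <- vapply(genomes, function(g) g$strain_id, character(1))
  units <- units[order(names(units))]
  canonical_clusters(dnc_units(units, batch_size, evalue_cutoff, inflation))
}

dnc_units <- function(units, batch_size, evalue_cutoff, inflation) {
  flat_cluster <- function(us) {
    df <- do.call(rbind, us)
    rownames(df) <- NULL
    class(df) <- c("gene_table", "data.frame")
    mcl(build_graph(df, evalue_cutoff = evalue_cutoff), inflation = inflation)
  }
  if (length(units) <= batch_size) return(flat_cluster(units))
  idx <- split(seq_along(units), ceiling(seq_along(units) / batch_size))
  members_of_rep <- list()
  pseudo <- list()
  for (b in seq_along(idx)) {
    us <- units[idx[[b]]]
    sub <- flat_cluster(us)
    df <- do.call(rbind, us)
    reps <- vapply(sub, function(m) {
      len <- nchar(df$nt_seq[match(m, df$gene_id)])
      cand <- m[len == max(len)]
      sort(cand)[1]
    }, character(1))
    for (k in seq_along(sub)) members_of_rep[[reps[k]]] <- sub[[k]]
    pseudo[[sprintf("pseudo%04d", b)]] <-
      df[match(reps, df$gene_id), , drop = FALSE]
  }
  top <- dnc_units(pseudo, batch_size, evalue_cutoff, inflation)
  lapply(top, function(repset) sort(unlist(members_of_rep[repset], use.names = FALSE)))
}
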