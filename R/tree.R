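# Gene/strain tree construction (neighbor joining on Jukes-Cantor distances,
# or an external builder), plus the small tree utilities shared by the
# post-processing and gain/loss modules.  Trees are `ape::phylo` objects.

JC_P_CAP <- 0.74  # p-distances at/above this are treated as saturated

#' Jukes-Cantor distance from a mismatch proportion
#'
#' `d = -(3/4) * log(1 - (4/3) p)`; proportions at or above the saturation
#' cap (0.74) are clamped to the cap before transforming, keeping distances
#' finite for unrelated sequences.
#'
#' @param p proportion of differing sites (pairwise deletion of gaps).
#' @return distance in substitutions/site.
#' @export
jc_distance <- function(p) {
  p <- pmin(p, JC_P_CAP)
  -0.75 * log(1 - 4 * p / 3)
}

#' Build a tree from a multiple alignment
#'
#' Internal backend: neighbor joining (ape) on Jukes-Cantor distances with
#' pairwise deletion of gap columns, negative branch lengths clamped to
#' zero, midpoint-rooted.  An external builder (e.g. FastTree) can be
#' plugged in via a command template with `{in}` and `{out}` placeholders;
#' its newick output is read back and midpoint-rooted the same way.
#'
#' @param aln named character vector of aligned rows (nucleotide by
#'   default; gene trees are built from codon alignments).
#' @param command optional external command template.
#' @return rooted `phylo` tree with the alignment row names as tip labels.
#' @export
build_tree <- function(aln, command = NULL) {
  n <- length(aln)
  if (n < 2) fatal("build_tree needs at least 2 sequences")
  if (!is.null(command)) {
    fin <- tempfile(fileext = ".fasta"); fout <- tempfile(fileext = ".nwk")
    on.exit(unlink(c(fin, fout)))
    write_fasta(aln, fin, type = "nt")
    cmd <- gsub("{out}", fout, gsub("{in}", fin, command, fixed = TRUE), fixed = TRUE)
    status <- system(cmd)
    if (status != 0 || !file.exists(fout))
      fatal("external tree builder failed (exit %d): %s", status, cmd)
    tr <- ape::read.tree(fout)
    tr$edge.length[is.na(tr$edge.length) | tr$edge.length < 0] <- 0
    return(midpoint_root(tr))
  }
  P <- pdist_cpp(unname(aln))
  P[is.na(P)] <- JC_P_CAP
  D <- jc_distance(P)
  dimnames(D) <- list(names(aln), names(aln))
  if (n == 2) {
    tr <- structure(list(edge = matrix(c(3L, 3L, 1L, 2L), 2, 2),
                         edge.length = rep(D[1, 2] / 2, 2),
                         tip.label = names(aln), Nnode = 1L),
                    class = "phylo", order = "cladewise")
    return(tr)
  }
  tr <- ape::nj(as.dist(D))
  tr$edge.length[tr$edge.length < 0] <- 0
  midpoint_root(tr)
}

midpoint_root <- function(tr) {
  out <- tryCatch(phangorn::midpoint(tr), error = function(e) NULL)
  if (is.null(out) || !ape::is.rooted(out))
    out <- ape::root(tr, outgroup = tr$tip.label[1], resolve.root = TRUE)
  out$edge.length[is.na(out$edge.length) | out$edge.length < 0] <- 0
  out
}

# Logical matrix (edges x tips): TRUE where the tip lies below the edge's
# child node.  Row order follows tree$edge.
edge_leaf_matrix <- function(tree) {
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  below <- matrix(FALSE, nn, nt)
  below[cbind(seq_len(nt), seq_len(nt))] <- TRUE
  eo <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(eo$edge))) {
    p <- eo$edge[k, 1]; ch <- eo$edge[k, 2]
    below[p, ] <- below[p, ] | below[ch, ]
  }
  out <- below[tree$edge[, 2], , drop = FALSE]
  colnames(out) <- tree$tip.label
  out
}

# Leaf groups obtained by deleting the given edge rows from the tree.
# Components that contain no leaf are dropped.
cut_tree_components <- function(tree, remove_edges) {
  nt <- length(tree$tip.label)
  keep <- setdiff(seq_len(nrow(tree$edge)), remove_edges)
  g <- igraph::graph_from_edgelist(cbind(tree$edge[keep, 1], tree$edge[keep, 2]),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nt + tree$Nnode - igraph::vcount(g)))
  memb <- igraph::components(g)$membership[seq_len(nt)]
  unname(split(tree$tip.label, memb))
}
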