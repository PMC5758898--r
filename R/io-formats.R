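# FASTA, cluster lists, metadata tables, newick: thin wrappers around
# Biostrings / ape readers and writers.

#' Read a FASTA file as a named character vector
#' @param path FASTA file.
#' @param type `"nt"` or `"aa"`.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path, type = c("nt", "aa")) {
  type <- match.arg(type)
  x <- if (type == "nt") Biostrings::readDNAStringSet(path) else
    Biostrings::readAAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write named sequences as FASTA
#' @param seqs named character vector.
#' @param path output file.
#' @param type `"nt"` or `"aa"`.
#' @export
write_fasta <- function(seqs, path, type = c("nt", "aa")) {
  type <- match.arg(type)
  if (!length(seqs)) fatal("refusing to write an empty FASTA")
  if (any(nchar(seqs) == 0)) fatal("empty sequence for record '%s'",
                                   names(seqs)[which(nchar(seqs) == 0)[1]])
  x <- if (type == "nt") Biostrings::DNAStringSet(seqs) else Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write a cluster's sequences as FASTA
#'
#' Headers are gene ids; sequences are looked up in the gene table.
#'
#' @param members character vector of gene ids (one cluster).
#' @param genes gene table.
#' @param path output file.
#' @param kind `"nt"` or `"aa"`.
#' @export
write_cluster_fasta <- function(members, genes, path, kind = c("nt", "aa")) {
  kind <- match.arg(kind)
  if (!length(members)) fatal("empty cluster")
  m <- match(members, genes$gene_id)
  if (anyNA(m)) fatal("unknown gene_id: %s", members[which(is.na(m))[1]])
  seqs <- setNames(if (kind == "nt") genes$nt_seq[m] else genes$aa_seq[m], members)
  write_fasta(seqs, path, type = kind)
}

#' Write clusters as a tab-separated gene list
#'
#' One cluster per line, members separated by tabs — the interchange format
#' for entering the pipeline with precomputed clusters.
#'
#' @param clusters list of character vectors of gene ids.
#' @param path output file.
#' @export
write_clusters <- function(clusters, path) {
  writeLines(vapply(clusters, paste, character(1), collapse = "\t"), path)
  invisible(path)
}

#' @rdname write_clusters
#' @export
read_clusters <- function(path) {
  strsplit(readLines(path, warn = FALSE), "\t", fixed = TRUE)
}

#' Read a strain metadata table
#'
#' Tab-separated, first column strain_id, remaining columns numeric or
#' categorical attributes; empty cells become `NA`.
#'
#' @param path TSV file.
#' @return data.frame with rownames = strain ids.
#' @export
read_metadata <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                   na.strings = c("", "NA"))
  rownames(df) <- df[[1]]
  df[, -1, drop = FALSE]
}

#' Extract one numeric phenotype from a metadata table
#' @param metadata data.frame from [read_metadata()].
#' @param column column name.
#' @return named numeric vector strain_id -> value (`NA` allowed).
#' @export
phenotype_vector <- function(metadata, column) {
  if (!column %in% names(metadata)) fatal("no metadata column '%s'", column)
  setNames(as.numeric(metadata[[column]]), rownames(metadata))
}
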