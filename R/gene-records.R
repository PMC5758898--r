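#' Construct a gene table
#'
#' The central per-gene container: one row per protein-coding gene with
#' identifiers, 0-based half-open genomic coordinates, strand, and both the
#' coding-strand nucleotide sequence and the amino-acid sequence.
#'
#' @param gene_id unique gene identifiers (`"<strain>|<locus>"`).
#' @param strain_id,contig_id strain and contig of each gene.
#' @param start,end 0-based half-open coordinates (`end > start`).
#' @param strand `"+"` or `"-"`; `nt_seq` always reads 5'->3' on the coding strand.
#' @param nt_seq,aa_seq nucleotide and amino-acid sequences.
#' @param annotation free-text product annotation.
#' @return a `data.frame` of class `gene_table`.
#' @export
gene_table <- function(gene_id, strain_id, contig_id, start, end, strand,
                       nt_seq, aa_seq, annotation = "") {
  df <- data.frame(
    gene_id = as.character(gene_id), strain_id = as.character(strain_id),
    contig_id = as.character(contig_id),
    start = as.integer(start), end = as.integer(end),
    strand = as.character(strand),
    nt_seq = as.character(nt_seq), aa_seq = as.character(aa_seq),
    annotation = rep_len(as.character(annotation), length(gene_id)),
    stringsAsFactors = FALSE
  )
  validate_gene_table(df)
  class(df) <- c("gene_table", "data.frame")
  df
}

validate_gene_table <- function(df) {
  if (anyDuplicated(df$gene_id)) fatal("duplicate gene_id values")
  if (any(df$end <= df$start)) fatal("gene with end <= start")
  if (any(!df$strand %in% c("+", "-"))) fatal("strand must be '+' or '-'")
  if (any(nchar(df$nt_seq) == 0 | nchar(df$aa_seq) == 0))
    fatal("empty nt or aa sequence")
  invisible(df)
}

#' Construct a strain genome
#'
#' One annotated genome: an ordered gene table plus optional contig sequences
#' and free-form metadata.
#'
#' @param strain_id strain identifier.
#' @param genes a [gene_table] whose rows all carry this `strain_id`.
#' @param contigs optional named character vector of contig sequences.
#' @param metadata optional named list of strain attributes.
#' @return an object of class `strain_genome`.
#' @export
strain_genome <- function(strain_id, genes, contigs = NULL, metadata = list()) {
  stopifnot(is.data.frame(genes))
  if (nrow(genes) && any(genes$strain_id != strain_id))
    fatal("gene table contains foreign strain_ids for genome '%s'", strain_id)
  ord <- order(genes$contig_id, genes$start)
  structure(
    list(strain_id = strain_id, genes = genes[ord, , drop = FALSE],
         contigs = contigs, metadata = metadata),
    class = "strain_genome"
  )
}

#' @export
print.strain_genome <- function(x, ...) {
  cat(sprintf("<strain_genome> %s: %d genes on %d contig(s)\n",
              x$strain_id, nrow(x$genes), length(unique(x$genes$contig_id))))
  invisible(x)
}

#' Bind the gene tables of several genomes
#' @param genomes list of [strain_genome] objects.
#' @return combined `gene_table`.
#' @export
combined_gene_table <- function(genomes) {
  df <- do.call(rbind, lapply(genomes, function(g) as.data.frame(g$genes)))
  rownames(df) <- NULL
  validate_gene_table(df)
  class(df) <- c("gene_table", "data.frame")
  df
}

#' Strain of each gene id
#' @param gene_ids gene identifiers.
#' @param genes gene table used as the lookup.
#' @return named character vector gene_id -> strain_id.
#' @export
strain_of <- function(gene_ids, genes) {
  m <- match(gene_ids, genes$gene_id)
  if (anyNA(m)) fatal("unknown gene_id: %s", gene_ids[which(is.na(m))[1]])
  setNames(genes$strain_id[m], gene_ids)
}
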