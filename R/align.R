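# Protein multiple alignment (internal progressive aligner or an external
# command), and codon back-translation of protein alignments.

#' Align protein sequences
#'
#' With the default internal backend, sequences are aligned progressively:
#' pairwise/profile Needleman-Wunsch under BLOSUM62 with a linear gap
#' penalty, guided by an average-linkage tree on 3-mer distances.  An
#' external aligner (e.g. MAFFT) can be plugged in via a command template
#' containing `{in}` and `{out}` placeholders.
#'
#' @param seqs named character vector of amino-acid sequences.
#' @param gap linear gap penalty per column (default 8, BLOSUM62 scale).
#' @param command optional external command template, e.g.
#'   `"mafft --quiet {in} > {out}"`.
#' @return named character vector of aligned rows (equal length, gap `-`).
#' @export
align_proteins <- function(seqs, gap = 8, command = NULL) {
  if (!length(seqs)) fatal("no sequences to align")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    fatal("sequences must carry unique names")
  if (length(seqs) == 1) return(seqs)
  if (!is.null(command)) return(align_external(seqs, command))
  d <- kmer_guide_dist(seqs, k = 3)
  hc <- hclust(as.dist(d), method = "average")
  aligned <- progressive_align_cpp(unname(seqs), hc$merge, gap_col = gap)
  setNames(as.character(aligned), names(seqs))
}

kmer_guide_dist <- function(seqs, k = 3) {
  n <- length(seqs)
  kms <- lapply(seqs, function(s) {
    if (nchar(s) < k) return(s)
    unique(substring(s, seq_len(nchar(s) - k + 1), seq_len(nchar(s) - k + 1) + k - 1))
  })
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    shared <- length(intersect(kms[[i]], kms[[j]]))
    denom <- min(length(kms[[i]]), length(kms[[j]]))
    d[i, j] <- d[j, i] <- 1 - shared / max(denom, 1)
  }
  d
}

align_external <- function(seqs, command) {
  fin <- tempfile(fileext = ".faa"); fout <- tempfile(fileext = ".afa")
  on.exit(unlink(c(fin, fout)))
  write_fasta(seqs, fin, type = "aa")
  cmd <- gsub("{out}", fout, gsub("{in}", fin, command, fixed = TRUE), fixed = TRUE)
  status <- system(cmd)
  if (status != 0 || !file.exists(fout))
    fatal("external aligner failed (exit %d): %s", status, cmd)
  aln <- read_fasta(fout, type = "aa")
  aln[names(seqs)]
}

#' Remove gaps from alignment rows
#' @param x character vector of gapped rows.
#' @return ungapped sequences.
#' @export
ungap <- function(x) gsub("-", "", x, fixed = TRUE)

#' Strip the terminal stop codon where present
#'
#' @param nt nucleotide coding sequences.
#' @param aa matching amino-acid sequences (no terminal stop).
#' @return nt sequences with a trailing stop codon removed when its removal
#'   makes the length exactly `3 * nchar(aa)`.
#' @export
strip_terminal_stop <- function(nt, aa) {
  last <- toupper(substring(nt, nchar(nt) - 2, nchar(nt)))
  drop <- nchar(nt) == 3 * nchar(aa) + 3 & last %in% c("TAA", "TAG", "TGA")
  nt[drop] <- substring(nt[drop], 1, nchar(nt[drop]) - 3)
  nt
}

#' Back-translate a protein alignment to a codon alignment
#'
#' Each amino-acid column is expanded to the underlying codon and each gap
#' to `---`, so the nucleotide alignment is exactly three times as long as
#' the protein alignment.
#'
#' @param aa_aln named character vector of aligned protein rows.
#' @param nt_seqs named nucleotide sequences; for every row the ungapped
#'   nucleotide length must equal three times the ungapped protein length
#'   (terminal stops removed upstream, see [strip_terminal_stop()]).
#' @return named character vector of codon-aligned nucleotide rows.
#' @export
codon_align <- function(aa_aln, nt_seqs) {
  out <- character(length(aa_aln))
  for (i in seq_along(aa_aln)) {
    id <- names(aa_aln)[i]
    aa <- aa_aln[[i]]
    nt <- nt_seqs[[id]]
    if (is.null(nt)) fatal("no nucleotide sequence for '%s'", id)
    n_res <- nchar(ungap(aa))
    if (nchar(nt) != 3 * n_res)
      fatal("codon back-translation length mismatch for '%s': %d nt vs %d aa residues",
            id, nchar(nt), n_res)
    chars <- strsplit(aa, "")[[1]]
    codons <- rep("---", length(chars))
    res <- which(chars != "-")
    starts <- 3L * (seq_along(res) - 1L) + 1L
    codons[res] <- substring(nt, starts, starts + 2L)
    out[i] <- paste(codons, collapse = "")
  }
  setNames(out, names(aa_aln))
}
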