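# GenBank flat-file reading/writing.  Only what the pipeline needs: LOCUS,
# CDS features with location + a few qualifiers, and the ORIGIN sequence.

parse_gb_location <- function(loc) {
  loc <- gsub("[<>]", "", gsub("\\s", "", loc))
  complement <- grepl("^complement\\(", loc)
  if (complement) loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  joined <- grepl("^(join|order)\\(", loc)
  if (joined) loc <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
  parts <- strsplit(loc, ",", fixed = TRUE)[[1]]
  segs <- lapply(parts, function(p) {
    m <- regmatches(p, regexec("^(\\d+)\\.\\.(\\d+)$", p))[[1]]
    if (length(m) == 3) return(c(as.integer(m[2]), as.integer(m[3])))
    if (grepl("^\\d+$", p)) return(c(as.integer(p), as.integer(p)))
    NULL
  })
  if (any(vapply(segs, is.null, logical(1)))) return(NULL)
  list(segments = do.call(rbind, segs), complement = complement)
}

split_gb_features <- function(flines) {
  # feature keys start at column 6; qualifier/continuation lines at column 22
  starts <- which(grepl("^ {5}\\S", flines))
  if (!length(starts)) return(list())
  ends <- c(starts[-1] - 1L, length(flines))
  lapply(seq_along(starts), function(i) flines[starts[i]:ends[i]])
}

parse_gb_feature <- function(block) {
  key <- sub("^ {5}(\\S+).*", "\\1", block[1])
  txt <- sub("^ {5}\\S+\\s*", "", block[1])
  rest <- sub("^\\s+", "", block[-1])
  # location may continue over lines until the first qualifier
  qual_start <- which(grepl("^/", rest))[1]
  loc_extra <- if (is.na(qual_start)) rest else head(rest, qual_start - 1L)
  loc <- paste0(txt, paste(loc_extra, collapse = ""))
  quals <- list()
  if (!is.na(qual_start)) {
    qlines <- rest[qual_start:length(rest)]
    idx <- cumsum(grepl("^/", qlines))
    for (q in split(qlines, idx)) {
      joined <- paste(q, collapse = "")
      name <- sub("^/([A-Za-z_0-9]+).*", "\\1", joined)
      val <- if (grepl("=", joined)) sub("^/[A-Za-z_0-9]+=", "", joined) else TRUE
      if (is.character(val)) {
        val <- gsub('^"|"$', "", val)
        if (name == "translation") val <- gsub("\\s", "", val)
      }
      quals[[name]] <- val
    }
  }
  list(key = key, location = loc, qualifiers = quals)
}

#' Read an annotated genome from a GenBank flat file
#'
#' Extracts one gene record per non-pseudo CDS feature.  GenBank 1-based
#' inclusive coordinates are converted to 0-based half-open; minus-strand
#' genes are reverse-complemented so `nt_seq` always reads 5'->3' on the
#' coding strand; compound (`join`) locations are concatenated exon by exon.
#' The amino-acid sequence is taken from the `/translation` qualifier when
#' present and otherwise translated with the bacterial code (table 11); a CDS
#' whose length is not a multiple of three and that lacks a `/translation`
#' is skipped with a warning.
#'
#' @param path GenBank file (one or more LOCUS records).
#' @param strain_id strain identifier used to prefix gene ids.
#' @return a [strain_genome].
#' @export
read_genbank <- function(path, strain_id) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) fatal("empty GenBank file: %s", path)
  rec_start <- which(grepl("^LOCUS", lines))
  if (!length(rec_start)) fatal("no LOCUS record in %s", path)
  rec_end <- c(rec_start[-1] - 1L, length(lines))
  rows <- list(); contigs <- character(0); ordinal <- 0L
  for (r in seq_along(rec_start)) {
    rec <- lines[rec_start[r]:rec_end[r]]
    contig <- strsplit(rec[1], "\\s+")[[1]][2]
    ori <- which(grepl("^ORIGIN", rec))
    if (!length(ori)) fatal("GenBank record '%s' has no ORIGIN sequence", contig)
    seq_lines <- rec[(ori[1] + 1):length(rec)]
    seq_lines <- seq_lines[!grepl("^//", seq_lines)]
    genome_seq <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
    if (!nchar(genome_seq)) fatal("GenBank record '%s' has an empty sequence body", contig)
    contigs[contig] <- genome_seq
    feat <- which(grepl("^FEATURES", rec))
    if (!length(feat)) next
    fblock <- rec[(feat[1] + 1):(ori[1] - 1)]
    for (f in split_gb_features(fblock)) {
      pf <- parse_gb_feature(f)
      if (pf$key != "CDS") next
      if (isTRUE(pf$qualifiers$pseudo)) next
      loc <- parse_gb_location(pf$location)
      if (is.null(loc)) {
        warning(sprintf("unparseable CDS location '%s' in %s; skipped", pf$location, contig))
        next
      }
      nt <- paste(apply(loc$segments, 1, function(s)
        substr(genome_seq, s[1], s[2])), collapse = "")
      if (loc$complement) nt <- revcomp(nt)
      aa <- pf$qualifiers$translation
      if (is.null(aa)) {
        if (nchar(nt) %% 3 != 0) {
          warning(sprintf("CDS at %s (%s): length not a multiple of 3 and no /translation; skipped",
                          pf$location, contig))
          next
        }
        aa <- translate_cds(nt)
      } else {
        if (nchar(nt) %% 3 == 0) {
          own <- translate_cds(nt)
          if (!identical(own, aa))
            message(sprintf("translation qualifier disagrees with internal translation for CDS at %s (%s); keeping the qualifier",
                            pf$location, contig))
        }
      }
      ordinal <- ordinal + 1L
      locus <- pf$qualifiers$locus_tag %||% sprintf("%s_%05d", contig, ordinal)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = paste0(strain_id, "|", locus), strain_id = strain_id,
        contig_id = contig,
        start = min(loc$segments[, 1]) - 1L, end = max(loc$segments[, 2]),
        strand = if (loc$complement) "-" else "+",
        nt_seq = nt, aa_seq = aa,
        annotation = as.character(pf$qualifiers$product %||% ""),
        stringsAsFactors = FALSE
      )
    }
  }
  genes <- if (length(rows)) do.call(rbind, rows) else
    gene_table(character(0), character(0), character(0), integer(0),
               integer(0), character(0), character(0), character(0))
  genes <- genes[nchar(genes$aa_seq) > 0, , drop = FALSE]
  class(genes) <- c("gene_table", "data.frame")
  validate_gene_table(genes)
  strain_genome(strain_id, genes, contigs = contigs)
}

#' Write a strain genome as a GenBank flat file
#'
#' Emits one LOCUS record per contig with CDS features (`/locus_tag`,
#' `/product`, `/translation`) and the ORIGIN sequence, readable back by
#' [read_genbank()].
#'
#' @param genome a [strain_genome] with contig sequences.
#' @param path output file.
#' @export
write_genbank <- function(genome, path) {
  if (is.null(genome$contigs)) fatal("genome '%s' carries no contig sequences", genome$strain_id)
  con <- file(path, "w"); on.exit(close(con))
  wrap <- function(prefix, text, width = 58) {
    chunks <- substring(text, seq(1, nchar(text), width),
                        pmin(seq(1, nchar(text), width) + width - 1, nchar(text)))
    paste0(c(prefix, rep(strrep(" ", 21), length(chunks) - 1)), chunks)
  }
  for (contig in names(genome$contigs)) {
    seqs <- genome$contigs[[contig]]
    writeLines(sprintf("LOCUS       %s %d bp    DNA     linear   BCT", contig, nchar(seqs)), con)
    writeLines(sprintf("DEFINITION  %s.", genome$strain_id), con)
    writeLines("FEATURES             Location/Qualifiers", con)
    g <- genome$genes[genome$genes$contig_id == contig, , drop = FALSE]
    for (i in seq_len(nrow(g))) {
      loc <- sprintf("%d..%d", g$start[i] + 1L, g$end[i])
      if (g$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
      writeLines(sprintf("     CDS             %s", loc), con)
      locus <- sub("^[^|]*\\|", "", g$gene_id[i])
      writeLines(sprintf('                     /locus_tag="%s"', locus), con)
      if (nzchar(g$annotation[i]))
        writeLines(sprintf('                     /product="%s"', g$annotation[i]), con)
      writeLines(wrap('                     /translation="', paste0(g$aa_seq[i], '"')), con)
    }
    writeLines("ORIGIN", con)
    pos <- seq(1, nchar(seqs), 60)
    for (p in pos) {
      row <- substring(seqs, p, min(p + 59, nchar(seqs)))
      row <- paste(substring(row, seq(1, nchar(row), 10),
                             pmin(seq(1, nchar(row), 10) + 9, nchar(row))), collapse = " ")
      writeLines(sprintf("%9d %s", p, tolower(row)), con)
    }
    writeLines("//", con)
  }
  invisible(path)
}
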