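`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of a DNA string
#' @param x character vector of DNA strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Translate coding sequences with the bacterial genetic code
#'
#' Translates with NCBI translation table 11 and removes a terminal stop.
#' Internal stops are retained as `*`.
#'
#' @param nt character vector of in-frame coding sequences (length multiple of 3).
#' @return character vector of amino-acid sequences.
#' @export
translate_cds <- function(nt) {
  if (any(nchar(nt) %% 3 != 0)) stop("coding sequence length not a multiple of 3")
  aa <- suppressWarnings(as.character(Biostrings::translate(
    Biostrings::DNAStringSet(nt),
    genetic.code = Biostrings::getGeneticCode("11"),
    if.fuzzy.codon = "solve"
  )))
  sub("\\*$", "", aa)
}

fatal <- function(...) stop(sprintf(...), call. = FALSE)
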