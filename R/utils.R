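# Small shared helpers. All internal coordinates in this package are
# 0-based, half-open; conversion to R's 1-based indexing happens at the
# substr()/seq boundary.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of a nucleotide string
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Translate a nucleotide string in frame 0
#'
#' Trailing bases that do not complete a codon are dropped. Codons with
#' ambiguous bases translate to "X"; stops are "*".
#' @param nt character vector of nucleotide sequences.
#' @return character vector of amino-acid sequences.
#' @keywords internal
translate_nt <- function(nt) {
  # direct codon-table lookup; no initiator-codon special-casing, since
  # fragments are arbitrary ORF windows, not mRNA starts
  gc_tab <- Biostrings::GENETIC_CODE
  vapply(nt, function(s) {
    n <- nchar(s)
    if (is.na(s) || n < 3L) return("")
    n <- n - n %% 3L
    codons <- substring(s, seq.int(1L, n, 3L), seq.int(3L, n, 3L))
    aa <- unname(gc_tab[codons])
    aa[is.na(aa)] <- "X"
    paste(aa, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Phred+33 helpers: quality strings <-> integer scores.
phred_decode <- function(q) {
  if (is.na(q) || !nzchar(q)) return(integer(0))
  utf8ToInt(q) - 33L
}

phred_encode <- function(p) {
  if (length(p) == 0L) return("")
  intToUtf8(pmin(p, 93L) + 33L)
}

mean_phred <- function(q) {
  p <- phred_decode(q)
  if (length(p) == 0L) return(NA_real_)
  mean(p)
}

# substring by 0-based half-open coordinates
substr0 <- function(x, start0, end0) substr(x, start0 + 1L, end0)

STOP_SYMBOL <- "*"

has_stop <- function(aa) grepl("*", aa, fixed = TRUE)

# deterministic alphabetical first element
lex_first <- function(x) sort(x, method = "radix")[1L]
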