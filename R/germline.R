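# Germline V/D/J reference sets.
#
# References travel as FASTA with pipe-delimited header metadata:
#   >allele_name|gene_class|chain|subgroup[|cdr3_anchor]
# cdr3_anchor is the 0-based offset of the conserved CDR3-boundary codon
# within the gene (V: first nt of the conserved Cys codon; J: first nt of
# the FR4-anchor codon). It is required for V and J genes so that CDR3
# delineation maps anchors instead of guessing motifs.

#' Construct a germline gene set
#'
#' @param genes data.frame with columns `allele_name`, `gene_class` (V/D/J),
#'   `chain` (IGH/IGK/IGL), `subgroup`, `cdr3_anchor` (integer, `NA` for D),
#'   `sequence` (nucleotides).
#' @param species `"human"` or `"mouse"`.
#' @return An object of class `germline_set`.
#' @export
germline_set <- function(genes, species = c("human", "mouse")) {
  species <- match.arg(species)
  required <- c("allele_name", "gene_class", "chain", "subgroup",
                "cdr3_anchor", "sequence")
  missing_cols <- setdiff(required, names(genes))
  if (length(missing_cols))
    stop("germline table lacks columns: ", paste(missing_cols, collapse = ", "))
  genes <- as.data.frame(genes)[required]
  genes$cdr3_anchor <- as.integer(genes$cdr3_anchor)
  validate_germline_set(genes)
  structure(list(species = species, genes = genes), class = "germline_set")
}

validate_germline_set <- function(genes) {
  if (anyDuplicated(genes$allele_name)) {
    dup <- genes$allele_name[duplicated(genes$allele_name)][1L]
    stop("duplicate allele name in germline set: ", dup)
  }
  bad <- !genes$gene_class %in% c("V", "D", "J")
  if (any(bad))
    stop("invalid gene_class for ", genes$allele_name[bad][1L])
  if (any(!nzchar(genes$sequence)) ||
      any(grepl("[^ACGT]", genes$sequence)))
    stop("germline sequences must be non-empty over {A,C,G,T}")
  vj <- genes$gene_class %in% c("V", "J")
  if (any(vj & is.na(genes$cdr3_anchor)))
    stop("V and J genes require a cdr3_anchor: ",
         genes$allele_name[vj & is.na(genes$cdr3_anchor)][1L])
  anc <- genes$cdr3_anchor[vj]
  if (any(anc %% 3L != 0L) || any(anc >= nchar(genes$sequence[vj])) ||
      any(anc < 0L))
    stop("cdr3_anchor must be an in-frame offset within the gene")
  for (ch in unique(genes$chain)) {
    sub <- genes[genes$chain == ch, ]
    for (cl in c("V", "J"))
      if (!any(sub$gene_class == cl))
        stop("no ", cl, " genes for ", ch)
  }
  invisible(genes)
}

#' Load a germline reference set from FASTA
#'
#' Headers must be `allele_name|gene_class|chain|subgroup[|cdr3_anchor]`.
#' V and J records without a `cdr3_anchor` field are rejected.
#'
#' @param path path to the germline FASTA file.
#' @param species `"human"` or `"mouse"`.
#' @return A [germline_set].
#' @export
load_germline_set <- function(path, species = c("human", "mouse")) {
  species <- match.arg(species)
  if (!file.exists(path)) stop("germline FASTA not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("empty germline FASTA: ", path)
  rows <- lapply(names(seqs), function(h) {
    f <- strsplit(h, "|", fixed = TRUE)[[1]]
    if (length(f) < 4L || any(!nzchar(f[1:4])))
      stop("malformed germline header (need allele|class|chain|subgroup): '",
           h, "'")
    data.frame(allele_name = f[1], gene_class = f[2], chain = f[3],
               subgroup = f[4],
               cdr3_anchor = if (length(f) >= 5L) as.integer(f[5]) else NA_integer_,
               stringsAsFactors = FALSE)
  })
  genes <- do.call(rbind, rows)
  genes$sequence <- as.character(seqs)
  germline_set(genes, species)
}

#' Write a germline set back to FASTA
#'
#' Inverse of [load_germline_set()]: headers are reassembled from the
#' metadata columns, so load-then-write is the identity on well-formed files.
#'
#' @param set a [germline_set].
#' @param path output FASTA path.
#' @export
write_germline_set <- function(set, path) {
  g <- set$genes
  hdr <- paste(g$allele_name, g$gene_class, g$chain, g$subgroup, sep = "|")
  hdr <- ifelse(is.na(g$cdr3_anchor), hdr, paste(hdr, g$cdr3_anchor, sep = "|"))
  x <- Biostrings::DNAStringSet(g$sequence)
  names(x) <- hdr
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

#' Append novel alleles to a germline set
#'
#' Extends the annotation search space with user-provided (e.g. provisional
#' novel) alleles. Extras whose `allele_name` already exists replace the base
#' entry; replacements are reported via message.
#'
#' @param base,extra [germline_set] objects of the same species.
#' @return The merged [germline_set].
#' @export
merge_novel_alleles <- function(base, extra) {
  stopifnot(inherits(base, "germline_set"), inherits(extra, "germline_set"))
  if (base$species != extra$species)
    stop("species mismatch: base is ", base$species, ", extra is ",
         extra$species)
  replaced <- intersect(base$genes$allele_name, extra$genes$allele_name)
  if (length(replaced))
    message("replacing germline alleles: ", paste(replaced, collapse = ", "))
  kept <- base$genes[!base$genes$allele_name %in% replaced, ]
  germline_set(rbind(kept, extra$genes), base$species)
}

#' Family-level subgroup of an allele name
#'
#' Returns the text before the first `-`; if there is none, the text before
#' the first `*`; otherwise the full name. E.g. `"IGHV1-69*01"` -> `"IGHV1"`,
#' `"IGHJ4*02"` -> `"IGHJ4"`.
#'
#' @param allele_name character vector of allele names.
#' @return character vector of subgroup labels.
#' @export
subgroup_of <- function(allele_name) {
  if (any(!nzchar(allele_name)) || any(is.na(allele_name)))
    stop("empty allele name")
  vapply(allele_name, function(a) {
    if (grepl("-", a, fixed = TRUE)) return(sub("-.*$", "", a))
    if (grepl("*", a, fixed = TRUE)) return(sub("\\*.*$", "", a))
    a
  }, character(1), USE.NAMES = FALSE)
}

genes_of <- function(set, chain, gene_class) {
  g <- set$genes
  g[g$chain == chain & g$gene_class == gene_class, , drop = FALSE]
}

#' @export
print.germline_set <- function(x, ...) {
  tab <- table(x$genes$chain, x$genes$gene_class)
  cat("germline_set (", x$species, "): ", nrow(x$genes), " alleles\n",
      sep = "")
  print(tab)
  invisible(x)
}
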