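# Per-replicate descriptive statistics. The unit of counting throughout is
# the unique amino-acid sequence (one vote per annotation record, regardless
# of its read count), matching the usage rule for subgroup frequencies and
# applied consistently to the CDR3-length, isotype and SHM tables.

#' Build a usage table
#'
#' @param labels vector of axis labels (one per unique amino-acid sequence).
#' @return data.frame of class `usage_table` with `label`, `count`,
#'   `frequency` (frequencies sum to 1 when non-empty).
#' @export
usage_table <- function(labels) {
  if (length(labels) == 0L) {
    return(structure(data.frame(label = character(0), count = integer(0),
                                frequency = numeric(0)),
                     class = c("usage_table", "data.frame")))
  }
  tab <- table(labels)
  out <- data.frame(label = names(tab), count = as.integer(tab),
                    frequency = as.numeric(tab) / sum(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(out$label, method = "radix"), ]
  rownames(out) <- NULL
  class(out) <- c("usage_table", "data.frame")
  out
}

#' Count somatic hypermutations on the V-gene span
#'
#' Mismatched aligned positions within the V span; each insertion or
#' deletion event counts once regardless of its length.
#'
#' @param v_map alignment map of the V gene call (as produced during
#'   annotation: `mismatches` and `indel_events` elements).
#' @return integer mutation count.
#' @export
count_shm <- function(v_map) {
  v_map$mismatches + v_map$indel_events
}

#' Classify V-gene mutations as synonymous or non-synonymous
#'
#' Every fully aligned codon (three consecutive matched positions, read
#' positions contiguous) is compared to its germline codon. A changed codon
#' counts as one non-synonymous event when the translated amino acids
#' differ, else one synonymous event; multi-nucleotide changes within one
#' codon are a single event. Rates are per compared codon; the Ka/Ks ratio
#' is defined only when Ks > 0.
#'
#' @param read_seq the read (nucleotides).
#' @param germline_seq the germline V sequence (frame starts at 0).
#' @param v_map alignment map (`germ`, `read` matched coordinate vectors).
#' @return list: `ka`, `ks` (event counts), `ka_per_codon`, `ks_per_codon`,
#'   `ka_ks_ratio` (`NA` when undefined), `codons_compared`.
#' @export
ka_ks <- function(read_seq, germline_seq, v_map) {
  germ <- v_map$germ; read <- v_map$read
  n_codons <- nchar(germline_seq) %/% 3L
  ka <- 0L; ks <- 0L; compared <- 0L
  for (c0 in seq_len(n_codons) - 1L) {
    gpos <- 3L * c0 + 0:2
    idx <- match(gpos, germ)
    if (anyNA(idx)) next
    rpos <- read[idx]
    if (rpos[2] != rpos[1] + 1L || rpos[3] != rpos[2] + 1L) next
    compared <- compared + 1L
    gcodon <- substr0(germline_seq, gpos[1], gpos[1] + 3L)
    rcodon <- substr0(read_seq, rpos[1], rpos[1] + 3L)
    if (gcodon != rcodon) {
      if (translate_nt(gcodon) == translate_nt(rcodon)) ks <- ks + 1L
      else ka <- ka + 1L
    }
  }
  if (compared == 0L)
    return(list(ka = 0L, ks = 0L, ka_per_codon = NA_real_,
                ks_per_codon = NA_real_, ka_ks_ratio = NA_real_,
                codons_compared = 0L, empty = TRUE))
  list(ka = ka, ks = ks,
       ka_per_codon = ka / compared, ks_per_codon = ks / compared,
       ka_ks_ratio = if (ks > 0L) ka / ks else NA_real_,
       codons_compared = compared, empty = FALSE)
}

#' Mutation profiles for a set of annotated reads
#'
#' One profile per unique amino-acid sequence (the representative read's V
#' alignment). Undefined Ka/Ks ratios are reported as `NA` and are simply
#' absent from ratio summaries.
#'
#' @param ann annotated reads from [annotate_reads()].
#' @param germlines the [germline_set] used for annotation.
#' @return data.frame with `aa_sequence`, `total_mutations`,
#'   `ka_per_codon`, `ks_per_codon`, `ka_ks_ratio`, `codons_compared`.
#' @export
mutation_profiles <- function(ann, germlines) {
  idx <- !duplicated(ann$aa_sequence)
  rows <- lapply(which(idx), function(i) {
    g <- germlines$genes
    germ_seq <- g$sequence[g$allele_name == ann$v_allele[i]][1L]
    kk <- ka_ks(ann$sequence[i], germ_seq, ann$v_map[[i]])
    data.frame(aa_sequence = ann$aa_sequence[i],
               total_mutations = count_shm(ann$v_map[[i]]),
               ka_per_codon = kk$ka_per_codon,
               ks_per_codon = kk$ks_per_codon,
               ka_ks_ratio = kk$ka_ks_ratio,
               codons_compared = kk$codons_compared,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows) %||% data.frame()
}

#' Somatic hypermutation histogram
#'
#' Bins are integer mutation counts, one vote per unique amino-acid
#' sequence.
#'
#' @param records an `annotation_records` table (with `v_mutations`).
#' @return a [usage_table()] over mutation counts.
#' @export
shm_histogram <- function(records) {
  usage_table(as.character(records$v_mutations))
}

#' CDR3 length distribution (amino acids)
#' @param records an `annotation_records` table.
#' @return a [usage_table()] over CDR3 amino-acid lengths.
#' @export
cdr3_length_distribution <- function(records) {
  ok <- nzchar(records$cdr3_aa)
  usage_table(as.character(nchar(records$cdr3_aa[ok])))
}

#' Subgroup usage for one gene class
#'
#' Frequencies of unique amino-acid sequences per family-level subgroup
#' (one vote per record, not per read).
#'
#' @param records an `annotation_records` table.
#' @param gene_class `"V"`, `"D"` or `"J"`.
#' @return a [usage_table()] over subgroups.
#' @export
subgroup_usage <- function(records, gene_class = c("V", "D", "J")) {
  gene_class <- match.arg(gene_class)
  col <- c(V = "v_subgroup", D = "d_subgroup", J = "j_subgroup")[[gene_class]]
  labels <- records[[col]]
  labels <- labels[!is.na(labels) & labels != "none"]
  usage_table(labels)
}

#' V(D)J combination usage
#'
#' Frequencies of subgroup combinations: V-J pairs and V-D-J triples
#' (missing D reported as `"none"` in the triple table).
#'
#' @param records an `annotation_records` table.
#' @return list of two [usage_table()]s: `vj` and `vdj`.
#' @export
vdj_combination_usage <- function(records) {
  if (nrow(records) == 0L)
    return(list(vj = usage_table(character(0)),
                vdj = usage_table(character(0))))
  list(vj = usage_table(paste(records$v_subgroup, records$j_subgroup,
                              sep = "|")),
       vdj = usage_table(paste(records$v_subgroup, records$d_subgroup,
                               records$j_subgroup, sep = "|")))
}

#' Isotype distribution
#' @param records an `annotation_records` table.
#' @return a [usage_table()] over isotype labels.
#' @export
isotype_distribution <- function(records) {
  usage_table(records$isotype)
}

#' Write a usage table as TSV
#' @param tab a [usage_table()].
#' @param path output path.
#' @export
write_usage_table <- function(tab, path) {
  utils::write.table(as.data.frame(tab), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
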