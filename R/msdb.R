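# Proteomics-ready exports. Variable-region amino-acid sequences are
# truncated at the framework-4 anchor and a proteolytic cleavage-site
# suffix is appended (human default ASTK, mouse default AK, introducing a
# trypsin cleavage site at the C terminus), so the resulting FASTA can be
# used to interpret LC-MS/MS spectra of serum antibodies. A companion file
# maps every amino-acid sequence to its supporting nucleotide variants and
# their original FASTQ read indices.

#' Cleavage-suffix rule
#'
#' @param species `"human"` or `"mouse"`; sets the default suffix (ASTK /
#'   AK) unless `default_suffix` is given.
#' @param default_suffix suffix appended when no isotype override applies
#'   (may be empty).
#' @param isotype_overrides named character vector, isotype label ->
#'   suffix.
#' @return a `cleavage_rule` list.
#' @export
cleavage_rule <- function(species = c("human", "mouse"),
                          default_suffix = NULL,
                          isotype_overrides = character(0)) {
  species <- match.arg(species)
  default_suffix <- default_suffix %||%
    c(human = "ASTK", mouse = "AK")[[species]]
  if (grepl("[^A-Z]", default_suffix) && nzchar(default_suffix))
    stop("suffix must be uppercase amino-acid letters")
  structure(list(species = species, default_suffix = default_suffix,
                 isotype_overrides = isotype_overrides),
            class = "cleavage_rule")
}

#' Truncate at the FR4 anchor and append the cleavage suffix
#'
#' Each heavy-chain record is truncated at the end of its framework-4
#' anchor (removing the constant-region fingerprint residues) and the
#' per-isotype override, or else the default suffix, is appended. Records
#' without a locatable anchor are emitted unmodified with a warning. Set
#' `truncate = FALSE` to append to the full sequence instead.
#'
#' @param records an `annotation_records` table.
#' @param rule a [cleavage_rule()].
#' @param table an [isotype_table()] matching the rule's species.
#' @param truncate drop residues beyond the anchor before suffixing
#'   (default TRUE).
#' @return `records` with an added `ms_aa` column.
#' @export
append_cleavage_suffix <- function(records, rule,
                                   table = isotype_table(rule$species),
                                   truncate = TRUE) {
  n <- nrow(records)
  ms <- character(n)
  n_unanchored <- 0L
  for (i in seq_len(n)) {
    aa <- records$aa_sequence[i]
    end0 <- locate_fr4_anchor(aa, table)
    iso <- records$isotype[i]
    sfx <- if (iso %in% names(rule$isotype_overrides))
      rule$isotype_overrides[[iso]] else rule$default_suffix
    if (is.na(end0)) {
      n_unanchored <- n_unanchored + 1L
      ms[i] <- aa
    } else {
      base <- if (truncate) substr0(aa, 0L, end0) else aa
      ms[i] <- paste0(base, sfx)
    }
  }
  if (n_unanchored > 0L)
    warning(n_unanchored, " record(s) without an FR4 anchor left unsuffixed")
  records$ms_aa <- ms
  records
}

#' Write the MS-ready FASTA for one chain
#'
#' Headers carry chain, isotype, CDR3, subgroups and the record count.
#'
#' @param records result of [append_cleavage_suffix()] (needs `ms_aa`).
#' @param path output FASTA path (paper-style names use underscores, e.g.
#'   `V_H_AA_sequences.fasta`).
#' @export
write_ms_fasta <- function(records, path) {
  if (nrow(records) == 0L) { file.create(path); return(invisible(path)) }
  hdr <- paste0(records$chain, "|", records$isotype,
                "|cdr3=", records$cdr3_aa, "|v=", records$v_subgroup,
                "|d=", records$d_subgroup, "|j=", records$j_subgroup,
                "|counts=", records$count)
  x <- Biostrings::AAStringSet(records$ms_aa)
  names(x) <- hdr
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

#' Write the amino-acid to DNA mapping file
#'
#' FASTA-like: each header is the variable-region amino-acid sequence; the
#' entries under it are the supporting nucleotide variants, each annotated
#' with the comma-separated 0-based indices of its originating FASTQ reads.
#' Every retained read index appears exactly once across the file.
#'
#' @param records an `annotation_records` table (uses the `members`
#'   list-column).
#' @param path output path (analogue of `V_H_AA_TO_DNA_reads.fasta`).
#' @export
aa_to_dna_map <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    writeLines(paste0(">", records$aa_sequence[i]), con)
    m <- records$members[[i]]
    for (k in seq_len(nrow(m))) {
      writeLines(paste0(m$nt[k], "\t",
                        paste(m$read_indices[[k]], collapse = ",")), con)
    }
  }
  invisible(path)
}
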