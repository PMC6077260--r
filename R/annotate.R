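# V(D)J annotation: germline gene assignment by fit alignment (the whole
# germline aligned within the read), CDR3 delineation via the germline
# cdr3_anchor metadata mapped through the alignment, ORF translation, and
# grouping into per-chain annotation records. An AIRR-style rearrangement
# TSV can be ingested instead, so any external annotator can stand in for
# the built-in one.

.cache <- new.env(parent = emptyenv())

dna_subst <- function() {
  # match +2 / mismatch -2; gap open 6, extend 1 (penalties)
  if (is.null(.cache$dna_subst))
    .cache$dna_subst <- Biostrings::nucleotideSubstitutionMatrix(
      match = 2, mismatch = -2, baseOnly = TRUE)
  .cache$dna_subst
}

chain_label <- function(chain) {
  c(IGH = "VH", IGK = "Vκ", IGL = "Vλ")[[chain]]
}

# Matched-coordinate map of a pairwise alignment (pattern = germline,
# subject = read), 0-based. Also counts mismatches and indel events.
alignment_map <- function(pa, i = 1L, read_offset = 0L) {
  gp <- strsplit(as.character(Biostrings::pattern(pa[i])), "")[[1]]
  gs <- strsplit(as.character(Biostrings::subject(pa[i])), "")[[1]]
  g <- Biostrings::start(Biostrings::pattern(pa))[i] - 1L
  r <- Biostrings::start(Biostrings::subject(pa))[i] - 1L + read_offset
  germ <- integer(0); read <- integer(0); mm <- 0L
  gpos <- g; rpos <- r
  for (k in seq_along(gp)) {
    pg <- gp[k] != "-"; ps <- gs[k] != "-"
    if (pg && ps) {
      germ <- c(germ, gpos); read <- c(read, rpos)
      if (gp[k] != gs[k]) mm <- mm + 1L
    }
    if (pg) gpos <- gpos + 1L
    if (ps) rpos <- rpos + 1L
  }
  gaps <- rle(paste0(as.integer(gp == "-"), as.integer(gs == "-")))
  indel_events <- sum(gaps$values %in% c("10", "01"))
  list(germ = germ, read = read, mismatches = mm,
       indel_events = indel_events,
       mutations = mm + indel_events,
       read_span = c(min(read), max(read) + 1L))
}

# Fit-align every candidate germline against the read (global in the
# germline, local in the read); choose by score, then fewer mutations, then
# lexicographically smaller allele name.
best_gene_call <- function(read_sub, genes, read_offset = 0L) {
  if (nrow(genes) == 0L || !nzchar(read_sub)) return(NULL)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(genes$sequence),
    Biostrings::DNAString(read_sub),
    type = "global-local", substitutionMatrix = dna_subst(),
    gapOpening = 6, gapExtension = 1)
  sc <- Biostrings::score(pa)
  cand <- which(sc == max(sc))
  if (length(cand) > 1L) {
    muts <- vapply(cand, function(i) alignment_map(pa, i)$mutations,
                   integer(1))
    cand <- cand[muts == min(muts)]
    if (length(cand) > 1L)
      cand <- cand[order(genes$allele_name[cand], method = "radix")]
  }
  i <- cand[1L]
  m <- alignment_map(pa, i, read_offset)
  list(allele_name = genes$allele_name[i], subgroup = genes$subgroup[i],
       cdr3_anchor = genes$cdr3_anchor[i], score = sc[i],
       mutations = m$mutations, mismatches = m$mismatches,
       map = m, read_span = m$read_span)
}

#' Assign V and J germline genes to a merged read
#'
#' The V call is the highest-scoring fit alignment of a whole germline V
#' gene within the read (match +2, mismatch -2, gap open -6, gap extend -1);
#' the J call is found the same way on the read suffix right of the V span.
#' The reading frame is the V gene's frame start mapped onto the read.
#' Tie-breaks are deterministic: higher score, then fewer mutations, then
#' lexicographically smaller allele name.
#'
#' @param sequence merged read (nucleotides).
#' @param germlines a [germline_set].
#' @param chain `"IGH"`, `"IGK"` or `"IGL"`.
#' @param min_v_score score floor below which the read is unannotatable
#'   (default 50).
#' @return list with `v`, `j` gene calls and `frame` (0-based ORF offset in
#'   the read), or `NULL` when the best V score is below the floor.
#' @export
assign_v_j <- function(sequence, germlines, chain = "IGH",
                       min_v_score = 50) {
  v <- best_gene_call(sequence, genes_of(germlines, chain, "V"))
  if (is.null(v) || v$score < min_v_score) return(NULL)
  v_end <- v$read_span[2L]
  jgenes <- genes_of(germlines, chain, "J")
  suffix <- substr0(sequence, v_end, nchar(sequence))
  j <- best_gene_call(suffix, jgenes, read_offset = v_end)
  if (is.null(j)) return(NULL)
  first <- 1L
  frame_raw <- v$map$read[first] - v$map$germ[first]
  frame <- if (frame_raw >= 0L) frame_raw else frame_raw %% 3L
  list(v = v, j = j, frame = as.integer(frame))
}

#' Assign a D gene by longest exact junction match
#'
#' @param junction_nt junction nucleotides between the V and J read spans.
#' @param germlines a [germline_set].
#' @param chain chain whose D genes to search (default IGH).
#' @param min_d_match minimum exact match length in nt (default 5).
#' @return list with `allele_name`, `subgroup`, `match_length`, or `NULL`
#'   when no D gene matches at least `min_d_match` nt (ties broken by
#'   allele name).
#' @export
assign_d <- function(junction_nt, germlines, chain = "IGH",
                     min_d_match = 5L) {
  dgenes <- genes_of(germlines, chain, "D")
  n <- nchar(junction_nt)
  if (nrow(dgenes) == 0L || n < min_d_match) return(NULL)
  maxL <- min(n, max(nchar(dgenes$sequence)))
  for (L in seq(maxL, min_d_match)) {
    subs <- unique(substring(junction_nt, 1:(n - L + 1L), L:n))
    hit <- vapply(dgenes$sequence, function(d)
      any(vapply(subs, grepl, logical(1), x = d, fixed = TRUE)),
      logical(1))
    if (any(hit)) {
      i <- which(hit)[order(dgenes$allele_name[hit], method = "radix")][1L]
      return(list(allele_name = dgenes$allele_name[i],
                  subgroup = dgenes$subgroup[i], match_length = L))
    }
  }
  NULL
}

# read coordinate (0-based) mapped from a germline coordinate, NA when the
# position is not covered by a matched alignment pair
map_germ_to_read <- function(map, germ_pos) {
  i <- match(germ_pos, map$germ)
  if (is.na(i)) NA_integer_ else map$read[i]
}

#' Delineate variable-region regions on a read
#'
#' CDR3 spans from the read position mapped from the V gene's `cdr3_anchor`
#' through the position mapped from the J gene's `cdr3_anchor` (exclusive);
#' FR4 runs from there to the end of the J span. Coordinates are 0-based,
#' half-open.
#'
#' @param calls result of [assign_v_j()].
#' @param read_len length of the read.
#' @return list of `c(start, end)` offsets per region (`fr_upstream`,
#'   `cdr3`, `fr4`), or `NULL` when an anchor is not covered by its
#'   alignment (the record is CDR3-undefined).
#' @export
delineate_regions <- function(calls, read_len) {
  cdr3_start <- map_germ_to_read(calls$v$map, calls$v$cdr3_anchor)
  cdr3_end <- map_germ_to_read(calls$j$map, calls$j$cdr3_anchor)
  if (is.na(cdr3_start) || is.na(cdr3_end) || cdr3_end <= cdr3_start)
    return(NULL)
  if ((cdr3_start - calls$frame) %% 3L != 0L ||
      (cdr3_end - cdr3_start) %% 3L != 0L)
    return(NULL)
  list(fr_upstream = c(calls$frame, cdr3_start),
       cdr3 = c(cdr3_start, cdr3_end),
       fr4 = c(cdr3_end, min(calls$j$read_span[2L], read_len)))
}

#' Annotate a table of merged reads
#'
#' Runs V/J assignment, D assignment (heavy chain), region delineation and
#' ORF translation for every merged read. Distinct sequences are annotated
#' once and results reused. Reads that cannot be annotated (V score below
#' floor) or whose CDR3 anchors are not covered are excluded and counted in
#' the attached log.
#'
#' @param merged data.frame of merged reads (`sequence`, `quality`,
#'   `read_indices`, `count`).
#' @param germlines a [germline_set].
#' @param chain `"IGH"`, `"IGK"` or `"IGL"`.
#' @param min_v_score V score floor (see [assign_v_j()]).
#' @param min_d_match D match threshold (see [assign_d()]).
#' @return data.frame of per-read annotations with attribute `log` (named
#'   counts: `n_unannotatable`, `n_cdr3_undefined`).
#' @export
annotate_reads <- function(merged, germlines, chain = "IGH",
                           min_v_score = 50, min_d_match = 5L) {
  uniq <- unique(merged$sequence)
  ann <- lapply(uniq, function(s) {
    calls <- assign_v_j(s, germlines, chain, min_v_score)
    if (is.null(calls)) return(list(status = "unannotatable"))
    regions <- delineate_regions(calls, nchar(s))
    if (is.null(regions)) return(list(status = "cdr3_undefined"))
    junction <- substr0(s, calls$v$read_span[2L], calls$j$read_span[1L])
    d <- assign_d(junction, germlines, chain, min_d_match)
    frame <- calls$frame
    nt_trimmed <- substr0(s, frame,
                          nchar(s) - (nchar(s) - frame) %% 3L)
    aa <- translate_nt(nt_trimmed)
    cdr3_nt <- substr0(s, regions$cdr3[1L], regions$cdr3[2L])
    list(status = "ok", calls = calls, regions = regions, d = d,
         nt_trimmed = nt_trimmed, aa = aa,
         cdr3_aa = translate_nt(cdr3_nt))
  })
  names(ann) <- uniq
  status <- vapply(merged$sequence, function(s) ann[[s]]$status,
                   character(1))
  keep <- status == "ok"
  out <- merged[keep, , drop = FALSE]
  a <- ann[out$sequence]
  out$chain <- if (nrow(out)) chain_label(chain) else character(0)
  out$v_allele <- vapply(a, function(x) x$calls$v$allele_name, character(1))
  out$v_subgroup <- vapply(a, function(x) x$calls$v$subgroup, character(1))
  out$v_mutations <- vapply(a, function(x) x$calls$v$mutations, integer(1))
  out$d_subgroup <- vapply(a, function(x)
    if (is.null(x$d)) "none" else x$d$subgroup, character(1))
  out$j_allele <- vapply(a, function(x) x$calls$j$allele_name, character(1))
  out$j_subgroup <- vapply(a, function(x) x$calls$j$subgroup, character(1))
  out$j_mutations <- vapply(a, function(x) x$calls$j$mutations, integer(1))
  out$frame <- vapply(a, function(x) x$calls$frame, integer(1))
  out$nt_trimmed <- vapply(a, function(x) x$nt_trimmed, character(1))
  out$aa_sequence <- vapply(a, function(x) x$aa, character(1))
  out$cdr3_aa <- vapply(a, function(x) x$cdr3_aa, character(1))
  out$has_stop <- has_stop(out$aa_sequence)
  out$v_map <- lapply(a, function(x) x$calls$v$map)
  rownames(out) <- NULL
  attr(out, "log") <- c(n_unannotatable = sum(status == "unannotatable"),
                        n_cdr3_undefined = sum(status == "cdr3_undefined"))
  out
}

#' Group annotated reads into unique amino-acid-sequence records
#'
#' Records are grouped by (chain, isotype, amino-acid sequence); counts are
#' summed. The representative nucleotide sequence is the most frequent
#' variant (ties: lexicographic); conflicting subgroup calls are resolved by
#' plurality over read counts (ties: lexicographic). Each record keeps its
#' member nucleotide variants with their originating read indices.
#'
#' @param ann annotated reads from [annotate_reads()], with an `isotype`
#'   column (see [assign_isotypes()]).
#' @return data.frame of class `annotation_records`: the nine-field record
#'   (`chain`, `isotype`, `nt_sequence`, `aa_sequence`, `cdr3_aa`,
#'   `v_subgroup`, `d_subgroup`, `j_subgroup`, `count`) plus bookkeeping
#'   columns (`v_allele`, `j_allele`, `v_mutations`, `members` list-column).
#' @export
build_annotation_records <- function(ann) {
  if (!"isotype" %in% names(ann)) ann$isotype <- "none"
  if (nrow(ann) == 0L) return(empty_records())
  key <- paste(ann$chain, ann$isotype, ann$aa_sequence, sep = "\r")
  plurality <- function(vals, w) {
    s <- rowsum(w, vals)
    top <- rownames(s)[s[, 1] == max(s[, 1])]
    lex_first(top)
  }
  rows <- lapply(split(seq_len(nrow(ann)), key), function(idx) {
    g <- ann[idx, , drop = FALSE]
    vars <- rowsum(g$count, g$nt_trimmed)
    top_nt <- rownames(vars)[vars[, 1] == max(vars[, 1])]
    rep_nt <- lex_first(top_nt)
    rep_row <- which(g$nt_trimmed == rep_nt)[1L]
    members <- data.frame(nt = rownames(vars),
                          count = as.integer(vars[, 1]),
                          stringsAsFactors = FALSE)
    members$read_indices <- lapply(members$nt, function(v)
      sort(unlist(g$read_indices[g$nt_trimmed == v])))
    r <- data.frame(
      chain = g$chain[1L], isotype = g$isotype[1L],
      nt_sequence = rep_nt, aa_sequence = g$aa_sequence[1L],
      cdr3_aa = plurality(g$cdr3_aa, g$count),
      v_subgroup = plurality(g$v_subgroup, g$count),
      d_subgroup = plurality(g$d_subgroup, g$count),
      j_subgroup = plurality(g$j_subgroup, g$count),
      count = sum(g$count),
      v_allele = plurality(g$v_allele, g$count),
      j_allele = plurality(g$j_allele, g$count),
      v_mutations = g$v_mutations[rep_row],
      stringsAsFactors = FALSE)
    r$members <- list(members)
    r
  })
  rec <- do.call(rbind, rows)
  rec <- rec[order(-rec$count, rec$aa_sequence, method = "radix"), ]
  rownames(rec) <- NULL
  class(rec) <- c("annotation_records", "data.frame")
  rec
}

empty_records <- function() {
  r <- data.frame(chain = character(0), isotype = character(0),
                  nt_sequence = character(0), aa_sequence = character(0),
                  cdr3_aa = character(0), v_subgroup = character(0),
                  d_subgroup = character(0), j_subgroup = character(0),
                  count = integer(0), v_allele = character(0),
                  j_allele = character(0), v_mutations = integer(0),
                  stringsAsFactors = FALSE)
  r$members <- list()
  class(r) <- c("annotation_records", "data.frame")
  r
}

#' Write the nine-column annotation TSV for one chain
#' @param records an `annotation_records` table.
#' @param path output path (e.g. `IGH_aa_sequence_annotations.tsv`).
#' @export
write_annotation_tsv <- function(records, path) {
  cols <- c("chain", "isotype", "nt_sequence", "aa_sequence", "cdr3_aa",
            "v_subgroup", "d_subgroup", "j_subgroup", "count")
  utils::write.table(as.data.frame(records)[cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Ingest a pre-annotated AIRR-style rearrangement table
#'
#' Alternative entry point replacing the built-in annotator. Mandatory
#' columns: `sequence`, `v_call`, `d_call`, `j_call`, `junction_aa`;
#' `sequence_aa` is translated from `sequence` when absent and
#' `duplicate_count` defaults to 1. Rows with stop codons in the amino-acid
#' sequence, or whose junction is not a substring of it, are dropped and
#' counted in the attached log.
#'
#' @param path path to the TSV.
#' @return an `annotation_records` table (attribute `log`: `n_dropped`).
#' @export
ingest_airr <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  mandatory <- c("sequence", "v_call", "d_call", "j_call", "junction_aa")
  miss <- setdiff(mandatory, names(tab))
  if (length(miss))
    stop("AIRR table lacks mandatory columns: ", paste(miss, collapse = ", "))
  if (!"sequence_aa" %in% names(tab))
    tab$sequence_aa <- translate_nt(tab$sequence)
  if (!"duplicate_count" %in% names(tab)) tab$duplicate_count <- 1L
  tab$duplicate_count[is.na(tab$duplicate_count)] <- 1L
  locus <- substr(tab$v_call, 1L, 3L)
  ok <- locus %in% c("IGH", "IGK", "IGL") & nzchar(tab$sequence_aa) &
    !has_stop(tab$sequence_aa) &
    mapply(grepl, tab$junction_aa, tab$sequence_aa,
           MoreArgs = list(fixed = TRUE))
  n_dropped <- sum(!ok)
  tab <- tab[ok, , drop = FALSE]
  if (nrow(tab) == 0L) {
    out <- empty_records()
    attr(out, "log") <- c(n_dropped = n_dropped)
    return(out)
  }
  ann <- data.frame(
    chain = vapply(substr(tab$v_call, 1L, 3L), chain_label, character(1)),
    isotype = if ("c_call" %in% names(tab)) tab$c_call else "unknown",
    nt_trimmed = tab$sequence,
    aa_sequence = tab$sequence_aa,
    cdr3_aa = tab$junction_aa,
    v_subgroup = subgroup_of(tab$v_call),
    d_subgroup = local({
      d <- rep("none", nrow(tab))
      idx <- !is.na(tab$d_call) & nzchar(tab$d_call)
      if (any(idx)) d[idx] <- subgroup_of(tab$d_call[idx])
      d
    }),
    j_subgroup = subgroup_of(tab$j_call),
    count = as.integer(tab$duplicate_count),
    v_allele = tab$v_call, j_allele = tab$j_call,
    v_mutations = if ("v_mutations" %in% names(tab))
      as.integer(tab$v_mutations) else 0L,
    stringsAsFactors = FALSE)
  ann$read_indices <- as.list(seq_len(nrow(ann)) - 1L)
  out <- build_annotation_records(ann)
  attr(out, "log") <- c(n_dropped = n_dropped)
  out
}
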