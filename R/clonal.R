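# Clonal analysis. A clone is the set of variable-region sequences sharing
# an identical CDRH3 amino-acid sequence. y = reads associated with the
# clone; x = unique amino-acid sequences within it (x <= y). Per-clone
# outputs: center-star multiple sequence alignment, column-plurality
# consensus, the member most similar to the consensus, and a position x
# residue logo frequency matrix.

#' Cluster annotation records into clones by identical CDR3
#'
#' @param records an `annotation_records` table; rows without a CDR3 are
#'   excluded (their number is attached as attribute `n_no_cdr3`).
#' @param heavy_only cluster only heavy-chain (VH) records (default TRUE;
#'   light chains can be clustered symmetrically by their CDR3).
#' @return data.frame of class `clone_set`: `cdrh3_aa`, `y` (reads), `x`
#'   (unique amino-acid sequences), and a `members` list-column
#'   (data.frames with `aa_sequence`, `count`, `nt_sequence`).
#' @export
cluster_clones <- function(records, heavy_only = TRUE) {
  rec <- as.data.frame(records)
  if (heavy_only && nrow(rec)) rec <- rec[rec$chain == "VH", , drop = FALSE]
  ok <- nzchar(rec$cdr3_aa) & !is.na(rec$cdr3_aa)
  n_no_cdr3 <- sum(!ok)
  rec <- rec[ok, , drop = FALSE]
  if (nrow(rec) == 0L) {
    out <- data.frame(cdrh3_aa = character(0), y = integer(0),
                      x = integer(0))
    out$members <- list()
    class(out) <- c("clone_set", "data.frame")
    attr(out, "n_no_cdr3") <- n_no_cdr3
    return(out)
  }
  rows <- lapply(split(seq_len(nrow(rec)), rec$cdr3_aa), function(idx) {
    g <- rec[idx, , drop = FALSE]
    r <- data.frame(cdrh3_aa = g$cdr3_aa[1L], y = sum(g$count),
                    x = nrow(g), stringsAsFactors = FALSE)
    r$members <- list(data.frame(aa_sequence = g$aa_sequence,
                                 count = g$count,
                                 nt_sequence = g$nt_sequence,
                                 stringsAsFactors = FALSE))
    r
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  stopifnot(all(out$x <= out$y))
  class(out) <- c("clone_set", "data.frame")
  attr(out, "n_no_cdr3") <- n_no_cdr3
  out
}

#' Top clones by read support
#'
#' Sorted by `y` descending, ties by `x` descending, then lexicographic
#' CDRH3; truncated at `k`.
#'
#' @param clones a `clone_set`.
#' @param k number of clones to report (default 100).
#' @return the ranked, truncated `clone_set`.
#' @export
top_k_clones <- function(clones, k = 100L) {
  ord <- order(-clones$y, -clones$x, clones$cdrh3_aa, method = "radix")
  out <- clones[ord[seq_len(min(k, nrow(clones)))], , drop = FALSE]
  rownames(out) <- NULL
  out
}

aa_align <- function(a, b) {
  Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 1)
}

# gap counts inserted before each center position (length n_center + 1)
gap_slots <- function(center_gapped, n_center) {
  runs <- rle(strsplit(center_gapped, "")[[1]] == "-")
  slots <- integer(n_center + 1L)
  pos <- 1L
  for (i in seq_along(runs$lengths)) {
    if (runs$values[i]) slots[pos] <- slots[pos] + runs$lengths[i]
    else pos <- pos + runs$lengths[i]
  }
  slots
}

# rebuild one aligned row under the master gap-slot pattern
lift_row <- function(row_gapped, own_slots, master_slots, n_center) {
  chars <- strsplit(row_gapped, "")[[1]]
  out <- character(0)
  p <- 1L
  for (k in seq_len(n_center + 1L)) {
    if (own_slots[k] > 0L) {
      out <- c(out, chars[p:(p + own_slots[k] - 1L)])
      p <- p + own_slots[k]
    }
    extra <- master_slots[k] - own_slots[k]
    if (extra > 0L) out <- c(out, rep("-", extra))
    if (k <= n_center) { out <- c(out, chars[p]); p <- p + 1L }
  }
  paste(out, collapse = "")
}

#' Center-star multiple sequence alignment of clone members
#'
#' The center is the member with the highest read count (ties: longest,
#' then lexicographic). Every other member is aligned pairwise to the
#' center by global alignment (BLOSUM62, gap open -10, extend -1) and the
#' pairwise alignments are merged under the once-a-gap-always-a-gap rule.
#'
#' @param members data.frame with `aa_sequence` and `count` (one clone's
#'   members, e.g. from [cluster_clones()]).
#' @return character vector of gap-aligned rows, in member order.
#' @export
align_clone_members <- function(members) {
  n <- nrow(members)
  if (n == 1L) return(members$aa_sequence)
  ord <- order(-members$count, -nchar(members$aa_sequence),
               members$aa_sequence, method = "radix")
  ci <- ord[1L]
  center <- members$aa_sequence[ci]
  nc <- nchar(center)
  others <- setdiff(seq_len(n), ci)
  pals <- lapply(others, function(i) {
    pa <- aa_align(center, members$aa_sequence[i])
    list(center = as.character(Biostrings::pattern(pa)),
         member = as.character(Biostrings::subject(pa)))
  })
  own <- lapply(pals, function(p) gap_slots(p$center, nc))
  master <- Reduce(pmax, own, integer(nc + 1L))
  rows <- character(n)
  rows[ci] <- lift_row(center, integer(nc + 1L), master, nc)
  for (k in seq_along(others))
    rows[others[k]] <- lift_row(pals[[k]]$member, own[[k]], master, nc)
  stopifnot(length(unique(nchar(rows))) == 1L)
  rows
}

msa_matrix <- function(msa) do.call(rbind, strsplit(msa, ""))

#' Column-plurality consensus of an MSA
#'
#' Per column, the plurality residue (ties: alphabetical); columns whose
#' plurality symbol is a gap are dropped.
#'
#' @param msa character vector of gap-aligned rows.
#' @return consensus amino-acid string.
#' @export
clone_consensus <- function(msa) {
  if (length(msa) == 1L) return(gsub("-", "", msa, fixed = TRUE))
  m <- msa_matrix(msa)
  cons <- apply(m, 2L, function(col) {
    tab <- table(col)
    res <- tab[names(tab) != "-"]
    gapn <- if ("-" %in% names(tab)) tab[["-"]] else 0L
    if (length(res) == 0L || gapn > max(res)) return("")
    lex_first(names(res)[res == max(res)])
  })
  paste(cons, collapse = "")
}

#' Clone member most similar to the consensus
#'
#' Similarity is the fraction of identical positions over the global
#' alignment length of member vs consensus. Ties go to the higher-count
#' member, then lexicographic.
#'
#' @param members one clone's member data.frame (`aa_sequence`, `count`,
#'   `nt_sequence`).
#' @param consensus consensus string from [clone_consensus()].
#' @return list: `representative_aa`, `similarity`, `representative_nt`.
#' @export
most_similar_member <- function(members, consensus) {
  sim <- vapply(members$aa_sequence, function(a) {
    if (a == consensus) return(1.0)
    pa <- aa_align(a, consensus)
    x <- strsplit(as.character(Biostrings::pattern(pa)), "")[[1]]
    y <- strsplit(as.character(Biostrings::subject(pa)), "")[[1]]
    sum(x == y) / length(x)
  }, numeric(1))
  ord <- order(-sim, -members$count, members$aa_sequence, method = "radix")
  i <- ord[1L]
  list(representative_aa = members$aa_sequence[i],
       similarity = unname(sim[i]),
       representative_nt = members$nt_sequence[i])
}

#' Position-by-residue logo frequency matrix of a clone MSA
#'
#' Per column, the frequency of each residue among non-gap symbols, with
#' rows weighted by member read counts (set `weights = NULL` for the
#' unweighted variant). Columns whose (weighted) plurality symbol is a gap
#' are dropped, as in the consensus.
#'
#' @param msa character vector of gap-aligned rows.
#' @param weights member read counts aligned with `msa` rows (default
#'   unweighted).
#' @return data.frame with `position` (1-based column after gap dropping),
#'   `residue`, `frequency`.
#' @export
sequence_logo_matrix <- function(msa, weights = NULL) {
  m <- msa_matrix(msa)
  w <- weights %||% rep(1, length(msa))
  out <- list(); pos <- 0L
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    tot <- rowsum(w, col)
    res <- tot[rownames(tot) != "-", , drop = FALSE]
    gapw <- if ("-" %in% rownames(tot)) tot["-", 1L] else 0
    if (nrow(res) == 0L || gapw > max(res[, 1L])) next
    pos <- pos + 1L
    out[[pos]] <- data.frame(position = pos, residue = rownames(res),
                             frequency = res[, 1L] / sum(res[, 1L]),
                             stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(position = integer(0), residue = character(0),
                      frequency = numeric(0)))
  r <- do.call(rbind, out)
  rownames(r) <- NULL
  r
}

#' Summarize clones with the seven-field clone report
#'
#' For each of the top `k` clones computes the member MSA, consensus,
#' most-similar member and similarity, yielding the clone file fields:
#' CDRH3, y, x, consensus, representative amino-acid sequence, similarity
#' score, and the representative's DNA sequence.
#'
#' @param clones a `clone_set`.
#' @param k how many top clones to report (default 100).
#' @return data.frame with one row per reported clone.
#' @export
clone_summary <- function(clones, k = 100L) {
  top <- top_k_clones(clones, k)
  rows <- lapply(seq_len(nrow(top)), function(i) {
    mem <- top$members[[i]]
    msa <- align_clone_members(mem)
    cons <- clone_consensus(msa)
    best <- most_similar_member(mem, cons)
    data.frame(cdrh3_aa = top$cdrh3_aa[i], y = top$y[i], x = top$x[i],
               consensus_aa = cons,
               representative_aa = best$representative_aa,
               similarity = best$similarity,
               representative_nt = best$representative_nt,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows) %||%
    data.frame(cdrh3_aa = character(0), y = integer(0), x = integer(0),
               consensus_aa = character(0),
               representative_aa = character(0), similarity = numeric(0),
               representative_nt = character(0))
  rownames(out) <- NULL
  out
}

#' Write the clone summary TSV (seven fields)
#' @param summary result of [clone_summary()].
#' @param path output path.
#' @export
write_clone_summary <- function(summary, path) {
  utils::write.table(summary, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write clonal-expansion plot data (rank, y, x)
#' @param clones a `clone_set`.
#' @param path output path.
#' @param k number of top clones (default 100).
#' @export
write_clonal_expansion <- function(clones, path, k = 100L) {
  top <- top_k_clones(clones, k)
  utils::write.table(
    data.frame(rank = seq_len(nrow(top)), cdrh3_aa = top$cdrh3_aa,
               y = top$y, x = top$x),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
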