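# Read preprocessing: paired-end overlap merging, UMI extraction and
# consensus collapsing, and the four-criterion filter (stop codon, no
# overlap, length, quality). Overlap failures are counted at merge time and
# forwarded into the filter report; the stop-codon criterion is evaluated
# after annotation supplies the reading frame.

#' Filtering configuration
#'
#' @param min_length minimum merged-read length in nucleotides (default 300).
#' @param min_quality minimum mean Phred score of the merged read
#'   (default 20).
#' @param require_overlap paired-end mates must overlap (always enforced at
#'   merge time).
#' @param reject_stop_codons reject reads whose variable-region ORF contains
#'   a stop codon (always enforced after annotation).
#' @return A `filter_config` list.
#' @export
filter_config <- function(min_length = 300L, min_quality = 20,
                          require_overlap = TRUE, reject_stop_codons = TRUE) {
  stopifnot(min_length > 0, min_quality >= 0, min_quality <= 41)
  structure(list(min_length = as.integer(min_length),
                 min_quality = min_quality,
                 require_overlap = isTRUE(require_overlap),
                 reject_stop_codons = isTRUE(reject_stop_codons)),
            class = "filter_config")
}

#' Read a pair of FASTQ files into a read-pair table
#'
#' Phred+33 is the only accepted quality encoding.
#'
#' @param r1,r2 paths to the forward and reverse FASTQ files.
#' @return data.frame with `read_index` (0-based position in the file),
#'   `fwd_seq`, `fwd_qual`, `rev_seq`, `rev_qual`.
#' @export
read_fastq_pair <- function(r1, r2) {
  rd <- function(p) {
    x <- Biostrings::readDNAStringSet(p, format = "fastq",
                                      with.qualities = TRUE)
    list(seq = as.character(x),
         qual = as.character(S4Vectors::mcols(x)$qualities))
  }
  f <- rd(r1); r <- rd(r2)
  if (length(f$seq) != length(r$seq))
    stop("R1 and R2 have different read counts")
  data.frame(read_index = seq_along(f$seq) - 1L,
             fwd_seq = unname(f$seq), fwd_qual = unname(f$qual),
             rev_seq = unname(r$seq), rev_qual = unname(r$qual),
             stringsAsFactors = FALSE)
}

# Core overlap merge for one pair, on already reverse-complemented mate 2.
# Returns NULL when no offset satisfies the thresholds.
merge_one <- function(fwd, fq, rc, rq, min_overlap, max_mismatch_frac) {
  nf <- nchar(fwd); nr <- nchar(rc)
  if (nf == 0L || nr == 0L) stop("empty mate in read pair")
  fv <- strsplit(fwd, "")[[1]]; rv <- strsplit(rc, "")[[1]]
  fqv <- phred_decode(fq); rqv <- phred_decode(rq)
  best <- NULL
  for (d in 0:(nf - min_overlap)) {
    ov <- min(nf - d, nr)
    if (ov < min_overlap) break
    fi <- (d + 1L):(d + ov); ri <- 1:ov
    mm <- sum(fv[fi] != rv[ri])
    if (mm / ov > max_mismatch_frac) next
    score <- (ov - mm) - mm
    if (is.null(best) || score > best$score ||
        (score == best$score && ov > best$ov)) {
      best <- list(d = d, ov = ov, mm = mm, score = score)
    }
  }
  if (is.null(best)) return(NULL)
  d <- best$d; ov <- best$ov
  fi <- (d + 1L):(d + ov); ri <- 1:ov
  # overlap consensus: disagreeing positions take the higher-Phred base
  # (ties: forward mate); quality is the elementwise max
  take_rev <- fv[fi] != rv[ri] & rqv[ri] > fqv[fi]
  mid <- fv[fi]; mid[take_rev] <- rv[ri][take_rev]
  midq <- pmax(fqv[fi], rqv[ri])
  seq_out <- c(if (d > 0L) fv[1:d], mid, if (nr > ov) rv[(ov + 1L):nr])
  qual_out <- c(if (d > 0L) fqv[1:d], midq, if (nr > ov) rqv[(ov + 1L):nr])
  list(sequence = paste(seq_out, collapse = ""),
       quality = phred_encode(qual_out))
}

#' Merge one paired-end read
#'
#' The reverse mate is reverse-complemented, then all overlap offsets with
#' overlap length >= `min_overlap` are scanned; the best-scoring offset
#' (matches minus mismatches; ties broken toward the longer overlap) with
#' mismatch fraction <= `max_mismatch_frac` is merged. Disagreeing overlap
#' positions take the base with the higher Phred score (ties: the forward
#' mate); the retained quality is the elementwise maximum.
#'
#' @param fwd_seq,fwd_qual,rev_seq,rev_qual one mate pair (quality strings,
#'   Phred+33).
#' @param min_overlap minimum overlap length in nt (default 20).
#' @param max_mismatch_frac maximum fraction of mismatched overlap positions
#'   (default 0.1).
#' @return list with `sequence` and `quality`, or `NULL` when the mates do
#'   not overlap under the thresholds.
#' @export
merge_pair <- function(fwd_seq, fwd_qual, rev_seq, rev_qual,
                       min_overlap = 20L, max_mismatch_frac = 0.1) {
  if (!nzchar(fwd_seq) || !nzchar(rev_seq)) stop("empty mate in read pair")
  rc <- revcomp(rev_seq)
  rq <- paste(rev(strsplit(rev_qual, "")[[1]]), collapse = "")
  merge_one(fwd_seq, fwd_qual, rc, rq, min_overlap, max_mismatch_frac)
}

#' Merge a table of read pairs
#'
#' Identical pairs are merged once and the result reused, so runtime scales
#' with the number of distinct pairs.
#'
#' @param pairs data.frame as from [read_fastq_pair()] (optionally carrying
#'   a `umi` column from [extract_umi()]).
#' @param min_overlap,max_mismatch_frac see [merge_pair()].
#' @return list with `merged` (data.frame: `sequence`, `quality`, `umi`,
#'   `read_indices` list-column, `count`) and `n_no_overlap`.
#' @export
merge_read_pairs <- function(pairs, min_overlap = 20L,
                             max_mismatch_frac = 0.1) {
  if (nrow(pairs) == 0L)
    return(list(merged = empty_merged(), n_no_overlap = 0L))
  key <- paste(pairs$fwd_seq, pairs$fwd_qual, pairs$rev_seq, pairs$rev_qual,
               sep = "\r")
  uk <- !duplicated(key)
  cache <- new.env(parent = emptyenv())
  for (i in which(uk)) {
    assign(key[i],
           merge_pair(pairs$fwd_seq[i], pairs$fwd_qual[i],
                      pairs$rev_seq[i], pairs$rev_qual[i],
                      min_overlap, max_mismatch_frac) %||% list(),
           envir = cache)
  }
  res <- lapply(key, get, envir = cache)
  ok <- lengths(res) > 0L
  merged <- data.frame(
    sequence = vapply(res[ok], `[[`, character(1), "sequence"),
    quality = vapply(res[ok], `[[`, character(1), "quality"),
    umi = if ("umi" %in% names(pairs)) pairs$umi[ok]
          else rep(NA_character_, sum(ok)),
    stringsAsFactors = FALSE)
  merged$read_indices <- as.list(pairs$read_index[ok])
  merged$count <- rep(1L, nrow(merged))
  list(merged = merged, n_no_overlap = sum(!ok))
}

empty_merged <- function() {
  d <- data.frame(sequence = character(0), quality = character(0),
                  umi = character(0), stringsAsFactors = FALSE)
  d$read_indices <- list()
  d$count <- integer(0)
  d
}

iupac_fixed <- c("A", "C", "G", "T")

#' Extract UMIs from read pairs
#'
#' The IUPAC pattern is matched against the 5' prefix of the targeted
#' mate(s): fixed positions (A/C/G/T) must equal the read base exactly;
#' degenerate positions (N, R, Y, ...) capture the read base. Captured bases
#' concatenate forward-then-reverse when `location = "both"`. Matched
#' prefixes are trimmed. Reads failing a fixed position (or shorter than the
#' pattern) are flagged UMI-unmatched and excluded.
#'
#' @param pairs read-pair data.frame (see [read_fastq_pair()]).
#' @param pattern UMI pattern in IUPAC nucleotide code, e.g. `"NNNNN"`.
#' @param location where the UMI sits: `"forward"`, `"reverse"`, or
#'   `"both"`.
#' @return list with `pairs` (trimmed, plus a `umi` column; unmatched rows
#'   dropped) and `n_unmatched`.
#' @export
extract_umi <- function(pairs, pattern,
                        location = c("forward", "reverse", "both")) {
  location <- match.arg(location)
  if (!nzchar(pattern) || grepl("[^ACGTURYSWKMBDHVN]", pattern))
    stop("UMI pattern must be non-empty IUPAC nucleotide code")
  pv <- strsplit(pattern, "")[[1]]
  np <- length(pv)
  fixed <- pv %in% iupac_fixed
  match_prefix <- function(seqs) {
    pref <- substr(seqs, 1L, np)
    ok <- nchar(seqs) >= np
    if (any(fixed)) {
      pm <- do.call(rbind, strsplit(ifelse(ok, pref, strrep(" ", np)), ""))
      for (j in which(fixed)) ok <- ok & pm[, j] == pv[j]
    }
    list(ok = ok, umi = substr(pref, 1L, np))
  }
  use_f <- location %in% c("forward", "both")
  use_r <- location %in% c("reverse", "both")
  okf <- rep(TRUE, nrow(pairs)); okr <- rep(TRUE, nrow(pairs))
  umif <- ""; umir <- ""
  if (use_f) { mf <- match_prefix(pairs$fwd_seq); okf <- mf$ok; umif <- mf$umi }
  if (use_r) { mr <- match_prefix(pairs$rev_seq); okr <- mr$ok; umir <- mr$umi }
  ok <- okf & okr
  out <- pairs[ok, , drop = FALSE]
  if (use_f) {
    out$fwd_seq <- substring(out$fwd_seq, np + 1L)
    out$fwd_qual <- substring(out$fwd_qual, np + 1L)
  }
  if (use_r) {
    out$rev_seq <- substring(out$rev_seq, np + 1L)
    out$rev_qual <- substring(out$rev_qual, np + 1L)
  }
  out$umi <- if (nrow(out) == 0L) character(0) else
    paste0(if (use_f) umif[ok] else "", if (use_r) umir[ok] else "")
  rownames(out) <- NULL
  list(pairs = out, n_unmatched = sum(!ok))
}

# Per-column majority vote over equal-length sequences; ties go to the base
# with the highest summed Phred, then alphabetical. Consensus quality per
# position is the max Phred among reads agreeing with the consensus base.
consensus_vote <- function(seqs, quals, weights = NULL) {
  n <- length(seqs)
  if (n == 1L) return(list(sequence = seqs, quality = quals))
  L <- nchar(seqs[1])
  sm <- do.call(rbind, strsplit(seqs, ""))
  qm <- do.call(rbind, lapply(quals, phred_decode))
  w <- weights %||% rep(1L, n)
  cons <- character(L); consq <- integer(L)
  for (j in seq_len(L)) {
    col <- sm[, j]
    votes <- rowsum(w, col)
    top <- rownames(votes)[votes[, 1] == max(votes[, 1])]
    if (length(top) > 1L) {
      qsum <- rowsum(qm[col %in% top, j, drop = FALSE],
                     col[col %in% top])
      top <- rownames(qsum)[qsum[, 1] == max(qsum[, 1])]
      top <- lex_first(top)
    }
    cons[j] <- top
    consq[j] <- max(qm[col == top, j])
  }
  list(sequence = paste(cons, collapse = ""), quality = phred_encode(consq))
}

#' Collapse reads sharing a UMI into consensus molecules
#'
#' Reads are grouped by exact UMI equality. Within a group, reads of the
#' modal length are collapsed to the per-position majority base (ties:
#' highest summed Phred, then alphabetical); reads whose length differs from
#' the modal length are emitted as their own singletons. The `count` field
#' of each output records how many reads it collapses; consensus quality per
#' position is the maximum Phred among agreeing bases.
#'
#' @param merged data.frame of merged reads carrying a `umi` column.
#' @return data.frame with the same columns, one row per consensus molecule.
#' @export
collapse_umi_groups <- function(merged) {
  if (nrow(merged) == 0L) return(merged)
  if (any(is.na(merged$umi))) stop("all reads must carry a UMI to collapse")
  out <- list()
  for (u in unique(merged$umi)) {
    g <- merged[merged$umi == u, , drop = FALSE]
    len <- nchar(g$sequence)
    lt <- table(len)
    modal <- as.integer(names(lt)[which.max(lt)])
    core <- g[len == modal, , drop = FALSE]
    rest <- g[len != modal, , drop = FALSE]
    cv <- consensus_vote(core$sequence, core$quality)
    row <- data.frame(sequence = cv$sequence, quality = cv$quality,
                      umi = u, stringsAsFactors = FALSE)
    row$read_indices <- list(sort(unlist(core$read_indices)))
    row$count <- sum(core$count)
    out[[length(out) + 1L]] <- row
    if (nrow(rest)) out[[length(out) + 1L]] <- rest
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Apply the length/quality/stop-codon filters
#'
#' A record failing several criteria is counted once, under the first
#' failing criterion in the fixed order stop codon, length, quality. The
#' no-overlap rejections (consumed at merge time) are forwarded into the
#' report so that its conservation invariant
#' `input_count == retained + sum(rejected)` holds for the whole run.
#'
#' @param records data.frame with columns `sequence`, `quality` (Phred+33
#'   string) and logical `has_stop`.
#' @param config a [filter_config()].
#' @param n_no_overlap count of read pairs rejected at merge time.
#' @return list with `retained` (the surviving rows) and `report` (a
#'   `filter_report` named integer vector).
#' @export
apply_filters <- function(records, config = filter_config(),
                          n_no_overlap = 0L) {
  n <- nrow(records)
  if (n == 0L) {
    rep0 <- filter_report(n_no_overlap, n_no_overlap, 0L, 0L, 0L, 0L)
    return(list(retained = records, report = rep0))
  }
  stop_fail <- config$reject_stop_codons & records$has_stop
  short_fail <- !stop_fail & nchar(records$sequence) < config$min_length
  qual_fail <- !stop_fail & !short_fail &
    vapply(records$quality, mean_phred, numeric(1)) < config$min_quality
  keep <- !(stop_fail | short_fail | qual_fail)
  report <- filter_report(
    input_count = n + n_no_overlap,
    rejected_no_overlap = n_no_overlap,
    rejected_stop_codon = sum(stop_fail),
    rejected_short = sum(short_fail),
    rejected_low_quality = sum(qual_fail),
    retained_count = sum(keep))
  list(retained = records[keep, , drop = FALSE], report = report)
}

filter_report <- function(input_count, rejected_no_overlap,
                          rejected_stop_codon, rejected_short,
                          rejected_low_quality, retained_count) {
  r <- c(input_count = input_count,
         rejected_no_overlap = rejected_no_overlap,
         rejected_stop_codon = rejected_stop_codon,
         rejected_short = rejected_short,
         rejected_low_quality = rejected_low_quality,
         retained_count = retained_count)
  r <- vapply(r, as.integer, integer(1))
  stopifnot(r["input_count"] ==
              r["retained_count"] + sum(r[grep("^rejected_", names(r))]))
  class(r) <- "filter_report"
  r
}

#' Write a filter report as a two-column TSV
#' @param report a `filter_report`.
#' @param path output path.
#' @export
write_filter_report <- function(report, path) {
  utils::write.table(
    data.frame(criterion = names(report), count = as.integer(report)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
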