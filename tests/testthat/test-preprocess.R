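# brute-force overlap oracle: scan every offset, return the best merge
brute_merge <- function(fwd, rev, min_overlap, max_mm_frac) {
  rc <- strsplit(as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(rev))), "")[[1]]
  fv <- strsplit(fwd, "")[[1]]
  best <- NULL
  for (d in 0:(length(fv) - min_overlap)) {
    ov <- min(length(fv) - d, length(rc))
    if (ov < min_overlap) next
    mm <- sum(fv[(d + 1):(d + ov)] != rc[1:ov])
    if (mm / ov > max_mm_frac) next
    sc <- ov - 2 * mm
    if (is.null(best) || sc > best$sc || (sc == best$sc && ov > best$ov))
      best <- list(d = d, ov = ov, sc = sc)
  }
  if (is.null(best)) return(NULL)
  paste(c(fv[seq_len(best$d)], rc), collapse = "")
}

test_that("full-overlap mates merge to the forward read with max qualities", {
  fwd <- "ACGTACGTACGTACGTACGTACGT"
  rev <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(fwd)))
  fq <- q_string(30, nchar(fwd))
  rq <- q_string(35, nchar(fwd))
  m <- merge_pair(fwd, fq, rev, rq, min_overlap = 10)
  expect_equal(m$sequence, fwd)
  expect_equal(unique(utf8ToInt(m$quality) - 33L), 35L)
})

test_that("partially overlapping mates reconstruct the template amplicon", {
  set.seed(21)
  template <- random_dna(400)
  fwd <- substr(template, 1, 250)
  rev <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(template, 151, 400))))
  m <- merge_pair(fwd, q_string(35, 250), rev, q_string(35, 250))
  expect_equal(m$sequence, template)
  expect_equal(nchar(m$sequence), 400L)
  # agrees with the brute-force offset scan
  expect_equal(m$sequence, brute_merge(fwd, rev, 20, 0.1))
})

test_that("non-overlapping mates yield the no-overlap signal", {
  set.seed(22)
  fwd <- random_dna(250)
  rev <- random_dna(250)
  expect_null(merge_pair(fwd, q_string(35, 250), rev, q_string(35, 250)))
  expect_error(merge_pair("", "", "ACGT", q_string(30, 4)), "empty mate")
})

test_that("overlap disagreements take the higher-quality base", {
  # 12-nt full overlap with one disagreement (8.3% < the 10% cap)
  fwd <- "AAAACCCCTTTT"
  rc <- "AAAACCCCTTTG"  # disagree at last position
  rev <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(rc)))
  fq <- paste0(q_string(20, 11), q_string(10, 1))
  rq_fwdorder <- paste0(q_string(20, 11), q_string(30, 1))
  rq <- paste(rev(strsplit(rq_fwdorder, "")[[1]]), collapse = "")
  m <- merge_pair(fwd, fq, rev, rq, min_overlap = 12)
  expect_equal(substr(m$sequence, 12, 12), "G")  # rev wins at Q30 vs Q10
  # tie goes to the forward mate
  m2 <- merge_pair(fwd, fq, rev, paste(rev(strsplit(
    paste0(q_string(20, 11), q_string(10, 1)), "")[[1]]), collapse = ""),
    min_overlap = 12)
  expect_equal(substr(m2$sequence, 12, 12), "T")
})

test_that("UMI extraction captures degenerate positions and trims", {
  pairs <- data.frame(read_index = 0:1,
                      fwd_seq = c("ACGTTTTTTTTT", "AACGTTTTTTTT"),
                      fwd_qual = q_string(30, 12),
                      rev_seq = c("GGCCAAAAAAAA", "GGCCAAAAAAAA"),
                      rev_qual = q_string(30, 12),
                      stringsAsFactors = FALSE)
  r <- extract_umi(pairs, "NNNN", "forward")
  expect_equal(r$pairs$umi, c("ACGT", "AACG"))
  expect_equal(r$pairs$fwd_seq, c("TTTTTTTT", "TTTTTTTT"))
  expect_equal(r$n_unmatched, 0L)

  # fixed-position mismatch excludes the read
  r2 <- extract_umi(pairs, "TNNN", "forward")
  expect_equal(r2$n_unmatched, 2L)
  expect_equal(nrow(r2$pairs), 0L)

  # both mates: forward bases come first
  r3 <- extract_umi(pairs[1, ], "NN", "both")
  expect_equal(r3$pairs$umi, "ACGG")
  expect_equal(r3$pairs$fwd_seq, "GTTTTTTTTT")
  expect_equal(r3$pairs$rev_seq, "CCAAAAAAAA")
})

test_that("UMI consensus matches the per-column vote oracle", {
  base <- "ACGTACGTACGTACGTACGT"
  mk <- function(seqs, umis = "AAAA") {
    d <- data.frame(sequence = seqs, quality = q_string(30, nchar(seqs[1])),
                    umi = rep_len(umis, length(seqs)),
                    stringsAsFactors = FALSE)
    d$read_indices <- as.list(seq_along(seqs) - 1L)
    d$count <- 1L
    d
  }
  # identical group collapses to one molecule with count 5
  out <- collapse_umi_groups(mk(rep(base, 5)))
  expect_equal(nrow(out), 1L)
  expect_equal(out$count, 5L)
  expect_equal(out$sequence, base)

  # single substitution in one read is outvoted
  mut <- base
  substr(mut, 7, 7) <- "T"
  out2 <- collapse_umi_groups(mk(c(rep(base, 4), mut)))
  expect_equal(out2$sequence, base)

  # distinct UMIs are never merged
  out3 <- collapse_umi_groups(mk(c(base, base), umis = c("AAAA", "CCCC")))
  expect_equal(nrow(out3), 2L)

  # randomized groups against an independent column-vote oracle
  set.seed(33)
  for (rep_i in 1:20) {
    n <- sample(3:9, 1)
    true_seq <- random_dna(30)
    seqs <- vapply(seq_len(n), function(i) {
      s <- true_seq
      if (i > ceiling(n / 2) + 1) {  # minority reads carry one error
        p <- sample(30, 1)
        substr(s, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                          substr(s, p, p)), 1)
      }
      s
    }, character(1))
    out <- collapse_umi_groups(mk(seqs))
    oracle <- paste(apply(do.call(rbind, strsplit(seqs, "")), 2, function(col) {
      tab <- sort(table(col), decreasing = TRUE)
      names(tab)[1]
    }), collapse = "")
    expect_equal(out$sequence, true_seq)
    expect_equal(out$sequence, oracle)
    expect_equal(sum(out$count), n)
  }
})

test_that("off-modal-length reads become their own singletons", {
  d <- data.frame(sequence = c("ACGTACGT", "ACGTACGT", "ACGTAC"),
                  quality = c(q_string(30, 8), q_string(30, 8),
                              q_string(30, 6)),
                  umi = "AAAA", stringsAsFactors = FALSE)
  d$read_indices <- as.list(0:2)
  d$count <- 1L
  out <- collapse_umi_groups(d)
  expect_equal(nrow(out), 2L)
  expect_setequal(out$count, c(2L, 1L))
})

test_that("filters reject in fixed order and conserve read counts", {
  mk_rec <- function(len, q, stop = FALSE) {
    data.frame(sequence = strrep("A", len), quality = q_string(q, len),
               has_stop = stop, stringsAsFactors = FALSE)
  }
  recs <- rbind(mk_rec(300, 30), mk_rec(299, 30), mk_rec(300, 19),
                mk_rec(200, 30, stop = TRUE))
  fl <- apply_filters(recs, filter_config(), n_no_overlap = 2L)
  r <- fl$report
  expect_equal(r[["retained_count"]], 1L)
  expect_equal(r[["rejected_short"]], 1L)
  expect_equal(r[["rejected_low_quality"]], 1L)
  # stop codon wins over the (also failing) length criterion
  expect_equal(r[["rejected_stop_codon"]], 1L)
  expect_equal(r[["rejected_no_overlap"]], 2L)
  expect_equal(r[["input_count"]], 6L)

  # conservation on random batches
  set.seed(44)
  for (i in 1:10) {
    n <- sample(5:40, 1)
    recs <- do.call(rbind, lapply(seq_len(n), function(j)
      mk_rec(sample(250:350, 1), sample(10:35, 1), runif(1) < 0.2)))
    fl <- apply_filters(recs, filter_config(), sample(0:5, 1))
    r <- fl$report
    expect_equal(r[["input_count"]],
                 r[["retained_count"]] + r[["rejected_no_overlap"]] +
                   r[["rejected_stop_codon"]] + r[["rejected_short"]] +
                   r[["rejected_low_quality"]])
  }
})

test_that("simulated mates with guaranteed overlap recover every amplicon", {
  set.seed(55)
  amps <- replicate(15, random_dna(sample(320:380, 1)))
  pairs <- data.frame(
    read_index = seq_along(amps) - 1L,
    fwd_seq = substr(amps, 1, 250),
    fwd_qual = q_string(35, 250),
    rev_seq = vapply(amps, function(a)
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(
        substr(a, nchar(a) - 249, nchar(a))))), character(1),
      USE.NAMES = FALSE),
    rev_qual = q_string(35, 250), stringsAsFactors = FALSE)
  mg <- merge_read_pairs(pairs)
  expect_equal(mg$n_no_overlap, 0L)
  expect_equal(mg$merged$sequence, unname(amps))
})
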