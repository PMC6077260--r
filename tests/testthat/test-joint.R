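rep_tab <- function(aa, count, iso = "IgM") {
  rec_df(aa = aa, count = count, isotype = iso,
         cdr3 = substr(aa, 1, 4))
}

test_that("replicate aggregation unions records and sums counts", {
  r1 <- rep_tab(c("CARWAAAA", "CDRXBBBB"), c(3L, 1L))
  r2 <- rep_tab(c("CARWAAAA", "CEEYCCCC"), c(2L, 4L))
  joint <- aggregate_replicates(list(r1, r2))
  expect_equal(nrow(joint$records), 3L)
  shared <- joint$records$aa_sequence == "CARWAAAA"
  expect_equal(joint$records$count[shared], 5L)
  expect_equal(joint$counts[shared, ], c(3L, 2L))
  # identical replicates double every count
  j2 <- aggregate_replicates(list(r1, r1))
  expect_equal(j2$records$count, 2L * sort(r1$count, decreasing = TRUE))
  # disjoint replicates concatenate
  j3 <- aggregate_replicates(list(rep_tab("CARWAAAA", 1L),
                                  rep_tab("CDRXBBBB", 1L)))
  expect_equal(nrow(j3$records), 2L)
  expect_equal(unname(colSums(j3$counts)), c(1L, 1L))
})

test_that("the replicate count is capped at six", {
  one <- rep_tab("CARWAAAA", 1L)
  expect_silent(j6 <- aggregate_replicates(rep(list(one), 6L)))
  expect_equal(j6$n_replicates, 6L)
  expect_error(aggregate_replicates(rep(list(one), 7L)),
               "too many replicates")
  expect_error(aggregate_replicates(list()), "no replicates")
})

test_that("projection restores each replicate's records and counts", {
  r1 <- rep_tab(c("CARWAAAA", "CDRXBBBB"), c(3L, 1L))
  r2 <- rep_tab(c("CARWAAAA", "CEEYCCCC"), c(2L, 4L))
  joint <- aggregate_replicates(list(r1, r2))
  for (pair in list(list(1L, r1), list(2L, r2))) {
    back <- project_replicate(joint, pair[[1]])
    orig <- pair[[2]]
    key <- function(d) order(d$aa_sequence)
    expect_equal(back$aa_sequence[key(back)], orig$aa_sequence[key(orig)])
    expect_equal(back$count[key(back)], orig$count[key(orig)])
  }
})

test_that("Pearson correlation matches direct computation", {
  r1 <- rep_tab(sprintf("CARW%04d", 1:5), c(1L, 2L, 3L, 4L, 5L))
  r2 <- rep_tab(sprintf("CARW%04d", 1:5), c(2L, 4L, 6L, 8L, 10L))
  joint <- aggregate_replicates(list(r1, r2))
  # proportional counts -> r = 1
  expect_equal(pairwise_correlation(joint, 1, 2), 1)
  # self-correlation is exactly 1
  j_self <- aggregate_replicates(list(r1, r1))
  expect_equal(pairwise_correlation(j_self, 1, 2), 1)

  # hand-computed r on a 5-row table via the covariance formula
  a <- c(5, 1, 3, 2, 9); b <- c(4, 1, 2, 2, 8)
  r1b <- rep_tab(sprintf("CARW%04d", 1:5), as.integer(a))
  r2b <- rep_tab(sprintf("CARW%04d", 1:5), as.integer(b))
  jb <- aggregate_replicates(list(r1b, r2b))
  got <- pairwise_correlation(jb, 1, 2)
  # records are reordered during aggregation; recompute from the joint
  # count matrix with the textbook formula as an independent oracle
  x <- jb$counts[, 1]; y <- jb$counts[, 2]
  hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(got, hand)
  expect_equal(got, stats::cor(x, y))

  # intersection mode restricts to co-occurring records
  r3 <- rep_tab(c(sprintf("CARW%04d", 1:5), "CZZZ9999"),
                c(1L, 2L, 3L, 4L, 5L, 7L))
  jc <- aggregate_replicates(list(r3, r2))
  keep <- jc$counts[, 1] > 0 & jc$counts[, 2] > 0
  expect_equal(pairwise_correlation(jc, 1, 2, mode = "intersection"),
               stats::cor(jc$counts[keep, 1], jc$counts[keep, 2]))
})

test_that("zero-variance margins give NA with a warning, never silent 0", {
  r1 <- rep_tab(c("CARWAAAA", "CDRXBBBB"), c(2L, 2L))
  r2 <- rep_tab(c("CARWAAAA", "CDRXBBBB"), c(1L, 5L))
  joint <- aggregate_replicates(list(r1, r2))
  expect_warning(r <- pairwise_correlation(joint, 1, 2), "zero variance")
  expect_true(is.na(r))
})

test_that("the correlation matrix is symmetric with unit diagonal", {
  reps <- list(rep_tab(sprintf("CARW%04d", 1:4), c(1L, 2L, 3L, 4L)),
               rep_tab(sprintf("CARW%04d", 1:4), c(2L, 3L, 4L, 6L)),
               rep_tab(sprintf("CARW%04d", c(1, 2, 4, 5)), c(1L, 1L, 2L, 3L)))
  m <- correlation_matrix(aggregate_replicates(reps))
  expect_equal(dim(m), c(3L, 3L))
  expect_equal(unname(diag(m)), rep(1, 3))
  expect_equal(m, t(m))
})

test_that("Venn regions partition the union and match brute force", {
  brute_venn <- function(sets) {
    keys <- unique(unlist(sets))
    pattern <- vapply(keys, function(k)
      paste(which(vapply(sets, function(s) k %in% s, logical(1))),
            collapse = "+"), character(1))
    table(pattern)
  }
  set.seed(202)
  for (trial in 1:5) {
    n_rep <- sample(2:4, 1)
    pool <- sprintf("CARW%04d", 1:200)
    sets <- lapply(seq_len(n_rep), function(i)
      sample(pool, sample(20:200, 1)))
    reps <- lapply(sets, function(s) rep_tab(s, rep(1L, length(s))))
    vc <- venn_counts(aggregate_replicates(reps))
    oracle <- brute_venn(sets)
    for (region in names(oracle))
      expect_equal(vc[[region]], as.integer(oracle[[region]]))
    expect_equal(sum(vc), length(unique(unlist(sets))))
    expect_equal(length(vc), 2L^n_rep - 1L)
  }
})

test_that("the joint FASTA header round-trips every field", {
  r1 <- rep_tab(c("CARWAAAA", "CDRXBBBB"), c(3L, 1L), iso = "IgG")
  r2 <- rep_tab("CARWAAAA", 2L, iso = "IgG")
  joint <- aggregate_replicates(list(r1, r2))
  path <- withr::local_tempfile(fileext = ".fasta")
  joint_fasta(joint, path)
  lines <- readLines(path)
  expect_true(any(grepl("^>VH\\|IgG\\|cdr3=CARW\\|", lines)))
  expect_true(any(grepl("counts=5\\|by_replicate=3,2$", lines)))
  back <- read_joint_fasta(path)
  expect_equal(nrow(back), 2L)
  i <- back$aa_sequence == "CARWAAAA"
  expect_equal(back$count[i], 5L)
  expect_equal(back$by_replicate[i][[1]], c(3L, 2L))
  expect_equal(back$isotype[i], "IgG")
  expect_equal(back$v_subgroup[i], "IGHV1")

  # empty joint repertoire: warning plus an empty file
  empty <- aggregate_replicates(list(empty_records()))
  p2 <- withr::local_tempfile(fileext = ".fasta")
  expect_warning(joint_fasta(empty, p2), "empty")
  expect_equal(file.size(p2), 0)
})

test_that("the joint annotation TSV carries per-replicate count columns", {
  r1 <- rep_tab(c("CARWAAAA", "CDRXBBBB"), c(3L, 1L))
  r2 <- rep_tab("CARWAAAA", 2L)
  joint <- aggregate_replicates(list(r1, r2))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_joint_annotation_tsv(joint, path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  expect_true(all(c("count_rep1", "count_rep2") %in% names(tab)))
  expect_equal(tab$count, tab$count_rep1 + tab$count_rep2)
})
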