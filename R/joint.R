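# Joint multi-replicate analysis: aggregation of annotation records across
# 2-6 replicates keyed by (chain, isotype, amino-acid sequence), pairwise
# Pearson correlation of per-record counts, Venn intersection counts, and
# the joint FASTA with per-replicate occurrence lists.

MAX_REPLICATES <- 6L

#' Aggregate annotation records across replicates
#'
#' @param replicates list of `annotation_records` tables (1 to 6; a single
#'   replicate is allowed for individual-only runs).
#' @return object of class `joint_repertoire`: `records` (union
#'   `annotation_records` with `count` = total over replicates) and
#'   `counts` (records x replicates integer matrix).
#' @export
aggregate_replicates <- function(replicates) {
  n <- length(replicates)
  if (n == 0L) stop("no replicates given")
  if (n > MAX_REPLICATES)
    stop("too many replicates: ", n, " (at most ", MAX_REPLICATES,
         " are supported)")
  keyed <- lapply(replicates, function(r)
    paste(r$chain, r$isotype, r$aa_sequence, sep = "\r"))
  all_keys <- unique(unlist(keyed))
  if (length(all_keys) == 0L)
    return(structure(list(records = empty_records(),
                          counts = matrix(0L, 0L, n), n_replicates = n),
                     class = "joint_repertoire"))
  counts <- matrix(0L, nrow = length(all_keys), ncol = n)
  for (j in seq_len(n)) {
    m <- match(keyed[[j]], all_keys)
    counts[m, j] <- replicates[[j]]$count
  }
  # record fields come from the replicate where the record is most abundant
  rows <- lapply(seq_along(all_keys), function(i) {
    js <- which(counts[i, ] > 0L)
    j <- js[which.max(counts[i, js])]
    replicates[[j]][match(all_keys[i], keyed[[j]]), , drop = FALSE]
  })
  rec <- do.call(rbind, rows)
  # merge member nt variants across replicates
  if ("members" %in% names(rec)) {
    rec$members <- lapply(seq_along(all_keys), function(i) {
      ms <- lapply(which(counts[i, ] > 0L), function(j) {
        replicates[[j]]$members[[match(all_keys[i], keyed[[j]])]]
      })
      m <- do.call(rbind, ms)
      agg <- rowsum(m$count, m$nt)
      out <- data.frame(nt = rownames(agg), count = as.integer(agg[, 1]),
                        stringsAsFactors = FALSE)
      out$read_indices <- lapply(out$nt, function(v)
        sort(unlist(m$read_indices[m$nt == v])))
      out
    })
  }
  rec$count <- as.integer(rowSums(counts))
  ord <- order(-rec$count, rec$aa_sequence, method = "radix")
  rec <- rec[ord, , drop = FALSE]
  counts <- counts[ord, , drop = FALSE]
  rownames(rec) <- NULL
  class(rec) <- c("annotation_records", "data.frame")
  structure(list(records = rec, counts = counts, n_replicates = n),
            class = "joint_repertoire")
}

#' Project one replicate back out of a joint repertoire
#' @param joint a `joint_repertoire`.
#' @param i replicate index.
#' @return the replicate's `annotation_records` (counts restored).
#' @export
project_replicate <- function(joint, i) {
  keep <- joint$counts[, i] > 0L
  rec <- joint$records[keep, , drop = FALSE]
  rec$count <- joint$counts[keep, i]
  rownames(rec) <- NULL
  class(rec) <- c("annotation_records", "data.frame")
  rec
}

#' Pairwise Pearson correlation between two replicates
#'
#' Correlation of per-record abundances of replicates `i` and `j`. In
#' `"union"` mode (default) records absent from one replicate enter as
#' zero; `"intersection"` mode restricts to co-occurring records. With
#' `values = "frequency"` counts are normalized to within-replicate
#' fractions first. When either margin has zero variance the result is
#' undefined and `NA` is returned with a warning (never silently 0).
#'
#' @param joint a `joint_repertoire`.
#' @param i,j replicate indices.
#' @param mode `"union"` or `"intersection"`.
#' @param values `"count"` or `"frequency"`.
#' @return Pearson r, or `NA` when undefined.
#' @export
pairwise_correlation <- function(joint, i, j,
                                 mode = c("union", "intersection"),
                                 values = c("count", "frequency")) {
  mode <- match.arg(mode)
  values <- match.arg(values)
  a <- joint$counts[, i]; b <- joint$counts[, j]
  if (sum(a) == 0L || sum(b) == 0L) stop("replicate without records")
  if (values == "frequency") { a <- a / sum(a); b <- b / sum(b) }
  if (mode == "intersection") {
    keep <- joint$counts[, i] > 0L & joint$counts[, j] > 0L
    a <- a[keep]; b <- b[keep]
  }
  if (length(a) < 2L || stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("correlation undefined: zero variance in a margin")
    return(NA_real_)
  }
  stats::cor(a, b, method = "pearson")
}

#' Correlation matrix over all replicate pairs
#' @inheritParams pairwise_correlation
#' @return symmetric matrix of Pearson r with unit diagonal.
#' @export
correlation_matrix <- function(joint, mode = "union", values = "count") {
  n <- joint$n_replicates
  m <- diag(1, n)
  if (n >= 2L)
    for (i in 1:(n - 1L)) for (j in (i + 1L):n)
      m[i, j] <- m[j, i] <- pairwise_correlation(joint, i, j, mode, values)
  dimnames(m) <- list(paste0("rep", 1:n), paste0("rep", 1:n))
  m
}

#' Venn region counts over replicates
#'
#' The number of unique amino-acid sequences present in exactly each
#' non-empty subset of replicates; the 2^n - 1 regions partition the union.
#'
#' @param joint a `joint_repertoire`.
#' @return named integer vector; names are `+`-joined replicate indices
#'   (e.g. `"1+3"`).
#' @export
venn_counts <- function(joint) {
  n <- joint$n_replicates
  present <- joint$counts > 0L
  pattern <- apply(present, 1L, function(p)
    paste(which(p), collapse = "+"))
  subsets <- unlist(lapply(1:n, function(k)
    utils::combn(1:n, k, paste, collapse = "+", simplify = FALSE)))
  out <- stats::setNames(integer(length(subsets)), subsets)
  tab <- table(pattern)
  out[names(tab)] <- as.integer(tab)
  out
}

joint_fasta_header <- function(rec, counts_row) {
  paste0(rec$chain, "|", rec$isotype, "|cdr3=", rec$cdr3_aa,
         "|v=", rec$v_subgroup, "|d=", rec$d_subgroup,
         "|j=", rec$j_subgroup, "|counts=", sum(counts_row),
         "|by_replicate=", paste(counts_row, collapse = ","))
}

#' Write the joint FASTA with per-replicate occurrence lists
#'
#' One record per unique amino-acid sequence; the header carries chain,
#' isotype, CDR3, subgroups, the total count and the comma-separated
#' per-replicate counts (`counts=5|by_replicate=3,0,2`).
#'
#' @param joint a `joint_repertoire`.
#' @param path output FASTA path.
#' @export
joint_fasta <- function(joint, path) {
  if (nrow(joint$records) == 0L) {
    warning("empty joint repertoire; writing empty FASTA")
    file.create(path)
    return(invisible(path))
  }
  hdr <- vapply(seq_len(nrow(joint$records)), function(i)
    joint_fasta_header(joint$records[i, ], joint$counts[i, ]),
    character(1))
  x <- Biostrings::AAStringSet(joint$records$aa_sequence)
  names(x) <- hdr
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

#' Read a joint FASTA back into a table
#'
#' Inverse of the [joint_fasta()] header format; used to round-trip joint
#' exports.
#'
#' @param path FASTA path.
#' @return data.frame with the header fields, `aa_sequence`, `count`, and a
#'   `by_replicate` list-column of integer vectors.
#' @export
read_joint_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  f <- strsplit(names(x), "|", fixed = TRUE)
  val <- function(parts, key) sub(paste0("^", key, "="), "",
                                  grep(paste0("^", key, "="), parts,
                                       value = TRUE))
  out <- data.frame(
    chain = vapply(f, `[`, character(1), 1L),
    isotype = vapply(f, `[`, character(1), 2L),
    cdr3_aa = vapply(f, val, character(1), "cdr3"),
    v_subgroup = vapply(f, val, character(1), "v"),
    d_subgroup = vapply(f, val, character(1), "d"),
    j_subgroup = vapply(f, val, character(1), "j"),
    count = as.integer(vapply(f, val, character(1), "counts")),
    aa_sequence = unname(as.character(x)),
    stringsAsFactors = FALSE)
  out$by_replicate <- lapply(f, function(p)
    as.integer(strsplit(val(p, "by_replicate"), ",")[[1]]))
  out
}

#' Write the joint annotation TSV (nine fields + per-replicate counts)
#' @param joint a `joint_repertoire`.
#' @param path output path.
#' @export
write_joint_annotation_tsv <- function(joint, path) {
  cols <- c("chain", "isotype", "nt_sequence", "aa_sequence", "cdr3_aa",
            "v_subgroup", "d_subgroup", "j_subgroup", "count")
  tab <- as.data.frame(joint$records)[cols]
  cm <- as.data.frame(joint$counts)
  names(cm) <- paste0("count_rep", seq_len(ncol(cm)))
  utils::write.table(cbind(tab, cm), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
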