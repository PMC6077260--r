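# Isotype assignment by fingerprint-peptide matching.
#
# The constant-region peptides immediately C-terminal to the framework-4
# anchor identify the isotype. The anchor is VTVSS in human and VTVSS /
# LTVSS / VTVSA in mouse; fingerprints are matched exactly, then by closest
# match with at most one amino-acid mismatch. More than one mismatch (or a
# tie between isotypes) yields "unknown". Human IgA1/IgA2 share the ASPTSP
# stem and are distinguished by their long fingerprints ending CSTQP (A1)
# and DSTPQ (A2); when the read is too short to reach the tail the call is
# the undifferentiated "IgA".

#' Isotype fingerprint table
#'
#' Anchors and fingerprints ship as an editable TSV (columns `species`,
#' `kind` = anchor|fingerprint, `label`, `peptide`) so additional species
#' can be added without code changes.
#'
#' @param species `"human"` or `"mouse"`.
#' @param path optional path to a custom fingerprint TSV; defaults to the
#'   table shipped with the package.
#' @return list with `species`, `anchors` (character vector) and
#'   `fingerprints` (named list label -> peptides).
#' @export
isotype_table <- function(species = c("human", "mouse"), path = NULL) {
  species <- match.arg(species)
  path <- path %||% system.file("extdata", "isotype_fingerprints.tsv",
                                package = "igseqr", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  tab <- tab[tab$species == species, , drop = FALSE]
  if (nrow(tab) == 0L) stop("no fingerprint entries for species ", species)
  anchors <- tab$peptide[tab$kind == "anchor"]
  fp <- tab[tab$kind == "fingerprint", , drop = FALSE]
  fingerprints <- split(fp$peptide, fp$label)
  if (any(nchar(anchors) != 5L))
    stop("FR4 anchors must be 5 residues")
  # precomputed flat views used by the matching hot path
  pep_labels <- rep(names(fingerprints), lengths(fingerprints))
  peptides <- unlist(fingerprints, use.names = FALSE)
  structure(list(species = species, anchors = anchors,
                 fingerprints = fingerprints,
                 pep_labels = pep_labels,
                 peptides = peptides,
                 pep_lens = nchar(peptides),
                 label_idx = split(seq_along(pep_labels), pep_labels)),
            class = "isotype_table")
}

#' Locate the framework-4 anchor in a translated read
#'
#' Returns the end offset (0-based, exclusive) of the rightmost occurrence
#' of any anchor peptide, or `NA` when none occurs. The rightmost occurrence
#' is used because somatic hypermutation could create spurious earlier
#' copies, while the true anchor terminates the variable region.
#'
#' @param aa_sequence amino-acid sequence.
#' @param table an [isotype_table()].
#' @return integer end offset or `NA_integer_`.
#' @export
locate_fr4_anchor <- function(aa_sequence, table) {
  if (!nzchar(aa_sequence)) stop("empty amino-acid sequence")
  best <- NA_integer_
  for (anchor in table$anchors) {
    hits <- gregexpr(anchor, aa_sequence, fixed = TRUE)[[1]]
    if (hits[1] == -1L) next
    end0 <- max(hits) - 1L + nchar(anchor)
    if (is.na(best) || end0 > best) best <- end0
  }
  best
}

#' Assign an isotype from a translated heavy-chain read
#'
#' The region C-terminal to the framework-4 anchor is matched against the
#' fingerprint peptides: an exact prefix match wins (longest fingerprint
#' first); otherwise the closest match by Hamming distance on the
#' equal-length prefix is taken when its minimum is unique and at most 1;
#' more than one mismatch, or a tie between isotypes, gives `"unknown"`.
#' A human IgA call via the short ASPTSP stem is refined against the long
#' IgA1/IgA2 fingerprints when the read reaches the discriminating tail;
#' otherwise the call is `"IgA"`.
#'
#' @param aa_sequence character vector of translated-read amino-acid
#'   sequences (vectorized).
#' @param table an [isotype_table()].
#' @return character vector of isotype labels (`"IgM"`, `"IgG"`, ...,
#'   `"IgA"`, or `"unknown"`), one per input sequence.
#' @export
assign_isotype <- function(aa_sequence, table) {
  n <- length(aa_sequence)
  if (n == 0L) return(character(0))
  if (any(!nzchar(aa_sequence))) stop("empty amino-acid sequence")
  # rightmost anchor end (0-based, exclusive) per sequence
  anchor_end <- rep(NA_integer_, n)
  for (anchor in table$anchors) {
    hits <- gregexpr(anchor, aa_sequence, fixed = TRUE)
    e <- vapply(hits, function(h)
      if (h[1] == -1L) NA_integer_ else max(h) - 1L + nchar(anchor),
      integer(1))
    upd <- !is.na(e) & (is.na(anchor_end) | e > anchor_end)
    anchor_end[upd] <- e[upd]
  }
  tails <- substr(aa_sequence, anchor_end + 1L, nchar(aa_sequence))
  tails[is.na(anchor_end)] <- NA_character_
  ntails <- nchar(tails)

  # per-peptide prefix Hamming distance matrix, column-wise over positions
  lens <- table$pep_lens
  labs <- table$pep_labels
  D <- matrix(Inf, n, length(lens))
  for (k in seq_along(lens)) {
    L <- lens[k]
    p <- table$peptides[k]
    covered <- which(!is.na(ntails) & ntails >= L)
    if (length(covered) == 0L) next
    mm <- integer(length(covered))
    for (j in seq_len(L))
      mm <- mm + (substr(tails[covered], j, j) != substr(p, j, j))
    D[covered, k] <- mm
  }

  # (i) exact prefix match; prefer the longest matching peptide so the long
  # IgA1/IgA2 fingerprints beat their shared ASPTSP stem
  label <- rep(NA_character_, n)
  for (k in order(lens, decreasing = TRUE)) {
    hit <- is.na(label) & D[, k] == 0
    label[hit] <- labs[k]
  }

  # (ii) closest match, tolerance one mismatch, ties -> unknown
  idx <- table$label_idx
  DL <- vapply(idx, function(ii) {
    m <- D[, ii[1]]
    for (k in ii[-1]) m <- pmin(m, D[, k])
    m
  }, numeric(n))
  if (n == 1L) DL <- matrix(DL, 1L, dimnames = list(NULL, names(idx)))
  dmin <- DL[, 1]
  for (j in seq_len(ncol(DL))[-1]) dmin <- pmin(dmin, DL[, j])
  nmin <- rowSums(DL == dmin)
  closest <- colnames(DL)[max.col(-DL, ties.method = "first")]
  need <- is.na(label)
  ok <- need & is.finite(dmin) & dmin <= 1 & nmin == 1L
  label[ok] <- closest[ok]

  # (iii) human IgA disambiguation via the long-tail fingerprints
  if (all(c("A1", "A2") %in% colnames(DL))) {
    isA <- !is.na(label) & label == "A"
    if (any(isA)) {
      d1 <- DL[isA, "A1"]
      d2 <- DL[isA, "A2"]
      sub <- ifelse(!is.finite(pmin(d1, d2)) | pmin(d1, d2) > 1 | d1 == d2,
                    "A", ifelse(d1 < d2, "A1", "A2"))
      label[isA] <- sub
    }
  }
  ifelse(is.na(label), "unknown", paste0("Ig", label))
}

#' Assign isotypes to an annotated read table
#'
#' Heavy-chain reads are assigned via [assign_isotype()]; light-chain reads
#' receive isotype `"none"` (the isotype is a property of the heavy-chain
#' constant region).
#'
#' @param ann annotated reads from [annotate_reads()].
#' @param table an [isotype_table()].
#' @return `ann` with an `isotype` column.
#' @export
assign_isotypes <- function(ann, table) {
  if (nrow(ann) == 0L) { ann$isotype <- character(0); return(ann) }
  heavy <- ann$chain == "VH"
  iso <- rep("none", nrow(ann))
  if (any(heavy)) {
    uniq <- unique(ann$aa_sequence[heavy])
    lab <- stats::setNames(assign_isotype(uniq, table), uniq)
    iso[heavy] <- lab[ann$aa_sequence[heavy]]
  }
  ann$isotype <- unname(iso)
  ann
}
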