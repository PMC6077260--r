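# Seeded repertoire simulator. Generates synthetic germline V/D/J sets,
# clonally structured repertoires with somatic hypermutation confined to
# the V gene, isotype constant-region stubs beginning with the fingerprint
# peptide, replicate structure, and paired-end FASTQ (optionally
# UMI-tagged) with a two-tier quality model — together with a per-read
# ground-truth table, so every pipeline stage is testable without any
# reference downloads.

codons_no_stop <- function() {
  if (is.null(.cache$codons_no_stop)) {
    gc_tab <- Biostrings::GENETIC_CODE
    .cache$codons_no_stop <- names(gc_tab)[gc_tab != "*"]
  }
  .cache$codons_no_stop
}

aa_to_codon <- function() {
  if (is.null(.cache$aa_to_codon)) {
    gc_tab <- Biostrings::GENETIC_CODE
    .cache$aa_to_codon <- vapply(split(names(gc_tab), gc_tab), `[`,
                                 character(1), 1L)
  }
  .cache$aa_to_codon
}

random_codons <- function(n) {
  paste(sample(codons_no_stop(), n, replace = TRUE), collapse = "")
}

encode_aa <- function(aa) {
  map <- aa_to_codon()
  paste(map[strsplit(aa, "")[[1]]], collapse = "")
}

#' Simulation configuration
#'
#' Defaults emulate the kind of dataset the pipeline targets: 2 x 250 bp
#' paired-end MiSeq reads of murine heavy-chain variable regions in
#' technical triplicates.
#'
#' @param seed RNG seed; all simulator randomness flows through it.
#' @param species `"human"` or `"mouse"`.
#' @param n_v,n_d,n_j germline gene counts per class.
#' @param n_clones number of clones.
#' @param clone_sizes explicit per-clone read counts; when `NULL`, sizes
#'   follow a power law with exponent `clone_size_exponent` scaled to
#'   `n_reads` total reads per replicate.
#' @param clone_size_exponent power-law exponent for clone sizes.
#' @param n_reads approximate reads per replicate when sizes are drawn.
#' @param shm_rate Poisson mean substitutions per read, confined to the V
#'   gene.
#' @param seq_error_rate per-base sequencing error probability.
#' @param read_length read length in nt.
#' @param umi_length UMI length in nt (0 = no UMIs).
#' @param reads_per_umi sequencing reads per tagged molecule.
#' @param isotype_mix named probabilities over isotype labels (must sum
#'   to 1); defaults to an IgM/IgG-dominated mix for the species.
#' @param n_replicates number of replicates (1-6).
#' @param replicate_overlap_frac fraction of clones shared by all
#'   replicates; the rest appear in a single random replicate.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L, species = c("mouse", "human"),
                       n_v = 5L, n_d = 4L, n_j = 3L, n_clones = 50L,
                       clone_sizes = NULL, clone_size_exponent = 1.5,
                       n_reads = 2000L, shm_rate = 4, seq_error_rate = 0.002,
                       read_length = 250L, umi_length = 0L,
                       reads_per_umi = 1L, isotype_mix = NULL,
                       n_replicates = 3L, replicate_overlap_frac = 0.5) {
  species <- match.arg(species)
  isotype_mix <- isotype_mix %||% switch(species,
    mouse = c(IgM = 0.45, IgG = 0.35, IgA = 0.1, IgD = 0.05, IgE = 0.05),
    human = c(IgM = 0.4, IgG = 0.3, IgA1 = 0.1, IgA2 = 0.1, IgD = 0.05,
              IgE = 0.05))
  stopifnot(abs(sum(isotype_mix) - 1) < 1e-9, all(isotype_mix >= 0),
            n_replicates >= 1L, n_replicates <= 6L,
            shm_rate >= 0, seq_error_rate >= 0, seq_error_rate <= 1,
            replicate_overlap_frac >= 0, replicate_overlap_frac <= 1)
  structure(list(seed = as.integer(seed), species = species,
                 n_v = n_v, n_d = n_d, n_j = n_j, n_clones = n_clones,
                 clone_sizes = clone_sizes,
                 clone_size_exponent = clone_size_exponent,
                 n_reads = n_reads, shm_rate = shm_rate,
                 seq_error_rate = seq_error_rate,
                 read_length = as.integer(read_length),
                 umi_length = as.integer(umi_length),
                 reads_per_umi = as.integer(reads_per_umi),
                 isotype_mix = isotype_mix,
                 n_replicates = as.integer(n_replicates),
                 replicate_overlap_frac = replicate_overlap_frac),
            class = "sim_config")
}

fr4_peptides <- function(species) {
  if (species == "human") "WGQGTLVTVSS"
  else c("WGQGTLVTVSS", "WGQGTLLTVSS", "WGQGTSVTVSA")
}

#' Generate a synthetic germline set
#'
#' V genes are random in-frame stop-free sequences ending in a Cys codon
#' (the CDR3 anchor); J genes carry two CDR3 codons followed by an encoded
#' FR4 peptide containing the species' framework-4 anchor motif; D genes
#' are short random segments. Reproducible from the caller's RNG state.
#'
#' @param config a [sim_config()].
#' @return a [germline_set].
#' @export
make_germline_set <- function(config) {
  n_fam <- 3L
  vs <- lapply(seq_len(config$n_v), function(i) {
    fam <- (i - 1L) %% n_fam + 1L
    data.frame(allele_name = sprintf("IGHV%d-%d*01", fam, i),
               gene_class = "V", chain = "IGH",
               subgroup = sprintf("IGHV%d", fam),
               cdr3_anchor = 285L,
               sequence = paste0(random_codons(95L), "TGC"),
               stringsAsFactors = FALSE)
  })
  ds <- lapply(seq_len(config$n_d), function(i) {
    fam <- (i - 1L) %% n_fam + 1L
    len <- sample(12:18, 1L)
    data.frame(allele_name = sprintf("IGHD%d-%d*01", fam, i),
               gene_class = "D", chain = "IGH",
               subgroup = sprintf("IGHD%d", fam),
               cdr3_anchor = NA_integer_,
               sequence = paste(sample(c("A", "C", "G", "T"), len,
                                       replace = TRUE), collapse = ""),
               stringsAsFactors = FALSE)
  })
  fr4 <- fr4_peptides(config$species)
  cs <- codons_no_stop()
  js <- lapply(seq_len(config$n_j), function(i) {
    # deterministic, index-distinct CDR3 codons: J alleles sharing an FR4
    # peptide must still be pairwise distinct sequences
    c1 <- cs[(2L * i - 2L) %% length(cs) + 1L]
    c2 <- cs[(2L * i - 1L) %% length(cs) + 1L]
    data.frame(allele_name = sprintf("IGHJ%d*01", i),
               gene_class = "J", chain = "IGH",
               subgroup = sprintf("IGHJ%d", i),
               cdr3_anchor = 6L,
               sequence = paste0(c1, c2,
                                 encode_aa(fr4[(i - 1L) %% length(fr4) + 1L])),
               stringsAsFactors = FALSE)
  })
  germline_set(do.call(rbind, c(vs, ds, js)), config$species)
}

# stub AA downstream of FR4: the isotype fingerprint peptide + padding
isotype_stub <- function(label, species) {
  tab <- isotype_table(species)
  key <- sub("^Ig", "", label)
  peptides <- tab$fingerprints[[key]]
  if (is.null(peptides)) stop("unknown isotype label ", label)
  paste0(peptides[1L], "VFPLA")
}

draw_clone_sizes <- function(config) {
  if (!is.null(config$clone_sizes)) return(as.integer(config$clone_sizes))
  w <- (seq_len(config$n_clones))^(-config$clone_size_exponent)
  sizes <- pmax(1L, round(config$n_reads * w / sum(w)))
  as.integer(sizes)
}

#' Simulate a clonally structured repertoire with ground truth
#'
#' Clones draw V/(D)/J alleles and a stop-free in-frame junction embedding
#' an exact D segment; each read applies Poisson-distributed substitutions
#' within the V gene (never in the anchor codon, never creating a stop) and
#' carries a constant-region stub beginning with its isotype's fingerprint
#' peptide. Replicate membership follows `replicate_overlap_frac`.
#'
#' @param germlines a [germline_set] from [make_germline_set()].
#' @param config a [sim_config()].
#' @return list with `molecules` (data.frame: `sequence`, `umi`,
#'   `replicate`, plus truth columns) and `truth` (per-molecule ground
#'   truth: clone id, alleles, SHM positions, CDR3, isotype, UMI,
#'   replicate).
#' @export
simulate_repertoire <- function(germlines, config) {
  vg <- genes_of(germlines, "IGH", "V")
  dg <- genes_of(germlines, "IGH", "D")
  jg <- genes_of(germlines, "IGH", "J")
  sizes <- draw_clone_sizes(config)
  n_clones <- length(sizes)
  shared <- seq_len(round(config$replicate_overlap_frac * n_clones))
  clones <- lapply(seq_len(n_clones), function(ci) {
    vi <- sample(nrow(vg), 1L); ji <- sample(nrow(jg), 1L)
    di <- sample(nrow(dg), 1L)
    repeat {
      dlen <- sample(6:min(9L, nchar(dg$sequence[di])), 1L)
      dstart <- sample(nchar(dg$sequence[di]) - dlen + 1L, 1L)
      dseg <- substr(dg$sequence[di], dstart, dstart + dlen - 1L)
      flank <- sample(0:5, 2L, replace = TRUE)
      jl <- dlen + sum(flank)
      pad <- (3L - jl %% 3L) %% 3L
      junction <- paste0(
        paste(sample(c("A", "C", "G", "T"), flank[1], replace = TRUE),
              collapse = ""),
        dseg,
        paste(sample(c("A", "C", "G", "T"), flank[2] + pad,
                     replace = TRUE), collapse = ""))
      amp_var <- paste0(vg$sequence[vi], junction, jg$sequence[ji])
      if (!has_stop(translate_nt(amp_var))) break
    }
    iso <- sample(names(config$isotype_mix), 1L,
                  prob = config$isotype_mix)
    stub <- encode_aa(isotype_stub(iso, config$species))
    amplicon <- paste0(amp_var, stub)
    cdr3_nt <- substr0(amplicon, 285L,
                       288L + nchar(junction) + 6L)
    reps <- if (ci %in% shared) seq_len(config$n_replicates)
            else sample(config$n_replicates, 1L)
    list(id = ci, v = vg$allele_name[vi], d = dg$allele_name[di],
         j = jg$allele_name[ji], amplicon = amplicon,
         cdr3_aa = translate_nt(cdr3_nt), isotype = iso,
         replicates = reps, size = sizes[ci])
  })
  v_len <- 285L  # mutable V span, excluding the anchor codon
  n_per_clone <- vapply(clones, function(cl)
    length(cl$replicates) * cl$size, integer(1))
  total <- sum(n_per_clone)
  clone_id <- integer(total); replicate <- integer(total)
  v_allele <- character(total); d_allele <- character(total)
  j_allele <- character(total); sequence <- character(total)
  shm_positions <- character(total); n_shm <- integer(total)
  cdr3_aa <- character(total); isotype <- character(total)
  umi <- rep(NA_character_, total)
  cur <- 0L
  for (cl in clones) {
    for (rep_i in cl$replicates) for (k in seq_len(cl$size)) {
      cur <- cur + 1L
      n_mut <- if (config$shm_rate > 0) stats::rpois(1L, config$shm_rate)
               else 0L
      seq_out <- cl$amplicon
      pos <- integer(0)
      if (n_mut > 0L) {
        for (tries in 1:50) {
          pos <- sort(sample(v_len, min(n_mut, v_len)))
          s <- strsplit(cl$amplicon, "")[[1]]
          for (p in pos)
            s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1L)
          cand <- paste(s, collapse = "")
          if (!has_stop(translate_nt(cand))) { seq_out <- cand; break }
          pos <- integer(0)
        }
      }
      if (config$umi_length > 0L)
        umi[cur] <- paste(sample(c("A", "C", "G", "T"), config$umi_length,
                                 replace = TRUE), collapse = "")
      clone_id[cur] <- cl$id; replicate[cur] <- rep_i
      v_allele[cur] <- cl$v; d_allele[cur] <- cl$d; j_allele[cur] <- cl$j
      sequence[cur] <- seq_out
      shm_positions[cur] <- paste(pos, collapse = ",")
      n_shm[cur] <- length(pos)
      cdr3_aa[cur] <- cl$cdr3_aa; isotype[cur] <- cl$isotype
    }
  }
  truth <- data.frame(
    clone_id = clone_id, v_allele = v_allele, d_allele = d_allele,
    j_allele = j_allele, sequence = sequence,
    shm_positions = shm_positions, n_shm = n_shm, cdr3_aa = cdr3_aa,
    isotype = isotype, umi = umi, replicate = replicate,
    molecule_id = seq_len(total) - 1L, stringsAsFactors = FALSE)
  list(molecules = truth, truth = truth)
}

inject_errors <- function(seqs, rate, hi = 35L, lo = 12L) {
  quals <- character(length(seqs))
  for (i in seq_along(seqs)) {
    s <- strsplit(seqs[i], "")[[1]]
    q <- rep(hi, length(s))
    err <- which(stats::runif(length(s)) < rate)
    for (p in err) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1L)
    q[err] <- lo
    seqs[i] <- paste(s, collapse = "")
    quals[i] <- phred_encode(q)
  }
  list(seq = seqs, qual = quals)
}

#' Emit paired-end FASTQ files per replicate
#'
#' Forward read = 5' UMI + amplicon prefix; reverse read = reverse
#' complement of the amplicon suffix (overlap is guaranteed when
#' `2 * read_length > amplicon length + umi_length`). Per-base errors are
#' injected at `seq_error_rate` under a two-tier quality model (Q35
#' everywhere, Q12 at error sites). Each molecule is sequenced
#' `reads_per_umi` times with independent errors.
#'
#' @param molecules the `molecules` table from [simulate_repertoire()].
#' @param config a [sim_config()].
#' @param dir output directory; files are `rep<i>_R1.fastq` /
#'   `rep<i>_R2.fastq`.
#' @return data.frame listing replicate, r1, r2 paths.
#' @export
emit_fastq_pairs <- function(molecules, config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- list()
  for (rep_i in sort(unique(molecules$replicate))) {
    m <- molecules[molecules$replicate == rep_i, , drop = FALSE]
    m <- m[rep(seq_len(nrow(m)), each = config$reads_per_umi), ,
           drop = FALSE]
    fwd_len <- config$read_length - config$umi_length
    fwd <- substr(m$sequence, 1L, fwd_len)
    if (config$umi_length > 0L) fwd <- paste0(m$umi, fwd)
    rev_ <- revcomp(substr(m$sequence,
                           pmax(1L, nchar(m$sequence) - config$read_length
                                + 1L),
                           nchar(m$sequence)))
    f <- inject_errors(fwd, config$seq_error_rate)
    r <- inject_errors(rev_, config$seq_error_rate)
    r1 <- file.path(dir, sprintf("rep%d_R1.fastq", rep_i))
    r2 <- file.path(dir, sprintf("rep%d_R2.fastq", rep_i))
    ids <- sprintf("mol%d_read%d", m$molecule_id, seq_len(nrow(m)))
    write_fastq(ids, f$seq, f$qual, r1)
    write_fastq(ids, r$seq, r$qual, r2)
    out[[length(out) + 1L]] <- data.frame(replicate = rep_i, r1 = r1,
                                          r2 = r2,
                                          stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

write_fastq <- function(ids, seqs, quals, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(quals))
  invisible(path)
}

#' Run the full simulator and write all fixtures to disk
#'
#' Sets the RNG from `config$seed`, generates the germline set, repertoire,
#' FASTQ pairs and ground-truth TSV.
#'
#' @param config a [sim_config()].
#' @param dir output directory.
#' @return list: `germlines`, `germline_fasta`, `fastq` (replicate/r1/r2
#'   table), `truth`, `truth_tsv`.
#' @export
simulate_run <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  germlines <- make_germline_set(config)
  gpath <- file.path(dir, "germline.fasta")
  write_germline_set(germlines, gpath)
  sim <- simulate_repertoire(germlines, config)
  fastq <- emit_fastq_pairs(sim$molecules, config, dir)
  tpath <- file.path(dir, "truth.tsv")
  utils::write.table(sim$truth, tpath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(germlines = germlines, germline_fasta = gpath, fastq = fastq,
       truth = sim$truth, truth_tsv = tpath)
}
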