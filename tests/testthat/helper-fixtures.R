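# Shared fixtures, built in code.

# tiny literal germline set for structural tests (no alignment involved)
tiny_germlines <- function(species = "human") {
  genes <- data.frame(
    allele_name = c("IGHV1-1*01", "IGHV2-3*01", "IGHD1-1*01", "IGHJ1*01"),
    gene_class = c("V", "V", "D", "J"),
    chain = "IGH",
    subgroup = c("IGHV1", "IGHV2", "IGHD1", "IGHJ1"),
    cdr3_anchor = c(57L, 57L, NA, 0L),
    sequence = c(
      paste0(strrep("GCTCAT", 9L), "GGT", "TGC"),
      paste0(strrep("TCAGAG", 9L), "ACT", "TGC"),
      "GGTACGTAGG",
      paste0("TGG", strrep("GGTACC", 5L))),
    stringsAsFactors = FALSE)
  germline_set(genes, species)
}

# realistic simulated germline set (RNG-dependent; caller controls seed)
sim_germlines <- function(seed = 11L, ...) {
  cfg <- sim_config(seed = seed, ...)
  set.seed(cfg$seed)
  list(config = cfg, germlines = make_germline_set(cfg))
}

# construct an amplicon read from germline parts: V (optionally mutated) +
# junction + J + optional constant stub
build_read <- function(germlines, v = 1L, j = 1L, junction = "GGGACTTCA",
                       stub_aa = NULL) {
  vg <- germlines$genes[germlines$genes$gene_class == "V", ][v, ]
  jg <- germlines$genes[germlines$genes$gene_class == "J", ][j, ]
  stub <- if (is.null(stub_aa)) "" else
    paste(vapply(strsplit(stub_aa, "")[[1]], function(a)
      names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == a][1],
      character(1)), collapse = "")
  list(sequence = paste0(vg$sequence, junction, jg$sequence, stub),
       v = vg, j = jg, junction = junction)
}

# minimal annotation_records table built by hand
rec_df <- function(aa, count = 1L, cdr3 = "CARW", chain = "VH",
                   isotype = "IgM", v = "IGHV1", d = "IGHD1", j = "IGHJ1",
                   nt = NULL, vmut = 0L) {
  n <- length(aa)
  nt <- nt %||% vapply(aa, function(a)
    paste(vapply(strsplit(a, "")[[1]], function(x)
      names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == x][1],
      character(1)), collapse = ""), character(1), USE.NAMES = FALSE)
  r <- data.frame(chain = rep_len(chain, n), isotype = rep_len(isotype, n),
                  nt_sequence = nt, aa_sequence = aa,
                  cdr3_aa = rep_len(cdr3, n),
                  v_subgroup = rep_len(v, n), d_subgroup = rep_len(d, n),
                  j_subgroup = rep_len(j, n),
                  count = rep_len(as.integer(count), n),
                  v_allele = paste0(rep_len(v, n), "-1*01"),
                  j_allele = paste0(rep_len(j, n), "*01"),
                  v_mutations = rep_len(as.integer(vmut), n),
                  stringsAsFactors = FALSE)
  r$members <- lapply(seq_len(n), function(i) {
    m <- data.frame(nt = r$nt_sequence[i], count = r$count[i],
                    stringsAsFactors = FALSE)
    m$read_indices <- list(seq_len(r$count[i]) - 1L + 100L * i)
    m
  })
  class(r) <- c("annotation_records", "data.frame")
  r
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

q_string <- function(phred, n) {
  paste(rep(intToUtf8(phred + 33L), n), collapse = "")
}
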