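# End-to-end orchestration: individual per-replicate runs (merge -> UMI ->
# annotate -> filter -> isotype -> statistics -> clones -> exports) and the
# joint analysis across replicates (aggregation, correlations, Venn,
# joint statistics/clones/FASTA/MS database). All results are TSV/FASTA for
# diffability; every run writes a manifest listing its artifacts with
# checksums.

#' Run configuration
#'
#' @param replicates data.frame with columns `r1`, `r2` (FASTQ paths), or
#'   a character vector of AIRR-style TSV paths (one per replicate).
#' @param germline path to the germline FASTA (ignored for AIRR input).
#' @param species `"human"` or `"mouse"`.
#' @param extra_germline optional FASTA of novel alleles to append.
#' @param chain chain to analyze (default `"IGH"`).
#' @param filter a [filter_config()].
#' @param umi_pattern optional IUPAC UMI pattern.
#' @param umi_location `"forward"`, `"reverse"` or `"both"`.
#' @param k_top_clones clones reported in the clone summary (default 100).
#' @param ms_rule a [cleavage_rule()]; defaults to the species rule.
#' @param out output directory.
#' @return a `run_config` list.
#' @export
run_config <- function(replicates, germline = NULL,
                       species = c("human", "mouse"),
                       extra_germline = NULL, chain = "IGH",
                       filter = filter_config(), umi_pattern = NULL,
                       umi_location = "forward", k_top_clones = 100L,
                       ms_rule = NULL, out = tempfile("igseqr_run_")) {
  species <- match.arg(species)
  airr <- is.character(replicates)
  n <- if (airr) length(replicates) else nrow(replicates)
  if (n < 1L || n > MAX_REPLICATES)
    stop("replicate count must be between 1 and ", MAX_REPLICATES,
         ", got ", n)
  paths <- if (airr) replicates else c(replicates$r1, replicates$r2)
  if (!is.null(germline)) paths <- c(paths, germline)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) stop("input path does not exist: ", missing[1L])
  if (!airr && is.null(germline)) stop("FASTQ input requires a germline set")
  structure(list(replicates = replicates, airr = airr, n_replicates = n,
                 germline = germline, extra_germline = extra_germline,
                 species = species, chain = chain, filter = filter,
                 umi_pattern = umi_pattern, umi_location = umi_location,
                 k_top_clones = as.integer(k_top_clones),
                 ms_rule = ms_rule %||% cleavage_rule(species), out = out),
            class = "run_config")
}

load_run_germlines <- function(config) {
  g <- load_germline_set(config$germline, config$species)
  if (!is.null(config$extra_germline))
    g <- merge_novel_alleles(
      g, load_germline_set(config$extra_germline, config$species))
  g
}

write_manifest <- function(dir, files) {
  files <- files[file.exists(files)]
  man <- data.frame(file = basename(files),
                    md5 = unname(tools::md5sum(files)),
                    size = file.size(files), stringsAsFactors = FALSE)
  utils::write.table(man, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(man)
}

write_all_stats <- function(records, dir, prefix) {
  p <- function(name) file.path(dir, paste0(prefix, name))
  combos <- vdj_combination_usage(records)
  files <- c(
    write_usage_table(shm_histogram(records), p("shm_histogram.tsv")),
    write_usage_table(cdr3_length_distribution(records),
                      p("cdr3_lengths.tsv")),
    write_usage_table(subgroup_usage(records, "V"), p("v_subgroups.tsv")),
    write_usage_table(subgroup_usage(records, "D"), p("d_subgroups.tsv")),
    write_usage_table(subgroup_usage(records, "J"), p("j_subgroups.tsv")),
    write_usage_table(combos$vj, p("vj_combinations.tsv")),
    write_usage_table(combos$vdj, p("vdj_combinations.tsv")),
    write_usage_table(isotype_distribution(records), p("isotypes.tsv")))
  files
}

export_chain_outputs <- function(records, config, dir, prefix = "") {
  p <- function(name) file.path(dir, paste0(prefix, name))
  files <- character(0)
  files <- c(files, write_annotation_tsv(
    records, p(paste0(config$chain, "_aa_sequence_annotations.tsv"))))
  files <- c(files, write_all_stats(records, dir, prefix))
  clones <- cluster_clones(records)
  files <- c(files,
             write_clone_summary(clone_summary(clones, config$k_top_clones),
                                 p("clones.tsv")),
             write_clonal_expansion(clones, p("clonal_expansion.tsv"),
                                    config$k_top_clones))
  iso_tab <- isotype_table(config$species)
  ms <- append_cleavage_suffix(records, config$ms_rule, iso_tab)
  files <- c(files, write_ms_fasta(ms, p("V_H_AA_sequences.fasta")),
             aa_to_dna_map(records, p("V_H_AA_TO_DNA_reads.fasta")))
  files
}

#' Run the individual analysis for one replicate
#'
#' Executes merge -> UMI -> annotate -> filter -> isotype -> statistics ->
#' clones -> exports for one replicate and writes a manifest. With AIRR
#' input the merge/UMI stages are skipped (and the skip logged).
#'
#' @param config a [run_config()].
#' @param i replicate index.
#' @return invisible list with `records`, `report` (filter report, FASTQ
#'   path only) and `dir` (the result directory).
#' @export
run_individual <- function(config, i) {
  dir <- file.path(config$out, paste0("replicate_", i))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(dir, "run.log")
  log_line <- function(...) cat(..., "\n", sep = "", file = logf,
                                append = TRUE)
  if (config$airr) {
    log_line("stage ingest_airr: ", config$replicates[i],
             " (merge/UMI stages skipped)")
    records <- ingest_airr(config$replicates[i])
    report <- NULL
  } else {
    germlines <- load_run_germlines(config)
    pairs <- read_fastq_pair(config$replicates$r1[i],
                             config$replicates$r2[i])
    log_line("stage read: ", nrow(pairs), " read pairs")
    n_umi_unmatched <- 0L
    if (!is.null(config$umi_pattern)) {
      eu <- extract_umi(pairs, config$umi_pattern, config$umi_location)
      pairs <- eu$pairs
      n_umi_unmatched <- eu$n_unmatched
      log_line("stage umi: ", n_umi_unmatched, " reads UMI-unmatched")
    }
    mg <- merge_read_pairs(pairs)
    merged <- mg$merged
    log_line("stage merge: ", nrow(merged), " merged, ",
             mg$n_no_overlap, " without overlap")
    if (!is.null(config$umi_pattern)) {
      merged <- collapse_umi_groups(merged)
      log_line("stage collapse: ", nrow(merged), " consensus molecules")
    }
    ann <- annotate_reads(merged, germlines, config$chain)
    alog <- attr(ann, "log")
    log_line("stage annotate: ", nrow(ann), " annotated; ",
             alog[["n_unannotatable"]], " unannotatable; ",
             alog[["n_cdr3_undefined"]], " cdr3-undefined")
    fl <- apply_filters(ann, config$filter, mg$n_no_overlap)
    report <- fl$report
    log_line("stage filter: ", report[["retained_count"]], " retained")
    write_filter_report(report, file.path(dir, "filter_report.tsv"))
    ann <- assign_isotypes(fl$retained, isotype_table(config$species))
    records <- build_annotation_records(ann)
  }
  files <- export_chain_outputs(records, config, dir)
  write_manifest(dir, c(files, file.path(dir, "filter_report.tsv")))
  invisible(list(records = records, report = report, dir = dir))
}

#' Run the joint analysis across all replicates
#'
#' Runs [run_individual()] for every replicate, then aggregates the
#' records, writes the correlation matrix, Venn table, joint statistics,
#' joint clones, joint FASTA and the MS-ready database. With a single
#' replicate the joint stage is skipped with a notice.
#'
#' @param config a [run_config()].
#' @return invisible list with `individual` (per-replicate results),
#'   `joint` (the `joint_repertoire`, or `NULL` for one replicate) and
#'   `dir`.
#' @export
run_joint <- function(config) {
  indiv <- lapply(seq_len(config$n_replicates), function(i)
    run_individual(config, i))
  if (config$n_replicates < 2L) {
    message("single replicate: joint analysis skipped")
    return(invisible(list(individual = indiv, joint = NULL,
                          dir = config$out)))
  }
  joint <- aggregate_replicates(lapply(indiv, `[[`, "records"))
  dir <- file.path(config$out, "joint")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  files <- c(files, {
    p <- file.path(dir, "joint_annotations.tsv")
    write_joint_annotation_tsv(joint, p); p
  })
  cm <- correlation_matrix(joint)
  pcor <- file.path(dir, "correlation_matrix.tsv")
  utils::write.table(cm, pcor, sep = "\t", quote = FALSE)
  vc <- venn_counts(joint)
  pvenn <- file.path(dir, "venn_counts.tsv")
  utils::write.table(data.frame(region = names(vc), count = vc),
                     pvenn, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, pcor, pvenn)
  files <- c(files, export_chain_outputs(joint$records, config, dir,
                                         prefix = "joint_"))
  pfa <- file.path(dir, "joint_sequences.fasta")
  joint_fasta(joint, pfa)
  files <- c(files, pfa)
  write_manifest(dir, files)
  invisible(list(individual = indiv, joint = joint, dir = config$out))
}
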