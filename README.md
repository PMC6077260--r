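# igseqr

End-to-end analysis of antibody variable-region sequencing (Ig-Seq /
AIRR-Seq) data, from raw paired-end reads to annotated repertoires, clonal
decompositions, multi-replicate reproducibility measures, and
proteomics-ready sequence databases.

## The problem

B cells diversify their immunoglobulin genes by V(D)J recombination and
somatic hypermutation (SHM). Sequencing the rearranged variable region of
the antibody repertoire — typically in several independent replicates of
the same sample — produces reads that must be merged, quality-filtered,
assigned to germline V, D and J genes, translated, and grouped into
**clones** before any biology can be read off. igseqr implements that
pipeline as a library of composable functions plus a small command-line
front end.

Two definitions anchor everything downstream:

- A **clone** is the set of sequences sharing an identical CDRH3
  (heavy-chain complementarity-determining region 3) amino-acid sequence —
  the hypervariable loop that dominates antigen binding.
- Each clone carries two sizes: **`y`**, its total read (or UMI-consensus
  molecule) count, and **`x`**, the number of *distinct* amino-acid
  sequences among its members. `x <= y` always; a large `y` with small `x`
  is an expanded clone of near-identical cells, while `x` close to `y`
  indicates ongoing diversification.

## What the pipeline does

1. **Preprocess** — merge paired-end mates over their overlap (disagreements
   resolved by Phred quality), optionally extract and collapse unique
   molecular identifiers (UMIs) into per-molecule consensus sequences, then
   filter: in-frame stop codons, length < 300 nt, mean quality < Q20. Every
   input read is accounted for: retained + rejected counts always sum to
   the input.
2. **Annotate** — assign V/D/J germline alleles against a user-supplied
   reference set, count V-region mutations, delineate CDR3
   anchor-to-anchor, and group reads into records keyed by chain, isotype,
   sequence, V/J allele and CDR3. Pre-annotated AIRR rearrangement TSVs can
   be ingested instead of FASTQ.
3. **Isotype** — locate the framework-4 anchor (`VTVSS` human; `VTVSS` /
   `LTVSS` / `VTVSA` mouse) and match the few constant-region residues
   beyond it against per-species fingerprint peptides, tolerating one
   mismatch (IgM/IgD/IgG/IgA/IgE; human IgA1/IgA2 resolved when the read
   reaches the discriminating tail).
4. **Repertoire statistics** — SHM profiles with synonymous /
   non-synonymous (Ka/Ks) stratification, CDR3 length distributions, V/D/J
   subgroup and combination usage, isotype distributions.
5. **Clonal analysis** — cluster by CDRH3, report the top 100 clones by
   `y`, and for each clone a center-star multiple alignment, plurality
   consensus, most-similar representative, and position-weight logo matrix.
6. **Joint analysis** — aggregate 2–6 replicates, quantify reproducibility
   by pairwise Pearson correlation of clone counts and Venn intersection
   counts, and export joint annotation tables and FASTAs.
7. **Proteomics export** — write variable-region amino-acid databases with
   trypsin cleavage-site suffixes (`ASTK` human, `AK` mouse) appended after
   the framework-4 anchor, plus the amino-acid-to-DNA read map, for mass
   spectrometry database search.
8. **Simulation** — a fully seeded repertoire simulator (germline set,
   clones, SHM, sequencing error, UMIs, paired-end FASTQ) with complete
   ground truth, used throughout the test suite.

## Worked example

Simulate a small two-replicate run and analyze it end to end:

```r
library(igseqr)

cfg <- sim_config(seed = 7, n_clones = 6, n_reads = 250, n_replicates = 2,
                  shm_rate = 1, seq_error_rate = 0)
run <- simulate_run(cfg, "ex_sim")           # FASTQ + germline + truth

rcfg <- run_config(run$fastq[, c("r1", "r2")], run$germline_fasta,
                   species = "mouse", out = "ex_out")
res <- run_joint(rcfg)                       # per-replicate + joint analysis

cl <- cluster_clones(res$individual[[1]]$records)
head(cl[, c("cdrh3_aa", "x", "y")], 4)
#>   cdrh3_aa  x   y
#> 1  CFASRLL 18  26
#> 2   CRESLL 29  48
#> 3   CTHKSS 77 137

round(correlation_matrix(res$joint), 3)
#>       rep1  rep2
#> rep1 1.000 0.958
#> rep2 0.958 1.000

venn_counts(res$joint)
#>   1   2 1+2
#> 115 117   9
```

(The 9 shared clones are the 6 simulated ones plus hypermutated CDR3
variants that happened to recur; singletons in the `1` / `2` classes are
SHM-derived CDR3 variants private to one replicate.)

Each replicate directory contains the filter report, annotation table,
usage and distribution TSVs, clonal expansion report, the proteomics FASTA
(`V_H_AA_sequences.fasta`) and its DNA map, a manifest with checksums, and
a run log:

```text
ex_out/replicate_1/cdr3_lengths.tsv
ex_out/replicate_1/clonal_expansion.tsv
ex_out/replicate_1/clones.tsv
ex_out/replicate_1/filter_report.tsv
ex_out/replicate_1/IGH_aa_sequence_annotations.tsv
ex_out/replicate_1/V_H_AA_sequences.fasta
...
ex_out/joint/correlation_matrix.tsv
ex_out/joint/venn_counts.tsv
```

The same analyses are available from the command line via
`inst/scripts/igseqr-cli.R` (subcommands `individual`, `joint`,
`simulate`), driven by a small `key = value` config file.

## License

MIT (see `LICENSE`).
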