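---
title: "Methods: the igseqr antibody repertoire pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the igseqr antibody repertoire pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette records what the pipeline computes, the parameter choices and
their rationale, the numerical conventions, and the places where the
behavioral contract left a genuine design decision to this implementation.
It is a methods document, not a tutorial; see the README for a worked
example.

## Problem and model

Ig-Seq / AIRR-Seq experiments sequence the rearranged variable region of
antibody heavy (and optionally light) chains. Each sequenced molecule is a
V(D)J rearrangement: a germline V gene, for heavy chains a D gene, and a J
gene, joined with junctional diversity and possibly carrying somatic
hypermutation (SHM). The pipeline turns paired-end reads from one to six
replicates of such a library into:

1. per-replicate annotated sequence records,
2. repertoire statistics (SHM, Ka/Ks, CDR3 lengths, gene usage, isotypes),
3. a clonal decomposition with per-clone alignments and consensus,
4. joint multi-replicate reproducibility measures, and
5. a proteomics-ready FASTA database of variable regions.

A **clone** is the set of sequences sharing an identical CDRH3 amino-acid
sequence. For each clone two sizes are reported: `y`, the total read (or
consensus-molecule) count, and `x`, the number of *distinct* amino-acid
sequences among its members. By construction `x <= y`; the ratio reflects
within-clone variant diversity.

## Preprocessing

**Paired-end merging** (`merge_pair`, `merge_read_pairs`). The reverse mate
is reverse-complemented and slid along the forward mate over all overlap
offsets of at least `min_overlap = 20` nt. Each offset is scored as
`matches - 2 * mismatches`; offsets whose mismatch fraction exceeds 10% of
the overlap are rejected outright. The best-scoring offset wins (ties go to
the longer overlap). Within the overlap, disagreeing positions take the base
with the higher Phred score, ties going to the forward mate; the merged
quality at each overlap position is the element-wise maximum. Pairs with no
admissible overlap are counted as `rejected_no_overlap` and excluded before
filtering.

**UMI handling** (`extract_umi`, `collapse_umi_groups`). A UMI pattern such
as `"NNNNN"` is matched at the 5' end of the forward mate, the reverse mate,
or both. `N` positions capture whatever base the read carries; fixed A/C/G/T
pattern positions must match exactly or the read is dropped as unmatched.
Captured bases are removed from the read. After merging, reads are grouped
by exact UMI; within a group, reads of the modal length are collapsed to a
per-column plurality-vote consensus (quality-weighted on ties), while
off-modal-length reads remain singletons. The consensus record's `count` is
the number of reads it absorbed — counts stay in *read units* throughout, so
the conservation invariant (inputs = retained + rejected, summed in reads)
holds across the UMI stage. Molecule-level multiplicities remain available
as the number of consensus records.

**Filtering** (`apply_filters`, `filter_config`). Merged sequences are
rejected, in fixed priority order: (1) in-frame stop codon, (2) length below
`min_length = 300` nt, (3) mean Phred quality below `min_quality = 20`.
A sequence failing several criteria is counted once, under the
highest-priority one. The 300 nt floor corresponds to the shortest credible
full variable region plus isotype-bearing constant-region stub; Q20 is a 1%
per-base error ceiling. The filter report records input, retained, and each
rejection class, and errors out if they fail to sum.

## Annotation

Germline V, D and J reference sets are supplied as FASTA
(`load_germline_set`); allele names follow the `IGHV1-2*01` convention and
`subgroup_of` derives the subgroup (`IGHV1`). Reads are aligned to every
allele of the appropriate set with Biostrings' global-local alignment, and
the highest-scoring allele is assigned; V mutation counts are mismatches
within the aligned span (`count_shm`). D assignment (`assign_d`) runs on the
junction between the V and J alignments and picks the allele with the
longest exact contiguous match, requiring at least 5 nt to call a D at all
(below that, random matches dominate).

CDR3 is delineated anchor-to-anchor and *anchor-inclusive*: from the
conserved cysteine codon at the 3' end of V through the conserved
W/F-G-X-G-derived anchor at the 5' end of J, both ends included. This is the
common "junction" convention and keeps CDR3 a substring of the translated
read. Reads whose anchors cannot be located (truncations, heavy mutation)
get an undefined CDR3 and are excluded from clonal analysis but retained in
the record table.

Records (`build_annotation_records`) group reads by the full identity key —
chain, isotype, nucleotide sequence, V/J allele, CDR3 — so two reads with
identical variable regions but different isotypes stay distinct records;
collapsing across isotypes would silently erase class-switch information.
Each record keeps its member reads' 0-based input indices, making every
downstream number traceable to raw reads. Pre-annotated AIRR rearrangement
TSVs can be ingested directly (`ingest_airr`); rows with stop codons are
dropped and the same grouping applies.

## Isotype assignment

The isotype is read from the few constant-region amino acids that survive
3' of the variable region. `locate_fr4_anchor` finds the *rightmost*
occurrence of the species' framework-4 anchor (`VTVSS` for human; `VTVSS`,
`LTVSS` or `VTVSA` for mouse) in the translated read; the residues after it
are compared against fingerprint peptides per species (human: IgM `GSASAPT`,
IgD `APTKAP`, IgG `ASTKGPS`, IgA `ASPTSP` with the longer `A1`/`A2`
extensions to split subclasses, IgE `ASTQSP`; mouse: IgM `ESQSFP`, IgD
`GDKKEP`, IgG `AKTTAP`/`AKTTPP`, IgA `ESARNP`, IgE `ASIRNP`). A fingerprint
matches if the post-anchor tail begins with it allowing at most **one**
mismatch — a tolerance of exactly one sequencing or SHM error, chosen
because two mismatches on 6–7-mer peptides begin to cross between isotype
fingerprints. Human IgA reads long enough to cover the A1/A2 extension are
subclassed; shorter ones are reported as `IgA`.

## Repertoire statistics

`mutation_profiles` summarizes per-record V-region SHM; `shm_histogram`
bins it. `ka_ks` classifies each mutated codon by comparing its translation
to the germline codon's: a changed amino acid counts toward Ka, a silent
change toward Ks, each codon counting once regardless of how many of its
bases changed (a codon is a single mutational event at the protein level).
Counts are normalized per mutated codon; the ratio is `Ka/Ks`, `NA` when
`Ks = 0`. `cdr3_length_distribution`, `subgroup_usage`,
`vdj_combination_usage` and `isotype_distribution` report proportion tables
summing to 1; per-record statistics weight each *record* once (votes), not
by read count, so one giant clone cannot masquerade as a repertoire-wide
trend.

## Clonal analysis

`cluster_clones` groups records by identical CDRH3 amino-acid sequence
(heavy chains only by default) and reports `x`, `y` and member lists;
`top_k_clones` ranks by `y` (ties by `x`, then lexicographic CDRH3 for
determinism) and keeps `k = 100` clones — enough to cover the expanded
component of a typical repertoire while keeping reports reviewable.
Per-clone multiple sequence alignment uses center-star alignment: the
member closest on average to the others is the star, every member is
pairwise-aligned to it, and gaps are merged ("once a gap, always a gap").
Center-star is O(n²) pairwise alignments, gives the classical 2-approximation
to the optimal SP-score alignment, and is fully deterministic — appropriate
for intra-clone alignments where members differ by point mutations.
`clone_consensus` takes the per-column plurality residue and drops columns
where the gap is the plurality; `sequence_logo_matrix` returns the
count-weighted per-column residue frequency matrix.

## Joint analysis

`aggregate_replicates` accepts 2–6 replicates (7+ is refused — the cap
mirrors the intended experimental design of at most six aliquots) and
unions their clone keys into a clone-by-replicate count matrix.
`pairwise_correlation` computes the Pearson correlation of per-clone counts
for each replicate pair, either over the union (absent = 0) or the
intersection of clones; `correlation_matrix` assembles the symmetric matrix
with unit diagonal. Zero-variance vectors yield `NA` with a warning rather
than an arbitrary value. `venn_counts` reports, for every nonempty subset
of replicates, the number of clones seen in exactly that subset.
`joint_fasta` writes the union of variable-region amino-acid sequences with
per-replicate provenance encoded in the headers.

## Proteomics database export

`append_cleavage_suffix` truncates each variable-region amino-acid sequence
at the end of the framework-4 anchor and appends the species' trypsin-site
suffix — `ASTK` (human) or `AK` (mouse) — so that in-silico tryptic digest
of the database produces the same C-terminal peptides as digestion of the
real antibody. Sequences without a locatable anchor are passed through with
a warning rather than silently dropped: a proteomics search can still use
them, and the warning preserves auditability. `aa_to_dna_map` writes the
inverse map from each database entry to its supporting nucleotide sequences
and read indices.

## Simulator scope

`simulate_repertoire`/`simulate_run` generate a seeded synthetic ground
truth: a germline set (random V genes with a fixed 3' cysteine anchor,
J genes with deterministic, pairwise-distinct CDR3 codons and an FR4
anchor), clones with chosen V/D/J, CDR3, isotype, replicate membership and
sizes, per-molecule SHM (Poisson), per-base sequencing error, optional
UMIs with configurable reads per UMI, and paired-end FASTQ emission with a
two-tier quality model. The simulator is deliberately simple: uniform
base-substitution errors, no indels, no chimeras, no quality-dependent
error profile, no biased gene usage. Tests passing on it demonstrate the
pipeline's bookkeeping and algorithms are correct under the model's
assumptions; they do not demonstrate robustness to real instrument error
profiles, indel-induced frameshifts, or primer artifacts.

## Numerical and representational conventions

- All internal coordinates are 0-based, half-open; conversion to R's
  1-based indexing happens only at the `substr()` boundary.
- Phred qualities are Phred+33 throughout.
- Translation is a direct codon-table lookup (standard genetic code);
  incomplete trailing codons are dropped, ambiguous codons give `X`, and
  there is **no** initiator-codon special-casing — reads are arbitrary ORF
  windows, not mRNA starts, so translating a leading `TTG`/`CTG` as `M`
  would be wrong.
- Ties anywhere (merging, voting, ranking) break deterministically:
  higher quality, then forward mate; larger `y`, then `x`, then radix-sorted
  lexicographic order. Given the same inputs and seed, every output file is
  byte-identical across runs.
- Problem sizes in the test and acceptance suites (for example 150 clones
  for the top-K check, 2,000 reads per replicate for end-to-end recovery)
  are this package's own choices: large enough that the property under test
  cannot pass by accident, small enough to run in seconds.

## Decisions the contract left open

- **UMI collapse ordering**: collapse happens after merging and before
  filtering, so consensus molecules are what get filtered and every
  rejection class is expressed in read units.
- **Mean-quality filter**: "quality below Q20" is read as the *mean* Phred
  score of the merged sequence, not a per-base minimum; a per-base minimum
  at Q20 would reject nearly every real read.
- **Record identity includes isotype**: see the annotation section.
- **Anchor-inclusive CDR3**: see the annotation section.
- **Truncate-then-suffix** in the proteomics export: the suffix replaces,
  rather than follows, any sequenced constant-region residue, so the
  database never contains a partial constant-region fragment between the
  variable region and the appended cleavage site.
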