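---
title: "Reconstructing near full-length 16S amplicons from dual molecular tags"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing near full-length 16S amplicons from dual molecular tags}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(longamp)
```

## The problem

Short-read amplicon surveys of the 16S rRNA gene usually sequence a single
hypervariable sub-region (often V4, ~250 nt), which caps taxonomic resolution
at roughly the genus or family level and cannot separate closely related
strains. Dual molecular tagging works around the read-length limit: every
template molecule in a sample receives a random 10-nt oligonucleotide on
*both* ends before amplification, the tagged amplicons are partly fragmented
by tagmentation, and 2×250 nt paired reads are grouped afterwards by their
tag pair so that each group can be assembled back into the >1300 nt molecule
it came from. The approach yields near full-length 16S sequences from a
standard short-read run, resolves strains that differ at a single
nucleotide, and exposes PCR chimeras and tag collisions as assembly
failures rather than silent artefacts.

`longamp` implements the complete workflow — a ground-truthed library
simulator, tag-based reconstruction, open-reference OTU clustering,
alpha-diversity statistics, and strain-level haplotype analysis — as a set
of tibble-first functions that chain with the pipe, plus `run_all()` to
execute everything from one validated configuration.

## The simulator and what it emulates

`generate_reference_templates()`, `compose_samples()`, `tag_and_amplify()`
and `fragment_and_sequence()` produce paired FASTQ-ready reads with a truth
table mapping every read to its source molecule. The physical model:

* **Amplicon layout.** A molecule is
  `barcode5 + tag5 + 27F + template + rc(1391R) + rc(tag3) + rc(barcode3)`.
  Barcodes are 8 nt with pairwise Hamming distance ≥ 3 (generated greedily);
  tags are uniform over $4^{10}$ per end, so collisions are essentially
  absent at desk scale unless forced (`collision_mode = "forced_k"`).
* **Community structure.** Samples belong to units (a fruit or a rearing
  colony); larvae in one unit share a taxon pool. Wild units draw richness
  from 3–5 taxa, domesticated from 1–3, and a dominant acetic-acid-bacterium
  analog is present in ~55/56 of samples with the largest molecule share.
  Templates carry concrete instances of the 515F/806R motifs at an interior
  position so the V4 sub-region is extractable, and strain variants differ
  from their base template by single substitutions at recorded positions.
* **Sequencing.** Read pairs come from two sources at a 1:7 molar ratio:
  intact amplicons (mate 1 reads the 5' tagged end, mate 2 the 3' tagged
  end — the pair observes both tags; at least two such pairs per molecule,
  since end observation is what the protocol guarantees) and tagmented
  fragments that keep one tagged end, 400–1000 nt long. Fragment sizes are
  drawn by stratified sampling with jitter across that window, split evenly
  between the two anchored ends: at the depths used here (tens of pairs per
  molecule, default 40; the original libraries ran far deeper) independent
  uniform draws would leave stochastic tiling gaps that say nothing about
  the method, while stratification represents the same size window at the
  depth available.
* **Errors.** PCR substitutions are applied per sequenced fragment at the
  effective rate $1-(1-r)^{c}$ for per-base/per-cycle rate $r$ (default
  $10^{-5}$) over $c = 35$ cycles — each fragment derives from a distinct
  amplified copy, so independent draws are the right marginal model (lineage
  correlations between copies are ignored). Sequencing substitutions default
  to 0.001/base with constant phred+33 qualities at the matching score
  (Q30). Chimeras (default 1% of molecules) fuse two same-sample molecules
  at a uniform breakpoint, keep the 5' parent's tag5 and the 3' parent's
  tag3, and receive read depth scaled by $2^{-\text{cycle}}$ for a formation
  cycle drawn from 2–7: only early-cycle chimeric products are abundant
  enough to sequence, and that low abundance is precisely why the
  completeness filter catches them.

What the simulator does **not** model: indels (configurable off by default,
and the assembler is correspondingly ungapped), quality decay along the
read, GC or position bias, multiple 16S operon copies per genome, and
flow-cell artefacts. Passing tests on this generator therefore demonstrate
the pipeline's logic — binning, assembly, filtering, statistics — not
robustness to every failure mode of real MiSeq data.

## Reconstruction

`trim_and_annotate()` classifies each mate by its prefix (exact barcode,
10-nt tag, primer with ≤ 2 IUPAC-aware mismatches), strips the prefix from
end reads, and quality-trims 3' tails with a width-4 sliding window
(floor Q15). Reads with a primer layout but an unknown barcode go to an
"unassigned" pool and are never assembled — their prefix is still attached.

`bin_reads()` keys bins on the canonical (tag5, tag3) pair: a pair whose
mates carry both tags defines a key; single-tag pairs join the unique
credible key (observed ≥ `min_tag_count` = 2 times) carrying their tag;
tag-less pairs are placed by best k-mer containment against each bin's
end-read payloads, or dropped if no unique winner emerges. Keys observed
once are classified error-tag bins — the singleton mode of the raw tag-count
histogram — and excluded. With `tag_merge_distance = 1`, a tag seen once
within Hamming distance 1 of a credible tag is absorbed instead (off by
default; exact matching is the stricter, more conservative choice).

`assemble_bin()` is a deliberately small overlap-layout-consensus engine:
optional in-bin k-mer correction (a base whose spanning 15-mers are all
singletons is replaced by the unique alternative whose 15-mers are trusted,
count ≥ 3), then greedy ungapped placement of reads (either orientation)
against the growing consensus, seeded by shared k-mers and accepted at
≥ 20 nt overlap with ≤ 5% mismatches. Consensus is per-column majority;
exact ties emit IUPAC ambiguity codes, which is where the degenerate
nucleotides seen in representative sequences come from. Scaffolds are
numbered by decreasing length from 0; a **complete** assembly has exactly
one scaffold of 1300–1500 nt (inclusive bounds — the narrative "> 1300 nt"
and the definition "1300–1500 nt" disagree at the boundary, and the
inclusive reading is implemented and configurable). Ungapped placement is a
real limitation for indel-rich platforms; it is exact for the
substitution-only error model simulated here, and per-bin read counts (tens)
keep the greedy layout well inside the regime where it matches exhaustive
search.

Tag collisions produce bins mixing two templates; random templates share no
seed k-mers, so such bins split into multiple scaffolds and fail the filter,
as do chimera keys (too few reads to tile) — `evaluate_against_truth()`
quantifies both against the simulator's truth.

## Identity, clustering and pooling

`pairwise_identity()` aligns globally with free terminal gaps (IUPAC-aware
+1/−2 matrix, gap open 4, extend 2) and reports compatible aligned columns
divided by the **longer** sequence length. The denominator matters: with
terminal-gap columns simply excluded, any short suffix–prefix match between
unrelated sequences would score 1.0 and 100% clustering would collapse
everything. With the longer-length denominator, identity 1.0 coincides with
string equality for plain ACGT inputs (so 100% clustering is exact
deduplication), a single substitution over 1400 nt gives 1399/1400, `"ARG"`
matches `"AAG"` at 1.0, and terminal length variants fall just below 1.0 —
they are handled by the dedicated pooling rule instead, mirroring how such
pairs first appeared as separate OTUs and were pooled on inspection.

`cluster_open_reference()` runs the two-step open-reference procedure:
closed-reference assignment to the best reference hit at ≥ 99% identity,
then greedy de novo clustering of the remainder in a fixed order
(length ↓, abundance ↓, lexicographic — determinism over speed; no
word-index heuristics are reproduced, full pairwise identity is affordable
at desk scale). OTUs with fewer than two sequences are discarded;
`pool_equivalent_otus()` merges representatives equal under IUPAC
compatibility up to a ≤ 4 nt terminal overhang; `remove_taxon()` drops
chloroplast ("Streptophyta") OTUs while keeping emptied sample columns.
Counts are conserved across all three steps (table + discarded singletons +
removed taxa = input).

## Diversity statistics

`rarefy()` subsamples without replacement (the observed-species metric's
standard definition), by default at depths 10–260 in steps of 10 with 1000
iterations; tests check it against the closed-form hypergeometric
expectation and `vegan::rarefy`. `mann_whitney_one_tailed()` implements the
U test three ways and reports which was used: the exact tie-free null
distribution by the counting recurrence for $n_a+n_b \le 25$; full
enumeration of group assignments when ties are present and
$\binom{n}{n_a} \le 2\times10^5$; otherwise the normal approximation with
tie and continuity corrections. On the packaged per-larva fixture
(35 wild vs 23 domesticated OTU counts, ties abundant) the normal route
applies and gives $p \approx 0.0012$ for wild > domesticated. The two
larvae that yielded no sequences are included by default — a zero OTU count
is real data — and `fixture_richness_test(FALSE)` shows the verdict is
unchanged without them ($p \approx 0.0002$). No multiple-testing correction
is applied: one planned comparison. `rank_abundance()` uses the strict
"> 50 sequences" cutoff with deterministic id-ordered ties, and
`relative_abundance_by_taxon()` pools greengenes-style labels at family or
genus rank, routing OTUs with ≤ 5 sequences to "Other".

## Strain haplotypes and the V4 comparison

`cluster_unique()` groups a focal OTU's members by exact string equality
(uppercase-normalised): length variants and ambiguity codes are distinct
haplotypes, so a representative carrying `R` is a different haplotype from
one carrying `A` — consistent with ambiguity codes appearing as variant
bases. `extract_v4()` takes the subsequence strictly between the best
IUPAC-aware matches of the 515F motif and the reverse complement of 806R
(≤ 2 mismatches each; motifs are configurable since the exact extraction
coordinates are a documented choice) and masks every non-ACGT character to
N — masking applies to the V4 analysis only. `variant_table()` aligns the
top five haplotypes anchored on the most abundant one, derives the
abundance-weighted majority consensus and lists 1-based differing positions;
applying a row's variants to the consensus reconstructs its representative
exactly (a tested invariant). Because masking and truncation can only merge
classes, the V4 haplotype count never exceeds the full-length count —
strictly fewer whenever a variant lies outside the V4 window, which is the
quantitative sense in which near full-length sequences resolve more strain
structure.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally (truth intervals); variant
  tables and motif positions are 1-based for people.
* A single top-level seed deterministically derives per-stage seeds
  (`derive_seed()`), and identical configurations give byte-identical
  outputs; the run manifest records the seed and a parameter hash.
* Empty inputs degrade explicitly: empty bins → empty output, single-read
  bins → `insufficient_reads`, empty assembly set → map-back 0 with a
  warning, all-zero count vectors → empty rarefaction curve, fewer than two
  haplotypes → an annotated empty variant table.
* Problem sizes in the tests: error-free correctness on 40 molecules,
  realistic recovery on 200 molecules at default settings (≥ 95% exact
  recovery of non-chimeric, non-collided molecules; ≥ 90% chimera
  exclusion), dedup equivalence on 1000 sequences, Mann-Whitney oracle
  checks over all-random small cases. These sizes were chosen as the
  smallest at which each property is meaningfully exercised.

## Known limitations

Real 16S data contain indels, chimeras formed between more than two
parents, intragenomic 16S copy variation and reference databases far larger
than a simulated template set; none of these are modelled, and the
clustering here looks taxonomy up in the user-supplied reference rather
than running a classifier. The Mann-Whitney enumeration route is
exponential and intentionally capped; beyond the cap the corrected normal
approximation is reported as such.
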