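---
title: "Classifying and summarizing chimeric RNA landscapes"
author: "chimerascape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying and summarizing chimeric RNA landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chimerascape)
```

## The problem

Paired-end RNA-seq followed by a split-read fusion caller (SOAPfuse and its
relatives) yields, per sample, a table of candidate chimeric junctions: two
partner gene symbols, per-side chromosome, strand and breakpoint coordinate,
and supporting read counts. Such call sets — including those from
non-cancerous cells, where chimeric RNAs arising from intergenic splicing
are now well documented — are noisy and heterogeneous. Before any biology
can be read off them they need systematic annotation: which junctions
coincide with known splice sites, how the parental genes relate to each
other on the genome, and whether the fusion could preserve the 3′ partner's
reading frame. `chimerascape` implements exactly this annotation layer, plus
the bookkeeping around it, as a tested R package. It begins where the caller
ends: read alignment and split-read discovery are out of scope.

## The three classifications

**Junction type (E/M taxonomy).** A junction side is called **E** when its
coordinate coincides with an annotated exon edge of its parental gene, taken
in transcription orientation: the 5′ side is compared against donor edges
(exon 3′ ends; on the minus strand these are the lower genomic coordinates)
and the 3′ side against acceptor edges (exon 5′ starts). Edges are pooled
across all isoforms of the gene, since a junction may be exonic in one
isoform only. A side that matches no edge is **M** (in practice mid-exon,
but also intronic or intergenic coordinates fall here). The four-way label
E/E, E/M, M/E, M/M lists the 5′ side first. The boundary comparison is exact
(`tol = 0`) by default: no tolerance window is part of the definition of a
"known" boundary, and exactness is the conservative choice; callers with
imprecise breakpoints can widen it via `tol`.

**Locus type.** `INTERCHR` when the partners lie on different chromosomes.
`READ_THROUGH` — the cis-splicing-between-adjacent-genes (cis-SAGe)
configuration — when both genes share a strand, the 5′ partner lies upstream
in transcription orientation, and at most `max_intervening` genes on that
same strand lie wholly between their spans. Everything else on a single
chromosome (reversed order, opposite strands, non-neighbouring) is
`INTRA_OTHERS`. Strict adjacency (`max_intervening = 0`) is the default,
matching the established read-through convention; opposite-strand genes
between the partners do not break adjacency because read-through transcription
runs through them on the other strand's template. Both knobs are plain
arguments, not hidden configuration.

**Frame type.** For each pair of coding isoforms (one per parent) the
package counts `r` = coding bases of the 5′ isoform retained at or upstream
of `pos5` (the last retained base) and `d` = coding bases of the 3′ isoform
strictly upstream of `pos3` (the first retained base). The pair is evaluable
only when both junction bases are themselves CDS bases of their isoform;
junctions in UTRs or introns of an isoform, and non-coding parents, make the
pair inert. An evaluable pair is in-frame exactly when `r ≡ d (mod 3)` —
splicing the retained 5′ coding prefix to the retained 3′ coding suffix then
keeps the 3′ codon boundaries intact. Aggregation over pairs: all in-frame →
`IN_FRAME`; all shifted → `FRAME_SHIFT`; mixed → `BOTH` (the outcome depends
on which splice isoform carries the chimera); none evaluable → `"NA"`.
Frame is evaluated for M sides too, as long as the junction base lies in
CDS: M/M fusions appear in frame summaries computed before filtering, so
they must be frame-classifiable. Whether a published analysis used one
canonical isoform per gene or all isoforms is generally not recoverable; the
per-pair outcome table returned by `predict_frame()` preserves enough
information for either convention.

The test suite validates the mod-3 rule against an independent
splice-and-translate oracle: build the chimeric mRNA from the genome, translate
it in the 5′ partner's frame, and check whether the protein suffix encoded
by the 3′ partner's own frame reappears verbatim. The two approaches agree on
every simulated coding construct.

**The M/M filter.** M/M junctions validate at a much lower rate and are
removed by `filter_mm()` before downstream interpretation. The filter is a
pure subset: it is idempotent, conserves counts
(`n_non_mm = n_all − n_MM`), and can only increase the E/E proportion
(the E/E count is untouched while the denominator shrinks) — a small theorem
the suite asserts on random inputs rather than on one example.

## Summaries, overlap, export

`summarize_landscape()` reports counts and exact proportions per scheme at a
named stage (`all` or `non_mm`); passing unfiltered data to the `non_mm`
stage is an error rather than a silent recount. Proportions are kept as
exact fractions and rounded only when printed. `compute_overlap()`
decomposes 2–5 per-sample sets into their disjoint Venn regions under either
junction-level identity (partner symbols plus both coordinates — the default,
consistent with how per-sample "unique fusion" counts are defined, since one
gene pair can produce two junction forms) or gene-pair identity.
`export_circos_links()` writes one 1-based single-base link per fusion,
tagged with its locus class, for standard Circos tooling. Figures
(`plot_landscape()`, `plot_overlap()`) are purely presentational.

Fusion identity deserves one note: `unique_fusions()` deduplicates at
junction resolution, keeping the row with the strongest junction-read
support, because validated examples exist of a single gene pair expressing
two distinct junction forms. Collapsing to gene pairs is offered only as an
overlap mode, never forced.

## Quantification arithmetic

`ddct()` implements the standard 2^−ΔΔCt relative-expression calculation:
replicate Cts are averaged arithmetically (the conventional choice; Ct is
already a log-scale quantity), the reference target (default `GAPDH`) is
subtracted within sample, the calibrator sample's ΔCt is subtracted, and the
result exponentiated. The calibrator returns exactly 1 and all fold changes
are invariant to a global Ct shift. `nc_ratio()` returns
2^−(Ct_nuc − Ct_cyt) for a fractionation experiment with *no* reference
normalization: fractionation controls (a cytoplasm-biased mRNA like GAPDH, a
nucleus-retained lncRNA like MALAT1) are themselves fraction-biased, so they
are reported as companion ratios instead of being divided out; equal input
loading of the two fractions is assumed.

`extract_junction_sequence()` produces the `k`-base flanks on each side of a
junction — the substrate for designing RT-PCR primers that anneal to the
parental genes and flank the junction. E sides follow the mature (spliced)
transcript of an isoform sharing the matched edge, since primers read cDNA;
M sides take the genomic path. Thermodynamic primer design (Tm, dimers) is
out of scope.

## What the synthetic data emulates

No public call sets accompany this kind of desk-scale analysis, so the
generator (`simulate_fusion_study()`) is a first-class module rather than a
test fixture. It emits a toy genome of random sequence, a GTF annotation,
per-sample call tables and a truth table with every fusion's three labels.

Defaults define the study conditions: 3 chromosomes × 20 genes, 3–6 exons of
100–300 bp per transcript, introns of 50–500 bp, intergenic gaps of
200–800 bp, 20% non-coding genes, UTRs of 12–45 / 12–60 bp — large enough
for real adjacency structure, small enough for sub-second generation. Five
fusions in each of the 12 locus × junction cells (60 total) with all four
frame classes rotated through every cell, three samples, and 20% of fusions
shared by all samples.

Construction is deliberately structural rather than rejection-sampled: genes
are laid out sequentially with a plus-strand block before a minus-strand
block (so same-strand neighbours exist on both strands) and non-coding genes
at a fixed spacing (so every locus class can host an NA-frame fusion with a
non-coding 3′ partner). E sides are placed exactly on generated exon edges
and M sides strictly inside exon bodies away from any pooled edge; in-frame
and frame-shift cases are built by choosing CDS positions with the required
mod-3 relation; `BOTH` cases add a second 3′-partner isoform whose CDS start
is shifted by one base (and such genes are then barred from any other
frame-evaluable fusion, which would otherwise retroactively change its
truth — for the same reason `BOTH` fusions are placed first). Exon-skipping
isoforms are added to a few unused non-coding genes to exercise
multi-isoform parsing without perturbing any truth label. Configurations
that cannot be realized (read-through with one gene per chromosome, NA
frames without non-coding genes) fail before any file is written.

Everything flows from a single seed: two runs with the same configuration
are byte-identical, and the generator restores the caller's RNG state.

The generator emulates the *class structure* of real call sets, not their
empirical texture: sequence is uniform random (no codon bias, no repeats, no
homology between partners), breakpoints are noiseless, read counts are
uniform draws, and per-class proportions are user-set rather than matched to
any published study. Passing tests therefore demonstrate that the
classifiers invert the construction exactly on annotation-faithful input —
not that they are robust to breakpoint slop, annotation mismatch or symbol
ambiguity, which real data exhibit and which the quarantine path
(`annotate_all()`'s rejects table) is designed to surface rather than hide.

`simulate_ct_table()` and `simulate_nc_table()` provide the same service for
the qPCR arithmetic: Cts derived from stated true fold changes or
localization ratios plus Gaussian replicate noise (default sd 0.1 cycles,
3 replicates). A 1000-table Monte-Carlo run recovers a 4-fold change with
mean error well under 2%.

## Numerical and design choices

- Coordinates are 1-based closed throughout, the GTF/GRanges convention;
  annotation coordinates are stored verbatim and no conversion layer exists.
  Gene models live in plain indexed data frames inside `GeneModelSet`, with
  GTF parsing delegated to `rtracklayer::import()` after a light pre-scan
  that produces line-numbered errors for malformed rows. CDS phase is
  recomputed from interval order; a disagreeing frame column earns a warning
  and the recomputed value wins.
- Caller symbols are resolved against `gene_name` first, then `gene_id`;
  ties are broken by requiring the gene span to contain the reported
  junction, and anything still ambiguous is quarantined with a reason.
  Unresolvable candidates never abort a batch.
- Deduplication ties (equal junction reads) keep the first row in input
  order; deduplicated output is sorted by (chrom5, pos5) for stable diffs.
- Empty stages are well-formed (zero counts, no proportions) rather than
  errors; an all-M/M input filtered to nothing is legal.
- Junction-sequence extraction clips at transcript or contig ends with a
  warning instead of failing, returning the bases that exist.
- The problem sizes used by the test suite and acceptance script — 60-fusion
  studies, 100 random label sets for the filter algebra, 1000 Monte-Carlo Ct
  tables — were chosen as the package's own desk-scale defaults; all run in
  seconds.

## Known limitations

- GTF only (Ensembl/GENCODE attribute dialect); no GFF3, and no chromosome
  alias resolution (`chr1` vs `1`) beyond what the user maps themselves.
- One caller dialect (SOAPfuse-like) with a configurable column mapping;
  STAR-Fusion/Arriba parsers would slot into the same mapping layer but are
  not included.
- Frame prediction is annotation-bound: it cannot see coding potential that
  short-read annotation misses, and desk-scale prediction of coding fate is
  known to disagree with fractionation evidence often enough that frame
  labels should be read as hypotheses, not conclusions.
- No protein-domain retention analysis and no DNA-level rearrangement
  inference; the package concerns RNA-level chimeras only.
- The annotation build is the user's choice and responsibility; the package
  is deliberately annotation-agnostic.
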