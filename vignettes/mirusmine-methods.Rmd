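---
title: "Methods: recovering mirusvirus genomes and their intron landscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: recovering mirusvirus genomes and their intron landscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope

Mirusviruses (*Mirusviricota*) are large double-stranded DNA viruses of
protists whose genomes are recovered almost exclusively as
metagenome-assembled genomes (MAGs). Unusually for viruses, many of their
genes carry spliceosomal introns, some of which harbour protein-coding
genes or behave as mobile elements (introners), and their terminase is
frequently assembled from two distant, trans-spliced gene fragments.

`mirusmine` implements the *decision layer* of a mirusvirus
genome-recovery and intron-annotation study: every rule that turns
upstream tool output (protein best-hit tables, gene prediction sets,
junction evidence, ANI tables, trees) into biological conclusions. The
upstream tools themselves (aligners, binners, gene predictors, tree
builders) are out of scope; their outputs are consumed as files. A
synthetic-community generator with complete truth tables stands in for
the upstream stack so that every rule is testable end to end.

## Contig taxonomy and MAG construction

A contig is assigned to a high-rank category (Bacteria, Archaea,
Eukarya, plastid, *Nucleocytoviricota*, *Mirusviricota*) when at least
25% of its proteins have their best hit in that category *and* that
fraction strictly exceeds every other category's. Ties therefore leave a
contig unassigned; this strictness is deliberate, since mis-assigned
contigs propagate into MAGs. Mirusvirus contigs additionally receive a
clade when at least half of their proteins best-match the same clade.
Contigs under 2,500 bp are dropped before any of this.

Per bin, contigs of one clade form a MAG; MAGs below 50 kb or above
650 kb are rejected (inclusive bounds survive: a 50 kb MAG is kept).
Bins whose marker-bearing contigs evade similarity-based assignment go
through a rescue cascade: bins over 1 Mb or with more than 25% of
proteins hitting the reference are excluded, then contigs under 10 kb or
with more than 10% cellular best hits, and the survivors form a
*putative* MAG when they total at least 50 kb. `iterate_binning()` runs
recruitment passes in which accepted MAG proteins are appended to the
reference database before the next pass; `n_iterations` counts these
growth passes after the initial one, so `n_iterations = 0` reduces to a
single `build_mags()`.

## Completeness, redundancy, dereplication

For each clade with at least ten genomes, single-copy core genes (sccg)
are the protein clusters present in exactly one copy in at least half of
the clade's genomes, where multiple occurrences on one contig collapse
to a single copy (intron-driven gene fragmentation would otherwise
inflate copy counts). Model vetting then drops sccg whose mean hit count
across genomes leaves [0.7, 1.5] or that yield exactly one hit in fewer
than 70% of genomes.

Completion is the percentage of sccg present at least once, redundancy
the percentage present at least twice, and the quality score is their
difference. Scored MAGs with quality below 50% or redundancy above 25%
are removed; genomes of clades too small to define sccg pass with an
`unscored` flag rather than being discarded — a deliberate choice, since
small clades carry most of the novel diversity. Genomes linked by
ANI >= 98% over at least 25% of the shorter genome are clustered by
single linkage (the tool-agnostic closure of pairwise links) and each
cluster keeps its highest-quality, then largest, member.

## Gene-model arbitration

Two independent prediction sets are merged: an intron-aware set (from a
spliced-alignment-trained predictor) and an intronless ORF set. The
intron-aware model wins wherever it exists, except for its two
characteristic failure modes:

* **Fusion.** A multi-exon model whose exons are all longer than 300 bp
  and each of which is covered >95% by a *distinct* ORF is replaced by
  those ORFs. "Distinct" is enforced by a maximum bipartite one-to-one
  matching between exons and ORFs; a greedy assignment could fail on
  overlapping ORFs.
* **Spurious short exon.** A two-exon model whose shorter exon is under
  5% of the longer one and whose genomic footprint is covered >95% by a
  single ORF is replaced by that ORF. The rule is restricted to two-exon
  models; the "second exon" in the 5% comparison is interpreted as the
  *longer* exon, which is the conservative reading (a short second exon
  of a long first exon triggers the same repair).

Overlap fractions use shared genomic bases over exon length (fusion) or
over model footprint (spurious exon). Inter-exon gaps must be at least
4 bp (donor plus acceptor); anything shorter is a validation error, not
an intron. Every substitution is recorded in a ledger so repairs can be
audited against a known corruption list.

## Introns and their analytics

Introns are the inter-exon gaps, with donor and acceptor dinucleotides
read 5'->3' on the coding strand: GT..AG is the major spliceosomal
class, AT..AC the minor class, anything else noncanonical. Each record
carries the oriented sequence and 10 bp exonic flanks.

*Density and enrichment.* Intron density is introns per kb of gene
sequence. The default denominator is the genomic footprint (first exon
start to last exon end), matching genome-scale per-kb figures; a summed
exon-length denominator is available (`footprint = FALSE`) and is the
scale on which a planted per-exonic-kb enrichment is recovered exactly —
on the footprint scale the extra intron bases of intron-rich genes
deflate the ratio by a predictable factor.

*Branch points.* `motif_fraction()` counts introns with at least one
IUPAC-motif match inside a window relative to the acceptor; the default
window [-40, -10] is a declared package default (typical branch points
sit 18-40 bp upstream of the 3' splice site), not a value inherited
from any upstream analysis. Discovery ranks k-mers (k = 5..7) by a
binomial upper-tail test of window occupancy against a
dinucleotide-preserving (Altschul-Erikson) shuffled background, with
Benjamini-Hochberg correction across all observed k-mers; motifs are
ordered by significance, since raw enrichment over-rewards long rare
k-mers that merely contain the true motif.

*Introners.* Candidate introners are groups of two or more introns from
the *same* genome whose flanked sequences align with a Karlin-Altschul
e-value below 1e-5. The aligner is an affine Smith-Waterman (match +2,
mismatch -3, gap open 5, gap extend 2; ungapped K = 0.41,
lambda = 0.625) implemented in C++ and cross-checked against an
independent dynamic-programming oracle in the tests. A pair is rejected
when the alignment consumes more than 2 bp of flank on *both* sequences
— similarity extending through the exon flanks indicates paralogous
genes, not a mobile intron; the 2 bp tolerance absorbs alignment end
jitter and is configurable. Pre-computed pair tables from an external
aligner can be supplied instead.

*Nested genes.* Introns longer than 300 bp (strict) are scanned on both
strands for ORFs (ATG to stop, standard code; start codons
configurable) longer than 100 aa. The scanner reports maximal ORFs, so
a planted ORF with an in-frame upstream ATG and no intervening stop is
reported with the longer extent; truth comparisons therefore test
containment, not equality. Target-gene specificity of intron-encoded
endonucleases is assessed with the Pearson chi-squared test (no
continuity correction) on contingency tables of target genes versus
endonuclease families; endonuclease family labels are inputs, as
structure-based annotation is out of scope.

*Trans-splicing.* A junction supported by at least ten reads whose donor
falls in one gene model and whose acceptor falls in a different one,
with canonical GT/AG genomic dinucleotides after strand orientation,
and either at least 1 kb of separation or opposite strands, is a
trans-splice event. The 1 kb floor is a package default — the
motivating biological case is ~30 kb apart — and exists to keep
tandem-gene read-through artifacts out.

## RED taxonomy

Relative evolutionary divergence (RED) normalizes node depth: the root
is 0, leaves are 1, and a node with parent RED $P$, parent branch $a$
and mean node-to-leaf distance $b$ gets $P + \frac{a}{a+b}(1-P)$. RED is
non-decreasing towards the leaves; zero-length subtrees inherit the
parent's value with a warning. Because the true root of the group is
unknown, RED is averaged over a set of candidate rootings (the tree is
rerooted at the midpoint of each candidate edge); nodes are matched
across rootings by their unrooted bipartition, values of nodes adjacent
to a rooting edge are averaged over the rootings where they exist and
flagged.

The candidate root list is an explicit input. The helper
`default_candidate_roots()` proposes basal edges plus bipartitions with
at least 5% of the leaves, but at desk scale (tens of leaves) the 5%
rule admits mid-depth edges, and rooting there systematically inflates
the averaged RED of shallow nodes; `run_pipeline()` therefore roots
only at the basal (root-child) edges, which corresponds to averaging
over the major deep-branching positions.

Orders are defined by each leaf's most recent ancestor with averaged
RED strictly below 0.22, families likewise below 0.65; leaves whose
family anchor covers no other leaf (including leaves with no qualifying
ancestor) are singleton families. Leaves sharing an anchor share the
rank, which makes the assignment automatically nested. Node support is
classed from dual supports: strong when SH-aLRT >= 80 *and*
UFBoot >= 95, moderate when exactly one holds, poor otherwise (missing
values count as unmet). Tree congruence is the Pearson correlation of
patristic distances over shared leaf pairs. Metagenomic marker proteins
are linked to an order only when their best database hit reaches 50%
identity and bitscore 100; weaker hits are "distant from the genomic
database".

## The synthetic community

`generate_community()` emulates, per genome: a 50-650 kb sequence cut
into 2-5 contigs; genes tiled at 0.7 genes per kb with exonic lengths
around 800 bp; introns planted at 0.2 per exonic kb with a log-normal
length model peaking at 80 bp; 3% minor-class (AT-AC) introns; a
branch-point motif (default WCTAAC) planted in 35% of introns inside
the search window; morphogenesis-labelled genes (5% of genes) with a
10-fold intron rate; three introner families of five identical copies
planted in one genome plus paralog-decoy pairs with identical flanks;
eight nested ORFs of 110-200 aa inside long introns; one terminase
split into two fragments 30 kb apart joined by a canonical junction;
cellular contaminant contigs at 30% of each bin; best-hit tables in
which 80% of viral proteins hit their own clade; per-clade sccg cluster
tables with 3% missingness and 2% duplication; an ANI table with one
planted redundant pair; and a clade tree with order stems at RED ~0.1
and family nodes at RED ~0.6, singleton-family genomes on long
branches. Where the source conditions state a value (genome bounds,
intron mode, splice classes, thresholds) the generator uses it; the
remaining rates are fixed, realistic choices documented here and not
revisited.

Determinism: a single integer seed drives the community, and per-genome
substreams are derived by a stable string hash of the genome identifier,
so the same configuration yields byte-identical output regardless of
evaluation order.

What the generator does *not* emulate: read-level sequencing error,
assembly fragmentation beyond simple contig cuts, genuine sequence
homology between clades (hit tables are generated from truth labels,
not alignment), low-complexity sequence structure, and intergenic
transcription. Tests passing on this community therefore demonstrate
the correctness of the decision rules, not the robustness of upstream
tools on real data.

## Numerical choices and known limitations

* Best-hit ties break by bitscore, then percent identity, then
  lexicographic subject id, making all downstream assignments
  order-invariant.
* Thresholds quoted as "at least" are inclusive; those quoted with
  strict inequalities ("<50%", ">1 Mb", "below 0.22") are strict.
* The e-value-only introner gate can join a chance pair of AT-rich
  same-genome introns (a ~16 bp chance match already reaches e < 1e-5
  between ~100 bp sequences); production pipelines additionally rely on
  the aligner's low-complexity masking, which is out of scope here, so
  community-wide introner precision is reported rather than assumed.
* The nested-ORF scanner reports maximal ORFs and measures its empirical
  false-positive rate on scrambled introns in the test suite rather
  than claiming zero.
* Problem sizes in the tests: communities of 4-6 genomes of 50-120 kb
  for unit-level checks, one 20-genome community at the full 50-650 kb
  range for the end-to-end check, 500 random trees of up to 8 leaves
  for the RED cross-check, and 200 subsampled genomes at 100 sccg for
  completion recovery.
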