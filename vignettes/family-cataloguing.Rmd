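---
title: "Cataloguing a transcription-factor gene family: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cataloguing a transcription-factor gene family: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, eval = FALSE}
library(nacfam)
```

# The problem

NAC transcription factors form one of the largest plant-specific gene
families. Cataloguing the family in a newly sequenced genome involves a
chain of classical comparative-genomics steps: find every family locus in
the genome (including decayed pseudogene copies), place each functional
gene into an orthologous group (OG) defined on reference species, resolve
the family's phylogeny despite a hypervariable C-terminal region, identify
tandem and whole-genome-duplication (WGD) paralogs, type each gene's
exon/intron and protein-motif architecture, profile promoter binding
sites, and intersect the catalogue with expression contrasts to nominate
senescence candidates. `nacfam` implements that chain as a set of
composable, deterministic, fully testable operations, with a seeded
synthetic-data generator that plants known truth for every stage.

# The procedures and their assumptions

## Locus mining (`mine_loci`)

A translated search: all six reading frames of each chromosome are
translated and scanned against reference family proteins with local
affine-gap alignment (BLOSUM62, gap open 11 / extend 1 — the defaults of
the tool family this mimics). For chromosome-scale inputs the scan is
windowed (400 aa windows, 250 aa step) and hits on one chromosome and
strand within 10 kb are merged into loci, a generous allowance for
introns. Each locus is then re-examined in detail: the best query is
re-aligned against the three frames of the locus, with alignments confined
to stop-free stretches of each frame so that introns are never bridged.
Two adjacent alignment segments covering consecutive parts of the query
indicate a lesion when their genomic gap is too short to be an intron
(< 30 bp): different frames mean a frameshift, the same frame across a
stop-containing gap means an in-frame stop. Both are pseudogene evidence;
distinguishing pseudogenes from genes beyond these flags (manual curation)
is out of scope.

The default seed-hit threshold of the desk-scale configuration is a raw
score of 80. The choice is an a-priori extreme-value argument: for a
~150-aa query against ~10^5 aa of translated random sequence the expected
maximum chance score is near 55–60, so a cutoff of 80 keeps random hits
out while family members (even at 40% identity) score far above it. The
function default remains 50, appropriate for small targeted searches; both
are configurable (`min_locus_score`).

## OG classification (`assign_og`, `assign_all`)

Each protein is ranked against a labelled reference database by local
alignment score; a gene is assigned to an OG only when its `k = 3` best
hits all carry that label. Raw scores are used for ranking rather than
E-values: the rule consumes hit *order*, and E-value calibration would add
constants that cannot be verified at this scale. Ties at the k-th place
are handled conservatively: the whole block of hits tied with the k-th
score must agree, which makes assignment independent of database order. A
database entry with the query's own id is excluded (reference and query
sets may overlap in tests); multiple hits to distinct subjects of one
species are all kept. Genes without a consensus stay `UNASSIGNED`; the
tree-based rescue is annotation only (`annotate_nearest_cluster`), never a
hard label.

## Alignment and cleaning (`progressive_msa`, `clean_blocks`)

The aligner is a deterministic progressive MSA: a UPGMA guide tree on
1 − shared-3-mer fractions, then profile–profile global alignment with
affine gaps along the tree. Input sequences are sorted by id first and all
dynamic-programming tie-breaks are fixed, so the output is a pure function
of the input set. Iterative re-alignment stages of full MSA engines are
deliberately not reproduced: the downstream consumer is column cleaning,
which is robust to small alignment differences.

Cleaning is a simplified conserved-block extraction based on identity
fractions: a column is *conserved* when its most frequent residue reaches
0.5 + 1/n and gaps occupy at most half the rows (the relaxed setting:
smaller final blocks, gaps tolerated inside blocks, flanks only need to be
conserved rather than highly conserved at 0.85). Non-conserved columns are
never retained, so any non-conserved run separates blocks — this is the
rule set under which the worked examples were derived by hand, and it
subsumes the "long non-conserved runs break blocks" clause. Blocks shorter
than 5 columns are dropped. Retained counts are monotone in both identity
thresholds.

## Trees and iterative refinement (`nj_tree`, `bootstrap_support`, `iterative_refine`)

Distances are p-distances over retained columns, skipping positions where
either sequence is gapped. Trees are canonical neighbor-joining, with
negative branch-length estimates clamped to zero and the deficit moved to
the sibling so paths through the parent are preserved. Branch support is
nonparametric bootstrap over retained columns (replicate NJ trees;
support = fraction of replicates containing the bipartition). NJ +
bootstrap stands in for maximum likelihood + aLRT; the refinement loop is
independent of the tree engine.

The refinement loop formalises the iterative strategy that motivates the
package: heterogeneous families clean poorly (few retained columns), so
clusters hanging from long, well-supported stems are split off and
re-analysed on their own, where cleaning retains more columns and the
within-cluster phylogeny sharpens. The split criterion had to be made
explicit because only its intuition is standard: a cluster is split when
its stem is at least twice the median internal branch length (or an
absolute `refine_min_stem`), its support is at least 0.95, and it has at
least 3 members. Sets re-enter as new rounds while they hold at least 8
sequences, which also guarantees termination. These thresholds are
declared defaults, not inferred values.

## Motif discovery and architectures (`discover_motifs`, `classify_architecture`, `map_subdomains`)

Motifs are ungapped position-weight models fitted by ZOOPS EM (each
sequence carries zero or one occurrence), discovered sequentially with
masking. Widths are searched on the grid {6, 9, 12, 15, 20, 29, 50}
clipped to the configured bounds; desk-scale runs cap the width at 20. Per
width the EM runs from 8 seeded restarts, followed by column-shift
refinement (re-seeding from occurrence positions shifted by ±1, ±2),
which removes the classic off-by-one local optima. Models are compared
across widths by a BIC-penalised likelihood ratio
(LLR − ½·19·w·log n): raw LLR alone always prefers wider models. The EM
objective — the likelihood ratio plus the Dirichlet pseudocount prior
(pseudocount 0.1 × background) — is asserted non-decreasing at every
iteration. An occurrence requires both posterior ≥ 0.5 and a window
log-odds of at least half the model's maximum attainable score, the same
relative-threshold convention as the promoter scanner; a posterior alone
is not evidence of presence, because ZOOPS posteriors saturate on the best
window of every sequence once γ is large.

Architectures are typed from motif presence with the declared precedence
D > C > B > A (D: motif 10 present; C: motif 9; B: motifs
{1,2,3,5,6,7,8} without 4; A: motifs 1–8): the literature gives anchor
motifs for C and D but not a complete required set, so precedence is the
package's rule. Discovered models are tied back to family motif numbers
via three anchored consensus patterns for motifs 5–7
(G-Y-W-K-A/T-T-G-x-D-x{1,2}-I/V; G-x-K-K-x-L-V-F-Y; T-x-W-x-M-H-E-Y, with
Z ≡ Q/E and B ≡ N/D); unanchored models are numbered by mean occurrence
offset. This mapping assumes each discovered model corresponds to one
family motif — see limitations.

## Exon architecture (`classify_structure`)

The family's basic gene structure is three exons with intron phases
[1, 0]: exon 1 carries subdomains A and B and ends one nucleotide into the
codon after B; exon 2 carries C and D and ends on a codon boundary; exon 3
opens with E and carries the C-terminal regulatory region. Subdomain
protein spans are mapped to exons through the cumulative-CDS coordinate
map (strand-independent), and deviations are labelled: merged first exons,
extra subdomain-free leading exons, extra exons wholly 3' of E, or
non-canonical. Subdomain spans can come from motif hits or be supplied
directly (the simulator records planted spans).

## Duplications (`detect_tandem_arrays`, `pair_wgd_paralogs`)

Tandem arrays chain same-chromosome, same-OG genes whose start-to-start
distance is at most 100 kb, transitively, reporting chains of two or more.
Start-to-start was chosen over inter-gene gap because "separated by" is
ambiguous at the kb scale; the distance measure is configurable. WGD
paralogs are *not* inferred: duplicated blocks are an input (published
synteny), and same-OG genes with one member inside each block side are
paired, resolving multi-candidate sides by alignment score. Self-pairs are
impossible by construction.

## Promoters (`extract_promoter`, `scan_promoter`, `og_tfbs_matrix`)

Promoters are the 2000 bp immediately 5' of the CDS start on the coding
strand, truncated with a warning at chromosome edges. Scanning is log-odds
over a uniform background at every offset on both strands, with `N`
scoring as background (zero contribution); a window is a hit at ≥ 80% of
the maximum attainable score, a relative threshold chosen because
per-matrix calibrated cutoffs are not reproducible offline. Hits on
opposite strands at one offset count once. Per-OG values are arithmetic
means of per-gene counts, with matrices of one TF family summed per gene
before averaging. Raw counts are reported rather than per-kb rates — over
a fixed 2000 bp window the two differ only by a constant.

## Expression (`call_status`, `categorize_expression`)

Differential status per record: `up` when log2 ratio ≥ 1.5 with p < 0.05,
`down` when ≤ −1.5 with p < 0.05, `ns` otherwise. p-values are taken as
given (the reproduced analysis used raw p-values); a Benjamini–Hochberg
switch exists but is off by default. A gene is *senescence-associated*
when differential in at least one of the four line/stage contrasts — a
declared proxy, since no explicit derivation rule exists for that count —
and *genotype-contrasting* when the two post-anthesis/anthesis contrasts
disagree in direction.

# What the synthetic generator emulates — and what it does not

`simulate_family()` builds, from one seed, a three-chromosome genome
carrying 8 OGs × 5 genes plus two pseudogene remnants, a labelled
reference database (founder + three mutated relatives per OG), a sharp PWM
per TF family with planted consensus sites, and a DE table with planted
statuses. Planted features and the reasons for their values:

* **Identity structure.** Members are point mutants of an OG founder;
  non-motif positions mutate at 0.15 and motif blocks at 0.03 per residue,
  giving ~0.8 expected pairwise within-OG identity (the scenario's
  stated target) against ~0.3 between OGs. Founders share the family
  motif blocks, as real OGs share the DNA-binding domain.
* **Motif plan.** Ten fixed consensus blocks; OGs carry the block sets of
  architectures A, B, C and D, with inter-motif spacing drawn per OG from
  4–20 aa — spacing variability across the family is what keeps
  single-motif models from fusing adjacent motifs, as in the real family.
* **Gene structures.** Canonical phase-[1,0] splits for basic OGs, one
  gene with merged first exons, one OG with extra C-terminal exons, and
  non-canonical splits for the OGs lacking a full subdomain set.
* **Duplications.** One 2-gene tandem at 60 kb, one 3-gene tandem at
  90 kb spacing, a same-OG pair at 150 kb as the negative case, and two
  WGD block pairs (one wide block containing a different-OG bystander, one
  tight). All other same-OG neighbours are laid out > 100 kb apart.
* **Pseudogenes.** Intronless founder copies with the two minimal lesions
  the miner must flag: one substituted in-frame stop, one single-base
  deletion. Introns elsewhere are ≥ 80 bp, well above the 30 bp
  frameshift-gap bound.
* **Promoters.** Exact consensus sites (width 12) planted at
  non-overlapping offsets, Poisson(0.8) per gene and family; a 12-bp sharp
  consensus keeps the chance-hit rate over the whole toy genome far below
  one, so planted counts equal scanned counts.
* **Expression.** Twelve genes planted differential across the four
  contrasts, including one genotype-contrasting gene; null records mix
  small ratios with large-but-insignificant ones to exercise both
  thresholds.

The generator does **not** emulate: indel evolution within OGs (members
are equal-length point mutants), codon-usage bias beyond a fixed
most-frequent-codon table, repeats or compositional structure in
intergenic DNA, UTRs (promoters start at the CDS), alternative
transcripts, or realistic TFBS degeneracy. Consequently, passing tests
demonstrate the *operations* are correct on data satisfying their stated
assumptions; they do not demonstrate robustness to alignment-shifting
indels, repeat-induced spurious loci, or weak binding sites, all of which
real genomes supply.

# Numerical choices

Internal coordinates are 0-based half-open throughout; GFF3's 1-based
closed convention is converted only at the readers/writers. One protein
per gene: the longest-CDS transcript (the isoform used when several exist
is otherwise unspecified). Alignment tie-breaks prefer
diagonal > gap-in-second > gap-in-first profiles. NJ requires symmetric
input to 1e-8 and clamps negative edges as described. EM: tolerance 1e-5
on the objective, at most 200 iterations, 8 restarts. Bootstrap: 100
replicates by default (60 inside refinement tests for speed). Problem
sizes used by the test-suite and the acceptance script — 40-gene genomes
of ~0.5 Mb chromosomes, 20-sequence motif sets of length 60, 20-member
divergent families, 50 random 6-leaf trees — were chosen as the smallest
sizes at which every planted signal is unambiguous.

# Known limitations

* Family-scale motif discovery finds the motifs shared by most sequences;
  OG-specific motifs present in ~5 of 40 proteins sit below the
  sensitivity of restart-seeded ZOOPS EM (an exhaustive starting-point
  search would be needed), so end-to-end architecture typing on the
  default scenario under-calls structures C and D. The classifier and the
  subdomain mapping are therefore specified and tested as pure functions
  of motif presence, and motif recovery is validated on dedicated planted
  scenarios.
* The miner's frameshift/intron disambiguation is a gap-length heuristic
  (< 30 bp); genuine micro-introns would be mis-flagged.
* NJ + bootstrap is a stand-in for maximum-likelihood inference with
  aLRT support; topologies inside poorly resolved clusters can differ.
  All outputs carrying supports record this.
* Raw alignment scores, not E-values, rank hits; rankings are comparable
  only within one query.
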