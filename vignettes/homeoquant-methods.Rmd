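---
title: "Homeolog-aware quantification: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homeolog-aware quantification: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homeoquant)
```

## The quantification model

homeoquant targets species with two co-resident, recently diverged
sub-genomes (labelled A and B), where a large fraction of short reads
aligns acceptably to the homeologous copy in either sub-genome. The unit
of quantification is the **merged gene**: an ortholog pair spanning both
sub-genomes, or a single sub-genome-specific gene. Treating the pair as
one gene makes the central assumption explicit: *the two homeologous
copies are not distinguished*. Their summed signal is quantified, which is
the only well-defined quantity when reads cannot be attributed to a copy;
the corollary is that homeolog-specific (allele-specific) methylation or
expression is out of reach by design.

Reads are classified by their joint mapping status across the two
alignments of the same library: `A_ONLY` / `B_ONLY` (type I — the
read distinguishes the copies), `BOTH` (type II — it does not), or
`UNMAPPED`. Counting follows one rule: **a read contributes at most once
to any (merged gene, region kind)**. A type II read overlapping the
promoter of both members of one pair is one observation of one merged
promoter, not two. A read overlapping regions of two *different* merged
genes contributes once to each — with per-gene quantification there is no
principled way to split it, and such reads are reported in an audit table.
Region kinds are tallied independently: a read straddling a promoter/body
boundary counts once in each kind, because each region's RPM is a
self-contained measurement.

RPM is `count × 10⁶ / total_clean_reads`, with the denominator the
*sequenced* clean-read total rather than the mapped total, so that a
sample's mapping rate does not leak into its abundance scale. RPKM is
deliberately not offered for merged genes: the two members of a pair can
differ in length, so a per-kb denominator is ill-defined for the merged
unit. RPM therefore supports comparisons of the same gene across samples,
not across genes.

## Analysis regions

Each gene contributes three fixed regions: the promoter (`flank_bp`,
default 2000 bp, upstream of the strand-aware 5′ end), the gene body, and
the TTR (2000 bp downstream of the 3′ end), clipped at chromosome edges.
Upstream/downstream are read strand-aware; for genomes annotated without
meaningful strand this reduces to left/right flanks.

CpG islands are detected with the Gardiner-Garden–Frommer rule: 200 bp
windows at 1 bp step qualify at GC ≥ 0.5 and observed/expected CpG ≥ 0.6
(`n_CpG·L / (n_C·n_G)`); overlapping qualifying windows merge into
islands, each flanked by two 2000 bp shores. Windows with more than 10%
ambiguous bases are skipped. The GGF rule is a conventional stand-in —
island definitions vary across the literature and the thresholds are
exposed as arguments; islands detected on AT-rich plant genomes are
sparser and shorter than on vertebrate genomes, which is expected.

## Orthology detection

Candidate pairs are **reciprocal** best protein hits below E < 10⁻²⁰.
One-directional best hits were the plausible alternative reading; the
reciprocal form was chosen because it is the standard operationalisation
of "best-hit gene pairs" and is symmetric in the two sub-genomes. Ties on
score break by lower E-value, then lexicographic id, so results do not
depend on input order.

Synteny confirmation tiles each chromosome into fixed, non-overlapping
100 kb blocks from the origin (a gene belongs to the tile holding its
start). A candidate pair survives when its A-block/B-block combination
holds ≥ 3 candidate pairs. Fixed tiles were chosen over gene-centred
windows for determinism and O(n) bookkeeping; `mode = "sliding"` provides
the gene-centred variant, which is slightly more permissive near tile
boundaries.

The built-in scorer is plain Smith–Waterman (BLOSUM62, gap 11/1) with
Karlin–Altschul E-values (λ = 0.267, K = 0.041, the standard gapped
BLOSUM62 constants; search space = query length × summed subject
lengths). It exists so that desk-scale runs and the test suite need no
external search tool; it is quadratic per pair, so genome-scale runs
should ingest a 12-column tabular hit file from a dedicated search tool
via `read_similarity_hits()`.

## Differential calls

Replicate RPM values are compared with Student's pooled-variance
two-sided t-test. With the two biological replicates common in MeDIP
designs, Welch degrees of freedom are degenerate, hence the pooled form.
Zero-pooled-variance cases are resolved by rule: equal means → p = 1;
unequal means with zero variance → the smallest representable positive p,
flagged `degenerate` (with two replicates of discrete counts this happens
and silently dropping such genes would bias calls). The default is raw
P < 0.05 with no multiple-testing correction — matching the convention of
low-replicate MeDIP designs where the raw-p DMG list is a screening set —
and `fdr = "bh"` is available when a controlled list is wanted. A gene is
a DMG/DEG when **any** of promoter/body/TTR is significant; the
significant regions are recorded.

DMEGs are genes significant in both methylation and expression for the
same contrast. The relation is `negative` when directions disagree. When
a gene is differentially methylated in several regions with conflicting
directions, the gene-level direction follows fixed precedence
promoter > body > TTR: the promoter is the region with the clearest
mechanistic link to expression, and a fixed precedence keeps the summary
deterministic. Per-region relations remain available upstream of the
collapse.

Gene-set enrichment is the hypergeometric upper tail over a user-supplied
set mapping; no live pathway database is consulted.

## Small-RNA association

The target-locus matcher is a deliberate simplification of dedicated
plant sRNA target software: every position on either strand of either
sub-genome where the sRNA matches with ≤ 2 substitutions (no indels),
found exhaustively. The mismatch budget is exposed. Locus methylation is
the MeDIP RPM in a ±100 bp window around the locus centre — a window the
size of a typical MeDIP fragment; the locus itself (24 nt) is too small to
accumulate counts. Concordance counts (abundance direction = methylation
direction, presence/absence included) operationalise "positively
associated"; sRNAs with unchanged abundance are not scored.

## The simulator: what it emulates and what it does not

`simulate_subgenomes()` builds sub-genome A on a fixed 6 kb slot grid
(2 kb promoter, 1.2 kb body, 2 kb TTR plus spacers) and derives B by
copying the orthologous fraction of slots with uniform point
substitutions at the configured divergence (default 1%, emulating the
~98–100% identity regime of a recent allotetraploid), permuting slot
order within each 100 kb block (so planted synteny still yields ≥ 3 pairs
per block), and replacing the rest with fresh sequence carrying
B-specific genes. Every substituted position is recorded; a read is
placed on the homeologous copy exactly when its span carries at most
`aligner_tolerance` (default 3) substitutions, which is what produces
type II reads mechanistically rather than by fiat. The no-indel mutation
model keeps A↔B coordinates exactly alignable; indel-induced soft
clipping and shifted placements are not emulated.

MeDIP reads are drawn multinomially over (merged gene, region) with
weights = true level × region length × per-library lognormal noise
(sdlog 0.25, a typical replicate CV for sequencing abundance data);
RNA reads likewise over gene bodies and expression levels. A configurable
5% of reads is unmappable, standing in for contaminants and unassembled
regions. Planted differential genes come in **mass-balanced up/down
pairs**: the up gene gains fold 4 in one region from its change stage on
while its partner (with 4× the base level) loses the same absolute mass.
This conserves genome-wide methylation mass across stages — under
fixed-depth sampling, an unbalanced plant would shift every null gene's
expected read share and turn composition bias into spurious calls. Real
MeDIP libraries are equally compositional; the balanced design encodes
the biological expectation that genome-wide methylation is roughly stable
across adjacent developmental stages.

Not emulated: MeDIP fragment-size and CpG-density capture bias,
sequencing errors beyond the divergence model, PCR duplicates,
paired-end structure, transposable elements, and intergenic methylation
outside the slot grid. Passing recovery tests therefore demonstrate the
*bookkeeping* (classification, once-only counting, RPM, testing) under a
faithful divergence/synteny structure — not robustness to every artefact
of real libraries.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally; GFF3 converts on read,
  BED on write. Promoters/TTRs clip at chromosome bounds rather than
  erroring.
* Two primary alignments for one read in one file abort the run (aligner
  misconfiguration); a read present in one alignment file only is treated
  as unmapped in the other, with a counted warning.
* Empty protein sets, empty anchor sets and zero `total_clean_reads` are
  hard errors; zero counts give RPM 0.
* All tie-breaks (best hits, one-pair-per-gene) order by score, then
  E-value, then id, making every output deterministic under input
  permutation; the simulator is byte-reproducible from its seed, and
  per-library seeds are derived from stage × replicate × assay.

## Problem sizes

Tests and the acceptance script run the simulator at 40–100 genes per
sub-genome, 20,000-read libraries, 2–3 replicates and 2,000-gene null
panels; brute-force oracle comparisons (window scans, read × region
enumeration, block enumeration) run on 10–50 kb sequences and
~200-gene layouts. These sizes give stable recovery statistics
(binomial error on a 20,000-read mapping rate is ±0.4 points) while the
whole suite stays fast; all of them scale linearly if larger runs are
wanted.

## Known limitations

* Homeolog-specific signal is out of scope by construction.
* Multi-mapping *within* one sub-genome relies on the upstream aligner's
  primary-alignment choice; only primary records are read.
* The built-in protein scorer is for fixtures and small genomes; use
  external tabular hits at genome scale.
* RPM inherits composition effects of fixed-depth sequencing: a large
  one-directional genome-wide methylation change between samples is
  indistinguishable from a global scale change.
* Methylation context (CG/CHG/CHH) is not resolved — MeDIP depth carries
  no base-level context.
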