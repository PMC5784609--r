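---
title: "apascan: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{apascan: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the model behind each pipeline stage, the assumptions
baked into defaults, the numerical choices made where the design was open,
and what the simulator does and does not emulate. The companion README shows
a worked run; here we explain *why* the stages look the way they do.

## Coordinate conventions

Internally everything is 1-based, fully closed, and strand-aware: a CPA site
is the coordinate of the last templated base of the transcript. BED output
is 0-based half-open with a 1-nt interval ending at the CPA base; GFF3/GTF
input is 1-based closed. These match each format's native convention and
make the "first base of Read 2" definition unambiguous: Read 2 is sequenced
from the polyA junction into the transcript, so it aligns antisense — a
minus-strand Read 2 implies a plus-strand transcript whose CPA site is the
rightmost aligned base, and symmetrically for the other orientation.

## Site universe and clustering

**Universe rule.** A position enters the analysis only when supported by at
least one read in at least `min_samples_support` (default 2) libraries.
This is a reproducibility filter: PCR stutter and rare mispriming tend to be
library-private, true cleavage sites recur. The rule counts libraries, not
conditions; replicates of one tissue each count separately. It is monotone —
adding a library can only add positions, never remove one.

**Greedy clustering.** Cleavage is sharp but not exact, so per-nucleotide
end counts around a true site form a tight peak. Clustering takes the
unassigned position with the highest summed count as a representative and
absorbs every unassigned position within `cluster_window` (default ±12 nt)
on the same contig and strand. Two numerical choices make this a total,
deterministic order:

* *Within-window ties* go to the 3′-most position (higher coordinate on
  `+`, lower on `-`), i.e. the downstream-most plausible cleavage base.
* *Between-window ties* (equal counts more than a window apart) are
  processed 3′-most first within a contig/strand, contigs in lexical order.
  This has no effect on which positions end up together when peaks are
  separated, but pins down the result exactly when they are not.

Absorbed positions can never seed later clusters (strict greedy), and the
window is applied once around the representative, not chained transitively:
a position 13 nt away starts its own cluster even if intermediate positions
were absorbed. The unit and acceptance suites verify exact agreement with an
independently coded brute-force implementation of the same rule on
1,000 random tallies, including tie cases on both strands.

## Mispriming filter

Oligo-dT priming on a genomically templated A-rich tract produces a 3′ end
whose "polyA tail" is actually genome. The filter therefore inspects the
sense-strand genomic window of `mispriming_downstream_window` (default 5)
bases *beginning at the CPA base*: if the first base is A and at least
`mispriming_min_A` (default 4) of the window are A, the site is suspect. The
window is anchored at the CPA base rather than one base after it because a
templated A at the cleavage position itself is exactly what makes a
mispriming product indistinguishable from a genuine tail; both parameters
are configurable so stricter published variants can be swapped in. Bases
beyond the contig end are treated as non-A (the conservative reading:
missing evidence never removes a site).

Suspects are then split by the PAS scan: no hexamer in the upstream window
→ `removed_mispriming`; hexamer present → `flagged_pas_positive`, kept in a
side set but excluded from the final site collection. This preserves the
trichotomy (every cluster gets exactly one status) and the monotonicity
property that adding a PAS can only move a site from removed to flagged,
never resurrect it into the final set.

A read-level variant of this filter (dropping remapped reads whose leading
T-stretch matches genome) is subsumed by the site-level test: once final
coordinates exist, the site-level decision is deterministic and equivalent
in intent, so it is the only implementation.

## PAS annotation

The scan searches the sense strand for each configured hexamer whose last
base falls within `pas_window` (default 8–25 nt) upstream of the CPA base.
Hit preference is motif rank first, then proximity to the modal 19 nt
offset, then the 3′-most hit — a total order chosen because only the
canonical motif's dominance and the modal offset are well established;
everything beyond that needs an explicit tie-break to be reproducible.

The shipped list of 15 hexamers (canonical `AAUAAA` first, then common
single-substitution variants) is a package assumption, not a measured
quantity: the composition and ranking of non-canonical variants differ
between surveys, so the list is an ordinary configuration value
(`pas_motifs`) and any analysis that depends on the weaker motifs should
set it explicitly.

## Gene assignment and 3′UTR classes

Assignment is two-tiered: unambiguous same-strand exon overlap wins;
otherwise the nearest gene whose exon 3′ boundary lies within
`max_upstream_assign` (default 1500 nt) *upstream* of the site (the gene is
upstream, the site is its candidate 3′ extension). Overlap with exons of
two genes is left unassigned as ambiguous rather than guessed. Exon overlap
is never overridden by proximity, and strand is always respected.

A site on a coding gene strictly 3′ of the gene's 3′-most stop codon is a
tandem APA isoform; its 3′UTR length is the genomic distance from the first
base after the stop codon through the CPA base inclusive. Genomic (not
spliced) distance is the only length computable from exon/CDS features
alone; when explicit 3′UTR features with introns exist the spliced length
would be preferable, but annotations rarely provide them for novel isoforms,
so the genomic convention is applied uniformly. Sites at or 5′ of the stop
codon are classed CDS-internal and carry no UTR length; sites on non-coding
genes are `ncRNA_end`. For genes with several annotated stop codons across
splice variants, the 3′-most is used throughout.

Isoforms of a gene are indexed 5′→3′ (`isoform_rank` 1 = most proximal), so
proximal/distal vocabulary is well defined downstream.

## Quantification

Size factors are the DESeq2 median-of-ratios calculation: factor *j* is the
median over genes of `count[g, j]` divided by the gene's geometric mean
across libraries, using only genes with nonzero counts everywhere. The
method assumes most genes do not change; when a substantial one-directional
fraction does (tens of percent), the median sits in the tail of the
unchanged genes' ratio distribution and absorbs a small bias (order 0.05
log2 at 30% changed genes in the simulations the acceptance script runs).
With no all-positive gene the function stops and points to
`pseudo_reference = TRUE`, which builds the reference over positive counts
only — an explicit opt-in because it changes the estimator.

The low-abundance isoform filter removes, per sample, isoforms carrying
less than `min_isoform_fraction` (default 5%) of the gene's clustered
reads. The per-sample maximal isoform is always retained so that a gene
with many weak isoforms cannot lose all of them; the reported cross-sample
isoform set is the union of per-sample retained sets. The filter is
idempotent. "Expressed gene" for summary profiles means ≥1 normalized
count by default (configurable); per-chromosome profiles report mean and
median normalized expression per contig plus an X:autosome ratio, with a
zero-X library flagged explicitly rather than producing NaN.

## Differential isoform usage

For each gene with ≥2 retained isoforms and at least `min_test_reads`
(default 20) reads per condition, each isoform is tested against the
collective usage of all its siblings in a 2×2 table (isoform vs rest ×
condition A vs B), pooled over replicate libraries within a condition. The
test is the two-sided exact hypergeometric (Fisher) test with the
probability-mass definition of two-sidedness; p-values are collected over
all isoform tests genome-wide and BH-adjusted as one family. Choices worth
making explicit:

* *Pooling* matches the per-sample-type library structure of typical
  3′-end studies; a replicate-aware model (e.g. beta-binomial) would be a
  natural extension and the test function is the single place to swap it.
* *Genome-wide BH* is the conservative default when no family structure is
  stated.
* *The coverage gate* exists because exact tests on tiny totals are
  uninformative; at realistic depths it is inactive.
* The exact test is conservative under the null (discreteness), so the raw
  p < 0.05 fraction under a simulated null sits below 0.05 — the acceptance
  suite checks calibration and power (≥80% sensitivity at 40-point usage
  shifts with 100 reads per condition, empirical FDR ≤10%).

Direction labels derive from the 5′→3′ isoform ordering: usage gained in
condition B on an isoform more proximal than the gene's ordering centre is
a proximal shift, and conversely; at the catalog level, a major isoform
whose rank decreases from A to B is a proximal shift in B. Ties in major
isoform selection resolve 3′-most (distal), consistent with the clustering
tie rule.

## Motif analytics

Motif counting is overlapping (`UUGUUGUU` contains two `UUGUU`), T≡U, and
IUPAC-aware in the pattern only. Overlap counting is the right reading for
"density of repeats" but is switchable in principle; the brute-force
positional scan in the test suite pins the semantics. Counts are computed on
sense transcript sequence: exons spliced 5′→3′, extended (or truncated) to
end at the isoform's CPA base, so motifs spanning exon–exon junctions are
counted once and intronic matches never. The GLD-1-class binding patterns
shipped in examples are configurable specs, not ground truth — consensus
definitions vary across studies.

The density-vs-fold-change summary buckets isoforms at 0/1/2/3+ motif
counts (configurable), reports per-bucket median fold-changes, and
quantifies the trend with a Spearman correlation whose p-value comes from a
seeded label-permutation null (default 10,000 permutations). Degenerate
inputs (constant counts, <10 isoforms) are flagged, not silently dropped.

## The simulator: what it emulates, and what it does not

The simulator writes a complete world — genome, annotation, reads, truth —
from one seed, byte-reproducibly:

* **Genome**: random contigs at the requested GC (default 0.35,
  nematode-like), scrubbed of accidental A/T homopolymers ≥8 nt so that
  every A-tract in the world is a deliberately injected trap; when ≥2
  contigs are made the last is named `X` for sex-chromosome dosage
  scenarios.
* **Genes**: two exons, one intron, a CDS ending at a known stop codon, and
  1–3 tandem CPA sites (the first inside the terminal exon, the others
  downstream of it within the assignment range), spaced >1500 nt apart
  unless ambiguity is explicitly requested. A canonical PAS is written
  ending 19 nt upstream of every site; the remaining upstream scan window
  is written adenosine-free so the programmed PAS is the only one, and the
  6 nt after each site are drawn U/G-rich — a downstream-sequence-element-
  like composition that also keeps true sites clear of the A-rule.
* **Reads**: per-gene totals are Poisson around `depth × expression`;
  isoform assignment is multinomial by programmed usage (default 0.7/0.3
  for two isoforms, 0.5/0.3/0.2 for three); each read's end is jittered by
  a symmetric discrete offset with P(0) = 0.61, P(±1) = 0.08, P(±2) = 0.05,
  P(±3..5) = 0.02 and the remaining 1% uniform on ±6..12 — a shape chosen
  to satisfy the two anchored precision constraints (61% exact, ≥90%
  within ±5 nt); the exact vector is one configurable argument. Trap reads
  are emitted at trap positions at `trap_rate × depth` per library.
  Programmed switches move `switch_delta` (default 0.4) of usage mass from
  the most proximal to the most distal isoform in condition B.

Deliberately not modelled: base-call errors and quality scores, fragment
length, alignment ambiguity, chained/overlapping cleavage peaks closer than
the clustering window, PAS-free true sites, spike-ins, batch effects, and
biological replicate dispersion beyond Poisson. Passing the recovery tests
therefore demonstrates the pipeline's correctness on data that satisfies
its assumptions — not robustness to aligner artifacts or overdispersed
replicates, which real data adds on top.

## Problem sizes and tolerances in the test suite

The suites run desk-scale worlds chosen to keep the whole default test run
in minutes on one CPU while leaving the statistical checks well-powered:
1,000 random tallies for the clustering oracle, 500 random tables for exact
test enumeration (tolerance 1e-9), 2,000 genes at depth 100 for null
calibration, 200 genes (30% switched by 40 usage points) for power and FDR,
40-gene worlds at depth 120 for site recovery under jitter, 30 traps for
the filter, and 16-gene noise-free worlds for the exact end-to-end identity
(usage fractions compared exactly to realized truth counts). Fold-change
recovery is asserted on the median over genes with ≥100 reads (tolerance
±0.1 log2), the aggregate reading of normalization accuracy at that depth —
per-gene Poisson noise at 100 reads is itself ~0.2 log2.

## Known limitations

* The per-library universe rule cannot distinguish biological replicates
  from distinct conditions; a site private to one library is discarded even
  at high depth.
* The upstream-proximity assignment takes the nearest gene; closely spaced
  same-strand genes within 1500 nt can still attract each other's distal
  isoforms.
* Pooled exact testing ignores replicate overdispersion; q-values on
  strongly overdispersed data will be anti-conservative.
* Genomic 3′UTR length overstates spliced length when the UTR contains an
  intron.
* The "≤95% identity" read filter is interpreted at the alignment stage
  (identity ≤ 0.95 excluded, boundary excluded as written); it applies only
  when edit distances are available from the aligner.
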