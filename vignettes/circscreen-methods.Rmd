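---
title: "Methods: screening circRNA-RBP interactions with circscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening circRNA-RBP interactions with circscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circscreen)
```

## The problem

Circular RNAs (circRNAs) arise when a downstream splice donor backsplices
to an upstream acceptor, producing a covalently closed transcript whose
only distinguishing sequence feature is the backsplice junction (BSJ).
Because circRNAs are stable, abundant, and not translated, they are
candidate binding platforms — potentially sponges — for RNA-binding
proteins (RBPs). circscreen implements the computational side of a
transcriptome-wide screen of circRNA-RBP interactions: cataloguing
circRNAs from junction-read evidence, overlaying experimentally defined
RBP binding sites (eCLIP peaks with a size-matched input control), and
asking (i) whether circularizing exons carry more RBP binding than
comparable linear exons, (ii) whether specific RBPs bind the introns
flanking circRNAs and affect their biogenesis, and (iii) whether any RBP
binds the BSJ itself.

## Catalog construction

Two independent callers contribute BSJ call tables; only junctions with
at least 2 junction-spanning reads in **both** callers enter the catalog
(`consensus_catalog()`), and all expression values come from caller A.
Because the bulk of calls are weakly supported, most analyses use the top
1% by BSJ reads: `top_percentile()` takes the `ceiling(0.01 * N)` most
supported junctions (this ceiling rule maps a 16,033-junction catalog to a
set of 161 and a 14,648-junction catalog to 147). Ties at the boundary are
broken by lexicographic junction id — the rule needed a deterministic
choice and the identifier is the only stable key.

The circular-to-linear ratio is `2c / (2c + l)`: a junction read comes
from the two ends of a circular junction but is counted once, whereas
linear reads across the same positions come from one end, so circular
counts are doubled before forming the proportion. It is undefined (NA)
when both counts are zero.

Exons are merged across isoforms per gene (`gene_merged_exons()`, the
`bedtools merge` semantics: bookended intervals join), and each merged
exon of a circRNA gene is categorized: a **BSJ circ-exon** has a boundary
that coincides exactly with a backsplice coordinate (boundary matching
wins over containment when an exon is internal to one circle but the
boundary of another), a **circ-exon** lies inside a circle's span, and
everything else is a **non-circ-exon**. Exact-coordinate matching (0 bp
tolerance) reflects that callers report splice-site-resolved coordinates.
First/last-exon status is decided on the merged list, after isoform
merging, because the exclusion rule downstream ("first and last exons of
each gene") operates on genes, not transcripts.

Coordinates are held in `GRanges` (1-based closed), the native convention
of the R genomics stack; BED-style inputs and outputs are converted at
the I/O boundary, and a caller-dialect flag on `read_circ_calls()`
declares whether a caller reports 1-based closed (CIRI2-style) or 0-based
half-open junctions. All interval algebra is strand-blind: regions are
compared within genes, where strand is constant; strand matters only for
first/last-exon orientation and inverted-Alu orientation.

## Binding sites and coverage

eCLIP peaks become binding sites after three independent filters:
at least 10 IP reads, log2 fold change over the size-matched input of at
least 3 (an 8-fold linear enrichment), and at least 4 bp of width; site
overlaps shorter than 4 bp are likewise discarded. When a peak table
carries a precomputed fold change it is trusted; otherwise the fold
change is `log2((ip + 1) / (input + 1))`, with the pseudocount keeping
zero-input peaks defined.

**Coverage** of a feature is the percentage of its exonic bases
overlapped by the union of filtered sites — sites are merged across RBPs
first, so coverage is invariant to how peaks are split and never exceeds
100%. Per-circRNA enrichment over its host gene divides circRNA coverage
by the mean coverage of the gene's internal non-circ-exons, with a
pseudocount of 1 on both sides so site-free features stay in the
analysis; the ratio is bounded to [1/101, 101] and is NA when the host
gene has no internal non-circ-exon.

**Expression matching.** Coverage increases with transcript abundance, so
comparing circRNA exons to arbitrary exons would confound binding with
expression. Genes with positive FPKM are ranked into 100 equal-size
quantile bins (ties broken by gene id, so the binning is deterministic),
and each of 100 resampling iterations draws, per bin, as many internal
non-circ-exons of genes *without* circRNAs as circRNA genes occupy that
bin. "Genes producing circRNAs" means any consensus circRNA, not only the
top set, so the pool is truly circRNA-free. Draws are without replacement
within a bin when the pool suffices, with replacement (flagged) when it
does not; a bin with no pool exons at all falls back to the nearest
populated bin (also flagged) rather than aborting — at desk scale a bin
can consist entirely of circRNA genes, and the nearest-bin draw keeps the
expression match as close as the pool allows. The empirical p-value uses
the add-one estimator `(1 + #(null >= obs)) / (1 + iterations)`, which
cannot reach zero: with 100 iterations the floor is 1/101, reported as
p < 0.01.

Per-RBP differential binding compares per-exon coverage of BSJ circ-exons
against internal non-circ-exons of circRNA genes with a two-sided
Wilcoxon rank-sum test (exact for small tie-free samples, normal
approximation with tie and continuity corrections otherwise), restricted
to RBPs with at least 20 binding sites, and adjusted by
Benjamini-Hochberg with significance at FDR < 0.1. The mean coverage per
category averages per-exon percentages (not pooled base counts), matching
how the per-category summaries are usually displayed.

## Flanking introns and knockdown

Biogenesis signals live in the introns flanking a circle. For each
feature, 10 kb windows on each side are intersected with purely intronic
bases (bases exonic in *any* isoform are excluded); windows are not
truncated at neighbouring genes — the analysis is positional, not
gene-bounded. An RBP "flanks" a feature when at least one site overlaps
each side's intronic bases (1 bp suffices; a site straddling the feature
boundary counts for its flank). Enrichment of flanked circRNAs over
internal non-circ-exons of the same genes (first/last exons removed,
circRNA exons removed) is a 2x2 chi-square with Yates continuity
correction — the correction is applied because the screen's statistics
follow R's `chisq.test()` defaults — reported with the fold change of
proportions.

An inverted-Alu (IRAlu) pair is an Alu in the upstream flank and an Alu
in the downstream flank on opposite strands — the standard
inverted-repeat criterion for sequences able to base-pair across the
feature. The definition is symmetric under swapping all strands.

Knockdown analysis sums RPM (reads per million; counts scaled by library
size) over a circRNA subset per sample and compares knockdown to control
samples with a Welch t-test (the unequal-variance form, since group
variances are not constrained). The headline contrast is the subset of
circRNAs with both-flank sites of the flank RBP versus the complement;
both the per-sample subset totals and per-circRNA means are computed, the
totals being the tested statistic.

## Backsplice-junction read mapping

To look for RBPs bound across the BSJ itself, an exhaustive junction
reference is built: for every transcript and every exon pair with
acceptor index i ≤ donor index j in transcript order (including i = j,
the single-exon circle), the last 30 bp of the donor exon are pasted to
the first 30 bp of the acceptor exon, in transcript orientation. Exons
shorter than 30 bp contribute what they have — no padding into introns —
and are flagged. A transcript with n exons yields n(n+1)/2 references
before identical sequences are collapsed (all source junction ids are
retained). Short (~20-25 bp) reads are aligned ungapped against every
reference in both orientations with at most 2 substitutions; indels are
not modeled because at these read lengths and budgets an indel-bearing
read cannot be confidently placed. A hit must cover at least 5 bp on
*each* side of the junction — the stricter reading of "spanning by
5 bp", chosen so every counted read genuinely crosses the backsplice.
PCR duplicates are removed by (barcode, junction, offset), keeping the
first read id; counting is per distinct junction id for multi-mapping
reads, and counts are not library-normalized. A junction is called when
each IP replicate has at least 10 deduplicated reads and each replicate's
log2 fold change over the input (pseudocount 1) is at least 3 — the
per-replicate reading of the dual condition, the stricter of the two
possible parses.

## GO enrichment and co-localization

RBPs binding BSJ circ-exons significantly more than non-circ-exons form
the subset tested for GO-term enrichment: terms annotated to at least two
background RBPs are tested with a one-tailed Fisher's exact test, and the
fold is the ratio of hit proportions `(k/n) / (K/N)`. A chi-square fold
claim is inherently unsigned, so folds are always reported alongside the
p-values. Co-localization asks, for each predicted circRNA-RBP pair,
whether the two share at least one subcellular compartment; pairs missing
from a localization table are excluded and counted as unresolved.

## The synthetic study conditions

The generator (`simulate_screen()`) creates every input with known ground
truth so the full screen runs end-to-end with no downloads. Its defaults
are the package's study conditions:

* 300 non-overlapping genes on 2 chromosomes, 3-8 exons of 80-400 bp,
  introns of 3-8 kb (so a 10 kb flank window spans roughly one or two
  introns, keeping flank signals local to the feature), and a second
  exon-skipping isoform for half of the eligible genes. FPKM is
  log-normal (`meanlog 1`, `sdlog 2.5`, spanning more than four orders of
  magnitude, as RNA-Seq expression does).
* 30 circRNA genes; circles span 1-3 internal exons (weights 0.5/0.3/0.2
  — single-exon circles are common in real catalogs, and the mixture
  keeps the number of observed BSJ exons close to the number of
  resampling draws, which keeps the null empirical p approximately
  uniform). BSJ counts are negative binomial (mean 30, size 5) with a
  planted top subset multiplied by 100; caller B counts are correlated
  copies, 10% of true circles fail the consensus in exactly one caller,
  and a few caller-specific junk calls are planted.
* 12 RBPs place sites as width-weighted uniform processes: 1.2 sites/kb
  per RBP on exons, 0.03/kb on introns, widths 20-80 bp. Four RBPs
  receive 3x exonic density on circularizing exons (the planted
  enrichment); KHSRP receives planted sites in both flanks of half the
  circRNAs. IP/input counts are drawn so these sites pass the filters;
  an extra 10% of peaks each fail exactly one filter. Site placement is
  *not* coupled to gene expression — the expression-matching machinery is
  exercised, but the coverage-abundance correlation of real eCLIP data is
  not emulated, so passing tests show the matching is implemented
  correctly, not that it removes a real confounder.
* Knockdown counts are negative binomial (log-normal means around 150,
  size 500 — low dispersion, so the planted effect is recoverable at
  n = 3 vs 3) with expected counts proportional to each sample's library
  size; the 0.85x effect applies to the circRNAs that *measurably* carry
  both-flank KHSRP sites, so the analysis target and the planted target
  coincide exactly.
* Junction reads (20-25 bp, barcoded, with at least 8 bp on each side so
  reads do not cross-map between references sharing a donor exon) are
  planted on three junctions at 15 reads per IP replicate against input
  1 — exactly the calling threshold pattern — plus two decoys that each
  miss one threshold, PCR duplicates at rate 0.3, and a few
  three-substitution reads that must not map.
* One GO term annotates all enriched RBPs plus two others; background
  terms are random. Localization tables make circRNAs cytoplasmic (some
  also nuclear) and RBPs mixed, as fractionation data typically shows.

Everything is drawn from one seeded stream: the same seed reproduces
byte-identical files. Control knockdown columns are drawn before
knockdown columns so the control data are invariant to the effect-size
parameter under a fixed seed.

What the generator does **not** emulate: realistic sequence composition
(Alu elements are positional records, not sequences), crosslink-position
biases within peaks, expression-coupled binding, overlapping genes
(host-gene assignment with overlapping genes is exercised with hand-built
fixtures in the tests instead), and dispersion estimation for
differential expression — the screen's knockdown comparison is a
group-mean contrast in RPM by design.

## Numerical choices and degenerate inputs

* Empirical p-values use the add-one estimator, never 0.
* `relative_ratio(0, 0)` is NA; a circRNA span overlapping no annotated
  exon is flagged and excluded from coverage analyses; a host gene
  without internal non-circ-exons yields an NA enrichment ratio.
* Wilcoxon switches from exact to approximate exactly where
  `wilcox.test()` does; two groups with all values identical return
  p = 1 directly (the ranking is uninformative).
* A zero margin makes the chi-square undefined (NA); both-zero variances
  make the Welch test NA with a warning.
* The statistical kernels delegate to R's `chisq.test`, `fisher.test`,
  `wilcox.test`, `t.test`, and `p.adjust`; every kernel is verified in
  the test suite against independent enumeration oracles (hypergeometric
  tail sums, exhaustive rank permutations, the step-up rule applied
  literally, a permutation t reference), so the delegation is checked,
  not assumed.
* Gene span for intron derivation is the exon hull (first to last exonic
  base), not an annotated gene feature: annotation gene records can
  extend beyond exons, and the hull keeps "intronic" meaning "between
  exons of this gene".
* Genes whose annotation places exons on several chromosomes or strands
  are rejected outright rather than silently split.

## Problem sizes

The default test-suite conditions are the generator defaults above
(300 genes, 30 circRNA genes, 12 RBPs, 100 resampling iterations).
Planted-effect recovery is evaluated over 100 generator seeds and null
calibration over 200 seeds; knockdown recovery over 50 seeds; kernel
type-I error over 2,000 null replicates per test; interval algebra
against a per-base oracle on 1,000 random instances. These sizes make the
planted effects detectable with comfortable margins while each analysis
stage remains a few seconds of work.

## Known limitations

Coverage treats all binding evidence as binary per base; no attempt is
made to model binding affinity or peak height. The screen cannot
distinguish binding to a circRNA from binding to the cognate linear exon
— the BSJ mapping stage exists precisely because junction-spanning reads
are the only direct evidence, and with 20-25 bp reads its sensitivity is
intrinsically low. The co-localization summary treats compartments as
sets, ignoring abundance. Host-gene assignment takes the
maximum-overlap strand-matched gene and can be wrong for nested or
read-through loci.
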