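---
title: "Models and methods behind zfpkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind zfpkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zfpkit)
```

`zfpkit` integrates multi-omic measurements of zinc-finger protein (ZFP)
function. This vignette documents the statistical models, the tunable
parameters and their defaults, the design decisions taken where several
reasonable implementations existed, what the synthetic-data generators do
and do not emulate, and the package's known limitations.

## Coordinate conventions

All genomic intervals are 0-based half-open (BED convention), including
protein residue intervals. Minimal GTF input (1-based closed) is converted
on read. TSS and TTS are single base coordinates derived from strand
(`tss = start` on `+`, `end - 1` on `-`). Unstranded (`.`) features are
treated as `+` with a warning, because the signed-distance and metagene
operations cannot orient unstranded data.

## Knockdown events and batch residuals

Significant events use the conventional thresholds for this assay family:
DEGs at FDR < 0.05 with fold change above 20% in either direction
(|log2FC| > log2 1.2), splicing and APA events at FDR < 0.05 with
|ΔΨ| > 0.2. All cutoffs are strict inequalities; records with missing FDR
are excluded and tallied.

Event counts across knockdowns are confounded by experimental batch. The
batch model is ordinary least squares of counts on batch indicators with
the intercept dropped (cell-means coding), so each dataset's predicted
count is its batch mean. This is the simplest model consistent with
"batch as covariate, count as response", and it makes the within-batch
residuals sum to zero exactly. Counts are modelled on the identity scale,
not log scale, matching the response being a raw event count.

Per-dataset outlier significance uses the externally studentized residual
referred to a *t* distribution with *n* − *k* − 1 degrees of freedom — the
standard single-case deletion test for OLS outliers. The test is two-sided
by default (one-sided is available), but flagging additionally requires
the residual percent fold change to exceed +20, so only excesses are
flagged. A dataset whose raw residual is numerically zero is never an
outlier; its studentized residual is forced to zero to avoid 0/0 in
perfectly fitting batches. The regression F-test p-value is reported as a
model-fit diagnostic attribute, and is `NA` for perfect fits; it plays no
part in flagging. Each batch must contain at least two datasets, otherwise
its residual variance is undefined and the fit refuses to run.

## eCLIP window annotation and enrichment

Windows are classified by their midpoint — deterministic and robust to
window length, given that upstream window callers emit roughly uniform
widths. Splice-site classes take precedence over containment classes:
within 50 bp of a donor or acceptor coordinate is ADJ, within 300 bp is
PROX; the nearer site wins and exact ties resolve to the 3' splice site
(acceptor). Donors and acceptors are strand-aware boundary coordinates of
internal exon junctions. Outside those tiers the class is the containment
feature holding the midpoint; genes without a CDS classify exonic
midpoints as `noncoding`; a window not overlapping its gene is
`intergenic`.

Feature enrichment is the sample odds ratio of a 2×2 table (window
in/out of class × IP/background) with a one-sided (greater) Fisher exact
p-value computed as the hypergeometric upper tail. The Haldane–Anscombe
0.5 correction is applied to all four cells only when some cell is zero,
and only for the ratio — the exact p always uses raw counts. The
background window set is caller-supplied: background generation
(region-matched sampling) is the window caller's job, and the synthetic
module supplies a length-uniform sample over genic space.

Binding breadth counts unique gene ids; `widespread` uses ≥ 500 (a
*minimum* of 500), while the dual-binder rule is strictly > 500.

## RBNS motif derivation

Pentamer counting (k configurable) slides over the full read including
constant flanks if present; reads with non-ACGU(T) symbols are skipped and
tallied. Enrichment R is the pulldown frequency over the input frequency
after adding a pseudocount of 1 to every count. The pseudocount keeps R
finite for k-mers unseen in one pool and perturbs abundant k-mers by well
under 1% at typical pool sizes.

The top 20 k-mers are aligned to the most enriched k-mer under the
priority exact > 1 mismatch > 1 offset > 1 offset + 1 mismatch >
2 mismatches, with offset magnitude capped at 1. The source protocols for
this alignment scheme describe the budget as "1 mismatch and/or 1 offset,
or 2 mismatches" but end the priority list with "2 offsets", which is
unsatisfiable for a single pair under a ±1 offset cap; the implementation
follows the budget reading and places 2 mismatches last. Within a
category, ties resolve to the smaller |offset|, then the negative offset —
an arbitrary but deterministic contract. K-mers admitting no category are
collected and the procedure recurses on them with a new anchor, so every
top k-mer belongs to exactly one motif group.

The weighted PWM adds each aligned k-mer's R to the matching base at every
covered position. Column support (total R) drives edge trimming: edge
columns with support below `trim_frac` (default 0.25) of the maximum
column support are removed iteratively from both ends, never from the
interior. The trimming threshold is configurable because the protocol
description gives none; 0.25 removes columns supported only by one or two
offset k-mers while keeping genuinely shared flanks. The reported
consensus is the per-column argmax of accumulated weight; because offset
k-mers widen the matrix, a planted consensus appears as a (typically
centered) substring of the group consensus.

## Protein features

ARM-like loci: a 0-based center is a locus when K/R frequency in the
5-residue window centered on it strictly exceeds 0.5 (i.e. at least 3 of
5) and the center is at least 2 residues from either terminus. IDRs are
maximal runs with disorder score strictly above 0.4; putative RBDs are
maximal runs with occlusion Z strictly below −1 (minimum run length 1 by
default, configurable — the source postprocessing merges per-residue calls
without a stated minimum). Overlap tallies use half-open interval
intersection; ARM centers count as width-1 intervals; zinc-finger domain
labels are configurable.

## Set integration

Overlap tests build the full 2×2 table within an explicit universe and
compute the one-sided Fisher p as the hypergeometric upper tail (the
hypergeometric ≥ test is the same quantity by duality; a two-sided Fisher
is available). The universe is the caller's choice; the natural default
in knockdown integration is the set of genes actually tested for
differential expression. Panels of tests get Benjamini–Hochberg adjusted
p-values alongside raw ones; flagging follows raw p by default since
panel-level decisions in this field conventionally show raw p against a
0.05 line. The regulated-cassette count links a window to an event when
the gap between the window interval and the nearer cassette junction
coordinate is at most 50 bp (0 when the junction lies inside the window),
counting each gene once.

## DNA/RNA colocalization

Dual binders (DRBPs) bind strictly more than 500 unique genes at both the
DNA and RNA level; DNA peaks farther than 100 kb from their nearest gene
are excluded from the DNA count. Peak-to-window distances are midpoint to
midpoint, restricted to windows on the same gene, signed positive when the
window lies 3' of the peak in the gene's orientation; the nearest window
is the smallest |distance| with ties resolving downstream. Midpoints are
the default anchor because the upstream peak callers disagree about
summits; a summit-based anchor is a one-line change at the call site.

Metagene profiles place each window at
100·(oriented distance from gene 5' end to midpoint)/(gene length),
clipped to [0, 100] and floored to integer percent — 101 bins, so
"within 2% of transcript length" is exactly bins {0,1,2} and {98,99,100}.
Profiles are normalized to sum to 1. The TSS/TTS test compares per-profile
proximal densities between groups with a two-sided Mann-Whitney U
(normal approximation), per end separately.

## SLAM-seq and Ribo-STAMP

SLAM filtering: CPM = conversions·10⁶/library total, strict > 5; a
replicate passes a gene only if it passes at all four timepoints
(0/2/4/8 h), and a gene is retained with the ≥ 2 replicates that pass.
Retained replicates are averaged per timepoint, normalized to the t = 0
mean, and fitted with y(t) = exp(−kt) by least squares on the linear scale
(one-parameter 1-D minimization, bracketed in k ∈ [−2, 50] h⁻¹, tolerance
10⁻¹²). The linear-scale fit is preferred to log-linear because normalized
points near zero at late timepoints would otherwise dominate; there is no
plateau term, matching a first-order model. R² is computed on the
normalized points and fits pass at R² > 0.6 with k > 0; half-life is
ln 2/k. Half-life shifts between conditions use a two-sided Mann-Whitney U
over passed target-gene half-lives, with the same test on non-targets
reported as a specificity control.

Ribo-STAMP EPR is edits over exon reads; genes need nonzero edits in all
four samples (2 knockdown + 2 control). The differential test is an
independent two-tailed t-test with pooled variance on n = 2 vs 2, BH
corrected, significant at FDR < 0.1. A t-test on two observations per
group is anti-conservative under non-normal noise; the null-calibration
test documents an observed significant fraction bound of 0.15 at the 0.1
threshold rather than pretending nominal control.

## Tethering reporters

Stability wells are normalized by the mean firefly/Renilla ratio of the
control construct (defaulting to a construct literally named `control`,
configurable since the baseline construct is a per-experiment choice).
Hits are one-tailed independent t-tests at p < 0.05 with at least three
wells per side. The splicing reporters are tested on a percent-inclusion
proxy, 100·firefly/(firefly + renilla) per well; the proxy is configurable
because the published readout ("change in percent inclusion") does not
print its conversion. Upstream- and downstream-tether constructs are
independent tests; a ZFP is a splice hit if either is significant. Hit
decisions are invariant under global rescaling of luminescence, which the
tests verify.

## The synthetic-data module

Every generator is a pure function of a configuration and the master seed;
each derives its own RNG stream from the seed and a fixed label, so adding
a generator never perturbs another's output, repeated calls are
byte-identical, and the caller's RNG state is untouched.

The generators emulate the *shapes and planted signals* of the real
assays, with the simplest noise model matching each data type's support:
Poisson for counts (event counts, SLAM conversions, edits, exon reads),
lognormal for luminescence, Bernoulli placement for binding windows.
Default study conditions follow the assay designs: SLAM timepoints
0/2/4/8 h with 3 replicates and Poisson depth 1000 (library total 4×10⁵,
so a depth-1 gene sits at 2.5 CPM and fails the filter); RBNS reads of
20 nt with the motif planted in 30% of pulldown reads; Ribo-STAMP with
2 + 2 samples at depth 20 000 and 2% lognormal rate noise; tethering wells
at 10% lognormal noise with 3 replicates; knockdown batches with
Poisson-distributed significant-event counts around configurable batch
means. Genes are 2–10 kb with 1–10 exons (30 bp minimum exon/intron),
both strands, non-overlapping, with a 15/60/25% UTR5/CDS/UTR3 partition of
exonic space in transcript order and a 10% noncoding fraction.

What the generators do *not* emulate — and therefore what passing tests do
not establish about real data: overdispersion beyond Poisson, correlated
replicates, sequence composition bias, mappability, overlapping genes,
crosslinking biases in eCLIP, RBNS secondary-structure effects, or partial
knockdown efficiency. The protein generator draws background residues
without K/R by default so planted ARM loci are exactly the positions
satisfying the window rule; a background K/R frequency can be switched on
for realism at the cost of exact ground truth.

One deliberate interaction: binding simulations plant feature odds over
*containment* classes, while the annotator's splice-site classes take
precedence by default. Scoring planted-odds recovery therefore disables
splice-site classes (`use_ss_classes = FALSE`); with them enabled, the
recovered odds ratio is biased toward 1 because both in- and out-of-class
windows near junctions are reassigned.

## Problem sizes and numerical choices

The test suite and acceptance script run at deliberately desk-scale sizes,
chosen as the smallest sizes at which each estimator's sampling error is
well inside the tested tolerance: 5000 windows for odds-ratio recovery
(log2 OR within ±0.3 of log2 8), 200 genes for half-life recovery (≥ 90%
of R²-passing genes within 15%), 50 000 reads for motif recovery, 1000
genes for EPR sensitivity, 8 datasets per batch across two batches for
outlier flagging. Exact-test oracles (hypergeometric enumeration,
brute-force alignment, per-position ARM recount, all-pairs cassette scan)
run on small universes where enumeration is exact to 10⁻¹².

Decay fitting brackets k in [−2, 50] h⁻¹, covering half-lives from 50 ms
to "no decay" with sign information retained so rising series report
k ≤ 0 and fail cleanly. Degenerate inputs are contracts, not accidents:
empty window files parse to empty frames; header-only tables are valid;
genes whose t = 0 mean is zero are dropped with a reason; batches with one
dataset, groups with one profile, and screens with fewer than three wells
are errors.

## Limitations

* The feature-class assignment rule (midpoint) is one of several
  defensible readings of upstream window annotation; any-overlap
  assignment would count windows in multiple classes and break the
  one-class-per-window invariant this package relies on.
* The per-dataset outlier p-value derivation for batch residuals is the
  standard studentized-residual test; published analyses of this design
  report a per-dataset p without deriving it, so other choices (e.g.
  Poisson tail tests) are plausible and would differ for small counts.
* The 2v2 EPR t-test is anti-conservative; treat its FDR as a ranking
  device rather than a calibrated error rate.
* Metagene profiles weight every window equally; no within-gene
  normalization is applied, so a single heavily bound transcript can
  dominate a profile with few windows.
* The pipeline consumes upstream tool outputs (window calls, peak calls,
  differential tables, conversion counts) as given; it does not model
  their internal uncertainties.
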