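---
title: "Methods: from methylation context to MeCP2 occupancy and expression change"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from methylation context to MeCP2 occupancy and expression change}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methocc)
```

# The analysis chain

`methocc` implements five connected analyses around one biological
question: does the density of MeCP2 binding sites (methylated CG and,
distinctively, methylated CAC tri-nucleotides) explain where the protein
sits on neuronal chromatin, and does that occupancy in turn predict which
genes move, and in which direction, when MeCP2 is deleted (KO) or
over-expressed (OE)?

1. **Context statistics** turn per-cytosine basecall counts into
   region-level summaries.
2. **Input-corrected occupancy** turns ChIP and Input fragment sets into a
   windowed log2 ratio, after first asking how much of the ChIP signal the
   Input alone predicts.
3. **Summit meta-profiles** test whether methylation density focuses at
   points of maximal enrichment.
4. **Multiscale segmentation** finds enrichment/depletion domains across a
   ladder of smoothing scales and annotates them with methylation density.
5. **Globally-rescaled differential expression** estimates per-gene fold
   changes under a correction for the knockout's global RNA reduction, and
   relates their sign to occupancy.

Each step is exposed as a tibble-in/tibble-out function so the chain can be
run whole (as `scripts/acceptance.R` does) or entered at any point with
external data read through `read_fasta()`, `read_intervals()`,
`read_cytosine_report()` and `read_bedgraph()`.

## Coordinates and formats

Internally everything is 0-based, half-open — BED semantics. The single
deviation at the boundary is the cytosine report, whose file dialect is
1-based; `read_cytosine_report()` preserves the file convention and
`attach_calls()` performs the single `-1` shift on ingest, so the shift
exists in exactly one place. Strand `"."` is legal on intervals but never
on cytosine records. Signal tracks are written as bedGraph with
six-significant-digit rendering, which bounds write→read round-trip error
at 1e-5 relative — tighter than any statistic downstream consumes.

# Methylation statistics

For a site $i$ the level is $m_i = \mathrm{mC}/\mathrm{C}$ over its
basecalls; sites with zero coverage are retained but excluded from means
(minimum coverage to enter a mean is 1 read, configurable). For a region of
length $L$ and context CX,

$$ m'_{CX} = \frac{1}{N_{CX}} \sum_i m_i, \qquad
   \text{density}_{CX} = \frac{N_{CX} \, m'_{CX}}{L}, $$

with density stored per bp and reported per kb (the plotting unit
throughout). Density is bounded by $N_{CX}/L$ with equality iff every site
is fully methylated — a property the test suite checks against a
brute-force per-site loop at 1e-12 on hundreds of random regions.

Contexts are read 5′→3′ on the cytosine's strand; a base beyond the
chromosome end or an `N` voids only the affected rank, so a site can carry
a di-context but an `NA` tri-context. Genome-wide tables report (i) the
context composition of all cytosines, (ii) modified-context fractions, and
(iii) mean methylation per tri-nucleotide. For (ii) the construction of
the corresponding published pie chart is not stated, so two modes exist:
the default weights each covered site by its level (expected-count
weighting), a binary mode counts sites with level ≥ 0.5. The default was
chosen because it is threshold-free and unbiased at any coverage.

BS and TAB channels are resolved as `hmc = tab`, `mc = max(0, bs − tab)`;
clamp events are counted and surfaced because systematically frequent
clamping indicates channel miscalibration rather than noise. The
non-conversion rate pools all spike-in sites into one binomial estimate
with an exact (Clopper–Pearson) interval; at zero observed events its
upper bound reproduces the familiar rule-of-three scale.

# Input-corrected occupancy

Fragments are assigned to the window containing their shifted 5′ position
(`start + shift` on +, `end − 1 − shift` on −). The shift is a plain
argument: the source protocol shifted reads by the full estimated fragment
length (134 bp), while the conventional choice is half a fragment; the
generator emits fragments whose half-fragment-shifted position is exact, so
the package default in examples is `shift = 67`. Counts are RPKM-normalised
by assigned-library size; fragments shifted off the partition go to a loss
tally so that `sum(counts) + lost == n_fragments` always holds.

Occupancy is $\log_2((\text{ChIP}+\psi)/(\text{Input}+\psi))$ with
pseudocount ψ = 0.5 RPKM by default — small enough not to bias covered
windows at the depths used, large enough to keep empty windows finite.

The Input-predictability model is ordinary least squares of ChIP on Input
across windows. The outlier partition has two modes because the published
analysis states only the resulting fractions, not the rule: `"quantile"`
labels the lowest 4.1% of residuals depleted and the top 1.7% enriched
(the printed fractions, used for reproduction-style displays), `"zscore"`
uses standardized residuals beyond ±2 (the statistically motivated mode,
used for recovery tests, since quantile mode labels outliers even under a
perfect null). The neutral-set R² is a full refit, not a residual
recomputation.

The AT-flank comparison asks whether isolated methylated sites flanked by
a run of ≥ 4 consecutive A/T bases *starting* within ±13 bp carry more
occupancy. "Isolated" (no other candidate site within ±50 bp) is our
choice, exposed as an argument; it prevents one summit-dense locus from
dominating both groups. The group difference carries a bootstrap 95% CI
(1000 resamples); on the uncoupled generator the CI covers zero at its
nominal rate.

# Summits and profiles

The summit caller is deliberately simple and documented as such: its
contract is summit *position*, not score, agreement with full peak
callers. Enrichment per fine window is smoothed by a centred running mean
(edge windows shrink rather than pad), candidate peaks are maximal runs
above the score threshold, and each peak must clear a Poisson upper-tail
test of its summed ChIP count against the library-scaled Input (floored at
the genome-mean Input so zero-Input runs cannot self-certify); default
p-threshold 1e-5. The summit is the argmax of smoothed enrichment,
leftmost on ties.

Profile matrices average a signal in fixed bins around anchors. Two signal
modes share one implementation via an exact step-function integral: tracks
take length-weighted means per bin; methylation sites take density per kb
per bin. Anchors whose full flank leaves the chromosome are dropped and
tallied rather than zero-padded, because zero-padding biases aggregate
edges downward. Minus-strand anchors are column-reversed so downstream is
always rightward. With an even bin count the anchor sits on the boundary
between the two central bins, so locality checks accept the maximum in
either.

# Multiscale domains

The segmentation is an explicitly simplified multiscale scheme — the
published multiscale representation tool is used as a black box in the
source analysis, so we preserve its *outputs* (segments with a scale, a
signed score, annotations) rather than its internals. At scale $s$ both
count tracks are mean-smoothed with window $w_0 2^s$; the score is the
library-ratio-corrected log2 ratio of the smoothed tracks; candidate
segments are maximal one-signed runs with $|score| \ge 0.3$; each is kept
if a two-sided binomial test of its summed raw ChIP count against the
library-scaled expectation gives $p < 10^{-6}$. The binomial test on raw
sums (not smoothed values) keeps the significance decision calibrated:
under a null generator the suite verifies the significant-segment count
stays within the binomial-null bound across 20 seeds. Scores are reported
as segment means; segments at different scales deliberately nest
(no pruning), matching the unpruned displays the analysis style calls for.
Mappability is assumed uniform — the published mappability-map background
is out of scope — and the 1e-6 threshold is retained.

The scale ladder default in examples is a 1 kb base window with 6–13
doublings, spanning sub-CGI scales (~1 kb depletions) up to
hundred-kb-to-Mb domains at the package's desk scale. Our scale indices are
not claimed to correspond numerically to any external tool's scale units.

# Differential expression with a global rescaling

Size factors are median-of-ratios (geometric means over genes positive in
all samples); the unit test cross-checks against an independent reference
implementation. `apply_global_scale()` multiplies one condition's factors
by a constant — the bespoke analytical element here, encoding externally
measured knowledge (total RNA per cell ~15% lower in KO; factor 1.15) that
count normalisation cannot see.

A note on direction, because it is easy to get wrong. In the real
experiment, libraries are loaded at equal mass, so a uniform 15% loss of
transcripts is invisible to counts; median-of-ratios then centres the
median gene at zero fold change, and *multiplying* KO size factors by 1.15
shifts all normalised KO expression down, revealing the global reduction.
In the synthetic world the generator plants the 0.85 scale directly in the
count expectations (libraries are not re-equalised), so plain unit factors
already *show* the reduction (median log2FC = log2 0.85 ≈ −0.234), and
recovering the pre-scaling truth requires the reciprocal move: an
effective KO factor of 0.85 (exactly) or 1/1.15 (the measured magnitude)
brings the median back to ≈ 0 and ≈ −0.033 respectively. The acceptance
script reports all three medians so the direction logic is visible in
numbers.

The NB test is self-contained: group means are means of
size-factor-normalised counts (chosen over the weighted pooled estimator
because it is *exactly* invariant to rescaling a sample's counts and
factor together — a property the suite asserts); per-gene moment
dispersions from within-group variances are shrunk toward a fitted
$a + b/\bar{q}$ trend and floored at 1e-8; the Wald statistic on the log
fold change is referred to the normal distribution, BH-adjusted over
tested genes. The shrinkage weight defaults to 0.7: with three replicates
per group, moment dispersions are noisy enough that weaker shrinkage
leaves the test mildly anticonservative, while 0.7 centres the type-I
fraction near nominal without costing power at |log2FC| = 1 and
mean counts ≥ 100 (both properties are asserted in the suite). No claim of
numerical agreement with any reference differential-expression tool is
made or needed: the acceptance surface is calibration and power on
simulation.

Classification applies the published thresholds — TPM < 5 in all samples →
`filtered`; padj < 0.05 with sign → `up`/`down`; padj > 0.5 and
|log2FC| < 0.01 → `unchanged`; else `other` — with BH recomputed over
unfiltered genes only. Gene occupancy defaults to the body ± 100 kb mean
(differential binding extends well past gene boundaries; a body-only mode
exists). Rolling curves use 400-gene windows stepped by 80; window curves
use groups of 1000; both sort stably so ties preserve input order.

# The synthetic-data generator

The generator is first-class, tested code. Its defaults *are* the study
conditions: two 5 Mb chromosomes; 50 planted CpG islands of 1 kb per
chromosome; mCG ≈ 0.8 outside islands and 0.05 inside; domain-structured
mCAC (0.20 in high domains, 0.05 in low, half of domains high — giving a
genome mean near the ~12% seen in neuronal CAC); per-site depth
Poisson(30) with a 0.5% non-conversion floor; Input depth 50 fragments per
1 kb window modulated by a logistic GC bias; ChIP intensity
$= \text{Input} \cdot \exp(\beta(d - \bar d))$ with $\beta = 0.15$ per
(sites/kb) of combined mCG+mCAC density $d$; 134 bp fragments; negative
binomial counts (dispersion 0.05, three replicates per condition) with
half the genes coupled at 1 log2FC per occupancy unit and a global KO
scale of 0.85. Each stage draws from its own seed-offset stream so
changing one stage's parameters never perturbs another's draws.

Where the generator needed a choice the literature did not fix: island
composition is ~65% GC with CpG observed/expected ≈ 0.65, like real
islands, rather than maximal CG density — with maximally CG-dense islands
the *absolute* mCG density inside islands exceeds the genome background
even at 5% methylation, and the characteristic occupancy dip over islands
(which the density coupling should produce by itself) inverts into a bump.
The coupling of occupancy to expression is linear in log2 space; the
source analyses assert only a monotone association, and linearity is the
simplest monotone choice with one interpretable parameter. The mCG and
mCAC contributions to ChIP intensity enter through their combined density;
separate weights can be emulated by adjusting the context levels.

What the generator does **not** emulate — and therefore what passing tests
do *not* establish about real data: long-range compositional
autocorrelation (isochores), so the synthetic Input is nearly pure Poisson
noise and the ChIP ~ Input R² is near zero by construction, whereas on
real data the same model explains most of the variance; mappability and
blacklist structure; read sequences and alignment error; bisulfite
conversion failure beyond one global rate; diploidy; and realistic
transcript structure (genes are single-exon spans). Conclusions about the
pipeline's *statistical* behaviour (calibration, recovery, sign fidelity)
transfer; conclusions about effect *sizes* on real genomes do not.

# Numerical conventions and degenerate inputs

Running means shrink at edges (no padding). Ties: summit argmax takes the
leftmost; sorting for curves is stable. Zero-coverage methylation sites are
excluded from means but never dropped from tables; regions with no sites
report density 0 and mean `NA`. Zero-variance Input aborts the linear fit
with a specific error, as do empty scale lists, empty regions, non-positive
window widths, and report records at non-cytosine positions (named with
their coordinate). Empty cytosine reports warn and return an empty tibble.
All randomised routines take explicit seeds.

# Problem sizes

The test suite and acceptance script run at the package's desk scale: 5–10
Mb of genome per simulation, 1–5 thousand windows per track, 1–2 thousand
genes, 20-seed loops for calibration and recovery properties, which keeps
the whole suite in the low minutes on one core while leaving every
statistical check comfortably powered.

# Limitations

The summit caller and multiscale segmentation are simplified stand-ins
whose contracts are positional and calibration properties, not score-level
agreement with MACS-style or wavelet-based tools. The published
genome-scale figures (an Input-model R² of 0.84, specific
differential-expression gene counts, specific rank correlations) are
properties of the deposited external datasets and are not reproduced at
desk scale; the package reproduces the *methods* and verifies them on
ground-truthed simulation instead.
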