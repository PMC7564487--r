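---
title: "Methods: copy-number markers and triple DNA FISH scoring for follicular thyroid neoplasms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: copy-number markers and triple DNA FISH scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Fine-needle aspiration cytology cannot separate classic follicular
adenoma (cFA) from classic follicular thyroid carcinoma (cFTC): the two
differ histologically only by capsular or vascular invasion, which
cytology cannot see. A small panel of somatic copy-number markers —
loss of 1p36.33–p35.1, loss of 22q13.2–q13.31, and gain of the whole X
chromosome — is carried by roughly half of cFTCs and essentially never
by cFAs, so a three-panel interphase FISH assay scoring these loci
(1p36.31 vs 1q25.3, 22q13.3 vs 22q11.2, CEP X vs CEP Y) can "rule in"
carcinoma on already-stained cytological slides.

`thyrofish` implements the complete computational side of this scheme:

1. an aCGH analysis chain that discovers the discriminating regions from
   two-class log2-ratio profiles;
2. a FISH nucleus-count scorer that turns per-nucleus signal counts into
   case-level marker calls;
3. DNA-index ploidy classification;
4. pooled diagnostic accuracy statistics with exact binomial confidence
   intervals and prevalence-adjusted predictive values;
5. a synthetic-cohort generator with the statistical structure the
   analysis assumes, so the whole chain runs end to end without patient
   data.

## The copy-number signal model

A specimen with tumor-cell fraction $\rho$ (purity) carrying $c$ copies
of a locus whose (sex-matched) reference copy number is $b$ has expected
log2 ratio

$$\mu(c, b, \rho) = \log_2\frac{\rho\,c + (1-\rho)\,b}{b}.$$

With the study's purity floor $\rho = 0.8$, a single-copy autosomal loss
sits at $\log_2 0.6 \approx -0.74$, a female whole-X gain (2→3 copies)
at $\log_2 1.4 \approx +0.49$, and a male whole-X gain (1→2 against a
male reference) at $\log_2 1.8 \approx +0.85$. The generator adds a
linear GC bias, a constant dye offset, and i.i.d. Gaussian probe noise.
The noise sd defaults to 0.12 log2 units — a free parameter of the
generator, chosen as typical for oligonucleotide arrays of this class;
no published figure exists for the source arrays.

## Normalization

`normalize_profile()` removes the GC trend by locally-weighted
regression (`lowess` of ratio on probe GC fraction, span 2/3) and then
median-centers the residuals (the dye offset).

One choice needs justification: on the default reduced probe grid
(chromosomes 1, 22 and X; one probe per 100 kb) the X chromosome holds
about a third of all probes, so a whole-X gain drags the global median
away from the true baseline and would push every other chromosome into
apparent loss. The pipeline therefore anchors the centering median on
**autosomal probes only** (`center_idx`), which is robust to
sex-chromosome dosage. On a genome-wide grid the distinction is nearly
immaterial; on the reduced grid it is essential. Profiles end centered
at median 0 (within 1e-9) over the anchoring set. Constant GC input
skips the GC step with a warning and only centers.

## Segmentation: circular binary segmentation

Each chromosome's probe values are arranged on a circle. For a cut pair
$(i, j)$ defining an arc of length $k$ out of $n$ probes, the mean-shift
statistic is

$$T^2(i,j) = \left(d - k\bar{x}\right)^2 \frac{n}{k\,(n-k)},$$

where $d$ is the arc sum — the two-sample $t$ statistic with unit
variance, whose scale is irrelevant under the permutation null. The scan
(compiled code; the k-outer/i-inner order also fixes the tie-break: the
first maximum in scan order wins) finds the maximizing arc; the split is
accepted when its permutation p-value is below `alpha` (default 0.01),
and accepted sub-segments are recursed into, depth-first in genome
order. Arcs narrower than `min_width` (default 2) probes are never
considered; chromosomes with fewer than `2*min_width` probes stay whole
with a warning.

The permutation test draws full permutations (`sample.int`) from a
seeded stream, capped at `nperm` (default 10,000), with a sequential
early-stopping rule: after $m$ draws with $e$ exceedances, stop and
reject the split once the final p-value $(1+e)/(1+m)$ is already
guaranteed to reach `alpha`, or once the Clopper–Pearson lower bound (at
level `1 - stop_delta`, default 0.999) on the exceedance probability
passes `alpha`; stop and accept once the corresponding upper bound falls
below `alpha`. The reported p-value is $(1+e)/(1+m)$ over the draws
actually made. The rule is deterministic given the seed, and the
brute-force reference implementation in the test suite replays the same
stream and the same rule while enumerating every arc naively — the two
agree exactly on every small profile in the suite.

No segment merging/pruning beyond the recursion stop is performed.

## Noise-adaptive calling

The per-profile noise is
$\tau = \mathrm{median}\,|x_{t+1} - x_t| / 4$ over consecutive probes in
genome order, never crossing a chromosome boundary (crossing would
inject spurious distances between unlinked loci). A segment is called a
gain (loss) when its mean is at or beyond $\pm\max(\tau,
\mathrm{floor})$ and it spans at least `min_probes` (default 3)
consecutive probes. The floor (default 0.05 log2 units) exists because
$\tau$ collapses to 0 on noise-free synthetic data, which would call
everything; it is configurable. $\tau$ is computed on the normalized,
unsegmented profile.

## Marker discovery

Sample segmentations are overlaid on the union of their breakpoints;
every resulting region lies inside exactly one segment of every sample
(probes belong to regions by midpoint). Per region, a two-sided Wilcoxon
rank-sum test compares cFA vs cFTC segment means — exact enumeration
when the smaller group has ≤ 10 values and no ties, normal approximation
with continuity and tie correction otherwise. Candidate markers must be
"normal" in **every** cFA (a hard filter, asserted on every run) and are
then selected greedily: first the region covering the most cFTC samples
in its aberrant direction, then repeatedly the region covering the most
not-yet-covered cFTC samples, ties broken by smaller raw p then genome
order, stopping when nothing new is covered.

**Why the raw-p gate is off by default.** With $m$ carriers among $n$
carcinomas versus $n$ marker-negative adenomas, the non-carriers are
exchangeable between classes, so the rank-sum z-statistic is bounded by
roughly $m\,\sqrt{3/n}\,\big/\,\sqrt{1 + n/n}$ — numerically
$z \lesssim 0.21\,m$ at $n = 33$ — and a two-sided p below 0.05 needs
$m \ge 10$. The markers of interest have $m = 5$–$8$: a 0.05 gate would
discard every true marker while the all-cFA-normal filter plus a minimum
coverage (default 2 carriers) does the actual discriminating work. The
p-value therefore serves as ranking key and tie-break; an explicit
`p_threshold` argument restores the gate when a caller wants it.

Because the greedy step picks cells of the union-breakpoint grid, a
selected cell can be a slice of the real alteration (an unrelated
breakpoint elsewhere slices the grid). Selected markers are therefore
refined to their **minimal common region**: each covering sample's
aberrant interval is grown to its maximal run of contiguous
same-direction calls, and the intervals are intersected across carriers.

## FISH scoring

Per nucleus, the locus panels (1p36.31/1q25.3 and 22q13.3/22q11.2) are
read as a target:control ratio so polyploid nuclei score correctly
(3 target vs 6 control is a loss): with ≥ 2 control signals, fewer
target than control signals is a loss, more a gain, equality normal.
Fewer than two control signals leaves the target dosage unanchored and
the nucleus is uninformative — deliberately including the ambiguous 1:1
pattern, which could equally be whole-chromosome loss; it is tallied as
uninformative rather than guessed. The CEP X/Y panel scores X dosage
against the expected sex baseline; the male 2X/1Y pattern counts as a
gain ("trisomic"), and the male 1X/0Y monosomy-like pattern is
uninformative.

A case's panel is "insufficient" below 100 informative nuclei
(uninformative nuclei leave both numerator and denominator). Otherwise
the marker is positive when the aberrant-pattern fraction reaches the
positivity cutoff. **The cutoff is a design constant of this
implementation** — the assay description does not state one — set to
0.20 of informative nuclei, a conventional clinical FISH deletion
cutoff; it is a mandatory, reported parameter of `score_case()`. A case
is positive iff at least one marker is positive. Raising the cutoff can
only remove positives (monotonicity, covered by tests).

## DNA-index ploidy

Single DNA indices classify by interval: [0.9, 1.1] diploid,
[0.6, 0.9) ∪ (1.1, 1.8) aneuploid, [0.5, 0.6) haploid, [1.8, 2.2]
tetraploid, outside [0.5, 2.2] unclassifiable. The source intervals
overlap at their printed endpoints; boundaries here go to the more
benign class (diploid closed, aneuploid open at 1.1), a documented and
configurable choice. Two or more *distinct* DIs mean multiploidy, with
"distinct" operationalized as separated by more than 0.05 — the scale of
flow-cytometric CVs; exact floating-point equality would be meaningless.

## Diagnostic accuracy

Per-set positive/tested counts pool cellwise into one 2×2 table
(positive = marker-positive call, disease = cFTC by histology; cases
with insufficient FISH are excluded, not counted negative). Sensitivity,
specificity, PPV, NPV, accuracy and prevalence each get an exact
Clopper–Pearson 95% interval on their numerator/denominator pair;
Clopper–Pearson was adopted because it reproduces the published
sensitivity and specificity intervals exactly after integer rounding.
Percent renderings round half **up** (55% from 18/33, where banker's
rounding would print 54). Predictive values at an assumed clinical
prevalence $\pi$ follow Bayes' rule:

$$\mathrm{PPV} = \frac{\mathrm{se}\,\pi}{\mathrm{se}\,\pi +
(1-\mathrm{sp})(1-\pi)}, \qquad
\mathrm{NPV} = \frac{\mathrm{sp}\,(1-\pi)}{(1-\mathrm{se})\,\pi +
\mathrm{sp}\,(1-\pi)}.$$

## The synthetic cohorts

`study_design()` fixes the three sets case by case rather than sampling
them: training 33 cFA + 33 cFTC with 5 × 1p-loss, 8 × 22q-loss,
8 × X-gain among the carcinomas (one case 1p+22q, one case all three —
18 distinct positives, 21 alterations; 24 cFTC and 20 cFA with FISH, one
cFA FISH-positive for 22q without an array correlate, modeling sub-clonal
tumor heterogeneity below array sensitivity); validation 26 + 34 with 16
positive carcinomas (three 1p+22q, nine 22q, four X); feasibility
13 + 14 with two carcinomas per marker and no co-occurrence. Sex ratios
follow the published per-set tallies where available. Shared
whole-chromosome background events (gains of 5, 7, 9, 12, 14, 16, 17,
20; losses of 3, 4, 8, 11, 21) are drawn per class (defaults 6% per
event in cFA, 15% in cFTC, reflecting the higher overall imbalance
burden of carcinomas) and recorded in the ground truth.

Deliberate simplifications — and hence what passing tests do *not*
show about real data: probes are a uniform grid (one per 100 kb by
default) restricted to chromosomes 1, 22 and X, so background events sit
off-grid and cannot confound discovery unless the grid is widened
(chromosome Y carries no probes at all: a female-vs-female reference
ratio is undefined there); noise is i.i.d. Gaussian with no wave
artifacts, no segmental mosaicism beyond the one configured
heterogeneous case, and no allele-specific structure; FISH counts mix an
aberrant and a normal pattern with independent per-signal dropout, with
no imaging artifacts or nuclear truncation effects. Real arrays are
harder on every one of these axes.

FISH simulation defaults: 200 nuclei per case and panel (so that ~5%
hybridization failure and ~10% normal-cell contamination still leave
well over 100 informative nuclei), aberrant-nucleus fraction 0.6. Under
these rates a negative case's apparent loss fraction stays near 9%, far
below the 0.20 cutoff, and a positive case's near 0.5 — the case-level
error probabilities are vanishingly small, which is what makes the
pooled 2×2 table reproduce the configured counts exactly at any seed
with overwhelming probability.

## Determinism and problem sizes

A single global seed fans out to per-stage seeds through a fixed integer
recurrence (`derive_seed`), so any stage can be re-run independently;
identical configuration and seed give bit-identical outputs, including
the permutation streams of the segmenter. All derived seeds stay below
2^31.

Problem sizes used by the package's own experiments: the end-to-end
reproduction runs 66 training profiles on a 4,557-probe grid (100-kb
spacing) plus 131 FISH cases at 200 nuclei × 3 panels; the
marker-recovery experiments (probe-level F1 of implanted events over 20
seeded cohorts) run on the same 100-kb grid, segmenting each event's
chromosome. A range bound on the centered partial sums prunes whole arc
lengths from the compiled scan without changing any result, which keeps
a full permutation test on a 2,500-probe chromosome in the
low-millisecond range; the complete reproduction takes seconds on one
core.

Coarser grids are supported but deserve a warning: a leftover fragment
of only 4 probes has a segment-mean standard error (noise sd / 2 = 0.06)
*above* the 0.05 calling floor, so slicing artifacts get called at
appreciable rates. The 100-kb default keeps every fragment that
slicing can produce an order of magnitude quieter than the floor.

## Known limitations

* The rank-sum test is structurally underpowered for minority-subset
  markers (see above); discovery leans on the zero-false-positive filter
  instead, which presumes the adenoma class is genuinely marker-free.
* The segmenter implements plain CBS; no wave correction, no
  allele-specific inference, no integer copy-number fitting.
* The FISH positivity cutoff (0.20) and the multiploidy distinctness gap
  (0.05) are design constants, not published values; both are exposed as
  parameters.
* The bundled cytoband table is a constructed, synthetic approximation
  of the hg19 ideogram (correct chromosome lengths and standard band
  names where the pipeline needs them; coarse bands elsewhere). Analyses
  that need exact band boundaries should supply a real `cytoBand.txt`.
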