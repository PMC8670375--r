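---
title: "Methods: compartment-resolved LFQ analysis of bacterial secretion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compartment-resolved LFQ analysis of bacterial secretion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(secretomics)
library(dplyr)
```

## The analysis problem

Secreting bacteria such as *Bacillus subtilis* are studied by fractionating
the proteome into subcellular compartments — cytosol, membrane, and the
growth medium (the secretome) — and quantifying each fraction separately by
label-free mass spectrometry (LFQ). A typical induction experiment compares
two conditions (an induced high-level secretion state against a
non-induced control) in a handful of biological replicates per condition,
often across two strains.

Three properties of such data drive the design of this package:

1. **Missingness is informative.** LFQ detection depends on abundance:
   low-abundance proteins drop below the detection limit in some or all
   replicates. A protein reproducibly detected in one condition only is a
   *presence change* (ON/OFF), not a fold change, and must be routed around
   the differential test rather than imputed into it.
2. **Compartments are noisy.** Fractionation is imperfect; abundant
   cytosolic proteins bleed into the medium fraction. Quantification is
   therefore restricted to proteins whose predicted localization matches
   the fraction in which they were measured.
3. **Replicates are few.** With three replicates per condition,
   per-protein variance estimates are unstable, which both motivates the
   S0 moderation of the test statistic and fundamentally limits achievable
   sensitivity (quantified below).

## Pipeline stages

### Qualification and presence calling

A protein qualifies for quantification in a (strain, fraction, condition)
block when it (i) carries at least 2 unique peptides, (ii) was detected in
at least 2 of the 3 biological replicates of that condition, and (iii) has
a localization class compatible with the fraction. The default
compatibility map sends `Cytoplasmic` to the cytosolic fraction,
`CytoplasmicMembrane` to the membrane fraction and `Extracellular` to the
medium fraction; cell-wall-associated and unknown-localization proteins
are excluded everywhere, since no cell-wall enrichment is part of the
fractionation. The map is a plain table argument and can be overridden.

Presence calls compare qualification between conditions within a block:
qualified exclusively under induction is **ON**, exclusively in the
control is **OFF**, in both conditions **both** (these enter the
differential test), anything else observed at least once is **neither**.
Two readings of "exclusively" exist: failing the 2-of-3 rule in the other
condition (default), or strictly zero detections there
(`strict_absence = TRUE`). The default is the quantification-centric
reading: a protein quantifiable in one condition and not reliably
quantifiable in the other cannot be given a finite fold change, so a
presence call is the honest summary. The replicate threshold is applied
per condition, not pooled, because the ON/OFF definition requires
per-condition presence statements.

### The moderated statistic and permutation FDR

For each "both" protein the effect size is the difference of replicate
means of log2 intensities (induced minus control), over the detected
replicates. Significance uses the S0-moderated two-sample statistic

$$ t_{S_0} = \frac{\bar{x}_I - \bar{x}_C}{\mathrm{se} + S_0}, $$

with the pooled-variance standard error by default (Welch by flag; at
equal group sizes the two differ little, and pooling is the conventional
choice for this statistic). The constant $S_0$ (default 0.1, on the log2
scale) damps proteins whose tiny variance would otherwise make a tiny,
biologically meaningless difference significant. At $S_0 = 0$ the
statistic is exactly the classical pooled t (verified against
`stats::t.test` in the tests), and it shrinks monotonically to zero as
$S_0$ grows.

False-discovery control is permutation-based. Within each (strain,
fraction) block the condition labels of the replicate columns are
permuted (default 250 randomizations) and all $|t_{S_0}|$ recomputed. At
a candidate threshold $c$,

$$ \widehat{\mathrm{FDR}}(c) =
   \frac{\text{mean permuted count of } |t_{S_0}| \ge c}
        {\text{observed count of } |t_{S_0}| \ge c}, $$

and a protein's q-value is the smallest estimated FDR over the thresholds
it exceeds (a running minimum over ascending thresholds, making q
non-increasing in $|t_{S_0}|$). Ties at a threshold are resolved
inclusively ($\ge$). Nominal p-values are empirical, pooled over the
block's permutation null with add-one smoothing; they exist for reporting
$-\log_{10}(p)$ and are not what the significance decision uses.

Two numerical choices deserve emphasis:

* **Exhaustive enumeration.** When the number of distinct label
  assignments is at most the randomization budget (20 for a 3-vs-3
  design), all assignments are enumerated instead of sampled, making the
  procedure fully deterministic for the canonical triplicate design.
* **The observed assignment is not a null draw.** The observed labeling
  and its group-swap mirror (which yields the same $|t_{S_0}|$ by
  antisymmetry) are excluded from the null ensemble. Including them would
  place every truly regulated protein's own statistic into the permuted
  tail, giving the estimated FDR a hard floor of $2/20 = 0.1$ in a 3-vs-3
  design — no protein could ever reach significance at FDR 0.05, which is
  inconsistent with this kind of experiment routinely reporting hundreds
  of regulated proteins at that level.

A conventional alternative is available with `method = "bh"`: per-protein
classical t-tests with a Student-t reference and Benjamini–Hochberg
adjustment. Both routes share the qualification, presence and
classification stages.

Finally, each tested protein is classed `up` (significant, positive
difference), `down` (significant, negative), or `unchanged`; ON/OFF
classes are carried over from the presence calls.

### Aggregation

Functional-category paths (SubtiWiki-export style, up to four levels) are
backfilled to exactly four levels by repeating the deepest available
label, so that every aggregation level is total. Tallies per category
level or per regulon count each class, with multi-annotated proteins
contributing to every group they belong to and a protein classed in
several fractions counted once per group (regulation classes take
precedence over `unchanged`). Strain-level "altered protein" totals
deduplicate across fractions by default, since a protein regulated in two
compartments is still one regulated protein; `per_fraction = TRUE`
disables this. Four-set Venn region counts over (strain x condition)
qualified sets give the core proteome. The treemap exporter emits the
weighted, colored category tree (leaf weight 1, inner weights summing
children, color = log2 difference on a symmetric scale, sentinel codes
for ON / OFF / gene-deleted / unidentified proteins) as JSON; computing
the Voronoi layout itself is a rendering concern left to external tools.

Replicate quality control uses PCA on the complete-case log2 matrix
(samples in rows, centred, unscaled), with per-condition 95% confidence
ellipses from the 2-D normal approximation
($\chi^2_2$ quantile on the eigendecomposed score covariance). Groups are
called separated when the between-centroid distance on the first two
components exceeds the mean within-group spread.

### Secretion statistics

The Sec-proportion statistic answers "what share of the secretome mass
left the cell through the general secretion route": per replicate, the
summed **linear** intensity of qualified extracellular proteins with a
predicted Sec-type signal peptide divided by the summed intensity of all
qualified extracellular proteins, under induction. Summation is only
meaningful on the linear scale. The proportion is computed per replicate
and then averaged — an SD across replicates requires per-replicate
values — with a pooled-intensity variant by flag; two strains are
compared by a two-sided t test on the replicate values. The denominator
uses all qualified induced-condition proteins (not only ON proteins),
which is the natural reading of "all quantified proteins in the
fraction". The mislocalization check lists signal-peptide-positive
proteins qualified in a cell-associated fraction under induction but not
extracellularly — candidates for stalled translocation.

### Plate-reader promoter activity (TAU)

Live-cell-array reporter data (OD600 and GFP every 10 min, 12 h) is
background-corrected per time point using the mean GFP of designated
control wells — background fluorescence grows with biomass, so a single
scalar would be wrong — and converted to transcriptional activity units

$$ \mathrm{TAU}_t = \frac{\mathrm{GFP}_t - \mathrm{GFP}_{t-1}}
   {\mathrm{OD600}_t}, $$

undefined (absent, not zero) at the first time point. OD600 enters raw;
no blank subtraction is applied unless the user supplies blanked values,
since the difference quotient is insensitive to constant GFP offsets but
TAU is not insensitive to OD rescaling, and blanking conventions vary by
instrument. Negative TAU values (bleaching, noise) are preserved. Strain
summaries report the time-resolved mean +/- SD across wells and a
trapezoidal area-under-TAU ranking.

## The synthetic-data generator

Every stage is validated against simulated data with known ground truth
(`simulate_quant_experiment()`), because deposited raw MS data cannot be
redistributed inside a package and reprocessing raw spectra is out of
scope. The generator emulates the features of real compartment-resolved
LFQ data that the pipeline's logic depends on:

* per-protein baseline log2 intensities drawn from a normal distribution
  (log-normal intensities), default mean 25, SD 2 — the range MaxQuant
  LFQ intensities typically occupy on the log2 scale. The true intensity
  distribution of any given experiment is unknowable from the pipeline's
  vantage point; log-normality is a modeling choice, not a claim about
  the source data;
* condition effects as +/- `effect_log2` shifts (default 2) in the
  induced condition for a configurable fraction of proteins (defaults:
  5% up, 5% down, 3% ON, 3% OFF), replicate noise SD 0.5 on the log2
  scale — a typical replicate CV for bacterial LFQ;
* **intensity-dependent detection**: each measurement is observed with
  probability `plogis(slope * (log2 intensity - midpoint))` (defaults:
  midpoint 20, slope 1), so missingness is missing-not-at-random exactly
  as in real LFQ data; ON proteins have detection probability forced to
  zero in the control, OFF proteins under induction. Undetected
  measurements are absent rows — zero is reserved as an invalid
  intensity;
* unique-peptide counts drawn once per protein (peptide evidence is a
  protein property, not a replicate property), uniform on 1..25, so a
  small share of proteins legitimately fails the 2-peptide filter;
* localization classes drawn with realistic *B. subtilis* proportions
  (58% cytoplasmic, 24% membrane, 12% extracellular, 3% cell wall, 3%
  unknown), each protein living in the fraction matching its class
  (cell-wall/unknown proteins are placed in a random fraction, where the
  localization filter must remove them); signal peptides are frequent
  among extracellular proteins (80%) and rare elsewhere (5%);
* a small invented four-level category hierarchy and regulon pool with
  random truncation of annotation depth, to exercise backfilling and
  multi-membership tallies.

The plate generator grows wells logistically, accumulates reporter GFP by
`activity * OD(t)` per step on top of a background shared with control
wells, so that in the noiseless case TAU recovers the injected activity
exactly from the second time point on — the closed form used by the
tests.

What the generator does **not** emulate: peptide-level quantification and
protein inference, correlated (batch) noise across replicates,
between-fraction cross-contamination, saturation at the high end of the
dynamic range, and real annotation structure. Passing tests therefore
demonstrate the correctness of the pipeline's logic and its statistical
calibration under a clean MNAR model — not performance on any particular
real dataset.

## Calibration results and a documented sensitivity limit

The acceptance checks (`tests/testthat/test-acceptance.R`,
`scripts/acceptance.R`) recompute, among others:

* exact agreement of the exhaustive permutation FDR with an independent
  brute-force enumeration oracle on a 10-protein 3-vs-3 toy;
* type-I control on a global null (1,000 proteins, 20 seeds): the
  realized false-positive fraction at FDR 0.05 stays within Monte-Carlo
  error of, and in practice far below, 0.05;
* ON/OFF recall >= 0.9 for spiked presence changes, measured among
  proteins the evidence filters admit (compatible localization, >= 2
  unique peptides) — presence calling is the operation under test, and
  the generator deliberately includes proteins the localization and
  peptide filters must remove;
* recovery on 2,000 proteins with 10% regulated at effect 2 (log2) and
  replicate SD 0.5: realized FDR is controlled (~0.05), sensitivity is
  ~0.64.

That last number deserves an honest explanation. With three replicates,
the pooled SD estimate has only 4 degrees of freedom; its sampling noise
(a scaled $\chi^2_4$) means a substantial minority of truly shifted
proteins draw a sample SD large enough that **no** threshold on
$|t_{S_0}|$ can admit them while controlling the FDR. An oracle threshold
chosen with full knowledge of the ground truth (the largest
$|t_{S_0}|$-prefix with realized FDR <= 0.1) reaches only ~0.78-0.82
sensitivity under these conditions; any FDR-controlling procedure on this
statistic necessarily sits below that. The corresponding acceptance
assertion of sensitivity >= 0.9 is retained unchanged in the test suite
and fails by design rather than being weakened; the realized-FDR half of
the same check passes. Users planning experiments at n = 3 should expect
this sensitivity regime for ~2-fold effects at replicate SD ~0.5.

## Problem sizes and determinism

Simulation-based tests use 80-2,000 proteins and 10-20 seeds per
property — sizes at which the binomial/Monte-Carlo error of each checked
quantity is comfortably below the asserted margin while the whole suite
runs in a few minutes. All generators and the permutation engine are
seeded; for the canonical 3-vs-3 design the differential test is
exhaustive and therefore deterministic regardless of seed. Degenerate
inputs are defined rather than left to chance: empty qualified blocks
warn and continue, all-constant blocks warn and return no significance,
zero-variance PCA ellipses are flagged degenerate, TAU at the first time
point is absent, and a zero denominator in the strain ratio is reported
as undefined rather than infinite.
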