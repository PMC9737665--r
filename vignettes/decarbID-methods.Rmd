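---
title: "Identifying decarboxylase substrates and products from LC-MS enzyme assays"
author: "decarbID"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying decarboxylase substrates and products from LC-MS enzyme assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(decarbID)
```

## The problem and the measurement model

Amino acid decarboxylases remove a carboxyl group from an amino acid and
release it as CO~2~, producing a biogenic amine. For an enzyme of unknown
specificity the central question is *which* metabolite it consumes. decarbID
implements an in-vitro assay readout for that question: a purified enzyme
(or an empty-vector control) is incubated with a complex metabolite pool,
the reaction mixtures are measured by LC-MS, and the data are searched for a
metabolite that is *depleted* in the enzyme arm (the candidate substrate)
together with one that *accumulates* (the candidate product).

Decarboxylation leaves a precise fingerprint in mass space. The neutral loss
of one CO~2~ is

$$\Delta m = m(\mathrm{C}) + 2\,m(\mathrm{O}) = 43.98983\ \mathrm{Da},$$

and because the package considers only singly charged
$[\mathrm{M{+}H}]^{+}$ / $[\mathrm{M{-}H}]^{-}$ ions, the *same* shift
applies to the ion m/z of substrate and product in either polarity — the
adduct term cancels in the difference. A depleted ion $d$ and an accumulated
ion $a$ of equal polarity are therefore called a substrate/product pair when

$$\left|\,10^6 \cdot \frac{a - (d - 43.98983)}{d - 43.98983}\,\right| \le
\text{tol}_{\mathrm{pair}},$$

with a default pairing tolerance of 10 ppm. The tolerance is looser than the
5 ppm annotation tolerance because the pairing error compounds two measured
m/z values. Monoisotopic masses are computed from Hill-notation formulas
with a fixed five-decimal IUPAC element table (C 12.000000, H 1.007825,
N 14.003074, O 15.994915, S 31.972071); the electron mass (≈0.5 mDa) is
ignored, well below every tolerance used. `knownDecarboxylationPairs()`
ships the six reactions of the human group II enzymes (glutamate→GABA,
histidine→histamine, cysteine sulfinic acid→hypotaurine, and the three
aromatic amino acids→their amines); all six differ by one CO~2~ to within
$10^{-4}$ Da, which the test suite asserts.

## The untargeted stack

The per-run processing reimplements a standard centroid-mode untargeted
chain with these parameters (all exposed through `featureParams()`):

| step | parameter | default |
|---|---|---|
| mass detection | intensity floor | 100 counts |
| EIC building | m/z tolerance | 0.002 m/z **or** 20 ppm |
| EIC building | group intensity threshold | 200 counts |
| EIC building | min group size | 5 scans |
| smoothing | Savitzky–Golay window / order | 7 / 2 |
| resolver | chromatographic threshold | 0.85 |
| resolver | min top/edge ratio | 1.7 |
| resolver | min data points | 5 |
| aligner | RT tolerance | 0.2 min |
| aligner | m/z, RT weights | 1, 1 |
| gap filling | intensity tolerance | 1.0 |
| gap filling | min data points | 1 |

Several of these names are conventional but not self-defining; the package
fixes one interpretation and documents it:

* **Combined m/z tolerance.** "0.002 m/z or 20 ppm" is read as
  $\max(0.002, 20\,\mathrm{ppm}\times m)$ — whichever is larger at a given
  mass, the conventional reading of "or".
* **EIC building** is intensity-seeded: all points of a run are pooled,
  visited in order of decreasing intensity, and each unassigned point seeds
  a trace that greedily collects, per scan, the nearest unassigned point
  within tolerance of the running intensity-weighted center. Each point
  belongs to at most one trace. The *group intensity threshold* is applied
  to the trace's maximum point (the alternatives — sum or seed intensity —
  are not distinguishable from the parameter name alone; the maximum is the
  strictest point-wise reading).
* **Chromatographic threshold 0.85** is interpreted as an intensity
  quantile: a candidate peak's apex must exceed the 0.85 quantile of its
  trace's intensities. Because one trace can legitimately carry several
  isomeric peaks at one exact mass (leucine/isoleucine), the quantile and
  the local-minimum search are evaluated per *contiguous scan block*; a
  block boundary is declared at a gap of more than 3 missing scans, and no
  peak is ever integrated across such a gap.
* **Savitzky–Golay smoothing** uses the central least-squares kernel
  (via `signal::sgolayfilt`) on the trace interior and leaves the
  half-window edge points untouched: the endpoint filters of the standard
  implementation overshoot on steeply truncated traces and would seed
  spurious local minima exactly at peak borders. Negative smoothed values
  are clamped to zero; m/z values are never smoothed.
* **Local-minimum resolution** splits a block at every interior local
  minimum (plateau minima split at their first index, so ties go to the
  left). A candidate peak is emitted iff its apex exceeds the quantile
  threshold, the apex is ≥ 1.7 times the larger of the two edge minima,
  and it spans ≥ 5 points. Area is trapezoidal over retention time.
* **Gap filling** grows a peak outward from the most intense raw point in
  the expected m/z×RT window and stops on either side once intensity rises
  more than $(1+\text{tol})$-fold above the running minimum on that side,
  so a neighbouring peak is not swallowed. The original meaning of
  "intensity tolerance 1.0" is not defined by the parameter list it comes
  from; this reading (1.0 = may double) is the package's choice. A one-point
  fill is valued as intensity × scan interval, since a one-point trapezoid
  would otherwise be identically zero despite `min data points = 1`
  explicitly allowing such fills.
* **Join alignment** merges runs sequentially into a master list with
  score $w_{mz}\,\Delta mz/\text{tol}_{mz} + w_{rt}\,\Delta rt/\text{tol}_{rt}$;
  normalizing by the tolerances is what makes the two unit weights
  comparable. Within a run, assignments are made in ascending score order
  and each row takes at most one feature per run. Order dependence of the
  sequential merge is real but minor; the test suite checks equivalence to
  an exhaustive minimum-total-score assignment oracle on toy instances.

## Ranking and calling

Per aligned feature the group means of the gap-filled areas are formed and
the **vector/enzyme ratio**

$$r = \frac{\bar{x}_{\mathrm{vector}} + c}{\bar{x}_{\mathrm{enzyme}} + c}$$

is ranked from low to high. The pseudocount $c$ defaults to half the
smallest nonzero intensity in the table: a product that is entirely absent
from the vector arm gives $\bar{x}_{\mathrm{vector}} = 0$, and without $c$
the ratio would be degenerate. Features with $r \ge$ `fold_threshold`
(default 2) are called depleted (candidate substrates), features with
$r \le 1/$`fold_threshold` accumulated (candidate products); both
boundaries are inclusive. The threshold is a package default — the
procedure it implements is a *ranking*, and in the original use the
stand-out metabolites are identified by prominence rather than by a stated
cutoff. No multiple-testing machinery is attached because no hypothesis
test is performed; `permutationP()` provides an optional descriptive
permutation p-value, clearly outside the core procedure.

Identification then proceeds in three steps: CO~2~-loss pairing of the
depleted against the accumulated set (above); annotation of each paired ion
against a metabolite library by accurate mass (5 ppm) and, when retention
times are available, RT (±0.5 min); and MS2 confirmation, where the
experimental product spectrum is matched against library fragment lists
with a greedy cosine — candidate fragment pairs within 0.02 Da are accepted
in order of decreasing intensity product, each fragment used once, and the
score is the normalized dot product of the matched intensities. Greedy
matching is standard practice and is verified against a brute-force
enumeration over all valid matchings at small fragment counts. Intensity
weighting (square-root transforms) is available but off by default, so the
score stays transparent. The minimum accepted score (0.7) is a package
default; no similarity metric or threshold is prescribed by the assay
itself.

## The targeted panel

For the simple-system experiment (a 20 amino acid mixture or rich medium),
`loadTransitions()` carries the built-in 19-analyte triple-quadrupole
transition panel (nominal Q1/Q3, collision energies, positive mode; the
panel has no glycine entry and carries cystine rather than cysteine, and
leucine/isoleucine legitimately share one transition — they are separated
by retention time). Nominal Q1 values are validated against
formula-derived $[\mathrm{M{+}H}]^{+}$ masses to 0.25 m/z as an advisory
check only, because printed transition tables mix rounding conventions
(tryptophan is listed at Q1 = 205 against a theoretical 205.1).
`integrateTrace()` integrates an MRM chromatogram over a reference window
(default: library RT ± 0.5 min) after subtracting a straight-line local
baseline clamped at zero, which makes the area invariant under constant
baseline offsets. `panelCompare()` then applies exactly the same
pseudocount-adjusted ratio and threshold rule as the untargeted ranking.
Note one consequence of the shared pseudocount rule: when every panel
analyte is abundant, the smallest nonzero area is itself a real signal and
the pseudocount visibly compresses large ratios (a constructed 10-fold
depletion reports as ≈7 with the default rule and exactly 10 with
`pseudocount = 0`).

## What the simulator emulates — and what it does not

Because the assay's raw data are not redistributable, the package ships a
seeded generator that reproduces the *statistical structure* the analysis
assumes, and every end-to-end claim in the test suite is made against it.

`buildLibrary(n_background, seed)` returns the 20 proteinogenic amino acids
plus `n_background` random-formula CHNOS metabolites emulating a tissue
extract. Retention times are uniform over the usable gradient, base peak
heights lognormal (median 2×10⁵ counts, log-sd 0.7 — a realistic 3-order
spread with essentially no peak near the detection floor), and each
metabolite carries a random 6-fragment MS2 pattern. Background ions are
kept ≥ 25 ppm away from every known substrate/product ion in both adduct
forms so a simulated enzyme effect is never shadowed *by construction*
(collisions among background ions themselves are allowed — they are part
of the complexity being emulated).

`simulateRun()` renders each metabolite as a Gaussian elution profile
(default σ = 0.05 min) sampled on a 1 Hz scan grid over a 10-min run, with
per-point Gaussian m/z jitter (default 5 ppm), per-run lognormal replicate
variation on peak heights (default σ = 0.15, ≈15% CV), and
Poisson-count baseline centroids (20 per scan, exponential intensities with
mean 30 counts — deliberately below the 100-count detection floor, so noise
rejection is exercised without swamping signal recovery).
`simulateExperiment()` builds the two-arm design: vector runs use unit
concentrations and no product; enzyme runs scale each substrate by
1/depletion factor and add its product. `gad65Effect()` (glutamate ×10 →
GABA) and `aadcEffect()` (phenylalanine and tryptophan ×8, tyrosine ×3 →
their amines, encoding the enzyme's stronger preference for Phe and Trp)
are shipped as presets; replicate count defaults to 3 per group. All
generators are bit-for-bit reproducible from their seed.

The simulator deliberately omits: peak tailing (peaks are symmetric
Gaussians), isotope envelopes and adduct multiplicity, retention-time drift
between samples (alignment is still exercised through m/z jitter and the
resolution of near-coincident RTs), and correlated chemical noise. Passing
tests therefore demonstrate that the *pipeline logic* is correct under the
assay's assumed data model — not that the workflow is robust to matrix
effects, RT drift, or detector saturation in real data.

## Numerical choices and degenerate inputs

* Noiseless, jitter-free simulations are the calibration standard: the full
  stack recovers every injected peak with trapezoidal areas within 1–2% of
  the analytic $h\sigma\sqrt{2\pi}$ (the residual bias is the detection
  floor clipping the extreme tails plus smoothing).
* Empty spectra, empty windows, and all-below-floor scans are legal inputs
  everywhere and produce empty results, not errors; an empty candidate set
  yields an empty pair table.
* Duplicate-row filtering keeps the row with the larger total intensity,
  ties broken toward lower m/z, and is idempotent.
* Ratio ties in the ranking are broken by ascending m/z so ranks are a
  deterministic permutation.
* Test problem sizes were chosen to exercise the full stack at realistic
  complexity while staying quick: the repeated-recovery study uses 20
  simulations of a 320-metabolite library with 3 replicates per group in
  positive mode (the polarity in which both glutamate and GABA give the
  canonical ions), 10-min runs at 1 Hz; the specificity study uses ten
  vector-vs-vector experiments on a reduced background.

## Known limitations

Only singly charged protonated/deprotonated adducts are considered —
appropriate for small polar metabolites on HILIC but not for larger or
multiply charged species. Only the CO~2~ neutral loss is searched; other
enzyme classes (deaminases, oxidases) would need their own mass deltas.
The sequential join aligner has no RT-warping model, so systematic
retention drift between samples must be small relative to the 0.2-min
tolerance. Positive- and negative-mode tables are processed independently
and never merged across polarity.
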