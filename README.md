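# decarbID

Substrate and product identification for amino acid decarboxylases from
LC-MS enzyme assays.

## The problem

Amino acid decarboxylases convert amino acids into biogenic amines by
removing a carboxyl group as CO2. For an enzyme whose specificity is
unknown — say, a gene merely *predicted* to be a decarboxylase — the key
experiment is an in-vitro reaction: incubate the purified enzyme with a
complex metabolite pool, run the mixture (and an empty-vector control)
through LC-MS, and look for the metabolite the enzyme consumed together
with the one it produced. decarbID is the data-analysis side of that
experiment, for mass-spectrometry bioinformaticians and enzymologists: a
tested, reproducible implementation of the whole readout, from centroided
scans to an annotated substrate→product report.

## The method

Four connected pieces, each exposed as ordinary functions:

1. **Untargeted feature extraction** (`extractFeatures`): intensity floor
   (100 counts), intensity-seeded EIC building (tolerance
   max(0.002 Da, 20 ppm), ≥5 scans, group threshold 200), Savitzky–Golay
   smoothing, and local-minimum peak resolution (quantile threshold 0.85,
   top/edge ≥1.7, ≥5 points), then cross-sample join alignment
   (ΔRT ≤ 0.2 min), gap filling, and duplicate filtering
   (`joinAlign`, `gapFill`, `filterDuplicates`).
2. **Ratio ranking** (`rankRatios`, `callCandidates`): per feature, the
   vector/enzyme ratio of group means,
   r = (x̄_vector + c)/(x̄_enzyme + c), ranked low→high. High r = depleted
   (candidate substrate), low r = accumulated (candidate product).
3. **CO2 neutral-loss pairing and annotation** (`pairDecarboxylation`,
   `annotateFeature`, `identifyMs2`): a depleted ion d and an accumulated
   ion a of the same polarity pair when a matches d − 43.98983 Da within
   10 ppm (the adduct shift cancels, so the test is polarity-safe);
   identities are then assigned by accurate mass (5 ppm), retention time,
   and MS2 cosine matching.
4. **Targeted panel** (`loadTransitions`, `panelCompare`): the 19-analyte
   amino acid MRM transition panel for simple-system assays, integrated and
   compared with the same ratio rule.

A seeded simulator (`buildLibrary`, `simulateExperiment`) generates
realistic two-arm experiments — complex background, substrate depletion,
product accumulation, replicate noise — and is itself first-class, tested
code; `gad65Effect()` and `aadcEffect()` preset the two classic enzymes.
See `vignettes/decarbID-methods.Rmd` for the model, every parameter
interpretation, and the simulator's scope.

## Worked example

Simulate a glutamate decarboxylase (GAD65) experiment on a 320-metabolite
tissue-extract-like background, 3 replicates per group, and run the full
untargeted workflow:

```r
library(decarbID)
cfg <- decarbConfig(preset = "gad65-liver", polarities = "positive",
                    n_background = 300, n_replicates = 3, seed = 42)
rep <- runUntargeted(cfg)
rep
#> DecarbReport
#>   positive mode: 319 features ranked, 2 calls
#>   substrate/product pairs: 1

tail(rep@ranked$positive[, c("mz", "rt", "ratio", "rank")], 3)
#>           mz       rt    ratio rank
#> 317 214.0458 1.733333 1.375100  317
#> 318 129.0295 2.266667 1.498616  318
#> 319 148.0604 2.800000 7.925336  319

rep@pairs[, c("substrate_mz", "product_mz", "ppm_error",
              "substrate_name", "product_name", "ms2_name", "ms2_score")]
#>   substrate_mz product_mz  ppm_error substrate_name product_name ms2_name ms2_score
#> 1     148.0604   104.0706 -0.1177726      glutamate         GABA     GABA         1
```

Reading the output: of 319 aligned features, the highest vector/enzyme
ratio (7.9, i.e. strongly depleted by the enzyme) belongs to the ion at
m/z 148.0604 — protonated glutamate. Its CO2-loss partner at m/z 104.0706
(protonated GABA) is the lone accumulated feature; the pair matches the
43.98983 Da shift within 0.12 ppm and the product's MS2 spectrum is
confirmed against the library at cosine 1.0. `writeReport(rep, "out/")`
materializes the ranked tables, calls, pairs and a stage-count log as CSV
plus a text summary. `runTargeted(cfg)` runs the MRM panel companion the
same way.

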