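# psmEnhance

MRI biomarkers of the paraspinous muscles (PSM) for assessing liver
cirrhosis severity, as an installable, fully tested R pipeline.

Contrast-enhanced abdominal MRI performed for routine hepatocellular
carcinoma screening in cirrhotic patients contains enough signal to
quantify three muscle biomarkers at the level of the superior mesenteric
artery origin:

* **signal fat fraction** (myosteatosis), from the paired two-point Dixon
  gradient-echo images:
  `sFF = (SI_in − SI_out) / (2 · SI_in)`
* **contrast enhancement fraction** (perfusion), per post-contrast
  fat-saturated T1 phase — arterial, portal-venous, delayed:
  `CEFR = (SI_ce − SI_nc) / SI_nc`
* **skeletal muscle index** (sarcopenia):
  `SMI = ((A_left + A_right)/2) / height²` in cm²·m⁻²

and compares them against clinical measures of cirrhosis severity:
ascites and varices on imaging, paracentesis and variceal-bleed history,
spontaneous bacterial peritonitis, and the MELD score (classic UNOS
equation, recomputed from creatinine, total bilirubin and INR) with its
MELD > 17 dichotomy.

The package provides:

* `renderPhantom()` / `psmPhantomSpec()` — a synthetic multi-phase
  phantom with known water/fat composition and per-phase enhancement, so
  the extraction chain is validated by parameter recovery (exact at zero
  noise);
* `roiStats()`, `measureBiomarkers()`, `computeSFF()`, `computeCEFR()`,
  `computeSMI()`, `computeMELD()`, `linCCC()` — the biomarker layer, on
  `PhaseImageSet`/`MaskSet` objects with NIfTI readers and writers;
* `simulateCohort()` — a Gaussian-copula patient-cohort generator with
  log-normal labs, a MELD column derived from those labs, and severity-
  coupled clinical indicators;
* `compareGroups()`, `pearsonCI()`, `categoricalTest()`, `rocAuc()` — the
  statistics engine (Shapiro-Wilk-driven Welch t / Mann-Whitney
  selection, Fisher-z intervals, expected-count rule, rank AUC);
* `loadCohort()`, `runAnalysis()`, `reproduceTables()` — the cohort
  pipeline that recomputes the published descriptive, comparison and
  correlation tables from any datasheet in the documented schema.

A thin command-line wrapper with `phantom`, `measure`, `cohort-sim`,
`analyze` and `reproduce` subcommands is installed at
`inst/scripts/psm-tools.R`.

## Worked example

Render a noisy phantom whose muscles have fat fraction 0.12 and
enhancement (0.08, 0.19, 0.23), then recover the biomarkers:

```r
library(psmEnhance)
ph <- renderPhantom(psmPhantomSpec(ff = 0.12,
                                   enhancement = c(0.08, 0.19, 0.23),
                                   noiseSd = 2, seed = 42))
measureBiomarkers(ph$images, ph$masks, height = 1.75)
#> BiomarkerPanel: sFF = 0.1197, CEFR(art/pv/del) = 0.0801/0.1901/0.2300, SMI = 5.309 cm2/m2
```

With ~1 600-voxel muscle regions, Gaussian noise of 2 on a baseline of
200 leaves the recovered values within a few 10⁻³ of the configured
truth; at `noiseSd = 0` recovery is exact to machine precision.

Simulate a 224-patient cohort at the published marginals and run the full
analysis grid:

```r
coh <- simulateCohort(cohortSimParams(n = 224, seed = 7))
rep <- runAnalysis(loadCohort(coh))
rep
#> psmAnalysisReport: n = 224 patients, MELD cutoff 17
#>   table2: 30 comparisons, 0 with p < 0.05
#>   table3: 40 correlations, 9 with p < 0.05
#>   ROC AUC (low CEFR predicts high MELD): cefr_art 0.586, cefr_pv 0.547, cefr_del 0.536
```

`rep$table2` holds the 5 biomarkers × 6 severity groupings comparison
grid (group means ± SD, complete-case n, Shapiro-Wilk p per group, the
test used and both candidate p-values); `rep$table3` the 40 Pearson
correlations with Fisher-z 95% intervals; `rep$roc` the three CEFR ROC
curves for the MELD > 17 group, oriented so that *low* enhancement
predicts high MELD. `writeAnalysisReport(rep, "out/")` writes
display-rounded CSVs and a full-precision, byte-deterministic JSON.
`reproduceTables()` additionally compares every recomputed cell against
the bundled transcription of the published values at printed precision
and reports each difference.

The methods vignette (`vignettes/psm-biomarkers.Rmd`) documents the
signal models, the copula construction, every statistical decision rule,
and the simulator's scope and limitations.

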