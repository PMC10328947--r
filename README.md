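# EndoResist

Molecular profiling of anti-proliferative response to aromatase inhibitors
(AIs) in ER+HER2− breast cancer.

In postmenopausal ER+ breast cancer, two weeks of neoadjuvant AI suppresses
tumour proliferation (Ki67 IHC) in most patients; a minority are
intrinsically resistant. EndoResist is an R package for the analysis that
asks *what distinguishes the poor responders*. It is written for
translational researchers working with bulk RNA-seq, targeted DNA panels
and clinical covariates from paired-biopsy endocrine-therapy studies.

The pipeline covers:

- **Responder selection** — proportional Ki67 change
  `100·(Ki67₂wk − Ki67₀)/Ki67₀`; poor responders (PR) are the worst 15% of
  eligible patients (baseline Ki67 > 10%, ER+, HER2−), good responders (GR)
  are drawn from the best 50% and matched 1:1 to PRs within baseline Ki67
  categories (10–20, 20–30, ≥30%); PRs are stratified at log2 normalized
  ESR1 counts of 12 (ESR1^HIGH / ESR1^LOW).
- **Intrinsic subtyping with cross-platform calibration** — nearest-centroid
  calls (LumA/LumB/HER2e/Basal) by Spearman correlation, centered either by
  whole-cohort gene medians (naive baseline) or by the **composition-matched
  random-subset calibration**: repeatedly draw k ∈ [5, 15] externally
  subtyped reference samples, match a training subset to their subtype
  composition, center by the difference of subset means, and keep the
  centering vector that maximizes concordance with the reference calls.
  This corrects the bias median centering suffers in a cohort skewed to
  ~85% luminal tumours.
- **Differential expression** — a compact negative-binomial Wald pipeline
  (median-of-ratios size factors, Cox–Reid-adjusted dispersions shrunk to an
  a₀ + a₁/mean trend, BH correction), validated by type-I/power calibration.
- **Signature scoring** — single-sample GSEA (weighted-ECDF running sum),
  preranked GSEA with a gene-permutation null, the HOXB13/IL17BR (H/I)
  ratio, and score–score / covariate–score Spearman correlation with the
  estradiol > 130 pmol/L exclusion rule.
- **Genomic alterations** — somatic-mutation filters (VAF ≥ 0.05, alt reads
  ≥ 5, high/moderate consequence, population AF < 1e-5), burden and
  per-gene Fisher comparisons, copy-number calling (±0.2 log2), 3-Mbp
  binning, chromosomal instability, and compound TP53 status (mutation +
  copy loss).
- **A synthetic-cohort generator** with complete ground truth (subtypes,
  resistance, immune score, mutations, CNAs, platform shift), because the
  motivating patient-level data are access-controlled. Every stage is
  validated against it and against brute-force oracles.

## Worked example

```r
library(EndoResist)

cfg    <- simConfig(nPatients = 400, seed = 42)
cohort <- generateCohort(cfg)
cohort
#> SyntheticCohort: 1112 genes x 400 samples, 1493 mutation rows, 19548 segments

norm       <- log2Normalized(cohortCounts(cohort))
assignment <- selectResponderGroups(clinicalTable(cohort))
assignment <- stratifyByEsr1(norm, assignment)
table(assignment$response_class, assignment$esr1_stratum)
#>              HIGH LOW
#>   GR           57   1
#>   PR           39  19
#>   unassigned  250  21
```

58 poor responders are selected (the worst 15% of the 400-patient cohort
after eligibility), 19 of them ESR1^LOW — low ESR1 concentrates in poor
responders, as the generator's resistance model intends. 58 matched good
responders are drawn from the best-50% pool.

```r
training  <- generateTrainingSet(cfg, nPerSubtype = 55)
centroids <- centroidsFromTraining(training$matrix, training$labels)
refCalls  <- generateReferenceCalls(cohortTruth(cohort), nRef = 59,
                                    errorRate = 0.03, seed = 43)
cal <- calibrationSearch(norm, refCalls, training$matrix, training$labels,
                         centroids, nIter = 50000, seed = 44)
cal
#> CalibrationResult
#>   best concordance : 0.9661
#>   best k           : 10 (LumA=5, LumB=5, HER2e=0, Basal=0)
#>   iterations       : 50000 (0 skipped)
#>   seed             : 44

calls <- assignSubtypes(norm, cal, centroids)
truth <- cohortTruth(cohort)
mean(calls$label == truth$subtype[match(calls$sample_id, truth$sample_id)])
#> [1] 0.948
```

The best of 50,000 iterations reproduces 57/59 reference calls (96.6%
concordance — the reference labels themselves carry 3% error) and the
calibrated centering vector recovers 94.8% of true subtypes across the
whole cohort, despite a per-gene platform shift of sd 0.8 between study
and training scales.

```r
filt   <- filterSomatic(mutationTable(cohort))
pr     <- assignment$patient_id[assignment$response_class == "PR"]
gr     <- assignment$patient_id[assignment$response_class == "GR"]
status <- tp53CompoundStatus(filt, callSegments(segmentTable(cohort)),
                             c(pr, gr))
tp53CompoundCompare(status[pr], status[gr])
#> $frac_a      # PRs with TP53 mutation + copy loss
#> [1] 0.0862069
#> $frac_b      # GRs
#> [1] 0.03448276
#> $p.value
#> [1] 0.4384743
```

Compound TP53 status is enriched in poor responders (8.6% vs 3.4%), though
at 58 patients per arm this single cohort does not reach significance —
the direction is the configured effect; power comes with cohort size.

## Documentation

The methods vignette (`vignettes/methods.Rmd`) explains the statistical
model behind each stage, the generator's assumptions and what passing
tests do and do not demonstrate, and every numerically consequential
design choice (boundary conventions, tie handling, dispersion shrinkage,
coordinate conventions).
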