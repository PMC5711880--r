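# fetalhand

Laterality analysis of fetal arm-movement kinematics: a tested R pipeline
for inferring postnatal handedness from prenatal reaching movements.

## The problem

Fetuses observed by 4D ultrasonography at gestational weeks (GW) 14, 18 and
22 reach toward targets of graded precision demand — their eye, their
mouth, the uterine wall — with either hand. Two kinematic features
summarise each movement: **MT**, the movement time in milliseconds, and
**TPV**, the time-to-peak-velocity as a percentage of MT (larger TPV =
shorter deceleration phase). The scientific question: do these kinematics
already encode the handedness the child will show years later?

Because overall movement speed is a property of the fetus (both hands are
fast or slow together), the informative statistic is the within-fetus
**hand-asymmetry advantage**

    HAA  = mean(RH) − mean(LH)
    rHAA = 2 (mean(RH) − mean(LH)) / (mean(RH) + mean(LH))

per fetus, week and target. For MT, `HAA < 0` (faster right hand) predicts
right-handedness. Around this sign rule the package provides the full
inferential toolkit for small, skewed, unbalanced cohorts:
Hodges–Lehmann location estimates, Welch *t*-tests on ranks,
Benjamini–Hochberg FDR control, label-permutation significance for
classification accuracy, a min-distance silhouette index,
leave-one-out cross-validated logistic regression, Spearman developmental
trends, and binned mutual information with the Panzeri–Treves small-sample
bias correction. A synthetic cohort generator reproduces the statistical
structure of such studies (29 fetuses, 25 right-handed; published
movement-count marginals; a 318 ms dominant-hand MT advantage for precise
targets from GW 18; a 2.1 percentage-point TPV advantage) so that every
stage is testable without clinical data.

## Worked example

```r
library(fetalhand)

coh <- generate_cohort(synthetic_config(movements_per_fetus_week = c(24, 24, 24)),
                       seed = 1)
coh
#> <fh_cohort> 29 fetuses (25 right-handed, 4 left-handed), 2091 movements

h    <- compute_haa(coh, "mt", gw = 18, target = "eye")
acc  <- classification_accuracy(sign_classify(h$haa, "mt"), h$handedness)
perm <- permutation_accuracy_test(h$haa, h$handedness, "mt",
                                  n_perm = 10000, seed = 2)
sep  <- group_haa_separation(h$haa, h$handedness)
```

This prints, for the eye target at GW 18:

```
eye/GW18: n=28  accuracy=0.929  p_perm=0.0000
HAA separation (left - right): 720 ms, Welch-U p=1.5e-07
```

93% of fetuses are classified correctly by the sign of their MT asymmetry
alone; no label permutation reached a higher accuracy in 10 000 shuffles;
and the left-handed group's HAA distribution sits ~720 ms above the
right-handed group's (the generator's ground truth is 2δ = 636 ms). The
supporting analyses:

```r
within_subject_correlation(coh, "mt")$median_r
#> 0.76      # both hands share the fetus's overall speed

pm <- pooled_mouth_analysis(coh, seed = 3)
#> pooled mouth: n=29  sign acc=0.86 (p=0.0007)  LOOCV acc=0.97  spearman rho=0.55

mt_development(coh, "eye", seed = 4)
#> eye MT trend: rho=0.28 (p=8.1e-15);  MI=0.049 bits (corrected, p=0.000)
```

`run_full_analysis()` sequences everything — counts, right-hand-use
proportions with exact binomial tests, the 18 per-condition
Hodges–Lehmann/Welch comparisons with FDR control, the per-condition
accuracy/separation grids, silhouette and LOOCV analyses, pooled-mouth
classification and developmental mutual information — into a deterministic
report bundle of tidy CSVs plus a JSON manifest:

```r
bundle <- run_full_analysis(coh, run_config(seed = 1), out_dir = "report")
```

A minimal CLI covers simulation and analysis from the shell:

```sh
Rscript -e 'fetalhand::fh_cli()' simulate --seed 1 --out cohort.csv
Rscript -e 'fetalhand::fh_cli()' analyze --input cohort.csv --out report --seed 1
```

## Notes

The methods vignette (`vignettes/fetal-handedness-methods.Rmd`) documents
the statistical model, every tunable parameter with its default and units,
what the synthetic generator does and does not emulate, the tie and
degenerate-input policies, and known limitations — including why the
literal strictly-greater permutation rule is anti-conservative with only
four minority labels and when to prefer `include_ties = TRUE`.
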