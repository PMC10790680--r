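# plspair

Paired lncRNA/mRNA biomarker discovery and single-component PLS response
prediction for two-class (responder / nonresponder) expression cohorts.

Many drugs for rheumatoid arthritis help only a subset of patients, and
single transcripts rarely separate responders from nonresponders. This
package implements a paired-biomarker strategy on peripheral-blood
expression: screen genes differentially expressed between response
groups, keep lncRNA–mRNA pairs that are Pearson-correlated within *both*
groups, intersect the mRNA side with a drug-target list, rank the
surviving candidates by network topology, and classify patients with a
one-component partial least squares (PLS) score on the selected pair.
Because no patient-level dataset is public for this design, a
synthetic-cohort generator with a planted signal pair makes the whole
pipeline testable end to end.

## The model

For a gene panel P with sample expression L, the classifier scores

&nbsp;&nbsp;&nbsp;&nbsp;S = Σᵢ W_Pᵢ · scaled(L_Pᵢ),&nbsp;&nbsp;
W = argmax_{‖w‖=1} cov²(Xw, Y),

with predictors standardized and Y coded ±1; the maximizer is the
closed form W = c/‖c‖ (c = per-gene covariance with Y), i.e. a single
PLS component. The decision threshold T maximizes Youden's
J = sensitivity + specificity − 1 over the training scores, and a
sample is called a responder iff S > T. Evaluation uses the
Mann–Whitney AUC with Hanley–McNeil SE and logit-normal 95% CI,
stratified fivefold cross-validation, and the DeLong test for comparing
the paired-gene ROC with each single-gene ROC.

## Worked example

The `analysis/` directory is a numbered workflow over the package; run
the scripts in order from the repository root:

```sh
for s in analysis/0*.R; do Rscript "$s"; done
```

Script 01 simulates a discovery cohort (20 responders / 20
nonresponders; planted pair `LNC0101`/`MRNA0151` with opposite shifts
of 1.5 log2 units and within-class correlation 0.8), a 118-edge
interaction network with the planted genes as hubs, a 57-gene target
list, and a 25/15 validation-shaped cohort as qPCR tables normalized to
RN18S and GAPDH. The discovery scripts then print:

```
DE lncRNAs: 8 of 101 (5 up / 3 down)
DE mRNAs:   14 of 153 (6 up / 8 down)
significant pairs: 10 (responders), 6 (nonresponders), 1 (both groups)
on the 57-gene target list: 1 candidate pair(s), 1 distinct target mRNA(s)
network after median filter: 50 nodes
top pair: LNC0101 / MRNA0151  (mean |r| = 0.808)
planted pair recovered: TRUE
```

— the DE filter (p < .05, |log2FC| ≥ 1) trims ~250 genes to 22, the
two-group correlation screen plus target intersection leaves a single
candidate, and the network ranking confirms it: the planted pair is
recovered. Training the classifier on the validation-shaped cohort
(script 05) prints, per reference-gene normalization:

```
[RN18S] weights (LNC0101, MRNA0151) = (0.7175, -0.6965), T = -0.4760 | CV: acc 1.000, sens 1.000, spec 1.000, AUC 1.000
[GAPDH] weights (LNC0101, MRNA0151) = (0.7152, -0.6989), T = -0.4856 | CV: acc 1.000, sens 1.000, spec 1.000, AUC 1.000
```

The weights are unit-norm (0.7175² + 0.6965² = 1), positive on the
lncRNA and negative on the mRNA — matching the planted directions — and
the cross-validated metrics are perfect on this strongly separated
cohort. Script 06 quantifies the value of pairing:

```
[RN18S] LNC0101 alone: AUC 0.885 (SE 0.052, CI 0.738-0.955) vs paired 1.000, DeLong p = 0.0271
[RN18S] MRNA0151 alone: AUC 0.872 (SE 0.055, CI 0.721-0.947) vs paired 1.000, DeLong p = 0.0205
```

Each gene alone is a decent classifier (AUC ≈ 0.87–0.89); the paired
PLS score is significantly better (DeLong p < 0.05 against either).
Tables behind these lines land under `results/`.

See `vignettes/paired-biomarker-pls.Rmd` for the model, the generator's
assumptions, and the numerical conventions.

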