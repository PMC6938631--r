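# funcevkit

Structured assessment of functional assay evidence for clinical variant
interpretation under the ACMG/AMP framework, following the ClinGen Sequence
Variant Interpretation (SVI) recommendations for the PS3/BS3 criteria.

Clinical laboratories disagree about when a published functional assay is
"well-established" enough to count as evidence that a variant damages (PS3)
or does not damage (BS3) gene or protein function, and at what strength.
funcevkit is for variant curators and expert panels who want that judgment
to be reproducible: it turns a table of classified variant controls and
their assay readouts into calibrated readout thresholds, an odds of
pathogenicity, and a defensible PS3/BS3 strength tier for each queried
variant.

## The model

An assay's clinical validation rests on control variants independently
classified pathogenic/likely pathogenic (P/LP) or benign/likely benign
(B/LB) *without* functional evidence (avoiding circularity). Writing P1 for
the proportion of pathogenic variants among the controls (prior) and P2 for
the proportion within a readout group (posterior), the evidence contributed
by that readout is the likelihood ratio

    OddsPath = [ P2 × (1 − P1) ] / [ (1 − P2) × P1 ]

To avoid posteriors of exactly 0 or 1 — and to price in the possibility
that the next variant tested is discordant — exactly one misclassified
variant is added to each readout set: with B benign and P pathogenic
concordant controls the abnormal-readout set is {P pathogenic + 1 benign}
and the normal-readout set {B benign + 1 pathogenic}, giving the closed
forms OddsPath_pathogenic = B and OddsPath_benign = 1/P. OddsPath maps to
evidence strength by fixed bounds: > 2.1 supporting, > 4.3 moderate,
> 18.7 strong, > 350 very strong toward pathogenicity; < 0.48 supporting,
< 0.23 moderate, < 0.053 strong toward benign; [0.48, 2.1] is
indeterminate. A consequence the package reproduces exactly: allowing one
indeterminate control, a minimum of **11** total controls is needed to
reach moderate-level evidence in both directions.

Around that core the package implements the four-step SVI procedure:
structured disease-mechanism statements, assay-class applicability,
validation-tier assignment for specific assay instances (no evidence /
supporting / moderate / OddsPath-based), variant-level evidence application
with hypomorph handling and context warnings (patient-derived material,
model organisms, cDNA constructs for NMD-subject variants, splicing
assays), the 50-nucleotide NMD boundary rule, and stacking rules for
multiple assays.

## Worked example

The packaged worked example pools 11 controls (6 B/LB, 5 P/LP; activity as
percent of wild type) across assay instances and evaluates three VUS:

```r
library(funcevkit)

fx  <- exampleFixture(seed = 17)
cal <- calibrate(fx$controls)
cal
#> CalibrationSummary
#>   controls: 5 benign concordant, 5 pathogenic concordant, 1 indeterminate, 0 discordant
#> ReadoutThresholds (higher_is_normal): normal >= 60, abnormal <= 30
#> OddsPathResult
#>   prior P1: 0.5   P2(abnormal): 0.8333   P2(normal): 0.1667
#>   OddsPath toward pathogenic: 5  -> PS3_moderate
#>   OddsPath toward benign:     0.2  -> BS3_moderate
```

Thresholds land at 60% (normal at or above) and 30% (abnormal at or
below); the benign control reading 45% is judged indeterminate rather than
discordant. With 5 concordant controls per class the adjusted contingency
gives OddsPath 5 toward pathogenic and 0.2 toward benign — moderate
strength each way. Applying that calibration to the VUS:

```r
mech <- DiseaseMechanismStatement("GENE1", "MONDO:0000001",
                                  "autosomal_recessive", "loss_of_function")
ev <- evaluateVariants(fx$controls, fx$calls, mech)
sapply(ev$applications, tierLabel)
#>           VUS1           VUS2           VUS3
#> "BS3_moderate"         "none" "PS3_moderate"
```

VUS1 (75%) reads like the benign controls, VUS3 (12%) like the pathogenic
ones, and VUS2 (45%) sits in the indeterminate zone, so no functional
evidence is applied to it. The same pipeline is scriptable via the thin CLI
in `inst/scripts/funcevkit` (subcommands `oddspath`, `grid`, `calibrate`,
`apply`, `fixture`); ready-made input files are in `inst/extdata/`.

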