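---
title: "Calibrating functional assay evidence for PS3/BS3"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating functional assay evidence for PS3/BS3}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(funcevkit)
```

## The problem

The ACMG/AMP criteria let a "well-established" functional assay contribute
strong evidence that a variant damages (PS3) or does not damage (BS3) gene
or protein function. In practice, laboratories apply these codes
inconsistently: assays differ in experimental controls, replication, and —
most importantly — in clinical validation against variants whose
pathogenicity is already known. funcevkit operationalizes the ClinGen SVI
recommendations: evidence starts from *nothing* and earns strength through
demonstrated validation, quantified where possible as an odds of
pathogenicity (OddsPath).

## OddsPath from classified controls

Validation controls are variants classified P/LP or B/LB using evidence
independent of functional data (the package refuses controls whose
classification basis cites PS3/BS3 — the circularity guard). With prior
`P1` (fraction pathogenic among controls) and posterior `P2` (fraction
pathogenic within a readout group),

$$\mathrm{OddsPath} = \frac{P_2\,(1-P_1)}{(1-P_2)\,P_1}.$$

A perfectly classifying assay would put `P2` at 0 or 1 and the odds at 0 or
infinity, which overstates what a finite control set shows. The adjustment:
exactly one misclassified variant is added to each readout set (one benign
to the abnormal set, one pathogenic to the normal set). This both
regularizes the posteriors and prices in the chance that the next control
tested is discordant. With `B` benign and `P` pathogenic concordant
controls the algebra collapses to

$$\mathrm{OddsPath}_\text{path} = B,\qquad \mathrm{OddsPath}_\text{benign} = 1/P,$$

independent of the class split — a closed form the test suite checks
exhaustively for all `B, P` in 1..20.

**Prior convention.** `P1` is computed over the determinate (concordant)
controls only: the two added members are artificial and indeterminate
controls carry no readout information. This convention reproduces the
package's reference worked example — 6 benign and 5 pathogenic controls
with one benign indeterminate yield OddsPath (5, 0.2), moderate evidence in
both directions; a prior over all 11 controls would not.

## Strength mapping and its boundaries

OddsPath maps to evidence tiers through fixed bounds (2.1 / 4.3 / 18.7 /
350 toward pathogenic; 0.48 / 0.23 / 0.053 toward benign; [0.48, 2.1]
indeterminate). These are carried as named constants, not re-derived. All
inequalities are strict: a value exactly on a bound falls in the weaker
tier, with equality detected at an absolute tolerance of 1e-9 so that
floating-point noise from the odds arithmetic (order 1e-15 relative) cannot
flip a tier, while probes 1e-6 away from a bound resolve correctly. The
emitted code follows the value: PS3 is never reported for OddsPath < 1 nor
BS3 for OddsPath > 1, and there is no very-strong benign tier (BS3 caps at
strong; moderate benign evidence is bookkept as two supporting-level
pieces by downstream consumers, which is why a distinct label exists).

A direct consequence, regenerated by `minimumControlsForModerate()`:
allowing one indeterminate control (taken from the benign side at an even
or benign-majority split), both directions reach moderate first at **11**
total controls — 6 benign (5 concordant) gives OddsPath 5 > 4.3, and 5
pathogenic gives 1/5 = 0.2 < 0.23; every total of 10 or fewer fails at
least one direction. Because no convention is fixed for *which* side loses
the indeterminate control, `minimumControlsGrid()` also reports the
worst-case placement per direction as separate columns.

## Threshold selection

Curators draw two cutoffs on the pooled control plot: readouts at/above
the normal cutoff are functionally normal, at/below the abnormal cutoff
functionally abnormal, and in between indeterminate. The package's default
rule mimics that judgment:

1. **Summarize.** Each variant's readouts across assay instances collapse
   to their median. The median keeps a control concordant when one instance
   out of three or more is an outlier (as for the packaged control P1,
   whose instances read 12/15/70); with two conflicting instances the
   midpoint tends to land indeterminate — the conservative outcome.
2. **Orient.** Under `lower_is_normal` polarity (e.g. gain-of-function
   readouts) values are negated; polarity is inferred from the class means
   when unstated.
3. **Outlier screen.** A control on the wrong side of the midpoint between
   the benign-class and pathogenic-class medians is demoted to
   indeterminate. It is never reassigned to the other class. This is what
   lets the rule call a benign control at 45% indeterminate even though a
   cutoff *could* be drawn below it: a readout closer to the opposite
   class's range than to its own class's core does not convincingly
   support either zone, and a curator would not anchor the normal zone to
   it.
4. **Snap.** The normal cutoff is the largest multiple of `gridStep`
   (default 5 units) at or below every remaining benign readout; the
   abnormal cutoff the smallest multiple at or above every remaining
   pathogenic readout. Snapping reproduces round cutoffs like 60/30 and
   avoids overfitting to control extremes.
5. **Relax.** If the cutoffs collide or any kept control lands in the
   opposite zone, controls are demoted greedily — fewest first, deepest
   offender first, ties demoting benign-class controls first (conservative
   for PS3) — and the cutoffs recomputed. If a class empties, the controls
   are inseparable and the user is directed to supply thresholds manually.

Zero discordance is an invariant of the default rule; discordant counts
can arise only under user-supplied thresholds, and such controls are then
excluded from the contingency and flagged.

The rule is a *default*, not a claim about committee intent — threshold
placement is explicitly left to curator judgment. `calibrate()` accepts
manual thresholds for exactly that reason.

## Validation tiers and evidence application

`assignValidationTier()` encodes the instance-level scenarios: documented
instances missing a wild-type or null control, or lacking both technical
and biological replicates, support no evidence; historically accepted or
kit-based assay classes without instance documentation, or instances with
10 or fewer validation controls, reach supporting; at least 11 controls
mixing both classes reach moderate without formal statistics; a formal
OddsPath sets the tier directly, with the benign direction capped at
strong. Ceilings are reported per direction.

`applyEvidence()` then maps a variant's functional call to a code:
abnormal and mechanism-consistent → PS3 at the pathogenic ceiling; normal
→ BS3 at the benign ceiling; indeterminate → none. Partial
loss-of-function (hypomorphic) results are downgraded one tier by default
with a warning — the committee asks only for "special consideration", so
the downgrade is a policy switch (`evidencePolicy(hypomorphDowngrade =)`)
that a gene with an intermediate-activity disease mechanism may disable.
An unknown abnormal subtype is treated as mechanism-consistent with a
warning. Normal results from assays limited to a single domain or readout
(`AssayClass(probesFullFunction = FALSE)`) carry a completeness warning.
Patient-derived evidence errors out unless the policy explicitly
acknowledges it, mirroring the recommendation to route such data to PP4;
model-organism, cDNA/NMD and splicing contexts produce advisories. No
decision ever depends on the entity that performed the assay.

**Stacking.** With multiple results for one variant, the most-validated
assay wins. "Most validated" has no committee-defined total order, so the
package uses a lexicographic one: tier ceiling, then validation-control
count, then presence of a formal OddsPath. Consistent directions take the
winner's strength; conflicting directions with strictly unequal validation
take the better-validated side; equal validation cancels to no evidence.
Promoting two same-direction supporting results from different assay
classes to moderate is disabled by default (independence of the measured
functions is rarely demonstrable) and available behind
`allowCrossClassStacking = TRUE`.

**NMD boundary.** `nmdSubject()` implements the 50-nucleotide rule:
premature termination codons before the 3'-most 50 nt of the penultimate
coding exon (i.e. at or before `junction − 50` in coding coordinates) are
expected to trigger nonsense-mediated decay; later PTCs, including the
whole last exon, escape. The boundary position itself (exactly 50 nt from
the junction) is counted as NMD-subject, matching the "before the 3'-most
50 nucleotides" phrasing. Single-exon transcripts return FALSE with an
inapplicability note rather than an error.

## What the generators emulate

`exampleFixture()` realizes the reference pooled-control scenario: five
benign controls with summarized readouts in 62–90% of wild-type activity,
one benign control fixed at 45%, five pathogenic controls in 5–28% (one
tested in three instances with a single discordant 70% reading), and three
VUS at 75/45/12%. Per-instance jitter is uniform ±1 unit around fixed
class bases; the bases are chosen so that every seed yields cutoffs
(60, 30), counts (5, 5, 1) and OddsPath (5, 0.2). `randomControlSet()`
draws uniform readouts within configurable class ranges (defaults 62–90
and 5–28, matching the example's geometry; a Gaussian-noise option exists
for stress tests), places planned indeterminate benign controls just above
the snapped edge of the pathogenic range (32.5 under the defaults, a
position the midpoint screen provably demotes when at least two concordant
benign controls remain), and stamps non-functional classification bases.
Seeds fully determine output.

What the generators do **not** emulate: instance-to-instance batch
effects, heteroskedastic or assay-specific noise, dose-response or
continuous multiplexed score distributions, and class overlap beyond the
single planned indeterminate. Passing tests therefore demonstrate the
arithmetic, threshold logic and decision rules — not robustness to messy
real-world readout distributions, where curator review of the pooled plot
remains essential.

## Numerical choices and problem sizes

Probabilities are validated to the open unit interval; counts are
integers and the adjustment is always exactly one added variant per set.
Boundary equality uses 1e-9 absolute tolerance; closed-form OddsPath
recovery is tested at 1e-12. The test suite runs the closed-form check
over all 400 (B, P) pairs in 1..20, property grids at 0.02–0.05 spacing,
order-invariance over explicit permutations, and 100-seed determinism and
parameter-recovery sweeps for the generators — sizes chosen so the whole
suite completes in well under a minute while covering every branch of the
decision logic.

## Limitations

- Splicing assays only receive a routing advisory; combining PS3 with
  PVS1 for splice-impact variants needs splice-specific guidance that is
  out of scope.
- No aggregation of PS3/BS3 with other ACMG/AMP codes into a final
  classification, and no PVS1 logic.
- Ontology identifiers (HGNC/MONDO/GO) are validated lexically only.
- The threshold rule is a reproducible default for unimodal,
  well-separated control classes; heavily overlapping classes are
  reported as inseparable rather than force-fitted.
- Readouts are assumed already normalized to wild type; no batch-effect
  correction or variance modeling is attempted.
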