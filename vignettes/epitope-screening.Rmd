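---
title: "Matrix-pooled CD8+ T cell epitope screening: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Matrix-pooled CD8+ T cell epitope screening: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(episcreen)
```

## The screening problem

Oncolytic virotherapy with VSV-GP — a vesicular stomatitis virus carrying
the lymphocytic choriomeningitis virus glycoprotein — raises anti-viral
CD8+ T cells alongside any anti-tumor response. Monitoring those anti-viral
cells requires knowing which viral peptides the host's MHC class I
molecules present. In the BALB/c mouse, the relevant alleles are H2-Kd,
H2-Dd and H2-Ld, each presenting 8--11-mer peptides.

Testing every window of a five-protein proteome in individual wells is not
feasible, so the screen is multi-level:

1. **Predict and rank.** All 8--11-mers are enumerated from the ordered
   proteome (N, P, M, GP, L in genome order) and ranked by predictor
   scores; the top 50 per allele form the candidate panel.
2. **Pool in a matrix.** The 50 candidates are arranged row-major in a
   7×7 grid. Each row is one of 7 horizontal pools and each column one of
   7 vertical pools (14 pools total), so each peptide sits in exactly two
   pools.
3. **Call pools, deconvolute.** Splenocytes of virus-immunised and
   untreated mice are stimulated pool-wise in IFN-γ ELISpot. Positive
   pools are identified statistically, and a candidate is nominated when
   *both* of its pools respond (the cross-product decode).
4. **Confirm singly.** Nominated candidates are retested as individual
   peptides with the same positivity rule; survivors are epitopes.
5. **Validate and characterise.** Confirmed epitopes are cross-validated
   by intracellular cytokine staining (ICS), compared across treatment
   routes and tissues, and characterised by protein position, length,
   anchor-residue motifs, nesting and multimer eligibility.

## The gene-position gradient

The genes of non-segmented negative-strand RNA viruses are transcribed
sequentially from the 3' end, so protein abundance falls with genome
position. Abundant proteins contribute disproportionately to the presented
peptide repertoire. The panel therefore allocates candidate slots as a
non-increasing per-protein quota in genome order — by default 15 (N),
15 (P), 10 (M), 5 (GP) and 5 (L), summing to the 50-candidate budget.
Candidate identifiers are the protein letter plus the global index in
genome-then-rank order (N1--N15, P16--P30, M31--M40, G41--G45, L46--L50),
so an identifier such as P25 localises a candidate to both a protein and a
rank block. When a protein cannot fill its quota the slots cascade forward
in genome order, preserving the budget.

## Ranking model

Predictors export, per peptide and allele, a predicted IC50 (nM), a
rank-normalised *percent rank*, and optionally stability and
immunogenicity scores. Tiers follow the conventional percent-rank cutoffs
(strong < 0.5, weak < 2, marginal < 10); values exactly at a boundary take
the weaker tier, a fixed documented convention.

The composite ranking across predictors is a rank-sum: each available
score is ranked (percent rank ascending; stability and immunogenicity
descending) and peptides are ordered by the mean of available ranks. This
is scale-free, robust to predictors with incommensurate units, and skips
missing predictors. Ties break deterministically by affinity, genome
position, then sequence, so panel selection is a pure function of its
inputs. Duplicate sequences across proteins are kept once and attributed
to the earlier protein — a peptide is a single stimulus regardless of its
genomic copy number.

For running the pipeline without external predictor tools, the package
includes a deterministic surrogate scorer built from the alleles' known
anchor motifs (H2-Kd: tyrosine at position 2, leucine/isoleucine C
terminus; H2-Dd: glycine 2, proline 3, lysine 5, hydrophobic C terminus;
H2-Ld: proline 2, hydrophobic C terminus). More anchor matches always mean
a strictly better percent rank. The surrogate is a stand-in scorer for
testing and demonstration, not a trained predictor.

## Matrix design and deconvolution

Fifty candidates do not fit in 49 cells: the lowest-ranked candidate
shares the last cell (7,7) with the 49th, and both are flagged. The
decoder never attempts to separate co-located candidates — both are
nominated (and marked ambiguous) when their shared pools respond, and the
single-peptide stage resolves them. Decoding itself is the exact
cross-product rule: a candidate is nominated iff its row pool *and* its
column pool are positive. The test suite checks this against an exhaustive
both-pools-positive enumeration on a toy 3×3 design and random subsets of
the full design, along with monotonicity of the decode in the positive
set.

With the validated reference identities planted (H2-Kd: N6, N7, N8, P16,
P25; H2-Dd: P23, P25, M33, M35; H2-Ld: N1, N13), the row-major layout puts
their pools at 9, 6 and 4 positives respectively, and the cross-product
decode nominates 20, 8 and 4 candidates — the arithmetic the pipeline is
designed to reproduce end to end.

## Positivity calling

A stimulus is called positive when three conditions hold simultaneously:

* an unpaired two-sample t test of treated versus untreated spot counts is
  significant at α = 0.05 (Student's equal-variance version by default,
  the common graphing-software convention; Welch is available);
* the treated group mean reaches the **60-count floor**; and
* the treated mean exceeds the control mean.

The 60-count threshold is applied in two places, because its role as a QC
criterion versus a biological-relevance floor is genuinely ambiguous: it
is a floor on the treated mean of every test stimulus, *and* the
acceptability bound for the ConA positive control in plate QC (with a
50-count background ceiling for negative controls). Both thresholds are
configurable in `screen_config()`. No multiple-testing correction is
applied by default — pool calls mirror per-stimulus raw tests —
but Benjamini–Hochberg adjustment across pools is available. Indeterminate
calls (fewer than two wells in a group, missing wells, or degenerate
constant data) are never positive, keeping the decode conservative.
Saturated ("too numerous to count") wells are excluded with a warning by
default, or capped at a configurable value.

## ICS summaries

ICS frequencies (% IFN-γ+ among CD8+ T cells) are validated against
ELISpot by the Pearson product-moment correlation over per-stimulus means.
Route comparisons fit a two-factor model `freq ~ stimulus * route` and
report Tukey-adjusted pairwise route contrasts *within* each stimulus
(via `emmeans`); the factor structure is documented here rather than
asserted to match any particular external analysis. Epitope composition
subtracts the negative-control mean from each epitope's mean frequency,
clamps negatives to zero — background subtraction prevents the NC signal
from inflating every slice, clamping prevents negative proportions — and
normalises to fractions summing to one. Polyfunctionality gates convert
event counts over the eight Boolean combinations of IFN-γ, TNF-α and
CD107a into percentages that must sum to 100.

Reported percentages are rounded to two decimals by convention; all
internal computation is full precision.

## The synthetic generator

No raw assay data ships with the package, so `simulation_config()` and the
`simulate_*()` functions generate well-level tables with planted ground
truth. Design choices:

* **Negative-binomial spot counts** (mean/dispersion parameterisation):
  ELISpot replicate wells are overdispersed relative to Poisson; Poisson
  is the `dispersion = Inf` limit.
* **Group sizes** default to 4 untreated and 6 treated mice, the typical
  ELISpot/ICS group sizes in this model system.
* **Means**: background 10 spots, immunogenic effect 300 spots, positive
  control 500 spots per 2.5×10^5 splenocytes. The effect sits far above
  the 60-count floor, as real immunodominant responses do.
* **Dispersion** defaults to 20, i.e. a well-to-well CV of ≈23% at 300
  spots — typical of replicate ELISpot wells — and small enough that a
  planted responder essentially never fails the three-part positivity
  rule (measured per-call miss probability < 10^-4, versus ≈0.6% at
  dispersion 5, which would visibly erode sensitivity over hundreds of
  planted calls). This value was fixed once, on those grounds.
* **Control mice never carry effects**: untreated animals are virus-naive.
* **One well per mouse × stimulus**: replicate information lives at the
  mouse level.
* **ICS effects are multiplicative**: route multipliers (intravenous above
  intratumoral), tissue multipliers (tumor-infiltrating lymphocytes above
  splenocytes), log-normal noise, clipped to [0, 100].

All randomness flows through integer seeds; the same seed reproduces the
same table on any platform, and simulation restores the caller's RNG
state.

What the generator deliberately does **not** emulate: inter-mouse
immune-hierarchy variation, cross-reactive or partially overlapping pool
responses, plate or day batch effects, bystander IFN-γ from non-CD8
cells, and saturating spot counts. Passing recovery tests therefore shows
that the pipeline's arithmetic and calling rules are correct under clean
planted signals — not that real campaigns with marginal responses will
reach the same sensitivity.

## The synthetic proteome

The package ships a deterministic synthetic proteome
(`synthetic_proteome()`, also as
`inst/extdata/synthetic_vsvgp_proteome.fasta`): random 20-letter
background at realistic protein lengths (N 422, P 265, M 229, GP 498 aa),
with the polymerase truncated to 600 aa to keep enumeration light
(≈7,900 windows), and the known reference epitope sequences embedded at
fixed positions in N and P. It is labelled synthetic everywhere; it
supports enumeration, location, selection and characterization without
redistributing real sequence data. Because panel membership of specific
sequences depends on the surrogate scores, end-to-end recovery tests
plant ground truth by candidate identifier, which is layout-determined
and independent of the underlying sequences.

## Problem sizes and numerical choices

The test suite runs the full campaign (three alleles, 50-candidate
panels, two assay stages) in well under a second per seed; stochastic
properties use 100 seeded campaigns for sensitivity/specificity and 1,000
simulated null plates for the type-I check, sizes chosen so the whole
suite completes in about a minute while the binomial uncertainty on the
estimated rates stays far below the asserted bounds. Statistical calls
delegate to `stats::t.test`, `stats::cor.test`, `stats::aov` and
`emmeans`; the test suite verifies them against independently hand-coded
closed forms (pooled-variance t, Pearson sum formula, studentized-range
Tukey) to 10^-8 or better.

Degenerate inputs are handled conservatively throughout: empty positive
pool sets decode to nothing; constant count vectors yield indeterminate
(never positive) calls; zero-variance correlation inputs and all-zero
composition signals are flagged rather than invented; ambiguity codes in
input sequences are rejected because predictor scores are undefined for
them.

## Known limitations

* The surrogate scorer ranks by anchor content only; it cannot reproduce
  the ranking of trained predictors, and panel composition from real
  predictor exports will differ.
* The 7×7 row-major layout with one doubled cell is one consistent
  realisation of a 14-pool, two-pools-per-peptide design; other layouts
  satisfy the same pool arithmetic, and the decoder works for any
  `pool_design` grid.
* Route comparison assumes a shared residual variance across
  stimulus × route cells (the two-way ANOVA assumption); strongly
  heteroscedastic frequency data would need a different model.
* The pipeline consumes pre-gated counts and frequencies; raw
  flow-cytometry event processing is out of scope.
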