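---
title: "Measuring MMEJ:NHEJ pathway balance and its chromatin context-dependency"
author: "breakbalance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring MMEJ:NHEJ pathway balance and its chromatin context-dependency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breakbalance)
```

## The measurement

Cas9-induced double-strand breaks in a barcoded integrated pathway reporter
(IPR) are repaired mostly by two mutagenic pathways that leave
distinguishable scars: non-homologous end-joining (NHEJ), whose signature at
this reporter is a +1 insertion, and microhomology-mediated end-joining
(MMEJ), whose signature is a -7 deletion. The local pathway balance at one
reporter in one sample is

$$\log_2 \mathrm{MMEJ{:}NHEJ} = \log_2 \frac{n_{-7}}{n_{+1}},$$

defined only when both signature classes have at least `min_reads_per_class`
reads (default 1; pooled-reporter inhibitor experiments use 40 because their
per-IPR coverage is shallow and ratio estimates from a handful of reads are
unstable). `call_indels()` scores reads by the spacing between two constant
anchor sequences flanking the break site, after demultiplexing on the
reporter barcode with at most one mismatch and a uniqueness requirement;
anything ambiguous is counted as unassigned rather than guessed. Anchor
spacing rather than full alignment suffices here because the reporter is a
fixed amplicon and the only variation of interest is the net indel size
between the anchors.

A knockout's effect is expressed relative to mock controls (samples carried
through the protocol without a gene-targeting guide). Per replicate and IPR,

$$\Delta\log_2\mathrm{MMEJ{:}NHEJ} = \log_2\mathrm{MMEJ{:}NHEJ}_{KO}
  - \overline{\log_2\mathrm{MMEJ{:}NHEJ}}_{mock},$$

averaged (unweighted) over replicates. Computing the mock mean within each
replicate makes the score invariant to replicate-wide batch shifts, which is
tested as a property. Mock conditions are retained in the matrix — their
deltas average to zero per IPR by construction — because they are the
negative controls for every downstream test.

## Global effects

The global score of a protein is the mean delta over its IPRs. The screen
has 33 mock conditions, enough to estimate an empirical null: each protein
is z-scored against the mean and sample standard deviation of the mock
global scores, converted to a two-sided normal p-value and
Benjamini-Hochberg corrected across proteins (direction called at FDR
0.001). For inhibitor experiments, where each replicate has only a single
vehicle control and no mock population exists, `global_effect_ttest()`
substitutes a two-sided pooled-variance Student's t-test across replicates.
The degenerate zero-variance cases are handled explicitly (identical groups:
t = 0, p = 1; separated constant groups: flagged, p reported as the limit 0)
rather than erroring mid-screen.

## Chromatin context-dependency (CCD)

Each IPR sits in a characterized chromatin environment summarized by a
feature matrix (25 features in the main screen), z-scored across IPRs
(`standardize_features()`; a feature with values 1, 2, 3 maps to -1, 0, 1).
CCD detection is a three-step linear modeling procedure per protein
(`ccd_test()`):

1. **Omnibus pre-filter.** Per IPR, the mock deltas give a null mean and sd;
   the protein's summed squared z-scores are referred to a chi-square with
   one degree of freedom per IPR. BH FDR <= 0.25 retains the protein. This
   step is deliberately lenient — it only removes proteins with no effect of
   any kind, so that step 2 controls the reported FDR. The statistic is a
   design choice of this package; the omnibus form was chosen because it is
   sensitive to both uniform and context-restricted shifts.
2. **Principal component regression.** The delta vector is regressed on the
   leading principal components of the feature matrix — the smallest number
   explaining 90% of feature variance, capped at (number of IPRs - 3) so the
   fit can never saturate 19 observations. The overall F-test p-value is the
   CCD p-value; BH across tested proteins gives the CCD FDR, significant
   below 0.05 (0.25 is the appropriate choice for low-power pooled reporter
   lines with fewer usable IPRs). Regressing on components rather than 25
   collinear features keeps the omnibus test well-posed; with all components
   retained the fit is identical to the raw-feature fit, which is tested.
3. **Per-feature synergy scores.** For significant proteins only, the delta
   vector is regressed on each feature separately. The slope is the synergy
   score: positive means the protein favors NHEJ where the feature is high
   (N-synergy), negative means it favors MMEJ there (M-synergy). Slopes with
   p >= 0.05 are stored as exact zeros, without further correction across
   the 25 features — the protein-level FDR is already controlled in step 2,
   and the sparsified vectors are what the downstream cosine similarity
   expects. A protein whose surviving slopes are all negative is classed M,
   all positive N, both signs mixed.

Mock conditions are pushed through the identical three steps and reported
separately; on simulated null screens the fraction of mocks (and of true-null
proteins) passing the CCD FDR stays at or below the nominal rate, which is
the package's standing calibration check.

`estimate_feature_delta()` evaluates a stored step-3 fit at a chosen feature
level; the default level of +1 sd above the mean is this package's
convention for quoting "the estimated delta in that chromatin context",
chosen because feature levels are on a z-score scale and +1 sd is the
natural "embedded in this feature" working point.

Because chromatin features are correlated, planting a coefficient on one
feature implies nonzero marginal slopes on its correlated neighbors: if
$\beta$ is the planted coefficient vector and $C$ the feature correlation
matrix, per-feature simple regressions estimate $C\beta$, not $\beta$. The
synthetic-data generator therefore stores $C\beta$ as the planted truth in
slope space, and recovery tests compare against it (sign recovery is still
checked at the planted feature itself, where the marginal slope equals
$\beta$).

## Comparing CCD patterns

Similarity between two proteins' synergy vectors is the cosine

$$\cos(A, B) = \frac{\sum_i A_i B_i}{\lVert A\rVert\,\lVert B \rVert},$$

appropriate for sparsified vectors with many exact zeros. For the
interaction analysis, the mean cosine over physically interacting pairs is
compared with the means of 1000 random draws of equally many distinct pairs;
the two-sided p-value comes from a Gaussian fit to those null means, because
1000 draws cannot resolve tail probabilities below 0.001 empirically.
Random pairs are drawn without replacement within a draw, self-pairs
excluded; known-interacting pairs are not excluded from the null (their
share of a large pair universe is negligible, and excluding them would
require the full interaction catalog). Maximal cliques in the interaction
graph are enumerated exactly (`find_cliques()`, cross-checked against
brute-force subset enumeration in the tests).

Across cell types, only chromatin features that the second cell type's
reporters actually sample are compared: a feature qualifies when at least 2
IPRs are embedded in it (feature z-score > 0.5). Matched-protein cosines are
compared with a null that pairs each protein with random screen proteins.
Signed cosine is used throughout; an anticorrelated pattern is evidence of
difference, not similarity.

## Tumor genomes

In whole-genome-sequenced tumors, MMEJ and NHEJ leave classifiable scars:
deletions longer than 5 bp with at least 2 bp of junctional microhomology
(MMEJ signature) or with none (NHEJ signature). One-basepair microhomology
is ambiguous and stays unclassified. `compute_microhomology()` takes the
longer of the left- and right-flank junctional homologies, capped at the
deletion length; this convention is isolated in one function so an
alternative (e.g. right-flank only) is a one-line change. Heterochromatin
and euchromatin are approximated by constitutive LADs and inter-LADs, the
only chromatin annotation stable enough to transfer across tumor types; a
deletion counts only if fully contained in one labeled interval, since a
boundary-spanning event has no unambiguous compartment.

Case samples for a gene of interest carry a loss-of-function driver in
exactly that gene, no marker of another repair deficiency, no mutagenic
treatment signature, and at least 500 genome-wide substitutions (a proxy for
adequate purity/coverage); controls satisfy the same quality filters with no
driver in any gene of interest. A gene is analyzed only with at least 5
cases, 3 of them in one cancer subtype, and datasets of one subtype are kept
as separate strata because their background balances differ measurably.

Per stratum, the four group-summed counts give

$$\Delta\log_2\mathrm{MMEJ{:}NHEJ}_{Het/Eu} =
  \log_2\frac{\mathrm{MMEJ}_{Het}}{\mathrm{NHEJ}_{Het}} -
  \log_2\frac{\mathrm{MMEJ}_{Eu}}{\mathrm{NHEJ}_{Eu}}.$$

If any of the four counts is zero, 0.5 is added to all four and the result
flagged — a continuity correction that keeps small strata usable instead of
discarding them. The case statistic is z-scored against a bootstrap built by
repeatedly drawing, with replacement from the control set, *as many samples
as there are cases*: the bootstrap emulates the sampling distribution of a
case-sized cohort under the control process. This sizing is what makes the
z-score calibrated; resampling the full control set instead would estimate
the (much smaller) variability of the control-cohort statistic and inflate
the null z by a factor of roughly $\sqrt{1 + v_{case}/v_{ctrl}}$. Even with
case-sized draws, exact standard-normal calibration additionally needs the
control set to be large relative to the case set (null variance is
approximately $1 + n_{case}/n_{ctrl}$) — with 10 cases against 50 controls
the null sd is about 1.1, which the calibration simulations reproduce.
Stratum z-scores are combined per gene with Stouffer's method,
$Z = \sum_k z_k / \sqrt{k}$, converted to a two-sided p-value and BH
corrected across genes (significant at adjusted p < 0.05). Long
microhomology-assisted deletions (1.4-272.9 kb, >= 2 bp microhomology) are
counted with the same containment rule and compared between cohorts with the
same bootstrap.

## The synthetic-data generators

`sim_chromatin()` emulates the screen's reporter panel: each IPR is assigned
one of four chromatin states (euchromatin; "triple" heterochromatin marked
jointly by H3K9me2/3, late replication and lamina interaction; H3K27me3
heterochromatin; other), and features of a state's defining block share a
latent variable (in-block correlation about 0.8) elevated on IPRs of that
state. The 25 feature names are a synthetic stand-in panel grouped 13/4/2/6
across the four blocks. `sim_screen()` draws per-(sample, IPR) read depth
from a negative binomial (dispersion 0.2 — amplicon libraries are clearly
overdispersed relative to Poisson), sets the MMEJ fraction among signature
reads by a logistic model on the log2-odds scale so that planted global
effects (gamma) and synergies (beta) are in the same log2 units the pipeline
estimates, fixes the other-indel and intact fractions at 0.2 and 0.3, and
shifts the baseline MMEJ odds up by 0.5 log2 units in heterochromatic
states, reproducing the higher MMEJ:NHEJ ratio observed there. Defaults
mirror the study design: 19 IPRs, 519 targeted proteins, 33 mocks, 3
replicates, 3000 reads per IPR. `sim_tumors()` generates an alternating
cLAD/ciLAD genome (10 intervals of 1 Mb per class), per-sample Poisson
deletion counts with control rates 20/10/10/20 per compartment and class
(again MMEJ-skewed in heterochromatin), planted multiplicative case effects,
microhomology 2-6 bp for MMEJ-class and 0 for NHEJ-class events, a short
unclassifiable background, and metadata that satisfies the case/control
filters by construction; the default 10 cases versus 50 controls mirrors the
few-mutants/many-controls design of tumor cohorts.

What the generators do *not* emulate: sequencing errors, the full indel
spectrum beyond the two signature classes, reporter-to-reporter differences
in cut efficiency, chromatin maps measured with noise, mutational-signature
confounding, or non-uniform deletion placement within compartments. Passing
tests on this synthetic data therefore demonstrate the statistical machinery
(calibration, recovery, invariances), not robustness to those real-data
complications.

## Problem sizes and numerical choices

The test suite and the acceptance script run 20 null screens of 100
conditions (67 targeted + 33 mocks) for calibration, 20 planted-effect
screens for recovery, 200 null tumor cohorts plus 20 planted cohorts (1000
bootstrap draws each) for the compartment statistic, and 1000 draws for the
similarity and Stouffer nulls — sizes at which the binomial standard errors
of the reported fractions are a few percent. p-values are floored at 1e-300
before BH correction (extreme z-scores underflow to exactly 0 otherwise);
ties in clustering are made deterministic by sorting proteins by name before
`hclust`; all stochastic functions take an explicit seed and restore the
caller's RNG state.

## Worked example

```{r example, eval = FALSE}
chrom <- sim_chromatin(n_ipr = 19, seed = 11)
scr <- sim_screen(chrom, n_proteins = 67, n_mock = 33, seed = 12,
                  gamma = c(KO001 = -1),
                  beta = list(KO002 = c(LMNB1 = -0.5)))
bal <- compute_balance(scr$counts)
dm <- delta_scores(bal, scr$samples, scr$truth$mock_ids)
glob <- global_effect_test(dm)          # KO001: score ~ -1, favors_MMEJ
ccd <- ccd_test(dm, chrom$features)     # KO002: M-synergy at LMNB1
ccd$synergy["KO002", "LMNB1"]
```

## Known limitations

Knockout penetrance is not modeled: in arrayed CRISPR screens incomplete
disruption shrinks all effect sizes toward zero, so recovered magnitudes on
real data underestimate the cell-biological effect; the synthetic generator
plants fully penetrant effects. The step-1 statistic, the PC count rule and
the per-feature significance rule are this package's documented choices
where the published description names only the steps; the mock calibration
bounds their behavior. The tumor analysis consumes precomputed deficiency
and signature flags and annotated deletion tables — variant calling, driver
calling and signature fitting are out of scope.
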