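---
title: "Models and methods in spurphos"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in spurphos}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

spurphos analyses spurious phosphorylation — phosphosites created by a
kinase with no evolved function in its host proteome — from DIA
phosphoproteomics through structural, evolutionary and fitness consequences.
This vignette explains each model, its assumptions, the tunable parameters,
and the design decisions that were genuinely open.

## Differential regulation

Each kinase is compared against its catalytically dead point mutant, the
expression-matched control. Precursors are filtered at ≤1% precursor and
global FDR, and phosphorylated precursors additionally at ≥75% localization
confidence (all bounds inclusive). A precursor enters a contrast only if
quantified in at least 75% of the replicates of one of the two conditions;
when one condition is entirely missing, that block is imputed from
N(μ − 1.8σ, (0.3σ)²), where μ and σ are the mean and standard deviation of
all observed log2 intensities of the contrast. Imputation is deliberately
narrow: partially missing cells in a retained condition stay missing and the
test uses available values, because left-shifted imputation of sporadic
holes biases the variance estimate downwards.

The test is a two-group moderated t. Per-feature residual variances s²_g on
d_g degrees of freedom are shrunk toward a prior (d₀, s₀²) estimated by the
closed-form moments method from the distribution of log s²_g (delegated to
`limma::squeezeVar`, the reference implementation); the moderated statistic
has d₀ + d_g degrees of freedom, capped at the pooled residual df. The
non-robust variant is used: the robust variant's winsorisation constants are
implementation-specific, and the package's unit tests pin the exact
closed-form behaviour against a full limma fit instead. BH correction is
applied within a contrast; the site-call threshold defaults to q < 0.01 and
is exposed as a parameter because reasonable site-count tables can be drawn
at 0.01 or 0.05.

Sites aggregate from precursors by an any-significant rule: a site is up for
a kinase if at least one covering precursor is significantly up. A site
called in both directions by different precursors is a localisation or
interference artefact; it is flagged and excluded from counts rather than
resolved by vote.

## Occupancy (stoichiometry)

For a site with phospho intensity x_s = κ·p_s·T_s and non-phospho intensity
y_s = κ′·(1 − p_s)·T_s (κ, κ′ ionization efficiencies, T_s protein amount,
p_s occupancy), dividing both by a protein-abundance estimate makes
(x_s, y_s) collinear: y = a + b·x with x_max = −a/b the fully phosphorylated
intensity and p_s = x_s/x_max. The algebra cancels κ and κ′, which is why
the estimate needs no calibration standards. Assumptions: the pair is the
only modified form of the peptide (enforced by the exactly-one-counterpart
filter), protein normalisation is accurate, and noise is multiplicative.

The regression is ordinary least squares of y on x in linear intensity
space — linear because the mixture algebra lives on the linear scale. x
carries the imputed zeros (a phospho precursor absent from a kinase-dead
sample is evidence of occupancy near zero, not a missing value), so the
orientation keeps imputed values as design points rather than targets; an
option flips the orientation. Groups with b ≥ 0 cannot yield occupancies in
[0, 1] and are discarded ("illegal"); per-sample estimates outside [0, 1]
from noise are clamped with the raw value retained. Per-condition occupancy
is the mean over replicates (median is available), and cohort summaries are
medians over sites.

maxLFQ protein profiles follow Cox et al: median pairwise log-ratios over
shared peptides, a least-squares solve of the ratio graph per connected
component, and rescaling so the protein intensity sum matches the peptide
intensity sum. `minRatioCount` defaults to 1 so that a single-peptide
protein still receives a (peptide-proportional) profile; 2 reproduces the
MaxQuant default. Non-phospho peptides whose phospho counterparts are
significantly regulated are excluded from the matrix, since their
non-phospho intensity is then confounded by occupancy changes.

The recovery precision of the whole stack depends visibly on how many
unmodified peptides support the protein profile: the pure regression error
at a 25% CV with 10 samples is ≈0.03 (median |p̂ − p|), while normalising by
a profile built from very few peptides adds the profile's own error to both
axes. The generator default of 15 unmodified peptides per protein reflects
deep DIA coverage of an average yeast protein; with it the end-to-end
median error is ≈0.02–0.04.

## Structural profiling

SASA is computed by Shrake–Rupley sphere sampling with a deterministic
golden-spiral point set (default 960 points per atom, probe 1.4 Å) and
element van-der-Waals radii; atoms are first mapped into a canonical
molecular frame (principal axes, third-moment sign convention), which makes
the result invariant under rigid transforms of the input to rounding error.
DSSP-computed SASA would differ in the second decimal; every downstream use
is threshold-based (0.2/0.4/0.581), so threshold behaviour, not bit-match,
is the contract.

RSA divides by the residue's maximum accessible area. For all-atom models
the Tien et al empirical maxima are used (Tyr = 255 Å²). The package's
synthetic structures are reduced Cα chains, for which those maxima are
meaningless; the analogous reference is the analytic SASA of a Cα sphere
flanked by two bonded neighbours in a straight chain (`maxSasaReference("calpha")`),
the Gly-X-Gly idea transplanted to the reduced representation.

Disorder is the windowed-RSA proxy: mean RSA over ±12 residues (truncated at
termini, no padding) ≥ 0.581. Burial is strict: buried < 0.2, exposed > 0.4.
Folding ΔΔG > 2 kcal/mol is destabilising; per-site ΔΔG is the mean over
FoldX runs (5 in the standard protocol; fewer are flagged). Interface calls
need monomer RSA > 0.15, ΔSASA > 1 Å² and, when a PAE matrix is available,
minimum cross-chain PAE < 8 Å. Proximity uses ≤4 residues (1D) and ≤8 Å
minimum heavy-atom distance (3D) after excluding pLDDT < 70 residues; no
phosphate atoms are modelled, so the ~1.6 Å phosphate extension should be
kept in mind when interpreting borderline 3D distances.

## Variant-effect weighting

Conservation-based variant-effect predictors score amino-acid substitutions,
not phosphorylation. The package converts a 19-substitution score row into a
pY score by weighting each substitution with its biophysical similarity to
pY: for every FoldX energy term, the correlation over sites between the
substitution's ΔΔG column and the pY column; weights are the mean
correlation across terms, floored at zero (they are similarities; a config
switch exposes raw weights) and renormalised to sum to one. The weighted
mean is then rank-normalised within each protein so 1 is the most harmful
position. Score orientation (whether lower raw scores are more harmful) is a
required flag, never assumed. One caveat found while testing: under pure
noise the floor censors about half the mean correlations, so individual
null tables do not give uniform weights — only their expectation is uniform —
which is the property the test suite asserts.

## Evolutionary tests

*Amino-acid deserts.* A protein (length ≥ 150) is a desert for an amino acid
if a contiguous stretch of ≥ ceil(L/2) residues lacks it. The null preserves
each protein's length and per-residue order/disorder labels and redraws
residues iid from the proteome-wide state-specific composition; the excess
is observed% − mean over 100 simulations. Percentages weight proteins
equally; a length-weighted alternative is not implemented.
The self-calibration experiment uses 6000 proteins of 800–1200 residues:
at realistic tryptophan frequencies shorter proteins put the Trp-desert
probability near 45%, where the sampling noise of a single observed proteome
alone exceeds one percentage point; at L ≈ 1000 all per-amino-acid desert
probabilities are ≤ 10% and the one-point calibration band is ≈2.5 standard
errors wide. The desert inner loop is compiled (Rcpp) and uses R's RNG, so
results are seed-reproducible.

*Site conservation.* A yeast pY is conserved at window k if any metazoan
ortholog carries a pY within ±k alignment columns; percentages are reported
over all pY, pY with an ortholog, and pY with a pY-carrying ortholog. The
permutation null reshuffles each ortholog's pY labels among that ortholog's
tyrosines (within-protein permutation preserves protein-level composition
confounders; a whole-proteome mode is a flag away), with the add-one
empirical p = (1 + #{null ≥ obs})/(1 + n_perm) so p is never zero at 100
permutations. The calibration experiment (200 seeds) uses 40 panels × 5
sites with a per-site null hit probability near 0.5: the statistic is a
count, and calibration against a continuous uniform is only meaningful when
tie probability is small, which requires the count's conditional spread to
be wide.

*Independent contrasts.* Felsenstein contrasts (via `ape::pic`; polytomies
resolved to zero-length branches) with correlation computed through the
origin and a t-test on n_contrasts − 1 df. The test suite pins equality with
the brute-force GLS correlation under Brownian covariance at 1e-10 on small
trees.

*Equilibrium-frequency shifts.* Δπ_Y = π_fungi(Y) − π_metazoa(Y) per site,
filtered at adjusted p < 0.05 (the substitution-model inference producing π
and its p-values is consumed as input, not computed), stratified by burial,
and compared pY vs non-pY by two-sample two-tailed KS; strata under 5 sites
per arm are reported NA.

## Fitness screen

Growth curves are baseline-subtracted at the first time point (negative
values clipped at zero and counted) and filtered on colony circularity
(default threshold 0.6; the screening literature uses 0.5–0.7 and the value
is a config parameter). AUC uses composite Simpson's rule — exact for cubics
on uniform grids; non-uniform grids fall back to interval-wise quadratics
and a trapezoid on an odd trailing interval. Colony AUCs are rescaled by the
plate's mean reference AUC, making scores comparable across plates and
invariant to per-plate scale. The WT − dead difference in mean rescaled AUC
is tested by Mann–Whitney U (exact below 21 per arm, normal approximation
with tie correction above) and BH-corrected jointly across kinase ×
condition pairs (a per-condition mode exists behind a flag).

The flow-cytometry threshold fits a 1-D two-component Gaussian mixture by
EM, initialised at the 25th/75th percentile split, and takes the root of
w₁φ₁ = w₂φ₂ between the means; if the weighted densities do not cross there
(extreme weight asymmetry), the midpoint is used with a warning. Events
negative or positive in both channels are discarded and the reported
frequency is the fraction of retained events without mCherry signal.

## The synthetic-data generator

The generator is the package's ground-truth instrument, not a fixture. It
emulates: state-specific amino-acid composition and geometric segment
lengths for proteomes; Cα chains as fixed-bond (3.8 Å) self-avoiding walks,
collapsed in ordered and extended in disordered segments, with SASA computed
by the package's own implementation so structural tests are internally
consistent; the occupancy mixture model with per-precursor ionization
efficiencies, per-sample protein amounts, multiplicative log-normal noise
parameterised by CV (default 25.3%, a typical DIA replicate CV) and
missingness that is completely-at-random by default with an optional
intensity-dependent (logistic in log-intensity) mode; logistic colony growth
with the WT effect as a multiplicative growth-rate reduction; and two-clade
ortholog panels with per-column categorical distributions and planted
metazoan tyrosine depletion Δπ_Y.

What it does not emulate: peptide chemistry (digestion, retention time,
charge-state envelopes), structured (batch or gradient) missingness,
real protein folds (the walks have no secondary structure, so burial
fractions are calibrated by the walk's compactness, not physics), indel
histories in alignments (panels are ungapped unless gaps are injected), and
selection acting on anything except the planted tyrosine shifts. Passing
recovery tests therefore demonstrates correctness of the estimators under
the stated noise model, not robustness to every artefact of real data.

Default study conditions (`defaultConfig()`): 4 kinases with 30/20/10/3
regulated sites and matched growth-rate costs 0.30/0.20/0.10/0, five
replicates per arm, occupancy 0.5 (WT) vs 0.05 (baseline), 16 growth
replicates over three conditions, 24 planted Δπ sites of 0.5 on a
480-column panel, 100 permutations and 100 desert simulations. These sizes
keep the full pipeline run to roughly two minutes while leaving every
recovery quantity with adequate precision; the desert and permutation
calibration sizes above were chosen by the power analyses described in
their sections.

## Numerical choices and degenerate inputs

Zero intensities in precursor reports are treated as not-quantified (DIA
software does not emit true zeros). The precursor identity key is (peptide,
charge, exact modification set). Imputation with σ = 0 degenerates to the
constant mean with a warning. `fitOccupancy` needs ≥3 usable samples, else
`insufficient_data`. Rank normalisation of a single position returns 0.5
with a warning; ties get mean ranks. The GMM floors component variances at
1e-9 and sorts components by mean. Desert spans use ceil() at the 50%
boundary and ≥ comparisons throughout; the ortholog coverage boundary at
exactly 0.5 is kept. Empirical permutation p-values use the add-one formula.
KS tests on tied data are run with `suppressWarnings`; their p-values are
approximate in the presence of ties.

## Known limitations

The moderated test implements the non-robust shrinkage variant. SASA is
sampling-based (≤2% error at 960 points) rather than analytic. The maxLFQ
solver computes all pairwise ratios, which is quadratic in samples — fine at
screen scale (tens of samples), slow for hundreds. The Δπ stage consumes
externally inferred equilibrium frequencies; it does not fit substitution
models. Fitness scoring uses AUC only; other growth parameters (rate, lag)
are generated but not scored.
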