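---
title: "Methods: pharmaceutical fate and active-community analysis in granular sludge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pharmaceutical fate and active-community analysis in granular sludge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(granulefate)
```

# Scope and model

`granulefate` analyses exposure experiments in which an aerobic granular
sludge (AGS) sequencing batch reactor (SBR) is dosed with trace
pharmaceuticals while a paired control reactor runs undosed. Three
questions drive the design: how much of each compound is removed and by
what route (sorption vs biodegradation, visible through a desorption
episode); which transformation products appear and when; and which
members of the granule community are metabolically active while
performance shifts.

## Quantification and mass balance

Concentrations come from ordinary least-squares calibration of peak area
against nominal standard concentration, inverted per sample. Measured
values are divided by the extraction recovery estimated from
prespiked/unspiked/postspiked duplicate triplets,
$R = (C_{pre} - C_{un}) / (C_{post} - C_{un})$.
Assumptions worth stating:

* Recovery above 1 (matrix signal enhancement) is accepted and propagated,
  not clipped; values outside $(0, 2]$ are rejected as physically
  implausible for this assay.
* Percent removal is a concentration mass balance,
  $100\,(C_{in}-C_{eff})/C_{in}$, treating per-cycle influent and effluent
  volumes as equal. SBR exchange volumes are operationally fixed, and this
  form reproduces the expected sign conventions (effluent at twice
  influent during desorption gives exactly $-100\%$). A volumetric term
  could be added if per-cycle volumes differed, but is deliberately out of
  scope.
* Concentrations quantified below the calibration intercept are clipped to
  zero and flagged `below_range`; corrected concentrations under the
  configurable limit of quantification (default 10 µg/L) are flagged
  `below_loq` rather than removed.

## Suspect screening

Candidate degradation-product peaks are screened against a compound
database carrying Hill-notation formulas. The theoretical m/z is the
monoisotopic mass plus the charge-carrier shift ([M+H]⁺ by default;
[M+Na]⁺ available). The reporting rule is two-part and asymmetric on
purpose: mass error strictly below 5 ppm, signal-to-noise inclusive at 10.
The absolute value of the signed ppm error is filtered, since the rule is
stated without sign. Atomic masses (standard atomic weights and
most-abundant-isotope masses) are embedded as a versioned constant table
so screening is bit-stable across machines.

Corrected peak areas are relative concentration proxies, not absolute
amounts: aqueous areas are multiplied by the SPE concentration factor and
divided by the same-run 100 µg/L parent standard's area; solid areas are
divided by standard area times dry weight. The aqueous form multiplies by
the concentration factor as printed in the source protocol even though a
division could also be argued; the choice is recorded here once and a
reader comparing runs with equal concentration factors is unaffected.
Peaks with no usable standard area are flagged `unnormalizable`, never
silently dropped. Non-detections are explicit gaps in the product time
series, not zeros — an absent peak carries no abundance information.

Two database notes: the diclofenac parent is stored as C14H11Cl2NO2
(molecular weight ≈ 296.1 g/mol), with the hydroxylated product DCF1 as
C14H11Cl2NO3; published tables sometimes conflate the two, and the
mass-consistent assignment is used. GEM2 has no printed formula in the
sources at hand; C15H20O4 is inferred from GEM1 (C15H22O4) by oxidation of
the hydroxymethyl group to a formyl group and is documented as inferred.

## Active-community caller

The caller consumes paired DNA (rRNA gene) and cDNA (rRNA transcript)
ZOTU count matrices. Per sample and per trial, both libraries are rarefied
without replacement to fixed depths and the taxon-wise ratio of rarefied
cDNA relative abundance to rarefied DNA relative abundance is computed.
Using relative abundances makes unequal DNA/cDNA depths comparable; when
depths are equal it reduces to the plain count ratio. Rules per trial:

* cDNA > 0, DNA = 0 — a *phantom* in that trial: the ratio is set to 100.
  The substitution is applied per trial, exactly, including for taxa that
  do have DNA reads overall but dropped out of that trial's subsample.
* Both zero — the taxon is absent from the trial and contributes no value
  to its across-trial mean (an alternative absent-as-zero mode exists
  behind a flag, off by default).

The across-trial mean ratio (default 100 trials) is thresholded at 1
(inclusive) for the active call. Structural phantoms — zero DNA reads in
the whole library with positive cDNA — therefore always carry mean 100 and
are active by construction. Active relative abundances renormalise the
*unrarefied DNA* reads over the active set; phantom taxa contribute their
DNA reads as-is, which for structural phantoms is zero. That zero is an
acknowledged ambiguity of the convention (a taxon can be called active yet
carry no abundance); no pseudo-count is introduced to hide it. Diversity
(observed richness and Shannon entropy, natural log) is computed from DNA
reads only, because reverse transcription can bias cDNA read numbers.

Rarefaction depth defaults to the minimum library total across both pools;
seeds are derived deterministically per (sample, trial) from one master
seed, so per-sample results are order-independent and reproducible.

## Response ratios and vector fitting

Between two timepoints the bounded response ratio $(b-a)/(b+a)$ is used.
The formula is chosen as the standard symmetric difference-over-sum
statistic matching the stated range $[-1, 1]$ and the interpretation of
the extremes (+1 appearance, −1 disappearance); $|r| \le 0.5$ (inclusive)
is neutral, making the three categories an exact partition with
deterministic boundaries. The 0.1 % minimum-abundance filter is applied as
"exceeds at either timepoint" (strict >), which retains exactly the taxa
that appear or vanish — the cases the extremes describe.

Vector fitting regresses a centred environmental variable on centred
ordination coordinates; the unit coefficient vector is the fitted
direction, the fraction of variance explained is $r^2$, and significance
is a permutation p-value $(1 + \#\{r^2_{perm} \ge r^2_{obs}\})/(1 +
n_{perm})$. Ordination itself (NMDS) is an input, not implemented here;
when the pipeline runs on simulated data without user-supplied
coordinates it substitutes classical metric MDS of the active composition
purely as stand-in coordinates, and labels them as such. The in-package
fit is cross-checked against `vegan::envfit` in the test suite.

# The synthetic-data generator

The generator is a stated world, not a tuning device. Its defaults encode
the reference scenario: two reactors over 80 days, each pharmaceutical
dosed at ~150 µg/L, partial removal through day 12, a desorption spike
with effluent ≈ 2× influent through day 23, then negligible removal; a
community of 150 ZOTUs with 20 % truly active (transcript:gene
concentration ratio 3), 5 % structural phantoms, inactive taxa at ratio
0.3, and 10,000-read libraries. Measurement noise is multiplicative
lognormal (CV 10 %), consistent with reported ±10–20 % spreads for these
assays; recoveries default to the reported means (aqueous 0.97/1.17/0.98
for DCF/ERY/GEM). Phase-1 removal defaults are 0.50 (DCF) and 0.18 (ERY)
from the reported peaks; gemfibrozil has no reported percentage and 0.40
was fixed once as a value between the two, consistent with the roughly
half-complete degradation its product pattern suggests.

Community abundances follow a lognormal profile with `sdlog = 0.6` and
Dirichlet (θ = 200) sample-to-sample wobble. That skew was chosen once so
that every non-phantom taxon stays deep enough (relative abundance above
~10⁻³) that undersampling-induced DNA dropout is negligible — phantoms are
then *structural by construction*, and the phantom rule is exercised
deterministically at any depth. Real communities have heavier rare tails;
the `undersampling_phantoms` option restores that behaviour by making
phantoms merely rare, at the cost of a caller specificity penalty that is
a genuine property of the method (a rare inactive taxon that drops out of
the DNA subsample in even ~1 % of trials inherits enough of the phantom
value 100 to push its mean ratio over 1). A green recovery test therefore
establishes that the caller works under moderate evenness and structural
phantoms; it does not establish robustness to heavy-tailed rare biospheres,
and users of the method on real data should expect phantom-driven false
positives among very rare taxa.

Degradation-product peaks are generated with small truncated mass errors
(SD 1.5 ppm, |error| ≤ 4.5 ppm) and S/N ≥ 10 when truly present, plus
decoy peaks with errors of 8–18 ppm after the desorption phase, so the
screen has both signal and foil. With noise set to zero every generated
relationship is exact, which is what the round-trip tests assert.

What the generator does **not** emulate: read-level sequences (no FASTQ),
hydraulic or biokinetic reactor dynamics (no ODE model), chromatographic
artifacts, inter-compound interactions, and temporal autocorrelation of
measurement noise.

# Numerical choices

* Lognormal noise uses `meanlog = -sdlog²/2` so noise factors have mean 1
  and zero-noise limits are exact.
* Rarefaction subsamples read indices without replacement
  (`sample.int` over the cumulative count boundaries); totals equal the
  requested depth exactly, checked in tests against the hypergeometric
  expectation and `vegan::rrarefy`.
* Child seeds are derived from the master seed by modular multiplication
  below 2³¹, keeping them valid R integers.
* Quantification tolerates least-squares rounding at the intercept
  (≤ 10⁻⁹ relative) before flagging a value below range.
* The ppm screen is evaluated on the signed error's absolute value;
  boundary semantics (5 ppm fails, S/N 10 passes) live in the tiny
  `screen_filter()` primitive so they are testable without floating-point
  round trips through m/z space.
* Pipeline determinism is asserted on MD5 content hashes of all written
  tables (`tools::md5sum`); the run log carries timestamps and is excluded
  from the manifest. The configuration file dialect is flat JSON — one
  coherent scenario per run — which round-trips types exactly and matches
  the manifest's dialect.

# Known limitations

* The mass balance ignores reactor volume terms; if per-cycle influent and
  effluent volumes differ, removal percentages shift accordingly.
* Response ratios are computed from active-community relative abundances
  (not whole-community abundances of active taxa); the two differ when the
  active fraction changes between timepoints. This is an assumption, made
  explicit here.
* The phantom value 100 is a convention, not an estimate; mean ratios of
  taxa with frequent trial-level phantoms are dominated by it.
* No multiple-testing correction is applied across fitted environmental
  vectors; p-values are reported raw.
* Degradation products are tracked relatively (corrected areas); no
  absolute quantification or isotope-pattern/MS² evidence is attempted.
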