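---
title: "Quantifying heavy-lysine labeled fly proteomes: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying heavy-lysine labeled fly proteomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(silafkit)
```

## The measurement model

In a SILAC/SILAF experiment two protein populations — one grown on a
"light" diet, one on a diet whose lysine carries six ^13^C atoms — are
mixed, digested with endoproteinase Lys-C, and analyzed together by
LC-MS/MS. Every lysine-containing peptide then appears as a pair of
isotopic species, and the heavy/light (H/L) intensity ratio of the pair is
a within-run relative quantification that survives fractionation and
enrichment. Two derived quantities carry all downstream analyses:

* the **incorporation rate** of the heavy label,
  $f = I_H / (I_H + I_L)$, computed from *not-normalized* intensities,
  which measures how much of a protein pool was synthesised on the
  labeled diet; and
* the **normalized H/L ratio**, whose log2 across conditions is the
  protein's fold change when the two channels are two experimental
  conditions.

Lys-C cleaves strictly C-terminal of lysine; the `/P` variant used here
also cleaves lysine–proline bonds. `lysc_digest()` implements exactly this
rule with up to a configurable number of missed cleavages (default 2), so
every fully cleaved peptide except the protein's C-terminal one ends in K.

## Labeling kinetics and turnover

Pulse labeling is modeled as a single-pool first-order process,
$f(t) = 1 - e^{-kt}$, with $k$ the per-day turnover rate constant and
half-life $\ln 2 / k$. This is the simplest model consistent with monotone
incorporation curves; it ignores precursor-pool enrichment delays, label
recycling and growth dilution. `fit_turnover()` estimates $k$ per protein
by unweighted least squares on the fraction scale (fractions are bounded
and approximately homoscedastic), using bounded scalar optimization over
$k \in (10^{-6}, 10]$ per day with an absolute tolerance of $10^{-10}$.
A fit is declared non-converged when it hits a bound (for example, a
protein whose fractions are all zero) or exceeds a configurable residual
threshold; this is a reported state, not an error. The asymptote is fixed
at 1: larvae reach near-complete labeling, and adult regimes that plateau
below 1 are better handled by restricting the fitted time range than by an
extra free parameter at 8 timepoints. $t = 0$ is anchored at the transfer
to labeled food with $f(0) = 0$.

## Ratio quantification

Quality filtering removes protein groups flagged as reversed decoys,
potential contaminants, or identified only by modified peptides, before
any statistic is computed; the per-flag removal counts are logged.
Peptide-level log2 H/L ratios are **median-centered per run** — the
normalization upstream search engines apply by default — with the shift
logged per run. Median centering assumes most proteins are unchanged; when
a substantial asymmetric fraction of the proteome moves, the centering
itself introduces a small opposite shift in the null proteins. The
synthetic designs here keep the changed fraction at 5–10%, where this
effect is well below the reported error tolerances, and this caveat is the
reason the empirical FDR of the default fixture is checked against 0.1
rather than the nominal 0.05.

Protein-level log2 fold changes are the **median** of peptide log2 ratios
per (biological, technical) replicate — robust to a single aberrant
peptide — then technical replicates are averaged on the log2 scale before
any inference, to avoid pseudo-replication, and the protein's
`mean_log2fc` is the mean over biological replicates. Peptides observed in
only one channel have no finite ratio; they are excluded from ratio
statistics but retained for incorporation sums and presence counts.
Incorporation aggregates sum raw intensities per protein *before* taking
the ratio (intensity weighting), matching the definition of the
incorporation rate; pooling across proteins for density summaries happens
after the per-protein fraction is formed.

## Phosphosite occupancy changes

Sites are retained only when the phospho-group's localization probability
is **strictly greater than 0.75**; a site at exactly 0.75 is removed. The
occupancy change of a site is defined as the difference between its log2
H/L ratio and its protein's log2 H/L ratio in the same replicate:
a site that merely follows its protein's abundance has occupancy change 0.
The alternative three-ratio stoichiometry estimator (site, unmodified
counterpart peptide, protein) requires counterpart-peptide ratios that
standard site tables do not carry, so the protein-normalized difference is
the default and only implemented method. Sites on proteins absent from
the filtered protein table are reported unmatched rather than silently
dropped, and sites on proteins whose own fold change exceeds a threshold
(default |log2FC| > 2) are flagged as potentially confounded — a strongly
changed protein can skew the apparent occupancy — but never removed.

## Moderated differential testing

With 2–4 biological replicates, per-feature variance estimates are
unstable; the package implements an empirical-Bayes moderated one-sample
t-test. Per-feature sample variances $s^2_g$ (with $d = n - 1$ degrees of
freedom) are shrunk toward a prior $s_0^2$ with weight $d_0$:

$$\tilde{s}^2_g = \frac{d_0 s_0^2 + d\, s^2_g}{d_0 + d},\qquad
  \tilde{t}_g = \frac{\bar{x}_g}{\tilde{s}_g / \sqrt{n}},$$

with two-sided p-values on $d_0 + d$ degrees of freedom. The
hyperparameters are estimated by method of moments on $\log s^2_g$: the
location gives $s_0^2$ and the dispersion in excess of
$\psi'(d/2)$ gives $d_0$ through Newton inversion of the trigamma
function. When the observed dispersion does not exceed the sampling
dispersion, the moment equation's root lies at infinity; the estimator
then returns $d_0 = \infty$ (complete shrinkage, a z-test against the
pooled variance) with a warning — this is the correct limit of the moment
equation, since trigamma is a decreasing bijection of $(0,\infty)$ onto
itself. $d_0 = 0$ reproduces the ordinary t-test exactly, which is used
as an identity check in the tests. A one-sample design is the default
because mixing the two channels makes every replicate self-paired.
Exactly zero-variance (noise-free) input is refused by the test with an
error advising a noise floor; the pipeline wrapper instead reports such
features as untested so that noise-free recovery runs still complete.

False-discovery control is Benjamini–Hochberg step-up, implemented once in
`bh_adjust()` and shared by every module. Significance conventions follow
common practice for this design: adjusted p < 0.01 for the proteome,
< 0.05 for occupancy changes, with direction taken from the sign of the
mean log2 fold change.

## Enrichment

`ora()` is a one-sided upper-tail hypergeometric test of a foreground
against a user-supplied background (sets intersected with the background
first; fewer than 3 foreground hits by default leaves a set untested).
`gsea()` is the weighted running-sum statistic over the ranked mean log2
fold changes (hit weight $|x|^w$, $w = 1$ by default; $w = 0$ recovers
the classic unweighted statistic). Significance is by gene-label
permutation — the only permutation scheme available for a single ranked
list — with the p-value computed conditionally on the enrichment-score
sign against same-signed permutation scores, and the normalized score
dividing by the mean magnitude of those scores. The permutation p-value is
floored at one over one plus the number of same-signed permutations.
Identifier mapping between accession spaces is out of scope: gene sets
must use the same identifiers as the results. Boxplot-style per-category
summaries use median, quartile box and ±1.5 IQR whiskers clipped to the
data, with a Wilcoxon rank-sum test of each category against all other
proteins.

## What the synthetic generator emulates — and what it does not

`make_ground_truth()` + `simulate_experiment()` generate a complete
experiment with persisted truth so every stage can be scored by parameter
recovery. The defaults define the study conditions used throughout the
tests and the acceptance script:

* 1000 random-sequence proteins (lysine frequency ~7%), log2-normal
  abundances (sd 2 on log2 scale, a ~4 orders-of-magnitude dynamic range);
* in-silico Lys-C/P digestion, detectable peptide window 7–40 residues,
  at most 8 observed peptides per protein;
* 4 biological × 2 technical replicates; technical replicates are
  independent re-draws of measurement noise around the same biological
  sample;
* multiplicative log-normal intensity noise, sd 0.25 on the log2 ratio
  scale — typical peptide-level SILAC ratio scatter;
* a 50-protein OXPHOS-like category at true log2FC −1 (the knockdown-like
  contrast), all other proteins unchanged;
* turnover rates log-normal around 0.05/day (slow adult-fly labeling,
  ~50% in two weeks), with ribosome-like proteins 3× faster and
  OXPHOS-like proteins ~3× slower, emulating the nonuniform labeling of
  functional categories;
* phosphosites on 30% of proteins at genuine S/T/Y positions, 25% of
  sites with a twofold true occupancy shift of random sign; localization
  probabilities from a two-component mixture with 80% of sites above the
  0.75 threshold;
* missing-not-at-random channel dropout (logistic in log intensity,
  capped at 20% for the faintest signals), and 2% contaminant, 1% decoy
  and 0.5% only-by-site rows to exercise the filters.

The generator does not simulate spectra, retention time, fractionation
chemistry, charge-state interference, arginine labeling or
proline-conversion artifacts, ratio compression, or shared (razor)
peptides between protein groups. Passing recovery tests therefore
demonstrates the correctness of the downstream arithmetic and inference
under a realistic noise/missingness model — not robustness to every
acquisition artifact of real LC-MS/MS data.

## Numerical conventions and degenerate inputs

* Absent intensities are `NA` end to end; no operation converts an absent
  value to 0. A peptide row with both channels absent is a format error.
* Decimal parsing accepts period decimals and scientific notation only;
  identifiers are opaque case-sensitive strings.
* Labeling quartile bins are right-closed: `[0-25]`, `(25-50]`,
  `(50-75]`, `(75-100]` percent.
* Flag columns follow the "+"-marker dialect; column names are
  configuration (`evidence_columns()` and friends), not hard-coded.
* Ground truths serialize to JSON with 17 significant digits so doubles
  round-trip bit-exactly and a reloaded truth regenerates byte-identical
  tables.
* Problem sizes in the test-suite simulations (200–1000 proteins, 1000
  turnover fits, 2000-feature calibration matrices, 20 × 1000-permutation
  GSEA runs) were chosen as the smallest designs at which the binomial /
  sampling noise of each recovery metric is comfortably below its
  tolerance.

## Open choices made here

* Whether per-protein incorporation should be pooled before or after
  aggregation is ambiguous in common practice; the package computes the
  per-protein fraction first and pools after, keeping the per-protein
  table available for either convention.
* "FDR" is interpreted as Benjamini–Hochberg; no q-value estimation.
* Proteome and phosphoproteome features are moderated separately — their
  variance structures differ, and pooling would let the larger table
  dominate the prior of the smaller.
* The ORA background is always user-supplied (the quantified universe),
  never an implicit all-annotated-genes universe.

## Limitations

Median-centering bias under strongly asymmetric regulation (discussed
above); no compartment models for turnover; no protein-inference or
peptide-sharing logic; no label-free quantification beyond presence
summaries; enrichment requires pre-mapped identifiers. These are
deliberate scope boundaries, not accidents of implementation.
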