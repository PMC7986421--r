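---
title: "Modelling total FLC dynamics during vernalization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling total FLC dynamics during vernalization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flcdyn)
```

## The model and its assumptions

*Brassica napus* carries nine expressed copies of the floral repressor
*FLC*. The package's central assumption is that the *total* FLC dose —
the sum of TPM over all nine paralogues — is what represses flowering,
and that each locus switches off stochastically at a constant per-day
probability during cold. That assumption makes the expected expression of
a paralogue an exponential in days of cold $x$:

$$\mathrm{M1}:\; y = a e^{bx}, \qquad \mathrm{M2}:\; y = a e^{bx} + c,$$

with $a, c \ge 0$ (TPM) setting the pre-vernalization level and $b$
(per day) the cold response. M1 models decay to silence; M2 decay to a
stable floor, appropriate for copies that are only partially silenced. A
single (monophasic) exponential is used throughout; a biphasic model is
out of scope here. The rate $b$ is deliberately unconstrained in sign:
one paralogue (`BnaFLC.C09b`-like behaviour) maintains or slightly
increases expression under cold, and forcing $b < 0$ would misfit it.

An accession is predicted to become competent to flower on the first day
its total-FLC trajectory drops to a competence threshold. The threshold
is taken from a spring reference with no cold requirement: its
pre-vernalization total is by definition already permissive, giving a
single global lower bound (the default synthetic reference is built at
75 TPM). A single shared threshold is a simplification — the true
permissive level will vary between accessions — and the package keeps it
global but overridable (`competence_threshold(override = ...)`).

## Fitting: variable projection, not generic optimisation

For fixed $b$ both models are *linear* in $(a, c)$, so `fit_decay()`
profiles the residual sum of squares over $b$: a coarse grid over
`b_range` (default $[-1.5, 0.5]$ per day, 201 points, augmented by a
log-linear regression start) locates the basin, and `stats::optimize()`
refines the minimiser to a tolerance of $10^{-10}$ in the bracketing
interval. The constrained linear solve at each $b$ compares the interior
solution with the $c = 0$ and $a = 0$ boundaries, which guarantees the
nesting property $\mathrm{SSE}_{M2} \le \mathrm{SSE}_{M1}$ exactly rather
than up to solver luck. Fitting is on the raw TPM scale (zeros occur, and
the model is stated on that scale); the log-linear regression on positive
replicate means is used only for initialisation. All replicate-level
points enter the SSE with equal weight.

Degenerate all-zero series — in the default archetypes, the unexpressed
pseudogene `BnaFLC.C03b` — are reported as a sentinel fit with $a = 0$
and flagged, and are excluded from downstream rate pooling.

```{r fit-example}
day <- rep(c(0, 7, 14, 21, 28, 42, 56, 84), each = 3)
fit <- fit_decay(day, 300 * exp(-0.05 * day) + 40, model = "auto")
fit
```

## Model selection

M2 is adopted only when its extra floor parameter earns its keep:
$F = (\mathrm{SSE}_1 - \mathrm{SSE}_2)/(\mathrm{SSE}_2/(n-3))$ on
$(1, n-3)$ degrees of freedom, $\alpha = 0.05$ (the selection level is a
package default; parsimony tie-breaks keep M1 when M2 does not improve
the fit beyond numerical tolerance, or when both interpolate exactly).
Because $c$ is constrained non-negative, about half of all floor-free
datasets land on the $c = 0$ boundary where $F = 0$, which makes the test
conservative; under iid Gaussian errors — the error model under which the
F-test's nominal level is defined, and the one used in the calibration
simulations — the measured type-I rate is ≈ 0.034 at $\alpha = 0.05$,
and under the generator's multiplicative noise it is more conservative
still. Power against a planted floor of half the amplitude is essentially 1.

## Uncertainty in the decay rate

`confint()` bootstraps the rate with a case (pairs) bootstrap: whole
$(day, y)$ observations are resampled with replacement and the model
refitted, and the 95% percentile interval of the refitted rates is
reported (default 1000 resamples, seedable). One design point deserves
a note: resampling replicates *within* each day looks natural for a
designed time course, but with three replicates per day it conditions on
the observed per-day spread and collapses the bootstrap variance — in
simulation its intervals covered the true rate only ~77% of the time,
while the unstratified pairs bootstrap covers at ≈ 0.93 at the same
design (8 days × 3 replicates, lognormal noise σ = 0.2). The package
therefore resamples unstratified. Series containing single-replicate days
fall back to residual resampling and the interval is flagged.

## Scenario-based prediction and censoring

Rates fitted in a measured panel are carried to accessions known only
pre-vernalization under three assumptions of increasing flexibility:
`common` (one grand-mean rate), `paralogue` (per-paralogue means across
accessions) and `extreme` (per paralogue, low-requirement crop types get
the most negative measured rate and high-requirement types the least
negative — the assignment that maximises the separation between the two
groups, and the unique one to do so given that crossing times are
monotone in each rate). Predictions use M1 with the measured
pre-vernalization level as $a$ and no floor. The total is then a sum of
exponentials with no closed-form crossing; `crossing_time_total()`
bisects to $10^{-6}$ d after a monotonicity check (a coarse 0.25 d
forward scan brackets the first down-crossing when some rate is
positive). Predictions are censored at a 365-day horizon and reported as
unbounded (`Inf`) beyond it; swede-type accessions, with slow rates on a
large stable complement, routinely censor.

## What the synthetic generator does and does not emulate

`generate_panel()` draws, per paralogue × timepoint × replicate,
$(a_p e^{b_p x} + c_p)\,e^{\varepsilon}$ with
$\varepsilon \sim N(0, \sigma^2_{\log})$, $\sigma_{\log} = 0.2$ by
default, 3 replicates on the grid $\{0, 7, 14, 21, 28, 42, 56, 84\}$
days — mirroring an up-to-12-week design. Multiplicative lognormal noise
was chosen because expression data are positive and heteroscedastic with
roughly constant coefficient of variation; values below a 0.1 TPM
detection floor are recorded as 0 (quantified-but-absent), as TPM
pipelines emit zeros rather than missing values. The seven default
archetypes encode the crop-type story: a spring reference whose day-0
total *is* the 75 TPM threshold, a second spring below it, a semi-winter
with ≥ 40% of its day-0 total on its fastest-decaying copy, three winter
composition strategies (A: high total, fast-copy heavy; B: low total,
stable heavy; C: high total, stable heavy) and a slow-responding swede.
These are generator conventions shaped like the observed composition
groups, not estimates of any real accession.

The generator does **not** emulate library-size or batch effects,
count-level (negative-binomial) noise at low expression, correlated
replicates, or empirical read-length/error distributions; reads carry
i.i.d. substitution errors only, no indels. Passing tests on this
generator therefore demonstrate correctness of the estimators under the
stated noise model, not robustness to everything real RNA-seq does.

`generate_paralogue_family()` evolves paralogues from a random ancestor
on a star topology with per-branch mutation counts chosen so realised
pairwise identities hit their targets essentially exactly; mutated codons
can be interleaved evenly along the gene, which guarantees a diagnostic
site in every read-length window at the default 98.5% identity / 600 nt
scale. Mutations are synonymous or nonsynonymous according to the
supplied weights; a codon that cannot realise the requested class (Met,
Trp for synonymous) passes its mutation to the nearest untouched codon
that can, so synonymous-only evolution leaves proteins identical by
construction.

## Clustering, read assignment, divergence: numerical choices

* **Clustering** uses Euclidean distance on TPM-scale features (no
  scaling by default, so fixed-height cuts are in TPM units) and average
  linkage (UPGMA); single, complete and Ward are available. The
  documented strategy-separation cut height for the default winter panel
  is `strategy_cut_height()` = 55 TPM: between-strategy centroid
  distances in the default archetypes exceed 70 TPM while within-strategy
  distances under default noise stay near 20. Gene-level features are
  replicate means at each (accession, day); a fitted-curve variant is
  available when measured grids differ.
* **Read assignment** scores each read against every reference on both
  strands with a compiled Smith–Waterman kernel (match +1, mismatch −1,
  gaps −2; a gap of length $L$ costs `gap_open` + $(L-1)$ `gap_extend`;
  `N` matches nothing). Ties within `tie_margin` (default 0, i.e. exact
  ties) are ambiguous; best scores below 0.6 × read length are
  unassigned. Ambiguous reads are excluded from the mis-assignment
  numerator but reported. Exhaustive best-score assignment replaces a
  heuristic aligner, which is feasible against a nine-gene reference set.
* **Divergence** follows Nei–Gojobori (1986) with equal-weight pathway
  averaging and Jukes–Cantor correction. Site counting keeps denominator
  3 at every codon position (changes to stop codons count as
  nonsynonymous), so $S + N = 3 \times$ codons exactly; pathways through
  stop codons are excluded from difference averaging unless every pathway
  is blocked. $dS = 0$ flags ω as undefined rather than dividing by
  zero; $p \ge 3/4$ flags saturation. Neighbour-joining trees come from
  Jukes–Cantor distances on the codon alignment; negative branch lengths
  are clamped to zero and flagged. Bootstrap support resamples whole
  codon columns. Protein alignment uses BLOSUM62 with gap open 10 /
  extend 1 — a conventional default, since "aligner defaults" pin down
  neither matrix nor penalties.

## Problem sizes used in the checks

The shipped test-suite simulations use: 5 series against an exhaustive
$(a, b)$ grid oracle at step $10^{-3}$; 200 series for rate recovery and
500 series × 1000 bootstrap resamples for interval coverage; 1000
null-model and 200 floor-model selections for calibration and power; 50
synthetic diversity panels (20 accessions each) for the scenario-ordering
property plus 250 random predictions for monotonicity; a 12-accession
winter panel for strategy recovery; 2000 simulated reads for the
assignment oracle; and the worked dN/dS example with 4- and 5-taxon
additive trees. These sizes were chosen so each property is measured with
useful precision while the whole suite stays comfortably
laptop-runnable.

## Known limitations

* A single global competence threshold; accession-specific thresholds
  and downstream (post-FLC) effects on flowering are out of scope.
* Monophasic decay only; no hierarchical pooling of rates across
  accessions, which would stabilise poorly-expressed paralogues.
* Arithmetic means pool rates across accessions in the `common` and
  `paralogue` scenarios; pooling on another scale is unexplored.
* The mis-assignment module scores full-length local alignments; it does
  not reproduce any specific aligner's seeding heuristics, spliced
  alignment, or quality-aware scoring.
* dN/dS is the pairwise NG86 estimator; branch-specific codon models and
  selection-intensity tests are out of scope.
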