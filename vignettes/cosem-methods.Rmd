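---
title: "Ribosome traffic, expression scoring, and codon design with cosem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ribosome traffic, expression scoring, and codon design with cosem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`cosem` studies how synonymous codon choice shapes protein output. It has
three layers: a stochastic codon-specific elongation model of ribosome
traffic on one mRNA, an additive statistical score that predicts log protein
abundance from sequence features, and a synonymous-sequence optimizer that
searches codon space for extreme scores. This vignette explains the models,
their assumptions, the tunable constants and their defaults, and the design
choices made where several readings were defensible.

## The traffic model

A transcript is a 1-based lattice of $n$ sense codons. A ribosome is
identified by the codon index $i$ of its A-site and occupies a footprint of
$d$ codons (default $d = 10$), so successive A-sites must differ by at
least $d$. Four elementary events drive the dynamics:

* **initiation** at rate $\alpha$ (1/s), allowed whenever placing an A-site
  at codon 1 keeps all gaps $\ge d$ (i.e. the first $d$ codons are clear);
* **elongation** from codon $i$ at the codon-specific rate $\omega_i$ (1/s);
* **drop-off** at rate $\gamma$ from any codon except the last — the
  ribosome detaches without making a protein;
* **termination** from the last codon at rate $\beta$, which by default
  equals the last codon's elongation rate (slow codons are rarely found at
  the end of a transcript, so termination is taken to proceed at elongation
  speed).

Trajectories are generated with an event-driven (Gillespie) scheme: with
$Q$ the sum of the rates of all *realizable* transitions, the waiting time
is $-\ln u / Q$ and each transition fires with probability (its rate)$/Q$.
A blocked forward step is not a realizable transition and carries zero
rate. We also implement a variant (`move_rule = "paired"`) in which blocked
attempts stay in the event set, set a flag on the blocked ribosome (or the
initiation site), and the flagged follower advances together with its
blocker's next step. The variant is kept for comparison because it is a
plausible literal reading of "two adjacent ribosomes move forward
simultaneously"; measured against the exclusion-process literature it
systematically inflates steady-state currents (e.g. $0.33$ instead of the
exact $1/4$ at the maximal-current point for $d = 1$), because every banked
attempt effectively doubles a queued ribosome's escape rate. All defaults
therefore use the strict-exclusion event set, which reproduces the known
closed forms — low-density current $\alpha(1-\alpha)$ and maximal current
$1/4$ for $d=1$, $\alpha(1-\alpha)/(1+(d-1)\alpha)$ for extended
footprints — within sampling error, as the test suite verifies against an
exact master-equation solution on short lattices.

A second integrator advances time in fixed increments $dt$, firing each
event with probability rate$\times dt$ (processing ribosomes from the 3'
leader backwards). It must satisfy $dt \cdot \max(\text{rate}) \le 0.1$
(warning above $0.01$) and exists purely to cross-validate the event-driven
scheme; the two agree within combined sampling error on random systems.

**Observables.** The current $p$ is completions per second per mRNA during
the measurement window; the density profile is the time-averaged A-site
occupancy per codon (not footprint coverage — the choice matters for
plotting but not for regime identification, and A-site occupancy is the
quantity conserved by our bookkeeping); transit times are recorded from
attachment to release. Exact count conservation (initiations = completions
+ drop-offs + ribosomes still bound) holds over any run and is asserted in
the tests.

**Steady state.** Statistics are collected only after a burn-in, default
$10\,n/\langle\omega\rangle_h$ seconds ($\langle\omega\rangle_h$ the
harmonic mean rate, i.e. ten sequential traversal times); the default
measurement window targets roughly 500 completions at the
initiation-limited current. Both are overridable, and every run takes an
explicit seed.

**Phase structure.** With uniform rates and reduced variables
$\bar\alpha = \alpha/\omega$, $\bar\beta = \beta/\omega$, the model shows
the classic low-density (initiation-limited), high-density (jammed) and
maximal-current regimes; the maximal-current corner sits at
$\bar\alpha^\ast = \bar\beta^\ast = 1/(\sqrt{d}+1) \simeq 0.24$ for
$d = 10$. `phase_diagram()` scans a reduced-rate grid and labels regimes;
`critical_corner()` evaluates the closed form.

**Analytic estimate.** Ignoring exclusion and drop-off, the expected time
to make one protein is $1/\alpha + \sum_i 1/\omega_i + 1/\beta$
(`estimate_synthesis_time()`). In the simulator the step off the last codon
*is* termination, so a single ribosome's attach-to-release time is
$\sum_{i<n} 1/\omega_i + 1/\beta$; the estimate's extra last-codon dwell is
an $O(1/n)$ bookkeeping difference that is invisible next to the
initiation wait, and the tests compare the full cycle (wait + transit)
against the estimate. The estimate is valid only in the initiation-limited
regime — traffic can only lengthen the true time.

**Drop-off.** A per-codon drop-off probability of $3\times10^{-4}$
combined with organism-scale mean elongation rates of roughly 22, 33 and
6 codons/s yields $\gamma \in [0.0018, 0.0099]$ 1/s; the package default
for feature computation is $\gamma = 0.003$ 1/s, inside that window.
Drop-off survival in the single-ribosome regime equals
$\prod_{i<n} \omega_i/(\omega_i+\gamma)$, another closed form the suite
checks by simulation.

## Codon rate tables

Per-codon elongation rates and accuracies (the probability that the
incorporated tRNA is cognate) live in a 61-row table, read and written as
TSV at full double precision. Where no measured table is available,
`synthesize_rate_table()` derives one from a tRNA pool by ternary-complex
competition: $\omega_c = \omega_0\,[c]/([c] + w_\text{near}[n] +
w_\text{non}[o])$ and $a_c = [c]/([c] + w_\text{near}[n])$ with
discrimination weights $w_\text{near} = 0.1$, $w_\text{non} = 0.01$. This
one-line scheme is a deliberate simplification — it captures the
concentration-competition logic without the full kinetic elongation cycle —
and only ratios of concentrations matter. `make_rate_table()` instead
draws independent uniform rates (default range 2–45 1/s, bracketing the
organism-scale means above) and accuracies (0.95–0.9999) so that every
synonym family has spread for the optimizer to exploit.

Terminal stop codons are stripped silently (termination is modeled by
$\beta$, not by a stop-codon rate); internal stops are hard errors; RNA
input (U) is normalized to DNA (T).

## Sequence features

`compute_features()` assembles the ten candidate predictors: simulated
current; arithmetic mean elongation rate (the arithmetic mean is kept as
the headline average because it is less redundant with the current than
the harmonic mean, which is carried alongside); bottleneck index (minimum
10-codon sliding-window mean rate); sequence accuracy $\prod_i a_i$,
computed in log space so it cannot underflow; 5' folding energy and
hairpin count over the first 30 codons (90 nt); log10 transcript
abundance (representable as absent, because designed constructs have no
measured transcript level); GC3 content; ramp index (mean rate over the
first 30 codons — the fixed 30-codon window is the operational choice, the
ramp literature quoting 30–50); and length in codons.

The folding engine is pluggable. The default is an internal deterministic
energy-minimization dynamic program over canonical pairs (GC $-3$, AU
$-2$, GU $-1$ kcal/mol, stacking bonus $-1$ per directly stacked pair,
hairpin loops of at least 3 nt). It is a coarse thermodynamic caricature:
adequate for ranking synonymous variants and for dependency-free testing,
not for quantitative structure prediction. `engine = "vienna"` shells out
to RNAfold when that binary is installed. "Hairpin" is not a standardized
count; we count innermost base pairs supported by stems of at least 3
stacked pairs, a convention stated here because any choice is one.

## The additive expression score

Log protein abundance is modeled as an additive function of the features,
$y = c + \sum_k f_k(x_k) + \varepsilon$, fitted by component-wise
least-squares boosting. Each feature gets one base-learner: a penalized
cubic B-spline (P-spline; 20 interior knots, second-order difference
penalty, ridge weight solved so each smoother has ~4 effective degrees of
freedom), constrained monotone increasing for current, mean elongation
rate and log transcript abundance (effects with a clear mechanistic
direction), and a plain linear effect for the hairpin count. At each
iteration every base-learner is fitted to the current residuals; the
candidate update (learning rate $\nu = 0.1$ times the fit, with the
monotone features' coefficient vectors projected to non-decreasing order
by isotonic regression — non-decreasing B-spline coefficients guarantee a
non-decreasing curve) that most reduces the training loss is committed.
Selecting by post-update loss rather than by raw base-learner RSS makes
the training loss non-increasing by construction even under the projection,
and the path stops early if no candidate improves it. The offset is the
outcome mean; features never selected contribute exactly zero.

The stopping iteration is chosen by 25-fold nonparametric bootstrap:
each replicate refits the path on in-bag rows and tracks out-of-bag
squared error. The default rule takes the *smallest* iteration within one
standard error of the out-of-bag minimum. We deliberately prefer this
parsimony rule to the raw minimizer: the out-of-bag curve is flat to a
fraction of a percent over tens of iterations around its minimum, and
under the raw argmin rule features that are pure noise by construction
entered the model in over half of replicated refits of the synthetic
benchmark, versus none under the one-standard-error rule, at essentially
identical held-out accuracy. `boosting_config(mstop_rule = "min")`
restores the argmin behaviour.

Model quality is reported as explained variance $R^2$ on a 30% hold-out
split made with a recorded seed. Scoring supports per-feature weights
$v_k \ge 0$ (`predict(..., weights =)`): the score becomes
$c + \sum_k v_k \hat f_k(x_k)$, so setting $v_k = 0$ removes a feature —
the standard configuration at design time weights transcript abundance 0
and everything else 1. Feature values outside the training range are
clamped to it (optimized sequences can exceed observed ranges; clamping is
reported via an attribute). A linear approximation with a quadratic GC3
term (`fit_simplified()` / `simplified_score()`) is provided for fast
screening; the quadratic term lets a balanced GC3 content be optimal.

`calibrate_initiation_rate()` recovers $\alpha$ by scanning a grid and
maximizing the correlation between simulated currents and observed protein
levels, with ties resolved toward the smallest rate. The correlation
profile is informative only when the grid straddles the transition from
initiation- to elongation-limited flow — deep in the low-density regime
currents of all genes scale together and the profile is flat, which the
function detects and reports.

## Synonymous sequence optimization

Candidate sequences are drawn position-wise: synonym $l$ at a position is
proposed with probability proportional to
$s_1\,\tilde\omega_l + s_2\,\tilde a_l + \epsilon$, where $\tilde\cdot$
rescales the family's rates and accuracies to $[0,1]$, $s_1 = s_2 = 1$ by
default, and $\epsilon = 0.05$ is the relative weight of the slowest,
least accurate synonym. A family with no kinetic spread reduces to the
uniform distribution (the $0/0$ normalization terms are taken as 0 — the
continuity limit). The first candidates evaluated are the wildtype itself
and the locally optimal sequence (position-wise argmax of the combined
normalized criterion, ties to the alphabetically smallest codon), so under
maximization the reported best is never worse than the wildtype. Frozen
positions (e.g. a slow-codon ramp over codons 1–50) always keep the
wildtype codon, and every candidate is asserted to translate to the
wildtype protein.

The search stops when the coefficient of variation of the running buffer
of the $m = 100$ best scores (values, duplicates allowed; a
most-recent-records variant is available via `buffer = "records"`) falls
below 5%, or at the proposal budget, in which case the result is flagged
non-converged. On an exactly flat landscape — a constant score function —
the buffer fills after $m$ evaluations with zero variance and the search
stops immediately; with any fitted non-constant model the landscape is
never exactly flat, because the current feature is itself a stochastic
simulation output. Score ratios relative to wildtype are guarded against
nonpositive wildtype scores by shifting both scores by $1 - s_\text{wt}$
(recorded in the result) before forming the ratio. A codon adaptation
index utility (`cai()`, geometric mean of usage ratios, single-codon
families excluded) is included purely as a comparison baseline.

## Synthetic fixtures and what they do (and do not) show

`make_benchmark()` generates genes (`make_genes()`: ATG start, random
sense codons, no internal stops), a rate table, log-normal transcript
abundances, runs the *real* feature pipeline, and then simulates outcomes
from a recorded additive truth on standardized features: by default a
saturating monotone effect of the current ($\tanh$) plus a centered
quadratic in GC3, with Gaussian noise scaled so the signal carries 50% of
the outcome variance. Because the partials and noise SD are recorded, the
generative $R^2$ is known exactly and recovery can be tested: held-out
$R^2$ within 0.1 of the generative fraction, monotone partials monotone,
and independent-by-construction features (transcript abundance, length)
selected in fewer than 20% of 50 refits with fresh noise.

The benchmark emulates the statistical structure of expression data —
additive feature effects on log abundance, realistic feature correlations
because the features come from real simulated traffic — but not real
codon-usage statistics, real structure thermodynamics, or measurement
error models of proteomics. Passing these tests therefore demonstrates
that the estimator recovers the structure it assumes, at these sample
sizes, under correlated features; it does not certify organism-scale
predictive power, which depends on external proteome data outside this
package's scope.

## Problem sizes and numerical choices

The test and acceptance workloads use: 300-codon uniform transcripts for
the phase scan (grid of 36 reduced-rate points, 3000 s burn-in, 20000 s
measurement); benchmarks of 60 genes (unit tests) and 2000 genes
(recovery checks) of 60–150 codons with per-gene measurement windows of a
few hundred completions; 25 bootstrap replicates with a path cap of
150–300 iterations; optimizer runs with reduced buffers ($m \le 15$) on
60–150-codon genes. These sizes were chosen so the statistical claims are
testable with comfortable margins on a single CPU. Ties are broken
deterministically everywhere (alphabetically smallest codon; smallest
grid value); all stochastic entry points take explicit integer seeds and
regenerate bit-identically.

## Known limitations

The traffic model omits tRNA recycling, density-dependent drop-off, and
bottleneck-induced mixed phases; initiation is a single rate with no
sequence dependence (no ribosome-binding-site model); the internal folding
engine is deliberately crude; the boosting implementation provides no
confidence bands for partial functions; and the optimizer searches by
independent position-wise resampling, which is blind to joint constraints
such as restriction sites or codon-pair effects.
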