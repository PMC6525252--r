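# cosem

Ribosome traffic simulation, protein-expression scoring, and synonymous
codon optimization in R.

Synonymous codons are decoded at very different speeds and accuracies, so
two sequences encoding the same protein can yield very different amounts
of it. `cosem` is for researchers who want to reason about that
quantitatively: it simulates ribosome traffic along a coding sequence with
codon-specific kinetics, condenses sequences into predictive features,
fits an additive statistical score for log protein abundance, and searches
synonymous sequence space for variants with extreme predicted expression
(maximization for yield, minimization for attenuation).

## The models in brief

**Traffic model.** Ribosomes with a footprint of *d* codons (default 10)
initiate at rate α when the first *d* codons are clear, advance from codon
*i* at its elongation rate ω*ᵢ* under mutual exclusion (A-sites ≥ *d*
apart), drop off at rate γ from any codon but the last, and terminate from
the last codon at rate β (default: the last codon's ω). Dynamics are
integrated with an event-driven Gillespie scheme (a fixed-increment
integrator cross-validates it). The steady-state current *p* — proteins
per second per mRNA — is the model's headline output. With uniform rates
the model reproduces the classic exclusion-process phase diagram: low
density, high density, and a maximal-current regime whose corner sits at
reduced rates 1/(√d + 1) ≈ 0.24 for d = 10.

**Expression score.** Log protein abundance is modeled as
ŷ = c + Σₖ f̂ₖ(xₖ) over ten sequence features (simulated current, mean
elongation rate, bottleneck index, decoding accuracy, 5′ folding energy,
log transcript abundance, GC3, ramp index, hairpin count, length), fitted
by component-wise boosting with monotone P-spline base-learners and
bootstrap early stopping. A weighted variant Σₖ vₖ f̂ₖ(xₖ) lets the
optimizer ignore features (e.g. transcript abundance, unknown for a
designed construct).

**Optimizer.** Synonymous variants are proposed position-wise with
probability ∝ s₁·norm(ω) + s₂·norm(a) + ε (defaults s₁ = s₂ = 1,
ε = 0.05), scored, and retained when they beat the best so far; the search
stops when the coefficient of variation of the top-*m* scores falls below
5% (default m = 100).

Everything runs on synthetic fixtures — rate tables, toy genes, benchmark
datasets with known additive ground truth — so no external data are
needed.

## Worked example

```r
library(cosem)

tb  <- make_rate_table(1)                 # synthetic 61-codon rate table
gene <- make_genes(2, 1, c(60, 80))[[1]]  # one toy CDS

prof <- sequence_profiles(gene, tb)
sys  <- translation_system(prof$rates, init_rate = 0.1, dropoff_rate = 0.003)
simulate(sys, seed = 5)
#> Ribosome traffic simulation (gillespie): 80 codons
#>   current p = 0.0908 proteins/(s*mRNA)  [454 completions / 5000 s]
#>   average A-site density 0.0048732, drop-offs 7
#>   mean transit of completed proteins: 4.2622 s (n = 454)

critical_corner(10)
#> [1] 0.2402531
```

The current (~0.091 proteins/s per mRNA) is just below the initiation rate
α = 0.1: traffic is initiation-limited, with a small loss to drop-off.
Fitting and using the expression score on a synthetic benchmark with a
known 50% explainable variance:

```r
b <- make_benchmark(1, n = 2000)          # real features, known truth
d <- b$data[, setdiff(names(b$data), c("id", "harmonic_rate"))]
m <- expression_score(y ~ ., d, seed = 2)
m
#> Additive protein expression score (component-wise P-spline boosting)
#>   10 candidate features, 44 boosting iterations (step 0.1)
#>   selected: current, gc3
#>   held-out R^2 = 0.532 (on 600 observations)

opt <- optimize_codons(b$genes[[1]], b$table, m,
                       m = 15, max_proposals = 60, seed = 9, measure = 400)
opt
#> Synonymous sequence optimization (maximize): 60 proposals, proposal budget reached
#>   wildtype score 1.47 -> best 3.3051 (relative 2.248)
```

The fitted score recovers the generative signal (held-out R² ≈ 0.53
against a true 0.50), and the optimizer finds a synonymous variant scoring
2.2× the wildtype while preserving the protein exactly.

A thin CLI wrapping these functions is installed at
`system.file("cli", "cosem", package = "cosem")` with subcommands
`simulate`, `phase-diagram`, `features`, `fit`, `score`, `optimize`,
`make-fixtures` and `pipeline`.

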