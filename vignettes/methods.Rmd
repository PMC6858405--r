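---
title: "Models and methods behind accumrate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind accumrate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The question

Bacteria sampled repeatedly from nature over months to centuries accumulate
substitutions at wildly different per-year rates — the two published
extremes, *Campylobacter jejuni* (3.23e-5 substitutions/site/year) and
*Mycobacterium leprae* (8.6e-9), differ by more than 3700-fold. This
**accumulation rate** sits between the mutation rate (per generation) and
the long-term substitution rate: it reflects mutations that arose recently
and have not yet been fully filtered by purifying selection. `accumrate`
implements the two halves of an analysis of why it varies: a
population-genetic model of how selection depresses the rate as the
sampling window lengthens, and a phylogenetic-comparative analysis of which
species traits predict it.

# The Wright–Fisher transition-matrix model

A new deleterious mutation (wild-type fitness 1, mutant `1 - s`) enters a
haploid population of `N` chromosomes as a single copy. Each generation,
its frequency `f` moves deterministically to `f' = (1 - s) f / (1 - s f)`
(selection) and the next generation's copy count is binomial around `f'`
(drift). Tracking the full probability vector over copy counts `0..N`
through an `(N+1) x (N+1)` column-stochastic matrix gives the exact
distribution at every generation; loss (0) and fixation (`N`) are retained
as absorbing classes. This retention matters: the printed recursion one
could naively implement sums only segregating classes, which leaks the
fixed mass that permanently contributes to divergence and breaks
probability conservation — our implementation conserves total probability
to better than 1e-12 over 4N generations (it is a checked invariant, not a
renormalisation).

The chance that a lineage sampled `t` generations after the mutation's
introduction differs from the ancestor is
`D(N, s, t) = sum_{v=1..t} sum_x P(N, x, s, v) x / N`, where generation
`v = 1` is the introduction itself (contributing exactly `1/N`). Under
neutrality the mean frequency is a martingale, so `D(N, 0, t) = t / N`
exactly; the **relative accumulation rate** is `A = D(N, s, t) / D(N, 0, t)`,
equal to 1 for neutral mutations and declining with `t` when `s > 0`.

Not all mutations feel the same selection, so `A` is averaged over 100
selection coefficients drawn from a gamma distribution of fitness effects
with shape 0.25–0.75 and mean `N s` of 10–1000 (shape/scale
parameterisation, scale = `mean_Ns / (shape N)`). Draws at or above `s = 1`
are impossible fitnesses; they are capped at `1 - 1e-6` (effectively
lethal), with a warning when more than half a sample is capped — at
`mean_Ns = 1000` and `N = 100` most draws are lethal, which is exactly the
regime where the curve drops fastest. The curves are computed with
`N = 100` over 0–4N generations and `N = 1000` over the first 0.1N, on a
geometric time grid reported in units of `N`.

**Scaling.** The model's dynamics depend on `(N s, t / N)`: `A(N, s, t) =
A(zN, s / z, z t)`, the classic diffusion scaling, which our implementation
satisfies to about 2e-3 on the grid we test. A tempting simpler identity —
rescaling time alone at fixed `s` — does *not* hold (we measured deviations
up to 0.19), which is why the scaling test in this package holds `N s` and
`t / N` fixed jointly. An independent forward simulator
(`monte_carlo_divergence`), sharing no code with the matrix recursion,
agrees with `expected_divergence` within Monte-Carlo error and serves as
the oracle in the test suite.

The scientific upshot, visible in `analysis/04_wf_model.R`'s output: over
the first 0.1N generations the DFE curves barely separate, so detecting a
sampling-time effect empirically requires both very short and very long
sampling windows.

# Data curation

Literature-style rate tables carry one row per estimate. Three rules
curate them, each with an audit trail: estimates sampled over more than
1500 years are excluded (the cutoff is inclusive); estimates reported only
for synonymous sites are excluded (most estimates cover all sites);
hypermutator strains are excluded. Replicate estimates for a species are
averaged as the arithmetic mean of raw rates — the simplest reading of
"the average"; a geometric-mean option exists because the choice is not
forced, and the difference never alters any qualitative conclusion at the
noise levels we simulate. All analyses use log10 rates, since the rates
span orders of magnitude (the base only rescales regression coefficients,
never correlations).

# piN/piS

The effectiveness of purifying selection is proxied by the ratio of
nucleotide diversity at nonsynonymous and synonymous sites. We count sites
and differences by the Nei–Gojobori (1986) proportion method: each codon
position contributes the fraction of its three possible changes that are
synonymous; multi-hit codon pairs average over all mutational pathways,
excluding pathways through stop codons unless every pathway is blocked.
Mutations *to* stop codons count as nonsynonymous in site counting.
Diversities are averaged over all unordered sequence pairs, skipping
gapped or ambiguous codons pairwise; no multiple-hit correction is applied
because within-species bacterial diversity is small (a Jukes–Cantor
correction would change the third decimal at the diversities simulated
here). When `piS = 0` the ratio is reported as undefined, never as 0.

# Phylogenetic comparative methods

Independent contrasts follow Felsenstein's pruning recursion (via
`ape::pic`): standardized differences at each internal node, each with an
expected SD equal to the square root of the summed, recursion-adjusted
branch lengths. Contrast-based correlations are computed through the
origin with `n - 1` degrees of freedom. Contrasts with expected SD below
0.21 can be filtered: a contrast between near-identical relatives is
dominated by trait measurement error, and 0.21 is the package default
(interpreting "standard deviation of a comparison" as the contrast's
expected SD, the natural quantity attached to one).

Pagel's lambda multiplies the off-diagonal Brownian covariance; we profile
out the ancestral mean and rate analytically and maximise the remaining
1-D likelihood on `[0, 1]` by Brent search (tolerance 1e-6, endpoints
checked explicitly; boundary ties are reported at the boundary).
Significance is a 1-df likelihood-ratio test against `lambda = 0`.
Blomberg's K is the observed-to-GLS mean-squared-error ratio normalised by
its Brownian expectation; its permutation p-value shuffles tip values
(999 permutations by default, seeded) and asks how often the variance of
contrasts is as small as observed. Both agree with the reference
implementation in `phytools::phylosig` to numerical precision on trees
where its unconstrained optimum lies inside `[0, 1]`; we constrain lambda
to `[0, 1]` because values above 1 have no interpretation in this analysis.
Polytomies are resolved arbitrarily with zero-length branches and flagged.

Lifestyle comparisons control phylogeny through sister pairs: the disjoint
cherries of the tree whose two tips carry different labels, fed into a
paired t-test. Unpaired group comparisons use Welch's correction since
equal variances are not defensible a priori; all tests are two-sided.

# Classical statistics

Correlations are Pearson with the standard t-test; the common-slope ANCOVA
fits `y ~ group + x` and reads the shared slope, dropping single-point
groups with a warning; the multiple regression z-scores response and
predictors and reports standardized coefficients (rank deficiency is an
error naming the collinear columns). The power analysis is the closed-form
Fisher-z calculation: with 34 species, alpha = 0.05 two-sided and 95%
power, the smallest detectable true correlation is 0.570. A published
figure of 0.51 for the same setting is not reproducible from this formula
under any combination we consider standard (one-sided alpha gives 0.531);
we report the formula's value and note the discrepancy rather than guess
at unstated assumptions.

# The synthetic-data generator

Real inputs are literature-curated tables that cannot be bundled, so the
generator produces structurally faithful stand-ins: a Yule tree
(`ape::rphylo`, depth rescaled to 1), multivariate-normal traits whose
among-tip covariance is the lambda-transformed Brownian matrix and whose
among-trait correlations default to the magnitudes the comparative
analysis targets (e.g. log-rate vs GC -0.50, genome size vs log mutation
rate -0.68), mapped onto realistic scales (rates ~1e-6/site/year spanning
a few hundred fold, genomes of a few Mb, GC 20–75%, piN/piS ~0.1);
replicate rate estimates per species (1–4, log-uniform sampling times over
1–1500 years, 0.3 log10 units of estimate noise, and a configurable
injected sampling-time slope, default 0); and biallelic codon alignments
whose expected piN/piS equals the injected omega. Every generator takes an
explicit seed and restores the caller's RNG state.

What the generator does *not* emulate: substitution-model sequence
evolution down the tree, rate heterogeneity among sites, correlated
estimate errors within studies, non-Brownian trait evolution, or the
heavy-tailed empirical distribution of real rate estimates. Passing tests
therefore demonstrate that the pipeline recovers known structure from data
obeying its own assumptions — not that the published numbers would be
reproduced from the original curated tables, which is exactly why the one
test that needs those tables reports their absence rather than
substituting synthetic values.

# Problem sizes and numerical choices

The test suite uses `N` of 10–200 for exact checks, 20,000 Monte-Carlo
replicates for the oracle comparison (3-SE agreement), 50 replicates for
lambda/K recovery on 100-tip trees, and 500 simulations for null-
uniformity (Kolmogorov–Smirnov at alpha = 0.01); the analysis scripts run
the fine-grained `N = 1000` model. These sizes make every stochastic check
stable across seeds while keeping a full run to a few minutes. Ties,
degenerate inputs and edge cases are handled explicitly: zero-length
sibling branches yield infinite contrasts unless the trait values agree;
paired t-tests on identical vectors return `t = 0, p = 1` rather than an
error; `filter_estimates` on an empty table returns an empty table.

# Known limitations

The model excludes beneficial mutations, recurrent mutation, and
recombination, and the DFE is purely deleterious — all deliberate scope
choices. Lambda above 1 is not considered. The ANCOVA assumes parallel
slopes; no phylogenetic GLS regression is offered beyond the
PIC-equivalence used in testing. Real supplementary tables, where
available, can be dropped into `inst/extdata/supplementary/` to run the
published-value comparison in the acceptance suite.
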