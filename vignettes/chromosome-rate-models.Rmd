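---
title: "Modelling trait-dependent chromosome-number evolution with karyorate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling trait-dependent chromosome-number evolution with karyorate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyorate)
```

## The question and the model

Chromosomal fusions and fissions are commonly underdominant: heterozygotes
for a rearrangement suffer meiotic problems, so new karyotypes should fix
mainly by drift in small populations. If that is so, lineages carrying
traits that shrink effective population size — winglessness is the
archetype in beetles, since flight dominates dispersal — should show
*faster* chromosome-number evolution. karyorate implements the machinery
to test this on phylogenies.

The state of a lineage is the pair (haploid autosome count $i$, binary
trait $s$). Three moves change the count:

* **fission** ($\gamma_s$): $i \to i + 1$,
* **fusion** ($\delta_s$): $i \to i - 1$,
* **whole-genome duplication** ($\rho_s$): $i \to 2i$,

each with a rate that may depend on the trait state, plus the trait
transition itself ($q_{\mathrm{winged}\to\mathrm{wingless}}$; the reverse
rate is zero by default, since wing regain has essentially no biological
support, but can be freed with `trait_reversible = TRUE`). All rates are
count-independent. `build_q_matrix()` assembles the generator over the
finite state space; `transition_probabilities()` exponentiates it.

Two reduced models serve clade-level analyses where no trait is modelled:
`clade_2p` (fission + fusion) and `clade_3p` (fission + fusion + WGD).

### The state space and its boundaries

The state space spans `min_count:max_count`, by default from one below the
smallest observed count to twice the largest (capped at 50), so at least
one fusion below and one duplication above the data are representable.
Moves whose target leaves the space are **dropped**: their rate simply
does not appear in the exit rate of the state. The alternative — piling
the probability onto the boundary state — creates artificial mass at
`max_count`; dropping is cleaner but means the boundary slightly *slows*
the process for states near it, so widen the bounds if your counts crowd
them. The stochastic simulator removes the same moves from its exit
rates, so simulation and likelihood describe the identical bounded
process.

## Likelihood

`prune_log_likelihood()` is Felsenstein pruning with per-branch
$e^{Qt}$ and rescaled partials. Tip observations are probability vectors:
a species with count $c$ and winglessness probability $p$ puts mass $p$
on $(c, \text{wingless})$ and $1-p$ on $(c, \text{winged})$. Species
reported wing-polymorphic get $p = 0.5$; species without wing data get a
genus-level imputed $p$ (`impute_wing_probability()`), e.g. 0.64 when 16
of 25 scored congeners are wingless.

The root partials $d_r$ are combined with weights proportional to the
partials themselves by default (`obs_weighted`, $\sum_r d_r^2 / \sum_r
d_r$), matching the common default of Bayesian comparative frameworks; a
flat mean over states and a fixed root state are available. For
parameter-recovery experiments on simulated data either default works —
the choice moved posterior means by far less than their Monte Carlo
spread in our checks.

Species present in a tree but absent from the karyotype table are pruned
with a warning before fitting; we prefer discarding to guessing a count
distribution for them.

### Numerics

Each likelihood call eigendecomposes $Q$ once and propagates partial
vectors as $V e^{\Lambda t} V^{-1} x$ — two matrix–vector products per
branch. The decomposition is accepted only if it reconstructs $Q$ to
about $10^{-12}$ relative error; eigenvector conditioning degrades on
large spaces, and in that case branch propagation falls back to
uniformization (the Poisson-weighted series with $P = I + Q/\Lambda$,
truncated at $10^{-13}$), which is unconditionally stable for branch-scale
$\Lambda t$. Full transition matrices fall back to `Matrix::expm`.
Zero-length branches use the identity map. Results are independent of the
path taken to about $10^{-11}$; the test suite pins the pruning
likelihood against brute-force enumeration over interior-node states at
$10^{-10}$ on small instances.

## Bayesian fitting

`run_mcmc()` updates each free parameter per generation with a univariate
slice sampler (step-out and shrinkage, width 1) on the log posterior.
Defaults follow the sampling protocol the package is built around:

* initial values drawn uniformly from $(0, 10)$, redrawn up to 100 times
  if the posterior is not finite (a state space too narrow for the data
  is reported as such);
* independent exponential priors with **rate 2** (mean 0.5) on every free
  rate, on the unit-tree scale. The conventional phrase "exponential
  prior with shape parameter 2" is ambiguous between rate 2 and mean 2;
  we take rate 2, the parameterisation the common R fitting frameworks
  use, and expose `prior_rate` so the other reading is one argument away;
* 200 generations per tree, the first 100 discarded as burnin;
* trees rescaled to **unit root-to-tip depth** before fitting. "Unit
  length" could also mean unit *total* branch length; both are
  implemented (`tree_scale`), unit depth is the default. Either way the
  trace records every rate both on the fitting scale and divided by the
  tree's own depth in My, and by the CTMC rescaling identity a fit on the
  unit tree rescaled afterwards is the same posterior as a fit in My
  directly (the acceptance suite verifies the chains agree to $10^{-6}$
  when prior, initialisation and slice width are transformed together).

`multi_tree_posterior()` replicates the fit over a posterior tree set:
per tree it draws one count uniformly for every multi-count species
(tip-state uncertainty), runs a chain seeded `seed + tree index`, drops
burnin, and pools. With 100 trees the pooled posterior holds exactly
10,000 samples. Convergence is not auto-assessed — chains in this regime
converge within tens of generations, but the per-tree traces are returned
so any standard diagnostic can be applied.

## Posterior summaries

`delta_r()` reports $\Delta R_x = x_{\mathrm{wingless}} -
x_{\mathrm{winged}}$ per posterior sample (per-My scale) with its mean,
central 95% credible interval and the fraction of negative samples. An
interval entirely above zero supports faster rates in wingless lineages.
`clade_mean_rate()` averages the free chromosome rates within each
generation, then summarises those means. Credible intervals are central
quantile intervals (type-7 interpolation) — reproducible without density
estimation; a shortest-interval HPD variant is available via
`method = "hpd"`. For the three-parameter clade model the mean is over
$\{\gamma, \delta, \rho\}$ including a zero $\rho$; for the
two-parameter model over $\{\gamma, \delta\}$.

## The fossil-scaled comparator

`coefficient_of_variation()` (sample SD over mean — the $n-1$ estimator
matters at clade sizes of a few dozen records) divided by the clade's
oldest fossil age (`scaled_cv()`) is the classical phylogeny-free rate
proxy. `kendall_tau()` correlates it with model-based rates. The bundled
`clade_cv_fossil.csv` carries literature CVs, fossil ages and model-based
mean rates (the rate and SCV columns multiplied by 100 for presentation)
for nine beetle clades; note that published versions of such tables can
contain internal inconsistencies between CV, age and the printed scaled
values, so the package always recomputes SCV from CV and age rather than
trusting a printed column. On synthetic clades with heterogeneous ages
the scaled CV decorrelates from the true rate while the model-based
estimate tracks it — the age denominator is simply unrelated to the
process when lineage spans and fossil ages diverge.

## What the synthetic generator does and does not emulate

`make_synthetic_study()` produces: a Yule tree (2 to ~150 tips) scaled to
a chosen depth (default 200 My, a plausible family-level age); a set of
pseudo-posterior replicates made by lognormal branch noise (log-sd 0.05)
followed by an exact proportional re-ultrametrisation (node heights
scaled by target over deepest-descendant depth — monotone, so branch
lengths stay positive); counts and wing states simulated by exact
Gillespie along each branch from a winged root with 15 autosomes within
bounds 1–35; conflicting second count reports for 10% of tips (true count
plus a neighbour — literature conflicts are typically off-by-one); and
genus-imputed wing probabilities for 25% of tips, via pseudo-genera of 8
tips each. Defaults were chosen once to mirror a family-level beetle
analysis (about a hundred usable species, 100 trees, counts centred in
the low teens, a third to half of tips wingless over the tree).

It does **not** emulate: extinction (pure-birth trees only), topological
uncertainty across the tree set (branch lengths vary, topology does not),
phylogenetically clustered genera (pseudo-genera are tip-index blocks, so
imputation mixes states more than real congeners would), count-dependent
rates, or sex-chromosome–autosome fusions. Passing tests therefore show
the estimator machinery is correct and calibrated under the model's own
assumptions, not that real beetle data satisfy those assumptions.

## Problem sizes used by the checks

The automated checks run, on one CPU, at sizes chosen to finish in
minutes while still being informative: likelihood-vs-enumeration on 50
random instances of up to 3 tips and 8 states; 20,000 single-branch
Gillespie replicates against a transition-probability row; 5,000-generation
prior-recovery chains; a 150-tip, 20-tree parameter-recovery experiment
(fission 2, fusion 1 on the unit-depth scale — both recovered within 35%
and inside the pooled 95% intervals); a 50-tip, 8-tree trait-independent
null showing every $\Delta R$ interval spans zero; and the exact
10,000-sample protocol arithmetic. A one-draw caveat: a single simulated
dataset can land in the tail — during development one 150-tip draw
produced tip scatter so smooth that the fission/fusion split was
essentially unidentified and the posterior hugged the prior; across
systematic replicate seeds the recovery check succeeded in every run.
The fission/fusion *split* (as opposed to the total rate) is genuinely
weakly identified when counts sit mid-space and the root is free, which
is why recovery experiments at these sizes need the full 150 tips.

## Known limitations

* Rates are count-independent; demi-duplication and arm-number evolution
  are out of scope.
* The slice sampler is serial per parameter; posteriors with strong
  ridges (e.g. fission vs fusion on uninformative data) mix slowly —
  lengthen chains or reparameterise externally if diagnostics demand it.
* `obs_weighted` root handling is a pragmatic default, not a subjective
  prior; for explicit root beliefs use `root_mode = "fixed"` or `"flat"`.
* The Newick reader expects one tree per line of the standard dialect;
  NEXUS and annotated formats should be converted upstream.
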