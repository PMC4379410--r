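---
title: "Models and methods behind coalcodon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind coalcodon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

coalcodon jointly estimates three population-genetic parameters from a
protein-coding multiple sequence alignment by approximate Bayesian
computation (ABC):

* the population-scaled recombination rate $\rho = 4Nrl$ ($N$ effective
  population size, $r$ recombination rate per nucleotide, $l$ alignment
  length in nucleotides),
* the scaled codon substitution rate $\theta = 4N\mu L$ ($\mu$
  substitution rate per codon, $L$ number of codons), and
* the nonsynonymous/synonymous rate ratio $\omega$.

Recombination biases phylogeny-based estimates of $\omega$, so the three
parameters are estimated jointly: the likelihood of a recombining coding
alignment is intractable, but simulating such alignments is cheap, which
is exactly the regime in which ABC shines.  This vignette records the
models, the frozen numerical conventions and the design choices made
where a published specification of the method was silent.

## The coalescent-with-recombination simulator

Genealogies are simulated backward in time under the neutral
constant-size coalescent with recombination (Hudson's scaling): time is
measured in units of $2N$ generations, each pair of active lineages
coalesces at rate 1, and a lineage whose ancestral material spans the
whole alignment recombines at rate $\rho/2$.  Breakpoints land on
nucleotide boundaries drawn uniformly over the lineage's
*recombinationally active span* — the interval between its leftmost and
rightmost ancestral material that has not yet reached a marginal MRCA.
Proposals in completely non-ancestral flanks therefore never occur,
which is equivalent to proposing over the whole sequence and rejecting
flank hits; material "trapped" between ancestral blocks remains
breakable.  Expected event counts under the alternative convention
(tracking fully non-ancestral flanks too) differ; only
convention-independent quantities (marginal tree distributions, numbers
of distinct marginal trees) are asserted in the tests.

Because breakpoints are nucleotide boundaries, not codon boundaries,
intracodon breakpoints arise naturally.  Each lineage carries an
interval set of ancestral segments with per-segment descendant counts; a
segment whose count reaches the sample size has found its most recent
common ancestor and is recorded together with its marginal tree.  The
backward process continues until a *single* lineage remains (not merely
until every position has coalesced) so that the recorded event graph is
connected; the extra trunk above the last marginal MRCA only
re-randomizes root states, which is immaterial because sequences start
from the stationary distribution.  Marginal trees are exactly
ultrametric by construction and segments follow the half-open 0-based
convention $[a, b)$: a breakpoint at $b$ separates position $b-1$ from
position $b$.

## GY94 codon evolution

Sequences evolve under the GY94 codon model over the 61 sense codons of
the universal genetic code (mutations into stop codons are structurally
impossible).  For codons $i \ne j$ differing at exactly one nucleotide,

$$q_{ij} \propto \pi_j\,\kappa^{[\text{transition}]}\,
\omega^{[\text{nonsynonymous}]},$$

zero otherwise, with the matrix normalized so that
$-\sum_i \pi_i q_{ii} = 1$ expected substitution per codon per unit
branch length.  The transition/transversion parameter is interpreted as
the HKY-style rate ratio $\kappa$ (not the realized ts/tv count ratio).
A codon site's event rate along a branch of coalescent length $t$ is
$\theta/(2L) \times$ site-rate $\times\,|q_{ii}|$: with two sequences
the expected path length is $2\,E[T_2] = 2$, giving $\theta/L$ expected
substitutions per codon site between a random pair, the defining
calibration of $\theta = 4N\mu L$.

Among-site rate variation uses *continuous* gamma draws with mean 1 (one
multiplier per codon site), not the 4-category discretization common in
likelihood software — a simulator can afford exactness.  A proportion
$p_\text{inv}$ of sites is invariable (multiplier 0) and variable-site
multipliers are divided by $1 - p_\text{inv}$, so the expected
multiplier is exactly 1 without empirical renormalization.  Rate
variation applies per codon site, not per nucleotide site.

Simulation is by Gillespie's algorithm (exact event-by-event CTMC
sampling) rather than transition-probability sampling.  This is fast on
coalescent trees, whose many short branches make matrix exponentials
wasteful, and it keeps the matrix exponential available as an
*independent* test oracle: the test suite checks empirical two-taxon
transition frequencies from 50,000 Gillespie runs against
`ape::matexpo(Q t)` and finds them in agreement within Monte-Carlo
error.

### Intracodon breakpoints

When a breakpoint splits a codon, the two fragments descend along
different marginal trees while GY94 rates still depend on the whole
codon.  coalcodon resolves this without approximation by evolving
*complete sequences forward over the recombination graph*: the backward
event list is replayed in reverse, every lineage carries a full codon
sequence, a coalescence hands identical copies to both descendants, and
a recombination splices the two parental sequences at the breakpoint.
Each nucleotide thus follows its own marginal tree and every
substitution rate is conditional on the current states of its partner
nucleotides, at the cost of also evolving trunk lineages.  One edge case
has no canonical convention: splicing two sense half-codons can yield a
stop codon at the junction; the junction codon is then inherited whole
from the left parent.  This affects at most one codon per recombination
event and no detectable marginal bias has been observed.  A simpler
diagnostic mode (`intracodon = "first_position"`) assigns each whole
codon the marginal tree of its first nucleotide.

## The 26 summary statistics

The summary vector concatenates, in a frozen, named order:

1. three recombination tests — PHI, NSS, MaxChi (3);
2. mean, SD, skewness and excess kurtosis of pairwise diversity at the
   codon and amino-acid levels (8);
3. the same four moments of per-site expected heterozygosity at both
   levels, with the $n/(n-1)$ small-sample correction (8);
4. segregating-site counts at the nucleotide, codon and amino-acid
   levels (3);
5. four joint codon/amino-acid statistics: the amino-acid/codon mean
   pairwise-diversity ratio, counts of codon sites with synonymous-only
   and with amino-acid-level variation, and the amino-acid/codon
   segregating-site ratio (4).

The recombination tests are returned as *raw statistics*, not
permutation p-values: ABC needs informative continuous summaries, and
permutation p-values are costly and discretized.  Site-pair
incompatibility is measured as the cycle rank $e - v + c$ of the
partition intersection graph over observed joint states, which equals
the minimum number of extra (homoplastic) changes needed to fit both
sites on one tree; the test suite verifies this against exhaustive
parsimony over all 105 six-taxon topologies.  PHI averages the score
over informative-site pairs within 100 nucleotides (the published
default window); NSS is the fraction of *adjacent* informative-site
pairs that are compatible; MaxChi places candidate breakpoints between
consecutive polymorphic columns of the alignment and, for every
sequence pair, contrasts that pair's differences vs identities in
windows of 30 polymorphic sites per side (truncated at the ends) with a
$2 \times 2$ chi-squared, reporting the maximum over pairs and
breakpoints.  Any
statistic undefined on an input (no informative sites, zero
denominator) is the sentinel 0, never `NaN`, so every simulation yields
a usable distance.  Gaps and ambiguities in observed data are handled
by pairwise deletion, and a codon containing any non-ACGT symbol is
treated as missing for that sequence at the codon and amino-acid
levels; simulated data are always clean, so these conventions only
affect the observed vector.

## The ABC engine

Summary columns are centered by their median and scaled by their median
absolute deviation over the reference table — robust to the heavy right
tail of MaxChi — with constant columns given scale 1.  The distance is
the Euclidean norm of standardized differences.  Rejection keeps the
$m = \max(1, \mathrm{round}(\text{tolerance} \times S))$ closest
simulations (ties broken by row order) with Epanechnikov weights
$w_i = 1 - (d_i/d_{\max})^2$.

Local-linear adjustment regresses each (transformed) parameter on the
standardized accepted summaries by weighted least squares and projects
every accepted draw to the observed point, `fitted(observed) +
residual`.  Two numerical choices matter:

* **Logit transform through the prior bounds.**  The priors are bounded
  uniforms, and mapping through the prior interval is the only choice
  that guarantees adjusted draws stay inside the prior support (asserted
  on every run).  Values are clamped $10^{-8}$ inside the bounds before
  transforming.
* **Residual-spread restoration.**  Fitting $q + 1$ coefficients to $m$
  weighted points removes part of the conditional spread, which makes
  raw local-linear credible intervals anti-conservative.  Residuals are
  therefore inflated by the usual least-squares degrees-of-freedom
  factor $\sqrt{m_\mathrm{eff}/(m_\mathrm{eff} - p)}$ computed on the
  Kish effective sample size $m_\mathrm{eff} = (\sum w)^2 / \sum w^2$
  and the weighted design rank $p$.  With this correction the
  prior-predictive coverage of the 95% intervals sits near nominal
  (rejection-only intervals are calibrated without it); without it,
  coverage drops several points below nominal at desk-scale table
  sizes.  This residual inflation is part of the package's adjustment
  contract and is exercised by the hand-computed weighted-least-squares
  test.

The optional heteroscedasticity correction fits a second weighted
regression of $\log|\text{residual}|$ on the same design and rescales
each residual by $\exp(\widehat{\ell}(s_\text{obs}) -
\widehat{\ell}(s_i))$, clamped to $e^{\pm 3}$; it is tested by its
variance behavior on a synthetic model with spread increasing in the
summary, not by equivalence to any external package.  Constant summary
columns are dropped from the design (with a warning) but kept in the
distance; a singular design is handled by zeroing unidentifiable
coefficients.  With fewer than $3\times$(summaries used) accepted
points the engine warns and falls back to rejection.

Posterior point estimates are the argmax of a weighted Gaussian kernel
density (Silverman bandwidth, 512-point grid over the prior range,
clipped to the bounds); 95% credible intervals are interpolated
(midpoint-rule) weighted 0.025/0.975 quantiles.  When all draws
coincide the mode and both interval ends equal that value.

## Pipeline conventions

Alignment dimensions for every simulation are copied from the observed
data: the summaries are dimension-sensitive, so simulated and observed
data must match exactly.  Nuisance parameters ($\kappa$ or GTR-style
exchangeabilities, codon-frequency scheme, gamma shape, invariable-site
proportion) are sampled from their priors or held fixed, recorded in the
reference table, and never estimated.  The default codon-frequency
scheme is equal frequencies, with fixed vectors and symmetric Dirichlet
draws available.

Reproducibility is by construction: one root seed expands into
per-simulation child seeds indexed by simulation number, so serial and
parallel runs produce identical tables row for row, and tables built
from disjoint seed ranges concatenate into valid larger tables.  A
failing simulation is retried once with a fresh child seed, then
excluded; more than 1% failures aborts the run.  Either an acceptance
*rate* (`tolerance`) or an acceptance *count* (`n_accept`) may be given,
since published advice mixes both conventions.

## What the synthetic-data generator does and does not emulate

The generator *is* the model: neutral constant-size haploid coalescent,
a single panmictic population, GY94 with optional gamma/invariant-site
rate variation, clean alignments.  Real data violate several of these
assumptions — demographic change, population structure, selection at
linked sites, sequencing error, gaps — so passing the recovery and
calibration suites demonstrates internal consistency of the estimator
under its own model, not robustness to misspecification.  The
prior-predictive envelope diagnostic (warning when the observed summary
leaves the central 99% of the table for more than 8 of 26 statistics) is
the first defense against applying the tool far outside its model.

## Problem sizes used by the validation suites

The package's own validation replays the benchmark factorial design
(alignments of 15 sequences $\times$ 300 codons, $N = 1000$,
$\kappa = 0.5$; $\rho \in \{10, 30\}$, $\omega \in \{0.5, 1.5\}$,
$\theta \in \{100, 200\}$; priors $\rho \sim U(0,50)$,
$\theta \sim U(0,300)$, $\omega \sim U(0,2)$; logit regression on 100
accepted points) in scaled-down form: 10 pseudo-observed datasets at the
low cell against fresh 3,000-simulation tables, reporting the median
posterior mode per parameter.  These sizes give stable medians while
keeping a desk-scale runtime; recombination is the weakest-identified
parameter, so its replicate-to-replicate spread is the widest, which the
wide pass band for $\rho$ reflects.

Coverage calibration uses the standard shared-table cross-validation
design: one 1,500-simulation reference table (10 sequences $\times$ 100
codons) plus 200 independent prior-predictive pseudo-observed datasets,
each estimated with 150 accepted points — a 10% tolerance, the usual
choice for coverage checks at this table size, since a 0.2% rate would
leave too few points to fit the 27-coefficient local-linear adjustment.
Monte-Carlo property suites (exponential inter-coalescent intervals,
recombination-count monotonicity, stationarity, directional responses
of the summaries to $\rho$ and $\omega$) use between 250 and 10,000
replicates per condition, chosen so each suite resolves its effect at
several Monte-Carlo standard errors.

## Known limitations

* Demography is constant-size and panmictic; no migration, growth,
  diploidy or longitudinal sampling.
* Codon models other than GY94-with-nucleotide-exchangeabilities (MG94,
  empirical codon matrices) are out of scope, as are amino-acid-level
  simulations.
* The local-linear adjustment is linear in 26 summaries; strongly
  nonlinear parameter-summary relationships at loose tolerances are
  only partially corrected (no neural/ridge variants).
* $\rho$ is intrinsically the hardest of the three parameters: its
  posterior intervals are wide and its mode is noticeably more variable
  across replicate datasets than those of $\theta$ and $\omega$.
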