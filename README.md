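# coalcodon

Joint estimation of recombination, substitution and molecular-adaptation
rates from protein-coding sequence alignments by approximate Bayesian
computation (ABC).

Recombination distorts phylogeny-based estimates of the
nonsynonymous/synonymous rate ratio, so the three quantities have to be
estimated together.  `coalcodon` does this with a simulation-based
(likelihood-free) approach aimed at molecular evolutionists analysing
recombining coding sequences (e.g. viral genes):

* **ρ = 4Nrl** — population-scaled recombination rate of the whole
  alignment (N effective population size, r recombination rate per
  nucleotide, l alignment length in nucleotides);
* **θ = 4NµL** — scaled codon substitution rate (µ substitution rate per
  codon, L codon count);
* **ω** — nonsynonymous/synonymous rate ratio (ω > 1 suggests positive
  selection).

The package contains every layer of the method:

1. a coalescent-with-recombination simulator (Hudson scaling, ancestral
   material tracking, breakpoints on nucleotide boundaries — including
   *intracodon* breakpoints) producing marginal trees per
   non-recombining segment;
2. a GY94 codon evolver (61 sense codons,
   q<sub>ij</sub> ∝ π<sub>j</sub> κ<sup>[ts]</sup> ω<sup>[nonsyn]</sup>
   for single-nucleotide neighbours, matrix normalised to one expected
   substitution per codon per unit coalescent time) with continuous
   gamma rate variation and invariable sites, run by exact Gillespie
   simulation of complete sequences forward over the recombination
   graph;
3. a 26-statistic summary vector: PHI, NSS and MaxChi recombination
   tests, four moments of pairwise diversity and of per-site
   heterozygosity at the codon and amino-acid levels, segregating-site
   counts at three levels, and four joint codon/amino-acid statistics;
4. an ABC engine: median/MAD-standardised Euclidean distances, rejection
   with Epanechnikov weights, weighted local-linear regression
   adjustment (none/log/logit transforms, optional heteroscedasticity
   correction), posterior mode + 95% credible interval per parameter;
5. a pipeline: uniform priors for the estimated triple, nuisance
   parameters (κ, codon frequencies, gamma shape, invariable-site
   proportion) sampled-but-not-estimated, deterministic per-simulation
   child seeds (parallel ≡ serial), FASTA/sequential-PHYLIP input, TSV
   reference tables, JSON/TSV reports, and a thin `exec/coalcodon` CLI
   (`sumstats`, `simulate`, `estimate`).

## Worked example

Simulate a pseudo-observed alignment (15 sequences × 300 codons) at
ρ = 10, θ = 100, ω = 0.5 and re-estimate the parameters from scratch:

```r
library(coalcodon)
set.seed(7)

obs <- simulate_validation_alignment(validation_design()[1, ])
spec <- prior_spec(rho = c(0, 50), theta = c(0, 300), omega = c(0, 2),
                   kappa = 0.5)
res <- run_estimation(obs, spec, n_simulations = 10000, n_accept = 100,
                      method = "loclinear", transform = "logit", seed = 8)
res
#> ABC posterior (loclinear, logit transform), 100 accepted draws
#>  parameter        mode      lower       upper
#>        rho   5.4794521  1.7251633  39.7758387
#>      theta 146.7710372 73.5032392 219.4074810
#>      omega   0.5127202  0.3809321   0.7406946
```

ω is recovered almost exactly; θ and ρ are recovered with the wide
intervals expected from a single dataset at this simulation budget (the
tool's recommended starting point for real analyses is 50,000
simulations).  Each 95% interval covers its generating value;
recombination is intrinsically the weakest-identified parameter of the
three.

The 26 summary statistics of any alignment are one call:

```r
compute_summary_vector(obs)[1:6]
#>          phi          nss       maxchi div_cdn_mean   div_cdn_sd div_cdn_skew
#>   0.05640423   0.99009901  25.45159118   0.24031111   0.11810929  -0.56536336
```

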