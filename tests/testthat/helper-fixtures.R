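# Shared fixtures built in code.

# alignment from a character vector of nucleotide sequences
aln_from_strings <- function(...) {
  coding_alignment(c(...))
}

# quick simulated alignment under simple settings
sim_alignment <- function(n = 8, L = 100, rho = 0, theta = 50, omega = 1,
                          kappa = 1, ...) {
  g <- simulate_arg(coalescent_config(n, 3L * L, rho))
  p <- substitution_params(theta = theta, omega = omega, kappa = kappa,
                           n_codons = L, ...)
  evolve_alignment(g, p)
}

.pairwise_div_for_test <- function(aln) {
  coalcodon:::.pairwise_diversity(aln$codon)
}

# default GY94 parameter set used across tests
default_params <- function(L = 50, theta = 30, omega = 0.5, kappa = 2,
                           ...) {
  substitution_params(theta = theta, omega = omega, kappa = kappa,
                      n_codons = L, ...)
}
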