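# Sequence evolution along simulated genealogies.

.alignment_from_codons <- function(codon_int, labels = NULL) {
  n <- nrow(codon_int)
  L <- ncol(codon_int)
  if (is.null(labels)) labels <- paste0("seq_", seq_len(n))
  cn <- .cc$CODON_NT
  nt <- matrix(NA_integer_, n, 3L * L)
  for (p in 1:3)
    nt[, seq(p, 3 * L, by = 3)] <- matrix(cn[codon_int, p], n, L)
  aa <- matrix(.cc$CODON_AA[codon_int], n, L)
  structure(list(nt = nt, codon = codon_int, aa = aa, labels = labels,
                 n_codons = L),
            class = "coding_alignment")
}

#' Evolve a coding alignment along simulated genealogies
#'
#' Simulates GY94 codon substitution by Gillespie simulation.  Root codon
#' states are drawn from the stationary codon frequencies; along a branch
#' of coalescent length t, substitution events at a codon site occur at
#' rate \eqn{\theta/(2L) \times \mathrm{site\ rate} \times |q_{ii}|} and
#' resolve to codon j with probability \eqn{q_{ij}/|q_{ii}|}.
#'
#' With `intracodon = "nucleotide"` (the default) complete sequences are
#' evolved forward over the full recombination graph: a recombination
#' event splices the two parental sequences at the nucleotide breakpoint,
#' so each nucleotide of a split codon follows its own marginal tree and
#' every substitution rate is conditional on the current states of its two
#' partner nucleotides.  `intracodon = "first_position"` is a simpler
#' diagnostic mode in which each whole codon follows the marginal tree of
#' its first nucleotide.
#'
#' @param genealogies A `"genealogy_set"` from [simulate_arg()]; its
#'   nucleotide length must equal `3 * params$n_codons`.
#' @param params A [substitution_params()].
#' @param intracodon Handling of codons split by intracodon breakpoints;
#'   see Details.
#' @param site_rates Optional vector of per-codon-site rate multipliers;
#'   drawn by [assign_site_rates()] when `NULL`.
#' @return A [coding_alignment()] with `n_samples` sequences.
#' @export
evolve_alignment <- function(genealogies, params,
                             intracodon = c("nucleotide", "first_position"),
                             site_rates = NULL) {
  stopifnot(inherits(genealogies, "genealogy_set"),
            inherits(params, "substitution_params"))
  intracodon <- match.arg(intracodon)
  L <- params$n_codons
  if (genealogies$l_nt != 3L * L)
    stop("genealogy length (", genealogies$l_nt,
         " nt) does not match 3 x n_codons (", 3L * L, ")")
  if (is.null(site_rates)) site_rates <- assign_site_rates(params, L)
  stopifnot(length(site_rates) == L, all(site_rates >= 0))
  qm <- build_gy94_matrix(params)
  seed <- .draw_seed()

  codon <- if (intracodon == "nucleotide") {
    cpp_evolve_arg(genealogies$n, L, genealogies$n_lineages,
                   genealogies$ev_time, genealogies$ev_type,
                   genealogies$ev_a, genealogies$ev_b, genealogies$ev_c,
                   genealogies$ev_bp, qm$q, params$codon_freqs, site_rates,
                   params$theta, .cc$CODON_NT - 1L,
                   ifelse(is.na(.cc$NT2CODON), -1L, .cc$NT2CODON - 1L),
                   seed)
  } else {
    cpp_evolve_marginal(genealogies$n, L, genealogies$tn_time,
                        genealogies$tn_left, genealogies$tn_right,
                        genealogies$seg_a, genealogies$seg_root, qm$q,
                        params$codon_freqs, site_rates, params$theta, seed)
  }
  .alignment_from_codons(codon)
}
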