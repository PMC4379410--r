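# GY94 codon substitution model: rate matrix construction and among-site
# rate multipliers.

#' Substitution model parameters for codon sequence evolution
#'
#' Bundles the parameters of the GY94 codon model used by
#' [evolve_alignment()]: the scaled codon substitution rate
#' \eqn{\theta = 4N\mu L} (with \eqn{\mu} the substitution rate per codon
#' and \eqn{L} the number of codons), the nonsynonymous/synonymous rate
#' ratio \eqn{\omega}, the HKY-style transition/transversion rate ratio
#' \eqn{\kappa}, stationary codon frequencies, and optional among-site
#' rate heterogeneity (continuous gamma with mean 1) plus a proportion of
#' invariable sites.
#'
#' @param theta Scaled codon substitution rate for the whole alignment,
#'   \eqn{\theta = 4N\mu L}; must be >= 0.
#' @param omega Nonsynonymous/synonymous rate ratio, >= 0.
#' @param n_codons Number of codons L (>= 1).
#' @param kappa Transition/transversion rate ratio, > 0.
#' @param codon_freqs Either `"equal"` or a numeric vector of 61
#'   stationary frequencies over the sense codons (order of
#'   [sense_codons()]), summing to 1.
#' @param gamma_shape Shape \eqn{\alpha} of the gamma distribution of site
#'   rate multipliers (mean 1), or `NULL` to disable rate variation.
#' @param prop_invariable Proportion of invariable sites, in `[0, 1)`.
#' @return An object of class `"substitution_params"`.
#' @export
substitution_params <- function(theta, omega, n_codons, kappa = 1,
                                codon_freqs = "equal", gamma_shape = NULL,
                                prop_invariable = 0) {
  stopifnot(is.numeric(theta), length(theta) == 1, theta >= 0,
            is.numeric(omega), length(omega) == 1, omega >= 0,
            is.numeric(kappa), length(kappa) == 1, kappa > 0,
            is.numeric(n_codons), length(n_codons) == 1, n_codons >= 1)
  K <- .cc$N_CODONS
  if (identical(codon_freqs, "equal")) {
    codon_freqs <- rep(1 / K, K)
  }
  if (!is.numeric(codon_freqs) || length(codon_freqs) != K)
    stop("codon_freqs must be 'equal' or a numeric vector of length ", K)
  if (any(codon_freqs < 0) || abs(sum(codon_freqs) - 1) > 1e-12)
    stop("codon frequencies must be non-negative and sum to 1")
  if (!is.null(gamma_shape)) {
    stopifnot(is.numeric(gamma_shape), length(gamma_shape) == 1)
    if (gamma_shape <= 0) stop("gamma_shape must be positive")
  }
  if (!is.numeric(prop_invariable) || prop_invariable < 0 ||
      prop_invariable >= 1)
    stop("prop_invariable must lie in [0, 1)")
  structure(
    list(theta = theta, omega = omega, kappa = kappa,
         codon_freqs = codon_freqs, gamma_shape = gamma_shape,
         prop_invariable = prop_invariable, n_codons = as.integer(n_codons)),
    class = "substitution_params")
}

#' @export
print.substitution_params <- function(x, ...) {
  cat("GY94 substitution parameters\n")
  cat(sprintf("  theta = %g, omega = %g, kappa = %g, L = %d codons\n",
              x$theta, x$omega, x$kappa, x$n_codons))
  cat(sprintf("  gamma shape: %s, prop. invariable: %g\n",
              if (is.null(x$gamma_shape)) "off" else format(x$gamma_shape),
              x$prop_invariable))
  invisible(x)
}

.is_transition <- function(a, b) {
  # A<->G, C<->T (indices 1,3 and 2,4 in A,C,G,T order)
  (a == 1 & b == 3) | (a == 3 & b == 1) | (a == 2 & b == 4) |
    (a == 4 & b == 2)
}

#' Build a GY94 instantaneous rate matrix
#'
#' Constructs the 61x61 GY94 rate matrix over sense codons.  Codon pairs
#' differing at more than one nucleotide have rate zero; a single
#' nucleotide change from codon i to j has rate proportional to
#' \eqn{\pi_j \kappa^{[\mathrm{transition}]} \omega^{[\mathrm{nonsyn}]}}.
#' The matrix is rescaled so that the expected number of substitutions per
#' codon per unit branch length at stationarity is 1, i.e.
#' \eqn{-\sum_i \pi_i q_{ii} = 1}.
#'
#' @param params A [substitution_params()] object.
#' @return A list of class `"codon_rate_matrix"` with elements `q` (the
#'   normalised 61x61 matrix, dimnames the sense codons), `scale` (the
#'   pre-normalisation mean rate divided out) and `freqs`.
#' @export
build_gy94_matrix <- function(params) {
  stopifnot(inherits(params, "substitution_params"))
  K <- .cc$N_CODONS
  pi_ <- params$codon_freqs

  q <- matrix(0, K, K, dimnames = list(.cc$CODONS, .cc$CODONS))
  gp <- .cc$GY_PAIRS
  rate <- pi_[gp$j] * ifelse(gp$ts, params$kappa, 1) *
    ifelse(gp$ns, params$omega, 1)
  q[cbind(gp$i, gp$j)] <- rate
  diag(q) <- -rowSums(q)
  scale <- -sum(pi_ * diag(q))
  if (scale > 0) q <- q / scale
  structure(list(q = q, scale = scale, freqs = pi_,
                 omega = params$omega, kappa = params$kappa),
            class = "codon_rate_matrix")
}

#' @export
print.codon_rate_matrix <- function(x, ...) {
  cat(sprintf(
    "GY94 codon rate matrix (61 x 61), omega = %g, kappa = %g\n",
    x$omega, x$kappa))
  cat(sprintf("  normalised from mean rate %g\n", x$scale))
  invisible(x)
}

#' Draw per-codon-site rate multipliers
#'
#' Each codon site independently is invariable (multiplier 0) with
#' probability `prop_invariable`; otherwise its multiplier is a continuous
#' Gamma(shape, mean 1) draw divided by `1 - prop_invariable`, so the
#' expected multiplier over all sites is exactly 1 (no empirical
#' renormalisation).  With rate variation disabled, variable sites get
#' multiplier `1 / (1 - prop_invariable)`.
#'
#' @param params A [substitution_params()] object.
#' @param L Number of codon sites; defaults to `params$n_codons`.
#' @return Numeric vector of L non-negative multipliers.
#' @export
assign_site_rates <- function(params, L = params$n_codons) {
  stopifnot(inherits(params, "substitution_params"), L >= 1)
  p_inv <- params$prop_invariable
  inv <- stats::runif(L) < p_inv
  mult <- if (is.null(params$gamma_shape)) {
    rep(1, L)
  } else {
    stats::rgamma(L, shape = params$gamma_shape, rate = params$gamma_shape)
  }
  mult <- mult / (1 - p_inv)
  mult[inv] <- 0
  mult
}
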