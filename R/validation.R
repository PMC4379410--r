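# Simulation-based validation: the factorial benchmark design, a
# scaled-down parameter-recovery experiment, and a prior-predictive
# coverage calibration.

#' The factorial benchmark design
#'
#' The benchmark grid for validating joint estimation: all combinations
#' of rho in {10, 30}, omega in {0.5, 1.5} and theta in {100, 200}, for
#' alignments of 15 sequences with 300 codons, effective population size
#' 1,000, GY94 with transition/transversion rate ratio 0.5 and equal
#' codon frequencies.
#'
#' @return Data frame with one row per factorial cell (8 rows) and
#'   columns `rho`, `omega`, `theta`, `n_samples`, `n_codons`,
#'   `effective_size_N`, `kappa`.
#' @export
validation_design <- function() {
  g <- expand.grid(rho = c(10, 30), omega = c(0.5, 1.5),
                   theta = c(100, 200))
  g$n_samples <- 15L
  g$n_codons <- 300L
  g$effective_size_N <- 1000L
  g$kappa <- 0.5
  g
}

#' Simulate one pseudo-observed alignment from a design cell
#'
#' @param cell One row of [validation_design()] (or a list with the same
#'   fields).
#' @return A [coding_alignment()].
#' @export
simulate_validation_alignment <- function(cell) {
  draw <- structure(list(rho = cell$rho, theta = cell$theta,
                         omega = cell$omega, kappa = cell$kappa,
                         gamma_shape = NULL, prop_invariable = 0,
                         codon_freqs = "equal", seed = .draw_seed()),
                    class = "parameter_draw")
  .simulate_one(draw, cell$n_samples, cell$n_codons,
                cell$effective_size_N)
}

#' Scaled-down parameter-recovery experiment
#'
#' Simulates `n_replicates` pseudo-observed alignments at one cell of
#' [validation_design()], estimates (rho, theta, omega) for each with a
#' fresh reference table under the wide priors rho ~ U(0,50),
#' theta ~ U(0,300), omega ~ U(0,2) (nuisance parameters fixed at the
#' generating values), accepting `n_accept` simulations and adjusting
#' with logit-transformed weighted linear regression, and reports the
#' posterior mode per parameter and replicate plus the median across
#' replicates.
#'
#' @param cell Row of [validation_design()]; default the low cell
#'   (rho = 10, omega = 0.5, theta = 100).
#' @param n_replicates Number of pseudo-observed datasets.
#' @param table_size Simulations per reference table.
#' @param n_accept Accepted simulations per estimate.
#' @param n_workers Parallel workers for table building.
#' @param seed Root seed.
#' @return List with `modes` (n_replicates x 3 matrix), `median_mode`
#'   (named length-3 vector) and `truth`.
#' @export
validation_recovery <- function(cell = validation_design()[1, ],
                                n_replicates = 10, table_size = 3000,
                                n_accept = 100, n_workers = 1,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  spec <- prior_spec(rho = c(0, 50), theta = c(0, 300), omega = c(0, 2),
                     kappa = cell$kappa, codon_freqs = "equal")
  rep_seeds <- sample.int(.Machine$integer.max - 1L, 2L * n_replicates)

  modes <- matrix(NA_real_, n_replicates, 3,
                  dimnames = list(NULL, c("rho", "theta", "omega")))
  for (r in seq_len(n_replicates)) {
    set.seed(rep_seeds[2L * r - 1L])
    obs <- simulate_validation_alignment(cell)
    res <- run_estimation(obs, spec, n_simulations = table_size,
                          n_accept = n_accept, method = "loclinear",
                          transform = "logit",
                          effective_size_N = cell$effective_size_N,
                          n_workers = n_workers,
                          seed = rep_seeds[2L * r])
    modes[r, ] <- res$summary$mode
  }
  list(modes = modes,
       median_mode = apply(modes, 2, stats::median),
       truth = c(rho = cell$rho, theta = cell$theta, omega = cell$omega))
}

#' Prior-predictive coverage calibration
#'
#' Draws `n_pseudo` pseudo-observed datasets from the prior, estimates
#' each against a shared reference table (the standard cross-validation
#' design for ABC coverage checks), and reports the fraction of datasets
#' whose generating value falls inside the 95% credible interval, per
#' parameter.  A well-calibrated procedure yields coverage near 0.95.
#' The default acceptance count corresponds to a 10% tolerance, the
#' usual choice for cross-validation coverage checks on tables of this
#' size (a 0.2% rate would retain too few points for the regression).
#'
#' @param n_pseudo Number of prior-predictive pseudo-observed datasets.
#' @param table_size Simulations in the shared reference table.
#' @param n_samples,n_codons Alignment dimensions.
#' @param n_accept Accepted simulations per estimate.
#' @param n_workers Parallel workers.
#' @param seed Root seed.
#' @return List with `coverage` (named length-3 vector) and `inside`
#'   (n_pseudo x 3 logical matrix).
#' @export
coverage_calibration <- function(n_pseudo = 200, table_size = 1500,
                                 n_samples = 10, n_codons = 100,
                                 n_accept = 150, n_workers = 1,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  spec <- prior_spec(rho = c(0, 50), theta = c(0, 300), omega = c(0, 2),
                     kappa = 0.5, codon_freqs = "equal")
  table_seed <- .draw_seed()
  pseudo_seed <- .draw_seed()

  table <- build_reference_table(spec, table_size, n_samples, n_codons,
                                 n_workers = n_workers, seed = table_seed)

  set.seed(pseudo_seed)
  inside <- matrix(NA, n_pseudo, 3,
                   dimnames = list(NULL, c("rho", "theta", "omega")))
  for (i in seq_len(n_pseudo)) {
    draw <- sample_prior(spec)
    set.seed(draw$seed)
    aln <- .simulate_one(draw, n_samples, n_codons, 1000)
    ss <- compute_summary_vector(aln)
    res <- abc_estimate(ss, table, n_accept = n_accept,
                        method = "loclinear", transform = "logit")
    truth <- c(draw$rho, draw$theta, draw$omega)
    inside[i, ] <- truth >= res$summary$lower & truth <= res$summary$upper
  }
  list(coverage = colMeans(inside), inside = inside)
}
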