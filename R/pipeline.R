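# Orchestration: prior sampling, reference-table construction (optionally
# parallel with per-simulation child seeds), end-to-end estimation and
# reference-table I/O.

.uniform_or_fixed <- function(x, name, lower_ok = 0) {
  if (is.null(x)) return(NULL)
  if (!is.numeric(x) || !length(x) %in% c(1, 2))
    stop("prior for ", name, " must be a fixed value or (low, high) bounds")
  if (length(x) == 2) {
    if (!all(is.finite(x)) || x[1] >= x[2])
      stop("prior bounds for ", name, " must be finite with low < high")
    if (x[1] < lower_ok)
      stop("lower prior bound for ", name, " must be >= ", lower_ok)
  }
  x
}

#' Prior specification for simulation and estimation
#'
#' The three estimated parameters (`rho`, `theta`, `omega`) take uniform
#' priors given as `(low, high)`; nuisance parameters (`kappa`,
#' `gamma_shape`, `prop_invariable`, codon frequencies) may each be a
#' fixed value or uniform bounds — they are sampled per simulation and
#' recorded in the reference table but never estimated.
#'
#' @param rho,theta,omega Length-2 uniform bounds for the estimated
#'   parameters (defaults are wide ranges appropriate for coding data:
#'   `rho` U(0,50), `theta` U(0,300), `omega` U(0,2)).
#' @param kappa Transition/transversion ratio: fixed value or bounds.
#' @param gamma_shape `NULL` (rate variation off), a fixed shape, or
#'   bounds.
#' @param prop_invariable Fixed value or bounds within `[0, 1)`.
#' @param codon_freqs `"equal"`, a fixed 61-vector, or `"dirichlet"`
#'   (symmetric Dirichlet(1) draw per simulation).
#' @return Object of class `"prior_spec"`.
#' @export
prior_spec <- function(rho = c(0, 50), theta = c(0, 300), omega = c(0, 2),
                       kappa = 1, gamma_shape = NULL, prop_invariable = 0,
                       codon_freqs = "equal") {
  for (nm in c("rho", "theta", "omega")) {
    v <- get(nm)
    if (length(v) != 2)
      stop(nm, " is an estimated parameter and needs (low, high) bounds")
  }
  spec <- list(rho = .uniform_or_fixed(rho, "rho"),
               theta = .uniform_or_fixed(theta, "theta"),
               omega = .uniform_or_fixed(omega, "omega"),
               kappa = .uniform_or_fixed(kappa, "kappa", lower_ok = 1e-12),
               gamma_shape = .uniform_or_fixed(gamma_shape, "gamma_shape",
                                               lower_ok = 1e-12),
               prop_invariable = .uniform_or_fixed(prop_invariable,
                                                   "prop_invariable"),
               codon_freqs = codon_freqs)
  if (is.numeric(spec$prop_invariable) &&
      any(spec$prop_invariable >= 1))
    stop("prop_invariable must stay below 1")
  structure(spec, class = "prior_spec")
}

.draw_value <- function(x) {
  if (length(x) == 2) stats::runif(1, x[1], x[2]) else x
}

#' Draw one parameter set from the priors
#'
#' @param spec A [prior_spec()].
#' @return A list (class `"parameter_draw"`) with `rho`, `theta`, `omega`,
#'   the nuisance values and a `seed` reserved for the simulator.
#' @export
sample_prior <- function(spec) {
  stopifnot(inherits(spec, "prior_spec"))
  freqs <- spec$codon_freqs
  if (identical(freqs, "dirichlet")) {
    g <- stats::rgamma(.cc$N_CODONS, 1)
    freqs <- g / sum(g)
  }
  structure(list(rho = .draw_value(spec$rho),
                 theta = .draw_value(spec$theta),
                 omega = .draw_value(spec$omega),
                 kappa = .draw_value(spec$kappa),
                 gamma_shape = if (is.null(spec$gamma_shape)) NULL
                               else .draw_value(spec$gamma_shape),
                 prop_invariable = .draw_value(spec$prop_invariable),
                 codon_freqs = freqs,
                 seed = .draw_seed()),
            class = "parameter_draw")
}

.simulate_one <- function(draw, n_samples, n_codons, effective_size_N) {
  cfg <- coalescent_config(n_samples, 3L * n_codons, draw$rho,
                           effective_size_N, seed = draw$seed)
  gen <- simulate_arg(cfg)
  par <- substitution_params(theta = draw$theta, omega = draw$omega,
                             kappa = draw$kappa,
                             codon_freqs = draw$codon_freqs,
                             gamma_shape = draw$gamma_shape,
                             prop_invariable = draw$prop_invariable,
                             n_codons = n_codons)
  evolve_alignment(gen, par)
}

#' Assemble a reference table container
#'
#' @param parameters Data frame/matrix with columns `rho`, `theta`,
#'   `omega`.
#' @param summaries Matrix/data frame of the 26 summary statistics.
#' @param nuisance Recorded nuisance draws (never estimated).
#' @param prior_bounds 3 x 2 matrix of the estimated parameters' bounds.
#' @return Object of class `"reference_table"`.
#' @export
reference_table <- function(parameters, summaries, nuisance = NULL,
                            prior_bounds) {
  parameters <- as.data.frame(parameters)
  summaries <- as.data.frame(summaries)
  stopifnot(nrow(parameters) == nrow(summaries),
            all(c("rho", "theta", "omega") %in% names(parameters)))
  if (!is.null(nuisance)) {
    nuisance <- as.data.frame(nuisance)
    stopifnot(nrow(nuisance) == nrow(parameters))
  }
  if (!all(vapply(summaries, function(x) all(is.finite(x)), logical(1))))
    stop("summaries contain non-finite values")
  prior_bounds <- as.matrix(prior_bounds)
  rownames(prior_bounds) <- c("rho", "theta", "omega")
  structure(list(parameters = parameters[c("rho", "theta", "omega")],
                 nuisance = nuisance, summaries = summaries,
                 prior_bounds = prior_bounds),
            class = "reference_table")
}

#' @export
print.reference_table <- function(x, ...) {
  cat(sprintf("ABC reference table: %d simulations, %d summary statistics\n",
              nrow(x$parameters), ncol(x$summaries)))
  invisible(x)
}

#' Build a reference table of simulations
#'
#' For each simulation: draw parameters from the priors, simulate a
#' genealogy set ([simulate_arg()]), evolve a coding alignment
#' ([evolve_alignment()]) with the observed data's dimensions, and
#' compute the 26 summary statistics.  Work is partitioned by simulation
#' index with per-simulation child seeds derived from `seed`, so results
#' are identical for any `n_workers`.  A simulation raising an error is
#' retried once with a fresh child seed, then recorded as failed and
#' excluded; more than 1% failures aborts.
#'
#' @param spec A [prior_spec()].
#' @param n_simulations Number of simulations.
#' @param n_samples,n_codons Alignment dimensions, which must match the
#'   observed data exactly.
#' @param effective_size_N Effective population size (bookkeeping).
#' @param n_workers Parallel workers (forked via \pkg{parallel}).
#' @param seed Root seed; expands deterministically into child seeds.
#' @return A [reference_table()].
#' @export
build_reference_table <- function(spec, n_simulations, n_samples, n_codons,
                                  effective_size_N = 1000, n_workers = 1,
                                  seed = NULL) {
  stopifnot(inherits(spec, "prior_spec"), n_simulations >= 1)
  if (!is.null(seed)) set.seed(seed)
  child <- sample.int(.Machine$integer.max - 1L, 2L * n_simulations)

  one <- function(i) {
    for (attempt in 1:2) {
      set.seed(child[2L * (i - 1L) + attempt])
      res <- tryCatch({
        draw <- sample_prior(spec)
        aln <- .simulate_one(draw, n_samples, n_codons, effective_size_N)
        ss <- compute_summary_vector(aln)
        list(par = c(rho = draw$rho, theta = draw$theta,
                     omega = draw$omega),
             nui = c(kappa = draw$kappa,
                     gamma_shape = if (is.null(draw$gamma_shape)) NA_real_
                                   else draw$gamma_shape,
                     prop_invariable = draw$prop_invariable),
             ss = ss)
      }, error = function(e) NULL)
      if (!is.null(res)) return(res)
    }
    NULL
  }

  results <- if (n_workers > 1) {
    parallel::mclapply(seq_len(n_simulations), one, mc.cores = n_workers)
  } else {
    lapply(seq_len(n_simulations), one)
  }

  failed <- vapply(results, is.null, logical(1))
  if (sum(failed) > 0.01 * n_simulations)
    stop(sum(failed), " of ", n_simulations,
         " simulations failed; aborting")
  if (any(failed))
    message(sum(failed), " simulation(s) failed after retry and were ",
            "excluded")
  results <- results[!failed]

  reference_table(
    parameters = do.call(rbind, lapply(results, function(r) r$par)),
    summaries = do.call(rbind, lapply(results, function(r) r$ss)),
    nuisance = do.call(rbind, lapply(results, function(r) r$nui)),
    prior_bounds = rbind(spec$rho, spec$theta, spec$omega))
}

#' Concatenate reference tables
#'
#' Two tables built with disjoint child-seed ranges concatenate into a
#' valid larger table, supporting incremental analyses with increasing
#' simulation counts.
#'
#' @param ... `"reference_table"` objects with identical prior bounds and
#'   summary columns.
#' @return A combined [reference_table()].
#' @export
bind_reference_tables <- function(...) {
  tabs <- list(...)
  stopifnot(length(tabs) >= 1,
            all(vapply(tabs, inherits, logical(1), "reference_table")))
  b0 <- tabs[[1]]$prior_bounds
  for (t in tabs)
    if (!isTRUE(all.equal(t$prior_bounds, b0)))
      stop("reference tables have different prior bounds")
  reference_table(
    parameters = do.call(rbind, lapply(tabs, `[[`, "parameters")),
    summaries = do.call(rbind, lapply(tabs, `[[`, "summaries")),
    nuisance = do.call(rbind, lapply(tabs, `[[`, "nuisance")),
    prior_bounds = b0)
}

#' Write / read a reference table as TSV
#'
#' Column order is `rho theta omega <nuisance...> <26 summary names>`,
#' one row per simulation.
#'
#' @param table A [reference_table()].
#' @param path TSV path.
#' @return `write_reference_table` invisibly returns `path`;
#'   `read_reference_table` returns a [reference_table()].
#' @export
write_reference_table <- function(table, path) {
  stopifnot(inherits(table, "reference_table"))
  df <- cbind(table$parameters, table$nuisance, table$summaries)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# prior_bounds\t",
                    paste(apply(table$prior_bounds, 1, paste,
                                collapse = ","), collapse = "\t")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_reference_table
#' @param path TSV path written by [write_reference_table()].
#' @export
read_reference_table <- function(path) {
  header <- readLines(path, n = 1)
  if (!startsWith(header, "# prior_bounds"))
    stop("not a reference-table TSV (missing prior_bounds header)")
  bounds <- do.call(rbind, lapply(strsplit(header, "\t")[[1]][-1],
                                  function(s)
                                    as.numeric(strsplit(s, ",")[[1]])))
  df <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1)
  ss_cols <- intersect(.summary_names, names(df))
  par_cols <- c("rho", "theta", "omega")
  nui_cols <- setdiff(names(df), c(ss_cols, par_cols))
  reference_table(df[par_cols], df[ss_cols],
                  nuisance = if (length(nui_cols)) df[nui_cols] else NULL,
                  prior_bounds = bounds)
}

#' End-to-end joint estimation of rho, theta and omega
#'
#' Computes the observed 26-statistic summary vector, builds (or reuses)
#' a reference table matched to the observed alignment's dimensions, runs
#' rejection (plus weighted local-linear regression for
#' `method = "loclinear"`), and reports the posterior mode and 95% CI per
#' parameter.  If the observed summary falls outside the table's
#' `[0.5%, 99.5%]` envelope for more than 8 of the 26 statistics, a
#' prior-predictive mismatch warning is raised (the analysis continues).
#'
#' @param observed A [coding_alignment()] or a path readable by
#'   [read_coding_alignment()].
#' @param spec A [prior_spec()].
#' @param n_simulations Simulations for the reference table (ignored if
#'   `table` is given).
#' @param table Optional pre-built [reference_table()].
#' @param tolerance,n_accept,method,transform,hetero_correction Passed to
#'   [abc_estimate()].
#' @param effective_size_N,n_workers,seed Passed to
#'   [build_reference_table()].
#' @return A `"posterior_result"` with extra fields `observed_summary`
#'   and `n_envelope_violations`.
#' @export
run_estimation <- function(observed, spec, n_simulations = 50000,
                           table = NULL, tolerance = 0.002,
                           n_accept = NULL,
                           method = c("loclinear", "rejection"),
                           transform = c("logit", "none", "log"),
                           hetero_correction = FALSE,
                           effective_size_N = 1000, n_workers = 1,
                           seed = NULL) {
  method <- match.arg(method)
  transform <- match.arg(transform)
  if (is.character(observed)) observed <- read_coding_alignment(observed)
  stopifnot(inherits(observed, "coding_alignment"))
  obs_ss <- compute_summary_vector(observed)

  if (is.null(table)) {
    table <- build_reference_table(spec, n_simulations,
                                   n_samples = nrow(observed$nt),
                                   n_codons = observed$n_codons,
                                   effective_size_N = effective_size_N,
                                   n_workers = n_workers, seed = seed)
  }

  lo <- apply(table$summaries, 2, stats::quantile, 0.005)
  hi <- apply(table$summaries, 2, stats::quantile, 0.995)
  n_out <- sum(obs_ss < lo | obs_ss > hi)
  if (n_out > 8)
    warning("observed summaries fall outside the reference table's ",
            "[0.5%, 99.5%] envelope for ", n_out, " of 26 statistics: ",
            "likely prior-predictive mismatch")

  res <- abc_estimate(obs_ss, table, tolerance = tolerance,
                      n_accept = n_accept, method = method,
                      transform = transform,
                      hetero_correction = hetero_correction)
  res$observed_summary <- obs_ss
  res$n_envelope_violations <- n_out
  res
}

#' Write a posterior result as JSON + TSV report
#'
#' @param result A `"posterior_result"`.
#' @param prefix Output path prefix; writes `<prefix>.json`,
#'   `<prefix>_summary.tsv` and `<prefix>_draws.tsv`.
#' @return Invisibly, the paths written.
#' @export
write_estimation_report <- function(result, prefix) {
  stopifnot(inherits(result, "posterior_result"))
  js <- paste0(prefix, ".json")
  jsonlite::write_json(
    list(method = result$method, transform = result$transform,
         tolerance = result$tolerance,
         estimates = result$summary), js, auto_unbox = TRUE, digits = NA)
  ts <- paste0(prefix, "_summary.tsv")
  utils::write.table(result$summary, ts, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  dr <- paste0(prefix, "_draws.tsv")
  draws <- if (is.null(result$accepted_adjusted)) result$accepted_raw
           else result$accepted_adjusted
  utils::write.table(
    data.frame(draws, weight = result$weights, check.names = FALSE), dr,
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(js, ts, dr))
}
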