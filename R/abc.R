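# ABC estimation layer: robust standardization and distances, rejection
# with Epanechnikov weights, weighted local-linear regression adjustment
# with none/log/logit transforms and optional heteroscedasticity
# correction, and posterior summaries.

.standardize_scales <- function(summaries) {
  med <- apply(summaries, 2, stats::median)
  mad_ <- apply(summaries, 2, stats::mad)
  mad_[mad_ <= 0 | !is.finite(mad_)] <- 1  # constant columns: scale 1
  list(center = med, scale = mad_)
}

#' Standardized Euclidean distances to an observed summary vector
#'
#' Each summary column is centered by its median and scaled by its median
#' absolute deviation over the reference table (constant columns keep
#' scale 1); the distance of each simulation is the Euclidean norm of the
#' standardized difference to the standardized observed vector.
#'
#' @param observed Named numeric summary vector (length = table columns).
#' @param table A [reference_table()] or a plain matrix/data frame of
#'   summaries (rows = simulations).
#' @return Numeric vector of distances, one per table row.
#' @export
standardize_and_distance <- function(observed, table) {
  summaries <- if (inherits(table, "reference_table"))
    as.matrix(table$summaries) else as.matrix(table)
  if (length(observed) != ncol(summaries))
    stop("observed vector length (", length(observed),
         ") does not match summary columns (", ncol(summaries), ")")
  if (nrow(summaries) == 0) stop("reference table is empty")
  sc <- .standardize_scales(summaries)
  z <- sweep(sweep(summaries, 2, sc$center), 2, sc$scale, "/")
  z0 <- (as.numeric(observed) - sc$center) / sc$scale
  sqrt(rowSums(sweep(z, 2, z0)^2))
}

#' Rejection step: accept the closest simulations
#'
#' Accepts the `m = max(1, round(tolerance * S))` smallest distances
#' (ties broken by table row order) and attaches Epanechnikov kernel
#' weights \eqn{w_i = 1 - (d_i/d_{max})^2}, with uniform weights when the
#' largest accepted distance is 0.
#'
#' @param distances Numeric distances from [standardize_and_distance()].
#' @param tolerance Acceptance rate, in `(0, 1]`.
#' @param n_accept Alternatively, the exact number of simulations to
#'   accept (overrides `tolerance`).
#' @return List with `index` (accepted row indices, in distance order)
#'   and `weights`.
#' @export
abc_reject <- function(distances, tolerance = NULL, n_accept = NULL) {
  S <- length(distances)
  if (is.null(n_accept)) {
    if (is.null(tolerance) || !is.numeric(tolerance) || tolerance <= 0 ||
        tolerance > 1)
      stop("tolerance must lie in (0, 1]")
    m <- max(1L, as.integer(round(tolerance * S)))
  } else {
    m <- as.integer(n_accept)
    if (m < 1 || m > S) stop("n_accept must lie in [1, S]")
  }
  ord <- order(distances)[seq_len(m)]  # stable: ties by row order
  d <- distances[ord]
  dmax <- d[m]
  w <- if (dmax > 0) 1 - (d / dmax)^2 else rep(1, m)
  if (all(w == 0)) w <- rep(1, m)  # single accepted point at dmax
  list(index = ord, weights = w)
}

.transform_param <- function(x, transform, bounds) {
  eps <- 1e-8
  switch(transform,
         none = x,
         log = {
           if (any(x <= 0))
             stop("log transform requires positive parameter values; ",
                  "use 'logit' or 'none'")
           log(x)
         },
         logit = {
           span <- bounds[2] - bounds[1]
           p <- pmin(pmax((x - bounds[1]) / span, eps), 1 - eps)
           log(p / (1 - p))
         })
}

.back_transform <- function(z, transform, bounds) {
  switch(transform,
         none = z,
         log = exp(z),
         logit = bounds[1] + (bounds[2] - bounds[1]) / (1 + exp(-z)))
}

.wls_fit <- function(X, y, w) {
  # weighted least squares with rank-deficiency tolerance: NA pivots -> 0
  fit <- stats::lm.wfit(X, y, w)
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  beta
}

#' Local-linear regression adjustment of accepted parameters
#'
#' Beaumont-style post-rejection correction: per estimated parameter, the
#' (optionally transformed) accepted values are regressed on the
#' standardized accepted summaries with the Epanechnikov weights; each
#' accepted draw is projected to the observed summaries by
#' `fitted(observed) + residual`.  Residuals are inflated by the
#' weighted-least-squares degrees-of-freedom factor (on the Kish
#' effective sample size) so that the spread removed by fitting the
#' regression coefficients is restored.  With `hetero_correction`, a second
#' weighted regression of `log |residual|` on the same design rescales
#' each residual by the ratio of the fitted spread at the observed point
#' to the fitted spread at that draw.  The logit transform maps through
#' the parameter's prior bounds, so adjusted draws cannot leave the
#' prior support.
#'
#' @param params Matrix of accepted parameter draws (m x p).
#' @param summaries Matrix of accepted standardized summaries (m x q).
#' @param observed Standardized observed summary vector (length q).
#' @param weights Epanechnikov weights from [abc_reject()].
#' @param transform `"none"`, `"log"` or `"logit"` (applied to every
#'   parameter column).
#' @param prior_bounds p x 2 matrix of (low, high) prior bounds.
#' @param hetero_correction Logical; rescale residuals by fitted
#'   conditional spread.
#' @return Matrix of adjusted draws, same shape as `params`.
#' @export
regression_adjust <- function(params, summaries, observed, weights,
                              transform = c("none", "log", "logit"),
                              prior_bounds = NULL,
                              hetero_correction = FALSE) {
  transform <- match.arg(transform)
  params <- as.matrix(params)
  summaries <- as.matrix(summaries)
  m <- nrow(params)
  if (transform == "logit" && is.null(prior_bounds))
    stop("logit transform requires prior bounds")
  if (is.null(prior_bounds))
    prior_bounds <- cbind(rep(-Inf, ncol(params)), rep(Inf, ncol(params)))
  prior_bounds <- as.matrix(prior_bounds)

  # drop constant summary columns (degenerate designs)
  keep <- apply(summaries, 2, function(x) stats::sd(x) > 1e-12)
  if (!all(keep))
    warning(sum(!keep), " constant summary column(s) dropped from the ",
            "regression design")
  if (!any(keep) || m < 3) return(params)  # no usable design: no adjustment

  X <- cbind(1, summaries[, keep, drop = FALSE])
  x0 <- c(1, as.numeric(observed)[keep])

  # residual-spread correction: fitting q+1 coefficients to m weighted
  # points shrinks the residual spread below the conditional posterior
  # spread, so residuals are inflated by the usual least-squares
  # degrees-of-freedom factor computed on the Kish effective sample size
  m_eff <- sum(weights)^2 / sum(weights^2)
  rank_w <- qr(X * sqrt(weights))$rank
  infl <- sqrt(m_eff / max(m_eff - rank_w, 1))

  adjusted <- params
  for (p in seq_len(ncol(params))) {
    y <- .transform_param(params[, p], transform, prior_bounds[p, ])
    beta <- .wls_fit(X, y, weights)
    fitted <- drop(X %*% beta)
    resid <- y - fitted
    fit0 <- sum(x0 * beta)
    if (hetero_correction) {
      ly <- log(abs(resid) + 1e-12)
      gam <- .wls_fit(X, ly, weights)
      lsd <- drop(X %*% gam)
      lsd0 <- sum(x0 * gam)
      resid <- resid * exp(pmin(pmax(lsd0 - lsd, -3), 3))
    }
    adjusted[, p] <- .back_transform(fit0 + resid * infl, transform,
                                     prior_bounds[p, ])
  }
  adjusted
}

.weighted_quantile <- function(x, w, probs) {
  ord <- order(x)
  x <- x[ord]
  w <- w[ord]
  cw <- (cumsum(w) - 0.5 * w) / sum(w)  # midpoint rule, interpolated
  stats::approx(cw, x, probs, rule = 2, ties = "ordered")$y
}

#' Posterior mode and 95% credible interval
#'
#' The mode is the argmax of a weighted Gaussian kernel density (Silverman
#' bandwidth, 512-point grid over the prior range, clipped to the prior
#' bounds); the credible interval is the weighted 0.025/0.975 quantile
#' pair.
#'
#' @param draws Numeric vector of posterior draws for one parameter.
#' @param weights Non-negative weights (default uniform).
#' @param prior_bounds Length-2 numeric `(low, high)`; also the density
#'   evaluation range.
#' @return Named numeric vector `(mode, lower, upper)`.
#' @export
summarize_posterior <- function(draws, weights = NULL, prior_bounds) {
  stopifnot(length(draws) >= 1, length(prior_bounds) == 2)
  if (is.null(weights)) weights <- rep(1, length(draws))
  stopifnot(length(weights) == length(draws), all(weights >= 0),
            max(weights) > 0)
  w <- weights / sum(weights)
  if (length(unique(draws)) == 1 || stats::sd(draws) < 1e-12) {
    v <- draws[1]
    return(c(mode = v, lower = v, upper = v))
  }
  dens <- stats::density(draws, weights = w, bw = stats::bw.nrd0(draws),
                         n = 512, from = prior_bounds[1],
                         to = prior_bounds[2])
  mode <- dens$x[which.max(dens$y)]
  mode <- min(max(mode, prior_bounds[1]), prior_bounds[2])
  ci <- .weighted_quantile(draws, w, c(0.025, 0.975))
  c(mode = mode, lower = ci[1], upper = ci[2])
}

#' End-to-end ABC estimation from a summary vector and a reference table
#'
#' Runs [standardize_and_distance()], [abc_reject()] and (for
#' `method = "loclinear"`) [regression_adjust()], then summarizes each
#' estimated parameter with [summarize_posterior()].
#'
#' @param observed Named 26-statistic summary vector of the observed data.
#' @param table A [reference_table()].
#' @param tolerance Acceptance rate in `(0, 1]`.
#' @param n_accept Number of accepted simulations (overrides `tolerance`).
#' @param method `"loclinear"` (rejection + weighted regression, default)
#'   or `"rejection"`.
#' @param transform Parameter transform for the regression: `"none"`,
#'   `"log"` or `"logit"` (through the prior bounds).
#' @param hetero_correction Logical, see [regression_adjust()].
#' @return Object of class `"posterior_result"`: accepted indices, raw
#'   and (if applicable) adjusted draws, weights, and a `summary` data
#'   frame with mode and 95% CI per parameter.
#' @export
abc_estimate <- function(observed, table, tolerance = 0.002,
                         n_accept = NULL,
                         method = c("loclinear", "rejection"),
                         transform = c("logit", "none", "log"),
                         hetero_correction = FALSE) {
  stopifnot(inherits(table, "reference_table"))
  method <- match.arg(method)
  transform <- match.arg(transform)
  d <- standardize_and_distance(observed, table)
  acc <- abc_reject(d, tolerance = tolerance, n_accept = n_accept)
  pars <- as.matrix(table$parameters)[acc$index, , drop = FALSE]
  bounds <- table$prior_bounds

  adjusted <- NULL
  if (method == "loclinear") {
    summaries <- as.matrix(table$summaries)
    sc <- .standardize_scales(summaries)
    z <- sweep(sweep(summaries[acc$index, , drop = FALSE], 2, sc$center),
               2, sc$scale, "/")
    z0 <- (as.numeric(observed) - sc$center) / sc$scale
    n_used <- sum(apply(z, 2, function(x) stats::sd(x) > 1e-12))
    if (nrow(pars) < 3 * max(n_used, 1)) {
      warning("fewer than 3 accepted points per summary statistic; ",
              "falling back to rejection-only estimates")
    } else {
      adjusted <- regression_adjust(pars, z, z0, acc$weights,
                                    transform = transform,
                                    prior_bounds = bounds,
                                    hetero_correction = hetero_correction)
    }
  }

  est_draws <- if (is.null(adjusted)) pars else adjusted
  summ <- t(vapply(seq_len(ncol(pars)), function(p) {
    summarize_posterior(est_draws[, p], acc$weights, bounds[p, ])
  }, numeric(3)))
  summary_df <- data.frame(parameter = colnames(pars),
                           mode = summ[, 1], lower = summ[, 2],
                           upper = summ[, 3], row.names = NULL)

  structure(list(accepted_index = acc$index, accepted_raw = pars,
                 accepted_adjusted = adjusted, weights = acc$weights,
                 summary = summary_df,
                 tolerance = if (is.null(n_accept)) tolerance
                             else length(acc$index) / length(d),
                 transform = if (method == "loclinear") transform else NA,
                 method = method),
            class = "posterior_result")
}

#' @export
print.posterior_result <- function(x, ...) {
  cat(sprintf("ABC posterior (%s%s), %d accepted draws\n", x$method,
              if (!is.na(x$transform)) paste0(", ", x$transform,
                                              " transform") else "",
              length(x$accepted_index)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
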