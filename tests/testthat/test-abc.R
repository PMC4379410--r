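# Rejection, regression adjustment and posterior summaries.

make_table <- function(S = 500, seed = 1) {
  set.seed(seed)
  pars <- data.frame(rho = runif(S, 0, 50), theta = runif(S, 0, 300),
                     omega = runif(S, 0, 2))
  ss <- matrix(rnorm(S * 26), S, 26,
               dimnames = list(NULL, summary_stat_names()))
  reference_table(pars, ss,
                  prior_bounds = rbind(c(0, 50), c(0, 300), c(0, 2)))
}

test_that("distances are zero for a matching row and match hand arithmetic", {
  tab <- make_table(100)
  obs <- as.numeric(tab$summaries[17, ])
  d <- standardize_and_distance(obs, tab)
  expect_equal(d[17], 0)

  # 2-row, 2-column toy by hand
  s <- matrix(c(1, 3, 10, 30), 2, 2)
  obs2 <- c(2, 20)
  med <- c(2, 20)
  madv <- c(stats::mad(c(1, 3)), stats::mad(c(10, 30)))
  z <- sweep(sweep(s, 2, med), 2, madv, "/")
  z0 <- (obs2 - med) / madv
  expect_equal(standardize_and_distance(obs2, s),
               sqrt(rowSums(sweep(z, 2, z0)^2)))

  # duplicating every row leaves distances unchanged (median/MAD robust)
  s2 <- rbind(s, s)
  expect_equal(standardize_and_distance(obs2, s2)[1:2],
               standardize_and_distance(obs2, s))

  expect_error(standardize_and_distance(c(1, 2, 3), s), "match")
})

test_that("rejection accepts round(tolerance * S) points with kernel weights", {
  d <- c(5, 1, 3, 2, 4)
  acc <- abc_reject(d, tolerance = 0.4)
  expect_identical(acc$index, c(2L, 4L))
  expect_equal(acc$weights, 1 - (c(1, 2) / 2)^2)

  expect_length(abc_reject(d, tolerance = 1)$index, 5)
  expect_error(abc_reject(d, tolerance = 0), "tolerance")
  expect_error(abc_reject(d, tolerance = 1.2), "tolerance")

  # all-equal distances: every accepted weight equal (and positive)
  acc0 <- abc_reject(rep(2, 10), tolerance = 0.5)
  expect_true(all(acc0$weights == acc0$weights[1]))
  expect_gt(acc0$weights[1], 0)

  # ties broken by row order
  acc_t <- abc_reject(c(1, 1, 1, 1), n_accept = 2)
  expect_identical(acc_t$index, c(1L, 2L))
})

test_that("acceptance sets are nested across tolerances", {
  set.seed(71)
  d <- runif(1000)
  for (i in 1:5) {
    t1 <- runif(1, 0.01, 0.5)
    t2 <- runif(1, t1, 1)
    a1 <- abc_reject(d, tolerance = t1)$index
    a2 <- abc_reject(d, tolerance = t2)$index
    expect_true(all(a1 %in% a2))
  }
})

test_that("weighted least squares matches the closed form on a 5-point toy", {
  x <- c(0, 1, 2, 3, 4)
  y <- c(1.2, 1.9, 3.1, 4.2, 4.8)
  w <- c(1, 2, 3, 2, 1)
  X <- cbind(1, x)
  beta_hand <- solve(t(X) %*% diag(w) %*% X, t(X) %*% (w * y))
  adj <- regression_adjust(matrix(y), matrix(x), observed = 2, weights = w,
                           transform = "none")
  # no hetero, no transform: adjusted = fit(2) + resid * inflation
  fitted <- drop(X %*% beta_hand)
  m_eff <- sum(w)^2 / sum(w^2)
  infl <- sqrt(m_eff / (m_eff - 2))
  expect_equal(drop(adj),
               drop(beta_hand[1] + 2 * beta_hand[2] + (y - fitted) * infl))
})

test_that("degenerate designs leave accepted values unadjusted", {
  y <- c(1, 2, 3, 4)
  # all accepted summaries identical to observed: constant design
  expect_warning(
    adj <- regression_adjust(matrix(y), matrix(rep(5, 4)), observed = 5,
                             weights = rep(1, 4), transform = "none"),
    "constant")
  expect_equal(drop(adj), y)
})

test_that("zero regression signal leaves the distribution unmoved", {
  set.seed(72)
  y <- rnorm(200)
  s <- matrix(rnorm(200), 200, 1)  # independent of y
  adj <- regression_adjust(matrix(y), s, observed = 0,
                           weights = rep(1, 200), transform = "none")
  expect_equal(mean(adj), mean(y), tolerance = 0.1)
  expect_equal(sd(adj), sd(y), tolerance = 0.1)
})

test_that("regression adjustment shrinks posterior spread toward truth", {
  # synthetic linear model: param = 2 s + noise, observed s known
  set.seed(73)
  wins <- replicate(200, {
    s <- rnorm(120)
    theta <- 2 * s + rnorm(120, sd = 0.3)
    s_obs <- 0.8
    adj <- regression_adjust(matrix(theta), matrix(s), observed = s_obs,
                             weights = rep(1, 120), transform = "none")
    c(var(adj) < var(theta), mean(adj))
  })
  expect_true(all(wins[1, ] == 1))
  # adjusted mean within 2 SE of the truth 2 * 0.8
  expect_lt(abs(mean(wins[2, ]) - 1.6), 2 * sd(wins[2, ]) / sqrt(200))
})

test_that("log transform rejects non-positive values with guidance", {
  expect_error(
    regression_adjust(matrix(c(-1, 1, 2, 5)), matrix(1:4), observed = 2,
                      weights = rep(1, 4), transform = "log"),
    "logit")
})

test_that("logit-adjusted draws never leave the prior bounds", {
  set.seed(74)
  for (i in 1:10) {
    m <- 50
    pars <- cbind(runif(m, 0, 50), runif(m, 0, 300), runif(m, 0, 2))
    s <- matrix(rnorm(m * 4), m, 4)
    obs <- rnorm(4, sd = 3)  # deliberately extrapolating
    adj <- regression_adjust(pars, s, obs, weights = runif(m),
                             transform = "logit",
                             prior_bounds = rbind(c(0, 50), c(0, 300),
                                                  c(0, 2)))
    expect_true(all(adj[, 1] > 0 & adj[, 1] < 50))
    expect_true(all(adj[, 2] > 0 & adj[, 2] < 300))
    expect_true(all(adj[, 3] > 0 & adj[, 3] < 2))
  }
})

test_that("heteroscedasticity correction rescales residual spread", {
  set.seed(75)
  m <- 400
  s <- runif(m, -1, 1)
  theta <- 1 + s + rnorm(m, sd = 0.1 + 0.5 * (s + 1))  # spread grows in s
  # observed at low-spread end: corrected draws should be tighter
  adj_h <- regression_adjust(matrix(theta), matrix(s), observed = -1,
                             weights = rep(1, m), transform = "none",
                             hetero_correction = TRUE)
  adj_p <- regression_adjust(matrix(theta), matrix(s), observed = -1,
                             weights = rep(1, m), transform = "none",
                             hetero_correction = FALSE)
  expect_lt(sd(adj_h), sd(adj_p))
})

test_that("posterior summaries behave on degenerate and known inputs", {
  expect_equal(summarize_posterior(rep(3, 10), prior_bounds = c(0, 10)),
               c(mode = 3, lower = 3, upper = 3))

  # normal draws: CI endpoints near +-1.96
  set.seed(76)
  x <- rnorm(100000)
  s <- summarize_posterior(x, prior_bounds = c(-10, 10))
  expect_equal(unname(s["lower"]), -1.96, tolerance = 0.05)
  expect_equal(unname(s["upper"]), 1.96, tolerance = 0.05)
  expect_lt(abs(s["mode"]), 0.1)

  # weights concentrated on one draw pull the mode onto it
  xx <- c(5, runif(50, 0, 10))
  ww <- c(1, rep(1e-8, 50))
  sm <- summarize_posterior(xx, ww, prior_bounds = c(0, 10))
  expect_equal(unname(sm["mode"]), 5, tolerance = 0.2)
})

test_that("abc_estimate returns finite estimates and nested structure", {
  tab <- make_table(2000, seed = 77)
  obs <- rnorm(26)
  res <- abc_estimate(obs, tab, tolerance = 0.05, method = "loclinear",
                      transform = "logit")
  expect_s3_class(res, "posterior_result")
  expect_identical(nrow(res$accepted_raw), 100L)
  expect_true(all(is.finite(as.matrix(res$summary[, 2:4]))))
  # rejection-only shares the same accepted set
  res_r <- abc_estimate(obs, tab, tolerance = 0.05, method = "rejection")
  expect_identical(res$accepted_index, res_r$accepted_index)
  expect_null(res_r$accepted_adjusted)
})
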