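# GY94 Gillespie evolution along genealogies.

test_that("theta = 0 leaves all sequences identical to the root draw", {
  set.seed(41)
  a <- sim_alignment(n = 6, L = 50, rho = 5, theta = 0)
  expect_true(all(a$codon == rep(a$codon[1, ], each = 6)))
})

test_that("mismatched genealogy and codon lengths are rejected", {
  set.seed(42)
  g <- simulate_arg(coalescent_config(4, 300, 0))
  p <- default_params(L = 50)
  expect_error(evolve_alignment(g, p), "does not match")
})

test_that("simulated alignments contain no stops, gaps or ambiguities", {
  set.seed(43)
  for (om in c(0, 1, 2)) {
    a <- sim_alignment(n = 6, L = 60, rho = 10, theta = 120, omega = om)
    expect_false(anyNA(a$codon))
    expect_false(anyNA(a$nt))
  }
})

test_that("low-rate pairwise divergence matches theta / L", {
  # two taxa, expected path length 2 E[T2] = 2, rate theta/(2L) per codon
  # site: expected pairwise codon differences per site = theta / L when
  # multiple hits are negligible
  set.seed(44)
  theta <- 3
  L <- 300
  p <- substitution_params(theta = theta, omega = 1, n_codons = L)
  d <- replicate(5000, {
    g <- simulate_arg(coalescent_config(2, 3 * L, 0))
    a <- evolve_alignment(g, p)
    mean(a$codon[1, ] != a$codon[2, ])
  })
  expect_equal(mean(d), theta / L, tolerance = 0.05)
})

test_that("Gillespie endpoint frequencies match the matrix exponential", {
  # independent oracle: scaling-and-squaring matrix exponential (ape)
  set.seed(45)
  p <- default_params(theta = 100, omega = 0.7, kappa = 2)
  q <- build_gy94_matrix(p)$q
  t_br <- 0.4
  start <- 5L
  nrep <- 50000L
  P <- ape::matexpo(q * t_br)
  ends <- coalcodon:::cpp_branch_endpoints(q, start, t_br, 1.0, nrep, 99L)
  emp <- tabulate(ends, 61) / nrep
  se <- sqrt(pmax(P[start, ] * (1 - P[start, ]), 1e-12) / nrep)
  expect_true(all(abs(emp - P[start, ]) <= 3.5 * se))
})

test_that("long-branch simulation preserves the stationary distribution", {
  set.seed(46)
  f <- stats::rgamma(61, 2)
  f <- f / sum(f)
  p <- substitution_params(theta = 10, omega = 0.8, kappa = 1.5,
                           codon_freqs = f, n_codons = 10)
  q <- build_gy94_matrix(p)$q
  nrep <- 30000L
  starts <- sample.int(61, nrep, replace = TRUE, prob = f)
  ends <- vapply(unique(starts), function(s) {
    idx <- starts == s
    list(coalcodon:::cpp_branch_endpoints(q, s, 8, 1.0, sum(idx),
                                          1000L + s))
  }, list(1))
  emp <- tabulate(unlist(ends), 61) / nrep
  se <- sqrt(f * (1 - f) / nrep)
  expect_true(all(abs(emp - f) <= 4.5 * se))
})

test_that("omega = 0 yields zero amino-acid segregating sites", {
  set.seed(47)
  a <- sim_alignment(n = 8, L = 100, rho = 20, theta = 150, omega = 0,
                     kappa = 0.5)
  expect_identical(segregating_sites(a, "aa"), 0L)
  expect_gt(segregating_sites(a, "codon"), 0L)
})

test_that("amino-acid variation increases with omega at fixed theta", {
  set.seed(48)
  mean_aa_seg <- vapply(c(0.1, 0.8, 2), function(om) {
    mean(replicate(800, segregating_sites(
      sim_alignment(n = 6, L = 60, rho = 0, theta = 40, omega = om),
      "aa")))
  }, numeric(1))
  expect_true(all(diff(mean_aa_seg) > 0))
})

test_that("intracodon modes agree when there is no recombination", {
  # with a single marginal tree both code paths simulate the same process
  set.seed(49)
  g <- simulate_arg(coalescent_config(10, 300, 0))
  p <- default_params(L = 100, theta = 80)
  d_nt <- replicate(300, mean(.pairwise_div_for_test(
    evolve_alignment(g, p, intracodon = "nucleotide"))))
  d_fp <- replicate(300, mean(.pairwise_div_for_test(
    evolve_alignment(g, p, intracodon = "first_position"))))
  expect_equal(mean(d_nt), mean(d_fp), tolerance = 0.02)
})

test_that("site-rate heterogeneity concentrates variation on fast sites", {
  set.seed(50)
  g <- simulate_arg(coalescent_config(12, 300, 0))
  p <- substitution_params(theta = 60, omega = 1, n_codons = 100,
                           gamma_shape = 0.2)
  rates <- assign_site_rates(p)
  a <- evolve_alignment(g, p, site_rates = rates)
  seg <- apply(a$codon, 2, function(x) length(unique(x)) > 1)
  # variable sites should have higher assigned rates on average
  expect_gt(mean(rates[seg]), mean(rates[!seg]))
})
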