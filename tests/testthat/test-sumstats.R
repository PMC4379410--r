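# The 26-statistic summary vector.

# build an alignment of identical codons with selected columns replaced
toy_codon_aln <- function(n, L, base = "ATG") {
  aln_from_strings(rep(paste(rep(base, L), collapse = ""), n))
}

test_that("monomorphic alignments give an all-zero summary vector", {
  a <- toy_codon_aln(6, 20)
  ss <- compute_summary_vector(a)
  expect_length(ss, 26)
  expect_identical(names(ss), summary_stat_names())
  expect_true(all(ss == 0))
})

test_that("summary vector equals the concatenation of its components", {
  set.seed(61)
  a <- sim_alignment(n = 8, L = 80, rho = 10, theta = 80, omega = 0.8)
  ss <- compute_summary_vector(a)
  expect_identical(unname(ss[1]), phi_statistic(a))
  expect_identical(unname(ss[2]), nss_statistic(a))
  expect_identical(unname(ss[3]), maxchi_statistic(a))
  expect_identical(unname(ss[4:7]), unname(diversity_moments(a, "codon")))
  expect_identical(unname(ss[8:11]), unname(diversity_moments(a, "aa")))
  expect_identical(unname(ss[12:15]),
                   unname(heterozygosity_moments(a, "codon")))
  expect_identical(unname(ss[16:19]),
                   unname(heterozygosity_moments(a, "aa")))
  expect_identical(unname(ss[20]), as.numeric(segregating_sites(a, "nt")))
  expect_identical(unname(ss[21]),
                   as.numeric(segregating_sites(a, "codon")))
  expect_identical(unname(ss[22]), as.numeric(segregating_sites(a, "aa")))
  expect_identical(unname(ss[23:26]), unname(joint_codon_aa_stats(a)))
})

test_that("all 26 statistics are invariant to sequence order", {
  set.seed(62)
  a <- sim_alignment(n = 10, L = 60, rho = 15, theta = 100, omega = 1)
  chars <- apply(matrix(c("A", "C", "G", "T")[a$nt], nrow(a$nt)), 1,
                 paste, collapse = "")
  for (i in 1:5) {
    perm <- sample(length(chars))
    expect_equal(compute_summary_vector(coding_alignment(chars[perm])),
                 compute_summary_vector(coding_alignment(chars)))
  }
})

test_that("PHI matches an exhaustive parsimony oracle on 6 taxa", {
  skip_if_not_installed("phangorn")
  # two engineered sites; extra steps over all trees = cycle rank
  s1 <- c("A", "A", "A", "G", "G", "G")
  s2 <- c("A", "G", "G", "A", "A", "G")
  pad <- rep("ATG", 6)  # invariant context codon
  seqs <- paste0(pad, s1, s2, "T")  # ATG + [s1 s2 T] codon = 2 codons
  a <- aln_from_strings(seqs)
  inf <- coalcodon:::.informative_nt_sites(a$nt)
  expect_length(inf, 2)

  # oracle: minimum extra steps needed on a shared tree, by enumeration
  states <- rbind(s1, s2)
  taxa <- t(states)
  rownames(taxa) <- as.character(seq_len(6))
  trees <- phangorn::allTrees(6, rooted = FALSE)
  dat <- phangorn::phyDat(taxa, type = "USER",
                          levels = c("A", "C", "G", "T"))
  joint_min <- min(vapply(trees, function(tr) {
    tr$tip.label <- as.character(seq_len(6))
    phangorn::parsimony(tr, dat)
  }, numeric(1)))
  single_min <- sum(apply(states, 1,
                          function(x) length(unique(x)) - 1))
  oracle_extra <- joint_min - single_min
  expect_identical(phi_statistic(a), as.numeric(oracle_extra))
})

test_that("compatible site pairs give PHI 0", {
  # two informative sites generated by one clean bipartition: compatible
  s1 <- c("A", "A", "A", "G", "G", "G")
  s2 <- c("C", "C", "C", "T", "T", "T")
  seqs <- paste0("ATG", s1, s2, "T")
  a <- aln_from_strings(seqs)
  expect_identical(phi_statistic(a), 0)
  expect_identical(nss_statistic(a), 1)
})

test_that("NSS matches hand enumeration on a 4-site toy", {
  # sites 1-4: (1,2) compatible, (2,3) incompatible, (3,4) compatible
  s1 <- c("A", "A", "A", "G", "G", "G")   # bipartition 123|456
  s2 <- c("C", "C", "C", "T", "T", "T")   # same bipartition -> compatible
  s3 <- c("A", "G", "G", "A", "A", "G")   # all four gametes vs s2
  s4 <- c("A", "T", "T", "A", "A", "T")   # same bipartition as s3
  seqs <- paste0(s1, s2, s3, s4, "TA")
  a <- aln_from_strings(seqs)
  inf <- coalcodon:::.informative_nt_sites(a$nt)
  expect_length(inf, 4)
  expect_equal(nss_statistic(a), 2 / 3)
})

test_that("single informative site gives sentinel 0 for PHI and NSS", {
  s1 <- c("A", "A", "A", "G", "G", "G")
  seqs <- paste0("ATG", s1, "TA")
  a <- aln_from_strings(seqs)
  expect_identical(phi_statistic(a), 0)
  expect_identical(nss_statistic(a), 0)
})

# independent R implementation of the MaxChi contract
maxchi_oracle <- function(aln, k = 30) {
  nt <- aln$nt
  n <- nrow(nt)
  poly <- which(apply(nt, 2, function(col)
    length(unique(col[!is.na(col)])) > 1))
  if (length(poly) < 2) return(0)
  best <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    x <- nt[i, poly]
    y <- nt[j, poly]
    ok <- !is.na(x) & !is.na(y)
    df <- ok & x != y
    for (m in seq_along(poly)[-1]) {  # breakpoint before poly site m
      left <- max(1, m - k):(m - 1)
      right <- m:min(length(poly), m + k - 1)
      dl <- sum(df[left]); nl <- sum(ok[left])
      dr <- sum(df[right]); nr <- sum(ok[right])
      tab <- rbind(c(dl, nl - dl), c(dr, nr - dr))
      if (any(colSums(tab) == 0) || nl == 0 || nr == 0) next
      e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      best <- max(best, sum((tab - e)^2 / e))
    }
  }
  best
}

test_that("MaxChi finds a hand-built mosaic and matches the oracle", {
  set.seed(63)
  L <- 100
  codA <- sample(sense_codons(), L, replace = TRUE)
  codB <- codA
  flip <- sample(L, 20)  # 20% codon divergence between the parents
  codB[flip] <- vapply(codB[flip], function(b)
    sample(setdiff(sense_codons(), b), 1), character(1))
  parentA <- strsplit(paste(codA, collapse = ""), "")[[1]]
  parentB <- strsplit(paste(codB, collapse = ""), "")[[1]]
  mosaic <- c(parentA[1:150], parentB[151:300])
  a <- coding_alignment(rbind(parentA, parentB, mosaic))
  uniform <- coding_alignment(rbind(parentA, parentB))

  mx <- maxchi_statistic(a)
  expect_equal(mx, maxchi_oracle(a), tolerance = 1e-12)
  expect_gt(mx, maxchi_statistic(uniform))  # mosaic beats plain divergence
})

test_that("identical sequences give MaxChi 0", {
  expect_identical(maxchi_statistic(toy_codon_aln(4, 30)), 0)
})

test_that("diversity moments match direct enumeration", {
  a0 <- toy_codon_aln(4, 10)
  expect_equal(unname(diversity_moments(a0, "codon")), rep(0, 4))

  # two sequences differing at 3 of 300 codons: mean 0.01, single pair
  base <- strsplit(paste(rep("ATG", 300), collapse = ""), "")[[1]]
  s2 <- base
  s2[c(3, 33, 63)] <- "A"  # ATG -> ATA (Met -> Ile) x 3 codons
  a <- coding_alignment(rbind(base, s2))
  dm <- diversity_moments(a, "codon")
  expect_equal(unname(dm), c(0.01, 0, 0, 0))

  # 4 sequences, hand-counted pairwise differences over 6 pairs
  v <- c("ATGATG", "ATGATA", "ATAATG", "ATAATA")
  a4 <- aln_from_strings(v)
  d <- coalcodon:::.pairwise_diversity(a4$codon)
  expect_equal(sort(d), sort(c(0.5, 0.5, 1, 1, 0.5, 0.5)))
  mm <- diversity_moments(a4, "codon")
  expect_equal(unname(mm[1]), mean(d))
  expect_equal(unname(mm[2]), sqrt(mean((d - mean(d))^2)))
})

test_that("heterozygosity uses the n/(n-1) correction", {
  # one codon site with two states 50:50 among 4 sequences
  a <- aln_from_strings(c("ATG", "ATG", "ATA", "ATA"))
  hm <- heterozygosity_moments(a, "codon")
  expect_equal(unname(hm[1]), (1 - 0.5) * 4 / 3)
  expect_equal(unname(hm[2]), 0)  # single site: sd over sites is 0
})

test_that("segregating sites respect the level hierarchy", {
  a0 <- toy_codon_aln(5, 10)
  for (lev in c("nt", "codon", "aa"))
    expect_identical(segregating_sites(a0, lev), 0L)

  # one synonymous third-position change: nt = 1, codon = 1, aa = 0
  a <- aln_from_strings(c("CTTATG", "CTCATG"))
  expect_identical(segregating_sites(a, "nt"), 1L)
  expect_identical(segregating_sites(a, "codon"), 1L)
  expect_identical(segregating_sites(a, "aa"), 0L)

  set.seed(64)
  for (i in 1:5) {
    s <- sim_alignment(n = 6, L = 40, rho = 5, theta = 60, omega = 0.5)
    expect_lte(segregating_sites(s, "aa"), segregating_sites(s, "codon"))
    expect_lte(segregating_sites(s, "codon"), segregating_sites(s, "nt"))
  }
})

test_that("joint codon/amino-acid statistics match hand enumeration", {
  a0 <- toy_codon_aln(4, 10)
  expect_equal(unname(joint_codon_aa_stats(a0)), rep(0, 4))

  # 2 synonymous-only variable codon sites + 1 nonsynonymous
  s1 <- c("CTT", "GGA", "ATG", "AAA")
  s2 <- c("CTC", "GGG", "ATG", "GAA")  # syn, syn, same, nonsyn
  a <- aln_from_strings(c(paste(s1, collapse = ""),
                          paste(s2, collapse = "")))
  js <- joint_codon_aa_stats(a)
  expect_identical(unname(js[2]), 2)
  expect_identical(unname(js[3]), 1)

  # omega = 0 style data: only synonymous variation
  set.seed(65)
  az <- sim_alignment(n = 8, L = 60, rho = 0, theta = 100, omega = 0)
  jz <- joint_codon_aa_stats(az)
  expect_identical(unname(jz[1]), 0)
  expect_identical(unname(jz[3]), 0)
})

test_that("gaps and ambiguities are excluded by pairwise deletion", {
  a <- coding_alignment(c("CTTATG", "CT-ATG", "CTNATG"))
  expect_true(anyNA(a$nt))
  expect_identical(segregating_sites(a, "nt"), 0L)
  expect_identical(segregating_sites(a, "codon"), 0L)
  d <- coalcodon:::.pairwise_diversity(a$codon)
  expect_equal(d, rep(0, 3))  # gap codon excluded for that sequence
})

test_that("observed alignments with in-frame stops are rejected", {
  expect_error(coding_alignment(c("ATGTAA", "ATGTAC")), "stop codons")
})

test_that("recombination statistics separate rho = 0 from rho = 30", {
  set.seed(66)
  sim_ss <- function(r) replicate(250, {
    a <- sim_alignment(n = 15, L = 100, rho = r, theta = 60, omega = 0.5,
                       kappa = 0.5)
    c(phi_statistic(a), nss_statistic(a), maxchi_statistic(a))
  })
  s0 <- sim_ss(0)
  s30 <- sim_ss(30)
  expect_gt(mean(s30[1, ]), mean(s0[1, ]))  # PHI rises with recombination
  expect_lt(mean(s30[2, ]), mean(s0[2, ]))  # NSS falls
  expect_gt(mean(s30[3, ]), mean(s0[3, ]))  # MaxChi rises
})

test_that("amino-acid/codon diversity ratio increases with omega", {
  set.seed(67)
  means <- vapply(c(0.2, 0.8, 1.8), function(om) {
    mean(replicate(250, joint_codon_aa_stats(
      sim_alignment(n = 8, L = 60, rho = 0, theta = 60, omega = om))[1]))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})
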