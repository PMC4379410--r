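# The 26-statistic summary vector.
#
# Canonical enumeration (frozen; names are the output contract):
#   3  recombination tests: phi, nss, maxchi
#   8  diversity moments: mean/sd/skew/kurt of pairwise diversity at the
#      codon then amino-acid level
#   8  heterozygosity moments: mean/sd/skew/kurt of per-site expected
#      heterozygosity at the codon then amino-acid level
#   3  segregating sites: nucleotide, codon, amino acid
#   4  joint codon/amino-acid statistics
# Degenerate inputs map to sentinel 0, never NaN, so the ABC distance is
# computable on every simulation.

PHI_WINDOW_NT <- 100L   # published default of the PHI test
MAXCHI_WINDOW <- 30L    # polymorphic sites per side, published default

.summary_names <- c(
  "phi", "nss", "maxchi",
  "div_cdn_mean", "div_cdn_sd", "div_cdn_skew", "div_cdn_kurt",
  "div_aa_mean", "div_aa_sd", "div_aa_skew", "div_aa_kurt",
  "het_cdn_mean", "het_cdn_sd", "het_cdn_skew", "het_cdn_kurt",
  "het_aa_mean", "het_aa_sd", "het_aa_skew", "het_aa_kurt",
  "seg_nt", "seg_cdn", "seg_aa",
  "aa_cdn_div_ratio", "var_syn_only", "var_both", "aa_cdn_seg_ratio")

#' Canonical names of the 26 summary statistics
#'
#' @return Character vector of length 26, in the order produced by
#'   [compute_summary_vector()].
#' @export
summary_stat_names <- function() .summary_names

# population moments of a numeric vector; skewness/kurtosis (excess) are
# sentinel 0 when the spread vanishes
.moments <- function(x) {
  if (length(x) == 0) return(c(0, 0, 0, 0))
  m <- mean(x)
  v <- mean((x - m)^2)
  s <- sqrt(v)
  if (s < 1e-12) return(c(m, 0, 0, 0))
  c(m, s, mean((x - m)^3) / s^3, mean((x - m)^4) / v^2 - 3)
}

# per-column state counts: K x ncol matrix, NA entries ignored
.col_state_counts <- function(m, K) {
  jj <- rep(seq_len(ncol(m)), each = nrow(m))
  ok <- !is.na(m)
  matrix(tabulate((jj[ok] - 1L) * K + m[ok], nbins = K * ncol(m)),
         nrow = K)
}

.pair_indices <- function(n) {
  i <- rep(seq_len(n - 1), times = (n - 1):1)
  j <- unlist(lapply(seq_len(n - 1), function(a) (a + 1):n))
  cbind(i, j)
}

.pairwise_diversity <- function(m) {
  n <- nrow(m)
  if (n < 2) return(numeric(0))
  pr <- .pair_indices(n)
  a <- m[pr[, 1], , drop = FALSE]
  b <- m[pr[, 2], , drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  d <- (a != b) & ok
  nok <- rowSums(ok)
  out <- rowSums(d) / pmax(nok, 1)
  out[nok == 0] <- 0
  out
}

.site_heterozygosity <- function(m, K) {
  cnt <- .col_state_counts(m, K)
  nv <- colSums(cnt)
  f2 <- colSums((cnt / rep(pmax(nv, 1), each = K))^2)
  h <- (1 - f2) * nv / pmax(nv - 1, 1)
  h[nv < 2] <- 0
  h
}

.segregating_cols <- function(m, K) {
  cnt <- .col_state_counts(m, K)
  colSums(cnt > 0) >= 2
}

.informative_nt_sites <- function(nt) {
  cnt <- .col_state_counts(nt, 4L)
  which(colSums(cnt >= 2) >= 2)
}

#' Pairwise homoplasy index (PHI)
#'
#' Mean refined incompatibility score — the cycle rank of the partition
#' intersection graph of observed joint states — over pairs of
#' parsimony-informative nucleotide sites within a window of
#' `window` nucleotides.  Lower values indicate less recombination.  The
#' raw statistic is returned, not a permutation p-value.
#'
#' @param alignment A [coding_alignment()].
#' @param window Maximum nucleotide distance between paired sites.
#' @return Numeric scalar; sentinel 0 for degenerate inputs.
#' @export
phi_statistic <- function(alignment, window = PHI_WINDOW_NT) {
  stopifnot(inherits(alignment, "coding_alignment"))
  inf <- .informative_nt_sites(alignment$nt)
  if (length(inf) < 2) return(0)
  snp <- alignment$nt[, inf, drop = FALSE]
  snp[is.na(snp)] <- 0L
  cpp_phi(snp - 1L, as.integer(inf), as.integer(window))
}

#' Neighbor similarity score (NSS)
#'
#' Fraction of adjacent parsimony-informative site pairs that are
#' compatible (refined incompatibility 0); 1 when the whole alignment is
#' consistent with a single tree, lower when incompatibilities are
#' interleaved along the sequence.
#'
#' @inheritParams phi_statistic
#' @return Numeric scalar in `[0, 1]`; sentinel 0 with fewer than two
#'   informative sites.
#' @export
nss_statistic <- function(alignment) {
  stopifnot(inherits(alignment, "coding_alignment"))
  inf <- .informative_nt_sites(alignment$nt)
  if (length(inf) < 2) return(0)
  snp <- alignment$nt[, inf, drop = FALSE]
  snp[is.na(snp)] <- 0L
  cpp_nss(snp - 1L)
}

#' Maximum chi-squared (MaxChi) recombination statistic
#'
#' Candidate breakpoints lie between consecutive polymorphic columns of
#' the alignment; for every sequence pair and breakpoint, a 2x2
#' chi-squared contrasts the pair's differences vs identities at the
#' `window` polymorphic sites on each side (truncated at the alignment
#' ends, pairwise deletion of missing data).  The maximum over all pairs
#' and breakpoints is returned; it grows when the local density of
#' pairwise differences shifts at a point, the signature of a mosaic
#' (recombinant) sequence.
#'
#' @inheritParams phi_statistic
#' @param window Window half-width in polymorphic sites.
#' @return Numeric scalar >= 0; 0 for identical sequences.
#' @export
maxchi_statistic <- function(alignment, window = MAXCHI_WINDOW) {
  stopifnot(inherits(alignment, "coding_alignment"))
  nt <- alignment$nt
  nt[is.na(nt)] <- 0L
  cpp_maxchi(nt - 1L, as.integer(window))
}

#' Moments of pairwise diversity
#'
#' Pairwise diversity is the proportion of differing sites per unordered
#' sequence pair at the codon or amino-acid level (pairwise deletion of
#' missing data).  Population formulas are used; skewness and excess
#' kurtosis are sentinel 0 when the standard deviation is 0.
#'
#' @inheritParams phi_statistic
#' @param level `"codon"` or `"aa"`.
#' @return Named numeric vector `(mean, sd, skew, kurt)`.
#' @export
diversity_moments <- function(alignment, level = c("codon", "aa")) {
  stopifnot(inherits(alignment, "coding_alignment"))
  level <- match.arg(level)
  m <- if (level == "codon") alignment$codon else alignment$aa
  out <- .moments(.pairwise_diversity(m))
  names(out) <- c("mean", "sd", "skew", "kurt")
  out
}

#' Moments of per-site expected heterozygosity
#'
#' Per-site expected heterozygosity is \eqn{(1 - \sum_a f_a^2) n/(n-1)}
#' over the observed state frequencies at that site (small-sample
#' correction applied), at the codon or amino-acid level; the four
#' population moments over sites are returned.
#'
#' @inheritParams diversity_moments
#' @return Named numeric vector `(mean, sd, skew, kurt)`.
#' @export
heterozygosity_moments <- function(alignment, level = c("codon", "aa")) {
  stopifnot(inherits(alignment, "coding_alignment"))
  level <- match.arg(level)
  m <- if (level == "codon") alignment$codon else alignment$aa
  K <- if (level == "codon") .cc$N_CODONS else length(.cc$AA_LETTERS)
  out <- .moments(.site_heterozygosity(m, K))
  names(out) <- c("mean", "sd", "skew", "kurt")
  out
}

#' Number of segregating sites
#'
#' Columns with two or more observed states at the requested level;
#' gap/ambiguity symbols are ignored when counting states.
#'
#' @inheritParams phi_statistic
#' @param level `"nt"`, `"codon"` or `"aa"`.
#' @return Integer count.
#' @export
segregating_sites <- function(alignment, level = c("nt", "codon", "aa")) {
  stopifnot(inherits(alignment, "coding_alignment"))
  level <- match.arg(level)
  sum(switch(level,
             nt = .segregating_cols(alignment$nt, 4L),
             codon = .segregating_cols(alignment$codon, .cc$N_CODONS),
             aa = .segregating_cols(alignment$aa,
                                    length(.cc$AA_LETTERS))))
}

#' Joint codon/amino-acid summary statistics
#'
#' Four statistics coupling variation at the codon and amino-acid levels:
#' the ratio of mean amino-acid to mean codon pairwise diversity, the
#' count of codon sites variable at the codon level but invariant at the
#' amino-acid level (synonymous-only variation), the count variable at
#' both levels, and the ratio of amino-acid to codon segregating-site
#' counts.  Ratios with zero denominator are sentinel 0.
#'
#' @inheritParams phi_statistic
#' @return Named numeric vector of length 4.
#' @export
joint_codon_aa_stats <- function(alignment) {
  stopifnot(inherits(alignment, "coding_alignment"))
  div_c <- mean(.pairwise_diversity(alignment$codon))
  div_a <- mean(.pairwise_diversity(alignment$aa))
  var_c <- .segregating_cols(alignment$codon, .cc$N_CODONS)
  var_a <- .segregating_cols(alignment$aa, length(.cc$AA_LETTERS))
  c(aa_cdn_div_ratio = if (div_c > 0) div_a / div_c else 0,
    var_syn_only = sum(var_c & !var_a),
    var_both = sum(var_c & var_a),
    aa_cdn_seg_ratio = if (sum(var_c) > 0) sum(var_a) / sum(var_c) else 0)
}

#' Compute the 26-statistic summary vector
#'
#' Concatenates, in the frozen canonical order given by
#' [summary_stat_names()]: the three recombination tests (PHI, NSS,
#' MaxChi), the four moments of pairwise diversity at codon then
#' amino-acid level, the four moments of per-site heterozygosity at codon
#' then amino-acid level, the segregating-site counts at nucleotide,
#' codon and amino-acid level, and the four joint codon/amino-acid
#' statistics.
#'
#' @inheritParams phi_statistic
#' @return Named numeric vector of length 26; all entries finite.
#' @export
compute_summary_vector <- function(alignment) {
  stopifnot(inherits(alignment, "coding_alignment"))
  out <- c(
    phi_statistic(alignment), nss_statistic(alignment),
    maxchi_statistic(alignment),
    diversity_moments(alignment, "codon"),
    diversity_moments(alignment, "aa"),
    heterozygosity_moments(alignment, "codon"),
    heterozygosity_moments(alignment, "aa"),
    segregating_sites(alignment, "nt"),
    segregating_sites(alignment, "codon"),
    segregating_sites(alignment, "aa"),
    joint_codon_aa_stats(alignment))
  names(out) <- .summary_names
  stopifnot(all(is.finite(out)))
  out
}
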