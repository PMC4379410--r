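# Internal lookup tables for the universal genetic code, built once at
# load time.  All codon machinery works over the 61 sense codons in
# lexicographic (A < C < G < T) order; the three stop codons have no row
# anywhere, so mutations into stops are structurally impossible.

.cc <- new.env(parent = emptyenv())

NT_LETTERS <- c("A", "C", "G", "T")

.build_codon_tables <- function() {
  g <- expand.grid(p3 = NT_LETTERS, p2 = NT_LETTERS, p1 = NT_LETTERS,
                   stringsAsFactors = FALSE)
  all64 <- paste0(g$p1, g$p2, g$p3)           # lexicographic order
  aa64 <- unname(Biostrings::GENETIC_CODE[all64])
  sense <- aa64 != "*"

  codons <- all64[sense]
  aa <- aa64[sense]
  aa_letters <- sort(unique(aa))

  codon_nt <- t(vapply(strsplit(codons, ""),
                       function(x) match(x, NT_LETTERS), integer(3)))

  # nt triplet (1..4 each) -> sense codon index, NA for stops
  nt2codon <- rep(NA_integer_, 64)
  key <- (codon_nt[, 1] - 1L) * 16L + (codon_nt[, 2] - 1L) * 4L +
    (codon_nt[, 3] - 1L) + 1L
  nt2codon[key] <- seq_along(codons)

  # ordered single-nucleotide-neighbour codon pairs with change annotations
  pair_i <- integer(0); pair_j <- integer(0)
  pair_ts <- logical(0); pair_ns <- logical(0)
  K <- length(codons)
  for (p in 1:3) {
    for (i in seq_len(K)) {
      for (to in 1:4) {
        if (to == codon_nt[i, p]) next
        trip <- codon_nt[i, ]
        trip[p] <- to
        j <- nt2codon[(trip[1] - 1L) * 16L + (trip[2] - 1L) * 4L + trip[3]]
        if (is.na(j)) next
        pair_i <- c(pair_i, i); pair_j <- c(pair_j, j)
        from <- codon_nt[i, p]
        pair_ts <- c(pair_ts, (from == 1 && to == 3) || (from == 3 && to == 1) ||
                       (from == 2 && to == 4) || (from == 4 && to == 2))
        pair_ns <- c(pair_ns, aa[i] != aa[j])
      }
    }
  }
  assign("GY_PAIRS", list(i = pair_i, j = pair_j, ts = pair_ts, ns = pair_ns),
         envir = .cc)

  assign("CODONS", codons, envir = .cc)
  assign("N_CODONS", length(codons), envir = .cc)
  assign("CODON_AA_CHAR", aa, envir = .cc)
  assign("AA_LETTERS", aa_letters, envir = .cc)
  assign("CODON_AA", match(aa, aa_letters), envir = .cc)
  assign("CODON_NT", codon_nt, envir = .cc)
  assign("NT2CODON", nt2codon, envir = .cc)
}

.onLoad <- function(libname, pkgname) {
  .build_codon_tables()
}

#' Sense codons of the universal genetic code
#'
#' @return Character vector of the 61 sense codons in lexicographic order;
#'   this is the state order used by [build_gy94_matrix()] and by codon
#'   views of alignments.
#' @export
sense_codons <- function() .cc$CODONS

.codon_aa_index <- function() .cc$CODON_AA

.stop_codons <- function() {
  setdiff(apply(expand.grid(NT_LETTERS, NT_LETTERS, NT_LETTERS)[, 3:1], 1,
                paste0, collapse = ""),
          .cc$CODONS)
}
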