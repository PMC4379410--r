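# Coding alignment container: nucleotide, codon and amino-acid views.
#
# Canonical storage is an integer nucleotide matrix (n x 3L, values 1..4
# for A,C,G,T, NA for gaps/ambiguities) plus cached codon and amino-acid
# integer views.  Simulated alignments are clean; observed alignments may
# contain gaps/ambiguities, which are excluded from state counts and
# pairwise comparisons (pairwise deletion), and a codon site containing
# any non-ACGT symbol in a sequence is NA for that sequence at the codon
# and amino-acid levels.

.codon_view_from_nt <- function(nt_int) {
  n <- nrow(nt_int)
  L <- ncol(nt_int) %/% 3L
  p1 <- nt_int[, seq(1, 3 * L, by = 3), drop = FALSE]
  p2 <- nt_int[, seq(2, 3 * L, by = 3), drop = FALSE]
  p3 <- nt_int[, seq(3, 3 * L, by = 3), drop = FALSE]
  key <- (p1 - 1L) * 16L + (p2 - 1L) * 4L + p3
  cod <- matrix(.cc$NT2CODON[key], n, L)
  cod
}

.new_coding_alignment <- function(nt_int, labels, validate_stops = TRUE) {
  n <- nrow(nt_int)
  if (n < 1) stop("alignment has no sequences")
  if (ncol(nt_int) %% 3 != 0)
    stop("alignment length must be a multiple of 3")
  codon <- .codon_view_from_nt(nt_int)
  if (validate_stops) {
    # distinguish stop codons (all three nt observed, no sense codon) from
    # codons that are NA because of gaps/ambiguities
    L <- ncol(codon)
    complete <- matrix(TRUE, n, L)
    for (p in 1:3) {
      idx <- seq(p, 3 * L, by = 3)
      complete <- complete & !is.na(nt_int[, idx, drop = FALSE])
    }
    if (any(complete & is.na(codon)))
      stop("alignment contains in-frame stop codons")
  }
  aa <- matrix(.cc$CODON_AA[codon], nrow(codon), ncol(codon))
  structure(list(nt = nt_int, codon = codon, aa = aa,
                 labels = labels, n_codons = ncol(codon)),
            class = "coding_alignment")
}

#' Construct a coding alignment from character data
#'
#' @param x Character matrix (n sequences x l nucleotides) or a character
#'   vector of equal-length sequences; symbols other than A/C/G/T
#'   (case-insensitive) are treated as missing.
#' @param labels Sequence identifiers; defaults to names or `seq_1 ...`.
#' @return Object of class `"coding_alignment"` with fields `nt`, `codon`
#'   and `aa` (integer state matrices, NA = missing) and `labels`.
#' @export
coding_alignment <- function(x, labels = NULL) {
  if (is.character(x) && is.null(dim(x))) {
    if (is.null(labels)) labels <- names(x)
    x <- do.call(rbind, strsplit(toupper(x), ""))
  } else if (is.matrix(x) && is.character(x)) {
    x <- matrix(toupper(x), nrow(x), ncol(x), dimnames = dimnames(x))
    if (is.null(labels)) labels <- rownames(x)
  } else {
    stop("x must be a character matrix or vector of sequences")
  }
  if (is.null(labels)) labels <- paste0("seq_", seq_len(nrow(x)))
  nt_int <- matrix(match(x, NT_LETTERS), nrow(x), ncol(x))
  .new_coding_alignment(nt_int, labels)
}

#' @export
print.coding_alignment <- function(x, ...) {
  cat(sprintf("Coding alignment: %d sequences x %d codons (%d nt)\n",
              nrow(x$nt), x$n_codons, ncol(x$nt)))
  invisible(x)
}

#' @rdname coding_alignment
#' @param aln A `"coding_alignment"`.
#' @export
codon_view <- function(aln) {
  stopifnot(inherits(aln, "coding_alignment"))
  m <- matrix(.cc$CODONS[aln$codon], nrow(aln$codon), ncol(aln$codon))
  rownames(m) <- aln$labels
  m
}

#' @rdname coding_alignment
#' @export
aa_view <- function(aln) {
  stopifnot(inherits(aln, "coding_alignment"))
  m <- matrix(.cc$AA_LETTERS[aln$aa], nrow(aln$aa), ncol(aln$aa))
  rownames(m) <- aln$labels
  m
}

.nt_char_matrix <- function(aln) {
  m <- matrix(NT_LETTERS[aln$nt], nrow(aln$nt), ncol(aln$nt))
  m[is.na(m)] <- "N"
  rownames(m) <- aln$labels
  m
}

#' Read a protein-coding alignment
#'
#' Reads FASTA or sequential PHYLIP via \pkg{ape}, validates the coding
#' frame (length a multiple of 3, no in-frame stop codons) and returns a
#' [coding_alignment()].
#'
#' @param path File path.
#' @param format `"fasta"` or `"phylip"` (sequential); default guesses
#'   from the file extension.
#' @return A `"coding_alignment"`.
#' @export
read_coding_alignment <- function(path, format = c("auto", "fasta",
                                                   "phylip")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(phy|phylip)$", path, ignore.case = TRUE))
      "phylip" else "fasta"
  }
  dna <- if (format == "fasta") {
    ape::read.dna(path, format = "fasta", as.character = TRUE,
                  as.matrix = TRUE)
  } else {
    ape::read.dna(path, format = "sequential", as.character = TRUE)
  }
  coding_alignment(matrix(toupper(dna), nrow(dna), ncol(dna),
                          dimnames = dimnames(dna)),
                   labels = rownames(dna))
}

#' Write a coding alignment
#'
#' @param aln A `"coding_alignment"`.
#' @param path Output path.
#' @param format `"fasta"` (default) or `"phylip"` (sequential).
#' @param params Optional [substitution_params()] or parameter draw; when
#'   given, written as a tab-separated `#`-header sidecar
#'   `<path>.params.tsv` (never inside the alignment file).
#' @return Invisibly, `path`.
#' @export
write_coding_alignment <- function(aln, path, format = c("fasta", "phylip"),
                                   params = NULL) {
  stopifnot(inherits(aln, "coding_alignment"))
  format <- match.arg(format)
  m <- tolower(.nt_char_matrix(aln))
  dna <- ape::as.DNAbin(m)
  if (format == "fasta") {
    ape::write.dna(dna, path, format = "fasta", colsep = "")
  } else {
    ape::write.dna(dna, path, format = "sequential", colsep = "",
                   nbcol = -1)
  }
  if (!is.null(params)) {
    flat <- unlist(params)
    writeLines(c(paste0("# ", paste(names(flat), collapse = "\t")),
                 paste(unname(flat), collapse = "\t")),
               paste0(path, ".params.tsv"))
  }
  invisible(path)
}
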