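# Neutral constant-size coalescent with recombination: configuration,
# simulation wrapper and marginal-tree access.

#' Configuration for a coalescent-with-recombination simulation
#'
#' @param n_samples Number of sampled haploid sequences (>= 2).
#' @param l_nt Alignment length in nucleotides (>= 3 and a multiple of 3).
#' @param rho Population-scaled recombination rate \eqn{\rho = 4Nrl} for
#'   the whole alignment (N effective population size, r per-nucleotide
#'   recombination rate, l nucleotide length); >= 0.
#' @param effective_size_N Effective population size; bookkeeping only,
#'   since internal time is measured in units of 2N generations.
#' @param seed Optional integer seed for the simulation; if `NULL`, a seed
#'   is drawn from the R random number stream at simulation time.
#' @return Object of class `"coalescent_config"`.
#' @export
coalescent_config <- function(n_samples, l_nt, rho, effective_size_N = 1000,
                              seed = NULL) {
  if (!is.numeric(n_samples) || n_samples < 2)
    stop("n_samples must be an integer >= 2")
  if (!is.numeric(l_nt) || l_nt < 3 || l_nt %% 3 != 0)
    stop("l_nt must be >= 3 and divisible by 3")
  if (!is.numeric(rho) || rho < 0)
    stop("rho must be non-negative")
  structure(list(n_samples = as.integer(n_samples), l_nt = as.integer(l_nt),
                 rho = rho, effective_size_N = as.integer(effective_size_N),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "coalescent_config")
}

.draw_seed <- function() sample.int(.Machine$integer.max - 1L, 1L)

#' Simulate an ancestral recombination graph
#'
#' Runs the neutral constant-size coalescent with recombination backward
#' in time (Hudson scaling: time in units of 2N generations, pairwise
#' coalescence rate 1, recombination rate \eqn{\rho/2} per lineage with a
#' fully active span).  Breakpoints fall on nucleotide boundaries drawn
#' uniformly over each lineage's recombinationally active span, so
#' intracodon breakpoints occur.  Material that has reached its marginal
#' MRCA stops contributing recombination rate; the process continues until
#' a single lineage remains so that the full event graph is available for
#' sequence simulation.
#'
#' @param config A [coalescent_config()].
#' @return Object of class `"genealogy_set"` with elements `breakpoints`
#'   (nucleotide positions splitting `[0, l_nt)` into segments, 0-based
#'   half-open convention), `segments` (data frame with columns `a`, `b`,
#'   `root`), `n_recomb_events`, and the internal tree-node and event
#'   tables used by [evolve_alignment()].
#' @export
simulate_arg <- function(config) {
  stopifnot(inherits(config, "coalescent_config"))
  seed <- if (is.null(config$seed)) .draw_seed() else config$seed
  arg <- cpp_simulate_arg(config$n_samples, config$l_nt, config$rho, seed)
  arg$segments <- data.frame(a = arg$seg_a, b = arg$seg_b,
                             root = arg$seg_root)
  arg$breakpoints <- if (length(arg$seg_a) > 1) arg$seg_a[-1] else integer(0)
  arg$n_recomb_events <- arg$n_recomb
  arg$config <- config
  class(arg) <- "genealogy_set"
  arg
}

#' @export
print.genealogy_set <- function(x, ...) {
  cat(sprintf(
    "Coalescent genealogies: %d samples, %d nt, rho = %g\n", x$n, x$l_nt,
    x$rho))
  cat(sprintf("  %d marginal tree(s), %d recombination event(s)\n",
              nrow(x$segments), x$n_recomb_events))
  invisible(x)
}

.tree_as_phylo <- function(gen, root) {
  n <- gen$n
  tn_left <- gen$tn_left
  tn_right <- gen$tn_right
  tn_time <- gen$tn_time

  # collect internal nodes in preorder from the root
  internal <- integer(0)
  stack <- root
  while (length(stack)) {
    node <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (tn_left[node + 1] < 0) next
    internal <- c(internal, node)
    stack <- c(stack, tn_left[node + 1], tn_right[node + 1])
  }
  if (length(internal) != n - 1)
    stop("internal error: marginal tree is not a binary tree on n tips")

  # ape numbering: tips 1..n, root n+1, internals follow preorder
  idx <- integer(length(tn_time))
  idx[seq_len(n)] <- seq_len(n)          # tips (0-based ids 0..n-1)
  idx[internal + 1] <- n + seq_along(internal)

  edge <- matrix(0L, 2 * (n - 1), 2)
  elen <- numeric(2 * (n - 1))
  r <- 0
  for (node in internal) {
    for (ch in c(tn_left[node + 1], tn_right[node + 1])) {
      r <- r + 1
      edge[r, ] <- c(idx[node + 1], idx[ch + 1])
      elen[r] <- tn_time[node + 1] - tn_time[ch + 1]
    }
  }
  phy <- structure(list(edge = edge, edge.length = elen,
                        tip.label = as.character(seq_len(n) - 1L),
                        Nnode = n - 1L),
                   class = "phylo", order = "cladewise")
  phy
}

#' Extract the marginal tree governing a nucleotide position
#'
#' @param genealogies A `"genealogy_set"` from [simulate_arg()].
#' @param nt_position 0-based nucleotide position in `[0, l_nt)`; under
#'   the half-open segment convention, a breakpoint at b separates
#'   position b - 1 (left tree) from position b (right tree).
#' @return An [ape::as.phylo] tree with tips labelled `"0" ... "n-1"` and
#'   branch lengths in coalescent units (2N generations).
#' @export
marginal_tree_at <- function(genealogies, nt_position) {
  stopifnot(inherits(genealogies, "genealogy_set"))
  if (!is.numeric(nt_position) || nt_position < 0 ||
      nt_position >= genealogies$l_nt)
    stop("nt_position out of range [0, l_nt)")
  seg <- findInterval(nt_position, genealogies$seg_a)
  .tree_as_phylo(genealogies, genealogies$seg_root[seg])
}

#' All marginal trees of a genealogy set
#'
#' @param genealogies A `"genealogy_set"`.
#' @return List of [ape::as.phylo] trees, one per non-recombining segment,
#'   in left-to-right segment order.
#' @export
marginal_trees <- function(genealogies) {
  stopifnot(inherits(genealogies, "genealogy_set"))
  lapply(genealogies$seg_root, function(r) .tree_as_phylo(genealogies, r))
}

#' Write marginal trees as Newick, one per line
#'
#' Each line is prefixed with the half-open nucleotide range of the
#' segment as a Newick comment, e.g. `[0,300)`.
#'
#' @param genealogies A `"genealogy_set"`.
#' @param file Output path or connection.
#' @return Invisibly, the character vector written.
#' @export
write_newick_segments <- function(genealogies, file) {
  trees <- marginal_trees(genealogies)
  lines <- vapply(seq_along(trees), function(i) {
    paste0(sprintf("[%d,%d)", genealogies$seg_a[i], genealogies$seg_b[i]),
           ape::write.tree(trees[[i]]))
  }, character(1))
  writeLines(lines, file)
  invisible(lines)
}
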