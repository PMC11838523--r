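#' Draw an ancestral codon sequence
#'
#' i.i.d. draw of sense codons from the given codon frequencies.
#'
#' @param codon_freqs Named numeric vector over sense codons (sums to 1).
#' @param length Number of codons (0 allowed).
#' @param code A `genetic_code`.
#' @return Integer vector of positions in [all_codons()].
#' @export
ancestral_sequence <- function(codon_freqs, length, code = genetic_code()) {
  stopifnot(abs(sum(codon_freqs) - 1) < 1e-6)
  if (!all(names(codon_freqs) %in% code$sense)) {
    stop("frequencies must be over sense codons")
  }
  if (length == 0L) return(integer(0))
  drawn <- sample(names(codon_freqs), length, replace = TRUE,
                  prob = codon_freqs)
  match(drawn, all_codons())
}

#' Simulate a codon alignment along a tree (parametric Markov simulation)
#'
#' Root codons are drawn i.i.d. from the stationary distribution of the
#' rate matrix; each branch applies the transition kernel `exp(Q t)`.
#' Deterministic given the RNG state (call `set.seed()` first).
#'
#' @param rates A [codon_rate_matrix()].
#' @param tree An `ape::phylo` with branch lengths (substitutions per
#'   nucleotide site).
#' @param sites Number of codon sites.
#' @param code A `genetic_code`.
#' @return A `codon_alignment` over the tree's tips.
#' @export
simulate_alignment <- function(rates, tree, sites, code = genetic_code()) {
  stopifnot(inherits(rates, "codon_rate_matrix"), sites >= 1L)
  tree <- stats::reorder(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnodes <- ntip + tree$Nnode
  n <- nrow(rates$Q)
  states <- matrix(NA_integer_, nnodes, sites)
  root <- ntip + 1L
  states[root, ] <- sample.int(n, sites, replace = TRUE,
                               prob = rates$stationary)
  # walk edges root-down (reverse postorder)
  for (e in rev(seq_len(nrow(tree$edge)))) {
    parent <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    P <- transition_matrix(rates, tree$edge.length[e])
    ps <- states[parent, ]
    cs <- integer(sites)
    for (s in unique(ps)) {
      idx <- which(ps == s)
      cs[idx] <- sample.int(n, length(idx), replace = TRUE, prob = P[s, ])
    }
    states[child, ] <- cs
  }
  sense_idx <- match(code$sense, all_codons())
  m <- matrix(code$sense[states[seq_len(ntip), , drop = FALSE]], ntip,
              dimnames = list(tree$tip.label, NULL))
  codon_alignment(m, code)
}

#' Random gene trees for synthetic data
#'
#' Wraps [ape::rtree()] with exponential-ish branch lengths rescaled to a
#' target total tree length, giving fixtures the shape of typical gene
#' trees.
#'
#' @param ntaxa Number of tips.
#' @param tree_length Total branch length (expected substitutions per
#'   nucleotide site summed over branches).
#' @return An `ape::phylo`.
#' @export
random_gene_tree <- function(ntaxa, tree_length = 1.0) {
  tr <- ape::rtree(ntaxa, tip.label = paste0("t", seq_len(ntaxa)))
  tr$edge.length <- stats::rexp(length(tr$edge.length))
  tr$edge.length <- tr$edge.length / sum(tr$edge.length) * tree_length
  tr
}
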