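# Likelihood engine: pairs a codon alignment with a tree, compressing sites
# to patterns and laying out tip states for the compiled pruning kernel.
.make_engine <- function(aln, tree, code = genetic_code()) {
  stopifnot(inherits(aln, "codon_alignment"), inherits(tree, "phylo"))
  if (!all(tree$tip.label %in% aln$names)) {
    stop("tree tip labels missing from alignment: ",
         paste(setdiff(tree$tip.label, aln$names), collapse = ", "))
  }
  tree <- stats::reorder(tree, "postorder")
  sense_idx <- match(code$sense, all_codons())
  idx <- aln$codon_idx[tree$tip.label, , drop = FALSE]
  states <- matrix(match(idx, sense_idx), nrow(idx))  # NA stays NA
  states[is.na(states)] <- 0L
  key <- apply(states, 2, paste, collapse = ",")
  uk <- !duplicated(key)
  pattern <- states[, uk, drop = FALSE]
  wt <- as.numeric(table(factor(key, levels = key[uk])))
  list(tree = tree, edge = tree$edge, ntip = length(tree$tip.label),
       nnode = tree$Nnode, tipdata = pattern, wt = wt,
       n_sites = aln$n_sites, n_seq = length(tree$tip.label))
}

.engine_loglik <- function(eng, rates, lens = NULL, scale = 1) {
  if (is.null(lens)) lens <- eng$tree$edge.length
  if (is.null(lens)) stop("tree has no branch lengths")
  .cpp_pruning_loglik(rates$Q, pmax(rates$stationary, 1e-12),
                      eng$edge, lens * scale, eng$tipdata, eng$wt,
                      eng$nnode)
}

#' Phylogenetic log-likelihood of a codon alignment
#'
#' Felsenstein pruning under an MSS codon rate matrix, with independent
#' sites, missing codons fully marginalized, and the stationary distribution
#' at the root (root placement is immaterial for the reversible model).
#'
#' @param aln A `codon_alignment`.
#' @param tree An `ape::phylo` with branch lengths in expected substitutions
#'   per nucleotide site; tip labels must be a subset of the alignment names.
#' @param rates A [codon_rate_matrix()].
#' @param code The `genetic_code` the rate matrix was built with.
#' @return Log-likelihood (may be `-Inf` for impossible configurations).
#' @export
phylo_likelihood <- function(aln, tree, rates, code = genetic_code()) {
  eng <- .make_engine(aln, tree, code)
  .engine_loglik(eng, rates)
}
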