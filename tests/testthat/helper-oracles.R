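# Exhaustive ancestral-state enumeration oracle: sums the site likelihood
# over every assignment of internal-node states. Vectorized over the
# internal-state grid so trees with up to 3 internal codon nodes stay fast.
brute_force_loglik <- function(aln, tree, rates, code = universal) {
  tree <- stats::reorder(tree, "postorder")
  ntip <- length(tree$tip.label)
  ni <- tree$Nnode
  Pm <- lapply(tree$edge.length, function(t) transition_matrix(rates, t))
  sense <- code$sense
  n <- length(sense)
  idx <- matrix(match(as.character(aln), sense), length(aln$names),
                dimnames = list(aln$names, NULL))
  idx <- idx[tree$tip.label, , drop = FALSE]
  grid <- as.matrix(expand.grid(rep(list(seq_len(n)), ni)))
  pi <- unname(rates$stationary)
  total <- 0
  for (s in seq_len(aln$n_sites)) {
    states_of <- function(node) {
      if (node <= ntip) rep(idx[node, s], nrow(grid))
      else grid[, node - ntip]
    }
    p <- pi[grid[, 1]]  # root = ntip + 1 maps to grid column 1
    for (e in seq_len(nrow(tree$edge))) {
      p <- p * Pm[[e]][cbind(states_of(tree$edge[e, 1]),
                             states_of(tree$edge[e, 2]))]
    }
    total <- total + log(sum(p))
  }
  total
}
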