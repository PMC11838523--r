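# Shared fixtures for the test suite. Everything is generated in code; the
# sizes are kept small so the default run stays fast.

universal <- genetic_code()

# A deterministic positional frequency matrix (rows sum to 1).
fix_freqs <- function(seed = 5) {
  set.seed(seed)
  pf <- matrix(stats::rgamma(12, shape = 6), 3, 4)
  pf <- pf / rowSums(pf)
  dimnames(pf) <- list(paste0("pos", 1:3), c("A", "C", "G", "T"))
  structure(pf, class = c("positional_freq", "matrix"), source = "CF3x4")
}

uniform_freqs <- function() {
  structure(matrix(0.25, 3, 4,
                   dimnames = list(paste0("pos", 1:3),
                                   c("A", "C", "G", "T"))),
            class = c("positional_freq", "matrix"), source = "CF3x4")
}

fix_theta <- function() {
  nuc_rates(AC = 0.5, AT = 0.3, CG = 0.45, CT = 1.4, GT = 0.3)
}

# Small simulated gene: alignment + tree under a given spec.
fix_gene <- function(seed = 1, ntaxa = 6, codons = 80,
                     spec = mss_spec("standard", beta = 0.25),
                     tree_length = 1.0) {
  set.seed(seed)
  tr <- random_gene_tree(ntaxa, tree_length)
  rates <- codon_rate_matrix(spec, fix_theta(), fix_freqs(), universal)
  list(alignment = simulate_alignment(rates, tr, codons, universal),
       tree = tr)
}

# A restricted genetic code with 9 sense codons across 4 amino acids
# (Lys, Phe, Glu, Ile): D = 6 synonymous pairs, small enough to enumerate
# every rate partition exhaustively.
restricted_code <- function() {
  restrict_genetic_code(universal, c("AAA", "AAG", "TTT", "TTC",
                                     "GAA", "GAG", "ATT", "ATC", "ATA"))
}

fast_fit <- fit_options(multistart = 1L, iter_max = 50L, outer_tol = 1e-4,
                        outer_max = 5L)
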