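# One-step substitution structure of a genetic code: for every ordered pair
# of sense codons differing at exactly one position, the exchanged
# nucleotides, the position, and (if synonymous) the pair index. Cached per
# code name since it is pure combinatorics.
.code_structure <- function(code) {
  key <- paste0("struct_", code$name)
  if (!is.null(.code_cache[[key]]) && identical(code$name, "universal")) {
    return(.code_cache[[key]])
  }
  sense <- code$sense
  pairs <- synonymous_pairs(code)
  nt <- c("A", "C", "G", "T")
  from <- integer(0); to <- integer(0); pos <- integer(0)
  tnuc <- integer(0); thix <- integer(0); syn <- logical(0); pid <- integer(0)
  theta_names <- c("AC", "AG", "AT", "CG", "CT", "GT")
  for (i in seq_along(sense)) {
    nb <- codon_neighbors(sense[i], code, sense_only = TRUE)
    if (nrow(nb) == 0L) next
    j <- match(nb$codon, sense)
    p <- nb$position
    n_from <- substr(rep(sense[i], nrow(nb)), p, p)
    n_to <- substr(nb$codon, p, p)
    from <- c(from, rep(i, nrow(nb))); to <- c(to, j); pos <- c(pos, p)
    tnuc <- c(tnuc, match(n_to, nt))
    thix <- c(thix, match(.theta_key(n_from, n_to), theta_names))
    syn <- c(syn, nb$synonymous)
    key_pair <- ifelse(sense[i] < nb$codon,
                       paste(sense[i], nb$codon, sep = ":"),
                       paste(nb$codon, sense[i], sep = ":"))
    pid <- c(pid, ifelse(nb$synonymous, match(key_pair, pairs$pair),
                         NA_integer_))
  }
  st <- list(n = length(sense), sense = sense, from = from, to = to,
             pos = pos, target_nuc = tnuc, theta_idx = thix,
             synonymous = syn, pair_idx = pid, n_pairs = nrow(pairs))
  if (identical(code$name, "universal")) .code_cache[[key]] <- st
  st
}

#' Build an MSS codon rate matrix
#'
#' Assembles the instantaneous generator over the sense codons of the code.
#' For a one-nucleotide change from codon x to codon y at position p that
#' exchanges nucleotides n and m (target m):
#' synonymous entries are `alpha(x,y) * theta_nm * pi_pm`, nonsynonymous
#' entries are `beta * theta_nm * pi_pm`, and multi-nucleotide changes have
#' rate 0. Substitutions into stop codons are excluded by construction
#' (stops are outside the state space). The diagonal is set to minus the row
#' sum and, when `scale = TRUE`, the matrix is divided by (expected
#' substitutions per codon at stationarity) / 3 so that branch lengths are
#' measured in expected substitutions per nucleotide site.
#'
#' @param spec An [mss_spec()].
#' @param theta A [nuc_rates()] vector.
#' @param freqs A `positional_freq` matrix (CF3x4-corrected for inference).
#' @param code A `genetic_code`.
#' @param scale Apply the per-nucleotide-site scaling convention.
#' @return An object of class `codon_rate_matrix`: list with `Q` (n x n
#'   generator over sense codons), `stationary` (product codon frequencies),
#'   and `scale_factor` (expected substitutions per nucleotide site per unit
#'   time of the unscaled generator; 1 when `scale = FALSE`).
#' @export
codon_rate_matrix <- function(spec, theta = nuc_rates(), freqs,
                              code = genetic_code(), scale = TRUE) {
  stopifnot(inherits(spec, "mss_spec"))
  st <- .code_structure(code)
  if (st$n_pairs != nrow(spec$pairs)) {
    stop("spec pair universe does not match code")
  }
  pim <- unclass(freqs)
  alpha_pair <- spec$alpha[spec$class_of]
  rate <- numeric(length(st$from))
  rate[st$synonymous] <- alpha_pair[st$pair_idx[st$synonymous]]
  rate[!st$synonymous] <- spec$beta
  q <- rate * unclass(theta)[st$theta_idx] *
    pim[cbind(st$pos, st$target_nuc)]
  Q <- matrix(0, st$n, st$n, dimnames = list(st$sense, st$sense))
  Q[cbind(st$from, st$to)] <- q
  diag(Q) <- -rowSums(Q)
  pi <- .product_codon_freqs(pim, code)
  scale_factor <- 1
  if (scale) {
    per_codon <- -sum(pi * diag(Q))
    if (per_codon <= 0) stop("degenerate generator: zero total rate")
    scale_factor <- per_codon / 3
    Q <- Q / scale_factor
  }
  structure(list(Q = Q, stationary = pi, scale_factor = scale_factor,
                 code_name = code$name),
            class = "codon_rate_matrix")
}

#' @export
print.codon_rate_matrix <- function(x, ...) {
  cat("Codon rate matrix:", nrow(x$Q), "states; scale factor",
      signif(x$scale_factor, 4), "\n")
  invisible(x)
}

#' Transition probability matrix exp(Q t)
#'
#' Uses the symmetrized eigendecomposition available for reversible
#' generators. Small negative entries from round-off are clamped to 0 and
#' rows renormalized.
#'
#' @param rates A `codon_rate_matrix`.
#' @param t Branch length (expected substitutions per nucleotide site).
#' @return Stochastic matrix of transition probabilities.
#' @export
transition_matrix <- function(rates, t) {
  stopifnot(inherits(rates, "codon_rate_matrix"), t >= 0)
  n <- nrow(rates$Q)
  if (t == 0) return(diag(n))
  pi <- pmax(rates$stationary, 1e-12)
  sq <- sqrt(pi)
  S <- rates$Q * (sq %o% (1 / sq))
  S <- (S + t(S)) / 2
  es <- eigen(S, symmetric = TRUE)
  P <- (1 / sq) * (es$vectors %*% (exp(es$values * t) * t(es$vectors))) *
    rep(sq, each = length(sq))
  P[P < 0] <- 0
  P / rowSums(P)
}
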