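#' Empirical position-specific nucleotide frequencies (F3x4)
#'
#' Counts nucleotides at each of the three codon positions over all
#' non-missing codons of the alignment and normalizes each position to sum
#' to one. Codons containing gaps or ambiguity codes are skipped.
#'
#' @param aln A [codon_alignment()].
#' @return A 3 x 4 matrix (positions x `A`,`C`,`G`,`T`) of class
#'   `positional_freq` with attribute `source = "F3x4"`.
#' @export
position_frequencies <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  idx <- aln$codon_idx            # taxa x sites, NA for missing
  obs <- idx[!is.na(idx)]
  if (length(obs) == 0L) stop("empty alignment: no scoreable codons")
  codons <- all_codons()[obs]
  nt <- c("A", "C", "G", "T")
  pi <- matrix(0, 3, 4, dimnames = list(paste0("pos", 1:3), nt))
  for (p in 1:3) {
    tab <- table(factor(substr(codons, p, p), levels = nt))
    pi[p, ] <- as.numeric(tab) / length(codons)
  }
  structure(pi, class = c("positional_freq", "matrix"),
            source = "F3x4")
}

#' Corrected F3x4 (CF3x4) position frequencies
#'
#' The naive F3x4 product estimator is biased because stop codons are
#' excluded from the codon state space: the product of observed positional
#' frequencies, renormalized over sense codons, does not reproduce the
#' observed positional frequencies. CF3x4 solves for corrected positional
#' frequencies `pi` such that the sense-codon distribution they imply
#' reproduces the observed frequencies. The solve is a damped fixed-point
#' iteration on the positional frequencies with a Gauss-Newton style
#' least-squares fallback.
#'
#' @param raw A `positional_freq` matrix of observed frequencies (rows sum
#'   to 1).
#' @param code A `genetic_code`.
#' @param tol Residual tolerance (max abs difference between observed and
#'   implied positional frequencies).
#' @param max_iter Iteration cap for the fixed point.
#' @return A `positional_freq` matrix with attribute `source = "CF3x4"`.
#'   Fails with the residual norm if neither solver converges.
#' @export
cf3x4 <- function(raw, code = genetic_code(), tol = 1e-10, max_iter = 500L) {
  stopifnot(inherits(raw, "positional_freq") || (is.matrix(raw) &&
            all(dim(raw) == c(3, 4))))
  raw <- unclass(raw)
  if (max(abs(rowSums(raw) - 1)) > 1e-8) stop("raw rows must sum to 1")
  if (length(code$stops) == 0L) {
    return(structure(raw, class = c("positional_freq", "matrix"),
                     source = "CF3x4"))
  }
  implied <- function(pi) .implied_position_freqs(pi, code)
  pi <- raw
  for (it in seq_len(max_iter)) {
    f <- implied(pi)
    resid <- max(abs(f - raw))
    if (resid < tol) {
      return(structure(pi, class = c("positional_freq", "matrix"),
                       source = "CF3x4"))
    }
    # multiplicative update preserves zeros and positivity; damping 0.75
    upd <- ifelse(f > 0, raw / f, 1)
    pi_new <- pi * upd^0.75
    pi_new <- pi_new / rowSums(pi_new)
    pi <- pi_new
  }
  # fallback: least-squares on free logits of nonzero entries
  free <- which(raw > 0)
  obj <- function(x) {
    m <- matrix(0, 3, 4); m[free] <- exp(x)
    m <- m / rowSums(m)
    sum((implied(m) - raw)^2)
  }
  opt <- stats::optim(log(pmax(pi[free], 1e-12)), obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  m <- matrix(0, 3, 4, dimnames = dimnames(raw)); m[free] <- exp(opt$par)
  m <- m / rowSums(m)
  resid <- max(abs(implied(m) - raw))
  if (resid > 1e-6) {
    stop(sprintf("CF3x4 solver did not converge (residual %.3g)", resid))
  }
  structure(m, class = c("positional_freq", "matrix"), source = "CF3x4")
}

# Positional nucleotide frequencies implied by product frequencies pi after
# excluding stop codons and renormalizing.
.implied_position_freqs <- function(pi, code) {
  pc <- .product_codon_freqs(pi, code)   # over sense codons, sums to 1
  nt <- c("A", "C", "G", "T")
  out <- matrix(0, 3, 4, dimnames = list(paste0("pos", 1:3), nt))
  sense <- code$sense
  for (p in 1:3) {
    ch <- substr(sense, p, p)
    for (j in seq_along(nt)) out[p, j] <- sum(pc[ch == nt[j]])
  }
  out
}

# Product codon frequencies over sense codons, renormalized.
.product_codon_freqs <- function(pi, code) {
  nt <- c("A", "C", "G", "T")
  sense <- code$sense
  p1 <- pi[1, match(substr(sense, 1, 1), nt)]
  p2 <- pi[2, match(substr(sense, 2, 2), nt)]
  p3 <- pi[3, match(substr(sense, 3, 3), nt)]
  w <- p1 * p2 * p3
  s <- sum(w)
  if (s <= 0) stop("degenerate positional frequencies: all sense codons have mass 0")
  stats::setNames(w / s, sense)
}

#' Stationary codon distribution from positional frequencies
#'
#' Muse-Gaut stationary frequencies: the product of position-specific
#' nucleotide frequencies, renormalized over the sense codons of the code.
#'
#' @param freqs A `positional_freq` matrix (typically CF3x4-corrected).
#' @param code A `genetic_code`.
#' @return Named numeric vector over sense codons, summing to 1.
#' @export
codon_stationary <- function(freqs, code = genetic_code()) {
  .product_codon_freqs(unclass(freqs), code)
}
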