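test_that("empirical position frequencies count correctly", {
  aln <- codon_alignment(c(a = "AAAAAA", b = "AAAAAA"))
  pf <- position_frequencies(aln)
  expect_equal(pf[, "A"], c(pos1 = 1, pos2 = 1, pos3 = 1))
  expect_true(all(pf[, c("C", "G", "T")] == 0))
  aln2 <- codon_alignment(c(a = "AAAGGG", b = "AAAGGG"))
  pf2 <- position_frequencies(aln2)
  expect_equal(unname(pf2[, "A"]), rep(0.5, 3))
  expect_equal(unname(pf2[, "G"]), rep(0.5, 3))
  # hand count on a single pair of sequences
  aln3 <- codon_alignment(c(a = "ATGAAA", b = "ATGAAA"))
  pf3 <- position_frequencies(aln3)
  expect_equal(unname(pf3[1, "A"]), 1)
  expect_equal(unname(pf3[2, c("A", "T")]), c(0.5, 0.5))
})

test_that("CF3x4 reproduces observed frequencies after stop exclusion", {
  raw <- uniform_freqs()
  corr <- cf3x4(raw, universal)
  # corrected must deviate from uniform (stop codons removed mass)
  expect_gt(max(abs(corr - 0.25)), 1e-4)
  # fixed-point residual: implied observed frequencies match raw
  implied <- mssrates:::.implied_position_freqs(unclass(corr), universal)
  expect_lt(max(abs(implied - unclass(raw))), 1e-8)
  # a code without stop codons: identity
  all_sense <- genetic_code()
  all_sense$table[c("TAA", "TAG", "TGA")] <- "X"
  code2 <- mssrates:::new_genetic_code(all_sense$table, "nostops")
  expect_equal(unclass(cf3x4(raw, code2)), unclass(raw))
  # zero entries stay zero
  raw0 <- unclass(fix_freqs())
  raw0[3, 2] <- 0
  raw0 <- raw0 / rowSums(raw0)
  raw0 <- structure(raw0, class = c("positional_freq", "matrix"))
  corr0 <- cf3x4(raw0, universal)
  expect_equal(unname(corr0[3, 2]), 0)
})

test_that("stationary codon distribution is the renormalized product", {
  expect_equal(unname(codon_stationary(uniform_freqs(), universal)),
               rep(1 / 61, 61))
  pf <- uniform_freqs()
  pf[] <- 0; pf[, "A"] <- 1
  st <- codon_stationary(pf, universal)
  expect_equal(unname(st[names(st) == "AAA"]), 1)
  # arbitrary rows match direct enumeration over 64 codons minus stops
  f <- fix_freqs()
  st2 <- codon_stationary(f, universal)
  nt <- c("A", "C", "G", "T")
  w <- vapply(all_codons(), function(cd) {
    prod(vapply(1:3, function(p) f[p, match(substr(cd, p, p), nt)],
                numeric(1)))
  }, numeric(1))
  w <- w[universal$table[names(w)] != "*"]
  expect_equal(unname(st2), unname(w / sum(w)), tolerance = 1e-12)
})

test_that("mss_spec families have the expected parameter structure", {
  src <- mss_spec("synrevcodon", universal)
  expect_equal(src$n_classes, 67)
  expect_equal(n_free_alpha(src), 66)
  sr <- mss_spec("synrev", universal)
  expect_equal(sr$n_classes, 18)
  expect_equal(n_free_alpha(sr), 17)
  std <- mss_spec("standard", universal)
  expect_equal(n_free_alpha(std), 0)
  expect_error(mss_spec("standard", alpha = 2), "alpha = 1")
  # mean-1 constraint after construction
  set.seed(2)
  sp <- mss_spec("synrevcodon", alpha = rgamma(67, 1), beta = 0.5)
  expect_equal(mean(sp$alpha[sp$class_of]), 1, tolerance = 1e-12)
  # a_priori validation
  expect_error(mss_spec("a_priori", classes = rep(1, 67)), "1 < K")
  cls <- rep(1L, 67); cls[1:10] <- 2L
  ap <- mss_spec("a_priori", classes = cls, alpha = c(1, 0.5))
  expect_equal(ap$constraint, "reference_class_fixed_to_1")
  expect_error(mss_spec("a_priori", classes = cls, alpha = c(2, 0.5)),
               "reference class")
})

test_that("rate matrix entries follow the one-step MSS parameterization", {
  theta <- fix_theta()
  freqs <- fix_freqs()
  set.seed(3)
  sp <- mss_spec("synrevcodon", alpha = rgamma(67, 2), beta = 0.31)
  rm <- codon_rate_matrix(sp, theta, freqs, universal, scale = FALSE)
  Q <- rm$Q
  pairs <- sp$pairs
  alpha_pair <- sp$alpha[sp$class_of]
  # synonymous one-step: alpha(x,y) * theta_CT * pi(T at position 3)
  i <- match("AGC", rownames(Q)); j <- match("AGT", rownames(Q))
  a <- alpha_pair[match("AGC:AGT", pairs$pair)]
  expect_equal(Q[i, j], a * theta[["CT"]] * freqs[3, "T"])
  # nonsynonymous one-step: beta * theta_CG * pi(C at position 2)
  k <- match("ACC", rownames(Q))
  expect_equal(Q[i, k], 0.31 * theta[["CG"]] * freqs[2, "C"])
  # multi-nucleotide substitution is impossible
  expect_equal(Q[match("TCC", rownames(Q)), match("AGC", rownames(Q))], 0)
  # uniform everything: all one-step off-diagonals equal
  spu <- mss_spec("standard", beta = 1)
  Qu <- codon_rate_matrix(spu, nuc_rates(), uniform_freqs(), universal,
                          scale = FALSE)$Q
  offs <- Qu[Qu > 0]
  expect_equal(length(unique(round(offs, 12))), 1L)
})

test_that("generators satisfy reversibility, scaling and nesting", {
  theta <- fix_theta()
  freqs <- fix_freqs()
  specs <- list(
    mss_spec("standard", beta = 0.7),
    mss_spec("synrev", alpha = exp(rnorm(18, 0, 0.5)), beta = 0.2),
    mss_spec("synrevcodon", alpha = c(rep(0, 5), rgamma(62, 1)), beta = 1.3)
  )
  for (sp in specs) {
    rm <- codon_rate_matrix(sp, theta, freqs, universal)
    expect_lt(max(abs(rowSums(rm$Q))), 1e-10)
    flux <- rm$stationary * rm$Q
    expect_lt(max(abs(flux - t(flux))), 1e-10)
    # scaling convention: 3 expected substitutions per codon per unit time
    expect_equal(-sum(rm$stationary * diag(rm$Q)), 3, tolerance = 1e-10)
  }
  # SynREV expressed as SynREVCodon with equal within-amino-acid alpha
  set.seed(4)
  asr <- exp(rnorm(18, 0, 0.4))
  sp_sr <- mss_spec("synrev", alpha = asr, beta = 0.4)
  per_pair <- sp_sr$alpha[sp_sr$class_of]
  sp_src <- mss_spec("synrevcodon", alpha = per_pair, beta = 0.4)
  Q1 <- codon_rate_matrix(sp_sr, theta, freqs, universal)$Q
  Q2 <- codon_rate_matrix(sp_src, theta, freqs, universal)$Q
  expect_identical(Q1, Q2)
  # MG94 as SynREV with alpha = 1
  sp_one <- mss_spec("synrev", alpha = rep(1, 18), beta = 0.4)
  Q3 <- codon_rate_matrix(mss_spec("standard", beta = 0.4), theta, freqs,
                          universal)$Q
  expect_identical(codon_rate_matrix(sp_one, theta, freqs, universal)$Q, Q3)
})

test_that("transition matrices are stochastic and ergodic", {
  rm <- codon_rate_matrix(mss_spec("synrev", alpha = exp(rnorm(18, 0, .3)),
                                   beta = 0.5),
                          fix_theta(), fix_freqs(), universal)
  for (t in c(0, 0.01, 0.5, 50)) {
    P <- transition_matrix(rm, t)
    expect_lt(max(abs(rowSums(P) - 1)), 1e-9)
    expect_true(all(P >= 0))
  }
  P50 <- transition_matrix(rm, 50)
  expect_lt(max(abs(t(P50) - matrix(rm$stationary, 61, 61))), 1e-6)
})

test_that("specs round-trip through JSON", {
  set.seed(9)
  sp <- mss_spec("synrev", alpha = exp(rnorm(18, 0, 0.5)), beta = 0.37)
  tf <- tempfile(fileext = ".json")
  spec_to_json(sp, tf)
  sp2 <- spec_from_json(tf)
  expect_equal(sp2$alpha, sp$alpha, tolerance = 1e-12)
  expect_equal(sp2$beta, sp$beta)
  expect_equal(sp2$family, sp$family)
  unlink(tf)
})
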