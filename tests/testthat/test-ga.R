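test_that("canonicalization relabels by first occurrence and is idempotent", {
  expect_equal(canonicalize_model(c(1, 0, 0, 1, 0)), c(0L, 1L, 1L, 0L, 1L))
  v <- c(0L, 1L, 1L, 0L, 2L)
  expect_equal(canonicalize_model(v), v)
  expect_error(canonicalize_model(c(0, 3), M = 2), "\\[0, M\\)")
  # any class permutation maps to the same canonical form (exhaustive for
  # D <= 6, M <= 3)
  perms3 <- list(c(0, 1, 2), c(0, 2, 1), c(1, 0, 2), c(1, 2, 0),
                 c(2, 0, 1), c(2, 1, 0))
  set.seed(51)
  for (i in 1:25) {
    D <- sample(3:6, 1)
    v <- sample(0:2, D, replace = TRUE)
    canon <- canonicalize_model(v, 3)
    for (p in perms3) {
      w <- p[v + 1]
      expect_equal(canonicalize_model(w, 3), canon)
    }
  }
})

test_that("partition enumeration counts restricted growth strings", {
  # Bell-type counts: partitions of D elements into at most M classes
  expect_length(enumerate_partitions(3, 3), 5)   # Bell(3)
  expect_length(enumerate_partitions(4, 4), 15)  # Bell(4)
  expect_length(enumerate_partitions(6, 2), 32)  # 1 + S(6,2)
  expect_true(all(vapply(enumerate_partitions(5, 3), function(v) {
    identical(v, canonicalize_model(v, 3))
  }, logical(1))))
})

test_that("akaike weights follow the BIC-difference formula", {
  expect_equal(akaike_weights(c(10, 10)), c(0.5, 0.5))
  w <- akaike_weights(c(0, 2))
  expect_equal(w[1], 1 / (1 + exp(-1)))
  expect_equal(w[2], exp(-1) / (1 + exp(-1)))
  set.seed(52)
  for (i in 1:10) {
    b <- rnorm(sample(2:30, 1), 1000, 50)
    w <- akaike_weights(b)
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_true(all(w > 0))
    expect_equal(which.max(w), which.min(b))
  }
  expect_error(akaike_weights(numeric(0)), "empty")
  expect_error(akaike_weights(c(1, Inf)), "finite")
})

test_that("model-average categorization reproduces the worked ranking", {
  # model (0,1,1,2,0,2) with class rates (1, 0.8, 1.4):
  # rank 1 -> SELECTED, middle -> INT 1, top -> NEUTRAL
  cats <- mssrates:::.rate_categories(c(1, 0.8, 1.4))
  enc <- c(0L, 1L, 1L, 2L, 0L, 2L)
  expect_equal(cats[enc + 1L],
               c("INT 1", "SELECTED", "SELECTED", "NEUTRAL", "INT 1",
                 "NEUTRAL"))
  # single-class model collapses to one category
  expect_equal(mssrates:::.rate_categories(1), "NEUTRAL")
  # two classes: smaller is SELECTED
  expect_equal(mssrates:::.rate_categories(c(1, 0.4)),
               c("NEUTRAL", "SELECTED"))
})

test_that("model averaging accumulates weights and flags ambiguity", {
  pairs <- paste0("p", 1:4)
  mk <- function(enc, bic, alpha) list(encoding = enc, bic = bic,
                                       logL = 0, alpha = alpha)
  trace <- structure(list(
    models = list(
      mk(c(0L, 0L, 1L, 1L), 100, c(1, 0.5)),   # weight ~ 0.73
      mk(c(0L, 1L, 1L, 0L), 102, c(1, 0.5))    # weight ~ 0.27
    ),
    M = 2L, pairs = pairs), class = "ga_trace")
  ma <- model_average(trace)
  w1 <- akaike_weights(c(100, 102))
  expect_equal(unname(ma$weights["p1", "NEUTRAL"]), 1)
  expect_equal(unname(ma$weights["p2", "SELECTED"]), w1[2])
  expect_equal(unname(rowSums(ma$weights)), rep(1, 4))
  # p4 carries SELECTED weight 0.73 from the better model, NEUTRAL 0.27
  expect_equal(ma$label, c("NEUTRAL", "NEUTRAL", "SELECTED", "SELECTED"))
  # p2 and p4 split ~0.73/0.27 -> ambiguous at the 0.90 threshold
  expect_equal(unname(ma$ambiguous), c(FALSE, TRUE, FALSE, TRUE))
})

test_that("contingency summaries match hand-checked tables", {
  # perfect agreement on 25 selected / 42 neutral
  tab <- matrix(c(25, 0, 0, 42), 2, byrow = TRUE)
  expect_equal(mcc_from_table(tab), 1)
  # independence (one inferred margin empty) gives 0
  expect_equal(mcc_from_table(matrix(c(0, 0, 25, 42), 2, byrow = TRUE)), 0)
  # the strong-selection table (24, 0; 1, 42): MCC 0.97, Fisher p 2.6e-17
  tab5 <- matrix(c(24, 0, 1, 42), 2, byrow = TRUE)
  expect_equal(round(mcc_from_table(tab5), 2), 0.97)
  expect_equal(stats::fisher.test(tab5)$p.value, 2.6e-17,
               tolerance = 0.05)
})

test_that("GA fitness caches, orders, and recovers a planted partition", {
  set.seed(53)
  pairs <- synonymous_pairs(universal)
  slow <- pairs$amino_acid %in% c("A", "G")   # 12 pairs
  cls <- ifelse(slow, 2L, 1L)
  sp <- mss_spec("a_priori", classes = cls, alpha = c(1, 0.25), beta = 0.3)
  genes <- generate_fixture_genes(n_genes = 4, ntaxa = 6, codons = 120,
                                  spec = sp, seed = 54)
  ctx <- ga_gene_contexts(genes, universal, fast_fit)
  cfg <- ga_config(P = 12, g_conv = 8, max_generations = 40, seed = 3,
                   refine_best = TRUE)
  # cache contract: re-evaluating a model is free and identical
  v <- canonicalize_model(as.integer(slow), 2L)
  e1 <- mssrates:::.ga_evaluate(v, ctx, universal, cfg)
  e2 <- mssrates:::.ga_evaluate(v, ctx, universal, cfg)
  expect_identical(e1$bic, e2$bic)
  # true partition fits far better than the null
  null <- mssrates:::.ga_evaluate(rep(0L, 67), ctx, universal, cfg)
  expect_gt(null$bic - e1$bic, 10)
  expect_lt(e1$alpha[2], 1)   # planted class is slower
  tr <- chc_search(ctx, 2L, cfg, universal)
  # the search at least matches the planted partition's fit
  expect_lte(tr$best$bic, e1$bic + 20)
  expect_gt(tr$delta_bic_vs_null, 0)
  # best BIC is monotone nonincreasing across generations
  expect_true(all(diff(tr$best_history) <= 1e-9))
  # classification recovers the planted slow pairs well
  ct <- truth_contingency(model_average(tr),
                          stats::setNames(ifelse(slow, "selected",
                                                 "neutral"), pairs$pair))
  expect_gt(ct$mcc, 0.5)
})

test_that("GA equals exhaustive enumeration on a restricted code", {
  rc <- restricted_code()
  pairs_rc <- synonymous_pairs(rc)
  expect_equal(nrow(pairs_rc), 6)
  # simulate data under a 2-class spec on the restricted code
  set.seed(55)
  cls <- ifelse(pairs_rc$amino_acid == "I", 2L, 1L)
  sp <- mss_spec("a_priori", rc, classes = cls, alpha = c(1, 0.2),
                 beta = 0.4)
  theta <- fix_theta()
  pf <- fix_freqs()
  rates <- codon_rate_matrix(sp, theta, pf, rc)
  genes <- lapply(1:3, function(g) {
    tr <- random_gene_tree(6, 1.5)
    list(alignment = simulate_alignment(rates, tr, 200, rc), tree = tr)
  })
  ctx <- ga_gene_contexts(genes, rc, fast_fit)
  cfg <- ga_config(P = 10, g_conv = 6, max_generations = 30, seed = 9)
  # exhaustive search over all 32 partitions into <= 2 classes
  all_parts <- enumerate_partitions(6, 2)
  bics <- vapply(all_parts, function(v) {
    mssrates:::.ga_evaluate(v, ctx, rc, cfg)$bic
  }, numeric(1))
  best_exhaustive <- min(bics)
  tr <- chc_search(ctx, 2L, cfg, rc)
  expect_equal(tr$best$bic, best_exhaustive, tolerance = 0.05)
  expect_identical(tr$best$encoding,
                   all_parts[[which.min(bics)]])
  # determinism: same seed reproduces the search exactly
  tr2 <- chc_search(ctx, 2L, cfg, rc)
  expect_equal(tr2$best$bic, tr$best$bic)
  expect_identical(tr2$best$encoding, tr$best$encoding)
})
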