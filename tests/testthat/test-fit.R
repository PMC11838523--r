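test_that("MG94 fit recovers generating parameters within sampling error", {
  # simulated under MG94 with omega = 0.2; the fitted omega should land
  # close to truth (relative bias near zero at this size)
  gene <- fix_gene(seed = 41, ntaxa = 10, codons = 400,
                   spec = mss_spec("standard", beta = 0.2),
                   tree_length = 2.0)
  fit <- fit_gene(gene$alignment, gene$tree, "standard", universal,
                  options = fast_fit)
  expect_lt(abs(fit$beta - 0.2) / 0.2, 0.25)
  expect_equal(fit$convergence, 0L)
  # exchangeabilities recovered in relative order (CT fastest here)
  expect_gt(fit$theta[["CT"]], fit$theta[["GT"]])
  # free-parameter count: branches + 5 theta + 9 freq + 1 beta
  expect_equal(fit$k, fit$n_branches + 5L + 9L + 0L + 1L)
})

test_that("nesting inequality holds on a fitted gene", {
  gene <- fix_gene(seed = 42, ntaxa = 6, codons = 120,
                   spec = mss_spec("synrev",
                                   alpha = exp(rnorm(18, 0, 0.6)),
                                   beta = 0.3))
  f_std <- fit_gene(gene$alignment, gene$tree, "standard", universal,
                    options = fast_fit)
  f_sr <- fit_gene(gene$alignment, gene$tree, "synrev", universal,
                   options = fast_fit)
  f_src <- fit_gene(gene$alignment, gene$tree, "synrevcodon", universal,
                    options = fast_fit)
  expect_lte(f_std$logL, f_sr$logL + 1e-6)
  expect_lte(f_sr$logL, f_src$logL + 1e-6)
  expect_equal(f_sr$k - f_std$k, 17L)
  expect_equal(f_src$k - f_std$k, 66L)
  # fitted mean-constrained alphas satisfy the constraint
  expect_equal(mean(f_sr$spec$alpha[f_sr$spec$class_of]), 1,
               tolerance = 1e-10)
})

test_that("likelihood ratio tests follow the nested-model contract", {
  gene <- fix_gene(seed = 45, ntaxa = 5, codons = 60)
  f_std <- fit_gene(gene$alignment, gene$tree, "standard", universal,
                    options = fast_fit)
  f_sr <- fit_gene(gene$alignment, gene$tree, "synrev", universal,
                   options = fast_fit)
  cmp <- lrt(f_std, f_sr)
  expect_equal(cmp$df, 17L)
  expect_gte(cmp$lrt, 0)
  expect_true(cmp$p_value >= 0 && cmp$p_value <= 1)
  expect_error(lrt(f_sr, f_std), "not nested")
  expect_error(lrt(f_sr, f_sr), "not nested")
  # identical fits give statistic 0, p = 1
  cmp0 <- lrt(f_std, structure(list(logL = f_std$logL,
                                    k = f_std$k + 17L,
                                    n = f_std$n, family = "synrev"),
                               class = "gene_fit"))
  expect_equal(cmp0$lrt, 0)
  expect_equal(cmp0$p_value, 1)
})

test_that("information criteria use the sequences-x-sites sample size", {
  fit <- structure(list(logL = -1000, k = 10, n = 10L * 300L,
                        family = "standard"), class = "gene_fit")
  ic <- information_criteria(fit)
  expect_equal(ic$n, 3000L)
  expect_equal(ic$aic, 2 * 10 - 2 * (-1000))
  expect_equal(ic$bic, 10 * log(3000) - 2 * (-1000))
  # BIC monotone in n for fixed k and logL
  ic_nuc <- information_criteria(fit, sites = "nucleotides")
  expect_gt(ic_nuc$bic, ic$bic)
  # equal-k comparison collapses to the likelihood difference
  fit2 <- fit; fit2$logL <- -990
  expect_equal(information_criteria(fit)$aic - information_criteria(fit2)$aic,
               -2 * (fit$logL - fit2$logL))
})

test_that("p-value adjustment implements Holm and BH", {
  expect_equal(adjust_pvalues(0.03, "holm_bonferroni"), 0.03)
  expect_equal(adjust_pvalues(0.03, "benjamini_hochberg"), 0.03)
  expect_equal(adjust_pvalues(c(0.01, 0.04), "holm_bonferroni"),
               c(0.02, 0.04))
  expect_equal(adjust_pvalues(rep(1, 5), "holm_bonferroni"), rep(1, 5))
  expect_equal(adjust_pvalues(rep(1, 5), "benjamini_hochberg"), rep(1, 5))
  expect_error(adjust_pvalues(c(0.5, 1.2)), "\\[0, 1\\]")
  # monotonicity of BH in the sorted order
  set.seed(46)
  p <- runif(20)
  q <- adjust_pvalues(p, "benjamini_hochberg")
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("joint fitting shares alpha and scales per gene", {
  set.seed(47)
  alpha_true <- exp(rnorm(18, 0, 0.8))
  sp <- mss_spec("synrev", alpha = alpha_true, beta = 0.3)
  genes <- generate_fixture_genes(n_genes = 4, ntaxa = 6, codons = 120,
                                  spec = sp, seed = 48)
  expect_error(fit_joint(genes[1], "synrev"), "G > 1")
  jf <- fit_joint(genes, "synrev", universal, options = fast_fit)
  expect_length(jf$scalers, 4)
  expect_length(jf$alpha, 18)
  expect_equal(mean(jf$spec$alpha[jf$spec$class_of]), 1, tolerance = 1e-10)
  # joint alpha should recover the shared truth reasonably at this size
  truth <- mss_spec("synrev", alpha = alpha_true)$alpha
  expect_gt(rank_correlation(truth, jf$alpha)$rho, 0.5)
  # phase-2 likelihood at least matches the frozen phase-1 total
  base_total <- sum(vapply(jf$gene_fits, `[[`, numeric(1), "logL"))
  expect_gte(jf$logL, base_total - 1e-6)
})

test_that("joint machinery with one gene equals the constrained fit", {
  set.seed(49)
  sp <- mss_spec("synrev", alpha = exp(rnorm(18, 0, 0.5)), beta = 0.3)
  genes <- generate_fixture_genes(n_genes = 1, ntaxa = 5, codons = 80,
                                  spec = sp, seed = 50)
  jf <- fit_joint(genes, "synrev", universal, options = fast_fit,
                  allow_single = TRUE)
  # direct constrained fit: frozen standard nuisance, free alpha + scaler
  expect_length(jf$scalers, 1)
  expect_gte(jf$logL, jf$gene_fits[[1]]$logL - 1e-6)
})
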