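test_that("ancestral sequences follow the requested codon frequencies", {
  f1 <- stats::setNames(c(1, rep(0, 60)), universal$sense)
  set.seed(61)
  s <- ancestral_sequence(f1[f1 > 0], 300)
  expect_length(s, 300)
  expect_true(all(all_codons()[s] == names(f1)[1]))
  expect_length(ancestral_sequence(f1[f1 > 0], 0), 0)
  # uniform frequencies: chi-squared goodness of fit not rejected
  fu <- stats::setNames(rep(1 / 61, 61), universal$sense)
  set.seed(62)
  s2 <- ancestral_sequence(fu, 6100)
  tab <- table(factor(all_codons()[s2], levels = universal$sense))
  gof <- stats::chisq.test(tab, p = rep(1 / 61, 61))
  expect_gt(gof$p.value, 0.001)
})

test_that("parametric simulation matches the transition kernel", {
  rates <- codon_rate_matrix(mss_spec("standard", beta = 0.6), fix_theta(),
                             fix_freqs(), universal)
  # zero-length branches copy the root draw to every leaf
  tr0 <- ape::read.tree(text = "(a:0,b:0,c:0);")
  set.seed(63)
  aln0 <- simulate_alignment(rates, tr0, 50, universal)
  m <- as.character(aln0)
  expect_true(all(m[1, ] == m[2, ]) && all(m[1, ] == m[3, ]))
  # long branches: leaf frequencies converge to the stationary distribution
  trL <- ape::read.tree(text = "(a:60,b:60);")
  set.seed(64)
  alnL <- simulate_alignment(rates, trL, 5000, universal)
  tab <- table(factor(as.character(alnL), levels = universal$sense))
  gof <- stats::chisq.test(tab, p = rates$stationary)
  expect_gt(gof$p.value, 0.001)
  # single-branch empirical transitions track exp(Qt): condition on the
  # root state revealed by a zero-length sister branch
  P <- transition_matrix(rates, 0.4)
  tr1 <- ape::read.tree(text = "(a:0.0,b:0.4);")
  set.seed(65)
  aln1 <- simulate_alignment(rates, tr1, 30000, universal)
  m1 <- as.character(aln1)
  root_codon <- names(sort(rates$stationary, decreasing = TRUE))[1]
  sel <- m1["a", ] == root_codon
  expect_gt(sum(sel), 1000)
  emp <- table(factor(m1["b", sel], levels = universal$sense)) / sum(sel)
  expect_lt(max(abs(emp - P[match(root_codon, universal$sense), ])), 0.03)
})

test_that("selection schemes partition codons and imply 25/42 truth labels", {
  sch <- default_selection_scheme(s = -0.01)
  labels <- pair_truth_labels(sch)
  expect_length(labels, 67)
  expect_equal(sum(labels == "selected"), 25)
  expect_equal(sum(labels == "neutral"), 42)
  # within-class pairs are neutral, cross-class selected
  expect_equal(unname(labels["GCA:GCG"]), "neutral")   # both favored (Ala)
  expect_equal(unname(labels["GCA:GCC"]), "selected")  # cross class
  expect_equal(unname(labels["CTA:CTG"]), "neutral")   # Leu unsplit
  # malformed schemes are rejected
  expect_error(selection_scheme(list(K = list("AAA"))), "partition")
  expect_error(selection_scheme(list(Z = list("AAA", "AAG"))),
               "unknown amino acid")
})

test_that("neutral Wright-Fisher conserves size and resamples parents", {
  sch <- selection_scheme()          # no selection
  anc <- ancestral_sequence(stats::setNames(rep(1 / 61, 61),
                                            universal$sense), 30)
  pop <- wf_population(anc, N = 25, sch)
  expect_equal(dim(pop$copies), c(50L, 30L))
  set.seed(66)
  for (i in 1:5) {
    pop <- wf_generation(pop, mu = 0)
    expect_equal(nrow(pop$copies), 50L)
    # with mu = 0 every copy is a resample of the founders
    expect_true(all(pop$copies[, 1] == anc[1]))
  }
  expect_equal(pop$generation, 5L)
})

test_that("neutral fixation probability is near 1/(2N)", {
  # single new neutral mutant at N = 50: fixation probability 1/100
  sch <- selection_scheme()
  anc <- match("GGA", all_codons())
  reps <- 400L
  fixed <- 0L
  set.seed(67)
  for (r in seq_len(reps)) {
    pop <- wf_population(anc, N = 50, sch)
    pop$copies[1, 1] <- match("GGG", all_codons())  # one mutant copy
    repeat {
      pop <- wf_generation(pop, mu = 0, generations = 25L)
      n_mut <- sum(pop$copies[, 1] == match("GGG", all_codons()))
      if (n_mut == 0L || n_mut == 100L) break
    }
    if (n_mut == 100L) fixed <- fixed + 1L
  }
  ci <- stats::binom.test(fixed, reps, p = 1 / 100)
  expect_gt(ci$p.value, 0.001)
  # a strongly deleterious mutant (2Ns = -10) fixes less often
  sch_del <- selection_scheme(list(G = list(c("GGA", "GGC", "GGT"), "GGG")),
                              s = -0.1)
  fixed_del <- 0L
  for (r in seq_len(150L)) {
    pop <- wf_population(anc, N = 50, sch_del)
    pop$copies[1, 1] <- match("GGG", all_codons())
    repeat {
      pop <- wf_generation(pop, mu = 0, generations = 25L)
      n_mut <- sum(pop$copies[, 1] == match("GGG", all_codons()))
      if (n_mut == 0L || n_mut == 100L) break
    }
    if (n_mut == 100L) fixed_del <- fixed_del + 1L
  }
  expect_lt(fixed_del / 150, fixed / reps)
})

test_that("stop codons are lethal and never sampled", {
  sch <- selection_scheme()
  anc <- match("TGG", all_codons())  # Trp: one step from stops
  pop <- wf_population(anc, N = 10, sch)
  set.seed(68)
  pop <- wf_generation(pop, mu = 0.01, generations = 200L)
  codons <- all_codons()[pop$copies]
  expect_false(any(universal$table[codons] == "*"))
})

test_that("forward simulation yields 11 sampled populations with truth", {
  set.seed(69)
  cfg <- forward_sim_config(N = 30, codons = 60, burn_in_multiplier = 20,
                            split_times = seq(250, 2500, by = 250),
                            end_time = 2750, twoNs = 0)
  sim <- run_forward_simulation(cfg)
  expect_equal(length(sim$alignment$names), 11L)
  expect_equal(sim$alignment$n_sites, 60L)
  expect_length(sim$truth, 67)
  expect_equal(ape::Ntip(sim$tree), 11L)
  # tree depth runs from the first split (the root) to the sampling time
  expect_equal(max(ape::node.depth.edgelength(sim$tree)), 2750 - 250)
  # neutral mutation pressure yields several distinct haplotypes
  m <- as.character(sim$alignment)
  expect_gte(length(unique(apply(m, 1, paste, collapse = ""))), 4L)
  # population tree round-trips through Newick
  txt <- ape::write.tree(sim$tree)
  expect_true(ape::all.equal.phylo(ape::read.tree(text = txt), sim$tree,
                                   use.edge.length = TRUE))
})

test_that("split schedules are validated", {
  expect_error(forward_sim_config(split_times = c(100, 50)),
               "strictly increasing")
  expect_error(forward_sim_config(split_times = c(100, 200),
                                  end_time = 150), "exceed the last split")
})
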