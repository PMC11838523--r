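#' Options for maximum-likelihood fitting
#'
#' @param multistart Number of random restarts for the synonymous-rate block
#'   of alpha-rich families (`synrev`, `synrevcodon`); the first start is
#'   always alpha = 1.
#' @param iter_max Iteration cap per optimizer call.
#' @param rel_tol Relative convergence tolerance passed to [stats::nlminb()].
#' @param rate_max Upper bound for rate parameters (alpha, beta, theta).
#' @param branch_max Upper bound for branch lengths (substitutions/site).
#' @param seed Seed controlling the multi-start perturbations.
#' @param chain For `synrevcodon`, warm-start through an intermediate
#'   `synrev` stage (guarantees the nested-likelihood ordering numerically).
#' @param outer_tol Log-likelihood improvement between alternation passes
#'   below which the fit is declared converged.
#' @param outer_max Maximum number of alternation passes.
#' @return A list of class `fit_options`.
#' @export
fit_options <- function(multistart = 3L, iter_max = 60L, rel_tol = 1e-8,
                        rate_max = 100, branch_max = 25, seed = 1L,
                        chain = TRUE, outer_tol = 1e-6, outer_max = 8L) {
  structure(list(multistart = as.integer(multistart), iter_max = iter_max,
                 rel_tol = rel_tol, rate_max = rate_max,
                 branch_max = branch_max, seed = seed, chain = chain,
                 outer_tol = outer_tol, outer_max = as.integer(outer_max)),
            class = "fit_options")
}

.LOG_EPS <- log(1e-8)

# Assemble an mss_spec with given per-class alpha (free entries on log
# scale) for the fitting parameterization of each family.
.spec_from_pars <- function(family, code, log_alpha_free, beta, classes = NULL,
                            reference_class = 1L) {
  if (family == "standard") {
    return(mss_spec("standard", code, beta = beta))
  }
  if (family %in% c("synrev", "synrevcodon")) {
    alpha <- c(exp(log_alpha_free), 1)  # last class pinned pre-normalization
    return(mss_spec(family, code, alpha = alpha, beta = beta))
  }
  K <- max(classes)
  alpha <- numeric(K)
  alpha[reference_class] <- 1
  alpha[setdiff(seq_len(K), reference_class)] <- exp(log_alpha_free)
  mss_spec(family, code, classes = classes, alpha = alpha, beta = beta,
           reference_class = reference_class)
}

.n_alpha_free <- function(family, code, classes = NULL) {
  switch(family,
         standard = 0L,
         synrev = length(amino_acid_pair_groups(code)) - 1L,
         synrevcodon = nrow(synonymous_pairs(code)) - 1L,
         max(classes) - 1L)
}

#' Fit an MSS codon model to a single gene
#'
#' Maximizes the pruning likelihood over branch lengths, the five free
#' nucleotide exchangeabilities (AG = 1), the nonsynonymous rate beta, and
#' the family-specific synonymous rates alpha, with CF3x4 equilibrium
#' frequencies plugged in empirically. Optimization is direct (bounded
#' quasi-Newton on log-transformed parameters) with warm starts through the
#' nested model hierarchy, so the fitted log-likelihoods respect
#' MG94 <= SynREV <= SynREVCodon on any data.
#'
#' @param aln A `codon_alignment`.
#' @param tree An `ape::phylo`; existing branch lengths are used as starting
#'   values when present.
#' @param family Model family, see [mss_spec()].
#' @param code A `genetic_code`.
#' @param classes Class assignment over pairs for `a_priori`/`ga` families.
#' @param options A [fit_options()] list.
#' @return An object of class `gene_fit`: `logL`, `tree` (fitted branch
#'   lengths), `theta`, `beta`, `spec` (with fitted alpha), `freqs`,
#'   `k` (free parameter count: branches + 5 theta + 9 frequencies +
#'   alpha + 1 beta), `n` (sequences x codon sites), `convergence`.
#' @export
fit_gene <- function(aln, tree, family = "standard", code = genetic_code(),
                     classes = NULL, options = fit_options()) {
  eng <- .make_engine(aln, tree, code)
  freqs <- cf3x4(position_frequencies(aln), code)
  fit <- .fit_engine(eng, freqs, family, code, classes, options)
  fitted_tree <- eng$tree
  fitted_tree$edge.length <- fit$lens
  structure(list(
    logL = fit$logL, tree = fitted_tree, theta = fit$theta,
    beta = fit$spec$beta, spec = fit$spec, freqs = freqs, family = family,
    k = length(fit$lens) + 5L + 9L + n_free_alpha(fit$spec) + 1L,
    n = eng$n_seq * eng$n_sites, n_branches = length(fit$lens),
    convergence = fit$convergence
  ), class = "gene_fit")
}

#' @export
print.gene_fit <- function(x, ...) {
  cat(sprintf("MSS gene fit (%s): logL = %.3f, omega = %.4f, k = %d, n = %d\n",
              x$family, x$logL, x$beta, x$k, x$n))
  invisible(x)
}

.theta_from_logs <- function(th5) {
  th <- exp(th5)
  nuc_rates(AC = th[1], AG = 1, AT = th[2], CG = th[3], CT = th[4],
            GT = th[5])
}

# One pass of per-branch optimization. For each edge the likelihood as a
# function of that branch length alone is a weighted sum of exponentials in
# the eigenbasis (profile computed in compiled code), so each branch gets a
# cheap Brent search; all other parameters stay fixed.
.branch_sweep <- function(eng, rates, lens, bmax) {
  pi <- pmax(rates$stationary, 1e-12)
  for (e in seq_along(lens)) {
    prof <- .cpp_branch_profile(rates$Q, pi, eng$edge, lens, eng$tipdata,
                                eng$nnode, e - 1L)
    ls <- as.numeric(prof$ls)
    lam <- as.numeric(prof$lam)
    negll <- function(t) {
      s <- colSums(prof$F * (exp(lam * t) * prof$G))
      if (any(s <= 0) || any(!is.finite(s))) return(1e12)
      -sum(eng$wt * (log(s) + ls))
    }
    o <- stats::optimize(negll, c(1e-9, bmax), tol = 1e-9)
    if (o$objective < negll(lens[e])) lens[e] <- o$minimum
  }
  lens
}

# Alternating fit for one family: a bounded quasi-Newton pass over the rate
# block (theta, beta, alpha) with branches fixed, then branch-profile
# sweeps with rates fixed, until the log-likelihood improves by less than
# `tol_outer` between passes.
.fit_family_once <- function(eng, freqs, fam, cls, code, options, init) {
  na <- .n_alpha_free(fam, code, cls)
  lens <- init$lens
  p <- c(init$th5, init$lbeta, init$la)
  lower <- c(rep(log(1e-4), 5), .LOG_EPS, rep(.LOG_EPS, na))
  upper <- rep(log(options$rate_max), 6 + na)
  rates_for <- function(p) {
    spec <- .spec_from_pars(fam, code, p[6 + seq_len(na)], exp(p[6]), cls)
    codon_rate_matrix(spec, .theta_from_logs(p[1:5]), freqs, code)
  }
  obj <- function(p, lens_cur) {
    ll <- .engine_loglik(eng, rates_for(p), lens = lens_cur)
    if (!is.finite(ll)) return(1e12)
    -ll
  }
  tol_outer <- options$outer_tol
  ll_prev <- -obj(p, lens)
  conv <- 1L
  for (outer in seq_len(options$outer_max)) {
    opt <- stats::nlminb(p, obj, lens_cur = lens, lower = lower,
                         upper = upper,
                         control = list(iter.max = options$iter_max,
                                        rel.tol = options$rel_tol))
    if (opt$objective <= -ll_prev) p <- opt$par
    lens <- .branch_sweep(eng, rates_for(p), lens, options$branch_max)
    ll <- -obj(p, lens)
    if (abs(ll - ll_prev) < tol_outer) { ll_prev <- ll; conv <- 0L; break }
    ll_prev <- ll
  }
  list(logL = ll_prev, p = p, lens = lens, convergence = conv)
}

# Core fitter working on a prepared engine; warm-starts through the nested
# family hierarchy so fitted likelihoods respect the nesting order.
.fit_engine <- function(eng, freqs, family, code, classes, options) {
  nb <- nrow(eng$edge)
  lens0 <- eng$tree$edge.length
  if (is.null(lens0)) lens0 <- rep(0.1, nb)
  lens0 <- pmin(pmax(lens0, 1e-6), options$branch_max)

  init <- list(th5 = rep(0, 5), lbeta = log(0.3), la = numeric(0),
               lens = lens0)
  best <- .fit_family_once(eng, freqs, "standard", NULL, code, options, init)
  fam_chain <- switch(family,
                      standard = character(0),
                      synrev = "synrev",
                      synrevcodon = if (isTRUE(options$chain))
                        c("synrev", "synrevcodon") else "synrevcodon",
                      family)  # a_priori / ga
  cls <- classes
  prev_alpha <- NULL
  final_fam <- "standard"
  for (fam in fam_chain) {
    na <- .n_alpha_free(fam, code, cls)
    la0 <- rep(0, na)
    if (fam == "synrevcodon" && !is.null(prev_alpha)) {
      # map per-amino-acid alphas onto per-pair starting values
      pairs <- synonymous_pairs(code)
      groups <- sort(unique(pairs$amino_acid))
      per_pair <- prev_alpha[match(pairs$amino_acid, groups)]
      la0 <- log(pmax(per_pair[-length(per_pair)] /
                        per_pair[length(per_pair)], 1e-6))
    }
    winit <- list(th5 = best$p[1:5], lbeta = best$p[6], la = la0,
                  lens = best$lens)
    starts <- list(winit)
    if (options$multistart > 1L && na > 0) {
      more <- .with_seed(options$seed, function() lapply(
        seq_len(options$multistart - 1L), function(i) {
          s <- winit
          s$la <- la0 + stats::rnorm(na, 0, 0.5)
          s
        }))
      starts <- c(starts, more)
    }
    fits <- lapply(starts, function(s) {
      .fit_family_once(eng, freqs, fam, cls, code, options, s)
    })
    cand <- fits[[which.max(vapply(fits, `[[`, numeric(1), "logL"))]]
    if (cand$logL >= best$logL) {
      best <- cand
    } else {
      # keep the nested optimum expressed in the richer family
      best <- list(logL = best$logL,
                   p = c(best$p[1:6], rep(0, na)),
                   lens = best$lens, convergence = best$convergence)
    }
    final_fam <- fam
    if (fam == "synrev") {
      prev_alpha <- .spec_from_pars("synrev", code,
                                    best$p[6 + seq_len(na)],
                                    exp(best$p[6]))$alpha
    }
  }
  na <- .n_alpha_free(final_fam, code, cls)
  p <- best$p
  theta <- .theta_from_logs(p[1:5])
  beta <- exp(p[6])
  laf <- if (na > 0) p[6 + seq_len(na)] else numeric(0)
  spec <- .spec_from_pars(final_fam, code, laf, beta, cls)
  list(logL = best$logL, lens = best$lens, theta = theta, spec = spec,
       convergence = best$convergence)
}

.with_seed <- function(seed, fun) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  fun()
}

#' Jointly fit shared synonymous rates across several genes
#'
#' Two-phase multi-gene fit: phase 1 fits the standard MG94xREV model to
#' each gene separately (branch lengths, exchangeabilities, frequencies,
#' omega); phase 2 maximizes the summed log-likelihood over a single shared
#' alpha vector plus one multiplicative branch-length scaler per gene,
#' holding all per-gene nuisance parameters at their phase-1 estimates.
#'
#' @param genes List of `list(alignment, tree)` entries (G >= 2).
#' @param family `"synrev"` or `"synrevcodon"` (or `a_priori`/`ga` with
#'   `classes`).
#' @param code A `genetic_code`.
#' @param classes Optional class assignment for `a_priori`/`ga`.
#' @param options A [fit_options()].
#' @param allow_single Permit G = 1 (used to check that the joint machinery
#'   reduces to the constrained single-gene fit); the exported contract
#'   requires G >= 2.
#' @return An object of class `joint_fit`: `logL` (phase-2 summed), `spec`
#'   (shared alpha), `scalers`, `gene_fits` (phase-1), `k`, `n`.
#' @export
fit_joint <- function(genes, family = "synrev", code = genetic_code(),
                      classes = NULL, options = fit_options(),
                      allow_single = FALSE) {
  G <- length(genes)
  if (G < 2L && !allow_single) stop("joint fitting requires G > 1 genes")
  base <- vector("list", G)
  for (g in seq_len(G)) {
    base[[g]] <- tryCatch(
      fit_gene(genes[[g]]$alignment, genes[[g]]$tree, "standard", code,
               options = options),
      error = function(e) stop("phase-1 fit failed for gene ", g, ": ",
                               conditionMessage(e)))
  }
  engines <- lapply(seq_len(G), function(g) {
    .make_engine(genes[[g]]$alignment, base[[g]]$tree, code)
  })
  na <- .n_alpha_free(family, code, classes)
  obj <- function(p) {
    laf <- p[seq_len(na)]
    lsc <- p[na + seq_len(G)]
    total <- 0
    for (g in seq_len(G)) {
      spec <- .spec_from_pars(family, code, laf, base[[g]]$beta, classes)
      rates <- codon_rate_matrix(spec, base[[g]]$theta, base[[g]]$freqs,
                                 code)
      ll <- .engine_loglik(engines[[g]], rates, scale = exp(lsc[g]))
      if (!is.finite(ll)) return(1e12)
      total <- total + ll
    }
    -total
  }
  p0 <- c(rep(0, na), rep(0, G))
  opt <- stats::nlminb(p0, obj,
                       lower = c(rep(.LOG_EPS, na), rep(log(1e-3), G)),
                       upper = c(rep(log(options$rate_max), na),
                                 rep(log(1e3), G)),
                       control = list(iter.max = options$iter_max,
                                      rel.tol = options$rel_tol))
  laf <- opt$par[seq_len(na)]
  # beta is a per-gene nuisance here; the shared spec carries a unit value
  spec <- .spec_from_pars(family, code, laf, 1, classes)
  structure(list(
    logL = -opt$objective, spec = spec, family = family,
    alpha = spec$alpha, scalers = exp(opt$par[na + seq_len(G)]),
    gene_fits = base,
    k = sum(vapply(base, `[[`, numeric(1), "k")) + na + G,
    n = sum(vapply(base, `[[`, numeric(1), "n")),
    convergence = opt$convergence
  ), class = "joint_fit")
}

#' @export
print.joint_fit <- function(x, ...) {
  cat(sprintf("Joint MSS fit (%s): %d genes, logL = %.3f\n", x$family,
              length(x$gene_fits), x$logL))
  invisible(x)
}
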