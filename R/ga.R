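#' Canonicalize a rate-partition model vector
#'
#' A partition of the D synonymous rates into at most M classes is encoded
#' as a D-vector of integers in `[0, M)`. All encodings that differ only by
#' a permutation of class labels describe the same partition; the canonical
#' ("class-sorted") representative relabels classes in order of first
#' occurrence, so the first occurrence of class 0 precedes the first
#' occurrence of class 1, and so on. Idempotent.
#'
#' @param v Integer vector with entries in `[0, M)`.
#' @param M Maximum number of classes (defaults to `max(v) + 1`).
#' @return Canonical integer vector of the same length.
#' @examples
#' canonicalize_model(c(1, 0, 0, 1, 0))  # (0, 1, 1, 0, 1)
#' @export
canonicalize_model <- function(v, M = max(v) + 1L) {
  v <- as.integer(v)
  if (any(v < 0L) || any(v >= M)) stop("entries must lie in [0, M)")
  first <- unique(v)
  match(v, first) - 1L
}

#' CHC genetic-algorithm configuration
#'
#' Defaults are the standard CHC settings for this search: population 32, minimum relative
#' diversity 1e-6, 25 stagnant generations before mutagenesis, per-element
#' mutation probability 0.20, minimum BIC improvement 0.01, and 100
#' no-improvement generations to terminate.
#'
#' @param P Population size.
#' @param f_rel Minimum relative fitness range (worst - best)/|best| below
#'   which the population counts as converged and is mutagenized.
#' @param f_stagnant Consecutive generations without new models entering the
#'   population before mutagenesis.
#' @param mu Per-element mutation probability during mutagenesis.
#' @param delta_bic Minimum generation-to-generation BIC improvement that
#'   resets the termination counter.
#' @param g_conv Consecutive generations without sufficient improvement
#'   required to terminate.
#' @param max_generations Hard cap on generations (desk-scale runs).
#' @param seed Required seed; every stochastic draw of the search flows from
#'   it.
#' @param refit_beta Re-optimize each gene's nonsynonymous rate for every
#'   candidate model (slower); by default beta stays frozen at its
#'   baseline-fit estimate.
#' @param include_null Seed the initial population with the single-class
#'   (baseline) model as a standing incumbent, so the search can return the
#'   null model when no partition improves on it.
#' @param refine_best After termination, polish the best model by greedy
#'   single-rate reassignment (candidate moves screened at the incumbent's
#'   fitted class rates, accepted moves refit fully) until no move improves
#'   BIC. Useful when the generation budget is small.
#' @return A list of class `ga_config`.
#' @export
ga_config <- function(P = 32L, f_rel = 1e-6, f_stagnant = 25L, mu = 0.20,
                      delta_bic = 0.01, g_conv = 100L,
                      max_generations = Inf, seed = 1L,
                      refit_beta = FALSE, include_null = TRUE,
                      refine_best = FALSE) {
  structure(list(P = as.integer(P), f_rel = f_rel,
                 f_stagnant = as.integer(f_stagnant), mu = mu,
                 delta_bic = delta_bic, g_conv = as.integer(g_conv),
                 max_generations = max_generations, seed = seed,
                 refit_beta = refit_beta, include_null = include_null,
                 refine_best = refine_best),
            class = "ga_config")
}

#' Baseline (frozen-nuisance) gene contexts for the GA
#'
#' Step 1 of the search: fit the standard MG94xREV model to every training
#' alignment and freeze branch lengths, exchangeabilities, frequencies and
#' omega at their MLEs. Candidate partitions are then scored by refitting
#' only the synonymous class rates.
#'
#' @param genes List of `list(alignment, tree)` entries.
#' @param code A `genetic_code`.
#' @param options [fit_options()] for the baseline fits.
#' @return A list of class `ga_contexts` used by [chc_search()].
#' @export
ga_gene_contexts <- function(genes, code = genetic_code(),
                             options = fit_options(multistart = 1L)) {
  if (length(genes) < 1L) stop("need at least one gene")
  st <- .code_structure(code)
  ctx <- lapply(seq_along(genes), function(g) {
    fit <- tryCatch(
      fit_gene(genes[[g]]$alignment, genes[[g]]$tree, "standard", code,
               options = options),
      error = function(e) stop("baseline fit failed for gene ", g, ": ",
                               conditionMessage(e)))
    eng <- .make_engine(genes[[g]]$alignment, fit$tree, code)
    # precomputed one-step base rates theta * pi(target) for the hot path
    pim <- unclass(fit$freqs)
    brate <- unclass(fit$theta)[st$theta_idx] *
      pim[cbind(st$pos, st$target_nuc)]
    pi <- pmax(.product_codon_freqs(pim, code), 1e-12)
    # fixed scale divisor from the null (alpha = 1) model: candidate
    # partitions perturb rates relative to the frozen branch lengths
    # rather than being renormalized, so the reference class stays pinned
    q0 <- brate
    q0[!st$synonymous] <- q0[!st$synonymous] * fit$beta
    Q0 <- matrix(0, st$n, st$n)
    Q0[cbind(st$from, st$to)] <- q0
    scale0 <- sum(pi * rowSums(Q0)) / 3
    list(engine = eng, theta = fit$theta, freqs = fit$freqs,
         beta = fit$beta, logL0 = fit$logL, k = fit$k, n = fit$n,
         ij = cbind(st$from, st$to), brate = brate, pi = pi,
         scale0 = scale0)
  })
  structure(list(genes = ctx, code_name = code$name,
                 k0 = sum(vapply(ctx, `[[`, numeric(1), "k")),
                 n = sum(vapply(ctx, `[[`, numeric(1), "n")),
                 logL0 = sum(vapply(ctx, `[[`, numeric(1), "logL0"))),
            class = "ga_contexts")
}

# Evaluate one canonical model vector: optimize shared class rates (class 0
# is the reference, fixed to 1) over all genes with frozen nuisance
# parameters, and return BIC plus the fitted class rates.
.ga_evaluate <- function(v, contexts, code, config) {
  Mu <- max(v) + 1L
  D <- length(v)
  st <- .code_structure(code)
  n <- st$n
  syn <- st$synonymous
  pair_cls <- v + 1L            # 1-based class per pair
  # per-gene log-likelihood with frozen nuisance, lean Q assembly
  gene_ll_one <- function(ct, alpha_cls, beta) {
    q <- ct$brate
    q[syn] <- q[syn] * alpha_cls[pair_cls[st$pair_idx[syn]]]
    q[!syn] <- q[!syn] * beta
    Q <- matrix(0, n, n)
    Q[ct$ij] <- q
    diag(Q) <- -rowSums(Q)
    # renormalize so frozen branch lengths keep their units (expected
    # substitutions per site) under every candidate model
    per_codon <- -sum(ct$pi * diag(Q))
    if (per_codon <= 0) return(-1e12)
    Q <- Q / (per_codon / 3)
    .cpp_pruning_loglik(Q, ct$pi, ct$engine$edge,
                        ct$engine$tree$edge.length, ct$engine$tipdata,
                        ct$engine$wt, ct$engine$nnode)
  }
  gene_ll <- function(laf, beta_override = NULL) {
    alpha_cls <- c(1, exp(laf))
    total <- 0
    for (ct in contexts$genes) {
      beta <- if (is.null(beta_override)) ct$beta else beta_override
      ll <- gene_ll_one(ct, alpha_cls, beta)
      if (!is.finite(ll)) return(-1e12)
      total <- total + ll
    }
    total
  }
  if (Mu == 1L) {
    logL <- contexts$logL0
    alpha <- 1
    laf_hat <- numeric(0)
  } else if (Mu == 2L) {
    opt <- stats::optimize(function(x) -gene_ll(x),
                           interval = log(c(1e-3, 30)), tol = 0.03)
    logL <- -opt$objective
    alpha <- c(1, exp(opt$minimum))
    laf_hat <- opt$minimum
  } else {
    opt <- stats::nlminb(rep(0, Mu - 1L), function(x) -gene_ll(x),
                         lower = log(1e-3), upper = log(30),
                         control = list(iter.max = 100, rel.tol = 1e-8))
    logL <- -opt$objective
    alpha <- c(1, exp(opt$par))
    laf_hat <- opt$par
  }
  if (config$refit_beta && Mu > 1L) {
    # one alternation: per-gene beta given alpha, then alpha once more
    alpha_cls <- c(1, exp(laf_hat))
    for (gi in seq_along(contexts$genes)) {
      ct <- contexts$genes[[gi]]
      bopt <- stats::optimize(function(lb) {
        -gene_ll_one(ct, alpha_cls, exp(lb))
      }, interval = log(c(1e-6, 50)), tol = 0.01)
      contexts$genes[[gi]]$beta <- exp(bopt$minimum)
    }
    refit <- function(x) -gene_ll(x)
    if (Mu == 2L) {
      opt <- stats::optimize(refit, log(c(1e-3, 30)), tol = 0.03)
      logL <- -opt$objective
      alpha <- c(1, exp(opt$minimum))
    } else {
      opt <- stats::nlminb(laf_hat, refit, lower = log(1e-3),
                           upper = log(30),
                           control = list(iter.max = 100, rel.tol = 1e-8))
      logL <- -opt$objective
      alpha <- c(1, exp(opt$par))
    }
  }
  k <- contexts$k0 + (Mu - 1L)
  bic <- k * log(contexts$n) - 2 * logL
  list(encoding = v, bic = bic, logL = logL, alpha = alpha, k = k)
}


# Summed frozen-nuisance log-likelihood of a raw model vector at FIXED
# per-class rates (no optimization): used to screen candidate single-rate
# moves during best-model refinement.
.ga_screen_ll <- function(v, alpha_cls, contexts, st) {
  n <- st$n
  syn <- st$synonymous
  pair_cls <- v + 1L
  total <- 0
  for (ct in contexts$genes) {
    q <- ct$brate
    q[syn] <- q[syn] * alpha_cls[pair_cls[st$pair_idx[syn]]]
    q[!syn] <- q[!syn] * ct$beta
    Q <- matrix(0, n, n)
    Q[ct$ij] <- q
    diag(Q) <- -rowSums(Q)
    per_codon <- -sum(ct$pi * diag(Q))
    if (per_codon <= 0) return(-Inf)
    Q <- Q / (per_codon / 3)
    ll <- .cpp_pruning_loglik(Q, ct$pi, ct$engine$edge,
                              ct$engine$tree$edge.length,
                              ct$engine$tipdata, ct$engine$wt,
                              ct$engine$nnode)
    if (!is.finite(ll)) return(-Inf)
    total <- total + ll
  }
  total
}

.enc_key <- function(v) paste(v, collapse = ".")

#' CHC genetic-algorithm search over synonymous rate partitions
#'
#' Searches partitions of the D synonymous rates into at most M classes to
#' minimize BIC over a collection of training alignments. The search is the
#' CHC scheme: random unique initialization; free recombination (each child
#' entry drawn 50-50 from either parent) with elitist truncation of parents
#' plus offspring to the top P; cataclysmic mutagenesis of all but the best
#' individual when the population becomes too uniform (relative fitness
#' range below `f_rel`) or stagnant (`f_stagnant` generations without new
#' members); termination after `g_conv` generations without a BIC
#' improvement above `delta_bic`.
#'
#' @param genes List of `list(alignment, tree)`, or a precomputed
#'   [ga_gene_contexts()] object.
#' @param M Number of rate classes to allow (`1 < M < N`, N = number of
#'   amino acids with exchangeable synonymous codons). Vectors using fewer
#'   than M classes (including the single-class null) remain in the search
#'   space.
#' @param config A [ga_config()]; the seed is required.
#' @param code A `genetic_code`.
#' @param options [fit_options()] for the baseline fits.
#' @return An object of class `ga_trace`: `models` (every model evaluated:
#'   encoding, BIC, fitted class rates), `best`, `baseline_bic`,
#'   `delta_bic_vs_null`, `generations`, `best_history`, `termination`,
#'   `config`, `pairs`.
#' @export
chc_search <- function(genes, M, config = ga_config(), code = genetic_code(),
                       options = fit_options(multistart = 1L)) {
  N_aa <- length(amino_acid_pair_groups(code))
  if (M < 2L || M >= N_aa) stop("class count must satisfy 1 < M < ", N_aa)
  contexts <- if (inherits(genes, "ga_contexts")) genes
              else ga_gene_contexts(genes, code, options)
  D <- nrow(synonymous_pairs(code))
  cache <- new.env(parent = emptyenv())
  trace <- list()
  evaluate <- function(v) {
    key <- .enc_key(v)
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    res <- .ga_evaluate(v, contexts, code, config)
    cache[[key]] <- res
    trace[[length(trace) + 1L]] <<- res
    res
  }
  null_bic <- evaluate(rep(0L, D))$bic

  run <- function() {
    pop_enc <- list(); pop_key <- character(0)
    if (isTRUE(config$include_null)) {
      pop_enc[[1L]] <- rep(0L, D)
      pop_key <- .enc_key(pop_enc[[1L]])
    }
    guard <- 0L
    while (length(pop_enc) < config$P) {
      v <- canonicalize_model(sample.int(M, D, replace = TRUE) - 1L, M)
      key <- .enc_key(v)
      guard <- guard + 1L
      if (guard > 1000L * config$P) break
      if (key %in% pop_key) next
      pop_enc[[length(pop_enc) + 1L]] <- v
      pop_key <- c(pop_key, key)
    }
    pop_bic <- vapply(pop_enc, function(v) evaluate(v)$bic, numeric(1))
    ord <- order(pop_bic, pop_key)
    pop_enc <- pop_enc[ord]; pop_key <- pop_key[ord]; pop_bic <- pop_bic[ord]

    best_hist <- min(pop_bic)
    prev_best <- min(pop_bic)
    no_improve <- 0L; stagnant <- 0L; gen <- 0L
    termination <- "max_generations"
    while (gen < config$max_generations) {
      gen <- gen + 1L
      # Step 3: free recombination, elitist truncation
      kids_enc <- list(); kids_key <- character(0)
      for (i in seq_len(config$P)) {
        par <- sample.int(length(pop_enc), 2L)
        mask <- stats::runif(D) < 0.5
        child <- ifelse(mask, pop_enc[[par[1]]], pop_enc[[par[2]]])
        child <- canonicalize_model(child, M)
        key <- .enc_key(child)
        if (key %in% kids_key || key %in% pop_key) next
        kids_enc[[length(kids_enc) + 1L]] <- child
        kids_key <- c(kids_key, key)
      }
      kid_bic <- vapply(kids_enc, function(v) evaluate(v)$bic, numeric(1))
      all_enc <- c(pop_enc, kids_enc)
      all_key <- c(pop_key, kids_key)
      all_bic <- c(pop_bic, kid_bic)
      ord <- order(all_bic, all_key)
      keep <- utils::head(ord, config$P)
      new_key <- all_key[keep]
      entered <- any(!(new_key %in% pop_key))
      pop_enc <- all_enc[keep]; pop_key <- new_key; pop_bic <- all_bic[keep]
      stagnant <- if (entered) 0L else stagnant + 1L

      cur_best <- pop_bic[1]
      best_hist <- c(best_hist, cur_best)
      if (prev_best - cur_best > config$delta_bic) no_improve <- 0L
      else no_improve <- no_improve + 1L
      prev_best <- min(prev_best, cur_best)
      if (no_improve >= config$g_conv) { termination <- "converged"; break }

      # Step 4: cataclysmic mutagenesis when inbred or stagnant
      rel_range <- (pop_bic[length(pop_bic)] - pop_bic[1]) /
        max(abs(pop_bic[1]), .Machine$double.eps)
      if (rel_range < config$f_rel || stagnant >= config$f_stagnant) {
        mut_enc <- pop_enc[1]; mut_key <- pop_key[1]
        for (i in seq_along(pop_enc)[-1]) {
          v <- pop_enc[[i]]
          for (try in seq_len(10L)) {
            w <- v
            flip <- stats::runif(D) < config$mu
            if (any(flip)) {
              w[flip] <- sample.int(M, sum(flip), replace = TRUE) - 1L
            }
            w <- canonicalize_model(w, M)
            if (!(.enc_key(w) %in% mut_key)) break
          }
          if (!(.enc_key(w) %in% mut_key)) {
            mut_enc[[length(mut_enc) + 1L]] <- w
            mut_key <- c(mut_key, .enc_key(w))
          }
        }
        pop_enc <- mut_enc; pop_key <- mut_key
        pop_bic <- vapply(pop_enc, function(v) evaluate(v)$bic, numeric(1))
        ord <- order(pop_bic, pop_key)
        pop_enc <- pop_enc[ord]; pop_key <- pop_key[ord]
        pop_bic <- pop_bic[ord]
        stagnant <- 0L
      }
    }
    list(best_enc = pop_enc[[1]], best_bic = pop_bic[1],
         generations = gen, best_history = best_hist,
         termination = termination)
  }
  res <- .with_seed(config$seed, run)

  if (isTRUE(config$refine_best)) {
    st <- .code_structure(code)
    best <- cache[[.enc_key(res$best_enc)]]
    moves <- 0L
    while (moves < 200L) {
      v <- best$encoding
      Mu <- max(v) + 1L
      if (Mu < 2L) break
      alpha_cls <- best$alpha
      base_ll <- .ga_screen_ll(v, alpha_cls, contexts, st)
      best_gain <- 0; best_w <- NULL
      for (d in seq_len(D)) {
        for (cl in 0:(Mu - 1L)) {
          if (cl == v[d]) next
          w <- v; w[d] <- cl
          gain <- .ga_screen_ll(w, alpha_cls, contexts, st) - base_ll
          if (gain > best_gain) { best_gain <- gain; best_w <- w }
        }
      }
      if (is.null(best_w) || best_gain < 1e-6) break
      cand <- evaluate(canonicalize_model(best_w, M))
      if (cand$bic < best$bic - 1e-9) {
        best <- cand
        moves <- moves + 1L
      } else break
    }
    res$best_enc <- best$encoding
    res$best_bic <- best$bic
  }

  structure(list(
    models = trace, best = cache[[.enc_key(res$best_enc)]],
    baseline_bic = null_bic, baseline_logL = contexts$logL0,
    delta_bic_vs_null = null_bic - res$best_bic,
    generations = res$generations, best_history = res$best_history,
    termination = res$termination, config = config,
    pairs = synonymous_pairs(code)$pair, M = M, n = contexts$n
  ), class = "ga_trace")
}

#' @export
print.ga_trace <- function(x, ...) {
  cat(sprintf(
    "CHC search: %d models evaluated over %d generations (%s)\n",
    length(x$models), x$generations, x$termination))
  cat(sprintf("best BIC %.2f (delta vs null %.2f), best model uses %d class(es)\n",
              x$best$bic, x$delta_bic_vs_null, max(x$best$encoding) + 1L))
  invisible(x)
}

#' Akaike weights from BIC scores
#'
#' `w(m) = exp((min BIC - BIC(m)) / 2)`, normalized to sum to 1.
#'
#' @param bic Numeric vector of finite scores.
#' @return Weights in (0, 1] summing to 1.
#' @export
akaike_weights <- function(bic) {
  if (length(bic) == 0L) stop("empty score vector")
  if (any(!is.finite(bic))) stop("scores must be finite")
  w <- exp((min(bic) - bic) / 2)
  w / sum(w)
}

#' Model-averaged categorical rate assignment
#'
#' Every model in a GA trace is given an Akaike weight from its BIC. Within
#' each model the fitted class rates are ranked: the smallest is labeled
#' `SELECTED`, the largest `NEUTRAL`, and intermediates `INT 1`, `INT 2`,
#' ... by rank. Expanding over the model's partition gives a categorical
#' label per rate, and the weights accumulate per category per rate. A rate
#' is unambiguous when its top category carries at least `threshold` of the
#' total weight.
#'
#' @param trace A `ga_trace`.
#' @param threshold Unambiguity threshold on the cumulative weight.
#' @return Object of class `model_average`: `weights` (D x categories
#'   matrix), `label`, `ambiguous` (logical), `pairs`.
#' @export
model_average <- function(trace, threshold = 0.90) {
  stopifnot(inherits(trace, "ga_trace"))
  models <- trace$models
  if (length(models) == 0L) stop("empty trace")
  w <- akaike_weights(vapply(models, `[[`, numeric(1), "bic"))
  M <- trace$M
  cats <- c("SELECTED", if (M > 2L) paste("INT", seq_len(M - 2L)), "NEUTRAL")
  D <- length(models[[1]]$encoding)
  acc <- matrix(0, D, length(cats), dimnames = list(trace$pairs, cats))
  for (i in seq_along(models)) {
    m <- models[[i]]
    labels <- .rate_categories(m$alpha)
    acc[cbind(seq_len(D), match(labels[m$encoding + 1L], cats))] <-
      acc[cbind(seq_len(D), match(labels[m$encoding + 1L], cats))] + w[i]
  }
  top <- apply(acc, 1, max)
  structure(list(
    weights = acc,
    label = cats[apply(acc, 1, which.max)],
    ambiguous = top < threshold,
    threshold = threshold, pairs = trace$pairs
  ), class = "model_average")
}

# Rank class rates of one model into categorical labels: smallest ->
# SELECTED, largest -> NEUTRAL, intermediates INT k by rank. A single-class
# model is entirely the reference rate, labeled NEUTRAL.
.rate_categories <- function(alpha) {
  Mu <- length(alpha)
  if (Mu == 1L) return("NEUTRAL")
  r <- order(order(alpha))  # rank, ties broken by class index
  ifelse(r == 1L, "SELECTED",
         ifelse(r == Mu, "NEUTRAL", paste("INT", r - 1L)))
}

#' @export
print.model_average <- function(x, ...) {
  cat("Model-averaged assignment:", sum(x$label == "SELECTED"), "SELECTED /",
      sum(x$label == "NEUTRAL"), "NEUTRAL;",
      sum(x$ambiguous), "ambiguous at", x$threshold, "\n")
  invisible(x)
}

#' Contingency of inferred vs simulated pair classes
#'
#' Places each codon pair in the Selected or Neutral class according to
#' which of the two categories received more model-averaged support, then
#' cross-tabulates against the simulated truth, computing the Matthews
#' correlation coefficient and a two-sided Fisher exact p-value, and
#' counting pairs whose assignment stays ambiguous at the weight threshold.
#'
#' @param ma A [model_average()] result.
#' @param truth Character vector over the same pairs with values
#'   `"selected"`/`"neutral"` (named vectors are matched by pair name).
#' @return List with `table` (2 x 2), `mcc`, `fisher_p`, `n_ambiguous`,
#'   `inferred`.
#' @export
truth_contingency <- function(ma, truth) {
  stopifnot(inherits(ma, "model_average"))
  if (!is.null(names(truth))) truth <- truth[ma$pairs]
  if (length(truth) != length(ma$pairs)) {
    stop("truth labels do not cover the pair universe")
  }
  truth <- tolower(as.character(truth))
  if (!all(truth %in% c("selected", "neutral"))) {
    stop("truth labels must be 'selected' or 'neutral'")
  }
  w_sel <- ma$weights[, "SELECTED"]
  w_neu <- ma$weights[, "NEUTRAL"]
  inferred <- ifelse(w_sel > w_neu, "selected", "neutral")
  tab <- table(factor(inferred, c("selected", "neutral")),
               factor(truth, c("selected", "neutral")),
               dnn = c("inferred", "truth"))
  list(table = tab, mcc = mcc_from_table(tab),
       fisher_p = stats::fisher.test(tab)$p.value,
       n_ambiguous = sum(ma$ambiguous), inferred = inferred)
}

#' Matthews correlation coefficient of a 2x2 table
#'
#' Defined as 0 when any margin is empty (no association measurable).
#'
#' @param tab A 2x2 contingency table (`TP FP / FN TN` layout).
#' @return MCC in [-1, 1].
#' @export
mcc_from_table <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2L, 2L)))
  tp <- tab[1, 1]; fp <- tab[1, 2]; fn <- tab[2, 1]; tn <- tab[2, 2]
  den <- sqrt((tp + fp)) * sqrt((tp + fn)) * sqrt((tn + fp)) * sqrt((tn + fn))
  if (den == 0) return(0)
  (tp * tn - fp * fn) / den
}

#' Enumerate all canonical partitions of D rates into at most M classes
#'
#' Restricted-growth-string enumeration; feasible for small D only. Used to
#' check the GA against exhaustive search on restricted genetic codes.
#'
#' @param D Number of rates.
#' @param M Maximum number of classes.
#' @return List of canonical integer vectors.
#' @export
enumerate_partitions <- function(D, M) {
  out <- list()
  rec <- function(prefix, maxc) {
    if (length(prefix) == D) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (cl in 0:min(maxc + 1L, M - 1L)) {
      rec(c(prefix, cl), max(maxc, cl))
    }
  }
  rec(integer(0), -1L)
  out
}
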