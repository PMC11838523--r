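#' Generate a deterministic set of synthetic gene fixtures
#'
#' Simulates `n_genes` codon alignments under a chosen MSS spec along
#' random gene trees and (optionally) writes them in the single-file
#' alignment+tree format plus a file list consumable by the joint fitter
#' and the GA selector. Deterministic given the seed.
#'
#' @param n_genes Number of genes.
#' @param ntaxa Taxa per gene.
#' @param codons Codon sites per gene.
#' @param spec An [mss_spec()] (default standard MG94 with omega 0.25).
#' @param theta Nucleotide exchangeabilities.
#' @param tree_length Total tree length per gene (substitutions/site).
#' @param seed Seed for all randomness.
#' @param dir Optional output directory; when given, gene files
#'   `gene_XX.fa` and `files.txt` are written there.
#' @param code A `genetic_code`.
#' @return Invisibly, a list of `list(alignment, tree)`; with `dir`, the
#'   attribute `file_list` holds the list-file path.
#' @export
generate_fixture_genes <- function(n_genes = 4L, ntaxa = 8L, codons = 150L,
                                   spec = NULL, theta = NULL,
                                   tree_length = 1.0, seed = 1L, dir = NULL,
                                   code = genetic_code()) {
  if (is.null(spec)) spec <- mss_spec("standard", code, beta = 0.25)
  if (is.null(theta)) theta <- nuc_rates(AC = 0.6, AT = 0.35, CG = 0.45,
                                         CT = 1.25, GT = 0.4)
  genes <- .with_seed(seed, function() {
    lapply(seq_len(n_genes), function(g) {
      tr <- random_gene_tree(ntaxa, tree_length)
      pf <- matrix(stats::rgamma(12, shape = 8), 3, 4)
      pf <- pf / rowSums(pf)
      dimnames(pf) <- list(paste0("pos", 1:3), c("A", "C", "G", "T"))
      freqs <- structure(pf, class = c("positional_freq", "matrix"),
                         source = "CF3x4")
      rates <- codon_rate_matrix(spec, theta, freqs, code)
      list(alignment = simulate_alignment(rates, tr, codons, code),
           tree = tr)
    })
  })
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- character(n_genes)
    for (g in seq_len(n_genes)) {
      paths[g] <- file.path(dir, sprintf("gene_%02d.fa", g))
      write_gene_file(genes[[g]]$alignment, genes[[g]]$tree, paths[g])
    }
    list_path <- file.path(dir, "files.txt")
    writeLines(basename(paths), list_path)
    attr(genes, "file_list") <- list_path
  }
  invisible(genes)
}

#' Serialize a gene fit to JSON
#'
#' Alpha estimates are keyed by the canonical pair ordering; the alpha
#' block is omitted for the standard family. The resolved configuration
#' (family, seed-bearing options) is embedded.
#'
#' @param fit A `gene_fit`.
#' @param path Optional output file.
#' @param comparison Optional `mss_comparison` (e.g. LRT vs MG94).
#' @param config Optional list recorded under `$config`.
#' @return JSON string (invisibly the path when `path` is given).
#' @export
fit_to_json <- function(fit, path = NULL, comparison = NULL, config = NULL) {
  ic <- information_criteria(fit)
  obj <- list(
    family = fit$family, logL = fit$logL, omega = fit$beta,
    k = fit$k, n = fit$n, aic = ic$aic, bic = ic$bic,
    theta = as.list(unclass(fit$theta)),
    branch_lengths = fit$tree$edge.length,
    convergence = fit$convergence
  )
  if (fit$family != "standard") {
    alpha_per_pair <- fit$spec$alpha[fit$spec$class_of]
    obj$alpha <- as.list(stats::setNames(alpha_per_pair, fit$spec$pairs$pair))
  }
  if (!is.null(comparison)) {
    obj$lrt_vs_mg94 <- list(stat = comparison$lrt, df = comparison$df,
                            p_value = comparison$p_value)
  }
  if (!is.null(config)) obj$config <- config
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Serialize a GA trace with model averaging to JSON
#'
#' Records every model considered (encoding, BIC, fitted class rates), the
#' best model, the baseline, the model-averaged categorical vector and
#' per-rate category weights.
#'
#' @param trace A `ga_trace`.
#' @param ma A [model_average()] result (computed from the trace when
#'   `NULL`).
#' @param path Optional output file.
#' @param config Optional list recorded under `$config`.
#' @return JSON string, or invisibly the path.
#' @export
ga_to_json <- function(trace, ma = NULL, path = NULL, config = NULL) {
  if (is.null(ma)) ma <- model_average(trace)
  obj <- list(
    models = lapply(trace$models, function(m) {
      list(encoding = m$encoding, bic = m$bic, logL = m$logL,
           alpha = m$alpha)
    }),
    best = list(encoding = trace$best$encoding, bic = trace$best$bic),
    baseline_bic = trace$baseline_bic,
    delta_bic_vs_null = trace$delta_bic_vs_null,
    generations = trace$generations, termination = trace$termination,
    pairs = trace$pairs,
    model_average = list(
      label = stats::setNames(as.list(ma$label), ma$pairs),
      weights = apply(ma$weights, 1, as.list),
      ambiguous = stats::setNames(as.list(ma$ambiguous), ma$pairs),
      threshold = ma$threshold
    ),
    config = c(list(P = trace$config$P, seed = trace$config$seed,
                    M = trace$M), config)
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
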