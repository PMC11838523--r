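#' Nucleotide exchangeabilities (REV component)
#'
#' Six rate multipliers over unordered nucleotide pairs. The model is
#' time-reversible so theta(x,y) = theta(y,x); for identifiability the AG
#' rate is the reference and is fixed to 1 during fitting.
#'
#' @param AC,AG,AT,CG,CT,GT Nonnegative rate multipliers.
#' @return Named numeric vector of length 6 with class `nuc_rates`.
#' @export
nuc_rates <- function(AC = 1, AG = 1, AT = 1, CG = 1, CT = 1, GT = 1) {
  th <- c(AC = AC, AG = AG, AT = AT, CG = CG, CT = CT, GT = GT)
  if (any(th < 0)) stop("exchangeabilities must be nonnegative")
  structure(th, class = "nuc_rates")
}

.theta_key <- function(n, m) paste0(pmin(n, m), pmax(n, m))

#' MSS model specification
#'
#' Defines how synonymous substitution rates alpha(x,y) vary over the
#' single-step synonymous codon pairs of a genetic code:
#' \describe{
#'   \item{standard}{one class, alpha = 1; the plain MG94xREV model.}
#'   \item{a_priori}{a fixed user partition into `K` classes with the
#'     designated reference class constrained to alpha = 1.}
#'   \item{ga}{same parameter structure as `a_priori`; the partition comes
#'     from a genetic-algorithm search instead of prior knowledge.}
#'   \item{synrev}{one class per amino acid (18 under the universal code),
#'     mean of alpha over all pairs constrained to 1.}
#'   \item{synrevcodon}{one class per codon pair (67 under the universal
#'     code), mean-1 constraint, i.e. 66 free relative synonymous rates.}
#' }
#'
#' @param family One of `"standard"`, `"a_priori"`, `"ga"`, `"synrev"`,
#'   `"synrevcodon"`.
#' @param code A `genetic_code`.
#' @param classes Integer vector over pairs (same order as
#'   [synonymous_pairs()]) giving 1-based class indices; required for
#'   `a_priori`/`ga`, derived automatically otherwise.
#' @param alpha Numeric vector of per-class rates (>= 0). Defaults to all 1.
#'   Mean-constrained families are renormalized so the mean over pairs is 1.
#' @param beta Nonsynonymous rate (dN/dS-like omega), >= 0.
#' @param reference_class Class whose alpha is fixed to 1 for
#'   `a_priori`/`ga` specs.
#' @return An object of class `mss_spec`: list with `family`, `pairs`,
#'   `class_of` (1-based class per pair), `alpha` (per class), `beta`,
#'   `constraint`, `reference_class`, `n_classes`.
#' @examples
#' sp <- mss_spec("synrev")
#' sp$n_classes  # 18 under the universal code
#' @export
mss_spec <- function(family = c("standard", "a_priori", "ga", "synrev",
                                "synrevcodon"),
                     code = genetic_code(), classes = NULL, alpha = NULL,
                     beta = 1, reference_class = 1L) {
  family <- match.arg(family)
  pairs <- synonymous_pairs(code)
  D <- nrow(pairs)
  if (beta < 0) stop("beta must be nonnegative")
  groups <- NULL
  if (family == "standard") {
    class_of <- rep(1L, D)
    if (is.null(alpha)) alpha <- 1
    if (length(alpha) != 1L || abs(alpha - 1) > 1e-12) {
      stop("standard family forces alpha = 1")
    }
    constraint <- "none"
  } else if (family == "synrev") {
    aa <- pairs$amino_acid
    groups <- sort(unique(aa))
    class_of <- match(aa, groups)
    if (is.null(alpha)) alpha <- rep(1, length(groups))
    constraint <- "mean_over_pairs_equals_1"
  } else if (family == "synrevcodon") {
    class_of <- seq_len(D)
    if (is.null(alpha)) alpha <- rep(1, D)
    constraint <- "mean_over_pairs_equals_1"
  } else {  # a_priori / ga
    if (is.null(classes)) stop("classes required for family ", family)
    classes <- as.integer(classes)
    if (length(classes) != D) stop("classes must have one entry per pair")
    K <- max(classes)
    if (!setequal(unique(classes), seq_len(K))) {
      stop("classes must use contiguous indices 1..K")
    }
    N_aa <- length(amino_acid_pair_groups(code))
    if (K <= 1L || K >= N_aa) {
      stop("class count must satisfy 1 < K < ", N_aa)
    }
    class_of <- classes
    if (is.null(alpha)) alpha <- rep(1, K)
    if (reference_class < 1L || reference_class > K) {
      stop("reference_class out of range")
    }
    if (abs(alpha[reference_class] - 1) > 1e-12) {
      stop("reference class alpha must equal 1")
    }
    constraint <- "reference_class_fixed_to_1"
  }
  M <- max(class_of)
  if (length(alpha) != M) stop("alpha must have one entry per class")
  if (any(alpha < 0)) stop("alpha must be nonnegative")
  if (constraint == "mean_over_pairs_equals_1") {
    mu <- mean(alpha[class_of])
    if (mu <= 0) stop("cannot normalize: all alpha are 0")
    alpha <- alpha / mu
  }
  structure(list(
    family = family, pairs = pairs, class_of = class_of,
    alpha = as.numeric(alpha), beta = as.numeric(beta),
    constraint = constraint,
    reference_class = if (constraint == "reference_class_fixed_to_1")
      as.integer(reference_class) else NA_integer_,
    n_classes = M, groups = groups
  ), class = "mss_spec")
}

#' @export
print.mss_spec <- function(x, ...) {
  cat("MSS spec:", x$family, "-", x$n_classes, "class(es) over",
      nrow(x$pairs), "synonymous pairs; beta =", signif(x$beta, 4), "\n")
  invisible(x)
}

#' Number of free rate parameters implied by an MSS spec
#'
#' Counts only the synonymous-rate parameters beyond the baseline model:
#' 0 for standard, K-1 for a_priori/ga (reference fixed to 1), and
#' `n_classes - 1` for the mean-constrained families (e.g. 66 for
#' SynREVCodon, 17 for SynREV under the universal code).
#'
#' @param spec An `mss_spec`.
#' @return Integer count.
#' @export
n_free_alpha <- function(spec) {
  stopifnot(inherits(spec, "mss_spec"))
  if (spec$family == "standard") 0L else spec$n_classes - 1L
}

#' Serialize an MSS spec to JSON
#' @param spec An `mss_spec`.
#' @param path Optional output file; if `NULL` the JSON string is returned.
#' @export
spec_to_json <- function(spec, path = NULL) {
  obj <- list(
    family = spec$family,
    pairs = spec$pairs$pair,
    class_of = spec$class_of,
    alpha = spec$alpha,
    beta = spec$beta,
    constraint = spec$constraint,
    reference_class = spec$reference_class
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Deserialize an MSS spec from JSON
#' @param x JSON string or file path produced by [spec_to_json()].
#' @param code A `genetic_code` (must match the pair universe).
#' @export
spec_from_json <- function(x, code = genetic_code()) {
  obj <- if (file.exists(x)) jsonlite::read_json(x, simplifyVector = TRUE)
         else jsonlite::fromJSON(x)
  pairs <- synonymous_pairs(code)
  if (!identical(as.character(obj$pairs), pairs$pair)) {
    stop("pair universe in JSON does not match the genetic code")
  }
  mss_spec(obj$family, code,
           classes = if (obj$family %in% c("a_priori", "ga")) obj$class_of,
           alpha = obj$alpha, beta = obj$beta,
           reference_class = if (!is.null(obj$reference_class) &&
                                 !is.na(obj$reference_class))
             obj$reference_class else 1L)
}
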