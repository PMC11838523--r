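#' Genetic code tables
#'
#' A `genetic_code` object maps all 64 codons (DNA alphabet, `A`/`C`/`G`/`T`)
#' to single-letter amino-acid symbols, with `*` marking stop codons. The
#' universal (standard) code has 61 sense codons and 3 stops. Codons are kept
#' in lexicographic order throughout the package so that pair and state
#' indices are stable across runs.
#'
#' @param name Identifier; only `"universal"` is built in. Other codes can be
#'   loaded with [genetic_code_from_json()].
#' @return An object of class `genetic_code`: a list with `table` (named
#'   character vector of length 64), `name`, `sense` (sense codons, sorted),
#'   and `stops`.
#' @examples
#' code <- genetic_code()
#' translate_codon("ATG", code)
#' @export
genetic_code <- function(name = "universal") {
  if (!identical(name, "universal")) {
    stop("only the universal code is built in; use genetic_code_from_json()")
  }
  .universal_code()
}

# Built once per session from seqinr's standard-code translation.
.code_cache <- new.env(parent = emptyenv())

.universal_code <- function() {
  if (!is.null(.code_cache$universal)) return(.code_cache$universal)
  codons <- all_codons()
  aa <- vapply(codons, function(cd) {
    seqinr::translate(strsplit(cd, "")[[1]], numcode = 1)
  }, character(1))
  names(aa) <- codons
  code <- new_genetic_code(aa, "universal")
  .code_cache$universal <- code
  code
}

new_genetic_code <- function(table, name) {
  stopifnot(length(table) == 64L, !is.null(names(table)))
  table <- table[order(names(table))]
  if (!identical(names(table), all_codons())) {
    stop("genetic code table must cover all 64 codons over {A,C,G,T}")
  }
  structure(list(
    table = table,
    name  = name,
    sense = names(table)[table != "*"],
    stops = names(table)[table == "*"]
  ), class = "genetic_code")
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("Genetic code:", x$name, "-", length(x$sense), "sense codons,",
      length(x$stops), "stops\n")
  invisible(x)
}

#' Load a genetic code from a JSON codon table
#'
#' The file must contain a single JSON object mapping each of the 64 codons to
#' an amino-acid symbol, with `"*"` (or `"STOP"`) for stop codons. Restricted
#' codes (fewer sense codons, obtained by marking codons as stops) are allowed
#' and are useful for small exhaustive-search checks.
#'
#' @param path Path to the JSON file.
#' @param name Identifier stored on the object.
#' @return A `genetic_code` object.
#' @export
genetic_code_from_json <- function(path, name = basename(path)) {
  tab <- unlist(jsonlite::read_json(path))
  tab[tab == "STOP"] <- "*"
  new_genetic_code(tab, name)
}

#' Restrict a genetic code to a subset of sense codons
#'
#' Marks every sense codon outside `keep` as a stop. Used to build small
#' state spaces (e.g. a single amino-acid family) where exhaustive model
#' enumeration is feasible.
#'
#' @param code A `genetic_code`.
#' @param keep Character vector of codons to keep as sense codons.
#' @return A `genetic_code` with `length(keep)` sense codons.
#' @export
restrict_genetic_code <- function(code, keep) {
  stopifnot(inherits(code, "genetic_code"), all(keep %in% code$sense))
  tab <- code$table
  tab[setdiff(names(tab), keep)] <- "*"
  new_genetic_code(tab, paste0(code$name, "-restricted"))
}

#' All 64 codons in lexicographic order
#' @return Character vector of length 64.
#' @export
all_codons <- function() {
  nt <- c("A", "C", "G", "T")
  g <- expand.grid(p3 = nt, p2 = nt, p1 = nt, stringsAsFactors = FALSE)
  sort(paste0(g$p1, g$p2, g$p3))
}

#' Translate a single codon
#'
#' @param codon A 3-letter codon over `A`/`C`/`G`/`T`.
#' @param code A `genetic_code`.
#' @return The amino-acid symbol, or `"*"` for a stop codon.
#' @export
translate_codon <- function(codon, code = genetic_code()) {
  stopifnot(inherits(code, "genetic_code"))
  if (!is.character(codon) || length(codon) != 1L ||
      is.na(match(codon, names(code$table)))) {
    stop("unknown codon: ", paste(codon, collapse = ","))
  }
  unname(code$table[[codon]])
}

#' Single-nucleotide neighbors of a sense codon
#'
#' Every codon has exactly 9 single-nucleotide neighbors. Neighbors that are
#' stop codons are excluded when `sense_only = TRUE`.
#'
#' @param codon A sense codon.
#' @param code A `genetic_code`.
#' @param sense_only Drop neighbors that are stop codons.
#' @return A data frame with columns `codon`, `position` (1-3), `synonymous`.
#' @export
codon_neighbors <- function(codon, code = genetic_code(), sense_only = FALSE) {
  if (translate_codon(codon, code) == "*") stop("stop codon input: ", codon)
  nt <- c("A", "C", "G", "T")
  chars <- strsplit(codon, "")[[1]]
  out <- do.call(rbind, lapply(1:3, function(p) {
    alt <- setdiff(nt, chars[p])
    nb <- vapply(alt, function(a) {
      x <- chars; x[p] <- a; paste(x, collapse = "")
    }, character(1))
    data.frame(codon = nb, position = p, stringsAsFactors = FALSE)
  }))
  aa0 <- translate_codon(codon, code)
  out$synonymous <- unname(code$table[out$codon] == aa0 &
                             code$table[out$codon] != "*")
  if (sense_only) out <- out[code$table[out$codon] != "*", , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Enumerate single-step synonymous codon pairs
#'
#' Lists every unordered pair of sense codons that translate to the same amino
#' acid and differ at exactly one nucleotide position. Under the universal
#' code there are 67 such pairs; they are the rate classes of the
#' codon-pair-level MSS model. Ordering is lexicographic by (`codon_a`,
#' `codon_b`) with `codon_a < codon_b`, so pair indices are stable.
#'
#' @param code A `genetic_code`.
#' @return A data frame of class `synonymous_pairs` with columns `pair`
#'   (`"AAA:AAG"`-style label), `codon_a`, `codon_b`, `amino_acid`, `position`
#'   (differing position), `nuc_a`, `nuc_b` (exchanged nucleotides, with
#'   `nuc_a < nuc_b`).
#' @examples
#' nrow(synonymous_pairs())  # 67
#' @export
synonymous_pairs <- function(code = genetic_code()) {
  key <- paste0("pairs_", code$name)
  if (!is.null(.code_cache[[key]]) && identical(code$name, "universal")) {
    return(.code_cache[[key]])
  }
  sense <- code$sense
  rows <- list()
  for (a in sense) {
    nb <- codon_neighbors(a, code, sense_only = TRUE)
    nb <- nb[nb$synonymous & nb$codon > a, , drop = FALSE]
    if (nrow(nb) == 0L) next
    for (k in seq_len(nrow(nb))) {
      b <- nb$codon[k]; p <- nb$position[k]
      nn <- sort(c(substr(a, p, p), substr(b, p, p)))
      rows[[length(rows) + 1L]] <- data.frame(
        pair = paste(a, b, sep = ":"), codon_a = a, codon_b = b,
        amino_acid = translate_codon(a, code), position = p,
        nuc_a = nn[1], nuc_b = nn[2], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$codon_a, out$codon_b), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("synonymous_pairs", "data.frame")
  if (identical(code$name, "universal")) .code_cache[[key]] <- out
  out
}

#' Synonymous pairs grouped by amino acid
#'
#' @param code A `genetic_code`.
#' @return A named list mapping each amino acid that has at least one
#'   single-step synonymous pair to the subset of [synonymous_pairs()] rows
#'   for that amino acid. Under the universal code there are 18 groups.
#' @export
amino_acid_pair_groups <- function(code = genetic_code()) {
  pairs <- synonymous_pairs(code)
  split(pairs, pairs$amino_acid)
}
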