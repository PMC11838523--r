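#' Codon alignment container
#'
#' Stores an in-frame coding alignment as a taxa-by-sites matrix of codon
#' state indices (positions in [all_codons()]), with `NA` for missing codons
#' (gaps or ambiguity codes anywhere in the triplet). Stop codons in
#' non-missing cells are rejected, matching the alignment filtering rule that
#' coding alignments contain no stops and have length divisible by 3.
#'
#' @param x Either a named character vector of nucleotide sequences (equal
#'   lengths, divisible by 3) or a character matrix of codon strings
#'   (taxa x sites).
#' @param code A `genetic_code` used to validate that no stop codons occur.
#' @return An object of class `codon_alignment`: list with `names`,
#'   `codon_idx` (integer matrix taxa x sites), `n_sites`.
#' @export
codon_alignment <- function(x, code = genetic_code()) {
  if (is.matrix(x)) {
    codon_mat <- x
    taxa <- rownames(x)
    if (is.null(taxa)) stop("codon matrix must have row names (taxa)")
  } else {
    if (is.null(names(x))) stop("sequences must be named")
    lens <- nchar(x)
    if (length(unique(lens)) != 1L) stop("sequences must have equal length")
    if (lens[1] %% 3L != 0L) {
      stop("nucleotide length ", lens[1], " is not a multiple of 3")
    }
    taxa <- names(x)
    n_sites <- lens[1] %/% 3L
    codon_mat <- t(vapply(x, function(s) {
      substring(s, seq(1, lens[1], by = 3), seq(3, lens[1], by = 3))
    }, character(n_sites)))
    if (n_sites == 1L) codon_mat <- matrix(codon_mat, ncol = 1L,
                                           dimnames = list(taxa, NULL))
  }
  if (nrow(codon_mat) < 2L) stop("alignment needs >= 2 sequences")
  codon_mat[] <- toupper(gsub("U", "T", codon_mat, fixed = TRUE))
  idx <- matrix(match(codon_mat, all_codons()), nrow(codon_mat),
                dimnames = list(taxa, NULL))
  obs <- idx[!is.na(idx)]
  if (length(obs)) {
    bad <- code$table[all_codons()[obs]] == "*"
    if (any(bad)) {
      stop("alignment contains stop codons (e.g. ",
           all_codons()[obs[which(bad)[1]]], ")")
    }
  }
  structure(list(names = taxa, codon_idx = idx, n_sites = ncol(idx)),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("Codon alignment:", length(x$names), "sequences x", x$n_sites,
      "codon sites\n")
  invisible(x)
}

#' Convert a codon alignment back to codon strings
#' @param x A `codon_alignment`.
#' @param ... Unused.
#' @return Character matrix of codons, `NA` for missing.
#' @export
as.character.codon_alignment <- function(x, ...) {
  m <- matrix(all_codons()[x$codon_idx], nrow = length(x$names),
              dimnames = list(x$names, NULL))
  m
}

#' Read a codon alignment from FASTA or sequential NEXUS
#'
#' @param path File path.
#' @param format `"auto"` (sniff `#NEXUS` magic), `"fasta"`, or `"nexus"`.
#' @param code A `genetic_code` for validation.
#' @return A `codon_alignment`.
#' @export
read_codon_alignment <- function(path, format = c("auto", "fasta", "nexus"),
                                 code = genetic_code()) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- toupper(trimws(readLines(path, n = 1L)))
    format <- if (startsWith(first, "#NEXUS")) "nexus" else "fasta"
  }
  if (format == "nexus") {
    lst <- ape::read.nexus.data(path)
    seqs <- vapply(lst, function(s) paste(toupper(s), collapse = ""),
                   character(1))
  } else {
    bin <- ape::read.FASTA(path)
    seqs <- vapply(as.character(bin), function(s) {
      paste(toupper(s), collapse = "")
    }, character(1))
  }
  codon_alignment(seqs, code)
}

#' Write a codon alignment as FASTA
#' @param aln A `codon_alignment`.
#' @param path Output path.
#' @param missing_as Character used for missing codons (default `"---"`).
#' @export
write_fasta_alignment <- function(aln, path, missing_as = "---") {
  m <- as.character.codon_alignment(aln)
  m[is.na(m)] <- missing_as
  lines <- character(0)
  for (i in seq_along(aln$names)) {
    lines <- c(lines, paste0(">", aln$names[i]),
               paste(m[i, ], collapse = ""))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write an alignment together with its gene tree in one file
#'
#' The single-file format used for gene lists: FASTA records followed by one
#' Newick line. This mirrors the file-list contract of the joint fitter and
#' the GA selector, where each listed file carries an alignment and its tree.
#'
#' @param aln A `codon_alignment`.
#' @param tree An `ape::phylo` tree whose tip labels match the alignment.
#' @param path Output path.
#' @export
write_gene_file <- function(aln, tree, path) {
  write_fasta_alignment(aln, path)
  cat(ape::write.tree(tree), "\n", sep = "", file = path, append = TRUE)
  invisible(path)
}

#' Read a single-gene file (alignment + tree)
#'
#' Accepts either the FASTA-plus-Newick single-file format written by
#' [write_gene_file()], or a NEXUS file with a data block and a trees block.
#'
#' @param path File path.
#' @param code A `genetic_code`.
#' @return List with elements `alignment` (a `codon_alignment`) and `tree`
#'   (`ape::phylo`).
#' @export
read_gene_file <- function(path, code = genetic_code()) {
  first <- toupper(trimws(readLines(path, n = 1L)))
  if (startsWith(first, "#NEXUS")) {
    aln <- read_codon_alignment(path, "nexus", code)
    tree <- ape::read.nexus(path)
    if (inherits(tree, "multiPhylo")) tree <- tree[[1]]
    return(list(alignment = aln, tree = tree))
  }
  lines <- readLines(path)
  tree_ln <- which(startsWith(trimws(lines), "("))
  if (length(tree_ln) == 0L) {
    stop("no Newick tree line found in ", path)
  }
  tree <- ape::read.tree(text = lines[tree_ln[length(tree_ln)]])
  fasta <- lines[seq_len(tree_ln[length(tree_ln)] - 1L)]
  tf <- tempfile(fileext = ".fa")
  on.exit(unlink(tf))
  writeLines(fasta, tf)
  aln <- read_codon_alignment(tf, "fasta", code)
  if (!all(tree$tip.label %in% aln$names)) {
    stop("tree tip labels not found in alignment: ", path)
  }
  list(alignment = aln, tree = tree)
}

#' Read a newline-separated gene file list
#'
#' @param path Path to a text file of gene-file paths (one per line;
#'   relative paths are resolved against the list file's directory).
#'   Duplicate paths are dropped with a warning.
#' @param code A `genetic_code`.
#' @return List of `list(alignment, tree)` entries.
#' @export
read_file_list <- function(path, code = genetic_code()) {
  paths <- trimws(readLines(path))
  paths <- paths[nzchar(paths)]
  if (anyDuplicated(paths)) {
    warning("duplicate paths in file list; deduplicating")
    paths <- unique(paths)
  }
  base <- dirname(normalizePath(path))
  lapply(paths, function(p) {
    if (!file.exists(p)) p <- file.path(base, p)
    if (!file.exists(p)) stop("gene file not found: ", p)
    read_gene_file(p, code)
  })
}
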