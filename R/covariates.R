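#' Synonymous SNP density per codon pair
#'
#' For a population sample of haplotypes (an in-frame alignment), a codon
#' column contributes one segregating site to pair (a, b) when exactly the
#' two codons a and b segregate there and they form a single-step
#' synonymous pair. Columns with more than two segregating codons or any
#' nonsynonymous segregation are excluded. The density for a pair is its
#' SNP count divided by the number of codons of the pair's amino acid in
#' the gene, counted on the sample's majority-consensus sequence.
#'
#' @param aln A `codon_alignment` of >= 2 haplotypes.
#' @param code A `genetic_code`.
#' @return Data frame with columns `pair`, `amino_acid`, `snp_count`,
#'   `aa_count`, `density` (NA when the amino acid is absent from the
#'   consensus).
#' @export
snp_density <- function(aln, code = genetic_code()) {
  stopifnot(inherits(aln, "codon_alignment"))
  pairs <- synonymous_pairs(code)
  codons <- all_codons()
  counts <- stats::setNames(integer(nrow(pairs)), pairs$pair)
  consensus_aa <- character(aln$n_sites)
  for (j in seq_len(aln$n_sites)) {
    col <- aln$codon_idx[, j]
    col <- col[!is.na(col)]
    if (!length(col)) { consensus_aa[j] <- NA_character_; next }
    tab <- sort(table(col), decreasing = TRUE)
    consensus_aa[j] <- unname(code$table[codons[as.integer(names(tab)[1])]])
    seg <- as.integer(names(tab))
    if (length(seg) != 2L) next
    a <- codons[min(seg)]; b <- codons[max(seg)]
    key <- paste(a, b, sep = ":")
    hit <- match(key, pairs$pair)
    if (!is.na(hit)) counts[hit] <- counts[hit] + 1L
  }
  aa_counts <- table(factor(consensus_aa,
                            levels = sort(unique(pairs$amino_acid))))
  aa_n <- as.integer(aa_counts[pairs$amino_acid])
  data.frame(pair = pairs$pair, amino_acid = pairs$amino_acid,
             snp_count = as.integer(counts), aa_count = aa_n,
             density = ifelse(aa_n > 0, counts / aa_n, NA_real_),
             stringsAsFactors = FALSE)
}

#' Mean per-pair SNP density over genes
#'
#' Simple (unweighted) mean of per-gene densities, dropping genes where the
#' pair's amino acid is absent.
#'
#' @param alns List of `codon_alignment` population samples.
#' @param code A `genetic_code`.
#' @return Data frame with `pair` and `mean_density`.
#' @export
mean_snp_density <- function(alns, code = genetic_code()) {
  per_gene <- lapply(alns, snp_density, code = code)
  dens <- vapply(per_gene, `[[`, numeric(nrow(per_gene[[1]])), "density")
  data.frame(pair = per_gene[[1]]$pair,
             mean_density = rowMeans(as.matrix(dens), na.rm = TRUE),
             stringsAsFactors = FALSE)
}

# Anticodons (DNA alphabet) whose wobble-A is modified to inosine in
# eukaryotes, and the queuosine-modified wobble-G anticodons (His, Asp,
# Asn, Tyr).
.INOSINE_ANTICODONS <- c("AGC", "AGG", "ACG", "AGA", "AAG", "AAC", "AAT",
                         "AGT")
.QUEUOSINE_ANTICODONS <- c("GTG", "GTC", "GTT", "GTA")

# After modification pooling, six codons remain without a direct decoder;
# each is assigned the pooled abundance of its stated donor codon (wobble
# rules: a two-fold U/C-reading isoacceptor, or a G/A-reading isoacceptor
# for Arg and Gly).
.AMBIGUOUS_DONORS <- c(TTT = "TTC", AGT = "AGC", TGT = "TGC",
                       CGG = "CGA", GGG = "GGA", GGT = "GGC")

#' Read a tab-delimited tRNA abundance table
#'
#' Columns: anticodon (RNA or DNA alphabet), amino acid, raw transcript
#' count. Counts for the same anticodon are summed.
#'
#' @param path File path.
#' @return Data frame with `anticodon` (DNA alphabet), `amino_acid`,
#'   `count`.
#' @export
read_trna_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  names(df)[1:3] <- c("anticodon", "amino_acid", "count")
  df$anticodon <- toupper(gsub("U", "T", df$anticodon, fixed = TRUE))
  if (any(!grepl("^[ACGT]{3}$", df$anticodon))) {
    stop("unknown anticodon entries in ", path)
  }
  agg <- stats::aggregate(count ~ anticodon + amino_acid, df, sum)
  agg
}

.revcomp_codon <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  vapply(strsplit(x, ""), function(ch) {
    paste(comp[rev(ch)], collapse = "")
  }, character(1))
}

#' Pool tRNA decoder abundance per codon
#'
#' Raw per-anticodon transcript counts are normalized to counts per million
#' (CPM; no gene-length normalization since tRNA genes are nearly equal
#' length). Each anticodon's CPM enters the pool of its Watson-Crick
#' cognate codon (the reverse complement). Inosine-modified wobble-A
#' anticodons additionally decode the synonymous A- and C-ending codons;
#' queuosine-modified wobble-G anticodons (His, Asp, Asn, Tyr) additionally
#' decode the cognate T-ending codons. The six codons left without a
#' decoder after pooling (TTT, AGT, TGT, CGG, GGG, GGT) are assigned the
#' pooled abundance of their wobble-rule donor (TTC, AGC, TGC, CGA, GGA,
#' GGC respectively). All modifiable tRNAs are assumed modified, in all
#' tissues, with equal binding to every codon they recognize.
#'
#' @param table Data frame from [read_trna_table()] (or with the same
#'   columns).
#' @param code A `genetic_code`.
#' @return Named numeric vector of pooled decoder abundance (CPM) per sense
#'   codon; codons with no known decoder get `NA`.
#' @export
pool_trna_abundances <- function(table, code = genetic_code()) {
  stopifnot(all(c("anticodon", "count") %in% names(table)))
  if (any(table$count < 0)) stop("negative counts")
  cpm <- table$count / max(sum(table$count), 1) * 1e6
  anti <- table$anticodon
  pools <- stats::setNames(rep(NA_real_, length(code$sense)), code$sense)
  add <- function(codon, x) {
    hit <- match(codon, names(pools))
    ok <- !is.na(hit)
    for (i in which(ok)) {
      pools[[hit[i]]] <<- if (is.na(pools[[hit[i]]])) x[i]
                          else pools[[hit[i]]] + x[i]
    }
  }
  # Watson-Crick cognates
  add(.revcomp_codon(anti), cpm)
  aa_of <- function(cd) unname(code$table[cd])
  # inosine: wobble A reads A- and C-ending synonymous codons too
  ino <- which(anti %in% .INOSINE_ANTICODONS)
  for (i in ino) {
    cognate <- .revcomp_codon(anti[i])          # T-ending codon
    stem <- substr(cognate, 1, 2)
    for (endn in c("A", "C")) {
      target <- paste0(stem, endn)
      if (target %in% code$sense && aa_of(target) == aa_of(cognate)) {
        add(target, cpm[i])
      }
    }
  }
  # queuosine: wobble G additionally reads the T-ending synonymous codon
  que <- which(anti %in% .QUEUOSINE_ANTICODONS)
  for (i in que) {
    cognate <- .revcomp_codon(anti[i])          # C-ending codon
    target <- paste0(substr(cognate, 1, 2), "T")
    if (target %in% code$sense && aa_of(target) == aa_of(cognate)) {
      add(target, cpm[i])
    }
  }
  # wobble-rule donors for the six ambiguous codons
  for (cd in names(.AMBIGUOUS_DONORS)) {
    if (cd %in% names(pools)) {
      pools[[cd]] <- pools[[.AMBIGUOUS_DONORS[[cd]]]]
    }
  }
  pools
}

#' tRNA abundance ratio for a synonymous codon pair
#'
#' The abundance of the more common decoder pool over the less common one,
#' so the ratio is always >= 1 regardless of codon order.
#'
#' @param pools Named abundance vector from [pool_trna_abundances()].
#' @param pairs A `synonymous_pairs` table (defaults to the universal set).
#' @return Data frame with `pair` and `abundance_ratio` (`NA` when either
#'   pool is missing or the smaller pool is 0).
#' @export
abundance_ratio <- function(pools, pairs = synonymous_pairs()) {
  a <- pools[pairs$codon_a]; b <- pools[pairs$codon_b]
  hi <- pmax(a, b); lo <- pmin(a, b)
  ratio <- ifelse(is.na(hi) | is.na(lo) | lo <= 0, NA_real_, hi / lo)
  data.frame(pair = pairs$pair, abundance_ratio = as.numeric(ratio),
             stringsAsFactors = FALSE)
}

#' Spearman rank correlation
#'
#' Average ranks for ties, two-sided p-value, via [stats::cor.test()].
#'
#' @param x,y Equal-length numeric vectors (n >= 3 after dropping pairs
#'   with missing values).
#' @return List with `rho` and `p_value`.
#' @export
rank_correlation <- function(x, y) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("rank correlation undefined for a constant vector")
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}
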