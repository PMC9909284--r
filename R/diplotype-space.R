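# Diplotype enumeration, combined (unphased) definitions, Hardy-Weinberg
# population frequencies, indistinguishable groups, cross-population CV.

#' Canonical diplotype label
#'
#' Unordered pair of haplotype names rendered as `"A/B"` with `A <= B` in
#' byte (C-locale) order, so the label is unique per unordered pair.
#'
#' @param hap1,hap2 Haplotype names (vectorised).
#' @return Character vector of canonical labels.
#' @export
diplotype_label <- function(hap1, hap2) {
  lo <- ifelse(cmp_le(hap1, hap2), hap1, hap2)
  hi <- ifelse(cmp_le(hap1, hap2), hap2, hap1)
  paste0(lo, "/", hi)
}

# byte-order <= for character vectors, independent of the session locale
cmp_le <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  vapply(seq_len(n), function(i) {
    o <- order(c(a[i], b[i]), method = "radix")
    o[1L] == 1L || a[i] == b[i]
  }, TRUE)
}

#' Enumerate all diplotypes of a gene
#'
#' The combination of any two haplotypes of a gene (unordered, homozygous
#' pairs allowed) gives all possible diplotypes: H haplotypes yield
#' H(H+1)/2 diplotypes.
#'
#' @param gene A `pgx_gene` table (see [gene_table()]).
#' @return Data frame with columns `label`, `hap1`, `hap2`, ordered by
#'   canonical label.
#' @export
enumerate_diplotypes <- function(gene) {
  stopifnot(inherits(gene, "pgx_gene"))
  haps <- gene$haplotypes
  H <- length(haps)
  idx <- which(upper.tri(matrix(0L, H, H), diag = TRUE), arr.ind = TRUE)
  out <- data.frame(label = diplotype_label(haps[idx[, 1L]], haps[idx[, 2L]]),
                    hap1 = haps[idx[, 1L]], hap2 = haps[idx[, 2L]],
                    stringsAsFactors = FALSE)
  out <- out[radix_order(out$label), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Unordered allele-pair rendering shared by combined definitions (expected)
# and VCF ingestion (observed), so multiset equality is plain string equality.
genotype_string <- function(a, b) {
  lo <- ifelse(a <= b, a, b)
  hi <- ifelse(a <= b, b, a)
  paste0(lo, "/", hi)
}

# Expected per-position genotype strings ("a/b", multiset sorted) and declared
# masks for every candidate pair at once. Rows follow `pairs`.
combined_matrix <- function(gene, pairs = enumerate_diplotypes(gene)) {
  M <- gene$allele_matrix
  D <- gene$declared_matrix
  i1 <- match(pairs$hap1, gene$haplotypes)
  i2 <- match(pairs$hap2, gene$haplotypes)
  A <- M[i1, , drop = FALSE]
  B <- M[i2, , drop = FALSE]
  E <- matrix(genotype_string(A, B), nrow = nrow(pairs),
              dimnames = list(pairs$label, colnames(M)))
  Dm <- D[i1, , drop = FALSE] | D[i2, , drop = FALSE]
  dimnames(Dm) <- dimnames(E)
  list(expected = E, declared = Dm)
}

#' Combined (unphased) definition of a diplotype
#'
#' At each position of the gene's position set, the unordered pair of alleles
#' contributed by the two haplotypes; a haplotype contributes its declared
#' alternate allele where it declares one and the reference allele elsewhere.
#' A position is *declared* for the diplotype if at least one constituent
#' haplotype declares a variant there.
#'
#' @param gene A `pgx_gene` table.
#' @param hap1,hap2 Haplotype names (order irrelevant).
#' @return Object of class `pgx_combined`: list with `gene`, `label`,
#'   `expected` (named character vector, `"a/b"` per position) and
#'   `declared` (named logical vector).
#' @export
combined_definition <- function(gene, hap1, hap2) {
  stopifnot(inherits(gene, "pgx_gene"))
  missing_h <- setdiff(c(hap1, hap2), gene$haplotypes)
  if (length(missing_h)) {
    pgx_lookup_error(sprintf("haplotype %s not defined for gene %s", missing_h[1L], gene$gene))
  }
  pairs <- data.frame(label = diplotype_label(hap1, hap2), hap1 = hap1, hap2 = hap2)
  cm <- combined_matrix(gene, pairs)
  structure(list(gene = gene$gene, label = pairs$label,
                 expected = cm$expected[1L, ], declared = cm$declared[1L, ]),
            class = "pgx_combined")
}

#' Hardy-Weinberg diplotype frequency
#'
#' Expected population frequency of a diplotype under Hardy-Weinberg
#' equilibrium: `p^2` for a homozygote, `2 p q` for a heterozygote, where
#' `p`, `q` are the two haplotypes' frequencies in the given group.
#'
#' @param gene Gene symbol.
#' @param hap1,hap2 Haplotype names.
#' @param group Biogeographic group code.
#' @param freqs An epsilon-filled `pgx_freqs` table.
#' @return Numeric frequency (vectorised over `hap1`/`hap2`).
#' @export
diplotype_frequency <- function(gene, hap1, hap2, group, freqs) {
  check_group(group)
  if (!isTRUE(attr(freqs, "filled"))) {
    pgx_state_error("frequency table must be epsilon-filled before deriving diplotype frequencies")
  }
  sel <- freqs$gene == gene
  p <- freqs[[group]][sel][match(hap1, freqs$haplotype[sel])]
  q <- freqs[[group]][sel][match(hap2, freqs$haplotype[sel])]
  if (anyNA(p) || anyNA(q)) {
    pgx_state_error(sprintf("missing haplotype frequency for gene %s in group %s", gene, group))
  }
  ifelse(hap1 == hap2, p * q, 2 * p * q)
}

#' Indistinguishable diplotype groups of a gene
#'
#' Distinct haplotype pairs whose combined unphased variant multisets are
#' identical at every position cannot be told apart from short-read
#' genotypes. This partitions the gene's diplotypes by equality of combined
#' definition and returns the equivalence classes of size two or more.
#'
#' @param gene A `pgx_gene` table.
#' @return List of character vectors of diplotype labels (canonically
#'   ordered), one per indistinguishable group; empty list if none.
#' @export
indistinguishable_groups <- function(gene) {
  pairs <- enumerate_diplotypes(gene)
  cm <- combined_matrix(gene, pairs)
  sig <- vapply(seq_len(nrow(pairs)),
                function(i) paste(cm$expected[i, ], collapse = "\t"), "")
  grp <- split(pairs$label, sig)
  grp <- grp[vapply(grp, length, 0L) >= 2L]
  grp <- lapply(unname(grp), radix_sort)
  grp[radix_order(vapply(grp, `[`, "", 1L))]
}

#' Coefficient of variation of a diplotype's population frequencies
#'
#' Dispersion of a diplotype's Hardy-Weinberg frequency across the nine
#' biogeographic groups, as population standard deviation (n denominator —
#' the groups are an exhaustive partition, not a sample) divided by the mean.
#'
#' @param gene Gene symbol.
#' @param hap1,hap2 Haplotype names.
#' @param freqs Epsilon-filled `pgx_freqs` table.
#' @param groups Group codes to use (default: all nine).
#' @return A single non-negative number.
#' @export
frequency_cv <- function(gene, hap1, hap2, freqs, groups = pgx_groups()) {
  if (length(groups) < 2L) pgx_usage_error("frequency_cv needs at least two groups")
  f <- vapply(groups, function(g) diplotype_frequency(gene, hap1, hap2, g, freqs), 0)
  m <- mean(f)
  sd_pop <- sqrt(mean((f - m)^2))
  sd_pop / m
}

#' Export the diplotype/frequency matrix of a gene
#'
#' Writes one row per diplotype with its Hardy-Weinberg frequency in each of
#' the nine groups, for inspection.
#'
#' @param gene A `pgx_gene` table.
#' @param freqs Epsilon-filled `pgx_freqs` table.
#' @param path Output TSV path.
#' @return The exported data frame, invisibly.
#' @export
export_diplotype_frequencies <- function(gene, freqs, path) {
  pairs <- enumerate_diplotypes(gene)
  out <- data.frame(gene = gene$gene, diplotype = pairs$label)
  for (g in pgx_groups()) {
    out[[g]] <- diplotype_frequency(gene$gene, pairs$hap1, pairs$hap2, g, freqs)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
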