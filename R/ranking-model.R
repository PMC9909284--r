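# Two-step diplotype ranking: candidates are scored for consistency with the
# observed genotypes, disqualified candidates removed, the rest ranked first
# by total consistency score and then by population frequency.
#
# Scoring scheme per position of the gene's position set:
#   declared locus (>=1 constituent haplotype declares a variant there):
#     observed allele multiset equal to expected -> 0, unequal -> disqualified
#   undeclared locus (expected ref/ref):
#     equal -> 0, unequal -> -1 (an unexplained variant)
#   missing genotype: skipped and counted, never penalised.

# observed genotype strings for one gene, aligned to its position order
observed_for_gene <- function(genotypes, gene) {
  m <- match(gene$positions$pos_id, genotypes$calls$pos_id)
  if (anyNA(m)) {
    pgx_state_error(sprintf("genotype set does not cover all positions of gene %s", gene$gene))
  }
  obs <- genotypes$calls$genotype[m]
  obs[genotypes$calls$missing[m]] <- NA_character_
  stats::setNames(obs, gene$positions$pos_id)
}

#' Score one candidate diplotype against observed genotypes
#'
#' @param genotypes A `pgx_genotypes` object.
#' @param combined A `pgx_combined` definition (see [combined_definition()]),
#'   or a `pgx_gene` plus `hap1`/`hap2` via [combined_definition()].
#' @param gene The `pgx_gene` table the combined definition belongs to.
#' @return List of class `pgx_score`: `label`, `penalty_sum` (<= 0),
#'   `disqualified`, `positions_scored`, `positions_skipped_missing`,
#'   `skipped_declared`.
#' @export
score_candidate <- function(genotypes, combined, gene) {
  stopifnot(inherits(combined, "pgx_combined"), inherits(gene, "pgx_gene"))
  obs <- observed_for_gene(genotypes, gene)
  expected <- combined$expected[names(obs)]
  declared <- combined$declared[names(obs)]
  miss <- is.na(obs)
  mismatch <- !miss & (obs != expected)
  structure(list(
    label = combined$label,
    penalty_sum = -sum(mismatch & !declared),
    disqualified = any(mismatch & declared),
    positions_scored = sum(!miss),
    positions_skipped_missing = sum(miss),
    skipped_declared = sum(miss & declared)
  ), class = "pgx_score")
}

# vectorised scoring of every enumerated candidate of a gene
score_all_candidates <- function(gene, obs, pairs = enumerate_diplotypes(gene)) {
  cm <- combined_matrix(gene, pairs)
  P <- ncol(cm$expected)
  miss <- is.na(obs)
  if (P == 0L) {
    return(data.frame(label = pairs$label, hap1 = pairs$hap1, hap2 = pairs$hap2,
                      penalty = 0L, disqualified = FALSE,
                      scored = 0L, skipped = 0L, skipped_declared = 0L))
  }
  obs_m <- matrix(obs, nrow = nrow(pairs), ncol = P, byrow = TRUE)
  miss_m <- matrix(miss, nrow = nrow(pairs), ncol = P, byrow = TRUE)
  mism <- !miss_m & (obs_m != cm$expected)
  data.frame(label = pairs$label, hap1 = pairs$hap1, hap2 = pairs$hap2,
             penalty = -rowSums(mism & !cm$declared),
             disqualified = rowSums(mism & cm$declared) > 0L,
             scored = sum(!miss), skipped = sum(miss),
             skipped_declared = rowSums(miss_m & cm$declared))
}

#' Rank candidate diplotypes for one gene
#'
#' Implements the two-step ranking: (1) disqualified candidates (any
#' declared-locus mismatch) are excluded and the remainder kept at the
#' maximal consistency score (penalty sum closest to zero); (2) among those,
#' only candidates of maximal Hardy-Weinberg frequency in the given
#' biogeographic group are retained. Residual ties — typically members of
#' one indistinguishable group with identical frequencies — are all
#' reported, canonically ordered, rather than broken arbitrarily.
#'
#' @param genotypes A `pgx_genotypes` object.
#' @param gene Gene symbol.
#' @param group Biogeographic group code.
#' @param kb A `pgx_kb` knowledgebase with epsilon-filled frequencies.
#' @return Object of class `pgx_ranked_call`: list with `gene`, `status`
#'   (`"ok"`, `"undeterminable"` or `"not tested"`), `top` (character vector
#'   of diplotype labels, empty unless status `"ok"`), `best_penalty`,
#'   `top_frequency`, `exact_match`, `candidates_total` and the full
#'   candidate `scores` data frame.
#' @export
rank_diplotypes <- function(genotypes, gene, group, kb) {
  check_group(group)
  gt <- gene_table(kb, gene)
  obs <- observed_for_gene(genotypes, gt)
  pairs <- enumerate_diplotypes(gt)
  sc <- score_all_candidates(gt, obs, pairs)
  sc$frequency <- diplotype_frequency(gene, sc$hap1, sc$hap2, group, kb$freqs)

  if (all(is.na(obs))) {
    return(ranked_call(gene, "not tested", sc))
  }
  qual <- sc[!sc$disqualified, , drop = FALSE]
  if (nrow(qual) == 0L) {
    return(ranked_call(gene, "undeterminable", sc))
  }
  best_penalty <- max(qual$penalty)
  step1 <- qual[qual$penalty == best_penalty, , drop = FALSE]
  top_freq <- max(step1$frequency)
  top <- step1[step1$frequency == top_freq, , drop = FALSE]
  top <- top[radix_order(top$label), , drop = FALSE]
  exact <- best_penalty == 0L && all(top$skipped_declared == 0L)
  ranked_call(gene, "ok", sc, top = top$label, best_penalty = best_penalty,
              top_frequency = top_freq, exact_match = exact)
}

ranked_call <- function(gene, status, scores, top = character(0),
                        best_penalty = NA_integer_, top_frequency = NA_real_,
                        exact_match = FALSE) {
  structure(list(gene = gene, status = status, top = top,
                 best_penalty = best_penalty, top_frequency = top_frequency,
                 exact_match = exact_match, candidates_total = nrow(scores),
                 scores = scores),
            class = "pgx_ranked_call")
}

#' @export
print.pgx_ranked_call <- function(x, ...) {
  cat(sprintf("%s: ", x$gene))
  if (x$status == "ok") {
    cat(paste(x$top, collapse = " | "),
        sprintf(" (penalty %d, freq %.3g%s)\n", x$best_penalty, x$top_frequency,
                if (x$exact_match) ", exact match" else ""))
  } else {
    cat(x$status, "\n")
  }
  invisible(x)
}

#' Infer diplotypes for every multi-variant gene in the knowledgebase
#'
#' Runs [rank_diplotypes()] for each gene of the knowledgebase's allele
#' definition table. Genes with every position missing from the sample are
#' flagged `"not tested"` rather than called. With the bundled knowledgebase
#' this covers the thirteen genes of [pgx_gene_registry()].
#'
#' @inheritParams rank_diplotypes
#' @return Named list of `pgx_ranked_call`, one per gene, in canonical gene
#'   order.
#' @export
infer_all <- function(genotypes, group, kb) {
  check_group(group)
  genes <- radix_sort(names(kb$alleles$genes))
  stats::setNames(lapply(genes, function(g) rank_diplotypes(genotypes, g, group, kb)), genes)
}

#' Dump the per-candidate score table of a gene
#'
#' Diagnostic export (the CLI's `--debug-scores`): one row per candidate
#' diplotype with penalty, disqualification flag and population frequency.
#'
#' @param call A `pgx_ranked_call`.
#' @param path Output TSV path.
#' @return The data frame, invisibly.
#' @export
dump_scores <- function(call, path) {
  df <- call$scores[, c("label", "penalty", "disqualified", "frequency")]
  names(df)[1L] <- "diplotype"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
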