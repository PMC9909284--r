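# Independent brute-force oracles. These deliberately avoid the package's
# vectorised internals: plain scalar loops over haplotype declared sets.

# declared map of a haplotype as named vector pos_id -> alt, from a pgx_gene
decl_map <- function(gene_tab, hap) {
  i <- match(hap, gene_tab$haplotypes)
  d <- gene_tab$declared_matrix[i, ]
  stats::setNames(gene_tab$allele_matrix[i, d], gene_tab$positions$pos_id[d])
}

# brute-force combined definition: union/merge of the two declared sets,
# reference elsewhere; returns list pos_id -> sorted 2-vector of alleles
oracle_combined <- function(gene_tab, h1, h2) {
  d1 <- decl_map(gene_tab, h1); d2 <- decl_map(gene_tab, h2)
  out <- list()
  for (i in seq_len(nrow(gene_tab$positions))) {
    pid <- gene_tab$positions$pos_id[i]
    ref <- gene_tab$positions$ref[i]
    a1 <- if (pid %in% names(d1)) d1[[pid]] else ref
    a2 <- if (pid %in% names(d2)) d2[[pid]] else ref
    out[[pid]] <- sort(c(a1, a2))
  }
  out
}

# brute-force scoring of one candidate against observed genotype strings
# obs: named pos_id -> "a/b" or NA
oracle_score <- function(gene_tab, h1, h2, obs) {
  comb <- oracle_combined(gene_tab, h1, h2)
  d1 <- decl_map(gene_tab, h1); d2 <- decl_map(gene_tab, h2)
  penalty <- 0L; disq <- FALSE
  for (pid in gene_tab$positions$pos_id) {
    o <- obs[[pid]]
    if (is.na(o)) next
    observed <- sort(strsplit(o, "/", fixed = TRUE)[[1L]])
    declared <- (pid %in% names(d1)) || (pid %in% names(d2))
    consistent <- identical(observed, comb[[pid]])
    if (declared && !consistent) disq <- TRUE
    if (!declared && !consistent) penalty <- penalty - 1L
  }
  list(penalty = penalty, disqualified = disq)
}

# brute-force two-step ranking: exhaustive score + filter + argmax by
# (penalty, Hardy-Weinberg frequency), all ties kept
oracle_rank <- function(gene_tab, obs, freqs, group) {
  haps <- gene_tab$haplotypes
  cand <- list()
  for (i in seq_along(haps)) for (j in i:length(haps)) {
    h1 <- haps[i]; h2 <- haps[j]
    sc <- oracle_score(gene_tab, h1, h2, obs)
    p <- freqs[[group]][freqs$gene == gene_tab$gene & freqs$haplotype == h1]
    q <- freqs[[group]][freqs$gene == gene_tab$gene & freqs$haplotype == h2]
    f <- if (h1 == h2) p * q else 2 * p * q
    cand[[length(cand) + 1L]] <- list(label = diplotype_label(h1, h2),
                                      penalty = sc$penalty,
                                      disq = sc$disqualified, freq = f)
  }
  if (all(is.na(obs))) return(list(status = "not tested", top = character(0)))
  qual <- Filter(function(c) !c$disq, cand)
  if (!length(qual)) return(list(status = "undeterminable", top = character(0)))
  best_p <- max(vapply(qual, `[[`, 0L, "penalty"))
  step1 <- Filter(function(c) c$penalty == best_p, qual)
  best_f <- max(vapply(step1, `[[`, 0, "freq"))
  top <- Filter(function(c) c$freq == best_f, step1)
  labels <- sort(vapply(top, `[[`, "", "label"), method = "radix")
  list(status = "ok", top = labels, best_penalty = best_p, top_frequency = best_f)
}
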