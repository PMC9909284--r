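amb_gene <- function() {
  make_gene("G", list("*1" = character(0),
                      "*2" = c("chr1:100:A" = "G"),
                      "*3" = c("chr1:200:C" = "T"),
                      "*4" = c("chr1:100:A" = "G", "chr1:200:C" = "T")))
}

test_that("score_candidate implements the 0 / disqualify / -1 scheme", {
  g <- amb_gene()
  # exact match at every position -> penalty 0, qualified
  gs <- make_genotypes(g, c("chr1:100" = "A/G", "chr1:200" = "C/C"))
  sc <- score_candidate(gs, combined_definition(g, "*1", "*2"), g)
  expect_equal(sc$penalty_sum, 0L)
  expect_false(sc$disqualified)
  expect_equal(sc$positions_scored, 2L)

  # declared locus requires hom-alt but sample is heterozygous -> disqualified
  sc2 <- score_candidate(gs, combined_definition(g, "*2", "*2"), g)
  expect_true(sc2$disqualified)

  # sample variant at a locus the candidate leaves undeclared -> -1, qualified
  gs3 <- make_genotypes(g, c("chr1:100" = "A/G", "chr1:200" = "C/T"))
  sc3 <- score_candidate(gs3, combined_definition(g, "*1", "*2"), g)
  expect_equal(sc3$penalty_sum, -1L)
  expect_false(sc3$disqualified)

  # missing positions are skipped and counted
  gs4 <- make_genotypes(g, c("chr1:100" = "A/G", "chr1:200" = NA))
  sc4 <- score_candidate(gs4, combined_definition(g, "*1", "*2"), g)
  expect_equal(sc4$positions_skipped_missing, 1L)
  expect_equal(sc4$penalty_sum, 0L)
})

test_that("ranking keeps best consistency then best frequency, ties canonical", {
  g <- amb_gene()
  fr <- make_freqs(g, c("*1" = 0.60, "*2" = 0.25, "*3" = 0.10, "*4" = 0.05))
  kb <- make_kb(g, fr)

  # het at 100 only: *1/*2 is the unique penalty-0 candidate
  gs <- make_genotypes(g, c("chr1:100" = "A/G", "chr1:200" = "C/C"))
  rc <- rank_diplotypes(gs, "G", "EAS", kb)
  expect_equal(rc$status, "ok")
  expect_equal(rc$top, "*1/*2")
  expect_equal(rc$best_penalty, 0L)
  expect_true(rc$exact_match)

  # het at both positions: indistinguishable pair {*1/*4, *2/*3};
  # frequency breaks the tie: 2*0.6*0.05=0.06 vs 2*0.25*0.10=0.05
  gs2 <- make_genotypes(g, c("chr1:100" = "A/G", "chr1:200" = "C/T"))
  rc2 <- rank_diplotypes(gs2, "G", "EAS", kb)
  expect_equal(rc2$top, "*1/*4")
  expect_equal(rc2$top_frequency, 2 * 0.60 * 0.05)

  # equal frequencies: both members of the ambiguity class are reported
  fr_tie <- make_freqs(g, c("*1" = 0.25, "*2" = 0.25, "*3" = 0.25, "*4" = 0.25))
  rc3 <- rank_diplotypes(gs2, "G", "EAS", make_kb(g, fr_tie))
  expect_equal(rc3$top, c("*1/*4", "*2/*3"))

  # raising a tied candidate's frequency never removes it from the top
  fr_up <- make_freqs(g, c("*1" = 0.25, "*2" = 0.30, "*3" = 0.25, "*4" = 0.25))
  rc4 <- rank_diplotypes(gs2, "G", "EAS", make_kb(g, fr_up))
  expect_true("*2/*3" %in% rc4$top)
})

test_that("a genotype matching no definition falls back to tolerant penalties", {
  # observed allele declared by no haplotype: pairs declaring the locus are
  # disqualified, the reference homozygote survives with a -1 penalty
  g <- make_gene("G", list("*1" = character(0),
                           "*2" = c("chr1:100:A" = "G"),
                           "*3" = c("chr1:100:A" = "C")))
  fr <- make_freqs(g, c("*1" = 0.8, "*2" = 0.1, "*3" = 0.1))
  gs <- make_genotypes(g, c("chr1:100" = "G/T"))
  rc <- rank_diplotypes(gs, "G", "EAS", make_kb(g, fr))
  expect_equal(rc$top, "*1/*1")
  expect_equal(rc$best_penalty, -1L)
  expect_false(rc$exact_match)
})

test_that("every candidate disqualified yields an empty-top undeterminable call", {
  # fabricated gene whose nominal reference itself declares a variant, so no
  # candidate is free of declared loci; a third observed allele then
  # contradicts every candidate
  var <- data.frame(haplotype = c("*1", "*2"), chromosome = "chr1",
                    position = 100L, ref = "A", alt = c("C", "G"))
  g <- pgxdip:::build_gene_table("G", ref_name = "*1", var = var)
  fr <- make_freqs(g, c("*1" = 0.9, "*2" = 0.1))
  gs <- make_genotypes(g, c("chr1:100" = "T/T"))
  rc <- rank_diplotypes(gs, "G", "EAS", make_kb(g, fr))
  expect_equal(rc$status, "undeterminable")
  expect_length(rc$top, 0L)
  expect_equal(rc$candidates_total, 3L)
})

test_that("rank_diplotypes equals the brute-force oracle on random instances", {
  set.seed(555)
  n_agree <- 0L
  for (rep in 1:120) {
    H <- sample(2:12, 1)
    g <- random_gene(H, P = sample(3:6, 1))
    fr <- random_freqs(g)
    gs <- make_genotypes(g, random_obs(g))
    obs <- pgxdip:::observed_for_gene(gs, g)
    rc <- rank_diplotypes(gs, "G", "EUR", make_kb(g, fr))
    or <- oracle_rank(g, obs, fr, "EUR")
    expect_equal(rc$status, or$status)
    expect_equal(rc$top, or$top)
    if (rc$status == "ok") {
      expect_equal(rc$best_penalty, or$best_penalty)
      expect_equal(rc$top_frequency, or$top_frequency)
    }
    n_agree <- n_agree + 1L
  }
  expect_equal(n_agree, 120L)
})

test_that("indistinguishable-group members always score identically", {
  set.seed(99)
  for (rep in 1:15) {
    g <- random_gene(H = sample(4:8, 1), P = sample(2:4, 1))
    grps <- indistinguishable_groups(g)
    if (!length(grps)) next
    obs <- random_obs(g)
    sc <- pgxdip:::score_all_candidates(g, obs)
    for (grp in grps) {
      rows <- sc[sc$label %in% grp, ]
      expect_equal(length(unique(rows$penalty)), 1L)
      expect_equal(length(unique(rows$disqualified)), 1L)
    }
  }
})

test_that("infer_all covers every kb gene and flags fully-missing genes", {
  spec <- fixture_spec(seed = 3, n_genes = 3)
  dir <- withr::local_tempdir()
  kb <- generate_toy_knowledgebase(spec, dir)
  kb$freqs <- fill_null_frequencies(kb$freqs)
  genes <- names(kb$alleles$genes)
  truth <- lapply(genes, function(g) {
    haps <- gene_table(kb, g)$haplotypes
    sort(sample(haps, 2, replace = TRUE), method = "radix")
  })
  names(truth) <- genes
  vcf <- file.path(dir, "s.vcf")
  synthesize_vcf(kb, truth, spec, vcf)
  gs <- read_genotypes(vcf, kb)
  res <- infer_all(gs, "SSA", kb)
  expect_equal(names(res), sort(genes, method = "radix"))
  for (g in genes) {
    # the call is always combined-definition-equivalent to the truth; the
    # truth itself is reported unless an indistinguishable partner is more
    # frequent in the population
    gt <- gene_table(kb, g)
    truth_cd <- combined_definition(gt, truth[[g]][1], truth[[g]][2])$expected
    expect_equal(res[[g]]$status, "ok")
    for (lab in res[[g]]$top) {
      pr <- strsplit(lab, "/", fixed = TRUE)[[1]]
      expect_equal(combined_definition(gt, pr[1], pr[2])$expected, truth_cd)
    }
  }

  # a VCF covering nothing -> every gene "not tested"
  empty_vcf <- file.path(dir, "empty.vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
               "chrZ\t1\t.\tA\tG\t.\tPASS\t.\tGT\t0/1"), empty_vcf)
  res2 <- infer_all(read_genotypes(empty_vcf, kb), "SSA", kb)
  expect_true(all(vapply(res2, function(r) r$status == "not tested", TRUE)))
  expect_true(all(vapply(res2, function(r) length(r$top) == 0L, TRUE)))
})

test_that("the default registry lists the 13 multi-variant pharmacogenes", {
  reg <- pgx_gene_registry()
  expect_length(reg, 13L)
  kb <- default_kb()
  expect_setequal(names(kb$alleles$genes), reg)
})
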