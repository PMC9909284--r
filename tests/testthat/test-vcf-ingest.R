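test_that("variant normalization trims suffix then prefix and is idempotent", {
  v <- normalize_variant("chr1", 100L, "AC", "AT")
  expect_equal(v, list(chromosome = "chr1", position = 101L, ref = "C", alt = "T"))
  # SNV unchanged
  expect_equal(normalize_variant("chr1", 100L, "G", "T")$position, 100L)
  # deletion with shared suffix and prefix
  d <- normalize_variant("chr2", 50L, "CAGAG", "CAG")
  expect_equal(d[c("position", "ref", "alt")], list(position = 50L, ref = "CAG", alt = "C"))
  # idempotent
  d2 <- do.call(normalize_variant, d[c("chromosome", "position", "ref", "alt")])
  expect_equal(d2, d)
  expect_error(normalize_variant("chr1", 100L, "G", "G"), regexp = "non-variant")
  expect_error(normalize_variant("chr1", 100L, "", "G"), class = "pgxdip_input_error")
})

test_that("genotypes are read at kb positions; phase and record order are irrelevant", {
  dir <- tiny_kb_dir()
  kb <- load_kb(dir)
  recs <- data.frame(chrom = c("chr1", "chr1", "chr2", "chr3"),
                     pos = c(100L, 200L, 500L, 900L),
                     id = ".", ref = c("A", "C", "G", "C"),
                     alt = c("G", "T", "A", "."),
                     gt = c("0/1", "1|1", "0|0", "0/0"))
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(recs, vcf)
  gs <- read_genotypes(vcf, kb)
  calls <- gs$calls
  expect_equal(calls$genotype[calls$pos_id == "chr1:100"], "A/G")
  expect_equal(calls$genotype[calls$pos_id == "chr1:200"], "T/T")
  expect_equal(calls$genotype[calls$pos_id == "chr2:500"], "G/G")
  expect_equal(calls$genotype[calls$pos_id == "chr3:900"], "C/C")
  expect_false(any(calls$missing))

  # shuffled records and slash phasing give the identical genotype set
  vcf2 <- withr::local_tempfile(fileext = ".vcf")
  recs2 <- recs[c(3, 1, 4, 2), ]
  recs2$gt <- gsub("|", "/", recs2$gt, fixed = TRUE)
  write_vcf(recs2, vcf2)
  expect_equal(read_genotypes(vcf2, kb)$calls, calls)
})

test_that("absent positions and ./. genotypes are missing, not homozygous reference", {
  dir <- tiny_kb_dir()
  kb <- load_kb(dir)
  recs <- data.frame(chrom = "chr1", pos = 100L, id = ".", ref = "A", alt = "G",
                     gt = "./.")
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(recs, vcf)
  gs <- read_genotypes(vcf, kb)
  expect_true(all(gs$calls$missing))
  expect_true(all(is.na(gs$calls$genotype)))
})

test_that("multi-allelic records are split and normalized before matching", {
  dir <- tiny_kb_dir()
  kb <- load_kb(dir)
  # record anchored one base upstream: first ALT (TA>TG) normalizes onto the
  # kb SNV chr1:100 A>G; second ALT (TA>T) is a deletion normalizing to
  # position 99 and so contributes the reference allele at the SNV
  recs <- data.frame(chrom = "chr1", pos = 99L, id = ".", ref = "TA",
                     alt = "TG,T", gt = "1/2")
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(recs, vcf)
  gs <- read_genotypes(vcf, kb)
  expect_equal(gs$calls$genotype[gs$calls$pos_id == "chr1:100"], "A/G")
})

test_that("FILTER is ignored by default and respected on request", {
  dir <- tiny_kb_dir()
  kb <- load_kb(dir)
  recs <- data.frame(chrom = "chr1", pos = 100L, id = ".", ref = "A", alt = "G",
                     gt = "1/1", filter = "LowQual")
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(recs, vcf)
  expect_equal(read_genotypes(vcf, kb)$calls$genotype[1], "G/G")
  gs <- read_genotypes(vcf, kb, respect_filter = TRUE)
  expect_true(gs$calls$missing[gs$calls$pos_id == "chr1:100"])
})

test_that("multi-sample VCFs require a sample name and reject unknown samples", {
  dir <- tiny_kb_dir()
  kb <- load_kb(dir)
  vcf <- withr::local_tempfile(fileext = ".vcf")
  lines <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
             "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/1\t1/1")
  writeLines(lines, vcf)
  expect_error(read_genotypes(vcf, kb), class = "pgxdip_input_error", regexp = "S1, S2")
  expect_equal(read_genotypes(vcf, kb, sample = "S2")$calls$genotype[1], "G/G")
  expect_error(read_genotypes(vcf, kb, sample = "S9"), class = "pgxdip_input_error")
  expect_error(read_genotypes(withr::local_tempfile(fileext = ".vcf"), kb),
               class = "pgxdip_input_error")
})

test_that("single-variant alleles report measured genotypes and 'not tested' otherwise", {
  dir <- tiny_kb_dir()
  kb <- load_kb(dir)
  # hom-alt at the registry position
  recs <- data.frame(chrom = "chr3", pos = 900L, id = "rs1", ref = "C", alt = "T",
                     gt = "1/1")
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(recs, vcf)
  gs <- read_genotypes(vcf, kb)
  sv <- call_single_variant_alleles(gs, kb)
  expect_equal(sv$genotype[sv$gene == "SV1"], "T/T")
  expect_equal(sv$status[sv$gene == "SV1"], "called")

  # hom-ref record
  recs$alt <- "."; recs$gt <- "0/0"
  write_vcf(recs, vcf)
  sv <- call_single_variant_alleles(read_genotypes(vcf, kb), kb)
  expect_equal(sv$genotype[sv$gene == "SV1"], "C/C")

  # position entirely absent
  recs2 <- data.frame(chrom = "chr1", pos = 100L, id = ".", ref = "A", alt = "G", gt = "0/1")
  write_vcf(recs2, vcf)
  sv <- call_single_variant_alleles(read_genotypes(vcf, kb), kb)
  expect_equal(sv$status[sv$gene == "SV1"], "not tested")
  expect_true(is.na(sv$genotype[sv$gene == "SV1"]))
})

test_that("HLA calls come from symbolic ALT records or a sidecar, with validation", {
  dir <- tiny_kb_dir()
  kb <- load_kb(dir)
  recs <- data.frame(chrom = "chr6", pos = 31268749L, id = ".", ref = "N",
                     alt = "<HLA-B*57:01>", gt = "0/1")
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(recs, vcf)
  gs <- read_genotypes(vcf, kb)
  hla <- extract_hla_calls(gs)
  expect_equal(hla$allele, "HLA-B*57:01")
  expect_equal(hla$copies, 1L)

  sidecar <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("HLA-A*31:01\t2"), sidecar)
  hla2 <- extract_hla_calls(gs, sidecar = sidecar)
  expect_equal(hla2$allele, c("HLA-A*31:01", "HLA-B*57:01"))
  expect_equal(hla2$copies, c(2L, 1L))

  # nothing provided -> empty set
  expect_equal(nrow(extract_hla_calls()), 0L)

  writeLines(c("HLA-A*31:01\tx"), sidecar)
  expect_error(extract_hla_calls(sidecar = sidecar), class = "pgxdip_input_error",
               regexp = "line 1")
})

test_that("a VCF synthesized from a genotype set re-ingests identically", {
  spec <- fixture_spec(seed = 7, n_genes = 2, dropout_rate = 0, spurious_rate = 0)
  dir <- withr::local_tempdir()
  kb <- generate_toy_knowledgebase(spec, dir)
  kb$freqs <- fill_null_frequencies(kb$freqs)
  genes <- names(kb$alleles$genes)
  truth <- lapply(genes, function(g) {
    haps <- gene_table(kb, g)$haplotypes
    c(haps[2], haps[length(haps)])
  })
  names(truth) <- genes
  vcf <- file.path(dir, "s.vcf")
  synthesize_vcf(kb, truth, spec, vcf)
  gs <- read_genotypes(vcf, kb)
  for (g in genes) {
    gt <- gene_table(kb, g)
    cm <- combined_definition(gt, truth[[g]][1], truth[[g]][2])
    obs <- pgxdip:::observed_for_gene(gs, gt)
    expect_equal(obs, cm$expected)
  }
})
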