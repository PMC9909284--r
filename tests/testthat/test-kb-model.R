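test_that("allele definitions load with one reference per gene and schema checks", {
  dir <- tiny_kb_dir()
  tab <- load_allele_definitions(file.path(dir, "alleles.tsv"))
  expect_s3_class(tab, "pgx_allele_table")
  expect_setequal(names(tab$genes), c("G1", "G2"))
  g1 <- gene_table(tab, "G1")
  expect_equal(g1$reference, "*1")
  expect_equal(length(g1$haplotypes), 4L)
  expect_equal(nrow(g1$positions), 2L)
  expect_error(gene_table(tab, "NOPE"), class = "pgxdip_lookup_error")

  # duplicate declared position for one haplotype
  dup <- rbind(alleles_df("G", list("*1" = character(0), "*2" = c("chr1:10:A" = "C"))),
               data.frame(gene = "G", haplotype = "*2", chromosome = "chr1",
                          position = "10", ref = "A", alt = "C", is_reference = 0L))
  expect_error(load_alleles(dup), class = "pgxdip_schema_error", regexp = "duplicate.*\\*2")

  # zero or two reference haplotypes
  noref <- alleles_df("G", list("*2" = c("chr1:10:A" = "C")))
  expect_error(load_alleles(noref), class = "pgxdip_schema_error", regexp = "reference")
  tworef <- rbind(alleles_df("G", list("*1" = character(0), "*2" = c("chr1:10:A" = "C"))),
                  alleles_df("G", list("*9" = character(0))))
  expect_error(load_alleles(tworef), class = "pgxdip_schema_error", regexp = "reference")

  # ref == alt row
  same <- alleles_df("G", list("*1" = character(0), "*2" = c("chr1:10:A" = "A")))
  expect_error(load_alleles(same), class = "pgxdip_error", regexp = "non-variant")
})

test_that("a three-haplotype gene enumerates to six diplotypes end to end", {
  tab <- load_alleles(alleles_df("CYP4F2like", list(
    "*1" = character(0),
    "*2" = c("chr19:1000:C" = "T"),
    "*3" = c("chr19:2000:G" = "A"))))
  expect_equal(nrow(enumerate_diplotypes(gene_table(tab, "CYP4F2like"))), 6L)
})

test_that("frequency table loads: numbers kept, empties null, bad columns rejected", {
  dir <- tiny_kb_dir()
  fr <- load_haplotype_frequencies(file.path(dir, "frequencies.tsv"))
  expect_false(attr(fr, "filled"))
  expect_equal(fr$AAC[fr$gene == "G1" & fr$haplotype == "*2"], 0.25)
  expect_true(is.na(fr$EAS[fr$gene == "G1" & fr$haplotype == "*4"]))

  bad <- data.frame(gene = "G", haplotype = "*1", ASN = 0.5)
  for (g in pgx_groups()) bad[[g]] <- 0.1
  path <- withr::local_tempfile(fileext = ".tsv")
  write_tsv_with_header(bad, path)
  expect_error(load_haplotype_frequencies(path),
               class = "pgxdip_schema_error", regexp = "AAC, AME, SAS")

  out_of_range <- data.frame(gene = "G", haplotype = "*1")
  for (g in pgx_groups()) out_of_range[[g]] <- 0.1
  out_of_range$EUR <- 1.5
  write_tsv_with_header(out_of_range, path)
  expect_error(load_haplotype_frequencies(path), class = "pgxdip_schema_error",
               regexp = "\\[0,1\\]")
})

test_that("haplotype frequency is the per-group minimum over defining variants, nulls propagate", {
  f <- haplotype_frequency_from_variant_frequencies(list(
    c(EAS = 0.30), c(EAS = 0.10), c(EAS = 0.20)))
  expect_equal(unname(f[["EAS"]]), 0.10)
  # identity on a single defining variant
  expect_equal(unname(haplotype_frequency_from_variant_frequencies(list(c(EUR = 0.5)))[["EUR"]]), 0.5)
  # any null defining variant makes the group null
  f2 <- haplotype_frequency_from_variant_frequencies(list(
    c(EAS = 0.30, EUR = 0.2), c(EAS = NA_real_, EUR = 0.1)))
  expect_true(is.na(f2[["EAS"]]))
  expect_equal(unname(f2[["EUR"]]), 0.1)
  # order-invariant
  vf <- list(c(EAS = 0.30, EUR = 0.2), c(EAS = NA_real_, EUR = 0.1))
  expect_identical(haplotype_frequency_from_variant_frequencies(vf),
                   haplotype_frequency_from_variant_frequencies(rev(vf)))
  expect_error(haplotype_frequency_from_variant_frequencies(list()),
               class = "pgxdip_usage_error")
})

test_that("epsilon fill replaces nulls only; zeros and values preserved", {
  df <- data.frame(gene = "G", haplotype = c("*1", "*2", "*3"))
  for (g in pgx_groups()) df[[g]] <- c(NA, 0, 0.25)
  tab <- structure(df, epsilon = 1e-5, filled = FALSE,
                   class = c("pgx_freqs", "data.frame"))
  filled <- fill_null_frequencies(tab)
  for (g in pgx_groups()) {
    expect_identical(filled[[g]], c(1e-5, 0, 0.25))
  }
  expect_true(attr(filled, "filled"))
  expect_error(fill_null_frequencies(tab, epsilon = 0), class = "pgxdip_usage_error")
  expect_error(fill_null_frequencies(tab, epsilon = -1), class = "pgxdip_usage_error")
})

test_that("guideline records parse with validated sources, categories and flags", {
  dir <- tiny_kb_dir()
  gl <- load_guidelines(file.path(dir, "guidelines.tsv"))
  expect_equal(nrow(gl), 3L)
  expect_equal(gl$category[gl$drug == "drugA"], "avoid")
  expect_type(gl$population_dependent, "logical")

  bad <- data.frame(source = "FDA", drug = "d", gene = "G", genotype_key = "*1/*1",
                    category = "avoid", population_dependent = 0L, multi_gene = 0L,
                    text = "x")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_tsv_with_header(bad, path)
  expect_error(load_guidelines(path), class = "pgxdip_schema_error",
               regexp = "CPIC, DPWG, CPNDS, RNPGx")
  bad$source <- "CPIC"; bad$category <- "forbidden"
  write_tsv_with_header(bad, path)
  expect_error(load_guidelines(path), class = "pgxdip_schema_error")
})

test_that("clinical annotations keep only evidence levels 1A/1B/2A/2B", {
  base <- data.frame(annotation_id = c("A1", "A2", "A3"), drug = "d", gene = "G",
                     genotype_key = "*1/*2",
                     evidence_level = c("1A", "3", "2B"),
                     category = "toxicity", direction = "increased")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_tsv_with_header(base, path)
  expect_message(ann <- load_clinical_annotations(path), "dropped 1")
  expect_equal(ann$annotation_id, c("A1", "A3"))

  base$direction <- c("higher", "normal", "normal")
  write_tsv_with_header(base, path)
  expect_error(load_clinical_annotations(path), class = "pgxdip_schema_error",
               regexp = "higher")
})

test_that("loader/writer round trips reproduce identical structures", {
  dir <- tiny_kb_dir()
  out <- withr::local_tempdir()
  kb <- load_kb(dir, fill = FALSE)

  write_allele_definitions(kb$alleles, file.path(out, "alleles.tsv"))
  expect_equal(load_allele_definitions(file.path(out, "alleles.tsv")), kb$alleles)

  write_haplotype_frequencies(kb$freqs, file.path(out, "frequencies.tsv"))
  expect_equal(load_haplotype_frequencies(file.path(out, "frequencies.tsv")), kb$freqs)

  write_guidelines(kb$guidelines, file.path(out, "guidelines.tsv"))
  expect_equal(load_guidelines(file.path(out, "guidelines.tsv")), kb$guidelines)

  write_clinical_annotations(kb$annotations, file.path(out, "clinical_annotations.tsv"))
  expect_equal(load_clinical_annotations(file.path(out, "clinical_annotations.tsv")),
               kb$annotations)

  write_single_variant_registry(kb$sva, file.path(out, "single_variant_alleles.tsv"))
  expect_equal(load_single_variant_registry(file.path(out, "single_variant_alleles.tsv")),
               kb$sva)

  write_hla_registry(kb$hla, file.path(out, "hla_alleles.tsv"))
  expect_equal(load_hla_registry(file.path(out, "hla_alleles.tsv")), kb$hla)
})

test_that("files without the format header are rejected", {
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(data.frame(gene = "G", allele = "*1"), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  expect_error(load_hla_registry(path), class = "pgxdip_schema_error",
               regexp = "format header")
})
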