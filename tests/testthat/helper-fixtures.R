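# In-code fixture builders shared across test files. Everything is generated
# at test time; nothing is read from stored data.

KB_HDR <- "#format=pgxkb-1 build=GRCh38"

write_tsv_with_header <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(KB_HDR, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  path
}

# allele-definition data frame for a gene given declared maps:
# haps = named list, each a named character vector position -> alt
# (names "chrom:pos:ref" encode the variant site); the reference haplotype
# is the element with an empty vector.
alleles_df <- function(gene, haps) {
  rows <- list()
  for (h in names(haps)) {
    decl <- haps[[h]]
    if (length(decl) == 0L) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene = gene, haplotype = h, chromosome = "", position = "", ref = "",
        alt = "", is_reference = 1L)
    } else {
      for (site in names(decl)) {
        p <- strsplit(site, ":", fixed = TRUE)[[1L]]
        rows[[length(rows) + 1L]] <- data.frame(
          gene = gene, haplotype = h, chromosome = p[1L], position = p[2L],
          ref = p[3L], alt = decl[[site]], is_reference = 0L)
      }
    }
  }
  do.call(rbind, rows)
}

load_alleles <- function(df) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  write_tsv_with_header(df, path)
  load_allele_definitions(path)
}

# build a pgx_gene directly (fast path for property tests)
make_gene <- function(gene = "G", haps, chrom = "chr1") {
  ref_name <- names(haps)[vapply(haps, length, 0L) == 0L][1L]
  rows <- list()
  for (h in setdiff(names(haps), ref_name)) {
    decl <- haps[[h]]
    for (site in names(decl)) {
      p <- strsplit(site, ":", fixed = TRUE)[[1L]]
      rows[[length(rows) + 1L]] <- data.frame(
        haplotype = h, chromosome = p[1L], position = as.integer(p[2L]),
        ref = p[3L], alt = decl[[site]])
    }
  }
  var <- if (length(rows)) do.call(rbind, rows) else
    data.frame(haplotype = character(0), chromosome = character(0),
               position = integer(0), ref = character(0), alt = character(0))
  pgxdip:::build_gene_table(gene, ref_name, var)
}

# random toy gene: H haplotypes (incl. reference *1) over P SNV positions,
# each variant haplotype declaring a distinct subset of size 1..min(P,3)
random_gene <- function(H, P, gene = "G") {
  H <- min(H, sum(choose(P, seq_len(min(P, 3L)))) + 1L)  # distinct subsets must exist
  bases <- c("A", "C", "G", "T")
  pos <- sort(sample.int(99999L, P)) + 100000L
  ref <- sample(bases, P, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
  sites <- sprintf("chr1:%d:%s", pos, ref)
  haps <- list("*1" = character(0))
  seen <- character(0)
  for (i in seq_len(H - 1L)) {
    repeat {
      k <- sample.int(min(P, 3L), 1L)
      s <- sort(sample.int(P, k))
      key <- paste(s, collapse = ",")
      if (!(key %in% seen)) break
    }
    seen <- c(seen, key)
    haps[[sprintf("*%d", i + 1L)]] <- stats::setNames(alt[s], sites[s])
  }
  make_gene(gene, haps)
}

# a gene with H haplotypes for pure enumeration tests (one variant each)
gene_with_H <- function(H, gene = "G") {
  haps <- c(list("*1" = character(0)),
            stats::setNames(lapply(seq_len(H - 1L), function(i) {
              stats::setNames("T", sprintf("chr1:%d:C", 1000L + i))
            }), sprintf("*%d", seq_len(H - 1L) + 1L)))
  make_gene(gene, haps)
}

# frequency table covering one gene's haplotypes; `values` is either a single
# named vector (recycled to all nine groups) or a list group -> named vector
make_freqs <- function(gene_tab, values, filled = TRUE, epsilon = 1e-5) {
  haps <- gene_tab$haplotypes
  df <- data.frame(gene = gene_tab$gene, haplotype = haps)
  for (g in pgx_groups()) {
    v <- if (is.list(values)) values[[g]] else values
    df[[g]] <- unname(v[haps])
  }
  structure(df, epsilon = epsilon, filled = filled,
            class = c("pgx_freqs", "data.frame"))
}

random_freqs <- function(gene_tab, normalize = TRUE) {
  vals <- lapply(pgx_groups(), function(g) {
    x <- stats::runif(length(gene_tab$haplotypes))
    if (normalize) x <- x / sum(x)
    stats::setNames(x, gene_tab$haplotypes)
  })
  make_freqs(gene_tab, stats::setNames(vals, pgx_groups()))
}

# minimal kb wrapper around a single gene + freqs (enough for ranking)
make_kb <- function(gene_tab, freqs) {
  structure(list(
    alleles = structure(list(genes = stats::setNames(list(gene_tab), gene_tab$gene)),
                        class = "pgx_allele_table"),
    freqs = freqs,
    sva = data.frame(gene = character(0), rsid = character(0),
                     chromosome = character(0), position = integer(0),
                     ref = character(0), alt = character(0), pos_id = character(0)),
    hla = data.frame(gene = character(0), allele = character(0))
  ), class = "pgx_kb")
}

# genotype set over a gene's positions from observed strings
# obs: named character vector pos_id -> "a/b" (NA = missing)
make_genotypes <- function(gene_tab, obs, sample = "S1") {
  p <- gene_tab$positions
  o <- obs[p$pos_id]
  alleles <- strsplit(ifelse(is.na(o), "NA/NA", o), "/", fixed = TRUE)
  calls <- data.frame(pos_id = p$pos_id, chrom = p$chrom, pos = p$pos, ref = p$ref,
                      a1 = vapply(alleles, `[`, "", 1L),
                      a2 = vapply(alleles, `[`, "", 2L),
                      genotype = unname(o), missing = is.na(o))
  calls$a1[calls$missing] <- NA_character_
  calls$a2[calls$missing] <- NA_character_
  structure(list(sample = sample, calls = calls,
                 hla = data.frame(allele = character(0), copies = integer(0))),
            class = "pgx_genotypes")
}

# random observed genotype over a gene (mix of ref/het/hom/missing)
random_obs <- function(gene_tab, p_missing = 0.15) {
  p <- gene_tab$positions
  obs <- vapply(seq_len(nrow(p)), function(i) {
    r <- p$ref[i]
    alts <- unique(gene_tab$allele_matrix[gene_tab$declared_matrix[, i], i])
    a <- if (length(alts)) sample(alts, 1L) else "T"
    pick <- sample(c("rr", "ra", "aa", "na"),
                   1L, prob = c(0.4, 0.25, 0.2, p_missing) / (0.85 + p_missing))
    switch(pick,
           rr = paste0(min(r, r), "/", max(r, r)),
           ra = paste0(min(r, a), "/", max(r, a)),
           aa = paste0(a, "/", a),
           na = NA_character_)
  }, "")
  stats::setNames(obs, p$pos_id)
}

# write a minimal single-sample VCF from records:
# records: data.frame(chrom, pos, id, ref, alt, gt) with alt possibly "A,T"
write_vcf <- function(records, path, sample = "S1", extra_header = character(0),
                      filter = "PASS") {
  if (!("filter" %in% names(records))) records$filter <- filter
  lines <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             extra_header,
             paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                    paste(sample, collapse = "\t")))
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    gts <- unlist(r[grepl("^gt", names(records))])
    lines <- c(lines, paste(r$chrom, r$pos, r$id, r$ref, r$alt, ".", r$filter, ".",
                            "GT", paste(gts, collapse = "\t"), sep = "\t"))
  }
  writeLines(lines, path)
  path
}

# a complete tiny kb directory on disk (exercises all six loaders)
tiny_kb_dir <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  alleles <- rbind(
    alleles_df("G1", list("*1" = character(0),
                          "*2" = c("chr1:100:A" = "G"),
                          "*3" = c("chr1:200:C" = "T"),
                          "*4" = c("chr1:100:A" = "G", "chr1:200:C" = "T"))),
    alleles_df("G2", list("*1" = character(0),
                          "*2" = c("chr2:500:G" = "A"))))
  write_tsv_with_header(alleles, file.path(dir, "alleles.tsv"))
  fr <- data.frame(gene = c(rep("G1", 4), rep("G2", 2)),
                   haplotype = c("*1", "*2", "*3", "*4", "*1", "*2"))
  set_freq <- c(0.55, 0.25, 0.15, 0.05, 0.9, 0.1)
  for (g in pgx_groups()) fr[[g]] <- set_freq
  fr$EAS[4] <- NA  # one null cell
  write_tsv_with_header(transform(fr, EAS = ifelse(is.na(EAS), "", EAS)),
                        file.path(dir, "frequencies.tsv"))
  gl <- data.frame(source = c("CPIC", "DPWG", "CPIC"),
                   drug = c("drugA", "drugB", "drugC"),
                   gene = c("G1", "G1", "G2"),
                   genotype_key = c("*2/*2", "*1/*2", "*1/*1"),
                   category = c("avoid", "caution", "routine"),
                   population_dependent = c(0L, 0L, 0L), multi_gene = c(0L, 0L, 0L),
                   text = c("Do not use.", "Reduce dose.", "Standard dosing."))
  write_tsv_with_header(gl, file.path(dir, "guidelines.tsv"))
  ann <- data.frame(annotation_id = c("A1", "A2", "A3"),
                    drug = c("drugB", "drugB", "drugC"),
                    gene = c("G1", "G1", "G2"),
                    genotype_key = c("*1/*2", "*1/*2", "*1/*1"),
                    evidence_level = c("1A", "2B", "1B"),
                    category = c("metabolism", "metabolism", "efficacy"),
                    direction = c("decreased", "decreased", "normal"))
  write_tsv_with_header(ann, file.path(dir, "clinical_annotations.tsv"))
  sva <- data.frame(gene = "SV1", rsid = "rs1", chromosome = "chr3",
                    position = 900L, ref = "C", alt = "T")
  write_tsv_with_header(sva, file.path(dir, "single_variant_alleles.tsv"))
  hla <- data.frame(gene = "HLA-B", allele = "HLA-B*57:01")
  write_tsv_with_header(hla, file.path(dir, "hla_alleles.tsv"))
  dir
}
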