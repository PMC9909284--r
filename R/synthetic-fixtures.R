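# Synthetic knowledgebases and VCFs: toy star-allele tables with controlled
# ambiguity, per-group frequencies, and single-sample VCFs synthesized from
# chosen true diplotypes with configurable variant dropout and spurious
# heterozygous noise. Everything is seeded and byte-reproducible.

#' Specification for synthetic fixtures
#'
#' @param seed Integer seed; one pseudo-random stream per generator call.
#' @param n_genes Number of multi-variant toy genes.
#' @param haplotypes_per_gene Inclusive range (length-2 integer) of haplotype
#'   counts per gene, reference included.
#' @param positions_per_gene Inclusive range of declared-position counts.
#' @param ambiguity Force at least one indistinguishable diplotype pair in
#'   the first gene (requires >= 4 haplotypes and >= 2 positions there).
#' @param dropout_rate Probability that a target position is omitted from a
#'   synthesized VCF (emulates uncovered loci).
#' @param spurious_rate Probability that a position expected homozygous
#'   reference instead carries a spurious heterozygous variant (emulates
#'   call artifacts). Spurious variants are only injected inside gene
#'   position sets — elsewhere they could never perturb scoring.
#' @param null_rate Fraction of haplotype-frequency cells left empty (null),
#'   emulating populations without frequency data.
#' @return List of class `pgx_fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_genes = 3L, haplotypes_per_gene = c(3L, 6L),
                         positions_per_gene = c(4L, 8L), ambiguity = TRUE,
                         dropout_rate = 0, spurious_rate = 0, null_rate = 0.1) {
  rates <- c(dropout_rate = dropout_rate, spurious_rate = spurious_rate, null_rate = null_rate)
  if (any(rates < 0 | rates > 1)) {
    pgx_usage_error(sprintf("%s must be in [0,1]", names(rates)[which(rates < 0 | rates > 1)[1L]]))
  }
  if (n_genes < 1L) pgx_usage_error("n_genes must be >= 1")
  if (length(haplotypes_per_gene) != 2L || haplotypes_per_gene[1L] > haplotypes_per_gene[2L] ||
      haplotypes_per_gene[1L] < 1L) {
    pgx_usage_error("haplotypes_per_gene must be an increasing range of positive integers")
  }
  if (length(positions_per_gene) != 2L || positions_per_gene[1L] > positions_per_gene[2L] ||
      positions_per_gene[1L] < 1L) {
    pgx_usage_error("positions_per_gene must be an increasing range of positive integers")
  }
  if (ambiguity && (haplotypes_per_gene[2L] < 4L || positions_per_gene[1L] < 2L)) {
    pgx_usage_error("ambiguity requires at least 4 haplotypes and 2 positions in range")
  }
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 haplotypes_per_gene = as.integer(haplotypes_per_gene),
                 positions_per_gene = as.integer(positions_per_gene),
                 ambiguity = isTRUE(ambiguity), dropout_rate = dropout_rate,
                 spurious_rate = spurious_rate, null_rate = null_rate,
                 groups = pgx_groups()),
            class = "pgx_fixture_spec")
}

BASES <- c("A", "C", "G", "T")

# uniform draw from an inclusive integer range (avoids the sample(n, 1) trap)
sample_range <- function(lo, hi) if (lo >= hi) lo else lo + sample.int(hi - lo + 1L, 1L) - 1L

#' Generate a toy knowledgebase
#'
#' Writes the six knowledgebase files (via the package's writers, so the
#' on-disk schema is shared with real loads). Each gene gets one reference
#' haplotype plus variant haplotypes with distinct declared sets; per-group
#' haplotype frequencies sum to 1 before null masking; guideline and
#' annotation records reference only generated genes and diplotypes. With
#' `ambiguity = TRUE` the first gene contains haplotypes declaring {v},
#' {w} and {v, w}, so reference/{v,w} and {v}/{w} are indistinguishable.
#'
#' @param spec A `pgx_fixture_spec`.
#' @param outdir Output directory (created if needed).
#' @param gene_names Optional gene symbols (length `n_genes`); default
#'   `TOYG01`, `TOYG02`, ...
#' @param chromosomes Optional per-gene contig labels; default `chr10`.
#' @param sva Optional single-variant registry data frame (gene, rsid,
#'   chromosome, position, ref, alt) to ship instead of the default two toy
#'   entries.
#' @param hla Optional HLA registry data frame (gene, allele).
#' @return The loaded `pgx_kb` (frequencies not epsilon-filled), invisibly
#'   carrying attribute `dir`.
#' @export
generate_toy_knowledgebase <- function(spec, outdir, gene_names = NULL,
                                       chromosomes = NULL, sva = NULL, hla = NULL) {
  stopifnot(inherits(spec, "pgx_fixture_spec"))
  set.seed(spec$seed)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  def_rows <- list(); freq_rows <- list()
  if (is.null(gene_names)) gene_names <- sprintf("TOYG%02d", seq_len(spec$n_genes))
  if (length(gene_names) != spec$n_genes) pgx_usage_error("gene_names must have length n_genes")
  if (is.null(chromosomes)) chromosomes <- rep("chr10", spec$n_genes)
  hap_sets <- list()
  for (gi in seq_len(spec$n_genes)) {
    g <- gene_names[gi]
    chrom <- chromosomes[gi]
    base_pos <- 1000000L * gi
    P <- sample_range(spec$positions_per_gene[1L], spec$positions_per_gene[2L])
    H <- sample_range(spec$haplotypes_per_gene[1L], spec$haplotypes_per_gene[2L])
    if (spec$ambiguity && gi == 1L) { H <- max(H, 4L); P <- max(P, 2L) }
    max_subsets <- sum(choose(P, seq_len(min(P, 3L))))
    H <- min(H, max_subsets + 1L)   # distinct declared sets must exist
    pos <- sort(sample.int(50000L, P)) + base_pos
    ref <- sample(BASES, P, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(BASES, r), 1L), "")
    haps <- c("*1", sprintf("*%d", seq_len(H - 1L) + 1L))

    # distinct nonempty declared subsets per variant haplotype
    declared <- list()
    seen <- character(0)
    for (h in haps[-1L]) {
      repeat {
        k <- sample.int(min(P, 3L), 1L)
        s <- sort(sample.int(P, k))
        key <- paste(s, collapse = ",")
        if (!(key %in% seen)) { seen <- c(seen, key); declared[[h]] <- s; break }
      }
    }
    if (spec$ambiguity && gi == 1L) {
      declared[[haps[2L]]] <- 1L          # *2 = {v}
      declared[[haps[3L]]] <- 2L          # *3 = {w}
      declared[[haps[4L]]] <- c(1L, 2L)   # *4 = {v,w}; *1/*4 ~ *2/*3
      # re-draw any later haplotype that now collides
      seen <- vapply(declared[haps[2:4]], paste, "", collapse = ",")
      for (h in haps[-(1:4)]) {
        key <- paste(declared[[h]], collapse = ",")
        while (key %in% seen) {
          k <- sample.int(min(P, 3L), 1L)
          declared[[h]] <- sort(sample.int(P, k))
          key <- paste(declared[[h]], collapse = ",")
        }
        seen <- c(seen, key)
      }
    }

    def_rows[[g]] <- rbind(
      data.frame(gene = g, haplotype = "*1", chromosome = "", position = "",
                 ref = "", alt = "", is_reference = TRUE),
      do.call(rbind, lapply(haps[-1L], function(h) {
        s <- declared[[h]]
        data.frame(gene = g, haplotype = h, chromosome = chrom,
                   position = as.character(pos[s]), ref = ref[s], alt = alt[s],
                   is_reference = FALSE)
      }))
    )
    hap_sets[[g]] <- haps

    fr <- data.frame(gene = g, haplotype = haps)
    for (grp in spec$groups) {
      x <- stats::rgamma(length(haps), shape = 0.5)
      f <- x / sum(x)
      f <- floor(f * 1e6) / 1e6   # truncate so the per-group sum stays <= 1
      f[stats::runif(length(f)) < spec$null_rate] <- NA_real_
      fr[[grp]] <- f
    }
    freq_rows[[g]] <- fr
  }

  defs <- do.call(rbind, def_rows)
  freqs <- do.call(rbind, freq_rows)
  write_allele_definitions(defs, file.path(outdir, "alleles.tsv"))
  write_haplotype_frequencies(freqs, file.path(outdir, "frequencies.tsv"))

  # single-variant registry: two toy SNV genes outside the multi-variant windows
  if (is.null(sva)) {
    sva <- data.frame(
      gene = c("TOYSV1", "TOYSV2"),
      rsid = c("rs9000001", "rs9000002"),
      chromosome = "chr16",
      position = c(31096368L, 31104878L),
      ref = c("C", "G"), alt = c("T", "A"))
  }
  write_single_variant_registry(sva, file.path(outdir, "single_variant_alleles.tsv"))

  if (is.null(hla)) {
    hla <- data.frame(gene = c("HLA-B", "HLA-A"), allele = c("HLA-B*57:01", "HLA-A*31:01"))
  }
  write_hla_registry(hla, file.path(outdir, "hla_alleles.tsv"))

  # guidelines: one avoid, one caution and routine records over generated calls
  drug_names <- sprintf("drug%02d", seq_len(max(3L, spec$n_genes)))
  gl <- list()
  for (gi in seq_len(spec$n_genes)) {
    g <- gene_names[gi]
    haps <- hap_sets[[g]]
    dip1 <- diplotype_label(haps[length(haps)], haps[length(haps)])
    dip2 <- diplotype_label("*1", haps[2L])
    drug <- drug_names[(gi - 1L) %% length(drug_names) + 1L]
    gl[[g]] <- rbind(
      data.frame(source = "CPIC", drug = drug, gene = g, genotype_key = dip1,
                 category = if (gi == 1L) "avoid" else "caution",
                 population_dependent = FALSE, multi_gene = FALSE,
                 text = sprintf("Adjust therapy for %s %s carriers.", g, dip1)),
      data.frame(source = "DPWG", drug = drug, gene = g, genotype_key = dip2,
                 category = "routine", population_dependent = gi == 2L, multi_gene = FALSE,
                 text = sprintf("No change for %s %s.", g, dip2)))
  }
  gl <- do.call(rbind, c(gl, list(
    data.frame(source = "CPIC", drug = "drugHLA", gene = hla$gene[1L],
               genotype_key = hla$allele[1L], category = "avoid",
               population_dependent = FALSE, multi_gene = FALSE,
               text = "Do not use in carriers."),
    data.frame(source = "RNPGx", drug = "drugSV", gene = sva$gene[1L],
               genotype_key = genotype_string(sva$alt[1L], sva$alt[1L]),
               category = "caution",
               population_dependent = FALSE, multi_gene = FALSE,
               text = "Reduce dose for homozygous carriers."))))
  rownames(gl) <- NULL
  write_guidelines(gl, file.path(outdir, "guidelines.tsv"))

  ann <- list()
  aid <- 0L
  for (gi in seq_len(spec$n_genes)) {
    g <- gene_names[gi]
    haps <- hap_sets[[g]]
    drug <- drug_names[(gi - 1L) %% length(drug_names) + 1L]
    for (key in c(diplotype_label("*1", haps[2L]),
                  diplotype_label(haps[2L], haps[2L]))) {
      aid <- aid + 1L
      ann[[aid]] <- data.frame(
        annotation_id = sprintf("ANN%04d", aid), drug = drug, gene = g,
        genotype_key = key,
        evidence_level = sample(EVIDENCE_LEVELS, 1L),
        category = sample(ANNOTATION_CATEGORIES, 1L),
        direction = sample(DIRECTIONS, 1L))
    }
  }
  aid <- aid + 1L
  ann[[aid]] <- data.frame(annotation_id = sprintf("ANN%04d", aid), drug = "drugSV",
                           gene = sva$gene[1L],
                           genotype_key = genotype_string(sva$ref[1L], sva$alt[1L]),
                           evidence_level = "1A", category = "metabolism",
                           direction = "decreased")
  ann <- do.call(rbind, ann)
  write_clinical_annotations(ann, file.path(outdir, "clinical_annotations.tsv"))

  invisible(load_kb(outdir, fill = FALSE))
}

#' Synthesize a single-sample VCF from chosen true diplotypes
#'
#' Emits one VCF record per position of every multi-variant gene's position
#' set — variant records where the truth diplotype's combined definition is
#' non-reference, homozygous-reference records elsewhere — plus records at
#' single-variant registry positions. Each target position is independently
#' dropped with probability `dropout_rate`; positions expected homozygous
#' reference become spurious heterozygotes with probability `spurious_rate`.
#' The truth is written to a JSON sidecar next to the VCF.
#'
#' @param kb A `pgx_kb`.
#' @param truth Named list/character: gene -> diplotype, either a canonical
#'   label `"A/B"` or a length-2 character vector of haplotype names. Genes
#'   absent from `truth` are emitted homozygous reference.
#' @param spec A `pgx_fixture_spec` (seed and noise rates are used).
#' @param out Output VCF path (plain text).
#' @param sample Sample name written to the VCF header.
#' @param sva_genotypes Optional named list rsid -> length-2 character vector
#'   of observed alleles at single-variant registry positions.
#' @return Invisibly, list with `vcf`, `truth_json` and the truth list.
#' @export
synthesize_vcf <- function(kb, truth, spec, out, sample = "SAMPLE01",
                           sva_genotypes = NULL) {
  stopifnot(inherits(spec, "pgx_fixture_spec"))
  set.seed(spec$seed)
  truth <- lapply(truth, function(v) {
    if (length(v) == 1L) strsplit(v, "/", fixed = TRUE)[[1L]] else v
  })
  for (g in names(truth)) {
    gt <- gene_table(kb, g)
    bad <- setdiff(truth[[g]], gt$haplotypes)
    if (length(bad)) {
      pgx_usage_error(sprintf("truth references unknown haplotype %s for gene %s", bad[1L], g))
    }
  }

  rows <- list()
  for (g in radix_sort(names(kb$alleles$genes))) {
    gt <- gene_table(kb, g)
    if (nrow(gt$positions) == 0L) next
    pair <- if (g %in% names(truth)) truth[[g]] else rep(gt$reference, 2L)
    cm <- combined_definition(gt, pair[1L], pair[2L])
    for (i in seq_len(nrow(gt$positions))) {
      if (stats::runif(1L) < spec$dropout_rate) next
      p <- gt$positions[i, ]
      alleles <- strsplit(cm$expected[[p$pos_id]], "/", fixed = TRUE)[[1L]]
      if (all(alleles == p$ref) && stats::runif(1L) < spec$spurious_rate) {
        # spurious het using the position's defined alternate allele
        alts <- unique(gt$allele_matrix[gt$declared_matrix[, i], i])
        spurious_alt <- if (length(alts)) radix_sort(alts)[1L] else setdiff(BASES, p$ref)[1L]
        alleles <- c(p$ref, spurious_alt)
      }
      rows[[length(rows) + 1L]] <- vcf_row(p$chrom, p$pos, ".", p$ref, alleles)
    }
  }
  for (i in seq_len(nrow(kb$sva))) {
    if (stats::runif(1L) < spec$dropout_rate) next
    r <- kb$sva[i, ]
    alleles <- if (!is.null(sva_genotypes[[r$rsid]])) sva_genotypes[[r$rsid]] else c(r$ref, r$ref)
    rows[[length(rows) + 1L]] <- vcf_row(r$chromosome, r$position, r$rsid, r$ref, alleles)
  }

  df <- do.call(rbind, rows)
  if (is.null(df)) {
    df <- data.frame(chrom = character(0), pos = integer(0), line = character(0))
  }
  df <- df[radix_order(df$chrom, df$pos), , drop = FALSE]
  header <- c("##fileformat=VCFv4.2",
              "##source=pgxdip-synthetic",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample))
  writeLines(c(header, df$line), out)

  truth_json <- paste0(sub("\\.vcf(\\.gz)?$", "", out), ".truth.json")
  jsonlite::write_json(list(sample = sample, seed = spec$seed,
                            truth = lapply(truth, function(p) diplotype_label(p[1L], p[2L]))),
                       truth_json, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(vcf = out, truth_json = truth_json, truth = truth))
}

# one VCF data line from an observed unordered allele pair at a position
vcf_row <- function(chrom, pos, id, ref, alleles) {
  alts <- radix_sort(unique(alleles[alleles != ref]))
  alt_field <- if (length(alts)) paste(alts, collapse = ",") else "."
  idx <- match(alleles, c(ref, alts)) - 1L
  gt <- paste(sort(idx), collapse = "/")
  data.frame(chrom = chrom, pos = pos,
             line = paste(chrom, pos, id, ref, alt_field, ".", "PASS", ".", "GT", gt,
                          sep = "\t"))
}
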