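#' Biogeographic groups
#'
#' The nine standardized biogeographic groups used to stratify star-allele
#' frequencies: African American/Afro-Caribbean (AAC), American (AME),
#' Central/South Asian (SAS), East Asian (EAS), European (EUR), Latino (LAT),
#' Near Eastern (NEA), Oceanian (OCE) and Sub-Saharan African (SSA).
#'
#' @return Character vector of the nine admissible group codes.
#' @export
pgx_groups <- function() {
  c("AAC", "AME", "SAS", "EAS", "EUR", "LAT", "NEA", "OCE", "SSA")
}

#' Validate a biogeographic group code
#'
#' @param code Single character string.
#' @return The code, invisibly, if admissible.
#' @export
check_group <- function(code) {
  if (!is.character(code) || length(code) != 1L || !(code %in% pgx_groups())) {
    shown <- if (is.character(code) && length(code) == 1L) shQuote(code) else "<non-string>"
    pgx_usage_error(sprintf("invalid biogeographic group %s; admissible codes: %s",
                            shown, paste(pgx_groups(), collapse = ", ")))
  }
  invisible(code)
}

#' Default multi-variant gene registry
#'
#' The thirteen pharmacogenes whose star alleles are defined by multiple
#' variants and therefore require the ranking model (as opposed to
#' single-variant alleles, which are read directly off the genotype).
#'
#' @return Character vector of 13 gene symbols.
#' @export
pgx_gene_registry <- function() {
  c("CYP2B6", "CYP2C19", "CYP2C8", "CYP2C9", "CYP2D6", "CYP3A4", "CYP3A5",
    "CYP4F2", "DPYD", "NUDT15", "SLCO1B1", "TPMT", "UGT1A1")
}

KB_HEADER <- "#format=pgxkb-1 build=GRCh38"

GUIDELINE_SOURCES <- c("CPIC", "DPWG", "CPNDS", "RNPGx")
GUIDELINE_CATEGORIES <- c("avoid", "caution", "routine")
EVIDENCE_LEVELS <- c("1A", "1B", "2A", "2B")
ANNOTATION_CATEGORIES <- c("toxicity", "dosage", "efficacy", "metabolism")
DIRECTIONS <- c("decreased", "normal", "increased")

# locale-independent ordering used everywhere a canonical order is promised
radix_order <- function(...) order(..., method = "radix")
radix_sort <- function(x) {
  if (is.null(x) || length(x) == 0L) return(character(0))
  x[order(x, method = "radix")]
}

read_kb_table <- function(path, required_cols) {
  if (!file.exists(path)) pgx_input_error(sprintf("knowledgebase file not found: %s", path))
  first <- readLines(path, n = 1L)
  if (!identical(first, KB_HEADER)) {
    pgx_schema_error(sprintf("%s: missing or wrong format header (expected '%s')", path, KB_HEADER))
  }
  df <- utils::read.delim(path, skip = 1L, header = TRUE, sep = "\t",
                          colClasses = "character", na.strings = character(0),
                          check.names = FALSE, quote = "", comment.char = "")
  missing_cols <- setdiff(required_cols, names(df))
  if (length(missing_cols)) {
    pgx_schema_error(sprintf("%s: missing required column(s): %s",
                             path, paste(missing_cols, collapse = ", ")))
  }
  df
}

write_kb_table <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(KB_HEADER, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "")
  invisible(path)
}

#' Load star-allele (haplotype) definitions
#'
#' Reads the `alleles.tsv` table of a knowledgebase directory. Each
#' non-reference haplotype occupies one row per declared variant
#' (gene, haplotype, chromosome, position, ref, alt, is_reference);
#' the reference (wild-type) haplotype of a gene is an explicit row with
#' empty variant columns and `is_reference = 1`. Variants are left-align
#' normalized on load (see [normalize_variant()]).
#'
#' @param path Path to `alleles.tsv`.
#' @return Object of class `pgx_allele_table`: a named list of per-gene
#'   tables (class `pgx_gene`, see [gene_table()]) plus the raw normalized
#'   definition rows in `$definitions`.
#' @export
load_allele_definitions <- function(path) {
  cols <- c("gene", "haplotype", "chromosome", "position", "ref", "alt", "is_reference")
  df <- read_kb_table(path, cols)[, cols]
  df$is_reference <- df$is_reference %in% c("1", "TRUE", "true")

  blank <- df$chromosome == "" & df$position == "" & df$ref == "" & df$alt == ""
  if (any(df$is_reference & !blank)) {
    bad <- df[df$is_reference & !blank, ][1L, ]
    pgx_schema_error(sprintf("reference haplotype %s %s declares a variant; reference rows must have empty variant columns",
                             bad$gene, bad$haplotype))
  }
  if (any(!df$is_reference & blank)) {
    bad <- df[!df$is_reference & blank, ][1L, ]
    pgx_schema_error(sprintf("haplotype %s %s has no declared variant but is not flagged as reference",
                             bad$gene, bad$haplotype))
  }

  # normalize declared variants
  var <- df[!df$is_reference, , drop = FALSE]
  if (nrow(var)) {
    if (any(var$ref == var$alt)) {
      bad <- var[var$ref == var$alt, ][1L, ]
      pgx_schema_error(sprintf("non-variant row (ref == alt) for %s %s at %s:%s",
                               bad$gene, bad$haplotype, bad$chromosome, bad$position))
    }
    norm <- Map(normalize_variant, var$chromosome, as.integer(var$position), var$ref, var$alt)
    var$position <- vapply(norm, function(v) v$position, 0L)
    var$ref <- vapply(norm, function(v) v$ref, "")
    var$alt <- vapply(norm, function(v) v$alt, "")
  } else {
    var$position <- integer(0)
  }

  key <- paste(var$gene, var$haplotype, var$chromosome, var$position)
  if (anyDuplicated(key)) {
    d <- var[duplicated(key), ][1L, ]
    pgx_schema_error(sprintf("duplicate declared position for (%s, %s) at %s:%d",
                             d$gene, d$haplotype, d$chromosome, d$position))
  }
  ref_rows <- df[df$is_reference, , drop = FALSE]
  if (anyDuplicated(paste(ref_rows$gene, ref_rows$haplotype))) {
    d <- ref_rows[duplicated(paste(ref_rows$gene, ref_rows$haplotype)), ][1L, ]
    pgx_schema_error(sprintf("duplicate reference row for (%s, %s)", d$gene, d$haplotype))
  }
  # a haplotype may not be both reference and variant-declaring
  both <- intersect(paste(ref_rows$gene, ref_rows$haplotype), unique(paste(var$gene, var$haplotype)))
  if (length(both)) {
    pgx_schema_error(sprintf("duplicate haplotype declared both reference and variant: (%s)", both[1L]))
  }

  # store normalized variant rows so that write/reload round-trips exactly
  df[!df$is_reference, c("position", "ref", "alt")] <-
    data.frame(position = as.character(var$position), ref = var$ref, alt = var$alt)

  genes <- radix_sort(unique(df$gene))
  tables <- lapply(genes, function(g) {
    n_ref <- sum(ref_rows$gene == g)
    if (n_ref != 1L) {
      pgx_schema_error(sprintf("gene %s has %d reference haplotypes; exactly one required", g, n_ref))
    }
    build_gene_table(g,
                     ref_name = ref_rows$haplotype[ref_rows$gene == g],
                     var = var[var$gene == g, , drop = FALSE])
  })
  names(tables) <- genes

  structure(list(genes = tables, definitions = df), class = "pgx_allele_table")
}

# Assemble the per-gene working representation: position table, per-haplotype
# declared maps, and H x P allele / declared matrices used by the scorer.
build_gene_table <- function(gene, ref_name, var) {
  if (nrow(var)) {
    pos_df <- unique(var[, c("chromosome", "position", "ref")])
    pos_key <- paste0(pos_df$chromosome, ":", pos_df$position)
    if (anyDuplicated(pos_key)) {
      pgx_schema_error(sprintf("gene %s: conflicting reference alleles declared at position %s",
                               gene, pos_key[duplicated(pos_key)][1L]))
    }
    o <- radix_order(pos_df$chromosome, pos_df$position)
    pos_df <- pos_df[o, , drop = FALSE]
    positions <- data.frame(pos_id = paste0(pos_df$chromosome, ":", pos_df$position),
                            chrom = pos_df$chromosome, pos = pos_df$position,
                            ref = pos_df$ref, stringsAsFactors = FALSE)
  } else {
    positions <- data.frame(pos_id = character(0), chrom = character(0),
                            pos = integer(0), ref = character(0))
  }
  rownames(positions) <- NULL

  hap_names <- radix_sort(unique(c(ref_name, var$haplotype)))
  H <- length(hap_names); P <- nrow(positions)
  allele_matrix <- matrix(rep(positions$ref, each = H), nrow = H, ncol = P,
                          dimnames = list(hap_names, positions$pos_id))
  declared_matrix <- matrix(FALSE, H, P, dimnames = list(hap_names, positions$pos_id))
  if (nrow(var)) {
    idx <- cbind(match(var$haplotype, hap_names),
                 match(paste0(var$chromosome, ":", var$position), positions$pos_id))
    allele_matrix[idx] <- var$alt
    declared_matrix[idx] <- TRUE
  }
  structure(list(gene = gene, reference = ref_name, haplotypes = hap_names,
                 positions = positions, allele_matrix = allele_matrix,
                 declared_matrix = declared_matrix),
            class = "pgx_gene")
}

#' Retrieve one gene's table from an allele-definition table or knowledgebase
#' @param x A `pgx_allele_table` or `pgx_kb` object.
#' @param gene Gene symbol.
#' @return A `pgx_gene` object.
#' @export
gene_table <- function(x, gene) {
  genes <- if (inherits(x, "pgx_kb")) x$alleles$genes else x$genes
  if (is.null(genes[[gene]])) pgx_lookup_error(sprintf("unknown gene: %s", gene))
  genes[[gene]]
}

#' Load per-population haplotype frequencies
#'
#' Reads `frequencies.tsv`: columns `gene`, `haplotype`, then the nine
#' biogeographic group codes. Empty cells are kept as `NA` ("no data", as
#' opposed to an observed frequency of zero) until [fill_null_frequencies()]
#' replaces them with epsilon.
#'
#' @param path Path to `frequencies.tsv`.
#' @param epsilon Fill value recorded on the table (default `1e-5`); the fill
#'   itself only happens in [fill_null_frequencies()].
#' @return A `pgx_freqs` data frame with attributes `epsilon` and `filled`.
#' @export
load_haplotype_frequencies <- function(path, epsilon = 1e-5) {
  df <- read_kb_table(path, c("gene", "haplotype"))
  extra <- setdiff(names(df), c("gene", "haplotype"))
  bad <- setdiff(extra, pgx_groups())
  if (length(bad)) {
    pgx_schema_error(sprintf("unknown population column(s) %s; admissible codes: %s",
                             paste(bad, collapse = ", "), paste(pgx_groups(), collapse = ", ")))
  }
  missing_groups <- setdiff(pgx_groups(), extra)
  if (length(missing_groups)) {
    pgx_schema_error(sprintf("missing population column(s): %s", paste(missing_groups, collapse = ", ")))
  }
  out <- df[, c("gene", "haplotype")]
  for (g in pgx_groups()) {
    v <- df[[g]]
    v[v == ""] <- NA_character_
    num <- suppressWarnings(as.numeric(v))
    if (any(!is.na(v) & is.na(num))) {
      pgx_schema_error(sprintf("non-numeric frequency %s in column %s", v[!is.na(v) & is.na(num)][1L], g))
    }
    if (any(num < 0 | num > 1, na.rm = TRUE)) {
      pgx_schema_error(sprintf("frequency outside [0,1] in column %s", g))
    }
    out[[g]] <- num
  }
  if (anyDuplicated(paste(out$gene, out$haplotype))) {
    pgx_schema_error("duplicate (gene, haplotype) row in frequency table")
  }
  structure(out, epsilon = epsilon, filled = FALSE,
            class = c("pgx_freqs", "data.frame"))
}

#' Derive a haplotype's population frequencies from its defining variants
#'
#' When a curated haplotype frequency is unavailable, the haplotype frequency
#' per population is taken as the minimum over the frequencies of its
#' defining variants in that population (a haplotype cannot be more common
#' than its rarest defining variant). If any defining variant has no data
#' (`NA`) for a group, the haplotype frequency for that group is `NA` —
#' a minimum over partially known values would overstate confidence — and is
#' later epsilon-filled.
#'
#' @param variant_freqs List (one element per defining variant) of named
#'   numeric vectors, names being biogeographic group codes; `NA` = no data.
#' @return Named numeric vector over the union of group codes.
#' @export
haplotype_frequency_from_variant_frequencies <- function(variant_freqs) {
  if (!is.list(variant_freqs) || length(variant_freqs) == 0L) {
    pgx_usage_error("variant_freqs must be a non-empty list of named numeric vectors")
  }
  groups <- radix_sort(unique(unlist(lapply(variant_freqs, names))))
  if (length(groups) == 0L) pgx_usage_error("variant frequency vectors must be named by group code")
  vapply(groups, function(g) {
    vals <- vapply(variant_freqs, function(v) if (g %in% names(v)) unname(v[[g]]) else NA_real_, 0)
    if (anyNA(vals)) NA_real_ else min(vals)
  }, 0)
}

#' Replace missing (null) frequencies by epsilon
#'
#' A null frequency reflects insufficient data, whereas an observed zero means
#' the haplotype is essentially absent from that population; therefore nulls
#' are replaced by a small positive epsilon (default `1e-5`) while exact
#' zeros are preserved.
#'
#' @param table A `pgx_freqs` table.
#' @param epsilon Positive fill value; defaults to the table's recorded epsilon.
#' @return The table with no remaining `NA` and attribute `filled = TRUE`.
#' @export
fill_null_frequencies <- function(table, epsilon = attr(table, "epsilon")) {
  if (is.null(epsilon)) epsilon <- 1e-5
  if (!is.numeric(epsilon) || length(epsilon) != 1L || is.na(epsilon) || epsilon <= 0) {
    pgx_usage_error("epsilon must be a single positive number")
  }
  for (g in intersect(pgx_groups(), names(table))) {
    v <- table[[g]]
    v[is.na(v)] <- epsilon
    table[[g]] <- v
  }
  attr(table, "epsilon") <- epsilon
  attr(table, "filled") <- TRUE
  table
}

#' Load dosing-guideline records
#'
#' Reads `guidelines.tsv` with columns source, drug, gene, genotype_key,
#' category, population_dependent, multi_gene, text. Sources are restricted to
#' the four consortia (CPIC, DPWG, CPNDS, RNPGx) and categories to
#' avoid / caution / routine.
#'
#' @param path Path to `guidelines.tsv`.
#' @return Data frame of guideline records (logical flag columns).
#' @export
load_guidelines <- function(path) {
  cols <- c("source", "drug", "gene", "genotype_key", "category",
            "population_dependent", "multi_gene", "text")
  df <- read_kb_table(path, cols)[, cols]
  bad_src <- setdiff(unique(df$source), GUIDELINE_SOURCES)
  if (length(bad_src)) {
    pgx_schema_error(sprintf("unknown guideline source %s; admissible: %s",
                             bad_src[1L], paste(GUIDELINE_SOURCES, collapse = ", ")))
  }
  bad_cat <- setdiff(unique(df$category), GUIDELINE_CATEGORIES)
  if (length(bad_cat)) {
    pgx_schema_error(sprintf("unknown guideline category %s; admissible: %s",
                             bad_cat[1L], paste(GUIDELINE_CATEGORIES, collapse = ", ")))
  }
  df$population_dependent <- df$population_dependent %in% c("1", "TRUE", "true")
  df$multi_gene <- df$multi_gene %in% c("1", "TRUE", "true")
  df
}

#' Load evidence-graded clinical-annotation records
#'
#' Reads `clinical_annotations.tsv`. Only evidence levels 1A, 1B, 2A and 2B
#' are retained; rows at other levels are dropped with a message reporting the
#' count. Phenotype categories (toxicity, dosage, efficacy, metabolism) and
#' direction tokens (decreased, normal, increased) are validated strictly.
#'
#' @param path Path to `clinical_annotations.tsv`.
#' @return Data frame of retained annotation records.
#' @export
load_clinical_annotations <- function(path) {
  cols <- c("annotation_id", "drug", "gene", "genotype_key", "evidence_level",
            "category", "direction")
  df <- read_kb_table(path, cols)[, cols]
  bad_cat <- setdiff(unique(df$category), ANNOTATION_CATEGORIES)
  if (length(bad_cat)) {
    pgx_schema_error(sprintf("unknown annotation category %s; admissible: %s",
                             bad_cat[1L], paste(ANNOTATION_CATEGORIES, collapse = ", ")))
  }
  bad_dir <- setdiff(unique(df$direction), DIRECTIONS)
  if (length(bad_dir)) {
    pgx_schema_error(sprintf("unknown direction token %s; admissible: %s",
                             bad_dir[1L], paste(DIRECTIONS, collapse = ", ")))
  }
  keep <- df$evidence_level %in% EVIDENCE_LEVELS
  if (any(!keep)) {
    message(sprintf("dropped %d clinical annotation(s) outside evidence levels %s",
                    sum(!keep), paste(EVIDENCE_LEVELS, collapse = "/")))
  }
  df <- df[keep, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Load the single-variant-allele registry
#'
#' Genes whose pharmacogenomic alleles are defined by one variant each
#' (for example VKORC1 rs9923231): their "diplotype" is simply the observed
#' genotype at that position, read directly off the VCF.
#'
#' @param path Path to `single_variant_alleles.tsv`.
#' @return Data frame with gene, rsid, chromosome, position, ref, alt, pos_id.
#' @export
load_single_variant_registry <- function(path) {
  cols <- c("gene", "rsid", "chromosome", "position", "ref", "alt")
  df <- read_kb_table(path, cols)[, cols]
  df$position <- as.integer(df$position)
  if (anyNA(df$position) || any(df$position < 1L)) {
    pgx_schema_error("single-variant registry: position must be a positive integer")
  }
  if (any(df$ref == df$alt)) pgx_schema_error("single-variant registry: ref == alt row")
  df$pos_id <- paste0(df$chromosome, ":", df$position)
  df[radix_order(df$gene, df$rsid), , drop = FALSE]
}

#' Load the HLA allele registry
#'
#' @param path Path to `hla_alleles.tsv` (columns gene, allele).
#' @return Data frame of registered HLA alleles.
#' @export
load_hla_registry <- function(path) {
  df <- read_kb_table(path, c("gene", "allele"))[, c("gene", "allele")]
  df[radix_order(df$gene, df$allele), , drop = FALSE]
}

#' Load a complete knowledgebase directory
#'
#' A knowledgebase is a directory of six tab-separated files, each headed by
#' a `#format=pgxkb-1 build=GRCh38` line: `alleles.tsv`, `frequencies.tsv`,
#' `guidelines.tsv`, `clinical_annotations.tsv`, `single_variant_alleles.tsv`
#' and `hla_alleles.tsv`.
#'
#' @param dir Knowledgebase directory.
#' @param fill If `TRUE` (default) epsilon-fill the frequency table on load.
#' @param epsilon Fill constant, default `1e-5`.
#' @return Object of class `pgx_kb`.
#' @export
load_kb <- function(dir, fill = TRUE, epsilon = 1e-5) {
  if (!dir.exists(dir)) pgx_input_error(sprintf("knowledgebase directory not found: %s", dir))
  kb <- structure(list(
    dir = dir,
    alleles = load_allele_definitions(file.path(dir, "alleles.tsv")),
    freqs = load_haplotype_frequencies(file.path(dir, "frequencies.tsv"), epsilon = epsilon),
    guidelines = load_guidelines(file.path(dir, "guidelines.tsv")),
    annotations = load_clinical_annotations(file.path(dir, "clinical_annotations.tsv")),
    sva = load_single_variant_registry(file.path(dir, "single_variant_alleles.tsv")),
    hla = load_hla_registry(file.path(dir, "hla_alleles.tsv"))
  ), class = "pgx_kb")
  if (fill) kb$freqs <- fill_null_frequencies(kb$freqs, epsilon)
  kb
}

#' The bundled synthetic demonstration knowledgebase
#'
#' A small, fully synthetic knowledgebase shipped with the package covering
#' the thirteen multi-variant pharmacogenes of [pgx_gene_registry()] plus a
#' few single-variant and HLA entries. Its allele definitions, frequencies,
#' guidelines and annotations are invented for demonstration and testing;
#' they are not curated clinical content and must not be used for
#' interpretation of real samples.
#'
#' @param fill Epsilon-fill frequencies on load (default `TRUE`).
#' @return A `pgx_kb` object.
#' @export
default_kb <- function(fill = TRUE) {
  dir <- system.file("extdata", "synthetic_kb", package = "pgxdip")
  if (dir == "") pgx_state_error("bundled synthetic knowledgebase not found")
  load_kb(dir, fill = fill)
}

#' @export
print.pgx_kb <- function(x, ...) {
  cat("pgxdip knowledgebase:", x$dir, "\n")
  cat("  multi-variant genes:", length(x$alleles$genes), "\n")
  cat("  haplotype frequency rows:", nrow(x$freqs),
      if (isTRUE(attr(x$freqs, "filled"))) "(epsilon-filled)" else "(raw)", "\n")
  cat("  guideline records:", nrow(x$guidelines), "\n")
  cat("  clinical annotations:", nrow(x$annotations), "\n")
  cat("  single-variant alleles:", nrow(x$sva), "  HLA alleles:", nrow(x$hla), "\n")
  invisible(x)
}

# ---- writers (round-trip partners of the loaders; used by the fixture
# generator so generated knowledgebases share one serialisation path) ----

#' Write knowledgebase tables
#'
#' Serialise in-memory knowledgebase tables back to the tab-separated on-disk
#' schema. Writing any loaded table and reloading yields an identical
#' in-memory structure.
#'
#' @param x The table to write (see the corresponding loader).
#' @param path Output file path.
#' @return The path, invisibly.
#' @name kb_writers
NULL

#' @rdname kb_writers
#' @export
write_allele_definitions <- function(x, path) {
  df <- if (inherits(x, "pgx_allele_table")) x$definitions else x
  df <- as.data.frame(df)
  df$is_reference <- as.integer(df$is_reference)
  write_kb_table(df, path)
}

#' @rdname kb_writers
#' @export
write_haplotype_frequencies <- function(x, path) {
  df <- as.data.frame(x)
  for (g in intersect(pgx_groups(), names(df))) {
    v <- df[[g]]
    df[[g]] <- ifelse(is.na(v), "", vapply(v, format_num, ""))
  }
  write_kb_table(df, path)
}

format_num <- function(x) format(x, scientific = FALSE, trim = TRUE, digits = 15)

#' @rdname kb_writers
#' @export
write_guidelines <- function(x, path) {
  df <- as.data.frame(x)
  df$population_dependent <- as.integer(df$population_dependent)
  df$multi_gene <- as.integer(df$multi_gene)
  write_kb_table(df, path)
}

#' @rdname kb_writers
#' @export
write_clinical_annotations <- function(x, path) write_kb_table(as.data.frame(x), path)

#' @rdname kb_writers
#' @export
write_single_variant_registry <- function(x, path) {
  df <- as.data.frame(x)
  df$pos_id <- NULL
  write_kb_table(df, path)
}

#' @rdname kb_writers
#' @export
write_hla_registry <- function(x, path) write_kb_table(as.data.frame(x), path)
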