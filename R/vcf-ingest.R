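# Single-sample VCF ingestion: variant normalization, genotype extraction at
# knowledgebase positions, single-variant-allele calls, HLA calls.
# Parsing of the VCF container is delegated to vcfR; this module owns the
# mapping from records to knowledgebase positions.

#' Normalize a variant to its parsimonious left-aligned form
#'
#' Trims the shared suffix, then the shared prefix (advancing the position),
#' keeping at least one base on each side. SNVs are unchanged. Idempotent.
#'
#' @param chromosome Contig label.
#' @param position 1-based position.
#' @param ref,alt Non-empty uppercase allele strings.
#' @return List with `chromosome`, `position`, `ref`, `alt`.
#' @export
normalize_variant <- function(chromosome, position, ref, alt) {
  if (!nzchar(ref) || !nzchar(alt)) pgx_input_error("ref and alt must be non-empty")
  position <- as.integer(position)
  if (is.na(position) || position < 1L) pgx_input_error("position must be a positive integer")
  r <- strsplit(ref, "", fixed = TRUE)[[1L]]
  a <- strsplit(alt, "", fixed = TRUE)[[1L]]
  # shared suffix
  while (length(r) > 1L && length(a) > 1L && r[length(r)] == a[length(a)]) {
    r <- r[-length(r)]; a <- a[-length(a)]
  }
  # shared prefix, advancing position
  while (length(r) > 1L && length(a) > 1L && r[1L] == a[1L]) {
    r <- r[-1L]; a <- a[-1L]; position <- position + 1L
  }
  ref <- paste(r, collapse = ""); alt <- paste(a, collapse = "")
  if (identical(ref, alt)) pgx_input_error("non-variant record: ref equals alt after trimming")
  list(chromosome = chromosome, position = position, ref = ref, alt = alt)
}

# target table: every knowledgebase-relevant position (multi-variant gene
# position sets plus single-variant registry positions), deduplicated
kb_target_positions <- function(kb) {
  per_gene <- lapply(kb$alleles$genes, function(g) g$positions[, c("pos_id", "chrom", "pos", "ref")])
  tg <- do.call(rbind, c(per_gene, list(kb$sva[, c("pos_id", "chromosome", "position", "ref")] |>
                                          stats::setNames(c("pos_id", "chrom", "pos", "ref")))))
  tg <- tg[!duplicated(tg$pos_id), , drop = FALSE]
  tg <- tg[radix_order(tg$chrom, tg$pos), , drop = FALSE]
  rownames(tg) <- NULL
  tg
}

#' Read sample genotypes at knowledgebase positions
#'
#' Extracts the GT field of a single-sample germline VCF at every
#' knowledgebase-relevant position. Phase separators `|` and `/` are treated
#' identically (the model is defined for unphased input); multi-allelic
#' records are split and normalized before matching; positions with no
#' record, or with GT `./.`, are flagged missing — absence is treated as
#' untyped, never as homozygous reference.
#'
#' @param vcf Path to a VCF file (plain or bgzipped).
#' @param kb A `pgx_kb` knowledgebase.
#' @param sample Sample name; required when the VCF has several samples.
#' @param respect_filter Drop records whose FILTER is neither `PASS` nor `.`
#'   (default `FALSE`: FILTER is ignored).
#' @return Object of class `pgx_genotypes`: list with `sample`, `calls`
#'   (data frame: pos_id, chrom, pos, ref, a1, a2, genotype, missing) and
#'   `hla` (data frame of HLA calls found as symbolic ALT records).
#' @export
read_genotypes <- function(vcf, kb, sample = NULL, respect_filter = FALSE) {
  rec <- read_vcf_records(vcf, sample = sample)
  targets <- kb_target_positions(kb)
  calls <- data.frame(targets,
                      a1 = NA_character_, a2 = NA_character_,
                      genotype = NA_character_, missing = TRUE,
                      stringsAsFactors = FALSE)
  tmap <- stats::setNames(seq_len(nrow(calls)), calls$pos_id)

  recs <- rec$records
  if (respect_filter && length(recs)) {
    recs <- Filter(function(r) r$filter %in% c("PASS", "."), recs)
  }
  for (r in recs) {
    if (is.null(r$gt)) next                      # no GT for this sample
    alleles <- r$alleles                          # index 0 = REF
    # normalized location of each ALT allele (NA for symbolic / spanning)
    norm <- r$norm
    # which targets does this record inform? the record's own start, plus the
    # normalized start of each concrete ALT
    cand <- unique(c(paste0(r$chrom, ":", r$pos),
                     stats::na.omit(vapply(norm, function(v)
                       if (is.null(v)) NA_character_ else paste0(v$chromosome, ":", v$position), ""))))
    for (pid in cand) {
      ti <- tmap[pid]
      if (is.na(ti)) next
      tref <- calls$ref[ti]
      # translate the two GT indices into allele strings at this target
      obs <- character(2L)
      ok <- TRUE
      for (k in 1:2) {
        gi <- r$gt[k]
        if (is.na(gi)) { ok <- FALSE; break }
        if (gi == 0L) { obs[k] <- tref; next }
        v <- norm[[gi]]
        if (is.null(v)) { ok <- FALSE; break }   # symbolic ALT: uninformative here
        if (paste0(v$chromosome, ":", v$position) == pid) {
          if (!identical(v$ref, tref)) { ok <- FALSE; break }  # incompatible representation
          obs[k] <- v$alt
        } else {
          obs[k] <- tref                          # this ALT falls elsewhere
        }
      }
      if (!ok) next
      has_nonref <- any(obs != tref)
      if (!calls$missing[ti] && !has_nonref) next # keep an earlier non-ref observation
      calls$a1[ti] <- obs[1L]; calls$a2[ti] <- obs[2L]
      calls$genotype[ti] <- genotype_string(obs[1L], obs[2L])
      calls$missing[ti] <- FALSE
    }
  }
  structure(list(sample = rec$sample, calls = calls, hla = rec$hla),
            class = "pgx_genotypes")
}

# Parse a VCF into a light record list via vcfR. Each record carries the two
# GT allele indices (unordered; NA when missing), the allele strings, the
# normalized form of each concrete ALT, and any symbolic HLA ALT calls.
read_vcf_records <- function(vcf, sample = NULL) {
  if (!file.exists(vcf)) pgx_input_error(sprintf("VCF file not found: %s", vcf))
  v <- tryCatch(vcfR::read.vcfR(vcf, verbose = FALSE),
                error = function(e) pgx_input_error(sprintf("cannot read VCF %s: %s", vcf, conditionMessage(e))))
  samples <- colnames(v@gt)[-1L]
  if (length(samples) == 0L) pgx_input_error("VCF has no sample columns")
  if (is.null(sample)) {
    if (length(samples) > 1L) {
      pgx_input_error(sprintf("VCF has %d samples; specify one of: %s",
                              length(samples), paste(samples, collapse = ", ")))
    }
    sample <- samples[1L]
  } else if (!(sample %in% samples)) {
    pgx_input_error(sprintf("sample %s not present in VCF (samples: %s)",
                            sample, paste(samples, collapse = ", ")))
  }
  fix <- v@fix
  n <- nrow(fix)
  gt_field <- if (n) vcfR::extract.gt(v, element = "GT")[, sample] else character(0)
  hla <- data.frame(allele = character(0), copies = integer(0))
  records <- vector("list", n)
  for (i in seq_len(n)) {
    chrom <- fix[i, "CHROM"]; pos <- as.integer(fix[i, "POS"])
    ref <- toupper(fix[i, "REF"])
    alt_raw <- fix[i, "ALT"]
    alts <- if (is.na(alt_raw) || alt_raw == ".") character(0) else strsplit(alt_raw, ",", fixed = TRUE)[[1L]]
    gt_str <- gt_field[i]
    idx <- if (is.na(gt_str) || gt_str %in% c(".", "./.", ".|.")) {
      c(NA_integer_, NA_integer_)
    } else {
      parts <- strsplit(gt_str, "[/|]")[[1L]]
      suppressWarnings(as.integer(parts))[1:2]
    }
    # symbolic HLA ALT entries contribute presence/copy-number calls
    sym_hla <- grepl("^<HLA-", alts)
    for (k in which(sym_hla)) {
      copies <- sum(idx == k, na.rm = TRUE)
      if (copies > 0L) {
        allele <- sub("^<(.*)>$", "\\1", alts[k])
        hla <- rbind(hla, data.frame(allele = allele, copies = copies))
      }
    }
    norm <- lapply(seq_along(alts), function(k) {
      a <- toupper(alts[k])
      if (grepl("[^ACGTN]", a)) return(NULL)    # symbolic, spanning (*), breakend
      tryCatch(normalize_variant(chrom, pos, ref, a), pgxdip_error = function(e) NULL)
    })
    records[[i]] <- list(chrom = chrom, pos = pos, ref = ref,
                         alleles = c(ref, toupper(alts)), norm = norm,
                         gt = if (all(is.na(idx))) NULL else idx,
                         filter = fix[i, "FILTER"])
  }
  if (nrow(hla)) {
    hla <- stats::aggregate(copies ~ allele, hla, max)
    hla <- hla[radix_order(hla$allele), , drop = FALSE]
  }
  list(sample = sample, records = records, hla = hla)
}

#' Call single-variant alleles directly from genotypes
#'
#' For genes whose alleles are defined by one variant (for example VKORC1
#' rs9923231), the diplotype is the observed genotype at the registry
#' position. Unmeasured positions are reported as `not tested`, never
#' guessed.
#'
#' @param genotypes A `pgx_genotypes` object.
#' @param kb A `pgx_kb` knowledgebase (uses its single-variant registry).
#' @return Data frame: gene, rsid, pos_id, genotype (`"a/b"` or `NA`),
#'   status (`"called"` or `"not tested"`).
#' @export
call_single_variant_alleles <- function(genotypes, kb) {
  reg <- kb$sva
  m <- match(reg$pos_id, genotypes$calls$pos_id)
  gt <- genotypes$calls$genotype[m]
  missing <- is.na(m) | genotypes$calls$missing[m]
  data.frame(gene = reg$gene, rsid = reg$rsid, pos_id = reg$pos_id,
             genotype = ifelse(missing, NA_character_, gt),
             status = ifelse(missing, "not tested", "called"),
             stringsAsFactors = FALSE)
}

#' Collect HLA presence / copy-number calls
#'
#' HLA typing is consumed, not performed: calls are accepted either as
#' symbolic ALT entries in the VCF (e.g. `<HLA-B*57:01>`, copy number from
#' the GT indices) or as a sidecar text file with lines `allele<TAB>copies`.
#'
#' @param genotypes Optional `pgx_genotypes` (symbolic ALT calls found there).
#' @param sidecar Optional path to a sidecar file.
#' @return Data frame with columns `allele`, `copies`; empty when nothing is
#'   provided.
#' @export
extract_hla_calls <- function(genotypes = NULL, sidecar = NULL) {
  out <- data.frame(allele = character(0), copies = integer(0))
  if (!is.null(genotypes) && nrow(genotypes$hla)) out <- genotypes$hla
  if (!is.null(sidecar)) {
    if (!file.exists(sidecar)) pgx_input_error(sprintf("HLA sidecar not found: %s", sidecar))
    lines <- readLines(sidecar)
    for (ln in seq_along(lines)) {
      line <- lines[ln]
      if (!nzchar(trimws(line)) || startsWith(line, "#")) next
      parts <- strsplit(line, "\t", fixed = TRUE)[[1L]]
      copies <- if (length(parts) == 2L) suppressWarnings(as.integer(parts[2L])) else NA_integer_
      if (length(parts) != 2L || is.na(copies) || copies < 1L) {
        pgx_input_error(sprintf("malformed HLA sidecar line %d: %s", ln, line))
      }
      out <- rbind(out, data.frame(allele = parts[1L], copies = copies))
    }
  }
  if (nrow(out)) {
    out <- stats::aggregate(copies ~ allele, out, max)
    out <- out[radix_order(out$allele), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' @export
print.pgx_genotypes <- function(x, ...) {
  cat("pgxdip genotypes for sample", x$sample, "\n")
  cat("  positions:", nrow(x$calls),
      sprintf("(%d typed, %d missing)", sum(!x$calls$missing), sum(x$calls$missing)), "\n")
  if (nrow(x$hla)) cat("  HLA calls:", paste(x$hla$allele, collapse = ", "), "\n")
  invisible(x)
}
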