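#' Annotate a germline VCF with pharmacogenomic calls
#'
#' End-to-end pipeline: read genotypes at knowledgebase positions, infer the
#' most likely star-allele diplotype per multi-variant gene with the
#' two-step ranking model, call single-variant alleles and collect HLA
#' calls, classify drugs from dosing guidelines into avoid / caution /
#' routine, and integrate clinical annotations into predicted drug-response
#' phenotypes.
#'
#' @param vcf Path to a single-sample germline VCF (GRCh38).
#' @param population Biogeographic group code, one of [pgx_groups()].
#' @param kb A `pgx_kb` or knowledgebase directory path; defaults to the
#'   bundled synthetic demonstration knowledgebase ([default_kb()]).
#' @param sample Sample name (required for multi-sample VCFs).
#' @param respect_filter Drop non-PASS records (default `FALSE`).
#' @param hla_sidecar Optional HLA sidecar file path.
#' @param timestamp Report timestamp; injected for reproducibility, defaults
#'   to the current UTC time.
#' @param notes Optional character vector of free-text notes for the report.
#' @return Object of class `pgx_annotation` with components `context`
#'   (a `pgx_report_context`), `inference`, `sva_calls`, `hla_calls`,
#'   `categories` and `drug_reports`.
#' @examples
#' spec <- fixture_spec(seed = 42)
#' kb_dir <- file.path(tempdir(), "toy_kb")
#' kb <- generate_toy_knowledgebase(spec, kb_dir)
#' vcf <- file.path(tempdir(), "toy.vcf")
#' synthesize_vcf(kb, list(TOYG01 = "*1/*2"), spec, vcf)
#' res <- pgx_annotate(vcf, "EAS", kb = kb_dir, timestamp = "2026-01-01T00:00:00Z")
#' print(res)
#' @export
pgx_annotate <- function(vcf, population, kb = NULL, sample = NULL,
                         respect_filter = FALSE, hla_sidecar = NULL,
                         timestamp = NULL, notes = character(0)) {
  check_group(population)
  if (is.null(kb)) kb <- default_kb()
  if (is.character(kb)) kb <- load_kb(kb)
  if (!inherits(kb, "pgx_kb")) pgx_usage_error("kb must be a pgx_kb object or a directory path")
  if (!isTRUE(attr(kb$freqs, "filled"))) kb$freqs <- fill_null_frequencies(kb$freqs)
  if (is.null(timestamp)) timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

  genotypes <- read_genotypes(vcf, kb, sample = sample, respect_filter = respect_filter)
  inference <- infer_all(genotypes, population, kb)
  sva_calls <- call_single_variant_alleles(genotypes, kb)
  hla_calls <- extract_hla_calls(genotypes, sidecar = hla_sidecar)

  calls <- call_keys(inference, sva_calls, hla_calls, kb)
  categories <- classify_drugs(calls, kb$guidelines)
  matched <- match_annotations(calls, kb$annotations, categories)
  drug_reports <- integrate_phenotypes(matched, categories, kb$guidelines, calls)

  context <- report_context(sample = genotypes$sample, group = population,
                            inference = inference, sva_calls = sva_calls,
                            hla_calls = hla_calls, drug_reports = drug_reports,
                            matched = matched, kb = kb, genotypes = genotypes,
                            timestamp = timestamp, notes = notes)
  structure(list(context = context, genotypes = genotypes, inference = inference,
                 sva_calls = sva_calls, hla_calls = hla_calls, calls = calls,
                 categories = categories, matched = matched,
                 drug_reports = drug_reports, kb = kb),
            class = "pgx_annotation")
}

#' Write the report files of an annotation run
#'
#' @param x A `pgx_annotation`.
#' @param prefix Output path prefix; writes `<prefix>.pgx.html` and
#'   `<prefix>.pgx.json`.
#' @param template Optional HTML template override.
#' @return Named character vector of the two paths, invisibly.
#' @export
write_annotation_report <- function(x, prefix, template = NULL) {
  stopifnot(inherits(x, "pgx_annotation"))
  write_report(x$context, prefix, template)
}

#' @export
print.pgx_annotation <- function(x, ...) {
  cat("pgxdip annotation —", x$context$sample, "·", x$context$group, "\n")
  typed <- sum(!x$genotypes$calls$missing)
  cat(sprintf("  positions typed: %d / %d\n", typed, nrow(x$genotypes$calls)))
  ok <- sum(vapply(x$inference, function(r) r$status == "ok", TRUE))
  cat(sprintf("  genes called: %d / %d\n", ok, length(x$inference)))
  tab <- table(factor(x$categories, levels = c("avoid", "caution", "routine")))
  cat(sprintf("  drugs: %d avoid, %d caution, %d routine\n",
              tab[["avoid"]], tab[["caution"]], tab[["routine"]]))
  invisible(x)
}

#' @export
summary.pgx_annotation <- function(object, ...) {
  x <- object
  print(x)
  cat("\nDiplotype calls:\n")
  for (g in names(x$inference)) print(x$inference[[g]])
  if (nrow(x$sva_calls)) {
    cat("\nSingle-variant alleles:\n")
    for (i in seq_len(nrow(x$sva_calls))) {
      r <- x$sva_calls[i, ]
      cat(sprintf("  %s (%s): %s\n", r$gene, r$rsid,
                  if (r$status == "called") r$genotype else r$status))
    }
  }
  if (nrow(x$hla_calls)) {
    cat("\nHLA:", paste(sprintf("%s x%d", x$hla_calls$allele, x$hla_calls$copies),
                        collapse = ", "), "\n")
  }
  if (length(x$drug_reports)) {
    cat("\nDrugs:\n")
    for (r in x$drug_reports) { cat("  "); print(r) }
  }
  invisible(x)
}
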