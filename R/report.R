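# Self-contained HTML report (five core sections) plus a machine-readable
# JSON twin. Timestamps are injected, never read from the clock here, so
# output is byte-identical across runs.

REPORT_SECTIONS <- c("Summary", "Prescribing info", "Diplotype detail",
                     "Phenotype prediction", "Clinical annotation")

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub('"', "&quot;", x, fixed = TRUE)
}

html_table <- function(df, empty = "none") {
  if (is.null(df) || nrow(df) == 0L) return(sprintf("<p class='empty'>%s</p>", empty))
  head <- paste0("<tr>", paste0("<th>", html_escape(names(df)), "</th>", collapse = ""), "</tr>")
  body <- vapply(seq_len(nrow(df)), function(i) {
    cells <- vapply(df[i, , drop = FALSE], function(v) {
      v <- if (is.numeric(v)) format_num(v) else as.character(v)
      if (is.na(v)) "" else html_escape(v)
    }, "")
    paste0("<tr>", paste0("<td>", cells, "</td>", collapse = ""), "</tr>")
  }, "")
  paste0("<table>", head, paste(body, collapse = ""), "</table>")
}

drug_anchor <- function(drug) paste0("drug-", gsub("[^A-Za-z0-9]+", "-", tolower(drug)))

#' Assemble a report context
#'
#' Bundles every result needed to render a report. Any component may be
#' empty; the renderer degrades gracefully. The timestamp is injected so
#' that rendering is deterministic.
#'
#' @param sample Sample name.
#' @param group Biogeographic group code.
#' @param inference Named list of `pgx_ranked_call`.
#' @param sva_calls Data frame of single-variant calls.
#' @param hla_calls Data frame of HLA calls.
#' @param drug_reports Named list of `pgx_drug_report`.
#' @param matched Data frame of matched clinical annotations.
#' @param kb The `pgx_kb` used (for diplotype detail tables).
#' @param genotypes Optional `pgx_genotypes` (for called alleles per position).
#' @param timestamp Character timestamp shown in the report.
#' @param notes Optional character vector of notes.
#' @return List of class `pgx_report_context`.
#' @export
report_context <- function(sample, group, inference = list(), sva_calls = NULL,
                           hla_calls = NULL, drug_reports = list(),
                           matched = NULL, kb = NULL, genotypes = NULL,
                           timestamp = "1970-01-01T00:00:00Z", notes = character(0)) {
  check_group(group)
  structure(list(sample = sample, group = group, timestamp = timestamp,
                 version = as.character(utils::packageVersion("pgxdip")),
                 inference = inference, sva_calls = sva_calls,
                 hla_calls = hla_calls, drug_reports = drug_reports,
                 matched = matched, kb = kb, genotypes = genotypes,
                 notes = notes),
            class = "pgx_report_context")
}

#' Render the HTML report
#'
#' Produces a single self-contained HTML document with, in order, the five
#' core sections: Summary (drugs grouped avoid / caution / routine, each
#' hyperlinked to its prescribing entry), Prescribing info (per drug: gene,
#' diplotype, phenotype, source recommendations), Diplotype detail (per-gene
#' defined vs called alleles, single-variant genotypes, untested genes),
#' Phenotype prediction (per drug the four category directions) and Clinical
#' annotation (supporting records). Sample metadata heads the document.
#'
#' @param context A `pgx_report_context`.
#' @param template Optional template override: a character scalar containing
#'   `{{body}}` (and optionally `{{title}}`) placeholders.
#' @return HTML document as a single character string.
#' @export
render_report <- function(context, template = NULL) {
  stopifnot(inherits(context, "pgx_report_context"))
  ctx <- context
  cats <- vapply(ctx$drug_reports, `[[`, "", "category")

  cat_labels <- c(avoid = "Avoid use", caution = "Use with caution", routine = "Routine use")
  summary_html <- paste0(vapply(names(cat_labels), function(catg) {
    drugs <- radix_sort(names(cats)[cats == catg])
    items <- if (length(drugs)) {
      paste0("<li><a href='#", drug_anchor(drugs), "'>", html_escape(drugs), "</a></li>", collapse = "")
    } else "<li class='empty'>none</li>"
    paste0("<h3>", cat_labels[[catg]], "</h3><ul>", items, "</ul>")
  }, ""), collapse = "")

  presc_html <- if (length(ctx$drug_reports)) {
    paste0(vapply(ctx$drug_reports[radix_order(names(ctx$drug_reports))], function(r) {
      gl <- r$guidelines
      gl_tab <- if (!is.null(gl) && nrow(gl)) {
        html_table(gl[, c("source", "gene", "genotype_key", "category", "text")])
      } else "<p class='empty'>no triggered guideline records</p>"
      dirs <- vapply(r$phenotypes, `[[`, "", "direction")
      shown <- dirs[dirs != "not_predicted"]
      phen <- if (length(shown)) {
        paste(sprintf("%s: %s", names(shown), shown), collapse = "; ")
      } else "not predicted"
      paste0("<div class='drug' id='", drug_anchor(r$drug), "'><h3>", html_escape(r$drug),
             "</h3><p>Category: <b>", r$category, "</b>. Phenotype: ", html_escape(phen),
             "</p>", gl_tab, "</div>")
    }, ""), collapse = "")
  } else "<p class='empty'>no drugs triggered</p>"

  dip_html <- local({
    blocks <- character(0)
    for (g in radix_sort(names(ctx$inference))) {
      rc <- ctx$inference[[g]]
      call_str <- if (rc$status == "ok") paste(rc$top, collapse = " | ") else rc$status
      tab <- ""
      if (!is.null(ctx$kb)) {
        gt <- gene_table(ctx$kb, g)
        det <- gt$positions
        # defined alternate allele(s) at each position vs reference
        det$defined_alt <- vapply(seq_len(nrow(det)), function(i) {
          alts <- unique(gt$allele_matrix[gt$declared_matrix[, i], i])
          paste(radix_sort(alts), collapse = ",")
        }, "")
        det$called <- if (!is.null(ctx$genotypes)) {
          m <- match(det$pos_id, ctx$genotypes$calls$pos_id)
          ifelse(is.na(m) | ctx$genotypes$calls$missing[m], "missing",
                 ctx$genotypes$calls$genotype[m])
        } else ""
        tab <- html_table(det[, c("pos_id", "ref", "defined_alt", "called")])
      }
      blocks <- c(blocks, paste0("<h3>", html_escape(g), "</h3><p>Inferred diplotype: <b>",
                                 html_escape(call_str), "</b>",
                                 if (isTRUE(rc$exact_match)) " (exact match)" else "",
                                 "</p>", tab))
    }
    sva_tab <- html_table(
      if (!is.null(ctx$sva_calls)) ctx$sva_calls[, c("gene", "rsid", "genotype", "status")],
      empty = "no single-variant alleles in the knowledgebase")
    hla_tab <- html_table(ctx$hla_calls, empty = "no HLA calls provided")
    paste0(paste(blocks, collapse = ""),
           "<h3>Single-variant alleles</h3>", sva_tab,
           "<h3>HLA alleles</h3>", hla_tab)
  })

  phen_html <- if (length(ctx$drug_reports)) {
    df <- do.call(rbind, lapply(ctx$drug_reports[radix_order(names(ctx$drug_reports))], function(r) {
      dirs <- vapply(r$phenotypes, `[[`, "", "direction")
      data.frame(drug = r$drug, toxicity = dirs[["toxicity"]], dosage = dirs[["dosage"]],
                 efficacy = dirs[["efficacy"]], metabolism = dirs[["metabolism"]])
    }))
    html_table(df)
  } else "<p class='empty'>no predictions</p>"

  ann_html <- html_table(
    if (!is.null(ctx$matched) && nrow(ctx$matched)) {
      ctx$matched[, c("annotation_id", "drug", "gene", "genotype_key",
                      "evidence_level", "category", "direction")]
    } else NULL,
    empty = "no matched clinical annotations")

  meta <- paste0("<p class='meta'>Sample: <b>", html_escape(ctx$sample),
                 "</b> · Biogeographic group: <b>", html_escape(ctx$group),
                 "</b> · Reported: ", html_escape(ctx$timestamp),
                 " · pgxdip ", html_escape(ctx$version), "</p>")
  notes <- if (length(ctx$notes)) {
    paste0("<div class='notes'><h2>Notes</h2><ul>",
           paste0("<li>", html_escape(ctx$notes), "</li>", collapse = ""), "</ul></div>")
  } else ""

  bodies <- c(summary_html, presc_html, dip_html, phen_html, ann_html)
  body <- paste0(meta, paste0("<section><h2>", REPORT_SECTIONS, "</h2>",
                              bodies, "</section>", collapse = ""), notes)

  if (is.null(template)) template <- default_template()
  if (!grepl("{{body}}", template, fixed = TRUE)) {
    pgx_template_error("template is missing the required {{body}} block")
  }
  out <- sub("{{title}}", paste0("PGx report — ", html_escape(ctx$sample)), template, fixed = TRUE)
  sub("{{body}}", body, out, fixed = TRUE)
}

default_template <- function() {
  paste0("<!DOCTYPE html>\n<html><head><meta charset='utf-8'><title>{{title}}</title>",
         "<style>body{font-family:sans-serif;margin:2em;max-width:60em}",
         "table{border-collapse:collapse;margin:0.5em 0}",
         "td,th{border:1px solid #999;padding:2px 8px;text-align:left}",
         "h2{border-bottom:2px solid #333}.empty{color:#777;font-style:italic}",
         ".meta{color:#333}</style></head><body>\n{{body}}\n</body></html>\n")
}

#' Write the HTML report and its JSON twin
#'
#' Writes `<prefix>.pgx.html` and `<prefix>.pgx.json`. The JSON twin carries
#' the same content in machine-readable form so downstream pipelines need
#' not scrape HTML.
#'
#' @param context A `pgx_report_context`.
#' @param prefix Output path prefix.
#' @param template Optional HTML template override.
#' @return Named character vector of the two paths, invisibly.
#' @export
write_report <- function(context, prefix, template = NULL) {
  html <- render_report(context, template)
  html_path <- paste0(prefix, ".pgx.html")
  json_path <- paste0(prefix, ".pgx.json")
  writeLines(html, html_path, sep = "")
  jsonlite::write_json(report_json(context), json_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(c(html = html_path, json = json_path))
}

report_json <- function(ctx) {
  list(
    sample = ctx$sample,
    biogeographic_group = ctx$group,
    timestamp = ctx$timestamp,
    tool = list(name = "pgxdip", version = ctx$version),
    diplotypes = lapply(ctx$inference, function(rc) list(
      gene = rc$gene, status = rc$status, diplotypes = as.list(rc$top),
      penalty = if (is.na(rc$best_penalty)) NULL else rc$best_penalty,
      frequency = if (is.na(rc$top_frequency)) NULL else rc$top_frequency,
      exact_match = rc$exact_match, candidates = rc$candidates_total)),
    single_variant_alleles = df_to_rows(ctx$sva_calls),
    hla = df_to_rows(ctx$hla_calls),
    drugs = lapply(ctx$drug_reports, function(r) list(
      drug = r$drug, category = r$category,
      phenotypes = lapply(r$phenotypes, function(ph) list(
        direction = ph$direction,
        mean_score = if (is.na(ph$mean_score)) NULL else ph$mean_score,
        annotation_ids = as.list(ph$records$annotation_id))))),
    clinical_annotations = df_to_rows(ctx$matched),
    notes = as.list(ctx$notes)
  )
}

df_to_rows <- function(df) {
  if (is.null(df) || nrow(df) == 0L) return(list())
  lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
}
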