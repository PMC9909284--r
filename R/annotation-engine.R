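# Guideline-based drug classification (avoid / caution / routine) and
# integration of evidence-graded clinical annotations into predicted
# drug-response phenotypes per category (toxicity, dosage, efficacy,
# metabolism).

#' Assemble the set of (gene, genotype key) calls for annotation matching
#'
#' Keys are: the canonical diplotype labels of each gene's top call(s)
#' (multi-variant genes, status `"ok"` only), the observed genotype string of
#' each measured single-variant allele, and the allele name of each present
#' HLA call (gene looked up in the HLA registry).
#'
#' @param inference Named list of `pgx_ranked_call` (see [infer_all()]).
#' @param sva_calls Data frame from [call_single_variant_alleles()].
#' @param hla_calls Data frame from [extract_hla_calls()].
#' @param kb A `pgx_kb` (for the HLA registry).
#' @return Data frame with columns `gene`, `key`.
#' @export
call_keys <- function(inference = list(), sva_calls = NULL, hla_calls = NULL, kb = NULL) {
  out <- data.frame(gene = character(0), key = character(0))
  for (rc in inference) {
    if (rc$status == "ok" && length(rc$top)) {
      out <- rbind(out, data.frame(gene = rc$gene, key = rc$top))
    }
  }
  if (!is.null(sva_calls) && nrow(sva_calls)) {
    called <- sva_calls[sva_calls$status == "called", , drop = FALSE]
    if (nrow(called)) out <- rbind(out, data.frame(gene = called$gene, key = called$genotype))
  }
  if (!is.null(hla_calls) && nrow(hla_calls)) {
    gene <- if (!is.null(kb)) kb$hla$gene[match(hla_calls$allele, kb$hla$allele)] else NA_character_
    gene[is.na(gene)] <- sub("\\*.*$", "", hla_calls$allele[is.na(gene)])
    out <- rbind(out, data.frame(gene = gene, key = hla_calls$allele))
  }
  unique(out)
}

#' Classify drugs into prescribing categories
#'
#' A guideline record is *triggered* when its (gene, genotype_key) matches a
#' call. Per drug, the most conservative triggered category wins: any
#' triggered avoid record makes the drug "avoid"; otherwise any triggered
#' caution record — or any triggered record flagged population-dependent or
#' multi-gene — makes it "caution"; otherwise "routine". Drugs with no
#' triggered record are omitted.
#'
#' @param calls Data frame of (gene, key) calls (see [call_keys()]).
#' @param guidelines Guideline data frame (see [load_guidelines()]).
#' @return Named character vector drug -> category, in canonical drug order.
#' @export
classify_drugs <- function(calls, guidelines) {
  if (nrow(calls) == 0L || nrow(guidelines) == 0L) return(stats::setNames(character(0), character(0)))
  hit <- paste(guidelines$gene, guidelines$genotype_key) %in% paste(calls$gene, calls$key)
  trig <- guidelines[hit, , drop = FALSE]
  if (nrow(trig) == 0L) return(stats::setNames(character(0), character(0)))
  eff <- ifelse(trig$category == "avoid", "avoid",
         ifelse(trig$category == "caution" | trig$population_dependent | trig$multi_gene,
                "caution", "routine"))
  rank <- c(avoid = 3L, caution = 2L, routine = 1L)
  per_drug <- tapply(rank[eff], trig$drug, max)
  out <- names(rank)[match(as.integer(per_drug), rank)]
  names(out) <- names(per_drug)
  out[radix_order(names(out))]
}

#' Numeric coding of an annotation's direction
#'
#' Drug-response directions are coded 0.5 (decreased), 1 (normal) and
#' 2 (increased) so that multiple annotations for one drug can be averaged.
#'
#' @param direction One of `"decreased"`, `"normal"`, `"increased"`
#'   (vectorised).
#' @return Numeric score(s).
#' @export
code_annotation <- function(direction) {
  codes <- c(decreased = 0.5, normal = 1, increased = 2)
  if (any(!direction %in% names(codes))) {
    pgx_usage_error(sprintf("inadmissible direction token: %s",
                            direction[!direction %in% names(codes)][1L]))
  }
  unname(codes[direction])
}

#' Match clinical annotations to the sample's calls
#'
#' An annotation matches when its genotype_key equals a called diplotype of
#' its gene or the observed genotype at a single position. All records for
#' avoid-use drugs are excluded (those drugs receive no phenotype
#' prediction), as are records for drugs absent from the guideline
#' classification.
#'
#' @param calls Data frame of (gene, key) calls.
#' @param annotations Annotation data frame (see [load_clinical_annotations()]).
#' @param categories Named vector drug -> category (see [classify_drugs()]).
#' @return Data frame of matched records with a numeric `score` column.
#' @export
match_annotations <- function(calls, annotations, categories) {
  hit <- paste(annotations$gene, annotations$genotype_key) %in% paste(calls$gene, calls$key)
  m <- annotations[hit, , drop = FALSE]
  m <- m[m$drug %in% names(categories), , drop = FALSE]
  m <- m[categories[m$drug] != "avoid", , drop = FALSE]
  m <- m[radix_order(m$drug, m$category, m$annotation_id), , drop = FALSE]
  if (nrow(m)) m$score <- code_annotation(m$direction) else m$score <- numeric(0)
  rownames(m) <- NULL
  m
}

#' Integrate matched annotations into per-drug phenotype predictions
#'
#' Per drug and phenotype category, the mean of the coded scores of all
#' matched annotations is mapped to a direction: below 1 is decreased, equal
#' to 1 (within 1e-9) is normal, above 1 is increased. Categories with no
#' matched record are `not_predicted`. Avoid-use drugs carry no prediction
#' in any category.
#'
#' @param matched Data frame from [match_annotations()].
#' @param categories Named vector drug -> category (see [classify_drugs()]).
#' @param guidelines Optional guideline data frame; triggered records are
#'   attached to each report.
#' @param calls Optional calls data frame (to subset triggered guidelines).
#' @return Named list of `pgx_drug_report` objects, one per classified drug.
#' @export
integrate_phenotypes <- function(matched, categories, guidelines = NULL, calls = NULL) {
  reports <- lapply(radix_sort(names(categories)), function(drug) {
    cat_ <- unname(categories[[drug]])
    trig <- NULL
    if (!is.null(guidelines) && !is.null(calls)) {
      hit <- guidelines$drug == drug &
        paste(guidelines$gene, guidelines$genotype_key) %in% paste(calls$gene, calls$key)
      trig <- guidelines[hit, , drop = FALSE]
    }
    phen <- lapply(ANNOTATION_CATEGORIES, function(pc) {
      if (cat_ == "avoid") {
        return(list(direction = "not_predicted", mean_score = NA_real_, records = matched[0, ]))
      }
      rec <- matched[matched$drug == drug & matched$category == pc, , drop = FALSE]
      if (nrow(rec) == 0L) {
        return(list(direction = "not_predicted", mean_score = NA_real_, records = rec))
      }
      mu <- mean(rec$score)
      dir <- if (abs(mu - 1) <= 1e-9) "normal" else if (mu < 1) "decreased" else "increased"
      list(direction = dir, mean_score = mu, records = rec)
    })
    names(phen) <- ANNOTATION_CATEGORIES
    structure(list(drug = drug, category = cat_, guidelines = trig, phenotypes = phen),
              class = "pgx_drug_report")
  })
  stats::setNames(reports, radix_sort(names(categories)))
}

#' @export
print.pgx_drug_report <- function(x, ...) {
  cat(sprintf("%s [%s]", x$drug, x$category))
  dirs <- vapply(x$phenotypes, `[[`, "", "direction")
  shown <- dirs[dirs != "not_predicted"]
  if (length(shown)) {
    cat(" —", paste(sprintf("%s: %s", names(shown), shown), collapse = ", "))
  }
  cat("\n")
  invisible(x)
}

#' Export per-drug annotation results as a table
#'
#' @param reports Named list of `pgx_drug_report`.
#' @param path Optional output TSV path.
#' @return Data frame with one row per drug: category, four phenotype
#'   directions, mean scores and supporting annotation ids.
#' @export
drug_report_table <- function(reports, path = NULL) {
  rows <- lapply(reports, function(r) {
    out <- data.frame(drug = r$drug, category = r$category)
    for (pc in ANNOTATION_CATEGORIES) {
      ph <- r$phenotypes[[pc]]
      out[[pc]] <- ph$direction
      out[[paste0(pc, "_mean")]] <- ph$mean_score
      out[[paste0(pc, "_records")]] <- paste(ph$records$annotation_id, collapse = ",")
    }
    out
  })
  df <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (!is.null(path)) utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  df
}
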