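# filterreport: diagnostic variant filtering, classification with
# persistence and cross-patient recurrence, family/group analysis, and
# report generation.

VALID_CATEGORIES <- c("pathogenic", "likely_pathogenic",
                      "uncertain_significance", "likely_benign", "benign",
                      "artefact", "false_reference")

#' Diagnostic variant filter specification
#'
#' Unset bounds pass. A missing population frequency is treated as 0, so
#' novel variants pass a maximum-frequency gate (novel variants are the
#' diagnostic interest).
#'
#' @param min_vaf,max_vaf variant-allele-frequency bounds.
#' @param min_depth minimum depth.
#' @param min_strand_balance minimum `min(fwd, rev) / alt_count`.
#' @param min_quality minimum mean alt base quality.
#' @param max_population_frequency maximum known population frequency.
#' @param consequence_whitelist consequence terms to keep (compared to the
#'   worst-overall term).
#' @param gene_whitelist gene symbols to keep.
#' @param phenotype_terms keep variants whose gene phenotype terms
#'   intersect this set.
#' @param exclude_artefacts drop variants flagged by the store as artefact
#'   or false_reference (see [recurrence_lookup()]).
#' @return object of class `variant_filter_spec`.
#' @export
variant_filter_spec <- function(min_vaf = NULL, max_vaf = NULL,
                                min_depth = NULL, min_strand_balance = NULL,
                                min_quality = NULL,
                                max_population_frequency = NULL,
                                consequence_whitelist = NULL,
                                gene_whitelist = NULL,
                                phenotype_terms = NULL,
                                exclude_artefacts = FALSE) {
  chk01 <- function(x, nm) {
    if (!is.null(x) && (x < 0 || x > 1)) stop(nm, " must lie in [0, 1]")
  }
  chk01(min_vaf, "min_vaf"); chk01(max_vaf, "max_vaf")
  chk01(min_strand_balance, "min_strand_balance")
  chk01(max_population_frequency, "max_population_frequency")
  if (!is.null(consequence_whitelist)) {
    bad <- setdiff(consequence_whitelist, CONSEQUENCE_SEVERITY)
    if (length(bad)) stop("unknown consequence term: ", bad[1])
  }
  structure(list(min_vaf = min_vaf, max_vaf = max_vaf,
                 min_depth = min_depth,
                 min_strand_balance = min_strand_balance,
                 min_quality = min_quality,
                 max_population_frequency = max_population_frequency,
                 consequence_whitelist = consequence_whitelist,
                 gene_whitelist = gene_whitelist,
                 phenotype_terms = phenotype_terms,
                 exclude_artefacts = isTRUE(exclude_artefacts)),
            class = "variant_filter_spec")
}

#' Apply diagnostic filters to annotated variants
#'
#' A variant is kept iff it passes every set bound. Rejections are
#' attributed to the first failing rule in a fixed order (min_depth,
#' min_vaf, max_vaf, min_strand_balance, min_quality,
#' max_population_frequency, consequence, gene, phenotype, artefact) so
#' summaries are reproducible.
#'
#' @param variants annotated variant data.frame.
#' @param spec a [variant_filter_spec()].
#' @return list with `kept` (data.frame) and `rejected` (named counts).
#' @export
apply_filters <- function(variants, spec) {
  n <- nrow(variants)
  reason <- rep(NA_character_, n)
  col <- function(nm) if (nm %in% names(variants)) variants[[nm]] else
    rep(NA, n)
  fail <- function(reason, bad, nm) {
    ifelse(is.na(reason) & bad, nm, reason)
  }
  if (!is.null(spec$min_depth)) {
    reason <- fail(reason, col("depth") < spec$min_depth, "min_depth")
  }
  if (!is.null(spec$min_vaf)) {
    reason <- fail(reason, col("vaf") < spec$min_vaf, "min_vaf")
  }
  if (!is.null(spec$max_vaf)) {
    reason <- fail(reason, col("vaf") > spec$max_vaf, "max_vaf")
  }
  if (!is.null(spec$min_strand_balance)) {
    sb <- pmin(col("fwd"), col("rev")) / col("alt_count")
    reason <- fail(reason, sb < spec$min_strand_balance,
                   "min_strand_balance")
  }
  if (!is.null(spec$min_quality)) {
    reason <- fail(reason, col("mean_alt_quality") < spec$min_quality,
                   "min_quality")
  }
  if (!is.null(spec$max_population_frequency)) {
    pf <- col("population_frequency")
    pf[is.na(pf)] <- 0  # novel variants pass
    reason <- fail(reason, pf > spec$max_population_frequency,
                   "max_population_frequency")
  }
  if (!is.null(spec$consequence_whitelist)) {
    reason <- fail(reason,
                   !col("worst_consequence") %in% spec$consequence_whitelist,
                   "consequence")
  }
  if (!is.null(spec$gene_whitelist)) {
    hit <- vapply(strsplit(as.character(col("genes")), ",", fixed = TRUE),
                  function(g) any(g %in% spec$gene_whitelist), logical(1))
    reason <- fail(reason, !hit, "gene")
  }
  if (!is.null(spec$phenotype_terms)) {
    hit <- vapply(strsplit(as.character(col("phenotype_terms")), ",",
                           fixed = TRUE),
                  function(t) any(t %in% spec$phenotype_terms), logical(1))
    reason <- fail(reason, !hit, "phenotype")
  }
  if (spec$exclude_artefacts) {
    flagged <- col("artefact_flagged")
    flagged[is.na(flagged)] <- FALSE
    reason <- fail(reason, as.logical(flagged), "artefact")
  }
  kept <- variants[is.na(reason), , drop = FALSE]
  rownames(kept) <- NULL
  rej <- reason[!is.na(reason)]
  counts <- if (length(rej)) {
    t <- table(rej)
    setNames(as.integer(t), names(t))
  } else setNames(integer(0), character(0))
  list(kept = kept, rejected = counts)
}

#' Open (or create) a persistent variant classification store
#'
#' The store is an append-only tab-separated journal keyed by
#' (contig, pos, ref, alt); classifications accumulate across patients and
#' projects and survive process restarts.
#'
#' @param path journal file.
#' @return object of class `variant_store`.
#' @export
variant_store <- function(path) {
  if (!file.exists(path)) {
    writeLines(paste("contig", "pos", "ref", "alt", "category",
                     "patient_id", "project_id", "timestamp", "comment",
                     sep = "\t"), path)
  }
  structure(list(path = path), class = "variant_store")
}

#' Record a manual variant classification
#'
#' Categories follow the five ACMG tiers plus the bookkeeping categories
#' `artefact` and `false_reference` used to flag recurrent sequencing
#' errors of a particular setup.
#'
#' @param store a [variant_store()].
#' @param variant list/row with contig, pos, ref, alt.
#' @param category one of pathogenic, likely_pathogenic,
#'   uncertain_significance, likely_benign, benign, artefact,
#'   false_reference.
#' @param patient_id,project_id provenance labels.
#' @param comment free text (tabs/newlines replaced by spaces).
#' @return the store, invisibly.
#' @export
classify <- function(store, variant, category, patient_id,
                     project_id = "default", comment = "") {
  if (!category %in% VALID_CATEGORIES) {
    stop("invalid category: ", category, " (valid: ",
         paste(VALID_CATEGORIES, collapse = ", "), ")")
  }
  comment <- gsub("[\t\n\r]", " ", comment)
  line <- paste(variant$contig, variant$pos, variant$ref, variant$alt,
                category, patient_id, project_id,
                format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), comment,
                sep = "\t")
  cat(line, "\n", sep = "", file = store$path, append = TRUE)
  invisible(store)
}

#' Read all classifications from a store
#' @param store a [variant_store()].
#' @return data.frame of classifications in journal order.
#' @export
store_classifications <- function(store) {
  read.table(store$path, header = TRUE, sep = "\t",
             stringsAsFactors = FALSE, quote = "",
             colClasses = c(pos = "integer", ref = "character",
                            alt = "character", contig = "character",
                            comment = "character"))
}

#' Look up prior classifications of variants
#'
#' Exact (contig, pos, ref, alt) key lookup. Variants previously
#' classified artefact or false_reference gain the machine-readable
#' `artefact_flagged` column usable by [apply_filters()].
#'
#' @param store a [variant_store()].
#' @param variants variant data.frame.
#' @return list with `variants` (input plus n_prior and artefact_flagged
#'   columns) and `prior` (per-variant list of classification rows).
#' @export
recurrence_lookup <- function(store, variants) {
  cls <- store_classifications(store)
  skey <- paste(cls$contig, cls$pos, cls$ref, cls$alt)
  vkey <- paste(variants$contig, variants$pos, variants$ref, variants$alt)
  prior <- lapply(vkey, function(k) {
    cls[skey == k, , drop = FALSE]
  })
  variants$n_prior <- vapply(prior, nrow, integer(1))
  variants$artefact_flagged <- vapply(prior, function(p) {
    any(p$category %in% c("artefact", "false_reference"))
  }, logical(1))
  list(variants = variants, prior = prior)
}

#' Family/group variant filtering
#'
#' Keeps variants (by (contig, pos, ref, alt) key) present in every
#' `include` patient and absent from every `exclude` patient.
#'
#' @param variant_sets named list patient -> variant data.frame.
#' @param include patient ids that must all carry the variant.
#' @param exclude patient ids that must not carry it.
#' @return the kept variants (rows taken from the first include patient).
#' @export
group_filter <- function(variant_sets, include, exclude = character(0)) {
  if (length(include) == 0) stop("include set must be non-empty")
  if (length(intersect(include, exclude))) {
    stop("include and exclude sets must be disjoint")
  }
  unknown <- setdiff(c(include, exclude), names(variant_sets))
  if (length(unknown)) stop("unknown patient id: ", unknown[1])
  keyof <- function(df) paste(df$contig, df$pos, df$ref, df$alt)
  keys <- keyof(variant_sets[[include[1]]])
  for (p in include[-1]) keys <- intersect(keys, keyof(variant_sets[[p]]))
  for (p in exclude) keys <- setdiff(keys, keyof(variant_sets[[p]]))
  first <- variant_sets[[include[1]]]
  out <- first[keyof(first) %in% keys, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Generate the final diagnostic report
#'
#' Contains the patient metadata, the alignment/coverage QC section (with
#' regions below the reporting depth listed explicitly, so negative
#' findings are justified), the filtered variant table with annotations,
#' and the filter settings used. The JSON schema is stable and versioned;
#' a zero-variant report is still emitted with its coverage table.
#'
#' @param patient list with at least `id`; optionally name and
#'   phenotype_terms.
#' @param kept_variants variant data.frame after filtering.
#' @param stats `align_stats`.
#' @param coverages data.frame from [region_coverage()].
#' @param path output file.
#' @param format "json" or "html".
#' @param filter_spec the [variant_filter_spec()] used (recorded in the
#'   report).
#' @param report_min_depth regions whose minimum depth falls below this are
#'   listed as insufficiently covered.
#' @return `path`, invisibly.
#' @export
generate_report <- function(patient, kept_variants, stats, coverages, path,
                            format = c("json", "html"), filter_spec = NULL,
                            report_min_depth = 20L) {
  format <- match.arg(format)
  low <- coverages[!is.na(coverages$min_depth) &
                     coverages$min_depth < report_min_depth, , drop = FALSE]
  payload <- list(
    schema_version = "1.0",
    patient = patient,
    filter_settings = if (is.null(filter_spec)) NULL
                      else Filter(Negate(is.null), unclass(filter_spec)),
    qc = list(alignment = list(total = stats$total, mapped = stats$mapped,
                               unmapped = stats$unmapped,
                               proper_pairs = stats$proper_pairs,
                               per_contig = as.list(stats$per_contig)),
              coverage = coverages,
              low_coverage_regions = low,
              report_min_depth = report_min_depth),
    variants = kept_variants)
  if (format == "json") {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  } else {
    writeLines(html_report_page(
      paste("Diagnostic variant report:", patient$id %||% "unknown"), c(
        "<h2>Patient</h2>",
        html_table(as.data.frame(lapply(patient, function(x)
          paste(x, collapse = ", ")), stringsAsFactors = FALSE)),
        "<h2>Alignment QC</h2>",
        sprintf("<p>mapped: %d; unmapped: %d; proper pairs: %d</p>",
                stats$mapped, stats$unmapped, stats$proper_pairs),
        "<h2>Coverage of regions of interest</h2>",
        html_table(coverages),
        sprintf("<h2>Regions below %dx</h2>", report_min_depth),
        html_table(low),
        "<h2>Variants</h2>",
        html_table(kept_variants))), path)
  }
  invisible(path)
}
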