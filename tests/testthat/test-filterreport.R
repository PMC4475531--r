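# Diagnostic filters, classification store, recurrence, group analysis,
# report generation.

five_variant_fixture <- function() {
  data.frame(
    contig = "chr1", pos = c(100L, 200L, 300L, 400L, 500L),
    ref = "A", alt = "G",
    depth = c(10L, 25L, 30L, 8L, 50L),
    vaf = c(0.5, 0.4, 0.45, 0.9, 0.05),
    fwd = c(3L, 5L, 7L, 4L, 2L), rev = c(2L, 5L, 7L, 3L, 1L),
    alt_count = c(5L, 10L, 14L, 7L, 3L),
    mean_alt_quality = c(30, 35, 28, 33, 20),
    worst_consequence = c("missense", "synonymous", "missense",
                          "stop_gained", "intronic"),
    genes = c("GENE1", "GENE1", "GENE2", "GENE3", ""),
    population_frequency = c(NA, 0.12, NA, 0.001, NA),
    phenotype_terms = c("hearing loss", "", "hearing loss,deafness", "",
                        ""),
    stringsAsFactors = FALSE)
}

test_that("filters keep exactly the variants passing every set bound", {
  v <- five_variant_fixture()
  # depths 10,25,30,8,50; only the depth-30 missense passes both gates
  res <- apply_filters(v, variant_filter_spec(
    min_depth = 20, consequence_whitelist = "missense"))
  expect_equal(res$kept$pos, 300L)
  expect_equal(nrow(res$kept) + sum(res$rejected), nrow(v))

  res2 <- apply_filters(v, variant_filter_spec(
    min_depth = 20, consequence_whitelist = c("missense", "synonymous")))
  expect_equal(res2$kept$pos, c(200L, 300L))

  # empty spec is the identity
  res0 <- apply_filters(v, variant_filter_spec())
  expect_equal(res0$kept, v)
  expect_length(res0$rejected, 0)

  # missing population frequency passes a max-frequency gate
  resf <- apply_filters(v, variant_filter_spec(
    max_population_frequency = 0.01))
  expect_true(all(c(100L, 300L, 400L, 500L) %in% resf$kept$pos))
  expect_false(200L %in% resf$kept$pos)
})

test_that("rejections are attributed to the first failing rule", {
  v <- five_variant_fixture()
  res <- apply_filters(v, variant_filter_spec(
    min_depth = 20, min_vaf = 0.3, consequence_whitelist = "missense"))
  # pos 100/400 fail depth first; pos 500 fails vaf before the
  # consequence rule; pos 200 reaches the consequence rule
  expect_equal(sum(res$rejected), 4L)
  expect_equal(unname(res$rejected["min_depth"]), 2L)
  expect_equal(unname(res$rejected["min_vaf"]), 1L)
  expect_equal(unname(res$rejected["consequence"]), 1L)
  expect_equal(res$kept$pos, 300L)
})

test_that("filters agree with a brute-force oracle on random variants", {
  set.seed(51)
  for (trial in 1:10) {
    n <- 40
    v <- data.frame(
      contig = "c", pos = seq_len(n), ref = "A", alt = "G",
      depth = sample(1:60, n, TRUE), vaf = runif(n),
      fwd = sample(0:20, n, TRUE), rev = sample(0:20, n, TRUE),
      mean_alt_quality = runif(n, 5, 40),
      worst_consequence = sample(CONSEQUENCE_SEVERITY, n, TRUE),
      genes = sample(c("G1", "G2", "G3"), n, TRUE),
      population_frequency = ifelse(runif(n) < 0.4, NA, runif(n)),
      phenotype_terms = sample(c("", "t1", "t1,t2", "t3"), n, TRUE),
      stringsAsFactors = FALSE)
    v$alt_count <- v$fwd + v$rev
    spec <- variant_filter_spec(
      min_depth = sample(c(list(NULL), as.list(5:40)), 1)[[1]],
      min_vaf = sample(c(list(NULL), as.list(c(0.1, 0.4))), 1)[[1]],
      max_vaf = sample(c(list(NULL), as.list(c(0.6, 0.95))), 1)[[1]],
      min_quality = sample(c(list(NULL), as.list(c(10, 25))), 1)[[1]],
      max_population_frequency =
        sample(c(list(NULL), as.list(c(0.05, 0.5))), 1)[[1]],
      consequence_whitelist = if (runif(1) < 0.5) NULL
        else sample(CONSEQUENCE_SEVERITY, 5),
      gene_whitelist = if (runif(1) < 0.5) NULL else c("G1", "G3"),
      phenotype_terms = if (runif(1) < 0.5) NULL else "t1")
    res <- apply_filters(v, spec)
    pf <- ifelse(is.na(v$population_frequency), 0,
                 v$population_frequency)
    ok <- rep(TRUE, n)
    if (!is.null(spec$min_depth)) ok <- ok & v$depth >= spec$min_depth
    if (!is.null(spec$min_vaf)) ok <- ok & v$vaf >= spec$min_vaf
    if (!is.null(spec$max_vaf)) ok <- ok & v$vaf <= spec$max_vaf
    if (!is.null(spec$min_quality)) {
      ok <- ok & v$mean_alt_quality >= spec$min_quality
    }
    if (!is.null(spec$max_population_frequency)) {
      ok <- ok & pf <= spec$max_population_frequency
    }
    if (!is.null(spec$consequence_whitelist)) {
      ok <- ok & v$worst_consequence %in% spec$consequence_whitelist
    }
    if (!is.null(spec$gene_whitelist)) {
      ok <- ok & v$genes %in% spec$gene_whitelist
    }
    if (!is.null(spec$phenotype_terms)) {
      ok <- ok & vapply(strsplit(v$phenotype_terms, ","), function(t)
        any(t %in% spec$phenotype_terms), logical(1))
    }
    expect_equal(res$kept$pos, v$pos[ok])
    expect_equal(nrow(res$kept) + sum(res$rejected), n)
  }
})

test_that("tightening any bound never increases the kept count", {
  v <- five_variant_fixture()
  k <- function(...) nrow(apply_filters(v, variant_filter_spec(...))$kept)
  expect_true(k(min_depth = 30) <= k(min_depth = 10))
  expect_true(k(min_vaf = 0.45) <= k(min_vaf = 0.05))
  expect_true(k(max_population_frequency = 0.0001) <=
                k(max_population_frequency = 0.2))
})

test_that("the classification store persists and accumulates append-only", {
  path <- tempfile(fileext = ".tsv")
  store <- variant_store(path)
  v <- list(contig = "chr1", pos = 100L, ref = "A", alt = "G")
  classify(store, v, "pathogenic", patient_id = "P1", project_id = "prj1")
  classify(store, v, "artefact", patient_id = "P2", project_id = "prj2",
           comment = "recurrent\tnoise")
  # reopen from disk
  store2 <- variant_store(path)
  cls <- store_classifications(store2)
  expect_equal(nrow(cls), 2)
  expect_equal(cls$category, c("pathogenic", "artefact"))
  expect_equal(cls$patient_id, c("P1", "P2"))
  expect_false(any(grepl("\t", cls$comment)))

  expect_error(classify(store, v, "bogus", "P1"), "invalid category")
})

test_that("persistence round-trips 100 random classifications", {
  set.seed(52)
  path <- tempfile(fileext = ".tsv")
  store <- variant_store(path)
  cats <- character(100)
  for (i in 1:100) {
    cats[i] <- sample(diagseq:::VALID_CATEGORIES, 1)
    classify(store,
             list(contig = sample(c("chr1", "chr2"), 1),
                  pos = sample(1:500, 1), ref = "A",
                  alt = sample(c("C", "G", "T"), 1)),
             cats[i], patient_id = sprintf("P%02d", sample(1:10, 1)))
  }
  cls <- store_classifications(variant_store(path))
  expect_equal(nrow(cls), 100)
  expect_equal(cls$category, cats)  # journal order preserved
})

test_that("recurrence lookup flags artefacts usable by the filters", {
  path <- tempfile(fileext = ".tsv")
  store <- variant_store(path)
  v1 <- list(contig = "chr1", pos = 10L, ref = "A", alt = "G")
  v2 <- list(contig = "chr1", pos = 20L, ref = "C", alt = "T")
  classify(store, v1, "artefact", "P1")
  classify(store, v1, "artefact", "P2")
  variants <- data.frame(contig = "chr1", pos = c(10L, 20L, 30L),
                         ref = c("A", "C", "G"), alt = c("G", "T", "A"),
                         stringsAsFactors = FALSE)
  rl <- recurrence_lookup(store, variants)
  expect_equal(rl$variants$n_prior, c(2L, 0L, 0L))
  expect_equal(rl$variants$artefact_flagged, c(TRUE, FALSE, FALSE))
  expect_equal(nrow(rl$prior[[1]]), 2)
  expect_equal(nrow(rl$prior[[2]]), 0)

  res <- apply_filters(rl$variants,
                       variant_filter_spec(exclude_artefacts = TRUE))
  expect_equal(res$kept$pos, c(20L, 30L))
  expect_equal(unname(res$rejected["artefact"]), 1L)
})

test_that("group filtering equals brute-force set algebra", {
  mk <- function(keys) {
    data.frame(contig = "c", pos = keys, ref = "A", alt = "G",
               stringsAsFactors = FALSE)
  }
  sets <- list(affected1 = mk(c(1, 2, 3, 5)), affected2 = mk(c(2, 3, 4)),
               parent = mk(c(3, 6)))
  got <- group_filter(sets, include = c("affected1", "affected2"),
                      exclude = "parent")
  expect_equal(got$pos, 2)

  single <- group_filter(sets, include = "affected1")
  expect_equal(single$pos, c(1, 2, 3, 5))

  expect_error(group_filter(sets, include = character(0)), "non-empty")
  expect_error(group_filter(sets, include = "affected1",
                            exclude = "affected1"), "disjoint")
  expect_error(group_filter(sets, include = "nobody"), "unknown patient")

  set.seed(53)
  for (trial in 1:20) {
    pts <- paste0("p", 1:4)
    sets <- setNames(lapply(pts, function(p)
      mk(sort(sample(1:30, sample(5:20, 1))))), pts)
    inc <- sample(pts, sample(1:3, 1))
    exc <- setdiff(sample(pts, sample(0:2, 1)), inc)
    got <- group_filter(sets, inc, exc)
    keys <- Reduce(intersect, lapply(sets[inc], function(s) s$pos))
    for (p in exc) keys <- setdiff(keys, sets[[p]]$pos)
    expect_equal(sort(got$pos), sort(keys))
  }
})

test_that("reports round-trip through JSON and list low-coverage regions", {
  v <- five_variant_fixture()
  stats <- structure(list(total = 120L, mapped = 100L, unmapped = 20L,
                          proper_pairs = 90L,
                          per_contig = c(chr1 = 100L)),
                     class = "align_stats")
  cov <- data.frame(contig = "chr1", start = c(0L, 1000L),
                    end = c(500L, 1500L), label = c("ROI1", "ROI2"),
                    mean_depth = c(45.2, 8.1), min_depth = c(30L, 2L),
                    pct_ge_20 = c(1, 0.1), error = NA_character_,
                    stringsAsFactors = FALSE)
  patient <- list(id = "P01", name = "case 1",
                  phenotype_terms = c("hearing loss"))
  js <- tempfile(fileext = ".json")
  generate_report(patient, v, stats, cov, js, "json",
                  filter_spec = variant_filter_spec(min_depth = 20))
  back <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(back$schema_version, "1.0")
  expect_equal(back$patient$id, "P01")
  expect_equal(nrow(back$variants), nrow(v))
  expect_equal(back$qc$alignment$mapped, 100)
  expect_equal(back$qc$low_coverage_regions$label, "ROI2")
  expect_equal(back$filter_settings$min_depth, 20)

  # zero kept variants still yields a report with the coverage table
  js0 <- tempfile(fileext = ".json")
  generate_report(patient, v[0, ], stats, cov, js0, "json")
  back0 <- jsonlite::read_json(js0, simplifyVector = TRUE)
  expect_equal(length(back0$variants), 0)
  expect_equal(nrow(back0$qc$coverage), 2)

  # html variant table has one row per kept variant
  ht <- tempfile(fileext = ".html")
  generate_report(patient, v, stats, cov, ht, "html")
  html <- paste(readLines(ht), collapse = "\n")
  # patient (1) + coverage (2) + low-coverage (1) + variants (5) data rows
  expect_equal(lengths(regmatches(html, gregexpr("<tr><td>", html))),
               1L + 2L + 1L + nrow(v))
})
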