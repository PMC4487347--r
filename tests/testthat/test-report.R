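scored_fixture <- function() {
  focus <- leukemia_focus()
  e <- dplyr::bind_rows(
    # damaging on both predictors, unreported frequency, focus-matching
    make_enriched(
      pos = 10L, sift = 0.02, polyphen = 0.99, pubmed = 9L,
      cosmic = 150L, protein_length = 500L,
      diseases = "Leukemia associated disorder", terms = "Apoptosis",
      is_census = TRUE, gene = "DRV1"
    ),
    # SIFT present but tolerated
    make_enriched(
      pos = 20L, sift = 0.20, polyphen = 0.99,
      diseases = "Leukemia associated disorder", terms = "Apoptosis",
      gene = "TOL1"
    ),
    # damaging but common
    make_enriched(
      pos = 30L, sift = 0.01, polyphen = 0.95, gmaf = 0.2,
      terms = "Apoptosis", gene = "COM1", interacts_census = TRUE
    ),
    # no predictor at all
    make_enriched(pos = 40L, terms = "Apoptosis", gene = "NOP1"),
    # damaging but no focus process term
    make_enriched(
      pos = 50L, sift = 0.01, polyphen = 0.95, terms = "Axon guidance",
      gene = "OFF1"
    )
  )
  rank_variants(score_variants(e, focus))
}

test_that("the default thresholds keep damaging focus variants only", {
  s <- scored_fixture()
  out <- result_table(s, leukemia_focus(), filter_thresholds())
  expect_setequal(out$gene_symbol, c("DRV1", "COM1"))
  # gmaf = 1 is a no-op: the common variant survives the frequency test
  expect_true("COM1" %in% out$gene_symbol)
  # ranks preserved in order
  expect_false(is.unsorted(out$rank))
})

test_that("each threshold bites on its own channel", {
  s <- scored_fixture()
  focus <- leukemia_focus()
  keep <- function(t) result_table(s, focus, t)$gene_symbol

  expect_false("COM1" %in% keep(filter_thresholds(gmaf = 0.01)))
  expect_true("DRV1" %in% keep(filter_thresholds(gmaf = 0.01)))
  expect_equal(keep(filter_thresholds(pubmed = 1L)), "DRV1")
  expect_equal(keep(filter_thresholds(cosmic = 1L)), "DRV1")
  expect_equal(keep(filter_thresholds(disassociation = 1L)), "DRV1")
})

test_that("damage mode 'any' admits one passing predictor", {
  s <- scored_fixture()
  focus <- leukemia_focus()
  all_mode <- result_table(s, focus, filter_thresholds())
  any_mode <- result_table(s, focus, filter_thresholds(),
    damage_mode = "any"
  )
  # TOL1 fails all-mode (SIFT present and tolerated) but its PolyPhen passes
  expect_false("TOL1" %in% all_mode$gene_symbol)
  expect_true("TOL1" %in% any_mode$gene_symbol)
  expect_true(all(all_mode$gene_symbol %in% any_mode$gene_symbol))
})

test_that("census modes 1 and 2 partition mode 3", {
  s <- scored_fixture()
  focus <- leukemia_focus()
  k1 <- result_table(s, focus, filter_thresholds(census = 1L))$gene_symbol
  k2 <- result_table(s, focus, filter_thresholds(census = 2L))$gene_symbol
  k3 <- result_table(s, focus, filter_thresholds(census = 3L))$gene_symbol
  expect_equal(length(intersect(k1, k2)), 0L)
  expect_setequal(union(k1, k2), k3)
  expect_equal(k1, "DRV1")
  expect_equal(k2, "COM1")
})

test_that("stricter thresholds always select a subset", {
  set.seed(41L)
  s <- scored_fixture()
  focus <- leukemia_focus()
  for (i in 1:25) {
    loose <- filter_thresholds(
      sift = round(stats::runif(1L, 0.02, 1), 3L),
      polyphen = round(stats::runif(1L, 0, 0.9), 3L),
      gmaf = round(stats::runif(1L, 0.05, 1), 3L),
      pubmed = sample(0:5, 1L), cosmic = sample(0:50, 1L),
      disassociation = sample(0:1, 1L), census = 0L
    )
    strict <- filter_thresholds(
      sift = loose$sift / 2, polyphen = min(1, loose$polyphen + 0.05),
      gmaf = loose$gmaf / 2, pubmed = loose$pubmed + 1L,
      cosmic = loose$cosmic + 10L,
      disassociation = loose$disassociation + 1L, census = 0L
    )
    k_loose <- vkey(result_table(s, focus, loose))
    k_strict <- vkey(result_table(s, focus, strict))
    expect_true(all(k_strict %in% k_loose))
  }
})

test_that("gmaf = 1 retains exactly the damage-predicate survivors when focus is empty", {
  s <- scored_fixture()
  plain_focus <- focus_config()
  out <- result_table(s, plain_focus, filter_thresholds())
  damage_ok <- (!is.na(s$sift) | !is.na(s$polyphen)) &
    (is.na(s$sift) | s$sift <= 0.05) &
    (is.na(s$polyphen) | s$polyphen >= 0.85)
  expect_setequal(vkey(out), vkey(s[damage_ok, ]))
})

test_that("heatmap rows are the gene's expression over its own mean", {
  evidence <- tibble::tibble(
    gene_symbol = c("A", "B", "C"),
    pubmed_count = 0L, cosmic_count = 0L, protein_length = 1L,
    disease_names = list(character(), character(), character()),
    process_terms = list(character(), character(), character()),
    is_census = FALSE, interacts_census = FALSE,
    expression = list(
      c(t1 = 2, t2 = 4, t3 = 6),
      c(t1 = 5, t2 = 5, t3 = 5),
      NULL
    )
  )
  table <- tibble::tibble(gene_symbol = c("A", "B", "C", "D"))
  hm <- heatmap_matrix(table, evidence)
  expect_equal(unname(hm["A", ]), c(0.5, 1.0, 1.5))
  expect_equal(unname(hm["B", ]), c(1, 1, 1))
  expect_setequal(attr(hm, "not_found"), c("C", "D"))
  expect_equal(unname(rowMeans(hm)), rep(1, 2L), tolerance = 1e-9)
})

test_that("all-zero expression rows are excluded with a warning", {
  evidence <- tibble::tibble(
    gene_symbol = "Z", pubmed_count = 0L, cosmic_count = 0L,
    protein_length = 1L, disease_names = list(character()),
    process_terms = list(character()), is_census = FALSE,
    interacts_census = FALSE, expression = list(c(t1 = 0, t2 = 0))
  )
  expect_warning(
    hm <- heatmap_matrix(tibble::tibble(gene_symbol = "Z"), evidence),
    "all-zero"
  )
  expect_equal(nrow(hm), 0L)
  expect_equal(attr(hm, "not_found"), "Z")
})

test_that("disjoint gene sets give an empty matrix plus a full not-found list", {
  evidence <- tibble::tibble(
    gene_symbol = "X", pubmed_count = 0L, cosmic_count = 0L,
    protein_length = 1L, disease_names = list(character()),
    process_terms = list(character()), is_census = FALSE,
    interacts_census = FALSE, expression = list(c(t1 = 1))
  )
  hm <- heatmap_matrix(tibble::tibble(gene_symbol = c("P", "Q")), evidence)
  expect_equal(nrow(hm), 0L)
  expect_setequal(attr(hm, "not_found"), c("P", "Q"))
})

test_that("reports render deterministically and an empty table is valid", {
  s <- scored_fixture()
  out <- result_table(s, leukemia_focus(), filter_thresholds())
  evidence <- tibble::tibble(
    gene_symbol = out$gene_symbol, pubmed_count = 0L, cosmic_count = 0L,
    protein_length = 1L,
    disease_names = purrr::map(out$gene_symbol, ~character()),
    process_terms = purrr::map(out$gene_symbol, ~character()),
    is_census = FALSE, interacts_census = FALSE,
    expression = purrr::map(out$gene_symbol, ~ c(t1 = 3, t2 = 9))
  )
  hm <- heatmap_matrix(out, evidence)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- render_report(out, hm, d1)
  p2 <- render_report(out, hm, d2)
  expect_identical(readLines(p1["tsv"]), readLines(p2["tsv"]))
  expect_true(file.exists(p1["html"]))
  tsv <- readr::read_tsv(p1["tsv"], show_col_types = FALSE)
  expect_equal(nrow(tsv), nrow(out))

  empty <- render_report(out[0L, ], NULL, withr::local_tempdir())
  expect_true(file.exists(empty["tsv"]))
  expect_true(file.exists(empty["html"]))
})

test_that("an eva_heatmap autoplots as a tile chart", {
  evidence <- tibble::tibble(
    gene_symbol = "A", pubmed_count = 0L, cosmic_count = 0L,
    protein_length = 1L, disease_names = list(character()),
    process_terms = list(character()), is_census = FALSE,
    interacts_census = FALSE, expression = list(c(t1 = 2, t2 = 4))
  )
  hm <- heatmap_matrix(tibble::tibble(gene_symbol = "A"), evidence)
  expect_s3_class(autoplot(hm), "ggplot")
})
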