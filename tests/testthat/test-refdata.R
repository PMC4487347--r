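test_that("GenePred rows map directly onto transcript models", {
  path <- withr::local_tempfile(fileext = ".genepred")
  writeLines(
    "NM_X\tchr1\t+\t100\t500\t150\t450\t2\t100,300,\t200,500,\tGENEA",
    path
  )
  m <- read_gene_models(path)
  expect_equal(nrow(m), 1L)
  expect_equal(m$gene_symbol, "GENEA")
  expect_equal(m$tx_start, 100L)
  expect_equal(m$cds_end, 450L)
  expect_equal(m$exon_starts[[1]], c(100L, 300L))
  expect_equal(m$exon_ends[[1]], c(200L, 500L))
})

test_that("invariant-violating rows are rejected with their line numbers", {
  path <- withr::local_tempfile(fileext = ".genepred")
  writeLines(c(
    "NM_1\tchr1\t+\t100\t500\t150\t450\t2\t100,300,\t200,500,\tGENEA",
    # cds_start > cds_end
    "NM_2\tchr1\t+\t100\t500\t460\t450\t2\t100,300,\t200,500,\tGENEB",
    # overlapping exons
    "NM_3\tchr1\t+\t100\t500\t150\t450\t2\t100,150,\t200,500,\tGENEC"
  ), path)
  expect_warning(m <- read_gene_models(path), "line")
  expect_equal(nrow(m), 1L)
  rejected <- attr(m, "rejected")
  expect_equal(sort(rejected$line), c(2L, 3L))
})

test_that("malformed coordinate lists raise an error naming the line", {
  path <- withr::local_tempfile(fileext = ".genepred")
  writeLines(c(
    "NM_1\tchr1\t+\t100\t500\t150\t450\t2\t100,300,\t200,500,\tGENEA",
    "NM_2\tchr1\t+\t100\t500\t150\t450\t2\t100,banana,\t200,500,\tGENEB"
  ), path)
  expect_error(read_gene_models(path), "line 2")
})

test_that("a generated GenePred file loads back with every invariant intact", {
  d <- withr::local_tempdir()
  cfg <- sim_config(seed = 7L, n_genes = 25L, chrom_spans = c(
    chr1 = 500000L, chr2 = 500000L
  ))
  simulate_universe(cfg, d)
  m <- read_gene_models(file.path(d, "genes.genepred"))
  expect_equal(nrow(attr(m, "rejected")), 0L)
  expect_equal(length(unique(m$gene_symbol)), 25L)
  for (i in seq_len(nrow(m))) {
    expect_true(m$tx_start[i] <= m$cds_start[i])
    expect_true(m$cds_start[i] <= m$cds_end[i])
    expect_true(m$cds_end[i] <= m$tx_end[i])
    s <- m$exon_starts[[i]]
    e <- m$exon_ends[[i]]
    expect_equal(length(s), length(e))
    expect_true(all(s < e))
    expect_true(!is.unsorted(s, strictly = TRUE))
    if (length(s) > 1L) expect_true(all(e[-length(e)] <= s[-1L]))
    expect_true(s[1L] >= m$tx_start[i] && e[length(e)] <= m$tx_end[i])
  }
})

test_that("evidence channels default sensibly and census status propagates", {
  d <- withr::local_tempdir()
  write_tsv_ <- function(x, name) {
    readr::write_tsv(x, file.path(d, name))
  }
  write_tsv_(tibble::tibble(
    gene = c("A", "B"), mesh_term = c("leukemia", "lymphoma"),
    count = c(9L, 99L)
  ), "literature.tsv")
  write_tsv_(tibble::tibble(
    gene = "A", entries = 150L, protein_length = 500L
  ), "cosmic.tsv")
  write_tsv_(tibble::tibble(
    gene = "A", disease_name = "Chronic lymphocytic leukemia"
  ), "disease.tsv")
  write_tsv_(tibble::tibble(gene = "B", term = "Apoptosis"), "process.tsv")
  write_tsv_(tibble::tibble(gene = "C"), "census.tsv")
  write_tsv_(tibble::tibble(geneA = "G", geneB = "C"), "interactions.tsv")
  write_tsv_(tibble::tibble(
    gene = "A", Blood = 10, Brain = 2
  ), "expression.tsv")

  ev <- read_evidence_tables(d, "leukemia")
  rowof <- function(g) ev[ev$gene_symbol == g, ]

  expect_equal(rowof("A")$pubmed_count, 9L)
  # count under a different MeSH term is not picked up
  expect_equal(rowof("B")$pubmed_count, 0L)
  expect_equal(rowof("A")$cosmic_count, 150L)
  expect_equal(rowof("A")$protein_length, 500L)
  expect_true(rowof("C")$is_census)
  expect_false(rowof("G")$is_census)
  expect_true(rowof("G")$interacts_census)
  expect_equal(rowof("A")$disease_names[[1]], "Chronic lymphocytic leukemia")
  expect_equal(rowof("B")$process_terms[[1]], "Apoptosis")
  expect_equal(rowof("A")$expression[[1]], c(Blood = 10, Brain = 2))
  expect_null(rowof("B")$expression[[1]])
})

test_that("interactor status is symmetric in pair order", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  base_tables <- function(d, pairs) {
    readr::write_tsv(
      tibble::tibble(gene = character(), mesh_term = character(),
                     count = integer()),
      file.path(d, "literature.tsv")
    )
    readr::write_tsv(
      tibble::tibble(gene = character(), entries = integer(),
                     protein_length = integer()),
      file.path(d, "cosmic.tsv")
    )
    readr::write_tsv(
      tibble::tibble(gene = character(), disease_name = character()),
      file.path(d, "disease.tsv")
    )
    readr::write_tsv(
      tibble::tibble(gene = character(), term = character()),
      file.path(d, "process.tsv")
    )
    readr::write_tsv(tibble::tibble(gene = "C"), file.path(d, "census.tsv"))
    readr::write_tsv(pairs, file.path(d, "interactions.tsv"))
    readr::write_tsv(tibble::tibble(gene = character()),
      file.path(d, "expression.tsv")
    )
  }
  base_tables(d1, tibble::tibble(geneA = "G", geneB = "C"))
  base_tables(d2, tibble::tibble(geneA = "C", geneB = "G"))
  e1 <- read_evidence_tables(d1, "leukemia")
  e2 <- read_evidence_tables(d2, "leukemia")
  expect_true(e1$interacts_census[e1$gene_symbol == "G"])
  expect_true(e2$interacts_census[e2$gene_symbol == "G"])
})

test_that("a missing mandatory table is reported by name", {
  d <- withr::local_tempdir()
  expect_error(read_evidence_tables(d, "leukemia"), "literature.tsv")
})

test_that("non-positive protein lengths are a validation error", {
  d <- withr::local_tempdir()
  for (f in c(
    "literature.tsv", "disease.tsv", "process.tsv", "census.tsv",
    "interactions.tsv", "expression.tsv"
  )) {
    file.create(file.path(d, f))
  }
  readr::write_tsv(
    tibble::tibble(gene = "BAD", entries = 5L, protein_length = 0L),
    file.path(d, "cosmic.tsv")
  )
  # rewrite the empty files with headers so parsing succeeds
  readr::write_tsv(
    tibble::tibble(gene = character(), mesh_term = character(),
                   count = integer()),
    file.path(d, "literature.tsv")
  )
  readr::write_tsv(
    tibble::tibble(gene = character(), disease_name = character()),
    file.path(d, "disease.tsv")
  )
  readr::write_tsv(
    tibble::tibble(gene = character(), term = character()),
    file.path(d, "process.tsv")
  )
  readr::write_tsv(tibble::tibble(gene = character()),
    file.path(d, "census.tsv")
  )
  readr::write_tsv(
    tibble::tibble(geneA = character(), geneB = character()),
    file.path(d, "interactions.tsv")
  )
  readr::write_tsv(tibble::tibble(gene = character()),
    file.path(d, "expression.tsv")
  )
  expect_error(read_evidence_tables(d, "leukemia"), "protein_length")
})

test_that("evidence tables round-trip through write and reload", {
  d <- withr::local_tempdir()
  cfg <- sim_config(seed = 11L, n_genes = 15L, chrom_spans = c(
    chr1 = 400000L, chr2 = 400000L
  ))
  simulate_universe(cfg, d)
  ev <- read_evidence_tables(d, "leukemia")
  d2 <- withr::local_tempdir()
  write_evidence_tables(ev, d2, "leukemia")
  ev2 <- read_evidence_tables(d2, "leukemia")
  expect_equal(ev2, ev)
})

test_that("focus_config validates its numeric parameters and weights", {
  expect_error(focus_config(rarity_gmax = 0), "rarity_gmax")
  expect_error(focus_config(rarity_gmax = 0.6), "rarity_gmax")
  expect_error(focus_config(cosmic_cap = -1), "cosmic_cap")
  expect_error(focus_config(weights = c(bogus = 2)), "bogus")
  f <- focus_config(weights = c(literature = 2))
  expect_equal(unname(f$weights[["literature"]]), 2)
  expect_equal(unname(f$weights[["rarity"]]), 1)
})
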