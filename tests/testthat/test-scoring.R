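test_that("rarity ramps linearly and treats absence as maximally rare", {
  expect_equal(score_rarity(NA_real_, 0.05), 1.0)
  expect_equal(score_rarity(0.05, 0.05), 0.0)
  expect_equal(score_rarity(0.01, 0.05), 0.8)
  expect_equal(score_rarity(0.3, 0.05), 0.0) # clamped
  expect_equal(score_rarity(0, 0.05), 1.0)
  expect_error(score_rarity(0.6, 0.05), "gmaf")
  expect_error(score_rarity(0.01, 0), "gmax")
})

test_that("literature scoring is log10(1 + n)", {
  expect_equal(score_literature(0L), 0.0)
  expect_equal(score_literature(9L), 1.0)
  expect_equal(score_literature(99L), 2.0)
  expect_error(score_literature(-1L), ">= 0")
})

test_that("COSMIC burden is length-normalized and capped", {
  expect_equal(score_cosmic(150L, 500L, 1.0), 0.3)
  expect_equal(score_cosmic(600L, 300L, 1.0), 1.0)
  expect_equal(score_cosmic(0L, 500L, 1.0), 0.0)
  expect_equal(score_cosmic(100L, 100L, 2.0), 0.5)
  expect_error(score_cosmic(10L, 0L), "protein_length")
})

test_that("the composite score is the hand-computed sum of its channels", {
  focus <- leukemia_focus()
  e <- make_enriched(
    gmaf = NA, sift = 0.02, polyphen = 0.97, pubmed = 9L,
    cosmic = 150L, protein_length = 500L,
    diseases = "Leukemia associated disorder",
    terms = "Apoptosis", zygosity = "het"
  )
  s <- score_variants(e, focus)
  expect_equal(s$rarity, 1.0)
  expect_equal(s$sift_damage, 1.0)
  expect_equal(s$polyphen_damage, 0.97)
  expect_equal(s$literature, 1.0)
  expect_equal(s$cosmic, 0.3)
  expect_equal(s$disease, 1.0)
  expect_equal(s$`function`, 1.0)
  expect_equal(s$zygosity_score, 0.5)
  # 1 + 1 + 0.97 + 1 + 0.3 + 1 + 1 + 0.5
  expect_equal(s$total, 6.77, tolerance = 1e-9)
})

test_that("an all-absent record scores rarity plus zygosity only", {
  s <- score_variants(make_enriched(), leukemia_focus())
  expect_equal(s$total, 1.5, tolerance = 1e-9)
})

test_that("the total is the weighted sum of components for any weights", {
  set.seed(17L)
  for (i in 1:20) {
    w <- stats::runif(8L, 0, 3)
    names(w) <- c(
      "rarity", "sift_damage", "polyphen_damage", "literature",
      "cosmic", "disease", "function", "zygosity"
    )
    focus <- leukemia_focus(weights = w)
    e <- make_enriched(
      gmaf = sample(c(NA, round(stats::runif(1L, 0, 0.5), 3L)), 1L),
      sift = round(stats::runif(1L), 3L),
      polyphen = round(stats::runif(1L), 3L),
      pubmed = sample(0:500, 1L),
      cosmic = sample(0:800, 1L), protein_length = sample(100:900, 1L),
      diseases = sample(c("Leukemia", "Asthma"), 1L),
      terms = sample(c("Apoptosis", "Axon guidance"), 1L),
      zygosity = sample(c("het", "hom_alt", "unknown"), 1L)
    )
    s <- score_variants(e, focus)
    manual <- sum(w * c(
      s$rarity, s$sift_damage, s$polyphen_damage, s$literature,
      s$cosmic, s$disease, s$`function`, s$zygosity_score
    ))
    expect_equal(s$total, manual, tolerance = 1e-9)
  }
})

test_that("doubling the literature weight doubles only that contribution", {
  e <- make_enriched(pubmed = 9L)
  base <- score_variants(e, leukemia_focus())
  doubled <- score_variants(e, leukemia_focus(weights = c(literature = 2)))
  expect_equal(doubled$total - base$total, base$literature, tolerance = 1e-9)
})

test_that("scores are monotone in evidence strength", {
  focus <- leukemia_focus()
  tot <- function(...) score_variants(make_enriched(...), focus)$total
  # non-decreasing in pubmed and cosmic counts
  expect_true(tot(pubmed = 100L) > tot(pubmed = 10L))
  expect_true(tot(cosmic = 300L, protein_length = 500L) >
    tot(cosmic = 100L, protein_length = 500L))
  # non-increasing in gmaf
  expect_true(tot(gmaf = 0.01) > tot(gmaf = 0.04))
  expect_true(tot(gmaf = 0.04) >= tot(gmaf = 0.2))
  # strict step when SIFT crosses the damage threshold
  expect_equal(tot(sift = 0.05) - tot(sift = 0.051), 1.0, tolerance = 1e-9)
})

test_that("components stay in their stated ranges over a synthetic corpus", {
  d <- withr::local_tempdir()
  simulate_universe(sim_config(seed = 23L), d)
  models <- read_gene_models(file.path(d, "genes.genepred"))
  evidence <- read_evidence_tables(d, "leukemia")
  v <- read_mutect(file.path(d, "mutect.tsv"), "tumor")
  coding <- find_coding(annotate_variants(v, models), models)
  e <- enrich_variants(read_vep(file.path(d, "vep.tsv")), coding, evidence,
    leukemia_focus()
  )
  s <- score_variants(e, leukemia_focus())
  bounded <- c(
    "rarity", "sift_damage", "polyphen_damage", "cosmic", "disease",
    "function", "zygosity_score"
  )
  for (comp in bounded) {
    expect_true(all(s[[comp]] >= 0 & s[[comp]] <= 1), info = comp)
  }
  expect_true(all(s$literature >= 0))
  expect_equal(
    s$total,
    s$rarity + s$sift_damage + s$polyphen_damage + s$literature +
      s$cosmic + s$disease + s$`function` + s$zygosity_score,
    tolerance = 1e-9
  )
})

test_that("ranking sorts by score with deterministic tie-breaks", {
  mk <- function(pos, total_driver) {
    # build enriched rows whose totals are controlled via pubmed counts
    make_enriched(pos = pos, pubmed = total_driver)
  }
  e <- dplyr::bind_rows(mk(100L, 9L), mk(50L, 9L), mk(200L, 999L))
  s <- rank_variants(score_variants(e, leukemia_focus()))
  expect_equal(s$pos, c(200L, 50L, 100L)) # tie at pos 50/100 -> lower pos first
  expect_equal(s$rank, 1:3)
})

test_that("ranking is stable under input permutation", {
  set.seed(31L)
  e <- dplyr::bind_rows(lapply(1:50, function(i) {
    make_enriched(
      pos = i * 10L, pubmed = sample(0:50, 1L),
      gmaf = sample(c(NA, 0.2), 1L),
      zygosity = sample(c("het", "hom_alt"), 1L)
    )
  }))
  s1 <- rank_variants(score_variants(e, leukemia_focus()))
  s2 <- rank_variants(score_variants(e[sample.int(nrow(e)), ], leukemia_focus()))
  expect_equal(s1$pos, s2$pos)
  expect_equal(s1$rank, s2$rank)
})

test_that("multi-gene variants keep their best-scoring gene", {
  e <- dplyr::bind_rows(
    make_enriched(gene = "WEAK", pubmed = 0L),
    make_enriched(gene = "STRONG", pubmed = 999L)
  )
  s <- rank_variants(score_variants(e, leukemia_focus()))
  expect_equal(nrow(s), 1L)
  expect_equal(s$gene_symbol, "STRONG")
})

test_that("tidy, glance and autoplot summarize a ranked set", {
  e <- dplyr::bind_rows(
    make_enriched(pos = 10L, pubmed = 9L),
    make_enriched(pos = 20L, pubmed = 99L, gene = "GENEB")
  )
  s <- rank_variants(score_variants(e, leukemia_focus()))
  long <- tidy(s)
  expect_equal(nrow(long), 2L * 8L)
  expect_setequal(
    unique(long$component),
    c(
      "rarity", "sift_damage", "polyphen_damage", "literature", "cosmic",
      "disease", "function", "zygosity"
    )
  )
  g <- glance(s)
  expect_equal(g$n_variants, 2L)
  expect_equal(g$top_gene, "GENEB")
  p <- autoplot(s)
  expect_s3_class(p, "ggplot")
})
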