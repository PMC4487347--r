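#' Rarity score from global minor allele frequency
#'
#' A variant with no reported GMAF is treated as maximally rare (score 1):
#' absence from the frequency table is read as "likely unreported in the
#' 1000 Genomes Project", not imputed as common. Otherwise the score ramps
#' linearly from 1 at frequency 0 down to 0 at `gmax` and stays 0 above it:
#' `clamp((gmax - gmaf) / gmax, 0, 1)`.
#'
#' @param gmaf Numeric vector of allele frequencies in \[0, 0.5\]; `NA` for
#'   unreported.
#' @param gmax Frequency at which the score reaches 0; in (0, 0.5\].
#' @return Numeric vector in \[0, 1\].
#' @export
score_rarity <- function(gmaf, gmax = 0.05) {
  if (!is.numeric(gmax) || length(gmax) != 1L || gmax <= 0 || gmax > 0.5) {
    abort("gmax must lie in (0, 0.5]")
  }
  bad <- !is.na(gmaf) & (gmaf < 0 | gmaf > 0.5)
  if (any(bad)) {
    abort("gmaf values must lie in [0, 0.5]")
  }
  ifelse(is.na(gmaf), 1, pmin(pmax((gmax - gmaf) / gmax, 0), 1))
}

#' Literature score from a PubMed reference count
#'
#' `log10(1 + n)`: logarithmic so that widely described biomarkers with
#' thousands of references do not drown out sparsely described genes.
#'
#' @param n Non-negative integer vector of reference counts.
#' @return Numeric vector, 0 at `n = 0`, unbounded above.
#' @export
score_literature <- function(n) {
  if (any(!is.na(n) & n < 0)) {
    abort("literature counts must be >= 0")
  }
  log10(1 + n)
}

#' COSMIC burden score normalized to protein length
#'
#' Entries per protein residue, saturated at `cap` and rescaled to \[0, 1\]:
#' `min(entries / protein_length, cap) / cap`. Length normalization stops
#' long genes from dominating purely by target size.
#'
#' @param entries Non-negative integer vector of COSMIC entry counts.
#' @param protein_length Positive integer vector of protein lengths
#'   (residues).
#' @param cap Entries-per-residue value at which the score saturates; > 0.
#' @return Numeric vector in \[0, 1\].
#' @export
score_cosmic <- function(entries, protein_length, cap = 1.0) {
  if (!is.numeric(cap) || length(cap) != 1L || cap <= 0) {
    abort("cap must be > 0")
  }
  if (any(!is.na(protein_length) & protein_length < 1)) {
    abort("protein_length must be >= 1")
  }
  pmin(entries / protein_length, cap) / cap
}

#' Compute component and composite relevance scores
#'
#' Evaluates the eight evidence channels for every enriched (variant, gene)
#' row and combines them as a weighted sum:
#'
#' * `rarity` — [score_rarity()] of the GMAF under `focus$rarity_gmax`;
#' * `sift_damage` — 1 if a SIFT score is present and at most 0.05, else 0;
#' * `polyphen_damage` — the PolyPhen-2 score itself (0 when absent);
#' * `literature` — [score_literature()] of the MeSH-scoped PubMed count;
#' * `cosmic` — [score_cosmic()] under `focus$cosmic_cap`;
#' * `disease` — 1 if any associated disease name contains any
#'   `focus$disease_focus` phrase (case-insensitive substring), else 0;
#' * `function` — 1 if any process term matches any `focus$function_focus`
#'   phrase (case-insensitive, non-alphanumerics ignored), else 0;
#' * `zygosity` — 1 for `hom_alt`, 0.5 for `het` or `unknown`.
#'
#' `total` is the `focus$weights`-weighted sum of the components. An empty
#' disease or function focus makes that channel identically 0 (inert).
#'
#' @param enriched Tibble from [enrich_variants()].
#' @param focus A [focus_config()].
#' @return `enriched` with the eight component columns,
#'   `n_focus_diseases` (count of focus-matching disease associations, used
#'   by the report filter) and `total`.
#' @export
score_variants <- function(enriched, focus = focus_config()) {
  stopifnot(inherits(focus, "eva_focus"))
  w <- focus$weights
  out <- enriched |>
    dplyr::mutate(
      rarity = score_rarity(.data$gmaf, focus$rarity_gmax),
      sift_damage = as.numeric(!is.na(.data$sift) & .data$sift <= 0.05),
      polyphen_damage = coalesce(.data$polyphen, 0),
      literature = score_literature(.data$pubmed_count),
      cosmic = score_cosmic(
        .data$cosmic_count, .data$protein_length, focus$cosmic_cap
      ),
      n_focus_diseases = purrr::map_int(
        .data$disease_names, n_phrase_matches, phrases = focus$disease_focus
      ),
      disease = as.numeric(.data$n_focus_diseases > 0L),
      `function` = as.numeric(purrr::map_int(
        .data$process_terms, n_term_matches, phrases = focus$function_focus
      ) > 0L),
      zygosity_score = ifelse(.data$zygosity == "hom_alt", 1, 0.5)
    )
  out$total <- with(out,
    w[["rarity"]] * rarity +
      w[["sift_damage"]] * sift_damage +
      w[["polyphen_damage"]] * polyphen_damage +
      w[["literature"]] * literature +
      w[["cosmic"]] * cosmic +
      w[["disease"]] * disease +
      w[["function"]] * `function` +
      w[["zygosity"]] * zygosity_score
  )
  out
}

#' Rank scored variants
#'
#' Collapses multi-gene variants to one row per variant key — the
#' best-scoring gene wins and is the one reported (gene symbol order breaks
#' exact score ties deterministically) — then sorts by total score
#' descending. Score ties between variants are broken by (chrom lexical,
#' pos ascending, alt lexical), so the ranking is stable across runs and
#' input orderings. Ranks are assigned 1..n.
#'
#' @param scored Tibble from [score_variants()].
#' @return A tibble of class `eva_scores`, one row per variant, with a
#'   `rank` column. Has [tidy()], [glance()] and [autoplot()] methods.
#' @export
rank_variants <- function(scored) {
  out <- scored |>
    dplyr::group_by(.data$chrom, .data$pos, .data$ref, .data$alt) |>
    dplyr::arrange(dplyr::desc(.data$total), .data$gene_symbol,
      .by_group = TRUE
    ) |>
    dplyr::slice(1L) |>
    dplyr::ungroup()
  ord <- order_radix(-out$total, out$chrom, out$pos, out$alt)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  class(out) <- unique(c("eva_scores", class(out)))
  out
}

#' @describeIn rank_variants One row per (variant, component): columns
#'   `chrom`, `pos`, `ref`, `alt`, `gene_symbol`, `rank`, `component`,
#'   `score`, `weighted_score`.
#' @param x,object An `eva_scores` tibble.
#' @param focus The [focus_config()] used for scoring (for the weights).
#' @param ... Ignored.
#' @export
tidy.eva_scores <- function(x, focus = focus_config(), ...) {
  comp <- c(score_channels[score_channels != "zygosity"], "zygosity_score")
  long <- x |>
    dplyr::select(
      "chrom", "pos", "ref", "alt", "gene_symbol", "rank",
      dplyr::all_of(comp)
    ) |>
    tidyr::pivot_longer(
      dplyr::all_of(comp),
      names_to = "component", values_to = "score"
    ) |>
    dplyr::mutate(
      component = ifelse(
        .data$component == "zygosity_score", "zygosity", .data$component
      ),
      weighted_score = .data$score * focus$weights[.data$component]
    )
  long
}

#' @describeIn rank_variants One-row summary: variant and gene counts, score
#'   spread, and the top-ranked gene.
#' @export
glance.eva_scores <- function(x, ...) {
  tibble::tibble(
    n_variants = nrow(x),
    n_genes = length(unique(x$gene_symbol)),
    top_gene = if (nrow(x) > 0L) x$gene_symbol[x$rank == 1L] else NA_character_,
    max_total = if (nrow(x) > 0L) max(x$total) else NA_real_,
    mean_total = if (nrow(x) > 0L) mean(x$total) else NA_real_,
    sd_total = if (nrow(x) > 1L) stats::sd(x$total) else NA_real_
  )
}

#' @describeIn rank_variants Stacked bar chart of the weighted score
#'   components for the top-ranked variants.
#' @param top_n Number of top-ranked variants to display.
#' @export
autoplot.eva_scores <- function(object, top_n = 10L,
                                focus = focus_config(), ...) {
  long <- tidy(object, focus = focus) |>
    dplyr::filter(.data$rank <= top_n) |>
    dplyr::mutate(
      label = stats::reorder(
        paste0(.data$gene_symbol, " ", .data$chrom, ":", .data$pos),
        -.data$rank
      )
    )
  ggplot2::ggplot(
    long,
    ggplot2::aes(
      x = .data$weighted_score, y = .data$label, fill = .data$component
    )
  ) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = "weighted component score", y = NULL, fill = "channel",
      title = "Composite relevance score, top-ranked variants"
    ) +
    ggplot2::theme_minimal()
}
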