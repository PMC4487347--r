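#' Report filter thresholds
#'
#' The threshold set applied by [result_table()]. The defaults mirror the
#' workflow's standard call — `sift = 0.05, polyphen = 0.85, gmaf = 1,
#' pubmed = 0, cosmic = 0, disassociation = 0, census = 0` — under which
#' only the damage and function-focus predicates bite. `gmaf = 1` is the
#' documented no-op sentinel: every real allele frequency is at most 0.5,
#' so no variant is removed on frequency.
#'
#' @param sift Maximum SIFT score counted as damaging, in \[0, 1\].
#' @param polyphen Minimum PolyPhen-2 score counted as damaging, in \[0, 1\].
#' @param gmaf Maximum allowed GMAF, in (0, 1\]; variants without a reported
#'   GMAF always pass.
#' @param pubmed Minimum MeSH-scoped PubMed count.
#' @param cosmic Minimum raw COSMIC entry count for the gene.
#' @param disassociation Minimum number of focus-matching disease
#'   associations.
#' @param census Census mode: 0 no constraint, 1 census genes only, 2 genes
#'   interacting with a census gene but not census themselves, 3 either.
#'   Modes 1 and 2 partition mode 3.
#' @return A list of class `eva_thresholds`.
#' @export
filter_thresholds <- function(sift = 0.05, polyphen = 0.85, gmaf = 1,
                              pubmed = 0L, cosmic = 0L, disassociation = 0L,
                              census = 0L) {
  stopifnot(
    sift >= 0, sift <= 1, polyphen >= 0, polyphen <= 1,
    gmaf > 0, gmaf <= 1,
    pubmed >= 0, cosmic >= 0, disassociation >= 0,
    census %in% 0:3
  )
  structure(
    list(
      sift = sift, polyphen = polyphen, gmaf = gmaf,
      pubmed = as.integer(pubmed), cosmic = as.integer(cosmic),
      disassociation = as.integer(disassociation), census = as.integer(census)
    ),
    class = "eva_thresholds"
  )
}

#' Filter ranked variants into a result table
#'
#' Retains a variant iff all of the following hold:
#'
#' * damage — at least one of SIFT/PolyPhen is present, and every predictor
#'   that is present meets its threshold (`sift <= t$sift`,
#'   `polyphen >= t$polyphen`). With `damage_mode = "any"` one passing
#'   predictor suffices;
#' * frequency — GMAF absent or `<= t$gmaf`;
#' * literature — PubMed count `>= t$pubmed`;
#' * COSMIC — raw entry count `>= t$cosmic`;
#' * disease — number of focus-matching disease associations
#'   `>= t$disassociation`;
#' * census — per the mode in `t$census`;
#' * function — `focus$function_focus` empty, or at least one process-term
#'   match.
#'
#' Rank order is preserved. Tightening any threshold can only shrink the
#' result set.
#'
#' @param scored Ranked variants from [rank_variants()].
#' @param focus The [focus_config()] used in scoring.
#' @param thresholds A [filter_thresholds()].
#' @param damage_mode `"all"` (default: every present predictor must pass)
#'   or `"any"` (one passing predictor suffices).
#' @return The retained subset, same class and order as `scored`.
#' @export
result_table <- function(scored, focus = focus_config(),
                         thresholds = filter_thresholds(),
                         damage_mode = c("all", "any")) {
  damage_mode <- match.arg(damage_mode)
  stopifnot(inherits(thresholds, "eva_thresholds"))
  t <- thresholds
  if (nrow(scored) == 0L) {
    return(scored)
  }

  sift_ok <- !is.na(scored$sift) & scored$sift <= t$sift
  pp_ok <- !is.na(scored$polyphen) & scored$polyphen >= t$polyphen
  any_present <- !is.na(scored$sift) | !is.na(scored$polyphen)
  damage <- if (damage_mode == "all") {
    any_present &
      (is.na(scored$sift) | sift_ok) &
      (is.na(scored$polyphen) | pp_ok)
  } else {
    sift_ok | pp_ok
  }

  freq <- is.na(scored$gmaf) | scored$gmaf <= t$gmaf
  lit <- scored$pubmed_count >= t$pubmed
  cos <- scored$cosmic_count >= t$cosmic
  dis <- scored$n_focus_diseases >= t$disassociation
  cen <- switch(as.character(t$census),
    "0" = rep(TRUE, nrow(scored)),
    "1" = scored$is_census,
    "2" = scored$interacts_census & !scored$is_census,
    "3" = scored$is_census | scored$interacts_census
  )
  fun <- if (length(focus$function_focus) == 0L) {
    rep(TRUE, nrow(scored))
  } else {
    scored$`function` > 0
  }

  scored[damage & freq & lit & cos & dis & cen & fun, , drop = FALSE]
}

#' Mean-normalized expression matrix for result-table genes
#'
#' Builds a genes-by-tissues matrix for the genes of a result table, each
#' expression row divided by its own mean across tissues, so every emitted
#' row has mean 1 and the values read as fold-change relative to that gene's
#' average expression. Genes are ordered by variant rank. Genes without an
#' expression profile are reported in the `"not_found"` attribute rather
#' than zero-filled; all-zero profiles are excluded with a warning (the
#' normalization is undefined).
#'
#' @param table A result table from [result_table()] (or any ranked variant
#'   tibble with a `gene_symbol` column).
#' @param evidence Evidence tibble from [read_evidence_tables()].
#' @return A numeric matrix of class `eva_heatmap` (rows genes, columns
#'   tissues) with attribute `not_found`.
#' @export
heatmap_matrix <- function(table, evidence) {
  genes <- unique(table$gene_symbol)
  expr <- setNames(evidence$expression, evidence$gene_symbol)
  profiles <- purrr::map(genes, function(g) expr[[g]])
  has <- !purrr::map_lgl(profiles, is.null)
  not_found <- genes[!has]
  genes <- genes[has]
  profiles <- profiles[has]

  all_zero <- purrr::map_lgl(profiles, ~ all(.x == 0))
  if (any(all_zero)) {
    warn(paste0(
      "excluding gene(s) with all-zero expression profile: ",
      paste(genes[all_zero], collapse = ", ")
    ))
    not_found <- c(not_found, genes[all_zero])
    genes <- genes[!all_zero]
    profiles <- profiles[!all_zero]
  }

  if (length(genes) == 0L) {
    m <- matrix(numeric(0L), nrow = 0L, ncol = 0L)
  } else {
    m <- do.call(rbind, purrr::map(profiles, ~ .x / mean(.x)))
    rownames(m) <- genes
    colnames(m) <- names(profiles[[1L]])
  }
  structure(m, not_found = not_found, class = c("eva_heatmap", class(m)))
}

#' @describeIn heatmap_matrix Tile plot of the normalized matrix; bright
#'   green marks the highest values and red the lowest.
#' @param object An `eva_heatmap` matrix.
#' @param ... Ignored.
#' @export
autoplot.eva_heatmap <- function(object, ...) {
  m <- unclass(object)
  attr(m, "not_found") <- NULL
  df <- tibble::as_tibble(m, rownames = "gene") |>
    tidyr::pivot_longer(-"gene", names_to = "tissue", values_to = "relative") |>
    dplyr::mutate(gene = factor(.data$gene, levels = rev(rownames(m))))
  ggplot2::ggplot(
    df,
    ggplot2::aes(x = .data$tissue, y = .data$gene, fill = .data$relative)
  ) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(
      low = "red", mid = "black", high = "green", midpoint = 1
    ) +
    ggplot2::labs(
      x = NULL, y = NULL, fill = "expr / gene mean",
      title = "Tissue expression, normalized to each gene's mean"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Write the ranked report as TSV and HTML
#'
#' The TSV flattens list-columns to comma-joined strings and is byte-stable
#' for a fixed input. The HTML file is a static, self-contained report: the
#' ranked table followed by the expression heatmap rendered as a colored
#' table (bright green highest, red lowest within each gene row).
#'
#' @param table Result table from [result_table()].
#' @param heatmap Matrix from [heatmap_matrix()], or `NULL` to omit.
#' @param dir Output directory (created if needed).
#' @param name Basename for the output files (default `"report"`).
#' @return Named character vector of the written paths, invisibly.
#' @export
render_report <- function(table, heatmap = NULL, dir, name = "report") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv_path <- file.path(dir, paste0(name, ".tsv"))
  html_path <- file.path(dir, paste0(name, ".html"))
  write_variants_tsv(table, tsv_path)

  flat <- flatten_list_cols(table)
  html <- c(
    "<!DOCTYPE html>",
    "<html><head><meta charset=\"utf-8\"><title>Variant report</title>",
    "<style>",
    "body{font-family:sans-serif} table{border-collapse:collapse}",
    "td,th{border:1px solid #999;padding:2px 6px;font-size:12px}",
    "</style></head><body>",
    "<h1>Ranked variant report</h1>",
    html_table(flat)
  )
  if (!is.null(heatmap) && nrow(heatmap) > 0L) {
    html <- c(
      html,
      "<h2>Tissue expression (normalized to gene mean)</h2>",
      html_heatmap(heatmap),
      if (length(attr(heatmap, "not_found")) > 0L) {
        paste0(
          "<p>No expression profile for: ",
          paste(attr(heatmap, "not_found"), collapse = ", "), "</p>"
        )
      }
    )
  }
  html <- c(html, "</body></html>")
  readr::write_lines(html, html_path)
  invisible(c(tsv = tsv_path, html = html_path))
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

html_table <- function(df) {
  if (nrow(df) == 0L) {
    return("<p>No variants passed the filters.</p>")
  }
  cells <- purrr::map(df, function(col) html_escape(format(col, digits = 4L)))
  head_row <- paste0(
    "<tr>", paste0("<th>", html_escape(names(df)), "</th>", collapse = ""),
    "</tr>"
  )
  body <- purrr::map_chr(seq_len(nrow(df)), function(i) {
    paste0(
      "<tr>",
      paste0("<td>", purrr::map_chr(cells, i), "</td>", collapse = ""),
      "</tr>"
    )
  })
  paste0("<table>", head_row, paste(body, collapse = ""), "</table>")
}

# Green-to-red cell shading: highest relative expression bright green,
# lowest red.
html_heatmap <- function(m) {
  m <- unclass(m)
  attr(m, "not_found") <- NULL
  rng <- range(m)
  shade <- function(v) {
    f <- if (diff(rng) == 0) 0.5 else (v - rng[1L]) / diff(rng)
    sprintf("#%02x%02x00", round(255 * (1 - f)), round(255 * f))
  }
  head_row <- paste0(
    "<tr><th></th>",
    paste0("<th>", html_escape(colnames(m)), "</th>", collapse = ""), "</tr>"
  )
  body <- purrr::map_chr(seq_len(nrow(m)), function(i) {
    cells <- purrr::map_chr(seq_len(ncol(m)), function(j) {
      sprintf(
        "<td style=\"background:%s;color:white\">%.2f</td>",
        shade(m[i, j]), m[i, j]
      )
    })
    paste0(
      "<tr><th>", html_escape(rownames(m)[i]), "</th>",
      paste(cells, collapse = ""), "</tr>"
    )
  })
  paste0("<table>", head_row, paste(body, collapse = ""), "</table>")
}
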