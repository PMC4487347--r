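#' Read gene models from a GenePred file
#'
#' Parses a tab-separated GenePred table (UCSC refGene dialect: name, chrom,
#' strand, txStart, txEnd, cdsStart, cdsEnd, exonCount, exonStarts, exonEnds,
#' geneSymbol). All coordinates are 0-based half-open and are kept that way
#' internally; conversion to 1-based happens only where variants are compared
#' against intervals. Trailing commas in the exon lists are tolerated.
#'
#' Rows that parse but violate the coordinate invariants
#' (`tx_start <= cds_start <= cds_end <= tx_end`; exons sorted, non-overlapping,
#' inside the transcript span; exon list lengths equal and matching exonCount)
#' are dropped with a warning; the rejected line numbers and reasons are
#' attached as the `"rejected"` attribute. Structurally malformed rows (wrong
#' column count, non-numeric coordinates) raise an error naming the line.
#'
#' @param path Path to a GenePred TSV. A header line starting with `#` or with
#'   a literal `name` field is skipped.
#' @return A tibble with one row per transcript: `gene_symbol`,
#'   `transcript_id`, `chrom`, `strand`, `tx_start`, `tx_end`, `cds_start`,
#'   `cds_end` and list-columns `exon_starts`, `exon_ends`.
#' @examples
#' path <- tempfile(fileext = ".genepred")
#' writeLines("NM_X\tchr1\t+\t100\t500\t150\t450\t2\t100,300,\t200,500,\tGENEA",
#'            path)
#' read_gene_models(path)
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("gene model file not found: ", path))
  }
  lines <- readr::read_lines(path)
  idx <- which(!grepl("^#", lines) & nzchar(lines))
  if (length(idx) > 0L && grepl("^name\t", lines[idx[1L]])) {
    idx <- idx[-1L]
  }
  if (length(idx) == 0L) {
    return(empty_gene_models())
  }

  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  bad_ncol <- which(lengths(fields) < 11L)
  if (length(bad_ncol) > 0L) {
    abort(paste0(
      "malformed GenePred row (expected 11 tab-separated fields) at line ",
      paste(idx[bad_ncol], collapse = ", ")
    ))
  }

  parse_coord_list <- function(x, line) {
    parts <- strsplit(x, ",", fixed = TRUE)[[1L]]
    parts <- parts[nzchar(parts)]
    vals <- suppressWarnings(as.numeric(parts))
    if (length(vals) == 0L || anyNA(vals)) {
      abort(paste0("malformed coordinate list at line ", line))
    }
    as.integer(vals)
  }

  rows <- purrr::map2(fields, idx, function(f, line) {
    coords <- suppressWarnings(as.numeric(f[c(4L, 5L, 6L, 7L, 8L)]))
    if (anyNA(coords)) {
      abort(paste0("malformed numeric coordinate at line ", line))
    }
    tibble::tibble(
      line = line,
      transcript_id = f[1L], chrom = f[2L], strand = f[3L],
      tx_start = as.integer(coords[1L]), tx_end = as.integer(coords[2L]),
      cds_start = as.integer(coords[3L]), cds_end = as.integer(coords[4L]),
      exon_count = as.integer(coords[5L]),
      exon_starts = list(parse_coord_list(f[9L], line)),
      exon_ends = list(parse_coord_list(f[10L], line)),
      gene_symbol = f[11L]
    )
  })
  models <- dplyr::bind_rows(rows)

  reason <- purrr::pmap_chr(models, function(strand, tx_start, tx_end,
                                             cds_start, cds_end, exon_count,
                                             exon_starts, exon_ends, ...) {
    s <- exon_starts
    e <- exon_ends
    if (!strand %in% c("+", "-")) {
      return("strand must be + or -")
    }
    if (length(s) != length(e) || length(s) < 1L) {
      return("exon start/end lists differ in length or are empty")
    }
    if (length(s) != exon_count) {
      return("exon list length does not match exonCount")
    }
    if (!(tx_start <= cds_start && cds_start <= cds_end && cds_end <= tx_end)) {
      return("violates tx_start <= cds_start <= cds_end <= tx_end")
    }
    if (any(s >= e)) {
      return("empty or inverted exon interval")
    }
    if (is.unsorted(s, strictly = TRUE)) {
      return("exon starts not strictly ascending")
    }
    if (length(s) > 1L && any(e[-length(e)] > s[-1L])) {
      return("overlapping exons")
    }
    if (s[1L] < tx_start || e[length(e)] > tx_end) {
      return("exon outside transcript span")
    }
    NA_character_
  })

  rejected <- models[!is.na(reason), c("line", "transcript_id")]
  rejected$reason <- reason[!is.na(reason)]
  if (nrow(rejected) > 0L) {
    warn(paste0(
      "rejected ", nrow(rejected), " gene model row(s) at line(s) ",
      paste(rejected$line, collapse = ", ")
    ))
  }
  out <- models[is.na(reason), ]
  out$line <- NULL
  out$exon_count <- NULL
  out <- out[, c(
    "gene_symbol", "transcript_id", "chrom", "strand",
    "tx_start", "tx_end", "cds_start", "cds_end", "exon_starts", "exon_ends"
  )]
  attr(out, "rejected") <- rejected
  out
}

empty_gene_models <- function() {
  tibble::tibble(
    gene_symbol = character(), transcript_id = character(),
    chrom = character(), strand = character(),
    tx_start = integer(), tx_end = integer(),
    cds_start = integer(), cds_end = integer(),
    exon_starts = list(), exon_ends = list()
  )
}

evidence_files <- c(
  "literature.tsv", "cosmic.tsv", "disease.tsv", "process.tsv",
  "census.tsv", "interactions.tsv", "expression.tsv"
)

#' Read per-gene evidence tables from a reference directory
#'
#' Loads the seven local evidence tables that stand in for live database
#' queries: `literature.tsv` (gene, mesh_term, count), `cosmic.tsv`
#' (gene, entries, protein_length), `disease.tsv` (gene, disease_name),
#' `process.tsv` (gene, term), `census.tsv` (gene), `interactions.tsv`
#' (geneA, geneB) and `expression.tsv` (gene plus one column per tissue).
#' All are UTF-8 TSVs with a header row.
#'
#' Every gene appearing in any table gets one row; channels a gene is absent
#' from default to zero counts, empty term lists, `FALSE` flags and a missing
#' expression profile. Literature counts are taken only from rows whose
#' `mesh_term` equals `mesh_term` exactly (no query expansion).
#' `interacts_census` is `TRUE` iff the gene shares an interaction pair, in
#' either order, with a census gene.
#'
#' @param dir Directory containing the seven TSV files.
#' @param mesh_term MeSH term selecting the literature counts.
#' @return A tibble with one row per gene: `gene_symbol`, `pubmed_count`,
#'   `cosmic_count`, `protein_length`, list-columns `disease_names`,
#'   `process_terms`, logicals `is_census`, `interacts_census`, and a
#'   list-column `expression` of named numeric tissue vectors (`NULL` when
#'   the gene has no profile).
#' @export
read_evidence_tables <- function(dir, mesh_term) {
  missing <- evidence_files[!file.exists(file.path(dir, evidence_files))]
  if (length(missing) > 0L) {
    abort(paste0(
      "missing evidence table file(s) in ", dir, ": ",
      paste(missing, collapse = ", ")
    ))
  }
  read1 <- function(name) {
    readr::read_tsv(file.path(dir, name), show_col_types = FALSE,
                    progress = FALSE)
  }
  literature <- read1("literature.tsv")
  cosmic <- read1("cosmic.tsv")
  disease <- read1("disease.tsv")
  process <- read1("process.tsv")
  census <- read1("census.tsv")
  interactions <- read1("interactions.tsv")
  expression <- read1("expression.tsv")

  # column types cannot be guessed from a header-only table
  literature$count <- as.integer(literature$count)
  cosmic$entries <- as.integer(cosmic$entries)
  cosmic$protein_length <- as.integer(cosmic$protein_length)

  if (nrow(cosmic) > 0L && any(cosmic$protein_length <= 0)) {
    bad <- cosmic$gene[cosmic$protein_length <= 0]
    abort(paste0(
      "cosmic.tsv: protein_length must be >= 1 for gene(s) ",
      paste(bad, collapse = ", ")
    ))
  }

  genes <- sort(unique(c(
    literature$gene, cosmic$gene, disease$gene, process$gene,
    census$gene, interactions$geneA, interactions$geneB, expression$gene
  )))
  if (length(genes) == 0L) {
    return(empty_evidence())
  }

  census_genes <- unique(census$gene)
  # symmetric: either side of a pair may be the census partner
  interactors <- unique(c(
    interactions$geneA[interactions$geneB %in% census_genes],
    interactions$geneB[interactions$geneA %in% census_genes]
  ))

  lit <- literature[literature$mesh_term == mesh_term, , drop = FALSE]
  lit <- lit |>
    dplyr::group_by(gene = .data$gene) |>
    dplyr::summarise(pubmed_count = sum(.data$count), .groups = "drop")

  tissues <- setdiff(names(expression), "gene")
  expr_rows <- setNames(
    purrr::map(seq_len(nrow(expression)), function(i) {
      setNames(as.numeric(expression[i, tissues]), tissues)
    }),
    expression$gene
  )

  out <- tibble::tibble(gene_symbol = genes) |>
    dplyr::left_join(
      dplyr::rename(lit, gene_symbol = "gene"), by = "gene_symbol"
    ) |>
    dplyr::left_join(
      dplyr::select(cosmic,
        gene_symbol = "gene", cosmic_count = "entries",
        protein_length = "protein_length"
      ),
      by = "gene_symbol"
    ) |>
    dplyr::mutate(
      pubmed_count = as.integer(coalesce(.data$pubmed_count, 0L)),
      cosmic_count = as.integer(coalesce(.data$cosmic_count, 0L)),
      protein_length = as.integer(coalesce(.data$protein_length, 1L)),
      disease_names = purrr::map(
        .data$gene_symbol,
        ~ sort(unique(disease$disease_name[disease$gene == .x]))
      ),
      process_terms = purrr::map(
        .data$gene_symbol,
        ~ sort(unique(process$term[process$gene == .x]))
      ),
      is_census = .data$gene_symbol %in% census_genes,
      interacts_census = .data$gene_symbol %in% interactors,
      expression = purrr::map(.data$gene_symbol, function(g) {
        if (g %in% names(expr_rows)) expr_rows[[g]] else NULL
      })
    )
  out
}

empty_evidence <- function() {
  tibble::tibble(
    gene_symbol = character(), pubmed_count = integer(),
    cosmic_count = integer(), protein_length = integer(),
    disease_names = list(), process_terms = list(),
    is_census = logical(), interacts_census = logical(),
    expression = list()
  )
}

#' Write an evidence tibble back out as the seven reference TSVs
#'
#' Inverse of [read_evidence_tables()] up to channel defaults: reloading the
#' written directory with the same MeSH term reproduces the evidence tibble
#' exactly. Interaction pairs are re-synthesized as (gene, census partner)
#' pairs, which preserves `interacts_census` though not the original pair
#' list.
#'
#' @param evidence Tibble as returned by [read_evidence_tables()].
#' @param dir Output directory (created if needed).
#' @param mesh_term MeSH term written into `literature.tsv`.
#' @return `dir`, invisibly.
#' @export
write_evidence_tables <- function(evidence, dir, mesh_term) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, name) {
    readr::write_tsv(x, file.path(dir, name), progress = FALSE)
  }
  w(
    tibble::tibble(
      gene = evidence$gene_symbol, mesh_term = mesh_term,
      count = evidence$pubmed_count
    )[evidence$pubmed_count > 0L, ],
    "literature.tsv"
  )
  w(
    tibble::tibble(
      gene = evidence$gene_symbol, entries = evidence$cosmic_count,
      protein_length = evidence$protein_length
    ),
    "cosmic.tsv"
  )
  w(
    tidyr::unnest(
      tibble::tibble(
        gene = evidence$gene_symbol, disease_name = evidence$disease_names
      ),
      "disease_name"
    ),
    "disease.tsv"
  )
  w(
    tidyr::unnest(
      tibble::tibble(
        gene = evidence$gene_symbol, term = evidence$process_terms
      ),
      "term"
    ),
    "process.tsv"
  )
  w(
    tibble::tibble(gene = evidence$gene_symbol[evidence$is_census]),
    "census.tsv"
  )
  census_genes <- evidence$gene_symbol[evidence$is_census]
  partners <- evidence$gene_symbol[evidence$interacts_census]
  pairs <- if (length(partners) > 0L && length(census_genes) > 0L) {
    tibble::tibble(geneA = partners, geneB = census_genes[1L])
  } else {
    tibble::tibble(geneA = character(), geneB = character())
  }
  w(pairs, "interactions.tsv")

  has_expr <- !purrr::map_lgl(evidence$expression, is.null)
  if (any(has_expr)) {
    tissues <- names(evidence$expression[[which(has_expr)[1L]]])
    expr <- tibble::tibble(gene = evidence$gene_symbol[has_expr])
    for (t in tissues) {
      expr[[t]] <- purrr::map_dbl(evidence$expression[has_expr], ~ .x[[t]])
    }
  } else {
    expr <- tibble::tibble(gene = character())
  }
  w(expr, "expression.tsv")
  invisible(dir)
}

score_channels <- c(
  "rarity", "sift_damage", "polyphen_damage", "literature",
  "cosmic", "disease", "function", "zygosity"
)

#' Configure the disease / function focus and scoring parameters
#'
#' Bundles everything the enrichment and scoring steps need to know about the
#' analyst's area of interest: the MeSH term keying the literature counts,
#' substring lists defining the disease and functional focus, per-channel
#' score weights, the allele-frequency ceiling of the rarity ramp, and the
#' cap of the length-normalized COSMIC burden.
#'
#' @param mesh_term MeSH term used to select literature counts.
#' @param disease_focus Character vector of disease-name substrings (matched
#'   case-insensitively). Empty disables the disease channel and filter.
#' @param function_focus Character vector of functional/process term
#'   substrings (matched case-insensitively, ignoring non-alphanumerics).
#'   Empty disables the function channel and filter.
#' @param weights Named numeric vector of per-channel weights over
#'   `r paste(score_channels, collapse = ", ")`. Channels not named keep
#'   weight 1.
#' @param rarity_gmax Allele frequency at and above which the rarity score is
#'   0; must lie in (0, 0.5]. Default 0.05.
#' @param cosmic_cap COSMIC entries per protein residue at which the burden
#'   score saturates at 1. Default 1.
#' @return A list of class `eva_focus`.
#' @seealso [leukemia_focus()] for a ready-made hematological configuration.
#' @export
focus_config <- function(mesh_term = "leukemia",
                         disease_focus = character(),
                         function_focus = character(),
                         weights = NULL,
                         rarity_gmax = 0.05,
                         cosmic_cap = 1.0) {
  stopifnot(
    is.character(mesh_term), length(mesh_term) == 1L,
    is.character(disease_focus), is.character(function_focus)
  )
  if (!is.numeric(rarity_gmax) || rarity_gmax <= 0 || rarity_gmax > 0.5) {
    abort("rarity_gmax must lie in (0, 0.5]")
  }
  if (!is.numeric(cosmic_cap) || cosmic_cap <= 0) {
    abort("cosmic_cap must be > 0")
  }
  w <- setNames(rep(1.0, length(score_channels)), score_channels)
  if (!is.null(weights)) {
    unknown <- setdiff(names(weights), score_channels)
    if (length(unknown) > 0L) {
      abort(paste0("unknown score channel(s): ", paste(unknown, collapse = ", ")))
    }
    w[names(weights)] <- as.numeric(weights)
  }
  structure(
    list(
      mesh_term = mesh_term,
      disease_focus = disease_focus,
      function_focus = function_focus,
      weights = w,
      rarity_gmax = rarity_gmax,
      cosmic_cap = cosmic_cap
    ),
    class = "eva_focus"
  )
}

#' Hematological focus configuration
#'
#' The focus used by the shipped worked example: literature keyed to the
#' "leukemia" MeSH term, disease focus on myeloid/lymphoid neoplasms, and a
#' functional focus spanning signaling, proliferation, apoptosis, immune
#' function, chromatin and DNA repair.
#'
#' @inheritParams focus_config
#' @return A list of class `eva_focus`.
#' @export
leukemia_focus <- function(weights = NULL, rarity_gmax = 0.05,
                           cosmic_cap = 1.0) {
  focus_config(
    mesh_term = "leukemia",
    disease_focus = c(
      "Myeloprolif", "Leukemia", "Lymphoma", "Lymphocytosis", "Myelodysplas"
    ),
    function_focus = c(
      "SignalTransduction", "CellAdhesion", "SignalingPathway",
      "Differentiation", "CellProliferation", "RegulationOfTranscription",
      "Blood", "Apoptosis", "InflammatoryResponse", "Immune", "Chromatin",
      "SignalingCascade", "CellCycle", "CellDivision", "Mitosis",
      "Hemopoiesis", "B-cell", "Methylation", "Telomer", "DNARepair",
      "migration", "kappa", "SurfaceReceptor", "T-cell", "DefenceResponse",
      "DNADamage", "Phosporylation"
    ),
    weights = weights,
    rarity_gmax = rarity_gmax,
    cosmic_cap = cosmic_cap
  )
}
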