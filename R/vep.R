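#' Parse VEP default tabular output
#'
#' Reads the Variant Effect Predictor "default" text output (run with scores,
#' not predictions) and aggregates the per-transcript rows into one record
#' per (variant key, gene): SIFT is the minimum over transcripts and PolyPhen
#' the maximum (the most damaging transcript in each convention),
#' consequences are the union of terms, GMAF is taken where reported, and
#' the amino-acid change is the lexicographically smallest `ref/alt` pair
#' among rows that carry one — a deterministic choice that does not depend
#' on row order.
#'
#' The reference allele is recovered from the `#Uploaded_variation` column
#' (`chrom_pos_ref/alt`, the identifier VEP assigns to pileup-style input).
#'
#' @param path Path to a VEP default-format file. `##` comment lines are
#'   skipped; the `#Uploaded_variation ...` header is required.
#' @return A tibble with one row per (variant, gene): `chrom`, `pos`, `ref`,
#'   `alt`, `gene_symbol`, list-column `consequences`, `sift`, `polyphen`,
#'   `gmaf` (all `NA` when unreported), `existing_id`, `aa_ref`, `aa_alt`.
#' @export
read_vep <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("VEP output file not found: ", path))
  }
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^##", lines) & nzchar(lines)]
  if (length(lines) == 0L || !grepl("^#?Uploaded_variation\t", lines[1L])) {
    abort("not VEP default tabular output: missing #Uploaded_variation header")
  }
  header <- strsplit(sub("^#", "", lines[1L]), "\t", fixed = TRUE)[[1L]]
  if (length(lines) == 1L) {
    return(empty_vep())
  }
  df <- readr::read_tsv(
    I(lines[-1L]),
    col_names = header, col_types = readr::cols(.default = "c"),
    progress = FALSE
  )
  required <- c(
    "Uploaded_variation", "Location", "Allele", "Gene", "Consequence",
    "Amino_acids", "Existing_variation", "Extra"
  )
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    abort(paste0(
      "VEP output lacks required column(s): ", paste(missing, collapse = ", ")
    ))
  }

  loc <- stringr::str_match(df$Location, "^([^:]+):(\\d+)")
  uv <- stringr::str_match(df$Uploaded_variation, "^(.+)_(\\d+)_([ACGT])/([ACGT])$")
  ref <- uv[, 4L]
  if (anyNA(ref)) {
    warn(paste0(
      sum(is.na(ref)),
      " VEP row(s) lack a parseable chrom_pos_ref/alt identifier; ",
      "reference allele recorded as NA"
    ))
  }

  extra <- purrr::map(df$Extra, parse_vep_extra)
  out <- tibble::tibble(
    chrom = loc[, 2L],
    pos = as.integer(loc[, 3L]),
    ref = ref,
    alt = df$Allele,
    gene_symbol = df$Gene,
    consequence = df$Consequence,
    amino_acids = df$Amino_acids,
    existing = df$Existing_variation,
    sift = purrr::map_dbl(extra, "SIFT"),
    polyphen = purrr::map_dbl(extra, "PolyPhen"),
    gmaf = purrr::map_dbl(extra, "GMAF")
  )
  bad_pos <- is.na(out$pos)
  if (any(bad_pos)) {
    warn(paste0(sum(bad_pos), " VEP row(s) with unparseable Location dropped"))
    out <- out[!bad_pos, , drop = FALSE]
  }

  out |>
    dplyr::group_by(
      .data$chrom, .data$pos, .data$ref, .data$alt, .data$gene_symbol
    ) |>
    dplyr::summarise(
      consequences = list(sort(unique(unlist(
        strsplit(.data$consequence, "[,&]")
      )))),
      sift = safe_min(.data$sift),
      polyphen = safe_max(.data$polyphen),
      gmaf = safe_min(.data$gmaf),
      existing_id = {
        ids <- setdiff(.data$existing[!is.na(.data$existing)], "-")
        ids <- sort(unique(unlist(strsplit(ids, ",", fixed = TRUE))))
        if (length(ids) == 0L) NA_character_ else ids[1L]
      },
      aa_change = {
        aa <- .data$amino_acids
        aa <- aa[!is.na(aa) & aa != "-" & grepl("^[A-Za-z*]+/[A-Za-z*]+$", aa)]
        if (length(aa) == 0L) NA_character_ else sort(aa)[1L]
      },
      .groups = "drop"
    ) |>
    dplyr::mutate(
      aa_ref = ifelse(is.na(.data$aa_change), NA_character_,
        sub("/.*$", "", .data$aa_change)
      ),
      aa_alt = ifelse(is.na(.data$aa_change), NA_character_,
        sub("^.*/", "", .data$aa_change)
      )
    ) |>
    dplyr::select(-"aa_change")
}

empty_vep <- function() {
  tibble::tibble(
    chrom = character(), pos = integer(), ref = character(),
    alt = character(), gene_symbol = character(), consequences = list(),
    sift = double(), polyphen = double(), gmaf = double(),
    existing_id = character(), aa_ref = character(), aa_alt = character()
  )
}

safe_min <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) NA_real_ else min(x)
}

safe_max <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) NA_real_ else max(x)
}

# Parse the semicolon-separated key=value Extra column; malformed pairs are
# skipped with a warning. GMAF values of the form "C:0.0041" keep the part
# after the colon.
parse_vep_extra <- function(x) {
  out <- c(SIFT = NA_real_, PolyPhen = NA_real_, GMAF = NA_real_)
  if (is.na(x) || x == "-" || !nzchar(x)) {
    return(out)
  }
  pairs <- strsplit(x, ";", fixed = TRUE)[[1L]]
  pairs <- pairs[nzchar(pairs)]
  for (p in pairs) {
    eq <- regexpr("=", p, fixed = TRUE)
    if (eq < 1L) {
      warn(paste0("skipping unparseable VEP Extra pair: '", p, "'"))
      next
    }
    key <- substr(p, 1L, eq - 1L)
    val <- substr(p, eq + 1L, nchar(p))
    if (key %in% names(out)) {
      val <- sub("^.*:", "", val)
      num <- suppressWarnings(as.numeric(val))
      if (is.na(num)) {
        warn(paste0("skipping non-numeric VEP Extra value: '", p, "'"))
      } else {
        out[[key]] <- num
      }
    }
  }
  out
}

aa_polarity_class <- c(
  A = "nonpolar", V = "nonpolar", L = "nonpolar", I = "nonpolar",
  P = "nonpolar", F = "nonpolar", M = "nonpolar", W = "nonpolar",
  G = "nonpolar", C = "nonpolar",
  S = "polar", T = "polar", Y = "polar", N = "polar", Q = "polar",
  K = "charged", R = "charged", H = "charged", D = "charged", E = "charged"
)

#' Classify the polarity change of an amino-acid substitution
#'
#' Uses three side-chain classes — nonpolar (A V L I P F M W G C),
#' polar-uncharged (S T Y N Q) and charged (K R H D E; histidine counted as
#' charged). Substitutions within a class are `"none"`; nonpolar to
#' polar/charged is `"gain"`; polar/charged to nonpolar is `"loss"`; polar
#' to charged or back is `"swap"`. Missing input gives `NA`; an unknown
#' letter gives `NA` with a warning.
#'
#' @param ref_aa,alt_aa Single-letter amino-acid codes (vectorized).
#' @return Character vector over `none`, `gain`, `loss`, `swap`, `NA`.
#' @examples
#' classify_polarity("R", "W") # loss
#' classify_polarity("S", "K") # swap
#' @export
classify_polarity <- function(ref_aa, alt_aa) {
  ref_cl <- unname(aa_polarity_class[toupper(ref_aa)])
  alt_cl <- unname(aa_polarity_class[toupper(alt_aa)])
  known <- is.na(ref_aa) | is.na(alt_aa) | (!is.na(ref_cl) & !is.na(alt_cl))
  if (any(!known)) {
    warn(paste0(
      "unknown amino-acid letter(s); polarity left unclassified for ",
      sum(!known), " substitution(s)"
    ))
  }
  dplyr::case_when(
    is.na(ref_cl) | is.na(alt_cl) ~ NA_character_,
    ref_cl == alt_cl ~ "none",
    ref_cl == "nonpolar" ~ "gain",
    alt_cl == "nonpolar" ~ "loss",
    TRUE ~ "swap"
  )
}

#' Join VEP annotations with called variants and gene evidence
#'
#' Inner-joins VEP records and called variants on the full variant key
#' (chrom, pos, ref, alt), so each enriched row carries both the predictor
#' scores and the call's zygosity and read support. The per-gene evidence
#' bundle is attached by the VEP gene symbol; genes absent from the evidence
#' tables get empty defaults (zero counts, protein length 1, no terms, no
#' census status, no expression profile). A polarity-change class is derived
#' from the amino-acid substitution. Unmatched rows on either side are not
#' silently discarded: their counts are attached as the `"reconciliation"`
#' attribute.
#'
#' @param annotations Tibble from [read_vep()].
#' @param variants Variant tibble (typically the coding subset from
#'   [find_coding()]).
#' @param evidence Evidence tibble from [read_evidence_tables()].
#' @param focus A [focus_config()] (carried through to scoring; not used in
#'   the join itself).
#' @return A tibble with one row per joined (variant, gene): variant fields,
#'   VEP fields, evidence fields and `polarity_change`.
#' @export
enrich_variants <- function(annotations, variants, evidence,
                            focus = focus_config()) {
  stopifnot(inherits(focus, "eva_focus"))
  drop_cols <- intersect(c("genes", "n_genes", "intergenic"), names(variants))
  v <- variants[, setdiff(names(variants), drop_cols), drop = FALSE]
  joined <- dplyr::inner_join(
    annotations, v,
    by = c("chrom", "pos", "ref", "alt")
  )
  if (nrow(joined) == 0L && nrow(annotations) > 0L && nrow(v) > 0L) {
    abort(paste0(
      "no VEP annotation matched any called variant; if one input uses ",
      "'chr1' naming and the other '1', re-read with normalize_chrom"
    ))
  }
  ann_keys <- variant_key(
    annotations$chrom, annotations$pos, annotations$ref, annotations$alt
  )
  var_keys <- variant_key(v$chrom, v$pos, v$ref, v$alt)
  reconciliation <- c(
    n_annotations = nrow(annotations),
    n_variants = nrow(v),
    n_joined = nrow(joined),
    n_unmatched_annotations = sum(!ann_keys %in% var_keys),
    n_unmatched_variants = sum(!var_keys %in% ann_keys)
  )

  out <- dplyr::left_join(joined, evidence, by = "gene_symbol")
  out <- out |>
    dplyr::mutate(
      pubmed_count = as.integer(coalesce(.data$pubmed_count, 0L)),
      cosmic_count = as.integer(coalesce(.data$cosmic_count, 0L)),
      protein_length = as.integer(coalesce(.data$protein_length, 1L)),
      disease_names = purrr::map(.data$disease_names, ~ .x %||% character()),
      process_terms = purrr::map(.data$process_terms, ~ .x %||% character()),
      is_census = coalesce(.data$is_census, FALSE),
      interacts_census = coalesce(.data$interacts_census, FALSE),
      polarity_change = classify_polarity(.data$aa_ref, .data$aa_alt)
    )
  attr(out, "reconciliation") <- reconciliation
  out
}
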