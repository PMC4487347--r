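#' Read called SNVs from a VCF file
#'
#' Reads a VCF 4.x file and returns the biallelic SNV records as a tidy
#' variant table. Multiallelic records are split into one row per alternate
#' allele and each split record is re-checked for SNV-ness (single-base ref
#' and alt, `ref != alt`). Records whose FILTER field is anything other than
#' `PASS` or `.` are dropped unless `keep_filtered = TRUE`. Zygosity is taken
#' from the genotype: two copies of the alternate allele give `hom_alt`, one
#' gives `het`, a missing genotype gives `unknown`; an alternate allele with
#' zero copies in the sample's genotype is dropped as not called in that
#' sample. Read support is taken from the AD genotype field when present.
#'
#' @param path Path to an uncompressed or bgzipped VCF.
#' @param sample_id Genotype column to read, and the label attached to the
#'   returned variants. With a single-sample VCF it may be omitted; with a
#'   multi-sample VCF it must name one of the genotype columns (an error
#'   lists the available ones). For a site-only VCF it is just the label.
#' @param origin Either `"germline_called"` (default) or `"somatic_called"`.
#' @param keep_filtered Keep records failing FILTER? Default `FALSE`.
#' @param normalize_chrom `"none"` (default), `"strip"` (chrN -> N) or
#'   `"add"` (N -> chrN), applied at read time for cross-file joins.
#' @return A tibble with columns `chrom`, `pos` (1-based), `ref`, `alt`,
#'   `sample_id`, `origin`, `zygosity`, `quality`, `ref_reads`, `alt_reads`.
#'   A summary of skipped records (filtered, non-SNV, uncalled alleles) is
#'   attached as the `"skipped"` attribute.
#' @export
read_vcf <- function(path, sample_id = NULL,
                     origin = c("germline_called", "somatic_called"),
                     keep_filtered = FALSE,
                     normalize_chrom = c("none", "strip", "add")) {
  origin <- match.arg(origin)
  normalize_chrom <- match.arg(normalize_chrom)
  if (!file.exists(path)) {
    abort(paste0("VCF file not found: ", path))
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (!is.null(fix) && is.null(dim(fix))) {
    # a single-record VCF yields a bare named vector
    fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  }
  if (is.null(fix) || nrow(fix) == 0L) {
    out <- empty_variants()
    attr(out, "skipped") <- c(filtered = 0L, non_snv = 0L, uncalled = 0L)
    return(out)
  }

  samples <- colnames(v@gt)
  samples <- samples[samples != "FORMAT"]
  gt_vec <- rep(NA_character_, nrow(fix))
  ad_vec <- rep(NA_character_, nrow(fix))
  if (length(samples) > 0L) {
    if (is.null(sample_id)) {
      if (length(samples) > 1L) {
        abort(paste0(
          "VCF has multiple samples; pass sample_id as one of: ",
          paste(samples, collapse = ", ")
        ))
      }
      sample_id <- samples[1L]
    } else if (!sample_id %in% samples) {
      abort(paste0(
        "sample '", sample_id, "' not in VCF; available: ",
        paste(samples, collapse = ", ")
      ))
    }
    gt_vec <- vcfR::extract.gt(v, element = "GT")[, sample_id]
    ad <- tryCatch(vcfR::extract.gt(v, element = "AD"),
      error = function(e) NULL
    )
    if (!is.null(ad)) ad_vec <- ad[, sample_id]
  } else if (is.null(sample_id)) {
    sample_id <- basename(path)
  }

  df <- tibble::tibble(
    chrom = normalize_chrom_names(unname(fix[, "CHROM"]), normalize_chrom),
    pos = as.integer(fix[, "POS"]),
    ref = unname(fix[, "REF"]),
    alt_field = unname(fix[, "ALT"]),
    quality = suppressWarnings(as.numeric(fix[, "QUAL"])),
    filter = unname(fix[, "FILTER"]),
    gt = unname(gt_vec),
    ad = unname(ad_vec)
  )

  pass <- keep_filtered | is.na(df$filter) | df$filter %in% c("PASS", ".")
  n_filtered <- sum(!pass)
  df <- df[pass, , drop = FALSE]

  df$alts <- strsplit(df$alt_field, ",", fixed = TRUE)
  df$alt_index <- purrr::map(df$alts, seq_along)
  long <- tidyr::unnest(df, c("alts", "alt_index"))
  long <- dplyr::rename(long, alt = "alts")

  snv <- is_snv_allele(long$ref) & is_snv_allele(long$alt) &
    long$ref != long$alt
  n_non_snv <- sum(!snv)
  long <- long[snv, , drop = FALSE]

  gt_tokens <- strsplit(gsub("|", "/", long$gt, fixed = TRUE), "/", fixed = TRUE)
  copies <- purrr::map2_int(gt_tokens, long$alt_index, function(tok, i) {
    if (length(tok) == 0L || all(is.na(tok)) || any(tok == ".")) {
      return(NA_integer_)
    }
    sum(tok == as.character(i))
  })
  zyg <- dplyr::case_when(
    is.na(copies) ~ "unknown",
    copies >= 2L ~ "hom_alt",
    copies == 1L ~ "het",
    TRUE ~ "uncalled"
  )
  n_uncalled <- sum(zyg == "uncalled")
  keep <- zyg != "uncalled"
  long <- long[keep, , drop = FALSE]
  zyg <- zyg[keep]

  ad_tokens <- strsplit(long$ad, ",", fixed = TRUE)
  ref_reads <- purrr::map_int(ad_tokens, function(tok) {
    if (length(tok) < 1L || is.na(tok[1L])) NA_integer_ else
      suppressWarnings(as.integer(tok[1L]))
  })
  alt_reads <- purrr::map2_int(ad_tokens, long$alt_index, function(tok, i) {
    if (length(tok) < i + 1L) NA_integer_ else
      suppressWarnings(as.integer(tok[i + 1L]))
  })

  out <- tibble::tibble(
    chrom = long$chrom, pos = long$pos, ref = long$ref, alt = long$alt,
    sample_id = sample_id, origin = origin, zygosity = zyg,
    quality = long$quality, ref_reads = ref_reads, alt_reads = alt_reads
  )
  dup <- duplicated(variant_key(out$chrom, out$pos, out$ref, out$alt))
  if (any(dup)) {
    warn(paste0("dropping ", sum(dup), " duplicate variant record(s)"))
    out <- out[!dup, , drop = FALSE]
  }
  attr(out, "skipped") <- c(
    filtered = n_filtered, non_snv = n_non_snv, uncalled = n_uncalled
  )
  out
}

#' Read somatic SNVs from a MuTect call-stats file
#'
#' Parses the tab-separated MuTect call-stats format (header lines starting
#' with `##` are skipped). Rows with `judgement == "KEEP"` are retained by
#' default; `keep_all = TRUE` keeps REJECT rows too. Non-SNV rows are always
#' dropped. If a `tumor_f` column is present, a tumor allele fraction of at
#' least 0.9 is reported as `hom_alt`, otherwise `het`.
#'
#' @param path Path to a call-stats TSV with at least columns `contig`,
#'   `position`, `ref_allele`, `alt_allele`, `judgement`.
#' @param sample_id Label attached to the returned variants.
#' @param keep_all Retain rows regardless of judgement? Default `FALSE`.
#' @param normalize_chrom See [read_vcf()].
#' @return A tibble with the same columns as [read_vcf()], with
#'   `origin = "somatic_called"`.
#' @export
read_mutect <- function(path, sample_id, keep_all = FALSE,
                        normalize_chrom = c("none", "strip", "add")) {
  normalize_chrom <- match.arg(normalize_chrom)
  if (!file.exists(path)) {
    abort(paste0("MuTect call-stats file not found: ", path))
  }
  df <- readr::read_tsv(path, comment = "##", show_col_types = FALSE,
                        progress = FALSE)
  required <- c("contig", "position", "ref_allele", "alt_allele", "judgement")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    abort(paste0(
      "MuTect call-stats file lacks required column(s): ",
      paste(missing, collapse = ", ")
    ))
  }
  if (!keep_all) {
    df <- df[df$judgement == "KEEP", , drop = FALSE]
  }
  snv <- is_snv_allele(df$ref_allele) & is_snv_allele(df$alt_allele) &
    df$ref_allele != df$alt_allele
  n_non_snv <- sum(!snv)
  df <- df[snv, , drop = FALSE]

  zyg <- rep("het", nrow(df))
  if ("tumor_f" %in% names(df)) {
    zyg[!is.na(df$tumor_f) & df$tumor_f >= 0.9] <- "hom_alt"
  }
  out <- tibble::tibble(
    chrom = normalize_chrom_names(as.character(df$contig), normalize_chrom),
    pos = as.integer(df$position),
    ref = df$ref_allele,
    alt = df$alt_allele,
    sample_id = sample_id,
    origin = "somatic_called",
    zygosity = zyg,
    quality = NA_real_,
    ref_reads = if ("t_ref_count" %in% names(df)) {
      as.integer(df$t_ref_count)
    } else {
      NA_integer_
    },
    alt_reads = if ("t_alt_count" %in% names(df)) {
      as.integer(df$t_alt_count)
    } else {
      NA_integer_
    }
  )
  dup <- duplicated(variant_key(out$chrom, out$pos, out$ref, out$alt))
  if (any(dup)) {
    warn(paste0("dropping ", sum(dup), " duplicate variant record(s)"))
    out <- out[!dup, , drop = FALSE]
  }
  attr(out, "skipped") <- c(non_snv = n_non_snv)
  out
}

#' Write a variant set in pileup format for VEP upload
#'
#' Writes one line per SNV — `chrom TAB pos TAB ref TAB alt`, 1-based
#' position, explicit alternate allele — sorted by (chrom, pos, ref, alt)
#' with a locale-independent sort, so the output is byte-stable across runs.
#' Zygosity and read support are intentionally not encoded; they are
#' rejoined downstream from the variant table itself.
#'
#' @param variants A variant tibble ([read_vcf()] schema or any tibble with
#'   `chrom`, `pos`, `ref`, `alt`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pileup <- function(variants, path) {
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(variants)))
  ord <- order_radix(variants$chrom, variants$pos, variants$ref, variants$alt)
  v <- variants[ord, , drop = FALSE]
  lines <- paste(v$chrom, v$pos, v$ref, v$alt, sep = "\t")
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a 4-column pileup file back into a variant table
#'
#' @param path Pileup file written by [write_pileup()].
#' @param sample_id Label for the returned variants.
#' @return A variant tibble with `zygosity = "unknown"` and no read support
#'   (the pileup format carries neither).
#' @export
read_pileup <- function(path, sample_id = "pileup") {
  df <- readr::read_tsv(
    path,
    col_names = c("chrom", "pos", "ref", "alt"),
    col_types = readr::cols(
      chrom = readr::col_character(), pos = readr::col_integer(),
      ref = readr::col_character(), alt = readr::col_character()
    ),
    progress = FALSE
  )
  tibble::tibble(
    chrom = df$chrom, pos = df$pos, ref = df$ref, alt = df$alt,
    sample_id = sample_id, origin = "germline_called", zygosity = "unknown",
    quality = NA_real_, ref_reads = NA_integer_, alt_reads = NA_integer_
  )
}

#' Write any variant-like tibble as a TSV
#'
#' List-columns (overlapping genes, consequence terms, ...) are flattened to
#' comma-joined strings; the `expression` list-column, if present, is
#' dropped. Output is byte-stable for a fixed input.
#'
#' @param x A tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variants_tsv <- function(x, path) {
  flat <- flatten_list_cols(x)
  readr::write_tsv(flat, path, progress = FALSE)
  invisible(path)
}

flatten_list_cols <- function(x) {
  x <- x[, setdiff(names(x), "expression"), drop = FALSE]
  is_list <- purrr::map_lgl(x, is.list)
  for (nm in names(x)[is_list]) {
    x[[nm]] <- purrr::map_chr(x[[nm]], function(v) {
      if (length(v) == 0L) "" else paste(v, collapse = ",")
    })
  }
  x
}
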