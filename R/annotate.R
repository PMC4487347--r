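#' Map variants onto gene models
#'
#' Assigns each variant the gene symbols whose transcript span contains it.
#' A variant at 1-based position `pos` maps to gene `G` iff its 0-based
#' position lies in `[tx_start, tx_end)` of at least one transcript of `G`
#' (UTRs and introns included; strand is ignored). The genes list is
#' deduplicated and sorted. Variants overlapping no transcript are flagged
#' `intergenic`; mapped and intergenic rows together partition the input.
#'
#' @param variants A variant tibble (see [read_vcf()]).
#' @param models Gene models from [read_gene_models()].
#' @return The input tibble with added columns `genes` (list of gene
#'   symbols), `n_genes` and `intergenic`.
#' @seealso [find_coding()] for the subsequent narrowing to coding
#'   positions, [intersect_variants()] for pseudo-germline construction.
#' @export
annotate_variants <- function(variants, models) {
  genes <- rep(list(character()), nrow(variants))
  if (nrow(models) > 0L && nrow(variants) > 0L) {
    tx <- GenomicRanges::GRanges(
      seqnames = models$chrom,
      ranges = IRanges::IRanges(
        start = models$tx_start + 1L,
        end = models$tx_end
      )
    )
    hits <- overlap_hits(variants, tx)
    if (length(hits$q) > 0L) {
      by_var <- split(models$gene_symbol[hits$s], hits$q)
      idx <- as.integer(names(by_var))
      genes[idx] <- purrr::map(by_var, ~ sort(unique(.x)))
    }
  }
  out <- variants
  out$genes <- genes
  out$n_genes <- lengths(genes)
  out$intergenic <- out$n_genes == 0L
  out
}

# findOverlaps between 1-based variant positions and a GRanges subject;
# returns query/subject hit indices.
overlap_hits <- function(variants, subject) {
  q <- GenomicRanges::GRanges(
    seqnames = variants$chrom,
    ranges = IRanges::IRanges(start = variants$pos, end = variants$pos)
  )
  hits <- suppressWarnings(GenomicRanges::findOverlaps(q, subject))
  list(q = S4Vectors::queryHits(hits), s = S4Vectors::subjectHits(hits))
}

#' Select coding variants
#'
#' Keeps the mapped variants whose 0-based position `p` satisfies, for at
#' least one transcript of one of its genes, both `cds_start <= p < cds_end`
#' and `exon_start_i <= p < exon_end_i` for some exon `i` — i.e. positions in
#' translated exonic sequence. UTR-exonic and intronic positions are
#' excluded. Input order is preserved.
#'
#' @param annotated Output of [annotate_variants()] against the same models.
#' @param models The gene models used for annotation.
#' @return The coding subset of `annotated`, with a `coding` column
#'   (all `TRUE`).
#' @export
find_coding <- function(annotated, models) {
  coding <- is_coding_position(annotated, models)
  out <- annotated[coding, , drop = FALSE]
  out$coding <- TRUE
  out
}

# Logical vector: does each variant fall inside exon-intersect-CDS of any
# transcript?
is_coding_position <- function(variants, models) {
  if (nrow(variants) == 0L) {
    return(logical(0L))
  }
  cr <- coding_regions(models)
  if (nrow(cr) == 0L) {
    return(rep(FALSE, nrow(variants)))
  }
  subject <- GenomicRanges::GRanges(
    seqnames = cr$chrom,
    ranges = IRanges::IRanges(start = cr$start0 + 1L, end = cr$end0)
  )
  hits <- overlap_hits(variants, subject)
  seq_len(nrow(variants)) %in% hits$q
}

# All exon-intersect-CDS intervals over all transcripts, 0-based half-open.
coding_regions <- function(models) {
  if (nrow(models) == 0L) {
    return(tibble::tibble(
      chrom = character(), start0 = integer(), end0 = integer(),
      gene_symbol = character()
    ))
  }
  rows <- purrr::pmap(
    list(
      models$chrom, models$cds_start, models$cds_end,
      models$exon_starts, models$exon_ends, models$gene_symbol
    ),
    function(chrom, cds_start, cds_end, ex_s, ex_e, gene) {
      s <- pmax(ex_s, cds_start)
      e <- pmin(ex_e, cds_end)
      keep <- s < e
      tibble::tibble(
        chrom = chrom, start0 = s[keep], end0 = e[keep], gene_symbol = gene
      )
    }
  )
  dplyr::bind_rows(rows)
}

#' Intersect variant sets into a pseudo-germline set
#'
#' Returns the variants whose key (chrom, pos, ref, alt) occurs in every
#' input set — e.g. the calls shared by both members of a twin pair, treated
#' as germline in the absence of a true normal sample. Sample identity,
#' origin and zygosity play no part in the matching; row metadata is taken
#' from the first set. Output is sorted by (chrom, pos, ref, alt).
#'
#' @param sets A list of at least two variant tibbles.
#' @return A tibble of shared variants with the first set's metadata.
#' @export
intersect_variants <- function(sets) {
  if (!is.list(sets) || length(sets) < 2L) {
    abort("intersect_variants() needs a list of at least 2 variant sets")
  }
  keys <- purrr::map(sets, ~ variant_key(.x$chrom, .x$pos, .x$ref, .x$alt))
  shared <- purrr::reduce(keys, intersect)
  first_set <- sets[[1L]]
  out <- first_set[keys[[1L]] %in% shared, , drop = FALSE]
  ord <- order_radix(out$chrom, out$pos, out$ref, out$alt)
  out[ord, , drop = FALSE]
}
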