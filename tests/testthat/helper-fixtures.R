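# In-code fixture builders shared across tests.

make_model <- function(gene = "GENEA", tx = "NM_1", chrom = "chr1",
                       strand = "+", tx_start = 100L, tx_end = 500L,
                       cds_start = 150L, cds_end = 450L,
                       exon_starts = c(100L, 300L),
                       exon_ends = c(200L, 500L)) {
  tibble::tibble(
    gene_symbol = gene, transcript_id = tx, chrom = chrom, strand = strand,
    tx_start = tx_start, tx_end = tx_end,
    cds_start = cds_start, cds_end = cds_end,
    exon_starts = list(as.integer(exon_starts)),
    exon_ends = list(as.integer(exon_ends))
  )
}

make_variants <- function(chrom, pos, ref = "A", alt = "G",
                          sample_id = "s1", origin = "germline_called",
                          zygosity = "het") {
  n <- max(length(chrom), length(pos))
  tibble::tibble(
    chrom = rep_len(chrom, n), pos = as.integer(rep_len(pos, n)),
    ref = rep_len(ref, n), alt = rep_len(alt, n),
    sample_id = rep_len(sample_id, n), origin = rep_len(origin, n),
    zygosity = rep_len(zygosity, n), quality = NA_real_,
    ref_reads = NA_integer_, alt_reads = NA_integer_
  )
}

write_test_vcf <- function(records, path, sample = "s1") {
  # records: data.frame with chrom, pos, ref, alt, and optionally qual,
  # filter, gt, ad
  qual <- records$qual %||% rep(60L, nrow(records))
  filt <- records$filter %||% rep("PASS", nrow(records))
  gt <- records$gt %||% rep("0/1", nrow(records))
  has_gt <- !all(is.na(gt))
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste0(
      "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
      if (has_gt) paste0("\tFORMAT\t", sample)
    )
  )
  fmt <- if (!is.null(records$ad)) "GT:AD" else "GT"
  body <- vapply(seq_len(nrow(records)), function(i) {
    line <- paste(records$chrom[i], records$pos[i], ".", records$ref[i],
      records$alt[i], qual[i], filt[i], ".",
      sep = "\t"
    )
    if (has_gt) {
      g <- if (is.na(gt[i])) "./." else gt[i]
      sample_field <- if (!is.null(records$ad)) {
        paste0(g, ":", records$ad[i])
      } else {
        g
      }
      line <- paste(line, fmt, sample_field, sep = "\t")
    }
    line
  }, character(1L))
  writeLines(c(header, body), path)
  path
}

write_test_vep <- function(rows, path) {
  # rows: data.frame with chrom, pos, ref, alt, gene, feature, consequence,
  # amino_acids, existing, extra
  header <- paste0(
    "#",
    paste("Uploaded_variation", "Location", "Allele", "Gene", "Feature",
      "Feature_type", "Consequence", "cDNA_position", "CDS_position",
      "Protein_position", "Amino_acids", "Codons", "Existing_variation",
      "Extra",
      sep = "\t"
    )
  )
  body <- vapply(seq_len(nrow(rows)), function(i) {
    paste(
      paste0(rows$chrom[i], "_", rows$pos[i], "_", rows$ref[i], "/",
             rows$alt[i]),
      paste0(rows$chrom[i], ":", rows$pos[i]),
      rows$alt[i], rows$gene[i], rows$feature[i], "Transcript",
      rows$consequence[i], "-", "-", "-",
      rows$amino_acids[i], "-", rows$existing[i], rows$extra[i],
      sep = "\t"
    )
  }, character(1L))
  writeLines(c("## synthetic VEP-style output", header, body), path)
  path
}

# Minimal enriched row for scoring tests.
make_enriched <- function(gmaf = NA_real_, sift = NA_real_,
                          polyphen = NA_real_, pubmed = 0L, cosmic = 0L,
                          protein_length = 100L,
                          diseases = character(), terms = character(),
                          is_census = FALSE, interacts_census = FALSE,
                          zygosity = "het", chrom = "chr1", pos = 100L,
                          ref = "A", alt = "G", gene = "GENEA") {
  tibble::tibble(
    chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
    gene_symbol = gene, consequences = list("missense_variant"),
    sift = sift, polyphen = polyphen, gmaf = gmaf,
    existing_id = NA_character_, aa_ref = NA_character_,
    aa_alt = NA_character_, sample_id = "s1", origin = "somatic_called",
    zygosity = zygosity, quality = NA_real_, ref_reads = NA_integer_,
    alt_reads = NA_integer_,
    pubmed_count = as.integer(pubmed), cosmic_count = as.integer(cosmic),
    protein_length = as.integer(protein_length),
    disease_names = list(diseases), process_terms = list(terms),
    is_census = is_census, interacts_census = interacts_census,
    expression = list(NULL), polarity_change = NA_character_
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
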