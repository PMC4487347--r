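# Independent brute-force oracles: plain per-variant scans over every
# transcript, written without reference to the package's interval machinery.

# Gene symbols whose transcript span [tx_start, tx_end) (0-based half-open)
# contains each variant's 0-based position.
oracle_map_genes <- function(variants, models) {
  lapply(seq_len(nrow(variants)), function(i) {
    p0 <- variants$pos[i] - 1L
    hit <- models$chrom == variants$chrom[i] &
      models$tx_start <= p0 & p0 < models$tx_end
    sort(unique(models$gene_symbol[hit]))
  })
}

# TRUE iff some transcript has the 0-based position inside its CDS and
# inside one of its exons. Per-variant scan over every transcript's CDS,
# then an exon check on the candidates.
oracle_is_coding <- function(variants, models) {
  vapply(seq_len(nrow(variants)), function(i) {
    p0 <- variants$pos[i] - 1L
    cand <- which(
      models$chrom == variants$chrom[i] &
        models$cds_start <= p0 & p0 < models$cds_end
    )
    for (j in cand) {
      if (any(models$exon_starts[[j]] <= p0 & p0 < models$exon_ends[[j]])) {
        return(TRUE)
      }
    }
    FALSE
  }, logical(1L))
}

vkey <- function(x) paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")
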