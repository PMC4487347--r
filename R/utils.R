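# Internal helpers shared across modules.

# Canonical variant key: chrom, 1-based position, ref allele, alt allele.
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

# Locale-independent ordering (radix) so sorted output is byte-stable
# across machines and sessions.
order_radix <- function(...) order(..., method = "radix")

snv_bases <- c("A", "C", "G", "T")

is_snv_allele <- function(x) {
  !is.na(x) & nchar(x) == 1L & x %in% snv_bases
}

# Case-insensitive substring match of any `phrase` inside any element of
# `items`; returns the number of items matched.
n_phrase_matches <- function(items, phrases) {
  if (length(items) == 0L || length(phrases) == 0L) {
    return(0L)
  }
  lowered <- tolower(items)
  hit <- rep(FALSE, length(lowered))
  for (p in tolower(phrases)) {
    hit <- hit | stringr::str_detect(lowered, stringr::fixed(p))
  }
  sum(hit)
}

# Same idea but both sides are squashed to lowercase alphanumerics first,
# so "B-cell" matches "B cell receptor signaling".
n_term_matches <- function(items, phrases) {
  if (length(items) == 0L || length(phrases) == 0L) {
    return(0L)
  }
  squash <- function(x) gsub("[^a-z0-9]", "", tolower(x))
  lowered <- squash(items)
  phr <- squash(phrases)
  phr <- phr[nzchar(phr)]
  if (length(phr) == 0L) {
    return(0L)
  }
  hit <- rep(FALSE, length(lowered))
  for (p in phr) {
    hit <- hit | stringr::str_detect(lowered, stringr::fixed(p))
  }
  sum(hit)
}

# Normalize chromosome names at an I/O boundary for cross-file joins.
normalize_chrom_names <- function(chrom, mode = c("none", "strip", "add")) {
  mode <- match.arg(mode)
  switch(mode,
    none = chrom,
    strip = sub("^chr", "", chrom),
    add = ifelse(grepl("^chr", chrom), chrom, paste0("chr", chrom))
  )
}

empty_variants <- function() {
  tibble::tibble(
    chrom = character(), pos = integer(), ref = character(),
    alt = character(), sample_id = character(), origin = character(),
    zygosity = character(), quality = double(),
    ref_reads = integer(), alt_reads = integer()
  )
}
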