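#' Configure the synthetic fixture universe
#'
#' Parameters for [simulate_universe()], which emits a mutually consistent
#' set of gene models, variant calls, VEP-style annotations and evidence
#' tables emulating a twin control/target exome study: two control samples
#' and two target samples share a planted germline variant set, the targets
#' additionally carry target-only somatic variants, and a few of those
#' somatic variants are planted "drivers" with the full high-relevance
#' evidence profile (no reported GMAF, damaging SIFT and PolyPhen,
#' COSMIC-dense census gene, focus-matching disease and process terms).
#' All remaining variants follow a background profile (common allele
#' frequency, benign predictor scores, sparse evidence).
#'
#' @param seed Integer seed; the whole universe is a deterministic function
#'   of the configuration.
#' @param n_genes Number of genes (split across chromosomes).
#' @param transcripts_per_gene Integer range `c(min, max)` of transcripts
#'   per gene.
#' @param chrom_spans Named integer vector of chromosome lengths (bases).
#' @param n_shared_germline Germline variants shared by all four samples.
#' @param n_target_only Somatic variants present only in the target samples
#'   (includes the drivers).
#' @param n_private_per_control Private background variants per control
#'   sample.
#' @param coding_fraction Fraction of non-driver planted variants placed in
#'   coding sequence; drivers are always coding.
#' @param n_planted_drivers Number of driver variants
#'   (`<= n_target_only`).
#' @param n_mutect_reject REJECT rows added to the MuTect file.
#' @param tissues Tissue names for the expression matrix.
#' @param focus The [focus_config()] whose disease and function phrases the
#'   driver genes' evidence is built to match.
#' @return A list of class `eva_sim_config`.
#' @export
sim_config <- function(seed = 42L,
                       n_genes = 30L,
                       transcripts_per_gene = c(1L, 2L),
                       chrom_spans = c(chr1 = 600000L, chr2 = 600000L),
                       n_shared_germline = 100L,
                       n_target_only = 40L,
                       n_private_per_control = 15L,
                       coding_fraction = 0.6,
                       n_planted_drivers = 5L,
                       n_mutect_reject = 5L,
                       tissues = c(
                         "HematopoieticCD34", "BCell", "TCell",
                         "BoneMarrow", "Liver", "Brain", "Lung", "Kidney"
                       ),
                       focus = leukemia_focus()) {
  stopifnot(
    is.numeric(seed), length(seed) == 1L,
    n_genes >= 1L, length(transcripts_per_gene) == 2L,
    !is.null(names(chrom_spans)), all(chrom_spans > 0L),
    coding_fraction >= 0, coding_fraction <= 1,
    n_mutect_reject >= 0L,
    inherits(focus, "eva_focus")
  )
  if (n_planted_drivers > n_target_only) {
    abort("n_planted_drivers must be <= n_target_only")
  }
  if (n_planted_drivers > n_genes) {
    abort("n_planted_drivers must be <= n_genes (one driver gene each)")
  }
  structure(
    list(
      seed = as.integer(seed), n_genes = as.integer(n_genes),
      transcripts_per_gene = as.integer(transcripts_per_gene),
      chrom_spans = chrom_spans,
      n_shared_germline = as.integer(n_shared_germline),
      n_target_only = as.integer(n_target_only),
      n_private_per_control = as.integer(n_private_per_control),
      coding_fraction = coding_fraction,
      n_planted_drivers = as.integer(n_planted_drivers),
      n_mutect_reject = as.integer(n_mutect_reject),
      tissues = tissues, focus = focus
    ),
    class = "eva_sim_config"
  )
}

#' Generate the synthetic fixture universe
#'
#' Writes, under `outdir`: `genes.genepred`; `control1.vcf`, `control2.vcf`,
#' `target1.vcf`, `target2.vcf`; `mutect.tsv` (call-stats with KEEP rows for
#' every target-only variant plus REJECT decoys); `vep.tsv` (VEP-style
#' default-format annotation covering exactly the coding variants, with one
#' row per transcript); the seven evidence TSVs; and `manifest.tsv`
#' recording every planted variant's true class, coding status, gene and
#' zygosity — the ground-truth oracle for every downstream stage. The same
#' configuration always produces byte-identical files.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created if needed).
#' @return The manifest tibble, invisibly.
#' @export
simulate_universe <- function(config = sim_config(), outdir) {
  stopifnot(inherits(config, "eva_sim_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  withr::with_seed(config$seed, sim_build(config, outdir))
}

#' Generate the shipped worked example
#'
#' A fixed miniature of a leukemia-focused twin analysis: 20 target-only
#' somatic variants, 3 of them planted drivers, scored under
#' [leukemia_focus()]. Running the pipeline end-to-end on these fixtures
#' ranks the 3 drivers at positions 1–3.
#'
#' @param outdir Output directory.
#' @return The manifest tibble, invisibly.
#' @export
simulate_worked_example <- function(outdir) {
  config <- sim_config(
    seed = 1201L,
    n_genes = 12L,
    transcripts_per_gene = c(1L, 2L),
    chrom_spans = c(chr1 = 300000L, chr2 = 300000L),
    n_shared_germline = 10L,
    n_target_only = 20L,
    n_private_per_control = 4L,
    coding_fraction = 0.8,
    n_planted_drivers = 3L,
    n_mutect_reject = 3L,
    focus = leukemia_focus()
  )
  simulate_universe(config, outdir)
}

# ---- internals ------------------------------------------------------------

sim_build <- function(config, outdir) {
  models <- sim_gene_models(config)
  write_genepred(models, file.path(outdir, "genes.genepred"))

  cr <- coding_regions(models)
  coding_pool <- tibble::tibble(
    chrom = cr$chrom, start1 = cr$start0 + 1L, end1 = cr$end0,
    gene = cr$gene_symbol
  )
  noncoding_pool <- sim_noncoding_pool(coding_pool, config$chrom_spans)

  n_drv <- config$n_planted_drivers
  driver_genes <- sort(sample(unique(models$gene_symbol), n_drv))
  driver_pos <- purrr::map_dfr(driver_genes, function(g) {
    pool <- coding_pool[coding_pool$gene == g, , drop = FALSE]
    p <- pool_sample(pool, 1L)
    p$gene <- g
    p
  })

  n_t_bg <- config$n_target_only - n_drv
  n_g_cod <- round(config$n_shared_germline * config$coding_fraction)
  n_t_cod <- round(n_t_bg * config$coding_fraction)
  n_p_cod <- round(config$n_private_per_control * config$coding_fraction)
  n_g_non <- config$n_shared_germline - n_g_cod
  n_t_non <- n_t_bg - n_t_cod
  n_p_non <- config$n_private_per_control - n_p_cod

  total_cod <- n_g_cod + n_t_cod + 2L * n_p_cod
  cod_pos <- pool_sample_excluding(
    coding_pool, total_cod,
    exclude = variant_key(driver_pos$chrom, driver_pos$pos, "", "")
  )
  cod_pos$gene <- position_gene(cod_pos, coding_pool)
  cod_split <- split_rows(cod_pos, c(n_g_cod, n_t_cod, n_p_cod, n_p_cod))

  total_non <- n_g_non + n_t_non + 2L * n_p_non + config$n_mutect_reject
  non_pos <- pool_sample(noncoding_pool, total_non)
  non_pos$gene <- position_gene_span(non_pos, models)
  non_split <- split_rows(
    non_pos,
    c(n_g_non, n_t_non, n_p_non, n_p_non, config$n_mutect_reject)
  )

  mk <- function(pos_df, class, coding) {
    if (nrow(pos_df) == 0L) {
      return(tibble::tibble(
        chrom = character(), pos = integer(), ref = character(),
        alt = character(), class = character(), coding = logical(),
        gene = character(), zygosity = character()
      ))
    }
    ref <- sample(snv_bases, nrow(pos_df), replace = TRUE)
    alt <- purrr::map_chr(ref, ~ sample(setdiff(snv_bases, .x), 1L))
    zyg <- if (class == "germline_shared") {
      sample(c("het", "hom_alt"), nrow(pos_df),
        replace = TRUE, prob = c(0.8, 0.2)
      )
    } else {
      rep("het", nrow(pos_df))
    }
    tibble::tibble(
      chrom = pos_df$chrom, pos = pos_df$pos, ref = ref, alt = alt,
      class = class, coding = coding, gene = pos_df$gene, zygosity = zyg
    )
  }

  manifest <- dplyr::bind_rows(
    mk(driver_pos[c("chrom", "pos", "gene")], "driver", TRUE),
    mk(cod_split[[1L]], "germline_shared", TRUE),
    mk(non_split[[1L]], "germline_shared", FALSE),
    mk(cod_split[[2L]], "somatic", TRUE),
    mk(non_split[[2L]], "somatic", FALSE),
    mk(cod_split[[3L]], "private_control1", TRUE),
    mk(non_split[[3L]], "private_control1", FALSE),
    mk(cod_split[[4L]], "private_control2", TRUE),
    mk(non_split[[4L]], "private_control2", FALSE),
    mk(non_split[[5L]], "mutect_reject", FALSE)
  )
  ord <- order_radix(manifest$chrom, manifest$pos, manifest$alt)
  manifest <- manifest[ord, , drop = FALSE]

  # VEP-style predictor profile for every coding variant
  vep_profile <- sim_vep_profiles(manifest)
  manifest <- dplyr::left_join(
    manifest, vep_profile,
    by = c("chrom", "pos", "ref", "alt")
  )

  sim_write_vcfs(manifest, outdir)
  sim_write_mutect(manifest, file.path(outdir, "mutect.tsv"))
  sim_write_vep(manifest, models, file.path(outdir, "vep.tsv"))
  sim_write_evidence(config, models, driver_genes, outdir)
  readr::write_tsv(manifest, file.path(outdir, "manifest.tsv"),
    progress = FALSE
  )
  invisible(manifest)
}

sim_gene_models <- function(config) {
  chroms <- names(config$chrom_spans)
  rows <- list()
  cursor <- setNames(rep(0L, length(chroms)), chroms)
  tx_i <- 0L
  for (i in seq_len(config$n_genes)) {
    ch <- chroms[((i - 1L) %% length(chroms)) + 1L]
    gap <- sample(2000:8000, 1L)
    len <- sample(3000:12000, 1L)
    g_start <- cursor[[ch]] + gap
    g_end <- g_start + len
    if (g_end > config$chrom_spans[[ch]]) {
      abort(paste0(
        "unsatisfiable simulation config: chromosome ", ch,
        " too short for ", config$n_genes, " genes"
      ))
    }
    cursor[[ch]] <- g_end
    gene <- sprintf("GENE%03d", i)
    n_tx <- sample(
      seq(config$transcripts_per_gene[1L], config$transcripts_per_gene[2L]),
      1L
    )
    for (t in seq_len(n_tx)) {
      tx_i <- tx_i + 1L
      rows[[length(rows) + 1L]] <- sim_transcript(
        gene, sprintf("NM_%06d", tx_i), ch,
        strand = sample(c("+", "-"), 1L),
        tx_start = g_start, tx_end = g_end
      )
    }
  }
  dplyr::bind_rows(rows)
}

sim_transcript <- function(gene, tx_id, chrom, strand, tx_start, tx_end) {
  n_ex <- sample(2:4, 1L)
  inner <- sort(sample(seq(tx_start + 50L, tx_end - 50L), 2L * n_ex - 2L))
  bnd <- c(tx_start, inner, tx_end)
  starts <- bnd[seq(1L, length(bnd), by = 2L)]
  ends <- bnd[seq(2L, length(bnd), by = 2L)]
  cds_start <- starts[1L] + sample(10:60, 1L)
  cds_end <- ends[length(ends)] - sample(10:60, 1L)
  if (cds_start >= cds_end) {
    cds_start <- tx_start
    cds_end <- tx_end
  }
  tibble::tibble(
    gene_symbol = gene, transcript_id = tx_id, chrom = chrom,
    strand = strand, tx_start = tx_start, tx_end = tx_end,
    cds_start = cds_start, cds_end = cds_end,
    exon_starts = list(as.integer(starts)), exon_ends = list(as.integer(ends))
  )
}

write_genepred <- function(models, path) {
  lines <- purrr::pmap_chr(models, function(gene_symbol, transcript_id, chrom,
                                            strand, tx_start, tx_end,
                                            cds_start, cds_end,
                                            exon_starts, exon_ends) {
    paste(
      transcript_id, chrom, strand, tx_start, tx_end, cds_start, cds_end,
      length(exon_starts),
      paste0(paste(exon_starts, collapse = ","), ","),
      paste0(paste(exon_ends, collapse = ","), ","),
      gene_symbol,
      sep = "\t"
    )
  })
  readr::write_lines(lines, path)
}

# Complement of the (merged) coding intervals within each chromosome span.
sim_noncoding_pool <- function(coding_pool, chrom_spans) {
  purrr::map_dfr(names(chrom_spans), function(ch) {
    iv <- coding_pool[coding_pool$chrom == ch, , drop = FALSE]
    gaps <- complement_intervals(iv$start1, iv$end1, chrom_spans[[ch]])
    tibble::tibble(chrom = ch, start1 = gaps$start1, end1 = gaps$end1)
  })
}

# Merge 1-based inclusive intervals and return the gaps within [1, span].
complement_intervals <- function(start1, end1, span) {
  if (length(start1) == 0L) {
    return(tibble::tibble(start1 = 1L, end1 = as.integer(span)))
  }
  ord <- order(start1, end1)
  start1 <- start1[ord]
  end1 <- end1[ord]
  ms <- start1[1L]
  me <- end1[1L]
  gaps_s <- integer()
  gaps_e <- integer()
  emit_gap <- function(a, b) {
    if (b >= a) {
      gaps_s <<- c(gaps_s, a)
      gaps_e <<- c(gaps_e, b)
    }
  }
  for (i in seq_along(start1)[-1L]) {
    if (start1[i] <= me + 1L) {
      me <- max(me, end1[i])
    } else {
      emit_gap(me + 1L, start1[i] - 1L)
      ms <- start1[i]
      me <- end1[i]
    }
  }
  first_start <- start1[1L]
  out <- tibble::tibble(start1 = gaps_s, end1 = gaps_e)
  if (first_start > 1L) {
    out <- dplyr::bind_rows(
      tibble::tibble(start1 = 1L, end1 = first_start - 1L), out
    )
  }
  if (me < span) {
    out <- dplyr::bind_rows(
      out, tibble::tibble(start1 = me + 1L, end1 = as.integer(span))
    )
  }
  out
}

# Sample n distinct positions from a pool of 1-based inclusive intervals,
# uniform over total covered length.
pool_sample <- function(pool, n) {
  if (n == 0L) {
    return(tibble::tibble(chrom = character(), pos = integer()))
  }
  w <- pool$end1 - pool$start1 + 1L
  keep <- w > 0L
  pool <- pool[keep, , drop = FALSE]
  w <- w[keep]
  total <- sum(w)
  if (n > total) {
    abort(paste0(
      "unsatisfiable simulation config: requested ", n,
      " positions from a pool of ", total, " bases"
    ))
  }
  offs <- sort(sample.int(total, n))
  cs <- cumsum(c(0L, w))
  idx <- findInterval(offs - 1L, cs)
  tibble::tibble(
    chrom = pool$chrom[idx],
    pos = pool$start1[idx] + (offs - 1L - cs[idx])
  )
}

pool_sample_excluding <- function(pool, n, exclude) {
  got <- pool_sample(pool, min(n + length(exclude) + 10L, pool_size(pool)))
  key <- variant_key(got$chrom, got$pos, "", "")
  got <- got[!key %in% exclude, , drop = FALSE]
  if (nrow(got) < n) {
    abort("unsatisfiable simulation config: coding space exhausted")
  }
  got[seq_len(n), , drop = FALSE]
}

pool_size <- function(pool) {
  sum(pmax(pool$end1 - pool$start1 + 1L, 0L))
}

split_rows <- function(df, sizes) {
  stopifnot(sum(sizes) == nrow(df))
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  purrr::map2(starts, ends, function(s, e) {
    if (e < s) df[0L, , drop = FALSE] else df[s:e, , drop = FALSE]
  })
}

# Gene containing each coding position (positions were drawn from coding
# intervals, so a containing gene always exists).
position_gene <- function(pos_df, coding_pool) {
  purrr::map2_chr(pos_df$chrom, pos_df$pos, function(ch, p) {
    hit <- coding_pool$chrom == ch & coding_pool$start1 <= p &
      coding_pool$end1 >= p
    sort(coding_pool$gene[hit])[1L]
  })
}

# Gene whose transcript span contains each position, NA when intergenic.
position_gene_span <- function(pos_df, models) {
  purrr::map2_chr(pos_df$chrom, pos_df$pos, function(ch, p) {
    hit <- models$chrom == ch & models$tx_start < p & models$tx_end >= p
    g <- sort(unique(models$gene_symbol[hit]))
    if (length(g) == 0L) NA_character_ else g[1L]
  })
}

aa_pairs_changing <- c("R/W", "E/K", "S/F", "D/G", "C/R", "L/P", "G/E")
aa_pairs_neutral <- c("L/V", "I/M", "S/T", "D/E", "A/G", "K/R")

sim_vep_profiles <- function(manifest) {
  cod <- manifest[manifest$coding, , drop = FALSE]
  if (nrow(cod) == 0L) {
    return(tibble::tibble(
      chrom = character(), pos = integer(), ref = character(),
      alt = character(), sift = double(), polyphen = double(),
      gmaf = double(), aa = character()
    ))
  }
  is_drv <- cod$class == "driver"
  n <- nrow(cod)
  tibble::tibble(
    chrom = cod$chrom, pos = cod$pos, ref = cod$ref, alt = cod$alt,
    sift = round(ifelse(is_drv, stats::runif(n, 0, 0.05),
      stats::runif(n, 0.2, 0.9)
    ), 4L),
    polyphen = round(ifelse(is_drv, stats::runif(n, 0.9, 0.99),
      stats::runif(n, 0, 0.4)
    ), 4L),
    gmaf = ifelse(is_drv, NA_real_, round(stats::runif(n, 0.06, 0.4), 4L)),
    aa = ifelse(is_drv, sample(aa_pairs_changing, n, replace = TRUE),
      sample(aa_pairs_neutral, n, replace = TRUE)
    )
  )
}

sim_write_vcfs <- function(manifest, outdir) {
  members <- list(
    control1 = c("germline_shared", "private_control1"),
    control2 = c("germline_shared", "private_control2"),
    target1 = c("germline_shared", "somatic", "driver"),
    target2 = c("germline_shared", "somatic", "driver")
  )
  for (s in names(members)) {
    v <- manifest[manifest$class %in% members[[s]], , drop = FALSE]
    write_sim_vcf(v, s, file.path(outdir, paste0(s, ".vcf")))
  }
}

write_sim_vcf <- function(v, sample_name, path) {
  ord <- order_radix(v$chrom, v$pos, v$alt)
  v <- v[ord, , drop = FALSE]
  qual <- sample(50:99, nrow(v), replace = TRUE)
  depth <- sample(20:80, nrow(v), replace = TRUE)
  alt_reads <- ifelse(v$zygosity == "hom_alt", depth,
    pmax(1L, round(depth * 0.5))
  )
  ref_reads <- depth - alt_reads
  gt <- ifelse(v$zygosity == "hom_alt", "1/1", "0/1")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=evanno simulate (synthetic data)",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste0(
      "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample_name
    )
  )
  body <- paste(
    v$chrom, v$pos, ".", v$ref, v$alt, qual, "PASS", ".",
    "GT:AD", paste0(gt, ":", ref_reads, ",", alt_reads),
    sep = "\t"
  )
  readr::write_lines(c(header, body), path)
}

sim_write_mutect <- function(manifest, path) {
  v <- manifest[
    manifest$class %in% c("somatic", "driver", "mutect_reject"), ,
    drop = FALSE
  ]
  ord <- order_radix(v$chrom, v$pos, v$alt)
  v <- v[ord, , drop = FALSE]
  judgement <- ifelse(v$class == "mutect_reject", "REJECT", "KEEP")
  tumor_f <- sprintf("%.3f", stats::runif(nrow(v), 0.2, 0.6))
  t_alt <- sample(8:40, nrow(v), replace = TRUE)
  t_ref <- sample(10:60, nrow(v), replace = TRUE)
  lines <- c(
    "## muTector v1.1.4 (synthetic call-stats)",
    paste("contig", "position", "ref_allele", "alt_allele", "tumor_f",
      "t_ref_count", "t_alt_count", "judgement",
      sep = "\t"
    ),
    paste(v$chrom, v$pos, v$ref, v$alt, tumor_f, t_ref, t_alt, judgement,
      sep = "\t"
    )
  )
  readr::write_lines(lines, path)
}

sim_write_vep <- function(manifest, models, path) {
  cod <- manifest[manifest$coding, , drop = FALSE]
  ord <- order_radix(cod$chrom, cod$pos, cod$alt)
  cod <- cod[ord, , drop = FALSE]
  tx_by_gene <- split(models$transcript_id, models$gene_symbol)
  rows <- purrr::pmap(cod, function(chrom, pos, ref, alt, gene, sift,
                                    polyphen, gmaf, aa, ...) {
    txs <- tx_by_gene[[gene]]
    extra <- paste0(
      "SIFT=", sprintf("%.4f", sift),
      ";PolyPhen=", sprintf("%.4f", polyphen),
      if (!is.na(gmaf)) paste0(";GMAF=", sprintf("%.4f", gmaf)) else ""
    )
    tibble::tibble(
      Uploaded_variation = paste0(chrom, "_", pos, "_", ref, "/", alt),
      Location = paste0(chrom, ":", pos),
      Allele = alt,
      Gene = gene,
      Feature = txs,
      Feature_type = "Transcript",
      Consequence = "missense_variant",
      cDNA_position = "-", CDS_position = "-", Protein_position = "-",
      Amino_acids = aa, Codons = "-",
      Existing_variation = if (is.na(gmaf)) "-" else {
        paste0("rs", 900000 + (pos %% 100000))
      },
      Extra = extra
    )
  })
  df <- dplyr::bind_rows(rows)
  lines <- c(
    "## evanno simulate: synthetic VEP-style default output",
    paste0("#", paste(names(df), collapse = "\t")),
    purrr::map_chr(
      seq_len(nrow(df)),
      function(i) paste(unlist(df[i, ]), collapse = "\t")
    )
  )
  readr::write_lines(lines, path)
}

process_terms_focus <- c(
  "Apoptosis", "CellCycle regulation", "B-cell receptor SignalingPathway",
  "Chromatin remodeling", "DNARepair pathway", "Hemopoiesis",
  "RegulationOfTranscription"
)
process_terms_background <- c(
  "Lipid metabolism", "Axon guidance", "Muscle contraction",
  "Visual perception", "Ion transport", "Keratinization"
)
disease_names_background <- c(
  "Cardiomyopathy", "Type 2 diabetes", "Osteoarthritis", "Asthma",
  "Retinitis pigmentosa"
)

sim_write_evidence <- function(config, models, driver_genes, outdir) {
  genes <- sort(unique(models$gene_symbol))
  is_drv <- genes %in% driver_genes
  n <- length(genes)
  focus <- config$focus

  pubmed <- ifelse(is_drv, sample(50:500, n, replace = TRUE),
    sample(0:20, n, replace = TRUE)
  )
  protein_length <- ifelse(is_drv, sample(300:900, n, replace = TRUE),
    sample(200:1500, n, replace = TRUE)
  )
  entries <- ifelse(is_drv,
    round(protein_length * stats::runif(n, 0.8, 1.4)),
    sample(0:30, n, replace = TRUE)
  )

  disease <- purrr::map2_dfr(genes, is_drv, function(g, d) {
    if (d) {
      ph <- sample(focus$disease_focus, 2L)
      tibble::tibble(gene = g, disease_name = paste(ph, "associated disorder"))
    } else if (stats::runif(1L) < 0.7) {
      tibble::tibble(
        gene = g,
        disease_name = sample(disease_names_background, 1L)
      )
    } else {
      tibble::tibble(gene = character(), disease_name = character())
    }
  })

  process <- purrr::map2_dfr(genes, is_drv, function(g, d) {
    terms <- if (d) {
      sample(process_terms_focus, 2L)
    } else {
      sample(process_terms_background, sample(1:2, 1L))
    }
    tibble::tibble(gene = g, term = terms)
  })

  bg <- genes[!is_drv]
  census_genes <- sort(c(driver_genes, sample(bg, min(1L, length(bg)))))
  interactors <- sample(setdiff(genes, census_genes),
    min(3L, length(setdiff(genes, census_genes)))
  )
  interactions <- dplyr::bind_rows(
    tibble::tibble(geneA = interactors, geneB = census_genes[1L]),
    if (length(bg) >= 2L) {
      tibble::tibble(geneA = bg[1L], geneB = bg[2L])
    }
  )

  tissues <- config$tissues
  expr <- tibble::tibble(gene = genes)
  for (ti in seq_along(tissues)) {
    blood_like <- ti <= 3L
    expr[[tissues[ti]]] <- round(ifelse(
      is_drv & blood_like,
      stats::runif(n, 500, 3000),
      stats::runif(n, 5, 300)
    ), 1L)
  }

  w <- function(x, name) {
    readr::write_tsv(x, file.path(outdir, name), progress = FALSE)
  }
  w(
    tibble::tibble(gene = genes, mesh_term = focus$mesh_term, count = pubmed),
    "literature.tsv"
  )
  w(
    tibble::tibble(
      gene = genes, entries = entries, protein_length = protein_length
    ),
    "cosmic.tsv"
  )
  w(disease, "disease.tsv")
  w(process, "process.tsv")
  w(tibble::tibble(gene = census_genes), "census.tsv")
  w(interactions, "interactions.tsv")
  w(expr, "expression.tsv")
  invisible(outdir)
}
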