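#' Simulate an XY-system reference genome with known ground truth
#'
#' Generates a multi-contig diploid genome containing `n_autosomes`
#' autosomes and one X/Y pair simulated at equal, co-linear length.  The
#' Y contig carries the SDR as a mosaic of blocks: *Y-specific* blocks
#' have no X homolog (females carry no reads there) and *X-diverged*
#' blocks retain an X homolog at `sdr_divergence` per-site divergence.
#' A translocated, truncated duplicate of an autosomal 7-exon gene (the
#' candidate sex-determining gene, SDG) is placed inside a Y-specific
#' block, and LINE repeat density in its flank is elevated by
#' `line_enrichment_factor` over the genome background.
#'
#' All coordinates are 0-based half-open.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `genome_model` with elements `contigs`
#'   (data.frame: contig, length, true_class), `sequences`
#'   ([Biostrings::DNAStringSet]), `genes` and `exons` (data.frames),
#'   `repeats` (data.frame: contig, start, end, class), `sdr_truth`
#'   (list: contig, start, end), `sdr_blocks` (data.frame: start, end,
#'   type), `alignment_map` (X-Y co-linear aligned segments), `sdg`
#'   (gene id or `NA`), and `cfg`.
#' @export
#' @examples
#' g <- simulate_genome(sim_config(seed = 1))
#' g$sdr_truth
simulate_genome <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(stage_seed(cfg$seed, "genome"))

  contigs <- data.frame(
    contig = c(paste0("chr", seq_len(cfg$n_autosomes)), "chrX", "chrY"),
    length = c(rep(cfg$autosome_length, cfg$n_autosomes),
               cfg$sex_chrom_length, cfg$sex_chrom_length),
    true_class = c(rep("autosomal", cfg$n_autosomes), "X_linked", "Y_linked"),
    stringsAsFactors = FALSE
  )

  ## SDR mosaic on Y
  sdr_len <- cfg$sdr_end - cfg$sdr_start
  if (sdr_len > 0) {
    starts <- seq(cfg$sdr_start, cfg$sdr_end - 1, by = cfg$block_size)
    ends <- pmin(starts + cfg$block_size, cfg$sdr_end)
    type <- ifelse(runif(length(starts)) < cfg$y_specific_frac,
                   "y_specific", "diverged")
    # an SDR needs both signatures when the mixture parameter allows it
    if (length(type) >= 2 && cfg$y_specific_frac > 0 && cfg$y_specific_frac < 1) {
      if (!any(type == "y_specific")) type[1] <- "y_specific"
      if (!any(type == "diverged")) type[length(type)] <- "diverged"
    }
    sdr_blocks <- data.frame(start = starts, end = ends, type = type,
                             stringsAsFactors = FALSE)
  } else {
    sdr_blocks <- data.frame(start = numeric(0), end = numeric(0),
                             type = character(0), stringsAsFactors = FALSE)
  }

  ## Sequences: autosomes and X random; Y derived from X
  seqs <- lapply(seq_len(nrow(contigs) - 1L), function(i) {
    random_dna(contigs$length[i])
  })
  names(seqs) <- contigs$contig[seq_len(nrow(contigs) - 1L)]
  x_chars <- strsplit(seqs[["chrX"]], "", fixed = TRUE)[[1]]
  y_chars <- x_chars
  if (cfg$background_divergence > 0) {
    L <- length(y_chars)
    idx <- which(runif(L) < cfg$background_divergence)
    y_chars[idx] <- mutate_base(y_chars[idx])
  }
  for (i in seq_len(nrow(sdr_blocks))) {
    b <- sdr_blocks[i, ]
    pos <- (b$start + 1):b$end           # 1-based indices into the vector
    if (b$type == "y_specific") {
      y_chars[pos] <- strsplit(random_dna(length(pos)), "", fixed = TRUE)[[1]]
    } else {
      hit <- pos[runif(length(pos)) < cfg$sdr_divergence]
      y_chars[hit] <- mutate_base(y_chars[hit])
    }
  }
  seqs[["chrY"]] <- paste(y_chars, collapse = "")
  sequences <- Biostrings::DNAStringSet(unlist(seqs))

  ## X-Y alignment map: everything except Y-specific blocks, co-linear
  aligned <- IRanges::setdiff(
    IRanges::IRanges(start = 1, end = cfg$sex_chrom_length),
    IRanges::IRanges(start = sdr_blocks$start[sdr_blocks$type == "y_specific"] + 1,
                     end = sdr_blocks$end[sdr_blocks$type == "y_specific"])
  )
  alignment_map <- data.frame(
    x_contig = "chrX",
    x_start = IRanges::start(aligned) - 1L,
    x_end = IRanges::end(aligned),
    y_contig = "chrY",
    y_start = IRanges::start(aligned) - 1L,
    y_end = IRanges::end(aligned),
    strand = "+",
    stringsAsFactors = FALSE
  )

  ## Genes: a 7-exon autosomal parent and its truncated 4-exon Y duplicate
  genes <- list()
  exons <- list()
  parent <- gene_structure("amh_a", "chr1", start = 1e5, strand = "+",
                           n_exons = 7L)
  genes[[1]] <- parent$gene
  exons[[1]] <- parent$exons
  sdg_id <- NA_character_
  ys_blocks <- sdr_blocks[sdr_blocks$type == "y_specific", , drop = FALSE]
  if (nrow(ys_blocks) > 0) {
    sdg_id <- "amh_y"
    host <- ys_blocks[1, ]
    dup <- gene_structure(sdg_id, "chrY",
                          start = host$start + 1e3, strand = "+",
                          n_exons = 4L)
    genes[[2]] <- dup$gene
    exons[[2]] <- dup$exons
  }
  # background genes for annotation realism
  gi <- length(genes)
  for (ci in seq_len(nrow(contigs))) {
    for (k in 1:2) {
      gi <- gi + 1L
      gstart <- floor(runif(1, 0.1, 0.9) * (contigs$length[ci] - 1e4))
      bg <- gene_structure(sprintf("gene_%s_%d", contigs$contig[ci], k),
                           contigs$contig[ci], start = gstart,
                           strand = sample(c("+", "-"), 1), n_exons = 3L)
      genes[[gi]] <- bg$gene
      exons[[gi]] <- bg$exons
    }
  }
  genes <- do.call(rbind, genes)
  exons <- do.call(rbind, exons)

  ## Repeats: per-class Poisson interval process; LINE enriched in SDG flank
  set.seed(stage_seed(cfg$seed, "repeats"))
  mean_rep_len <- 800
  rep_classes <- c("LINE", "LTR", "DNA", "Simple")
  reps <- list()
  for (ci in seq_len(nrow(contigs))) {
    clen <- contigs$length[ci]
    for (cl in rep_classes) {
      n_int <- rpois(1, cfg$repeat_density * clen / mean_rep_len)
      if (n_int == 0) next
      st <- floor(runif(n_int, 0, clen - 1))
      len <- pmax(50, round(rgamma(n_int, shape = 2, scale = mean_rep_len / 2)))
      reps[[length(reps) + 1L]] <- data.frame(
        contig = contigs$contig[ci], start = st,
        end = pmin(st + len, clen), class = cl, stringsAsFactors = FALSE)
    }
  }
  if (!is.na(sdg_id) && cfg$line_enrichment_factor > 1) {
    sdg_row <- genes[genes$gene_id == sdg_id, ]
    fl_start <- max(0, sdg_row$start - cfg$sdg_flank)
    fl_end <- min(cfg$sex_chrom_length, sdg_row$end + cfg$sdg_flank)
    extra_rate <- cfg$repeat_density * (cfg$line_enrichment_factor - 1)
    n_int <- rpois(1, extra_rate * (fl_end - fl_start) / mean_rep_len)
    if (n_int > 0) {
      st <- floor(runif(n_int, fl_start, fl_end - 50))
      len <- pmax(50, round(rgamma(n_int, shape = 2, scale = mean_rep_len / 2)))
      reps[[length(reps) + 1L]] <- data.frame(
        contig = "chrY", start = st, end = pmin(st + len, fl_end),
        class = "LINE", stringsAsFactors = FALSE)
    }
  }
  repeats <- if (length(reps)) do.call(rbind, reps) else
    data.frame(contig = character(0), start = numeric(0), end = numeric(0),
               class = character(0), stringsAsFactors = FALSE)
  rownames(repeats) <- NULL

  structure(list(
    contigs = contigs,
    sequences = sequences,
    genes = genes,
    exons = exons,
    repeats = repeats,
    sdr_truth = list(contig = "chrY", start = cfg$sdr_start,
                     end = cfg$sdr_end),
    sdr_blocks = sdr_blocks,
    alignment_map = alignment_map,
    sdg = sdg_id,
    cfg = cfg
  ), class = "genome_model")
}

#' @exportS3Method base::print
print.genome_model <- function(x, ...) {
  cat("genome_model:", nrow(x$contigs), "contigs,",
      sum(x$contigs$length) / 1e6, "Mbp total\n")
  cat("  SDR truth:", x$sdr_truth$contig,
      sprintf("[%g, %g)", x$sdr_truth$start, x$sdr_truth$end), "\n")
  cat("  SDG:", x$sdg, "|", nrow(x$genes), "genes,",
      nrow(x$repeats), "repeat intervals\n")
  invisible(x)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitute each base for a uniformly chosen different base
mutate_base <- function(b) {
  if (!length(b)) return(b)
  alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
              G = c("A", "C", "T"), T = c("A", "C", "G"))
  vapply(b, function(x) sample(alt[[x]], 1L), character(1), USE.NAMES = FALSE)
}

# fixed gene geometry: 150 bp exons separated by 300 bp introns
gene_structure <- function(id, contig, start, strand, n_exons) {
  exon_len <- 150
  intron_len <- 300
  ex_start <- start + (seq_len(n_exons) - 1L) * (exon_len + intron_len)
  ex <- data.frame(gene_id = id, contig = contig, start = ex_start,
                   end = ex_start + exon_len, exon_index = seq_len(n_exons),
                   stringsAsFactors = FALSE)
  g <- data.frame(gene_id = id, contig = contig, start = min(ex$start),
                  end = max(ex$end), strand = strand,
                  stringsAsFactors = FALSE)
  list(gene = g, exons = ex)
}
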