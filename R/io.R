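#' Write a simulated dataset to standard formats
#'
#' Emits contig FASTA, duplicate-pair CDS FASTA, a VCF v4.2 with
#' per-sample GT, one BED depth file per individual (chrom, start, end,
#' depth; half-open 0-based non-overlapping bins tiling each contig), a
#' repeat BED (class in the name field), a GFF3 of genes/exons, a sex
#' map TSV and a ground-truth JSON (SDR interval, true contig classes,
#' SDG id, marker hits, gene-pair parameters).  Files round-trip
#' through [read_dataset()].
#'
#' @param genome A `genome_model`.
#' @param samples A `sample_set`.
#' @param pairs Optional list of `gene_pair` objects.
#' @param outdir Output directory (created if needed).
#' @return Named character vector of written paths (the manifest).
#' @export
write_dataset <- function(genome, samples, pairs = NULL, outdir) {
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE)) {
    stop("cannot create output directory: ", outdir, call. = FALSE)
  }
  manifest <- c()

  fa <- file.path(outdir, "contigs.fa")
  Biostrings::writeXStringSet(genome$sequences, fa)
  manifest["contigs"] <- fa

  if (!is.null(pairs)) {
    cds <- Biostrings::DNAStringSet(unlist(lapply(seq_along(pairs),
      function(i) {
        p <- pairs[[i]]
        setNames(c(p$parent_cds, p$duplicate_cds),
                 paste0("pair", i, c("_parent", "_duplicate")))
      })))
    pfa <- file.path(outdir, "cds_pairs.fa")
    Biostrings::writeXStringSet(cds, pfa)
    manifest["cds_pairs"] <- pfa
  }

  vcf <- file.path(outdir, "genotypes.vcf")
  write_vcf(samples, genome$contigs, vcf)
  manifest["vcf"] <- vcf

  ddir <- file.path(outdir, "depth")
  dir.create(ddir, showWarnings = FALSE)
  for (j in seq_len(ncol(samples$depth))) {
    id <- colnames(samples$depth)[j]
    f <- file.path(ddir, paste0(id, ".bed"))
    data.table::fwrite(
      data.frame(samples$depth_bins, depth = samples$depth[, j]),
      f, sep = "\t", col.names = FALSE)
  }
  manifest["depth_dir"] <- ddir

  sex <- file.path(outdir, "sex.tsv")
  data.table::fwrite(samples$individuals, sex, sep = "\t")
  manifest["sex"] <- sex

  rbed <- file.path(outdir, "repeats.bed")
  rgr <- GenomicRanges::GRanges(
    genome$repeats$contig,
    IRanges::IRanges(genome$repeats$start + 1, genome$repeats$end),
    name = genome$repeats$class)
  rtracklayer::export(rgr, rbed, format = "bed")
  manifest["repeats"] <- rbed

  gff <- file.path(outdir, "genes.gff3")
  write_genes_gff3(genome, gff)
  manifest["genes"] <- gff

  truth <- file.path(outdir, "truth.json")
  pair_meta <- if (is.null(pairs)) NULL else lapply(pairs, function(p)
    p[c("parent_exons", "duplicate_exons", "kept_exons", "true_ks",
        "true_ka", "saturation_warning")])
  jsonlite::write_json(list(
    sdr_truth = genome$sdr_truth,
    contig_classes = genome$contigs,
    sdr_blocks = genome$sdr_blocks,
    alignment_map = genome$alignment_map,
    sdg = genome$sdg,
    marker_hits = as.list(samples$marker_hits),
    marker_presence = as.list(samples$marker_presence),
    pairs = pair_meta,
    seed = genome$cfg$seed
  ), truth, auto_unbox = TRUE, digits = NA, null = "null")
  manifest["truth"] <- truth
  manifest
}

write_vcf <- function(samples, contigs, path) {
  gt <- matrix(c("0/0", "0/1", "1/1")[samples$geno + 1L],
               nrow = nrow(samples$geno))
  gt[is.na(samples$geno)] <- "./."
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", contigs$contig,
            as.integer(contigs$length)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples$individuals$id), collapse = "\t"))
  writeLines(header, path)
  body <- data.frame(samples$sites$contig,
                     samples$sites$pos + 1L,    # VCF is 1-based
                     ".", samples$sites$ref, samples$sites$alt, ".",
                     "PASS", paste0("TYPE=", samples$sites$type), "GT",
                     gt, stringsAsFactors = FALSE)
  data.table::fwrite(body, path, sep = "\t", col.names = FALSE,
                     append = TRUE, quote = FALSE)
}

write_genes_gff3 <- function(genome, path) {
  g <- genome$genes
  e <- genome$exons
  gr_gene <- GenomicRanges::GRanges(
    g$contig, IRanges::IRanges(g$start + 1, g$end), strand = g$strand,
    type = "gene", ID = g$gene_id)
  str_by_gene <- setNames(g$strand, g$gene_id)
  gr_exon <- GenomicRanges::GRanges(
    e$contig, IRanges::IRanges(e$start + 1, e$end),
    strand = str_by_gene[e$gene_id],
    type = "exon",
    ID = paste0(e$gene_id, ".exon", e$exon_index),
    Parent = e$gene_id)
  gr <- c(gr_gene, gr_exon)
  rtracklayer::export(gr, path, format = "gff3")
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir Directory produced by [write_dataset()].
#' @return List with `sequences`, `sites`, `geno`, `individuals`,
#'   `depth_bins`, `depth`, `repeats`, `genes`, `exons`, `truth`.
#' @export
read_dataset <- function(dir) {
  sequences <- Biostrings::readDNAStringSet(file.path(dir, "contigs.fa"))

  v <- vcfR::read.vcfR(file.path(dir, "genotypes.vcf"), verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  geno <- matrix(NA_integer_, nrow(gt), ncol(gt),
                 dimnames = list(NULL, colnames(gt)))
  geno[gt == "0/0"] <- 0L
  geno[gt == "0/1" | gt == "1/0"] <- 1L
  geno[gt == "1/1"] <- 2L
  fix <- vcfR::getFIX(v)
  sites <- data.frame(contig = fix[, "CHROM"],
                      pos = as.numeric(fix[, "POS"]) - 1,
                      ref = fix[, "REF"], alt = fix[, "ALT"],
                      type = sub("^TYPE=", "", v@fix[, "INFO"]),
                      stringsAsFactors = FALSE)
  rownames(sites) <- NULL

  individuals <- as.data.frame(data.table::fread(file.path(dir, "sex.tsv")))

  dfiles <- list.files(file.path(dir, "depth"), pattern = "\\.bed$",
                       full.names = TRUE)
  ids <- sub("\\.bed$", "", basename(dfiles))
  dfiles <- dfiles[match(individuals$id, ids)]
  dl <- lapply(dfiles, function(f)
    as.data.frame(data.table::fread(f, header = FALSE,
                                    col.names = c("contig", "start",
                                                  "end", "depth"))))
  depth_bins <- dl[[1]][, c("contig", "start", "end")]
  depth <- do.call(cbind, lapply(dl, `[[`, "depth"))
  colnames(depth) <- individuals$id

  rgr <- rtracklayer::import(file.path(dir, "repeats.bed"))
  repeats <- data.frame(contig = as.character(GenomicRanges::seqnames(rgr)),
                        start = GenomicRanges::start(rgr) - 1,
                        end = GenomicRanges::end(rgr),
                        class = rgr$name, stringsAsFactors = FALSE)

  ggr <- rtracklayer::import(file.path(dir, "genes.gff3"))
  is_gene <- ggr$type == "gene"
  genes <- data.frame(gene_id = ggr$ID[is_gene],
                      contig = as.character(GenomicRanges::seqnames(ggr)[is_gene]),
                      start = GenomicRanges::start(ggr)[is_gene] - 1,
                      end = GenomicRanges::end(ggr)[is_gene],
                      strand = as.character(GenomicRanges::strand(ggr)[is_gene]),
                      stringsAsFactors = FALSE)
  is_exon <- ggr$type == "exon"
  exons <- data.frame(
    gene_id = vapply(ggr$Parent[is_exon], `[`, character(1), 1),
    contig = as.character(GenomicRanges::seqnames(ggr)[is_exon]),
    start = GenomicRanges::start(ggr)[is_exon] - 1,
    end = GenomicRanges::end(ggr)[is_exon],
    exon_index = as.integer(sub("^.*\\.exon", "", ggr$ID[is_exon])),
    stringsAsFactors = FALSE)

  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)

  cds_path <- file.path(dir, "cds_pairs.fa")
  cds <- if (file.exists(cds_path)) Biostrings::readDNAStringSet(cds_path)
         else NULL

  list(sequences = sequences, sites = sites, geno = geno,
       individuals = individuals, depth_bins = depth_bins, depth = depth,
       repeats = repeats, genes = genes, exons = exons, truth = truth,
       cds_pairs = cds)
}
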