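#' Build and validate a pipeline run configuration
#'
#' A run configuration bundles the simulator settings, scan window
#' geometry, SDR-calling rules, classifier thresholds, duplicate-gene
#' parameters and stage toggles.  Unknown keys are rejected.  Desk-scale
#' defaults (2 Mbp sex pair, 20 kbp windows at 10 kbp steps) keep a full
#' run in the low seconds; study-scale geometry (tens of Mbp, 50/25 kbp
#' windows) is reached through the same fields.
#'
#' @param sim Named list of [sim_config()] overrides.
#' @param window,step Scan window width and step in bp.
#' @param rules Named list of [sdr_rules()] overrides.
#' @param classifier Named list of [classifier_config()] overrides.
#' @param kaks Named list: `target_ks`, `target_ka`, `truncation`,
#'   `n_exons`, `codons_per_exon`, and optionally `rate`
#'   (substitutions/site/year) to date the duplication — there is no
#'   default rate.
#' @param repeats Named list: `class`, `flank` (bp around the SDG and
#'   its parent used for the enrichment contrast).
#' @param stages Character vector of stages to run, from
#'   `c("classify", "scan", "kaks", "repeats")` (simulation always
#'   provides the inputs).
#' @param seed Master seed; overrides `sim$seed`.
#' @return List of class `run_config`.
#' @export
run_config <- function(sim = list(), window = 20000, step = 10000,
                       rules = list(), classifier = list(),
                       kaks = list(), repeats = list(),
                       stages = c("classify", "scan", "kaks", "repeats"),
                       seed = 1L) {
  known_kaks <- c("target_ks", "target_ka", "truncation", "n_exons",
                  "codons_per_exon", "rate")
  known_rep <- c("class", "flank")
  reject_unknown <- function(x, known, where) {
    bad <- setdiff(names(x), known)
    if (length(bad)) {
      stop("unknown ", where, " key(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  reject_unknown(sim, names(formals(sim_config)), "sim")
  reject_unknown(rules, names(formals(sdr_rules)), "rules")
  reject_unknown(classifier, names(formals(classifier_config)),
                 "classifier")
  reject_unknown(kaks, known_kaks, "kaks")
  reject_unknown(repeats, known_rep, "repeats")
  stopifnot(all(stages %in% c("classify", "scan", "kaks", "repeats")))
  sim$seed <- as.integer(seed)
  kaks <- modifyList(list(target_ks = 0.35, target_ka = 0.1,
                          truncation = 2:4, n_exons = 7L,
                          codons_per_exon = 60L, rate = NULL), kaks)
  repeats <- modifyList(list(class = "LINE", flank = 1e5), repeats)
  structure(list(sim = sim, window = window, step = step, rules = rules,
                 classifier = classifier, kaks = kaks, repeats = repeats,
                 stages = stages, seed = as.integer(seed)),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' @param path YAML file whose top-level keys are [run_config()]
#'   arguments.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  bad <- setdiff(names(y), names(formals(run_config)))
  if (length(bad)) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  do.call(run_config, y)
}

#' Run the full SDR-mapping pipeline on one simulated dataset
#'
#' Stages run in dependency order: simulate -> classify -> scan -> kaks
#' -> repeats.  Each stage's summary enters the report; with identical
#' configuration and seed the report is reproduced exactly.
#'
#' @param cfg A [run_config()].
#' @param outdir Optional directory: the report is written as
#'   `report.json` plus per-stage TSVs.
#' @return List of class `pipeline_report`: `linkage` (calls +
#'   `accuracy` vs truth), `scan` (window stats, `sdr_call`, `jaccard`
#'   vs truth, marker association), `kaks` (per-exon/gene table,
#'   `dating_my` when a rate is configured), `repeats` (per-window
#'   densities + enrichment), `truth`, `config`.
#' @export
run_pipeline <- function(cfg, outdir = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  scfg <- do.call(sim_config, cfg$sim)
  genome <- simulate_genome(scfg)
  samples <- simulate_samples(genome, scfg)
  truth <- list(sdr = c(genome$sdr_truth$start, genome$sdr_truth$end),
                classes = setNames(genome$contigs$true_class,
                                   genome$contigs$contig),
                sdg = genome$sdg)
  report <- list(truth = truth, config = cfg)

  profile <- NULL
  if (any(c("classify", "scan") %in% cfg$stages)) {
    profile <- normalize_depth(samples)
  }

  if ("classify" %in% cfg$stages) {
    ccfg <- do.call(classifier_config, cfg$classifier)
    calls <- classify_contigs(profile, samples$marker_hits, ccfg)
    calls$true_class <- truth$classes[calls$contig]
    report$linkage <- list(
      calls = calls,
      accuracy = mean(calls$class == calls$true_class))
  }

  if ("scan" %in% cfg$stages) {
    sex_contig <- genome$sdr_truth$contig
    rules <- do.call(sdr_rules, cfg$rules)
    win <- make_windows(scfg$sex_chrom_length, cfg$window, cfg$step)
    on_y <- samples$sites$contig == sex_contig
    assoc <- snp_sex_association(samples$geno[on_y, , drop = FALSE],
                                 samples$individuals$sex,
                                 samples$sites[on_y, , drop = FALSE])
    dxy <- window_dxy(as.character(genome$sequences[["chrX"]]),
                      as.character(genome$sequences[[sex_contig]]),
                      genome$alignment_map, win)
    ysp <- samples$sites$pos[on_y & samples$sites$type == "y_specific"]
    stats <- window_stats(win, assoc, profile, sex_contig, dxy,
                          y_specific_pos = ysp,
                          neg_log_p_min = rules$neg_log_p_min)
    call <- call_sdr(stats, rules)
    marker <- marker_presence_association(samples$marker_presence,
                                          samples$individuals$sex)
    report$scan <- list(
      windows = stats, sdr_call = call,
      jaccard = sdr_jaccard(call, truth$sdr),
      n_sites_skipped = attr(assoc, "skipped"),
      n_y_specific_sites = sum(samples$sites$type == "y_specific"),
      marker = marker)
  }

  if ("kaks" %in% cfg$stages) {
    k <- cfg$kaks
    pair <- simulate_gene_pair(k$target_ks, k$target_ka, k$truncation,
                               seed = cfg$seed, n_exons = k$n_exons,
                               codons_per_exon = k$codons_per_exon)
    kres <- ng86_kaks(pair$parent_aligned_cds, pair$duplicate_cds,
                      exons = pair$duplicate_exons)
    identity <- c(
      nucleotide = pairwise_identity(pair$parent_aligned_cds,
                                     pair$duplicate_cds),
      protein = pairwise_identity(pair$parent_aligned_cds,
                                  pair$duplicate_cds, level = "protein"))
    dating <- if (!is.null(k$rate)) {
      date_duplication(kres$Ks[kres$region == "gene"], k$rate)
    } else NA_real_
    report$kaks <- list(pair = pair, table = kres, identity = identity,
                        dating_my = dating)
  }

  if ("repeats" %in% cfg$stages) {
    sex_contig <- genome$sdr_truth$contig
    win <- make_windows(scfg$sex_chrom_length, cfg$window, cfg$step)
    dens <- repeat_density(genome$repeats, win, sex_contig)
    enrich <- NULL
    if (!is.na(genome$sdg)) {
      sdg_row <- genome$genes[genome$genes$gene_id == genome$sdg, ]
      par_row <- genome$genes[genome$genes$gene_id == "amh_a", ]
      fl <- cfg$repeats$flank
      enrich <- region_enrichment(
        genome$repeats,
        list(contig = sdg_row$contig,
             start = max(0, sdg_row$start - fl),
             end = min(scfg$sex_chrom_length, sdg_row$end + fl)),
        list(contig = par_row$contig,
             start = max(0, par_row$start - fl),
             end = min(scfg$autosome_length, par_row$end + fl)),
        cfg$repeats$class, seed = cfg$seed)
    }
    report$repeats <- list(density = dens, enrichment = enrich)
  }

  class(report) <- "pipeline_report"
  if (!is.null(outdir)) write_report(report, outdir)
  report
}

#' @exportS3Method base::print
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report\n")
  if (!is.null(x$linkage)) {
    cat(sprintf("  linkage: accuracy %.3f over %d contigs\n",
                x$linkage$accuracy, nrow(x$linkage$calls)))
  }
  if (!is.null(x$scan)) {
    cat(sprintf("  scan: %d SDR interval(s), Jaccard vs truth %.3f\n",
                nrow(x$scan$sdr_call$intervals), x$scan$jaccard))
    cat(sprintf("  marker: p = %.3g, perfect separation = %s\n",
                x$scan$marker$p_value,
                x$scan$marker$perfect_separation))
  }
  if (!is.null(x$kaks)) {
    g <- x$kaks$table[x$kaks$table$region == "gene", ]
    cat(sprintf("  kaks: Ka %.3f Ks %.3f omega %.3f (%s)\n",
                g$Ka, g$Ks, g$omega, g$selection_class))
  }
  if (!is.null(x$repeats) && !is.null(x$repeats$enrichment)) {
    cat(sprintf("  repeats: %s fold %.2f, perm p %.4f\n",
                x$repeats$enrichment$class, x$repeats$enrichment$fold,
                x$repeats$enrichment$p_perm))
  }
  invisible(x)
}

write_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  summary <- list(
    seed = report$config$seed,
    truth = report$truth[c("sdr", "sdg")],
    linkage_accuracy = report$linkage$accuracy,
    sdr_intervals = report$scan$sdr_call$intervals,
    sdr_jaccard = report$scan$jaccard,
    marker_p = report$scan$marker$p_value,
    marker_perfect_separation = report$scan$marker$perfect_separation,
    kaks_gene = report$kaks$table[report$kaks$table$region == "gene", ],
    dating_my = report$kaks$dating_my,
    line_fold = report$repeats$enrichment$fold,
    line_perm_p = report$repeats$enrichment$p_perm)
  jsonlite::write_json(summary, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "rows")
  if (!is.null(report$linkage)) {
    data.table::fwrite(report$linkage$calls,
                       file.path(outdir, "linkage_calls.tsv"), sep = "\t")
  }
  if (!is.null(report$scan)) {
    data.table::fwrite(report$scan$windows,
                       file.path(outdir, "window_stats.tsv"), sep = "\t")
    data.table::fwrite(report$scan$sdr_call$intervals,
                       file.path(outdir, "sdr_call.bed"), sep = "\t",
                       col.names = FALSE)
  }
  if (!is.null(report$kaks)) {
    data.table::fwrite(report$kaks$table,
                       file.path(outdir, "kaks.tsv"), sep = "\t")
  }
  if (!is.null(report$repeats)) {
    data.table::fwrite(report$repeats$density,
                       file.path(outdir, "repeat_density.tsv"),
                       sep = "\t")
  }
  invisible(outdir)
}

#' Parameter-recovery experiment over seeded simulations
#'
#' Runs the simulate-classify-scan pipeline across `n_seeds` seeds and
#' aggregates SDR recovery (Jaccard overlap with truth, boundary
#' errors), false-positive calls and classification accuracy.  Run it
#' once on a default configuration and once on a null configuration
#' (`sim$sdr_start == sim$sdr_end`) to measure recovery and the
#' false-positive rate respectively.
#'
#' @param n_seeds Number of seeds (>= 1); seed i of the experiment is
#'   `base_seed + i - 1`.
#' @param cfg A [run_config()]; its `seed` is the experiment base seed.
#' @param stages Stages to run per seed.
#' @return data.frame with one row per seed: `seed`, `jaccard`,
#'   `n_intervals`, `start_error`, `end_error` (bp, `NA` for empty
#'   calls), `accuracy`, `called_sdr`.
#' @export
recovery_experiment <- function(n_seeds, cfg = run_config(),
                                stages = c("classify", "scan")) {
  stopifnot(n_seeds >= 1)
  rows <- lapply(seq_len(n_seeds), function(i) {
    cfg_i <- cfg
    cfg_i$seed <- cfg$seed + i - 1L
    cfg_i$sim$seed <- cfg_i$seed
    cfg_i$stages <- stages
    rep_i <- run_pipeline(cfg_i)
    iv <- rep_i$scan$sdr_call$intervals
    truth <- rep_i$truth$sdr
    data.frame(
      seed = cfg_i$seed,
      jaccard = rep_i$scan$jaccard,
      n_intervals = nrow(iv),
      start_error = if (nrow(iv)) iv$start[1] - truth[1] else NA_real_,
      end_error = if (nrow(iv)) iv$end[1] - truth[2] else NA_real_,
      accuracy = if (!is.null(rep_i$linkage)) rep_i$linkage$accuracy
                 else NA_real_,
      called_sdr = nrow(iv) > 0)
  })
  do.call(rbind, rows)
}

#' Percentage of genes retained between two chromosomes
#'
#' Plain retention arithmetic, reported to two decimals: e.g. a Y
#' chromosome retaining 522 of the 545 X-chromosome genes has retained
#' 95.78%.
#'
#' @param retained,total Gene counts, `0 <= retained <= total`,
#'   `total > 0`.
#' @return `100 * retained / total`, rounded to 2 decimals.
#' @export
#' @examples
#' retention_percent(522, 545)   # 95.78
retention_percent <- function(retained, total) {
  stopifnot(total > 0, retained >= 0, retained <= total)
  round(100 * retained / total, 2)
}
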