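# Orchestration: configuration handling and the end-to-end run
# (simulate -> scan numts -> scan SVA flanks -> annotate -> abundance ->
# report), with per-stage filter funnel logging and truth-recovery
# metrics against the planted events.

#' Default end-to-end run configuration
#'
#' Every threshold exposed by the other modules, plus the synthetic-study
#' geometry. Thresholds default to the filter-chain values the method is
#' defined with (mtDNA segment <= 130 nt, flank >= 20 nt, 95% query
#' coverage, 1,000 nt tiles, identity 0.95 for subfamily queries, 150 nt
#' reads).
#'
#' @return a named list of defaults.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    # toy genome
    n_chroms = 2L, chrom_length = 50000L, gc_fraction = 0.41,
    mt_length = 16559L, n_germline_sva = 20L, n_germline_numt = 5L,
    n_alu = 20L, n_line = 6L, n_ltr = 6L, n_satellite = 3L,
    n_genes = 5L,
    # de novo events
    n_de_novo_sva = 10L, n_de_novo_numt = 10L,
    mt_len_min = 40L, mt_len_max = 400L, repeat_target_bias = 0,
    # sequencing
    read_len = 150L, coverage = 30, mt_copy_number = 10,
    error_rate = 0, n_wgs_datasets = 2L, n_rda_replicates = 3L,
    rda_adaptor = rda_adaptor_default(), rda_flank_len = 80L,
    subtraction_efficiency = 1.0, amplification = 20L,
    max_amplicon = 5000L,
    # filters
    min_mt_len = 30L, max_mt_len = 130L, min_flank = 20L,
    min_query_cov = 0.95, merge_window = 100L,
    exclusion_window = 100L, collapse_tol = 20L, overlap_tol = 20L,
    # abundance
    tile_len = 1000L, min_identity = 0.95,
    # recovery bookkeeping
    truth_tol = 15L
  )
}

#' Load and validate a run configuration
#'
#' Reads a YAML file (or takes a list), merges it over
#' [default_config()], and rejects unknown keys.
#'
#' @param config path to a YAML file, a list of overrides, or NULL for
#'   defaults.
#' @return the effective configuration list.
#' @export
load_config <- function(config = NULL) {
  base <- default_config()
  if (is.null(config)) return(base)
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), names(base))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  utils::modifyList(base, config)
}

#' Exact integer aggregation of per-replicate / per-dataset counts
#'
#' @param x numeric vector of counts.
#' @return their exact integer sum.
#' @export
aggregate_counts <- function(x) {
  stopifnot(all(x == round(x)))
  sum(as.integer(x))
}

log_funnel <- function(stage, funnel, verbose) {
  if (!verbose || is.null(funnel)) return(invisible())
  message(stage, ": ",
          paste(names(funnel), funnel, sep = "=", collapse = " "))
}

#' Run the full pipeline end to end on a synthetic study
#'
#' Simulates a proliferating/senescent genome pair with planted events,
#' generates WGS, RDA and AluScan reads, runs the numt and SVA callers,
#' annotates target sites, profiles mtDNA tile abundance, and assembles a
#' summary report with truth-recovery metrics. Deterministic for a fixed
#' seed.
#'
#' @param config see [load_config()].
#' @param outdir optional output directory; when given, FASTA/FASTQ/BED/
#'   TSV artifacts and the effective config are written there.
#' @param verbose emit per-stage funnel counts via `message()`.
#' @return a `senomob_report` list.
#' @export
run_all <- function(config = NULL, outdir = NULL, verbose = FALSE) {
  cfg <- load_config(config)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    yaml::write_yaml(cfg, file.path(outdir, "effective_config.yaml"))
  }

  # --- simulate -----------------------------------------------------------
  spec <- toy_genome_spec(
    n_chroms = cfg$n_chroms, chrom_length = cfg$chrom_length,
    gc_fraction = cfg$gc_fraction, mt_length = cfg$mt_length,
    n_germline_sva = cfg$n_germline_sva,
    n_germline_numt = cfg$n_germline_numt, n_alu = cfg$n_alu,
    n_line = cfg$n_line, n_ltr = cfg$n_ltr,
    n_satellite = cfg$n_satellite, n_genes = cfg$n_genes,
    seed = cfg$seed)
  tg <- make_toy_genome(spec)
  ev <- plant_de_novo_events(
    tg, n_sva = cfg$n_de_novo_sva, n_numt = cfg$n_de_novo_numt,
    params = list(mt_len_range = c(cfg$mt_len_min, cfg$mt_len_max),
                  repeat_target_bias = cfg$repeat_target_bias),
    seed = cfg$seed + 101L)
  truth <- ev$truth
  if (!is.null(outdir)) {
    write_toy_genome(tg, outdir)
    write_fasta(ev$senescent, file.path(outdir, "senescent.fa"))
    write_truth(truth, file.path(outdir, "truth.bed"))
  }

  # --- numt scanning (WGS datasets + AluScan) ----------------------------
  numt_calls <- list()
  sen_wgs_all <- list()
  for (d in seq_len(cfg$n_wgs_datasets)) {
    sen_reads <- simulate_wgs(ev$senescent, tg$mt, coverage = cfg$coverage,
                              read_len = cfg$read_len,
                              mt_copy_number = cfg$mt_copy_number,
                              error_rate = cfg$error_rate,
                              seed = cfg$seed + 200L + d,
                              prefix = sprintf("wgs%d_sen", d))
    pro_reads <- simulate_wgs(tg$nuclear, tg$mt, coverage = cfg$coverage,
                              read_len = cfg$read_len,
                              mt_copy_number = cfg$mt_copy_number,
                              error_rate = cfg$error_rate,
                              seed = cfg$seed + 300L + d,
                              prefix = sprintf("wgs%d_pro", d))
    sen_wgs_all[[d]] <- sen_reads
    sen_pl <- numt_scan_sample(sen_reads, tg$nuclear, tg$mt,
                               min_mt_len = cfg$min_mt_len,
                               max_mt_len = cfg$max_mt_len,
                               min_flank = cfg$min_flank,
                               min_query_cov = cfg$min_query_cov)
    log_funnel(sprintf("numt WGS%d senescent", d),
               attr(sen_pl, "funnel"), verbose)
    pro_pl <- numt_scan_sample(pro_reads, tg$nuclear, tg$mt,
                               min_mt_len = cfg$min_mt_len,
                               max_mt_len = cfg$max_mt_len,
                               min_flank = cfg$min_flank,
                               min_query_cov = cfg$min_query_cov)
    numt_calls[[sprintf("WGS%d", d)]] <- call_de_novo(
      sen_pl, pro_pl, known_numts = tg$numt,
      merge_window = cfg$merge_window, dataset = sprintf("WGS%d", d))
  }
  # AluScan: inter-Alu amplicons on both samples
  alus <- tg$repeats[tg$repeats$class == "SINE"]
  alus_sen <- alus
  if (length(alus) > 0) {
    GenomicRanges::ranges(alus_sen) <- IRanges::IRanges(
      ev$ref_to_sen(as.character(GenomicRanges::seqnames(alus)),
                    GenomicRanges::start(alus)),
      ev$ref_to_sen(as.character(GenomicRanges::seqnames(alus)),
                    GenomicRanges::end(alus)))
  }
  sen_alu <- simulate_aluscan(ev$senescent, alus_sen,
                              max_amplicon = cfg$max_amplicon,
                              read_len = cfg$read_len)
  pro_alu <- simulate_aluscan(tg$nuclear, alus,
                              max_amplicon = cfg$max_amplicon,
                              read_len = cfg$read_len)
  sen_pl <- numt_scan_sample(sen_alu, tg$nuclear, tg$mt,
                             min_mt_len = cfg$min_mt_len,
                             max_mt_len = cfg$max_mt_len,
                             min_flank = cfg$min_flank,
                             min_query_cov = cfg$min_query_cov)
  pro_pl <- numt_scan_sample(pro_alu, tg$nuclear, tg$mt,
                             min_mt_len = cfg$min_mt_len,
                             max_mt_len = cfg$max_mt_len,
                             min_flank = cfg$min_flank,
                             min_query_cov = cfg$min_query_cov)
  numt_calls[["AluScan"]] <- call_de_novo(
    sen_pl, pro_pl, known_numts = tg$numt,
    merge_window = cfg$merge_window, dataset = "AluScan")

  # --- SVA / RDA replicates ----------------------------------------------
  germ <- tg$sva
  germ_pos5 <- ifelse(as.character(GenomicRanges::strand(germ)) == "-",
                      GenomicRanges::end(germ), GenomicRanges::start(germ))
  sva_truth <- truth[truth$kind == "de_novo_sva", , drop = FALSE]
  loci <- rbind(
    if (length(germ) > 0) data.frame(
      chrom = as.character(GenomicRanges::seqnames(germ)),
      pos5 = ev$ref_to_sen(as.character(GenomicRanges::seqnames(germ)),
                           germ_pos5),
      strand = as.character(GenomicRanges::strand(germ)),
      is_de_novo = FALSE, stringsAsFactors = FALSE),
    if (nrow(sva_truth) > 0) data.frame(
      chrom = sva_truth$chrom, pos5 = sva_truth$sen_start,
      strand = "+", is_de_novo = TRUE, stringsAsFactors = FALSE))
  sva_calls <- list()
  for (r in seq_len(cfg$n_rda_replicates)) {
    reads <- simulate_rda(ev$senescent, loci, adaptor = cfg$rda_adaptor,
                          flank_len = cfg$rda_flank_len,
                          subtraction_efficiency =
                            cfg$subtraction_efficiency,
                          amplification = cfg$amplification,
                          read_len = cfg$read_len,
                          seed = cfg$seed + 400L + r)
    fl <- parse_amplicons(reads, adaptor_seq = cfg$rda_adaptor)
    calls <- call_insertions(fl, tg$nuclear, tg$sva,
                             exclusion_window = cfg$exclusion_window,
                             collapse_tol = cfg$collapse_tol,
                             min_query_cov = cfg$min_query_cov,
                             replicate = sprintf("Sen_%d", r))
    log_funnel(sprintf("sva Sen_%d", r), attr(calls, "funnel"), verbose)
    sva_calls[[sprintf("Sen_%d", r)]] <- calls
  }

  # --- annotation ---------------------------------------------------------
  sva_labels <- lapply(sva_calls, function(g)
    annotate_sites(g, tg$genes, tg$repeats))
  numt_all <- suppressWarnings(do.call(c, unname(numt_calls)))
  numt_labels <- annotate_sites(numt_all, tg$genes, tg$repeats)
  sva_fracs <- if (any(lengths(sva_labels) > 0))
    summarize_fractions(sva_labels[lengths(sva_labels) > 0]) else NULL
  numt_fracs <- if (length(numt_labels) > 0)
    summarize_fractions(numt_labels) else NULL
  all_sva_calls <- suppressWarnings(do.call(c, unname(sva_calls)))
  cleavage <- if (length(all_sva_calls) > 0)
    scan_cleavage_consensus(
      extract_flank_windows(tg$nuclear, all_sva_calls, window = 10L))
  else list(fraction = NA_real_, verdicts = logical(0))

  # --- abundance (mtDNA tiles, WGS1) -------------------------------------
  tiles <- tile_genome(tg$mt, tile_len = cfg$tile_len)
  sen_r <- sen_wgs_all[[1]]
  pro_r <- simulate_wgs(tg$nuclear, tg$mt, coverage = cfg$coverage,
                        read_len = cfg$read_len,
                        mt_copy_number = cfg$mt_copy_number,
                        error_rate = cfg$error_rate,
                        seed = cfg$seed + 301L, prefix = "wgs1_pro")
  tile_queries <- stats::setNames(tiles$seq, tiles$name)
  tile_profile <- abundance_profile(sen_r, pro_r, tile_queries,
                                    min_identity = 1.0)

  # --- summaries & truth recovery ----------------------------------------
  sva_sum <- lapply(sva_calls, summarize_sva)
  per_rep_total <- vapply(sva_sum, `[[`, numeric(1), "total")
  per_rep_unique <- vapply(sva_sum, `[[`, numeric(1), "unique")
  numt_per_dataset <- vapply(numt_calls, length, integer(1))
  venn <- if (length(sva_calls) >= 2)
    replicate_overlap(sva_calls, tolerance = cfg$overlap_tol) else NULL

  recovery <- truth_recovery(truth, sva_calls, numt_calls,
                             sen_wgs_all, tg, cfg)

  report <- list(
    config = cfg,
    sva = list(per_replicate_total = per_rep_total,
               per_replicate_unique = per_rep_unique,
               total = aggregate_counts(per_rep_total),
               unique = aggregate_counts(per_rep_unique),
               venn = venn, fractions = sva_fracs,
               cleavage_fraction = cleavage$fraction,
               calls = sva_calls),
    numt = list(per_dataset = numt_per_dataset,
                total = aggregate_counts(numt_per_dataset),
                fractions = numt_fracs,
                composition = mito_composition(numt_all, tg$mt_genes,
                                               L = cfg$mt_length),
                calls = numt_calls),
    abundance = tile_profile,
    recovery = recovery,
    truth = truth)
  class(report) <- "senomob_report"
  if (!is.null(outdir)) write_report(report, outdir)
  report
}

# Sensitivity and false-call counts against the planted truth.
truth_recovery <- function(truth, sva_calls, numt_calls, sen_wgs_all,
                           tg, cfg) {
  tol <- cfg$truth_tol
  near_truth <- function(chrom, pos, kind) {
    tt <- truth[truth$kind == kind, , drop = FALSE]
    if (nrow(tt) == 0) return(logical(length(pos)))
    mapply(function(c_, p_) any(tt$chrom == c_ & abs(tt$ins_at - p_) <= tol),
           chrom, pos, USE.NAMES = FALSE)
  }
  # SVA: recovered when any replicate calls within tol of the truth point
  sva_t <- truth[truth$kind == "de_novo_sva", , drop = FALSE]
  all_sva <- suppressWarnings(do.call(c, unname(sva_calls)))
  sva_recovered <- vapply(seq_len(nrow(sva_t)), function(i) {
    any(as.character(GenomicRanges::seqnames(all_sva)) == sva_t$chrom[i] &
          abs(GenomicRanges::start(all_sva) - sva_t$ins_at[i]) <= tol)
  }, logical(1))
  sva_false <- if (length(all_sva) > 0)
    sum(!near_truth(as.character(GenomicRanges::seqnames(all_sva)),
                    GenomicRanges::start(all_sva), "de_novo_sva")) else 0L
  # numts: detectable set from the WGS senescent reads
  wgs_reads <- do.call(c, sen_wgs_all)
  detectable <- detectable_numt_events(
    truth, wgs_reads, tg$nuclear, tg$mt, min_mt_len = cfg$min_mt_len,
    max_mt_len = cfg$max_mt_len, min_flank = cfg$min_flank,
    min_query_cov = cfg$min_query_cov)
  numt_t <- truth[truth$kind == "de_novo_numt", , drop = FALSE]
  all_numt <- suppressWarnings(do.call(c, unname(numt_calls)))
  numt_recovered <- vapply(seq_len(nrow(numt_t)), function(i) {
    any(as.character(GenomicRanges::seqnames(all_numt)) == numt_t$chrom[i] &
          abs(GenomicRanges::start(all_numt) - numt_t$ins_at[i]) <= tol)
  }, logical(1))
  names(numt_recovered) <- numt_t$event_id
  numt_false <- if (length(all_numt) > 0)
    sum(!near_truth(as.character(GenomicRanges::seqnames(all_numt)),
                    GenomicRanges::start(all_numt), "de_novo_numt")) else 0L
  list(
    sva_planted = nrow(sva_t), sva_recovered = sum(sva_recovered),
    sva_sensitivity = if (nrow(sva_t) > 0)
      mean(sva_recovered) else NA_real_,
    sva_false_calls = sva_false,
    numt_planted = nrow(numt_t),
    numt_detectable = sum(detectable),
    numt_detectable_recovered =
      sum(numt_recovered[names(detectable)[detectable]]),
    numt_sensitivity_detectable = if (sum(detectable) > 0)
      mean(numt_recovered[names(detectable)[detectable]]) else NA_real_,
    numt_false_calls = numt_false)
}

#' Write report artifacts (TSV + human-readable text)
#'
#' @param report a `senomob_report`.
#' @param outdir output directory.
#' @export
write_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(report$sva$calls))
    write_bed(report$sva$calls[[nm]],
              file.path(outdir, paste0("sva_calls_", nm, ".bed")))
  for (nm in names(report$numt$calls)) {
    g <- report$numt$calls[[nm]]
    write_bed(g, file.path(outdir, paste0("numt_calls_", nm, ".bed")))
    side <- data.frame(name = g$name, mt_start = g$mt_start0,
                       mt_end = g$mt_end0, support = g$support,
                       dataset = g$dataset)
    utils::write.table(side, file.path(outdir,
                                       paste0("numt_calls_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(report$abundance,
                     file.path(outdir, "mt_tile_profile.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$numt$composition,
                     file.path(outdir, "mito_composition.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$sva$fractions))
    utils::write.table(report$sva$fractions,
                       file.path(outdir, "sva_feature_fractions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$sva$venn))
    utils::write.table(report$sva$venn, file.path(outdir, "sva_venn.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  txt <- utils::capture.output(print(report))
  writeLines(txt, file.path(outdir, "report.txt"))
  invisible(outdir)
}

#' @export
print.senomob_report <- function(x, ...) {
  cat("== senomob end-to-end report ==\n")
  cat("SVA insertions: total", x$sva$total, "unique", x$sva$unique, "\n")
  cat("  per replicate totals:",
      paste(names(x$sva$per_replicate_total),
            x$sva$per_replicate_total, sep = "=", collapse = " "), "\n")
  cat("  per replicate uniques:",
      paste(names(x$sva$per_replicate_unique),
            x$sva$per_replicate_unique, sep = "=", collapse = " "), "\n")
  cat("De novo numts: total", x$numt$total, "(",
      paste(names(x$numt$per_dataset), x$numt$per_dataset, sep = "=",
            collapse = " "), ")\n")
  r <- x$recovery
  cat("Truth recovery: SVA", r$sva_recovered, "/", r$sva_planted,
      "(false calls:", r$sva_false_calls, ")\n")
  cat("  numts:", r$numt_detectable_recovered, "/", r$numt_detectable,
      "detectable of", r$numt_planted, "planted (false calls:",
      r$numt_false_calls, ")\n")
  invisible(x)
}
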