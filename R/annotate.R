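# Single-label genomic feature annotation of target sites with fixed
# precedence (a reimplementation of the usual peak-annotation logic), plus
# the deterministic L1-endonuclease consensus (TTTT/AA) scan.

FEATURE_PRECEDENCE <- c("Promoter", "3UTR", "Exon", "TTS", "SINE", "LINE",
                        "LTR", "Satellite", "DNA", "Intron", "Intergenic")
REPEAT_CLASSES <- c("SINE", "LINE", "LTR", "Satellite", "DNA")
GENE_FEATURE_MAP <- c(promoter = "Promoter", exon = "Exon",
                      intron = "Intron", `3UTR` = "3UTR", TTS = "TTS")

#' Annotate target sites with a single feature class
#'
#' Each site receives exactly one label under the fixed precedence
#' Promoter > 3UTR > Exon > TTS > SINE > LINE > LTR > Satellite > DNA >
#' Intron > Intergenic. By default a site is annotated by the features
#' containing its midpoint ("midpoint" rule); `mode = "any"` uses any >= 1
#' bp overlap instead. Promoter and TTS intervals are expected in the gene
#' annotation (the toy-genome generator emits promoter = TSS -1000..+100
#' and TTS = end -100..+1000).
#'
#' @param sites `GRanges` of target sites.
#' @param genes `GRanges` with a `feature` column in
#'   {promoter, exon, intron, 3UTR, TTS}.
#' @param repeats `GRanges` with a `class` column in
#'   {SINE, LINE, LTR, Satellite, DNA}.
#' @param mode overlap rule, "midpoint" or "any".
#' @return factor of labels (levels = the precedence order), one per site.
#' @export
annotate_sites <- function(sites, genes, repeats,
                           mode = c("midpoint", "any")) {
  mode <- match.arg(mode)
  if (length(repeats) > 0) {
    bad <- setdiff(unique(repeats$class), REPEAT_CLASSES)
    if (length(bad))
      stop("unknown repeat class tag(s): ", paste(bad, collapse = ", "),
           "; accepted tags are: ", paste(REPEAT_CLASSES, collapse = ", "))
  }
  if (length(genes) > 0) {
    bad <- setdiff(unique(genes$feature), names(GENE_FEATURE_MAP))
    if (length(bad))
      stop("unknown gene feature tag(s): ", paste(bad, collapse = ", "),
           "; accepted tags are: ",
           paste(names(GENE_FEATURE_MAP), collapse = ", "))
  }
  query <- if (mode == "midpoint") {
    mid <- floor((GenomicRanges::start(sites) +
                    GenomicRanges::end(sites)) / 2)
    GenomicRanges::GRanges(GenomicRanges::seqnames(sites),
                           IRanges::IRanges(mid, mid))
  } else GenomicRanges::granges(sites)
  labels <- rep("Intergenic", length(sites))
  feats <- c(
    if (length(genes) > 0) {
      g <- GenomicRanges::granges(genes)
      g$label <- unname(GENE_FEATURE_MAP[genes$feature])
      g
    },
    if (length(repeats) > 0) {
      r <- GenomicRanges::granges(repeats)
      r$label <- repeats$class
      r
    })
  if (!is.null(feats) && length(feats) > 0) {
    hits <- IRanges::findOverlaps(query, feats, ignore.strand = TRUE)
    if (length(hits) > 0) {
      qh <- S4Vectors::queryHits(hits)
      lab <- feats$label[S4Vectors::subjectHits(hits)]
      rank <- match(lab, FEATURE_PRECEDENCE)
      best <- tapply(seq_along(qh), qh, function(ii) lab[ii][which.min(rank[ii])])
      labels[as.integer(names(best))] <- unlist(best)
    }
  }
  factor(labels, levels = FEATURE_PRECEDENCE)
}

#' @rdname annotate_sites
#' @param site a single `GRanges` site.
#' @export
annotate_site <- function(site, genes, repeats,
                          mode = c("midpoint", "any")) {
  annotate_sites(site[1], genes, repeats, mode)[1]
}

#' Per-class fraction summary across replicates
#'
#' Per replicate, the class percentage is count/total x 100; the standard
#' error is sd/sqrt(n) across replicates (0 for a single replicate).
#' Classes absent everywhere are reported with 0.
#'
#' @param labels_per_replicate a factor (one replicate) or list of factors
#'   from [annotate_sites()].
#' @return data.frame with class, mean_pct, se and per-replicate counts.
#' @export
summarize_fractions <- function(labels_per_replicate) {
  if (!is.list(labels_per_replicate))
    labels_per_replicate <- list(labels_per_replicate)
  if (length(labels_per_replicate) == 0 ||
      all(lengths(labels_per_replicate) == 0))
    stop("summarize_fractions: no sites to summarize")
  pcts <- vapply(labels_per_replicate, function(lab) {
    lab <- factor(lab, levels = FEATURE_PRECEDENCE)
    100 * as.numeric(table(lab)) / length(lab)
  }, numeric(length(FEATURE_PRECEDENCE)))
  pcts <- matrix(pcts, nrow = length(FEATURE_PRECEDENCE))
  n <- ncol(pcts)
  se <- if (n > 1) apply(pcts, 1, stats::sd) / sqrt(n) else
    rep(0, nrow(pcts))
  data.frame(class = FEATURE_PRECEDENCE,
             mean_pct = rowMeans(pcts), se = se,
             stringsAsFactors = FALSE)
}

#' L1 endonuclease consensus (TTTT/AA) scan around insertion points
#'
#' A site matches when either strand of its flanking window contains TTTT
#' immediately followed by AA, allowing at most one mismatch within the
#' TTTT tract (the AA must be exact). Sequences are expected centered on
#' the insertion point, covering about +/- `window` nt.
#'
#' @param seqs character vector (or `DNAStringSet`) of flanking windows.
#' @param window half-window size in nt (>= 6); used only to trim
#'   overlong inputs symmetrically.
#' @return list with `fraction` (matched fraction) and `verdicts`
#'   (logical per site).
#' @export
scan_cleavage_consensus <- function(seqs, window = 10L) {
  stopifnot(window >= 6L)
  seqs <- toupper(as.character(as_dna_set(seqs)))
  trim <- function(s) {
    n <- nchar(s)
    if (n > 2 * window + 1) {
      mid <- ceiling(n / 2)
      substring(s, max(1L, mid - window), min(n, mid + window))
    } else s
  }
  seqs <- vapply(seqs, trim, character(1), USE.NAMES = FALSE)
  match_one_strand <- function(s) {
    n <- nchar(s)
    if (n < 6) return(FALSE)
    for (i in seq_len(n - 5L)) {
      tract <- substring(s, i, i + 3L)
      aa <- substring(s, i + 4L, i + 5L)
      if (aa != "AA") next
      mism <- sum(strsplit(tract, "")[[1]] != "T")
      if (mism <= 1) return(TRUE)
    }
    FALSE
  }
  verdicts <- vapply(seqs, function(s)
    match_one_strand(s) || match_one_strand(revcomp(s)),
    logical(1), USE.NAMES = FALSE)
  list(fraction = if (length(verdicts)) mean(verdicts) else NA_real_,
       verdicts = verdicts)
}

#' Extract flanking windows around insertion points
#'
#' @param genome `DNAStringSet`.
#' @param sites width-1 `GRanges` of insertion points.
#' @param window half-window in nt.
#' @return character vector of sequences (clipped at chromosome ends).
#' @export
extract_flank_windows <- function(genome, sites, window = 10L) {
  chrom_chr <- stats::setNames(as.character(genome), names(genome))
  ch <- as.character(GenomicRanges::seqnames(sites))
  pos <- GenomicRanges::start(sites)
  mapply(function(c_, p_) {
    substring(chrom_chr[[c_]], max(1L, p_ - window),
              min(nchar(chrom_chr[[c_]]), p_ + window))
  }, ch, pos, USE.NAMES = FALSE)
}
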