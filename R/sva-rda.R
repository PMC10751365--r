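# De novo SVA insertion calling from RDA amplicon reads. Each informative
# read carries the RDA adaptor, a nuclear flank, and the SVA 5' hexamer
# run (CCCTCT)n; the flank between the two landmarks is placed on the
# genome under the same uniqueness contract as the numt scanner, annotated
# SVA loci are excluded, and nearby placements collapse into insertion
# calls with read support.

#' Parse RDA amplicon reads into flank records
#'
#' Locates the adaptor (exact match, forward then reverse-complement
#' orientation) and the first downstream run of at least
#' `min_hexamer_repeats` exact CCCTCT units; the flank is the intervening
#' sequence. Reads lacking either landmark, or with a flank shorter than
#' 20 nt, are rejected with a reason.
#'
#' @param reads named `DNAStringSet` of amplicon reads.
#' @param adaptor_seq RDA adaptor sequence (nonempty).
#' @param hexamer hexamer unit (default CCCTCT).
#' @param min_hexamer_repeats minimum number of exact units.
#' @return data.frame with read_id, status ("ok", "no_adaptor",
#'   "no_hexamer", "short_flank"), orientation and flank_seq.
#' @export
parse_amplicons <- function(reads, adaptor_seq = rda_adaptor_default(),
                            hexamer = "CCCTCT", min_hexamer_repeats = 3L) {
  stopifnot(nzchar(adaptor_seq))
  n <- length(reads)
  res <- data.frame(read_id = if (n) names(reads) else character(0),
                    status = character(n), orientation = character(n),
                    flank_seq = character(n), stringsAsFactors = FALSE)
  if (n == 0) return(res)
  hexrun <- strrep(hexamer, min_hexamer_repeats)
  fwd <- as.character(reads)
  rev_ <- revcomp(fwd)
  for (i in seq_len(n)) {
    found <- FALSE
    for (orient in c("+", "-")) {
      s <- if (orient == "+") fwd[i] else rev_[i]
      ad <- regexpr(adaptor_seq, s, fixed = TRUE)
      if (ad < 0) next
      found <- TRUE
      ad_end <- ad + nchar(adaptor_seq) - 1L
      hx <- gregexpr(hexrun, s, fixed = TRUE)[[1]]
      hx <- hx[hx > ad_end]
      if (length(hx) == 0 || hx[1] < 0) {
        res$status[i] <- "no_hexamer"; res$orientation[i] <- orient
        break
      }
      flank <- substring(s, ad_end + 1L, hx[1] - 1L)
      if (nchar(flank) < 20L) {
        res$status[i] <- "short_flank"; res$orientation[i] <- orient
        break
      }
      res$status[i] <- "ok"; res$orientation[i] <- orient
      res$flank_seq[i] <- flank
      break
    }
    if (!found) res$status[i] <- "no_adaptor"
  }
  res
}

#' @rdname parse_amplicons
#' @param read a single read.
#' @export
parse_amplicon <- function(read, adaptor_seq = rda_adaptor_default(),
                           hexamer = "CCCTCT", min_hexamer_repeats = 3L) {
  r <- as_dna_set(read)
  if (is.null(names(r)) || !nzchar(names(r)[1])) names(r) <- "read"
  parse_amplicons(r, adaptor_seq, hexamer, min_hexamer_repeats)[1, ]
}

#' Call de novo SVA insertions from parsed flanks
#'
#' Each distinct flank sequence is placed on the genome
#' ([place_flank()] contract: >= 95% query coverage, gapless, unique best
#' score). The insertion point is the flank end adjacent to the hexamer.
#' Placements within `exclusion_window` nt of an annotated SVA are
#' discarded as germline-derived; surviving insertion points within
#' `collapse_tol` nt collapse into one call with summed read support.
#'
#' @param flanks data.frame from [parse_amplicons()] (rows with status
#'   "ok" are used).
#' @param nuclear `DNAStringSet` reference genome.
#' @param annotated_sva `GRanges` of annotated SVA elements.
#' @param exclusion_window exclusion distance around annotated SVAs (nt).
#' @param collapse_tol collapse tolerance between insertion points (nt).
#' @param min_query_cov placement query-coverage threshold.
#' @param replicate replicate label carried on calls.
#' @return `GRanges` of width-1 insertion calls with `support` and
#'   `replicate` metadata; a `funnel` attribute records per-stage counts.
#' @export
call_insertions <- function(flanks, nuclear, annotated_sva,
                            exclusion_window = 100L, collapse_tol = 20L,
                            min_query_cov = 0.95, replicate = "rep1") {
  empty <- GenomicRanges::GRanges(name = character(0), score = numeric(0),
                                  support = integer(0),
                                  replicate = character(0))
  ok <- flanks[flanks$status == "ok", , drop = FALSE]
  funnel <- c(flanks = nrow(ok), placed = 0L, not_unique = 0L,
              no_placement = 0L, near_annotated_sva = 0L)
  if (nrow(ok) == 0) { attr(empty, "funnel") <- funnel; return(empty) }
  uniq_seq <- unique(ok$flank_seq)
  placements <- lapply(uniq_seq, place_flank, nuclear = nuclear,
                       min_query_cov = min_query_cov)
  names(placements) <- uniq_seq
  pts <- list()
  for (i in seq_len(nrow(ok))) {
    pl <- placements[[ok$flank_seq[i]]]
    if (pl$status != "placed") {
      funnel[pl$status] <- funnel[pl$status] + 1L
      next
    }
    funnel["placed"] <- funnel["placed"] + 1L
    # insertion point: the base just past the flank end nearest the hexamer
    pt <- if (pl$strand == "+") pl$end + 1L else pl$start - 1L
    pts[[length(pts) + 1L]] <- data.frame(
      read_id = ok$read_id[i], chrom = pl$chrom, pos = pt,
      stringsAsFactors = FALSE)
  }
  if (length(pts) == 0) { attr(empty, "funnel") <- funnel; return(empty) }
  df <- do.call(rbind, pts)
  if (length(annotated_sva) > 0) {
    pgr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$pos, df$pos))
    near <- IRanges::overlapsAny(
      pgr, GenomicRanges::resize(
        GenomicRanges::granges(annotated_sva),
        GenomicRanges::width(annotated_sva) + 2L * exclusion_window,
        fix = "center"),
      ignore.strand = TRUE)
    funnel["near_annotated_sva"] <- sum(near)
    df <- df[!near, , drop = FALSE]
  }
  if (nrow(df) == 0) { attr(empty, "funnel") <- funnel; return(empty) }
  calls <- list()
  for (ch in unique(df$chrom)) {
    d <- df[df$chrom == ch, , drop = FALSE]
    d <- d[order(d$pos), , drop = FALSE]
    cl <- cumsum(c(1L, diff(d$pos) > collapse_tol))
    for (g in split(seq_len(nrow(d)), cl)) {
      calls[[length(calls) + 1L]] <- data.frame(
        chrom = ch, pos = round(stats::median(d$pos[g])),
        support = length(g), stringsAsFactors = FALSE)
    }
  }
  cd <- do.call(rbind, calls)
  gr <- GenomicRanges::GRanges(
    cd$chrom, IRanges::IRanges(cd$pos, cd$pos),
    name = sprintf("%s_sva_%04d", replicate, seq_len(nrow(cd))),
    score = cd$support, support = cd$support, replicate = replicate)
  gr <- sort_gr(gr)
  attr(gr, "funnel") <- funnel
  gr
}

#' Summaries of insertion calls: totals, uniques, chromosomal distribution
#'
#' Total = summed read support over calls; unique = number of distinct
#' collapsed coordinates; the chromosomal distribution is log10 of total
#' read support per chromosome (chromosomes with zero support are absent).
#'
#' @param calls `GRanges` from [call_insertions()].
#' @return list with `total`, `unique` and `per_chrom` (data.frame chrom,
#'   support, log10_support).
#' @export
summarize_sva <- function(calls) {
  if (length(calls) == 0)
    return(list(total = 0L, unique = 0L,
                per_chrom = data.frame(chrom = character(0),
                                       support = integer(0),
                                       log10_support = numeric(0))))
  supp <- tapply(calls$support,
                 as.character(GenomicRanges::seqnames(calls)), sum)
  supp <- supp[supp > 0]
  list(total = sum(calls$support), unique = length(calls),
       per_chrom = data.frame(chrom = names(supp),
                              support = as.integer(supp),
                              log10_support = log10(as.numeric(supp)),
                              row.names = NULL))
}

#' Replicate overlap (Venn counts) of insertion call sets
#'
#' Two coordinates are shared when they lie within `tolerance` nt on the
#' same chromosome; transitive clusters are counted once. Returns the
#' number of clusters for every replicate subset, consistent with
#' inclusion-exclusion by construction (each cluster is assigned to
#' exactly one subset, its exact membership).
#'
#' @param call_sets named list (>= 2) of `GRanges` call sets.
#' @param tolerance pairing tolerance in nt.
#' @return data.frame with one row per nonempty subset: `members`
#'   (comma-separated replicate names) and `count`.
#' @export
replicate_overlap <- function(call_sets, tolerance = 20L) {
  stopifnot(length(call_sets) >= 2)
  if (is.null(names(call_sets)))
    names(call_sets) <- paste0("rep", seq_along(call_sets))
  pts <- do.call(rbind, lapply(names(call_sets), function(nm) {
    g <- call_sets[[nm]]
    if (length(g) == 0)
      return(data.frame(chrom = character(0), pos = integer(0),
                        set = character(0)))
    data.frame(chrom = as.character(GenomicRanges::seqnames(g)),
               pos = GenomicRanges::start(g), set = nm,
               stringsAsFactors = FALSE)
  }))
  sets <- names(call_sets)
  if (nrow(pts) == 0)
    return(data.frame(members = character(0), count = integer(0)))
  clusters <- list()
  for (ch in unique(pts$chrom)) {
    d <- pts[pts$chrom == ch, , drop = FALSE]
    d <- d[order(d$pos), , drop = FALSE]
    cl <- cumsum(c(1L, diff(d$pos) > tolerance))
    for (g in split(seq_len(nrow(d)), cl))
      clusters[[length(clusters) + 1L]] <- sort(unique(d$set[g]))
  }
  members <- vapply(clusters, paste, character(1), collapse = ",")
  tab <- table(members)
  data.frame(members = names(tab), count = as.integer(tab),
             row.names = NULL, stringsAsFactors = FALSE)
}
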