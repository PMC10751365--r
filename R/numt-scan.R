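# De novo numt detection from chimeric reads. Filter chain: a maximal
# 100%-identity mtDNA segment per read (>= min_mt_len, default 30 nt;
# both strands, circular origin transparent), segments longer than 130 nt
# discarded, remaining nuclear flank of >= 20 nt placed on the nuclear
# genome (>= 95% query coverage, gapless, unique best score, no residual
# mtDNA), proliferating-sample placements and known numts subtracted,
# surviving placements merged into calls. Both boundaries are inclusive:
# segments of exactly 130 nt and flanks of exactly 20 nt pass.

empty_candidates <- function() {
  data.frame(read_id = character(0), read_len = integer(0),
             strand = character(0), r_start = integer(0),
             r_end = integer(0), mt_start0 = integer(0),
             mt_end0 = integer(0), seg_len = integer(0),
             full_read = logical(0), stringsAsFactors = FALSE)
}

#' Scan one read for perfect mtDNA segments
#'
#' Returns one candidate per maximal 100%-identity mtDNA segment of length
#' >= `min_mt_len` in the read (both strands; segments may span the
#' circular origin). `r_start`/`r_end` are 1-based closed positions on the
#' forward read; `mt_start0`/`mt_end0` are 0-based half-open on the mtDNA
#' with `mt_start0 < L` (`mt_end0` may exceed L for origin-spanning
#' segments).
#'
#' @param read a single read (`DNAString`, character, or 1-element
#'   `DNAStringSet`).
#' @param mt a [circular_genome()].
#' @param min_mt_len minimum countable mtDNA segment length (nt).
#' @return a candidate data.frame (possibly 0-row).
#' @export
scan_read <- function(read, mt, min_mt_len = 30L) {
  qq <- query_as_char(read)
  psl <- align_exact(read, mt, min_len = min_mt_len, query_name = qq$name)
  if (nrow(psl) == 0) return(empty_candidates())
  data.frame(read_id = psl$qName, read_len = psl$qSize,
             strand = psl$strand, r_start = psl$qStart + 1L,
             r_end = psl$qEnd, mt_start0 = psl$tStart, mt_end0 = psl$tEnd,
             seg_len = psl$qEnd - psl$qStart,
             full_read = psl$qEnd - psl$qStart == psl$qSize,
             stringsAsFactors = FALSE)
}

#' Scan many reads for perfect mtDNA segments (batched)
#'
#' Semantically identical to [scan_read()] applied per read, but runs a
#' single multi-pattern search of the (doubled) mtDNA k-mers over all
#' reads. Reads that are full-length exact mtDNA substrings are
#' short-circuited into whole-read candidates with NA mtDNA coordinates
#' (such reads have no nuclear flank and can never survive the filter
#' chain, so their exact mtDNA position is irrelevant). Reads with more
#' than 10% N are dropped; the number dropped is recorded in the
#' `n_dropped` attribute.
#'
#' @param reads a named `DNAStringSet`.
#' @inheritParams scan_read
#' @return a candidate data.frame.
#' @export
scan_reads <- function(reads, mt, min_mt_len = 30L) {
  if (length(reads) == 0) return(empty_candidates())
  nfrac <- Biostrings::letterFrequency(reads, "N", as.prob = TRUE)[, 1]
  dropped <- sum(nfrac > 0.10)
  reads <- reads[nfrac <= 0.10]
  if (length(reads) == 0) {
    out <- empty_candidates(); attr(out, "n_dropped") <- dropped
    return(out)
  }
  ids <- names(reads)
  widths <- Biostrings::width(reads)
  reads_chr <- as.character(reads)
  mt_chr <- as.character(mt$sequence)
  doubled <- Biostrings::DNAString(paste0(mt_chr, mt_chr))
  rc_doubled <- Biostrings::reverseComplement(doubled)

  # full-read shortcut: exact whole-read mtDNA substrings
  is_full <- logical(length(reads))
  clean <- !grepl("[^ACGT]", reads_chr)
  for (w in unique(widths)) {
    idx <- which(widths == w & clean)
    if (length(idx) == 0 || w > mt$length || w < min_mt_len) next
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(reads_chr[idx]))
    cf <- Biostrings::countPDict(pd, doubled)
    cr <- Biostrings::countPDict(pd, rc_doubled)
    is_full[idx] <- (cf + cr) > 0
  }
  full_df <- if (any(is_full)) {
    w <- widths[is_full]
    data.frame(read_id = ids[is_full], read_len = w, strand = "*",
               r_start = 1L, r_end = w, mt_start0 = NA_integer_,
               mt_end0 = NA_integer_, seg_len = w, full_read = TRUE,
               stringsAsFactors = FALSE)
  } else empty_candidates()

  rest <- which(!is_full)
  part_df <- empty_candidates()
  if (length(rest) > 0) {
    segs <- batch_exact_segments(reads_chr[rest], mt, k = min_mt_len)
    if (nrow(segs) > 0) {
      ridx <- rest[segs$read]
      part_df <- data.frame(
        read_id = ids[ridx], read_len = widths[ridx],
        strand = segs$strand, r_start = segs$r1, r_end = segs$r2,
        mt_start0 = segs$t1 - 1L, mt_end0 = segs$t2,
        seg_len = segs$r2 - segs$r1 + 1L,
        full_read = segs$r2 - segs$r1 + 1L == widths[ridx],
        stringsAsFactors = FALSE)
    }
  }
  out <- rbind(full_df, part_df)
  out <- out[order(out$read_id, out$r_start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- dropped
  out
}

#' Apply the mtDNA-length and flank-length filters to candidates
#'
#' A candidate is rejected when its mtDNA segment exceeds `max_mt_len`
#' ("mt_too_long"); otherwise the mtDNA segment is subtracted from the
#' read and the candidate is rejected when no remaining flank piece is at
#' least `min_flank` nt ("flank_too_short"). Both thresholds are
#' inclusive: a 130 nt segment and a 20 nt flank are accepted.
#'
#' @param cands candidate data.frame from [scan_reads()].
#' @param max_mt_len maximum mtDNA segment length (nt, inclusive).
#' @param min_flank minimum informative flank length (nt, inclusive).
#' @return list with `verdicts` (the candidates plus a `verdict` column)
#'   and `flanks` (one row per surviving flank piece: read coordinates and
#'   which side of the segment it lies on).
#' @export
filter_candidates <- function(cands, max_mt_len = 130L, min_flank = 20L) {
  if (nrow(cands) == 0)
    return(list(verdicts = cbind(cands, verdict = character(0)),
                flanks = data.frame()))
  left_len <- cands$r_start - 1L
  right_len <- cands$read_len - cands$r_end
  verdict <- ifelse(cands$seg_len > max_mt_len, "mt_too_long",
                    ifelse(pmax(left_len, right_len) < min_flank,
                           "flank_too_short", "pass"))
  flanks <- list()
  ok <- which(verdict == "pass")
  if (length(ok)) {
    lf <- ok[left_len[ok] >= min_flank]
    rf <- ok[right_len[ok] >= min_flank]
    flanks <- rbind(
      if (length(lf)) data.frame(cand = lf, side = "left",
                                 f_start = 1L,
                                 f_end = cands$r_start[lf] - 1L),
      if (length(rf)) data.frame(cand = rf, side = "right",
                                 f_start = cands$r_end[rf] + 1L,
                                 f_end = cands$read_len[rf]))
  }
  flanks_df <- if (length(flanks) && nrow(flanks) > 0) {
    data.frame(read_id = cands$read_id[flanks$cand],
               side = flanks$side, f_start = flanks$f_start,
               f_end = flanks$f_end,
               seg_strand = cands$strand[flanks$cand],
               mt_start0 = cands$mt_start0[flanks$cand],
               mt_end0 = cands$mt_end0[flanks$cand],
               stringsAsFactors = FALSE)
  } else data.frame()
  list(verdicts = cbind(cands, verdict = verdict), flanks = flanks_df)
}

#' @rdname filter_candidates
#' @param cand a single-row candidate.
#' @export
filter_candidate <- function(cand, max_mt_len = 130L, min_flank = 20L) {
  r <- filter_candidates(cand, max_mt_len, min_flank)
  list(verdict = r$verdicts$verdict[1], flanks = r$flanks)
}

#' Place a nuclear flank on the genome under the uniqueness contract
#'
#' The flank is aligned with the exact matcher at a minimum match length of
#' `ceiling(min_query_cov * nchar(flank))`, so every placement is gapless
#' and covers at least 95% of the query by default. Placement must be
#' unique: exactly one best-pslScore hit with no equal-score tie.
#' Optionally the flank is rejected when it still contains a perfect mtDNA
#' segment of >= `min_mt_len` nt.
#'
#' @param flank_seq flank sequence (character scalar).
#' @param nuclear `DNAStringSet` nuclear genome.
#' @param mt optional [circular_genome()] for the residual-mtDNA check.
#' @param min_query_cov minimum aligned query fraction.
#' @param min_mt_len residual mtDNA segment threshold.
#' @param precomp optional precomputed search structures from
#'   [numt_precomp()] (reused across many flanks).
#' @return list with `status` ("placed", "no_placement", "not_unique" or
#'   "residual_mt") and, when placed, `chrom`, `start`, `end` (1-based
#'   closed), `strand`, `q_start`, `q_end` (1-based closed on the flank).
#' @export
place_flank <- function(flank_seq, nuclear, mt = NULL,
                        min_query_cov = 0.95, min_mt_len = 30L,
                        precomp = NULL) {
  n <- nchar(flank_seq)
  min_len <- max(8L, as.integer(ceiling(min_query_cov * n)))
  if (!is.null(mt)) {
    if (!is.null(precomp)) {
      k <- precomp$mt_k
      if (n >= k) {
        st <- seq_len(n - k + 1L)
        kms <- substring(flank_seq, st, st + k - 1L)
        kms <- c(kms, revcomp_chr_fast(kms))
        hit <- any(vapply(kms, exists, logical(1), envir = precomp$mt_set,
                          inherits = FALSE, USE.NAMES = FALSE))
        if (hit) return(list(status = "residual_mt"))
      }
    } else {
      res <- align_exact(flank_seq, mt, min_len = min_mt_len)
      if (nrow(res) > 0) return(list(status = "residual_mt"))
    }
  }
  # fast path: full-length exact placements (the best-scoring kind; any
  # partial >= 95% hit scores strictly lower and cannot tie them)
  full <- list()
  nuc_cat <- if (!is.null(precomp) && !is.null(precomp$nuc_cat))
    precomp else nuclear_cat(nuclear)
  for (strand in c("+", "-")) {
    qs <- if (strand == "+") flank_seq else revcomp_chr_fast(flank_seq)
    if (grepl("[^ACGT]", qs)) next
    st <- Biostrings::start(Biostrings::matchPattern(qs, nuc_cat$nuc_cat))
    for (s in st) {
      ci <- findInterval(s, nuc_cat$nuc_offsets)
      full[[length(full) + 1L]] <- list(
        chrom = nuc_cat$nuc_names[ci],
        start = s - nuc_cat$nuc_offsets[ci],
        end = s - nuc_cat$nuc_offsets[ci] + n - 1L,
        strand = strand)
    }
  }
  if (length(full) > 1) return(list(status = "not_unique"))
  if (length(full) == 1) {
    p <- full[[1]]
    return(list(status = "placed", chrom = p$chrom, start = p$start,
                end = p$end, strand = p$strand, q_start = 1L, q_end = n))
  }
  # no full-length hit: fall back to maximal-match search for partial
  # (>= min_query_cov) placements
  psl <- align_exact(flank_seq, nuclear, min_len = min_len)
  if (nrow(psl) == 0) return(list(status = "no_placement"))
  sc <- psl_score(psl)
  best <- which(sc == max(sc))
  if (length(best) > 1) return(list(status = "not_unique"))
  p <- psl[best, ]
  list(status = "placed", chrom = p$tName, start = p$tStart + 1L,
       end = p$tEnd, strand = p$strand, q_start = p$qStart + 1L,
       q_end = p$qEnd)
}

#' Scan one sample's reads into filtered nuclear placements
#'
#' Runs the full per-sample filter chain: segment scan, length filters,
#' flank extraction and unique placement, including the residual-mtDNA
#' check. Identical flank sequences are placed once and the placement is
#' reused. Returns placements with a per-read junction coordinate (the
#' nuclear base adjacent to the mtDNA segment) and a `funnel` attribute
#' with accept/reject counts at every stage.
#'
#' @param reads named `DNAStringSet`.
#' @param nuclear `DNAStringSet` nuclear reference.
#' @param mt [circular_genome()].
#' @param min_mt_len,max_mt_len,min_flank,min_query_cov filter-chain
#'   thresholds.
#' @return data.frame of placements (read_id, side, chrom, start, end,
#'   strand, junction, mt_start0, mt_end0).
#' @export
numt_scan_sample <- function(reads, nuclear, mt, min_mt_len = 30L,
                             max_mt_len = 130L, min_flank = 20L,
                             min_query_cov = 0.95, precomp = NULL) {
  cands <- scan_reads(reads, mt, min_mt_len = min_mt_len)
  filt <- filter_candidates(cands, max_mt_len = max_mt_len,
                            min_flank = min_flank)
  funnel <- c(reads = length(reads),
              reads_dropped_N = attr(cands, "n_dropped") %||% 0L,
              candidates = nrow(cands),
              mt_too_long = sum(filt$verdicts$verdict == "mt_too_long"),
              flank_too_short =
                sum(filt$verdicts$verdict == "flank_too_short"),
              flanks = if (is.null(nrow(filt$flanks))) 0L
                       else nrow(filt$flanks))
  fl <- filt$flanks
  out <- data.frame()
  place_counts <- c(placed = 0L, no_placement = 0L, not_unique = 0L,
                    residual_mt = 0L)
  if (!is.null(nrow(fl)) && nrow(fl) > 0) {
    pc <- precomp %||% numt_precomp(mt, min_mt_len, nuclear)
    read_chr <- as.character(reads[fl$read_id])
    fseq <- substring(read_chr, fl$f_start, fl$f_end)
    placements <- place_flanks_batch(unique(fseq), nuclear, mt,
                                     min_query_cov = min_query_cov,
                                     min_mt_len = min_mt_len, precomp = pc)
    rows <- list()
    for (i in seq_len(nrow(fl))) {
      pl <- placements[[fseq[i]]]
      place_counts[pl$status] <- place_counts[pl$status] + 1L
      if (pl$status != "placed") next
      # junction: the placed base adjacent to the mtDNA segment
      junction <- if ((fl$side[i] == "left") == (pl$strand == "+"))
        pl$end + 1L else pl$start - 1L
      rows[[length(rows) + 1L]] <- data.frame(
        read_id = fl$read_id[i], side = fl$side[i], chrom = pl$chrom,
        start = pl$start, end = pl$end, strand = pl$strand,
        junction = junction, mt_start0 = fl$mt_start0[i],
        mt_end0 = fl$mt_end0[i], stringsAsFactors = FALSE)
    }
    if (length(rows)) out <- do.call(rbind, rows)
  }
  attr(out, "funnel") <- c(funnel, place_counts)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Precomputed search structures for repeated flank checks
#'
#' A multi-pattern dictionary of all `min_mt_len`-mers of the doubled
#' mtDNA, used to test many flanks for residual mtDNA without rebuilding
#' per-flank indexes.
#'
#' @param mt [circular_genome()].
#' @param min_mt_len k-mer length.
#' @param nuclear optional `DNAStringSet`; when given, a concatenated
#'   subject for fast full-length placement is included.
#' @return a list usable as `precomp` in [place_flank()].
#' @export
numt_precomp <- function(mt, min_mt_len = 30L, nuclear = NULL,
                         flank_k = 20L) {
  s <- as.character(mt$sequence)
  kk <- query_kmers(paste0(s, s), min_mt_len)
  set <- new.env(hash = TRUE, parent = emptyenv(),
                 size = length(kk$kmers))
  for (km in kk$kmers) assign(km, TRUE, envir = set)
  out <- list(mt_set = set, mt_k = min_mt_len)
  if (!is.null(nuclear)) {
    out <- c(out, nuclear_cat(nuclear))
    cat_chr <- as.character(out$nuc_cat)
    nk <- query_kmers(cat_chr, flank_k)  # N spacers drop cross-chrom k-mers
    out$nuc_pd <- Biostrings::PDict(Biostrings::DNAStringSet(nk$kmers))
    out$nuc_pos <- nk$starts
    out$flank_k <- flank_k
  }
  out
}

# Batch placement of many flank sequences: one multi-pattern pass of the
# nuclear k-mers over all flanks (both strands), diagonal-merged into
# full-length exact matches. Flanks with no full-length hit fall back to
# the partial-coverage path of place_flank. Returns a named list of
# place_flank-style results keyed by flank sequence.
place_flanks_batch <- function(fseqs, nuclear, mt, min_query_cov = 0.95,
                               min_mt_len = 30L, precomp) {
  res <- vector("list", length(fseqs))
  names(res) <- fseqs
  # residual mtDNA screen
  k <- precomp$mt_k
  residual <- vapply(fseqs, function(fs) {
    n <- nchar(fs)
    if (n < k) return(FALSE)
    st <- seq_len(n - k + 1L)
    kms <- substring(fs, st, st + k - 1L)
    kms <- c(kms, revcomp_chr_fast(kms))
    any(vapply(kms, exists, logical(1), envir = precomp$mt_set,
               inherits = FALSE, USE.NAMES = FALSE))
  }, logical(1), USE.NAMES = FALSE)
  res[residual] <- list(list(status = "residual_mt"))
  todo <- which(!residual)
  if (length(todo) == 0) return(res)
  fl <- fseqs[todo]
  nfull <- integer(length(fl))
  hit_info <- vector("list", length(fl))
  fk <- precomp$flank_k
  for (strand in c("+", "-")) {
    sub <- if (strand == "+") fl else revcomp_chr_fast(fl)
    hits <- concat_hits(precomp$nuc_pd, precomp$nuc_pos, sub, fk)
    if (nrow(hits) == 0) next
    runs <- merge_diagonal_runs(
      data.frame(tName = hits$read, qpos = hits$rpos, tpos = hits$tpos),
      fk)
    ridx <- as.integer(runs$tName)
    isfull <- runs$q1 == 1L & runs$q2 == nchar(sub)[ridx]
    runs <- runs[isfull, , drop = FALSE]
    ridx <- ridx[isfull]
    for (i in seq_along(ridx)) {
      r <- ridx[i]
      nfull[r] <- nfull[r] + 1L
      ci <- findInterval(runs$t1[i], precomp$nuc_offsets + 1L)
      hit_info[[r]] <- list(
        chrom = precomp$nuc_names[ci],
        start = runs$t1[i] - precomp$nuc_offsets[ci],
        end = runs$t2[i] - precomp$nuc_offsets[ci], strand = strand)
    }
  }
  for (j in seq_along(fl)) {
    r <- if (nfull[j] > 1) list(status = "not_unique")
    else if (nfull[j] == 1) {
      p <- hit_info[[j]]
      list(status = "placed", chrom = p$chrom, start = p$start,
           end = p$end, strand = p$strand, q_start = 1L,
           q_end = nchar(fl[j]))
    } else place_flank(fl[j], nuclear, mt = NULL,
                       min_query_cov = min_query_cov,
                       min_mt_len = min_mt_len, precomp = precomp)
    res[[todo[j]]] <- r
  }
  res
}

# Concatenate chromosomes with N spacers for single-call matchPattern;
# spacer of 200 N prevents cross-chromosome matches for queries < 200 nt.
nuclear_cat <- function(nuclear) {
  chr <- as.character(nuclear)
  spacer <- strrep("N", 200L)
  offsets <- unname(cumsum(c(0L, nchar(chr) + 200L))[seq_along(chr)])
  list(nuc_cat = Biostrings::DNAString(paste(chr, collapse = spacer)),
       nuc_offsets = offsets, nuc_names = names(nuclear))
}

revcomp_chr_fast <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Call de novo numts from two-sample placements
#'
#' Senescent placements overlapping (>= 1 bp) any proliferating placement
#' or any known-numt interval are removed; survivors are merged into calls
#' (placements whose junctions lie within `merge_window` nt on the same
#' chromosome and whose mtDNA intervals overlap collapse into one call
#' with summed read support).
#'
#' @param sen_placements,pro_placements placement data.frames from
#'   [numt_scan_sample()] (identical upstream parameters).
#' @param known_numts `GRanges` of known numts (may be empty).
#' @param merge_window merge window for supporting reads of one event
#'   (nt).
#' @param dataset dataset label carried on every call.
#' @param extra_exclusion optional additional exclusion `GRanges` (e.g.
#'   externally verified hits).
#' @return `GRanges` of calls (1-bp junction coordinates) with metadata
#'   columns mt_start0, mt_end0, support, dataset, read_ids.
#' @export
call_de_novo <- function(sen_placements, pro_placements,
                         known_numts = GenomicRanges::GRanges(),
                         merge_window = 100L, dataset = "WGS",
                         extra_exclusion = GenomicRanges::GRanges()) {
  empty <- GenomicRanges::GRanges(
    name = character(0), score = numeric(0), mt_start0 = integer(0),
    mt_end0 = integer(0), support = integer(0), dataset = character(0),
    read_ids = character(0))
  if (is.null(nrow(sen_placements)) || nrow(sen_placements) == 0)
    return(empty)
  # exclusion interval: the flank placement extended to include its
  # junction base, so a placement abutting a known numt (junction on the
  # numt's edge) is excluded too
  span_gr <- function(p) GenomicRanges::GRanges(
    p$chrom, IRanges::IRanges(pmin(p$start, p$junction),
                              pmax(p$end, p$junction)))
  sen_gr <- span_gr(sen_placements)
  drop <- rep(FALSE, length(sen_gr))
  if (!is.null(nrow(pro_placements)) && nrow(pro_placements) > 0) {
    drop <- drop | IRanges::overlapsAny(sen_gr, span_gr(pro_placements),
                                        ignore.strand = TRUE)
  }
  if (length(known_numts) > 0)
    drop <- drop | IRanges::overlapsAny(sen_gr, known_numts,
                                        ignore.strand = TRUE)
  if (length(extra_exclusion) > 0)
    drop <- drop | IRanges::overlapsAny(sen_gr, extra_exclusion,
                                        ignore.strand = TRUE)
  surv <- sen_placements[!drop, , drop = FALSE]
  if (nrow(surv) == 0) return(empty)

  # cluster junctions within merge_window per chromosome, then split
  # clusters whose mtDNA intervals do not overlap
  calls <- list()
  for (ch in unique(surv$chrom)) {
    s <- surv[surv$chrom == ch, , drop = FALSE]
    s <- s[order(s$junction), , drop = FALSE]
    cl <- cumsum(c(1L, diff(s$junction) > merge_window))
    for (g in split(seq_len(nrow(s)), cl)) {
      grp <- s[g, , drop = FALSE]
      mt_ir <- IRanges::IRanges(grp$mt_start0 + 1L, grp$mt_end0)
      sub <- S4Vectors::subjectHits(
        IRanges::findOverlaps(mt_ir, IRanges::reduce(mt_ir)))
      for (m in split(seq_len(nrow(grp)), sub)) {
        gg <- grp[m, , drop = FALSE]
        calls[[length(calls) + 1L]] <- data.frame(
          chrom = ch, junction = round(stats::median(gg$junction)),
          mt_start0 = min(gg$mt_start0), mt_end0 = max(gg$mt_end0),
          support = length(unique(gg$read_id)),
          read_ids = paste(sort(unique(gg$read_id)), collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
  }
  df <- do.call(rbind, calls)
  gr <- GenomicRanges::GRanges(
    df$chrom, IRanges::IRanges(df$junction, df$junction),
    name = sprintf("%s_numt_%03d", dataset, seq_len(nrow(df))),
    score = df$support, mt_start0 = df$mt_start0, mt_end0 = df$mt_end0,
    support = df$support, dataset = dataset, read_ids = df$read_ids)
  sort_gr(gr)
}

#' Mitochondrial gene composition of numt calls
#'
#' Assigns each call's mtDNA interval to every overlapped mitochondrial
#' feature (origin-spanning intervals are split at the origin); a segment
#' overlapping two features contributes to both. Percentages are over all
#' assignments and sum to 100.
#'
#' @param calls `GRanges` from [call_de_novo()] (or a data.frame with
#'   mt_start0/mt_end0 columns).
#' @param mt_gene_map `GRanges` feature map of the mtDNA (genes + D-Loop),
#'   with a `name` column.
#' @param L mtDNA length (for origin splitting); taken from the gene map
#'   when NULL.
#' @return data.frame with feature, count and pct columns (all features in
#'   the map reported, zero counts included).
#' @export
mito_composition <- function(calls, mt_gene_map, L = NULL) {
  if (is.null(L)) L <- max(GenomicRanges::end(mt_gene_map))
  mt_start0 <- if (inherits(calls, "GRanges")) calls$mt_start0 else
    calls$mt_start0
  mt_end0 <- if (inherits(calls, "GRanges")) calls$mt_end0 else
    calls$mt_end0
  feats <- unique(mt_gene_map$name)
  counts <- stats::setNames(integer(length(feats)), feats)
  if (length(mt_start0) > 0) {
    pieces <- list()
    for (i in seq_along(mt_start0)) {
      s <- mt_start0[i] + 1L; e <- mt_end0[i]
      if (e <= L) pieces[[length(pieces) + 1L]] <- c(s, e)
      else {
        pieces[[length(pieces) + 1L]] <- c(s, L)
        pieces[[length(pieces) + 1L]] <- c(1L, e - L)
      }
    }
    ir <- IRanges::IRanges(vapply(pieces, `[`, numeric(1), 1),
                           vapply(pieces, `[`, numeric(1), 2))
    hits <- IRanges::findOverlaps(ir, IRanges::ranges(mt_gene_map))
    tab <- table(mt_gene_map$name[S4Vectors::subjectHits(hits)])
    counts[names(tab)] <- as.integer(tab)
  }
  total <- sum(counts)
  data.frame(feature = names(counts), count = as.integer(counts),
             pct = if (total > 0) 100 * as.integer(counts) / total
                   else rep(0, length(counts)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Which planted numts are geometrically detectable in a read set
#'
#' A planted de novo numt counts as detectable when at least one simulated
#' read straddles one of its junctions with enough nuclear flank and mtDNA
#' in the same read to survive the per-read filter chain, including a
#' unique flank placement on the reference (an event whose full mtDNA
#' segment exceeds the per-read cap can still be detectable through a
#' junction read carrying a shorter sub-segment). The check runs the single-read
#' chain ([scan_read()], [filter_candidates()], [place_flank()]) on each
#' junction-straddling read, so junction microhomology shortening the
#' apparent flank is accounted for. Read source coordinates are parsed
#' from the simulator's read names.
#'
#' @param truth truth data.frame from [plant_de_novo_events()].
#' @param reads the senescent-sample WGS reads (names encode source
#'   coordinates).
#' @param nuclear reference genome for the uniqueness check.
#' @param mt [circular_genome()].
#' @inheritParams numt_scan_sample
#' @return logical vector over the numt rows of `truth` (named by
#'   event_id).
#' @export
detectable_numt_events <- function(truth, reads, nuclear, mt,
                                   min_mt_len = 30L, max_mt_len = 130L,
                                   min_flank = 20L, min_query_cov = 0.95) {
  ev <- truth[truth$kind == "de_novo_numt", , drop = FALSE]
  if (nrow(ev) == 0) return(stats::setNames(logical(0), character(0)))
  meta <- strsplit(names(reads), "|", fixed = TRUE)
  rch <- vapply(meta, `[`, character(1), 2)
  rst <- suppressWarnings(as.integer(vapply(meta, `[`, character(1), 3)))
  rw <- Biostrings::width(reads)
  r_end <- rst + rw - 1L
  out <- logical(nrow(ev))
  for (i in seq_len(nrow(ev))) {
    if (is.na(ev$mt_len[i])) next
    # note: events longer than max_mt_len can still be detectable — a
    # junction read carries only the sub-segment that fits beside its
    # flank; the per-read chain below is authoritative
    s <- ev$sen_start[i]; e <- ev$sen_end[i]
    on_ch <- !is.na(rst) & rch == ev$chrom[i]
    left_ok <- on_ch & rst <= s - min_flank & r_end >= s + min_mt_len - 1L
    right_ok <- on_ch & rst <= e - min_mt_len + 1L & r_end >= e + min_flank
    for (j in which(left_ok | right_ok)) {
      cand <- scan_read(reads[[j]], mt, min_mt_len = min_mt_len)
      if (nrow(cand) == 0) next
      cand$read_id <- names(reads)[j]
      filt <- filter_candidates(cand, max_mt_len = max_mt_len,
                                min_flank = min_flank)
      fl <- filt$flanks
      if (is.null(nrow(fl)) || nrow(fl) == 0) next
      rchr <- as.character(reads[[j]])
      ok <- FALSE
      for (q in seq_len(nrow(fl))) {
        fseq <- substring(rchr, fl$f_start[q], fl$f_end[q])
        pl <- place_flank(fseq, nuclear, mt = mt,
                          min_query_cov = min_query_cov,
                          min_mt_len = min_mt_len)
        if (pl$status == "placed") { ok <- TRUE; break }
      }
      if (ok) { out[i] <- TRUE; break }
    }
  }
  stats::setNames(out, ev$event_id)
}
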