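# Tiled and query-based read counting with RPM normalization and log2
# fold change: the mtDNA copy-number profile (1,000 nt tiles over the
# circular genome) and SVA subfamily 5'-region abundance. Fold changes
# are always reported on the log2 scale and may be corrected for each
# sample's overall alignment rate.

#' Partition a circular genome into ordered tiles
#'
#' Tiles cover positions 1..L without overlap; the last tile is short when
#' L is not a multiple of `tile_len` (16,559 nt at 1,000 nt gives 17
#' tiles, the last of 559 nt).
#'
#' @param mt a [circular_genome()] (or anything with a `length` field /
#'   a `DNAStringSet` of one sequence).
#' @param tile_len tile length in nt.
#' @return `GRanges` of tiles named `tile_<i>` with the tile sequence in
#'   the `seq` column.
#' @export
tile_genome <- function(mt, tile_len = 1000L) {
  if (!inherits(mt, "circular_genome")) mt <- circular_genome(mt)
  L <- mt$length
  starts <- seq(1L, L, by = tile_len)
  ends <- pmin(starts + tile_len - 1L, L)
  gr <- GenomicRanges::GRanges(mt$id, IRanges::IRanges(starts, ends),
                               name = sprintf("tile_%02d",
                                              seq_along(starts)),
                               score = 0)
  gr$seq <- substring(as.character(mt$sequence), starts, ends)
  gr
}

count_reads_in_query <- function(reads, query_chr, min_identity = 1.0) {
  if (length(reads) == 0) return(0L)
  qlen <- nchar(query_chr)
  widths <- Biostrings::width(reads)
  reads_chr <- as.character(reads)
  hit <- logical(length(reads))
  if (min_identity >= 1.0) {
    qdna <- Biostrings::DNAString(query_chr)
    clean <- !grepl("[^ACGT]", reads_chr)
    for (w in unique(widths)) {
      idx <- which(widths == w & !hit)
      if (length(idx) == 0) next
      shorter <- w <= qlen
      sub_idx <- idx[clean[idx]]
      if (shorter && length(sub_idx)) {
        sub <- Biostrings::DNAStringSet(reads_chr[sub_idx])
        pd <- Biostrings::PDict(sub)
        cf <- Biostrings::countPDict(pd, qdna)
        cr <- Biostrings::countPDict(
          Biostrings::PDict(Biostrings::reverseComplement(sub)), qdna)
        hit[sub_idx] <- (cf + cr) > 0
      } else if (!shorter) {
        # query shorter than the read: query-within-read role
        for (i in idx) {
          hit[i] <- nrow(align_exact(query_chr, reads_chr[i],
                                     min_len = max(8L, qlen))) > 0
        }
      }
    }
  } else {
    for (i in seq_along(reads_chr)) {
      if (widths[i] <= qlen)
        hit[i] <- nrow(align_near(reads_chr[i], query_chr,
                                  min_identity = min_identity)) > 0
      else
        hit[i] <- nrow(align_near(query_chr, reads_chr[i],
                                  min_identity = min_identity)) > 0
    }
  }
  sum(hit)
}

#' Count reads matching a query and normalize to RPM
#'
#' A read counts toward a query when it has at least one ungapped
#' alignment at >= `min_identity` with the shorter sequence fully inside
#' the longer (read-within-query or query-within-read); each read counts
#' at most once per query. RPM = count / (total reads / 1e6).
#'
#' @param reads `DNAStringSet`.
#' @param query query sequence (character / `DNAString`).
#' @param min_identity identity threshold in [0.5, 1].
#' @param total_reads denominator for RPM (defaults to `length(reads)`).
#' @return list with `count` and `rpm`.
#' @export
count_query <- function(reads, query, min_identity = 1.0,
                        total_reads = length(reads)) {
  stopifnot(min_identity >= 0.5, min_identity <= 1.0)
  qchr <- toupper(as.character(as_dna_set(query))[1])
  count <- count_reads_in_query(reads, qchr, min_identity)
  list(count = count, rpm = count / (total_reads / 1e6))
}

#' log2 fold change between two RPM values with alignment-rate correction
#'
#' FC = log2((rpm_test / rate_test) / (rpm_ref / rate_ref)). A zero (or
#' missing) reference RPM yields NA, never +/- infinity.
#'
#' @param rpm_test,rpm_ref RPM values.
#' @param rate_test,rate_ref overall alignment rates in (0, 1].
#' @return numeric log2 fold change (vectorized).
#' @export
fold_change <- function(rpm_test, rpm_ref, rate_test = 1.0,
                        rate_ref = 1.0) {
  stopifnot(all(rate_test > 0), all(rate_test <= 1),
            all(rate_ref > 0), all(rate_ref <= 1))
  out <- log2((rpm_test / rate_test) / (rpm_ref / rate_ref))
  out[!is.finite(out)] <- NA_real_
  out
}

#' Abundance profile of queries across two samples
#'
#' Counts and RPM per query in each sample plus the per-query log2 fold
#' change. Queries are typically mtDNA tiles ([tile_genome()]) or SVA
#' subfamily 5' 200-mers ([sva_subfamily_queries()]). A read matching two
#' queries counts toward each.
#'
#' @param reads_test,reads_ref `DNAStringSet` for the two samples.
#' @param queries named character vector / `DNAStringSet` of query
#'   sequences.
#' @param min_identity identity threshold.
#' @param rate_test,rate_ref overall alignment rates.
#' @return data.frame: query, count_test, count_ref, rpm_test, rpm_ref,
#'   log2fc.
#' @export
abundance_profile <- function(reads_test, reads_ref, queries,
                              min_identity = 1.0, rate_test = 1.0,
                              rate_ref = 1.0) {
  qset <- as_dna_set(queries)
  rows <- lapply(seq_along(qset), function(i) {
    qt <- count_query(reads_test, qset[i], min_identity)
    qr <- count_query(reads_ref, qset[i], min_identity)
    data.frame(query = names(qset)[i],
               count_test = qt$count, count_ref = qr$count,
               rpm_test = qt$rpm, rpm_ref = qr$rpm,
               log2fc = fold_change(qt$rpm, qr$rpm, rate_test, rate_ref),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' SVA subfamily 5'-region query sequences
#'
#' The first `head_len` nt of each subfamily consensus 5' region (the
#' informative, subfamily-specific part; the tandem-repetitive remainder
#' is excluded to avoid redundant hits). Bundled synthetic stand-ins by
#' default; pass `consensus` to substitute real subfamily sequences.
#'
#' @param head_len query length in nt (default 200).
#' @param consensus optional named character vector of full consensus
#'   sequences.
#' @return named character vector of queries (SVA_A..SVA_F by default).
#' @export
sva_subfamily_queries <- function(head_len = 200L, consensus = NULL) {
  if (is.null(consensus)) consensus <- element_consensus()$SVA
  vapply(consensus, substring, character(1), first = 1L, last = head_len)
}
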