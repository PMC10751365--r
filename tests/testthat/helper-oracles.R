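# Independent oracles used across the suite. These deliberately use naive
# enumeration (per-base sets, all-diagonal scanning) so they share no code
# path with the implementation they check.

rand_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rc <- function(x) {
  vapply(x, function(s)
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = ""),
    character(1), USE.NAMES = FALSE)
}

# Brute-force maximal exact matches of q against a single target string on
# one strand: scan every diagonal for runs of equal characters.
brute_matches_one <- function(q, t, min_len) {
  n <- nchar(q); m <- nchar(t)
  qc <- strsplit(q, "")[[1]]; tc <- strsplit(t, "")[[1]]
  out <- list()
  for (d in (-(n - 1)):(m - 1)) {
    i1 <- max(1L, 1L - d); i2 <- min(n, m - d)
    if (i2 - i1 + 1L < min_len) next
    eq <- qc[i1:i2] == tc[(i1:i2) + d] & qc[i1:i2] != "N"
    r <- rle(eq)
    pos <- cumsum(c(0L, r$lengths[-length(r$lengths)])) + i1
    for (k in seq_along(r$lengths)) {
      if (r$values[k] && r$lengths[k] >= min_len) {
        qs <- pos[k]
        out[[length(out) + 1L]] <- c(q1 = qs, q2 = qs + r$lengths[k] - 1L,
                                     t1 = qs + d, t2 = qs + d +
                                       r$lengths[k] - 1L)
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(q1 = integer(0), q2 = integer(0), t1 = integer(0),
                      t2 = integer(0)))
  as.data.frame(do.call(rbind, out))
}

# Brute-force both-strand maximal matches in align_exact's coordinate
# dialect (forward-query 0-based half-open) against a linear target set.
brute_align_exact <- function(q, targets, min_len) {
  rows <- list()
  n <- nchar(q)
  for (tn in names(targets)) {
    for (strand in c("+", "-")) {
      qs <- if (strand == "+") q else rc(q)
      hits <- brute_matches_one(qs, targets[[tn]], min_len)
      if (nrow(hits) == 0) next
      if (strand == "+") {
        qs0 <- hits$q1 - 1L; qe0 <- hits$q2
      } else {
        qs0 <- n - hits$q2; qe0 <- n - hits$q1 + 1L
      }
      rows[[length(rows) + 1L]] <- data.frame(
        tName = tn, strand = strand, qStart = qs0, qEnd = qe0,
        tStart = hits$t1 - 1L, tEnd = hits$t2)
    }
  }
  if (length(rows) == 0)
    return(data.frame(tName = character(0), strand = character(0),
                      qStart = integer(0), qEnd = integer(0),
                      tStart = integer(0), tEnd = integer(0)))
  df <- do.call(rbind, rows)
  df[order(df$tName, df$tStart, df$qStart), , drop = FALSE]
}

# Per-base set-membership oracle for the record-level interval algebra.
base_set <- function(gr) {
  if (length(gr) == 0) return(character(0))
  unlist(lapply(seq_along(gr), function(i)
    paste0(as.character(GenomicRanges::seqnames(gr))[i], ":",
           seq(GenomicRanges::start(gr)[i], GenomicRanges::end(gr)[i]))))
}

oracle_keep_overlapping <- function(a, b) {
  bs <- base_set(b)
  vapply(seq_along(a), function(i)
    any(base_set(a[i]) %in% bs), logical(1))
}

random_granges <- function(n, n_chrom = 3, max_pos = 2000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ch <- sample(paste0("chr", seq_len(n_chrom)), n, replace = TRUE)
  st <- sample.int(max_pos - 50, n, replace = TRUE)
  w <- sample.int(50, n, replace = TRUE)
  GenomicRanges::GRanges(ch, IRanges::IRanges(st, st + w),
                         name = paste0("iv", seq_len(n)), score = 0)
}

# A small chimeric read: nuclear left flank + mtDNA segment + nuclear
# right flank, on a toy genome pair.
make_chimera <- function(nuclear_chr, mt_chr, flank_left, mt_at, mt_len,
                         flank_right, nuc_at = 1000) {
  paste0(substring(nuclear_chr, nuc_at, nuc_at + flank_left - 1L),
         substring(paste0(mt_chr, mt_chr), mt_at, mt_at + mt_len - 1L),
         substring(nuclear_chr, nuc_at + flank_left,
                   nuc_at + flank_left + flank_right - 1L))
}
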