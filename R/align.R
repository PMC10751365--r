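# Deterministic exact / near-exact ungapped aligner. This is the package's
# internal stand-in for BLAT/blastn at toy-genome scale:
#   - align_exact: every maximal exact substring match >= min_len, both
#     strands, reported as gapless PSL records.
#   - align_near: full-query ungapped placements at >= min_identity
#     (pigeonhole seeding + Hamming verification).
# Circular targets (mtDNA) are searched on a doubled linearization; target
# starts are reduced modulo L, so tEnd may exceed L for origin-spanning
# hits. 'N' never matches; orderings are fully defined, no randomness.

query_kmers <- function(q, k) {
  n <- nchar(q)
  if (n < k) return(list(starts = integer(0), kmers = character(0)))
  starts <- seq_len(n - k + 1L)
  kmers <- substring(q, starts, starts + k - 1L)
  ok <- !grepl("[^ACGT]", kmers)
  list(starts = starts[ok], kmers = kmers[ok])
}

# k-mer match positions of query k-mers in each target sequence.
# Returns data.frame(tName, qpos, tpos), 1-based starts.
exact_kmer_hits <- function(q, tset, k) {
  kk <- query_kmers(q, k)
  if (length(kk$starts) == 0)
    return(data.frame(tName = character(0), qpos = integer(0),
                      tpos = integer(0)))
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(kk$kmers))
  out <- vector("list", length(tset))
  for (i in seq_along(tset)) {
    m <- Biostrings::matchPDict(pd, tset[[i]])
    st <- Biostrings::startIndex(m)
    cnt <- lengths(st)
    if (sum(cnt) == 0) next
    out[[i]] <- data.frame(tName = names(tset)[i],
                           qpos = rep(kk$starts, cnt),
                           tpos = unlist(st, use.names = FALSE))
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0)
    return(data.frame(tName = character(0), qpos = integer(0),
                      tpos = integer(0)))
  do.call(rbind, out)
}

# Merge k-mer hits lying on one diagonal into maximal exact matches.
# Input 1-based (qpos, tpos) starts; output runs with 1-based closed
# query/target intervals of length run + k - 1.
merge_diagonal_runs <- function(hits, k) {
  if (nrow(hits) == 0)
    return(data.frame(tName = character(0), q1 = integer(0), q2 = integer(0),
                      t1 = integer(0), t2 = integer(0)))
  d <- hits$tpos - hits$qpos
  o <- order(hits$tName, d, hits$qpos)
  tn <- hits$tName[o]; dg <- d[o]; qp <- hits$qpos[o]
  nn <- length(qp)
  new_run <- c(TRUE, tn[-1] != tn[-nn] | dg[-1] != dg[-nn] |
                 qp[-1] != qp[-nn] + 1L)
  s_i <- which(new_run)
  e_i <- c(s_i[-1] - 1L, nn)
  data.frame(tName = tn[s_i],
             q1 = qp[s_i], q2 = qp[e_i] + k - 1L,
             t1 = qp[s_i] + dg[s_i], t2 = qp[e_i] + dg[s_i] + k - 1L,
             stringsAsFactors = FALSE)
}

# For circular targets, an origin-spanning match also surfaces as a
# truncated run abutting the doubled-sequence boundary (same diagonal
# modulo L, query interval contained in the spanning run). Drop such
# artifacts.
dedupe_circular <- function(df, L) {
  if (nrow(df) < 2) return(df)
  keep <- rep(TRUE, nrow(df))
  diag <- df$tStart - df$qStart
  for (i in seq_len(nrow(df))) {
    for (j in seq_len(nrow(df))) {
      if (i == j || !keep[i]) next
      if (df$strand[i] != df$strand[j]) next
      if ((diag[i] - diag[j]) %% L != 0) next
      wi <- df$qEnd[i] - df$qStart[i]
      wj <- df$qEnd[j] - df$qStart[j]
      if (wj > wi && df$qStart[j] <= df$qStart[i] &&
          df$qEnd[j] >= df$qEnd[i])
        keep[i] <- FALSE
    }
  }
  df[keep, , drop = FALSE]
}

prepare_target <- function(target) {
  if (inherits(target, "circular_genome")) {
    s <- as.character(target$sequence)
    tset <- Biostrings::DNAStringSet(paste0(s, s))
    names(tset) <- target$id
    list(tset = tset, circular = TRUE, L = target$length,
         sizes = stats::setNames(target$length, target$id))
  } else {
    tset <- as_dna_set(target)
    list(tset = tset, circular = FALSE, L = NA_integer_,
         sizes = stats::setNames(Biostrings::width(tset), names(tset)))
  }
}

query_as_char <- function(query) {
  if (inherits(query, "DNAStringSet")) {
    nm <- if (!is.null(names(query))) names(query)[1] else "query"
    return(list(seq = toupper(as.character(query[[1]])), name = nm))
  }
  if (inherits(query, "DNAString"))
    return(list(seq = toupper(as.character(query)), name = "query"))
  nm <- if (!is.null(names(query))) names(query)[1] else "query"
  list(seq = toupper(as.character(query)[1]),
       name = if (is.na(nm) || !nzchar(nm)) "query" else nm)
}

#' Exact maximal substring matches of a query against a genome
#'
#' Finds every maximal exact substring match of length >= `min_len` between
#' the query (both strands) and the target, reported as gapless PSL records
#' with zero mismatches. Circular targets are searched across the origin.
#' Output is ordered by (tName, tStart, qStart); results are deterministic.
#'
#' @param query a `DNAString`, character scalar, or single-sequence
#'   `DNAStringSet`.
#' @param target a `DNAStringSet` / named character vector (one entry per
#'   chromosome) or a [circular_genome()].
#' @param min_len minimum match length, >= 8.
#' @param query_name query name used in PSL output (defaults to the
#'   query's own name).
#' @return a PSL data.frame; query coordinates always refer to the forward
#'   query. For circular targets tStart < L and tEnd may exceed L
#'   (origin-spanning hit).
#' @export
align_exact <- function(query, target, min_len = 20, query_name = NULL) {
  stopifnot(min_len >= 8)
  tg <- prepare_target(target)
  qq <- query_as_char(query)
  if (is.null(query_name)) query_name <- qq$name
  n <- nchar(qq$seq)
  rows <- list()
  for (strand in c("+", "-")) {
    qs <- if (strand == "+") qq$seq else revcomp(qq$seq)
    runs <- merge_diagonal_runs(exact_kmer_hits(qs, tg$tset, min_len),
                                min_len)
    if (nrow(runs) == 0) next
    if (tg$circular) {
      d0 <- data.frame(strand = strand, qStart = runs$q1 - 1L,
                       qEnd = runs$q2, tStart = runs$t1 - 1L,
                       tEnd = runs$t2, row = seq_len(nrow(runs)))
      runs <- runs[dedupe_circular(d0, tg$L)$row, , drop = FALSE]
    }
    if (strand == "+") {
      q_start0 <- runs$q1 - 1L; q_end0 <- runs$q2
    } else {
      q_start0 <- n - runs$q2; q_end0 <- n - runs$q1 + 1L
    }
    t_start0 <- runs$t1 - 1L; t_end0 <- runs$t2
    keep <- rep(TRUE, nrow(runs))
    if (tg$circular) keep <- t_start0 < tg$L
    if (!any(keep)) next
    rows[[strand]] <- data.frame(
      tName = runs$tName[keep], strand = strand,
      qStart = q_start0[keep], qEnd = q_end0[keep],
      tStart = t_start0[keep], tEnd = t_end0[keep],
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) return(empty_psl())
  df <- do.call(rbind, rows)
  psl <- make_psl(qName = query_name, qSize = n,
                  qStart = df$qStart, qEnd = df$qEnd,
                  tName = df$tName,
                  tSize = unname(tg$sizes[df$tName]),
                  tStart = df$tStart, tEnd = df$tEnd,
                  strand = df$strand)
  psl[order(psl$tName, psl$tStart, psl$qStart), , drop = FALSE]
}

#' Near-exact full-query ungapped placements
#'
#' Returns gapless alignments of the whole query against the target with
#' identity >= `min_identity` (ungapped model, both strands). Candidate
#' offsets come from exact pigeonhole seeds (the query is split into
#' floor(mismatch budget) + 1 segments, one of which must match exactly);
#' each candidate is verified by Hamming distance. At `min_identity = 1`
#' the result is the subset of [align_exact()] hits covering the full
#' query.
#'
#' @inheritParams align_exact
#' @param min_identity minimum fraction of identical bases, in [0.5, 1].
#' @return a PSL data.frame of full-query gapless hits.
#' @export
align_near <- function(query, target, min_identity = 0.95,
                       query_name = NULL) {
  stopifnot(min_identity >= 0.5, min_identity <= 1.0)
  tg <- prepare_target(target)
  qq <- query_as_char(query)
  if (is.null(query_name)) query_name <- qq$name
  n <- nchar(qq$seq)
  max_mm <- floor(n * (1 - min_identity) + 1e-9)
  rows <- list()
  for (strand in c("+", "-")) {
    qs <- if (strand == "+") qq$seq else revcomp(qq$seq)
    qdna <- Biostrings::DNAString(qs)
    n_seed <- max_mm + 1L
    bounds <- unique(round(seq(0L, n, length.out = n_seed + 1L)))
    seed_len_min <- min(diff(bounds))
    for (ti in seq_along(tg$tset)) {
      subj <- tg$tset[[ti]]
      slen <- length(subj)
      if (slen < n) next
      if (seed_len_min >= 8) {
        cand <- integer(0)
        for (si in seq_len(length(bounds) - 1L)) {
          off <- bounds[si]
          seed <- substring(qs, off + 1L, bounds[si + 1L])
          if (grepl("[^ACGT]", seed)) next
          hits <- Biostrings::start(
            Biostrings::matchPattern(seed, subj, fixed = TRUE))
          cand <- c(cand, hits - off)
        }
        cand <- sort(unique(cand))
      } else {
        cand <- seq_len(slen - n + 1L)
      }
      cand <- cand[cand >= 1L & cand + n - 1L <= slen]
      if (length(cand) == 0) next
      mm <- Biostrings::neditStartingAt(qdna, subj, starting.at = cand,
                                        with.indels = FALSE, fixed = TRUE)
      keep <- mm <= max_mm
      cand <- cand[keep]; mm <- mm[keep]
      if (tg$circular) {
        keep <- cand - 1L < tg$L
        cand <- cand[keep]; mm <- mm[keep]
      }
      if (length(cand) == 0) next
      rows[[paste(strand, ti)]] <- data.frame(
        tName = names(tg$tset)[ti], strand = strand,
        tStart = cand - 1L, mism = mm, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) return(empty_psl())
  df <- do.call(rbind, rows)
  psl <- make_psl(qName = query_name, qSize = n, qStart = 0L, qEnd = n,
                  tName = df$tName, tSize = unname(tg$sizes[df$tName]),
                  tStart = df$tStart, tEnd = df$tStart + n,
                  strand = df$strand,
                  matches = n - df$mism, misMatches = df$mism)
  psl[order(psl$tName, psl$tStart, psl$qStart), , drop = FALSE]
}

# ---- batched scanning (many reads against one small genome) -------------
# Used by the numt scanner: patterns are the k-mers of the (doubled) mtDNA,
# the subject is all reads concatenated with N spacers, so a single
# Aho-Corasick pass finds every seed hit. Semantically identical to running
# align_exact per read (tested), but orders of magnitude faster in R.

concat_hits <- function(pd, pat_pos, reads_chr, k) {
  spacer <- strrep("N", k)
  offsets <- cumsum(c(0L, nchar(reads_chr) + k))[seq_along(reads_chr)]
  subject <- Biostrings::DNAString(paste(reads_chr, collapse = spacer))
  m <- Biostrings::matchPDict(pd, subject)
  st <- Biostrings::startIndex(m)
  cnt <- lengths(st)
  if (sum(cnt) == 0)
    return(data.frame(read = integer(0), rpos = integer(0),
                      tpos = integer(0)))
  tpos <- rep(pat_pos, cnt)
  s <- unlist(st, use.names = FALSE)
  ridx <- findInterval(s, offsets)
  data.frame(read = ridx, rpos = s - offsets[ridx], tpos = tpos)
}

# Maximal exact segments between each read and a circular genome.
# Returns data.frame(read, strand, r1, r2, t1, t2) with 1-based closed
# coordinates; r1/r2 on the forward read, t1 reduced modulo L.
batch_exact_segments <- function(reads_chr, circ, k) {
  s <- as.character(circ$sequence)
  doubled <- paste0(s, s)
  kk <- query_kmers(doubled, k)
  stopifnot(length(kk$starts) > 0)
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(kk$kmers))
  out <- list()
  for (strand in c("+", "-")) {
    rc <- if (strand == "+") reads_chr else revcomp(reads_chr)
    hits <- concat_hits(pd, kk$starts, rc, k)
    if (nrow(hits) == 0) next
    # diagonal merge with read index in place of tName
    runs <- merge_diagonal_runs(
      data.frame(tName = hits$read, qpos = hits$rpos, tpos = hits$tpos), k)
    if (nrow(runs) == 0) next
    # drop origin-boundary artifacts per read (pre-conversion coords)
    runs <- do.call(rbind, lapply(split(runs, runs$tName), function(g) {
      if (nrow(g) < 2) return(g)
      d0 <- data.frame(strand = strand, qStart = g$q1 - 1L, qEnd = g$q2,
                       tStart = g$t1 - 1L, tEnd = g$t2,
                       row = seq_len(nrow(g)))
      g[dedupe_circular(d0, circ$length)$row, , drop = FALSE]
    }))
    ridx <- as.integer(runs$tName)
    rl <- nchar(reads_chr)[ridx]
    if (strand == "+") {
      r1 <- runs$q1; r2 <- runs$q2
    } else {
      r1 <- rl - runs$q2 + 1L; r2 <- rl - runs$q1 + 1L
    }
    df <- data.frame(read = ridx, strand = strand, r1 = r1, r2 = r2,
                     t1 = runs$t1, t2 = runs$t2)
    df <- df[df$t1 <= circ$length, , drop = FALSE]  # dedupe modulo L
    out[[strand]] <- df
  }
  if (length(out) == 0)
    return(data.frame(read = integer(0), strand = character(0),
                      r1 = integer(0), r2 = integer(0),
                      t1 = integer(0), t2 = integer(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$read, res$r1, res$strand), , drop = FALSE]
}
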