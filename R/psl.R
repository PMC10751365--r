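# PSL alignment records, validation, and UCSC pslScore / milliBad
# percent-identity computation. Gapless records (blockCount = 1) are the
# common case produced by the internal aligner; gapped records may be
# ingested from external PSL files and pass through the same filters.

#' Construct gapless PSL alignment rows
#'
#' All coordinate arguments are 0-based half-open, per the PSL convention.
#' Vectorized over all arguments.
#'
#' @param qName,qSize,qStart,qEnd query name/size/interval.
#' @param tName,tSize,tStart,tEnd target name/size/interval.
#' @param strand "+" or "-".
#' @param matches,misMatches,repMatches,nCount base counts; their sum must
#'   equal the block span.
#' @return a PSL data.frame (21 columns).
#' @export
make_psl <- function(qName, qSize, qStart, qEnd, tName, tSize, tStart, tEnd,
                     strand = "+", matches = qEnd - qStart, misMatches = 0L,
                     repMatches = 0L, nCount = 0L) {
  n <- max(length(qName), length(tName), length(qStart), length(tStart))
  span <- qEnd - qStart
  df <- data.frame(
    matches = as.integer(matches), misMatches = as.integer(misMatches),
    repMatches = as.integer(repMatches), nCount = as.integer(nCount),
    qNumInsert = 0L, qBaseInsert = 0L, tNumInsert = 0L, tBaseInsert = 0L,
    strand = strand, qName = qName, qSize = as.integer(qSize),
    qStart = as.integer(qStart), qEnd = as.integer(qEnd),
    tName = tName, tSize = as.integer(tSize),
    tStart = as.integer(tStart), tEnd = as.integer(tEnd),
    blockCount = 1L,
    blockSizes = paste0(span, ","),
    qStarts = paste0(as.integer(qStart), ","),
    tStarts = paste0(as.integer(tStart), ","),
    stringsAsFactors = FALSE
  )
  validate_psl(df)
  df
}

parse_int_list <- function(x) {
  lapply(strsplit(sub(",$", "", x), ","), as.integer)
}

#' Validate a PSL data.frame against the PSL structural invariants
#'
#' Checks that block sizes sum to the accounted bases, that block lists
#' have `blockCount` entries, and that query/target intervals are ordered.
#'
#' @param psl PSL data.frame.
#' @param context optional file name for error messages.
#' @param lines optional original line numbers.
#' @return invisibly, `psl`.
#' @export
validate_psl <- function(psl, context = "psl", lines = seq_len(nrow(psl))) {
  if (nrow(psl) == 0) return(invisible(psl))
  bs <- parse_int_list(psl$blockSizes)
  bad <- which(lengths(bs) != psl$blockCount |
                 lengths(parse_int_list(psl$qStarts)) != psl$blockCount |
                 lengths(parse_int_list(psl$tStarts)) != psl$blockCount)
  if (length(bad))
    stop("malformed PSL '", context, "' line ", lines[bad[1]],
         ": block lists do not have blockCount entries")
  sums <- vapply(bs, sum, numeric(1))
  acct <- psl$matches + psl$misMatches + psl$repMatches + psl$nCount
  bad <- which(sums != acct)
  if (length(bad))
    stop("malformed PSL '", context, "' line ", lines[bad[1]],
         ": field 'blockSizes' sums to ", sums[bad[1]],
         " but matches+misMatches+repMatches+nCount = ", acct[bad[1]])
  bad <- which(!(psl$qStart < psl$qEnd & psl$qEnd <= psl$qSize &
                   psl$tStart < psl$tEnd))
  if (length(bad))
    stop("malformed PSL '", context, "' line ", lines[bad[1]],
         ": field 'qStart/qEnd/tStart/tEnd' violates ordering")
  invisible(psl)
}

#' UCSC pslScore of alignments
#'
#' score = matches + repMatches - misMatches - qNumInsert - tNumInsert.
#'
#' @param psl PSL data.frame.
#' @return integer vector of scores, one per row.
#' @export
psl_score <- function(psl) {
  psl$matches + psl$repMatches - psl$misMatches -
    psl$qNumInsert - psl$tNumInsert
}

#' Percent identity of alignments (UCSC milliBad convention)
#'
#' Computed as `(100 - 0.1 * milliBad) / 100` with the untranslated-DNA
#' milliBad formula (gap openings on both query and target penalized).
#' Equals 1.0 exactly when misMatches, qNumInsert and tNumInsert are all
#' zero.
#'
#' @param psl PSL data.frame.
#' @return numeric vector of identities in [0, 1].
#' @export
percent_identity <- function(psl) {
  q_ali <- psl$qEnd - psl$qStart
  t_ali <- psl$tEnd - psl$tStart
  ali <- pmin(q_ali, t_ali)
  size_dif <- abs(q_ali - t_ali)
  insert_factor <- psl$qNumInsert + psl$tNumInsert
  total <- psl$matches + psl$repMatches + psl$misMatches
  milli_bad <- ifelse(
    ali <= 0 | total == 0, 1000,
    1000 * (psl$misMatches + insert_factor + round(3 * log(1 + size_dif))) /
      total)
  (100 - milli_bad * 0.1) / 100
}
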