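# Record-level interval algebra in BEDTools `intersect` semantics: an
# interval of `a` is kept (or removed) when it overlaps any interval of
# `b` by at least one base. Output is sorted by (chrom, start).

sort_gr <- function(gr) {
  GenomicRanges::sort(GenomeInfoDb::sortSeqlevels(gr), ignore.strand = TRUE)
}

# c() for GRanges built on different chromosome subsets (no shared
# seqlevels is expected here, not an error signal)
c_gr <- function(...) suppressWarnings(c(...))

#' Keep intervals of `a` overlapping `b` (BEDTools intersect -u semantics)
#'
#' @param a,b `GRanges`.
#' @return the members of `a` with >= 1 bp overlap with some member of `b`,
#'   sorted by (chrom, start). Strand is ignored.
#' @export
bed_intersect <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) return(sort_gr(a[0]))
  # sets commonly live on different chromosome subsets; that is not an
  # error signal here
  keep <- suppressWarnings(IRanges::overlapsAny(a, b,
                                                ignore.strand = TRUE))
  sort_gr(a[keep])
}

#' Remove intervals of `a` overlapping `b` (BEDTools intersect -v semantics)
#'
#' @param a,b `GRanges`.
#' @return the members of `a` overlapping no member of `b`, sorted by
#'   (chrom, start). Empty `b` returns all of `a`.
#' @export
bed_subtract <- function(a, b) {
  if (length(a) == 0) return(sort_gr(a))
  if (length(b) == 0) return(sort_gr(a))
  keep <- !suppressWarnings(IRanges::overlapsAny(a, b,
                                                 ignore.strand = TRUE))
  sort_gr(a[keep])
}
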