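# Read simulators for the three sequencing products the pipelines consume:
# uniform single-end WGS (nuclear + high-copy circular mtDNA), RDA
# subtraction amplicons of SVA 5' flanks, and inter-Alu (AluScan)
# amplicons. Reads are 150 nt and error-free by default; read names encode
# the source coordinates so truth-aware helpers can compute which planted
# junctions are covered.

#' Simulate single-end WGS reads
#'
#' Reads are drawn uniformly from the nuclear genome at the requested
#' coverage; mtDNA is drawn at `mt_copy_number`-fold relative depth with
#' origin-wrapping starts. Read names are
#' `wgs_<i>|<chrom>|<start>|<strand>`.
#'
#' @param nuclear `DNAStringSet` of nuclear chromosomes.
#' @param mt a [circular_genome()] or NULL to skip mtDNA reads.
#' @param coverage nuclear fold-coverage (> 0).
#' @param read_len read length in nt.
#' @param mt_copy_number mtDNA copies per nuclear genome equivalent.
#' @param error_rate per-base substitution rate (default 0, error-free).
#' @param seed integer RNG seed.
#' @param prefix read-name prefix.
#' @return a named `DNAStringSet`.
#' @export
simulate_wgs <- function(nuclear, mt = NULL, coverage = 3,
                         read_len = 150L, mt_copy_number = 100,
                         error_rate = 0, seed = 1L, prefix = "wgs") {
  stopifnot(coverage > 0)
  chrom_chr <- stats::setNames(as.character(nuclear), names(nuclear))
  lens <- nchar(chrom_chr)
  with_seed(seed, {
    n_nuc <- round(coverage * sum(lens) / read_len)
    ch <- sample(names(lens), n_nuc, replace = TRUE, prob = lens)
    starts <- vapply(lens[ch] - read_len + 1L, function(m) sample.int(m, 1),
                     integer(1))
    seqs <- substring(chrom_chr[ch], starts, starts + read_len - 1L)
    strands <- sample(c("+", "-"), n_nuc, replace = TRUE)
    src_ch <- ch; src_st <- starts
    if (!is.null(mt) && mt_copy_number > 0) {
      n_mt <- round(coverage * mt_copy_number * mt$length / read_len)
      doubled <- paste0(as.character(mt$sequence), as.character(mt$sequence))
      mst <- sample.int(mt$length, n_mt, replace = TRUE)
      mseq <- substring(doubled, mst, mst + read_len - 1L)
      mstr <- sample(c("+", "-"), n_mt, replace = TRUE)
      seqs <- c(seqs, mseq)
      strands <- c(strands, mstr)
      src_ch <- c(src_ch, rep(mt$id, n_mt))
      src_st <- c(src_st, mst)
    }
    minus <- strands == "-"
    if (any(minus)) seqs[minus] <- revcomp(seqs[minus])
    if (error_rate > 0)
      seqs <- vapply(seqs, mutate_dna, character(1), rate = error_rate,
                     USE.NAMES = FALSE)
    reads <- Biostrings::DNAStringSet(seqs)
    names(reads) <- sprintf("%s_%06d|%s|%d|%s", prefix, seq_along(seqs),
                            src_ch, src_st, strands)
    reads
  })
}

#' Default RDA adaptor sequence
#'
#' The RDA-adaptor ligated to tester fragments; a synthetic 24-mer default
#' (the bench adaptor is a protocol parameter, substitutable via config).
#' @export
rda_adaptor_default <- function() "AGCACTCTCCAGCCTCTCACCGCA"

#' Simulate RDA subtraction amplicons of SVA 5' flanks
#'
#' For each SVA 5' locus in the tester (senescent) genome an amplicon
#' `adaptor + upstream nuclear flank + (CCCTCT)n + SVA 5' head` is built
#' from the tester sequence. Loci also present in the driver (germline
#' loci) are suppressed with probability `subtraction_efficiency`;
#' surviving loci are amplified `amplification`-fold. Amplicons are
#' fragmented into `read_len` nt reads (sliding windows of `frag_step`).
#'
#' @param tester `DNAStringSet`, the senescent sample genome.
#' @param loci data.frame with columns `chrom`, `pos5` (1-based tester
#'   coordinate of the 5'-most element base: the first hexamer base),
#'   `strand` and `is_de_novo` (logical; de novo loci are absent from the
#'   driver).
#' @param adaptor RDA adaptor sequence.
#' @param flank_len nuclear flank length captured upstream of the element.
#' @param head_len length of element 5' head included in the amplicon.
#' @param subtraction_efficiency probability a driver-shared locus is
#'   suppressed.
#' @param amplification copy number of surviving loci.
#' @param read_len,frag_step fragmentation geometry.
#' @param seed integer RNG seed.
#' @return a named `DNAStringSet` of amplicon reads
#'   (`rda_<locus>_<frag>_<copy>`).
#' @export
simulate_rda <- function(tester, loci, adaptor = rda_adaptor_default(),
                         flank_len = 80L, head_len = 120L,
                         subtraction_efficiency = 0.99, amplification = 50L,
                         read_len = 150L, frag_step = 50L, seed = 1L) {
  chrom_chr <- stats::setNames(as.character(tester), names(tester))
  with_seed(seed, {
    out <- character(0); nm <- character(0)
    for (i in seq_len(nrow(loci))) {
      if (!loci$is_de_novo[i] &&
          stats::runif(1) < subtraction_efficiency) next
      ch <- loci$chrom[i]; pos <- loci$pos5[i]
      if (loci$strand[i] == "-") {
        a <- pos - head_len + 1L; b <- pos + flank_len
        if (a < 1L || b > nchar(chrom_chr[[ch]])) next
        region <- revcomp(substring(chrom_chr[[ch]], a, b))
      } else {
        a <- pos - flank_len; b <- pos + head_len - 1L
        if (a < 1L || b > nchar(chrom_chr[[ch]])) next
        region <- substring(chrom_chr[[ch]], a, b)
      }
      amplicon <- paste0(adaptor, region)
      fs <- seq(1L, max(1L, nchar(amplicon) - read_len + 1L), by = frag_step)
      frags <- substring(amplicon, fs, pmin(fs + read_len - 1L,
                                            nchar(amplicon)))
      for (cp in seq_len(amplification)) {
        out <- c(out, frags)
        nm <- c(nm, sprintf("rda_L%03d_f%02d_c%03d", i, seq_along(frags),
                            cp))
      }
    }
    if (length(out) == 0) return(Biostrings::DNAStringSet())
    reads <- Biostrings::DNAStringSet(out)
    names(reads) <- nm
    reads
  })
}

#' Simulate inter-Alu (AluScan) amplicons
#'
#' Emits an amplicon for every convergent Alu pair (a '+'-strand Alu
#' followed downstream by a '-'-strand Alu) whose amplicon, spanning from
#' the inward-facing primer site in the first Alu to the one in the
#' second, is at most `max_amplicon` nt. Amplicons are fragmented into
#' `read_len` nt reads (deterministic tiling; `seed` is accepted for API
#' symmetry but no randomness is used).
#'
#' @param genome `DNAStringSet` (the sample genome, in its own
#'   coordinates).
#' @param alus `GRanges` of Alu elements with strand, in the same
#'   coordinates.
#' @param max_amplicon maximum amplicon span in nt.
#' @param primer_len length of the primer-binding portion inside each Alu.
#' @param read_len,frag_step fragmentation geometry.
#' @param seed unused; present for interface symmetry.
#' @return a named `DNAStringSet` of amplicon reads.
#' @export
simulate_aluscan <- function(genome, alus, max_amplicon = 5000L,
                             primer_len = 25L, read_len = 150L,
                             frag_step = 50L, seed = 1L) {
  chrom_chr <- stats::setNames(as.character(genome), names(genome))
  out <- character(0); nm <- character(0)
  k <- 0L
  for (ch in names(chrom_chr)) {
    a <- alus[GenomicRanges::seqnames(alus) == ch]
    plus <- a[GenomicRanges::strand(a) == "+"]
    minus <- a[GenomicRanges::strand(a) == "-"]
    if (length(plus) == 0 || length(minus) == 0) next
    for (i in seq_along(plus)) {
      p_end <- GenomicRanges::end(plus)[i]
      from <- p_end - primer_len + 1L
      cand <- which(GenomicRanges::start(minus) > p_end)
      for (j in cand) {
        to <- GenomicRanges::start(minus)[j] + primer_len - 1L
        if (to - from + 1L > max_amplicon) next
        amplicon <- substring(chrom_chr[[ch]], from, to)
        k <- k + 1L
        fs <- seq(1L, max(1L, nchar(amplicon) - read_len + 1L),
                  by = frag_step)
        frags <- substring(amplicon, fs,
                           pmin(fs + read_len - 1L, nchar(amplicon)))
        out <- c(out, frags)
        nm <- c(nm, sprintf("alu_%04d|%s|%d_f%02d", k, ch,
                            from + fs - 1L, seq_along(frags)))
      }
    }
  }
  if (length(out) == 0) return(Biostrings::DNAStringSet())
  reads <- Biostrings::DNAStringSet(out)
  names(reads) <- nm
  reads
}
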