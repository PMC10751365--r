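# RDA amplicon parsing, insertion calling, summaries and replicate overlap.

test_that("amplicon parsing finds adaptor and hexamer landmarks", {
  set.seed(81)
  ad <- rda_adaptor_default()
  flank <- rand_dna(80)
  read <- paste0(ad, flank, strrep("CCCTCT", 35))
  p <- parse_amplicon(read, ad)
  expect_equal(p$status, "ok")
  expect_equal(p$flank_seq, flank)
  expect_equal(nchar(p$flank_seq), 80L)

  # reverse-complemented amplicon yields the same flank
  prc <- parse_amplicon(rc(read), ad)
  expect_equal(prc$status, "ok")
  expect_equal(prc$flank_seq, flank)
  expect_equal(prc$orientation, "-")

  expect_equal(parse_amplicon(paste0(ad, flank, rand_dna(40)), ad)$status,
               "no_hexamer")
  expect_equal(parse_amplicon(paste0(flank, strrep("CCCTCT", 5)),
                              ad)$status, "no_adaptor")
  expect_equal(parse_amplicon(paste0(ad, rand_dna(10),
                                     strrep("CCCTCT", 5)), ad)$status,
               "short_flank")
  # fewer than min_hexamer_repeats exact units does not count
  expect_equal(parse_amplicon(paste0(ad, flank, strrep("CCCTCT", 2),
                                     rand_dna(30)), ad)$status,
               "no_hexamer")
})

test_that("insertion calling recovers planted loci and excludes germline", {
  tg <- make_toy_genome(toy_genome_spec(
    n_chroms = 2L, chrom_length = 30000L, n_germline_sva = 10L,
    n_alu = 6L, n_line = 2L, n_ltr = 2L, n_satellite = 1L, n_genes = 2L,
    seed = 21))
  ev <- plant_de_novo_events(tg, n_sva = 5, n_numt = 0, seed = 22)
  tt <- ev$truth
  ref <- tg$nuclear
  flanks <- data.frame(
    read_id = paste0("f", seq_len(nrow(tt))), status = "ok",
    orientation = "+",
    flank_seq = vapply(seq_len(nrow(tt)), function(i)
      substring(as.character(ref[[tt$chrom[i]]]), tt$ins_at[i] - 80,
                tt$ins_at[i] - 1), character(1)))
  calls <- call_insertions(flanks, ref, tg$sva, replicate = "Sen_1")
  expect_equal(length(calls), nrow(tt))
  for (i in seq_len(nrow(tt)))
    expect_true(any(
      as.character(GenomicRanges::seqnames(calls)) == tt$chrom[i] &
        abs(GenomicRanges::start(calls) - tt$ins_at[i]) <= 20))

  # flank upstream of a germline (annotated) SVA is excluded
  g <- tg$sva[as.character(GenomicRanges::strand(tg$sva)) == "+"][1]
  gpos <- GenomicRanges::start(g)
  gfl <- data.frame(read_id = "g1", status = "ok", orientation = "+",
                    flank_seq = substring(
                      as.character(ref[[as.character(
                        GenomicRanges::seqnames(g))]]),
                      gpos - 80, gpos - 1))
  expect_equal(length(call_insertions(gfl, ref, tg$sva)), 0L)

  # ambiguous flank (two perfect copies) yields no call
  chr1 <- as.character(ref[[1]])
  dup <- Biostrings::DNAStringSet(c(
    chr1 = paste0(chr1, "N", substring(chr1, 5001, 5080))))
  afl <- data.frame(read_id = "a1", status = "ok", orientation = "+",
                    flank_seq = substring(chr1, 5001, 5080))
  expect_equal(length(call_insertions(afl, dup, tg$sva)), 0L)
})

test_that("calls are invariant to read order", {
  tg <- make_toy_genome(toy_genome_spec(
    n_chroms = 1L, chrom_length = 30000L, n_germline_sva = 5L,
    n_alu = 4L, n_line = 2L, n_ltr = 2L, n_satellite = 1L, n_genes = 2L,
    seed = 23))
  ev <- plant_de_novo_events(tg, n_sva = 4, n_numt = 0, seed = 24)
  tt <- ev$truth
  loci <- data.frame(chrom = tt$chrom, pos5 = tt$sen_start, strand = "+",
                     is_de_novo = TRUE)
  reads <- simulate_rda(ev$senescent, loci, amplification = 5, seed = 25)
  fl1 <- parse_amplicons(reads)
  set.seed(26)
  fl2 <- parse_amplicons(reads[sample(length(reads))])
  c1 <- call_insertions(fl1, tg$nuclear, tg$sva)
  c2 <- call_insertions(fl2, tg$nuclear, tg$sva)
  expect_equal(GenomicRanges::start(c1), GenomicRanges::start(c2))
  expect_equal(c1$support, c2$support)
})

test_that("summaries compute totals, uniques and log10 distribution", {
  calls <- GenomicRanges::GRanges(
    c("chr1", "chr1", "chr2"), IRanges::IRanges(c(100, 900, 50), width = 1),
    support = c(5L, 3L, 2L), replicate = "Sen_1")
  s <- summarize_sva(calls)
  expect_equal(s$total, 10L)
  expect_equal(s$unique, 3L)
  expect_equal(s$per_chrom$log10_support[s$per_chrom$chrom == "chr1"],
               log10(8))
  s0 <- summarize_sva(GenomicRanges::GRanges())
  expect_equal(s0$total, 0L)
  expect_equal(s0$unique, 0L)
  expect_equal(nrow(s0$per_chrom), 0L)
})

test_that("replicate overlap counts transitive clusters once per subset", {
  mk <- function(pos, chrom = "chr1")
    GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos),
                           support = 1L)
  a <- mk(c(100, 500, 1000)); b <- mk(c(110, 2000)); c_ <- mk(c(95, 3000))
  venn <- replicate_overlap(list(A = a, B = b, C = c_), tolerance = 20)
  expect_equal(venn$count[venn$members == "A,B,C"], 1L)  # 95/100/110 chain
  expect_equal(sum(venn$count), 5L)  # 5 distinct clusters overall
  # identical sets: everything is shared
  v2 <- replicate_overlap(list(A = a, B = a))
  expect_equal(v2$members, "A,B")
  expect_equal(v2$count, 3L)
  # disjoint sets share nothing
  v3 <- replicate_overlap(list(A = mk(c(100, 200)), B = mk(c(5000, 9000))))
  expect_true(!any(grepl(",", v3$members)))
  # inclusion-exclusion: subset counts sum to total clusters
  expect_equal(sum(v3$count), 4L)
})
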