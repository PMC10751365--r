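# Toy genome generation, de novo event planting and the read simulators.

small_spec <- function(seed = 1L)
  toy_genome_spec(n_chroms = 2L, chrom_length = 30000L,
                  n_germline_sva = 8L, n_germline_numt = 3L, n_alu = 8L,
                  n_line = 3L, n_ltr = 3L, n_satellite = 2L, n_genes = 3L,
                  seed = seed)

test_that("toy genome generation is deterministic and honors the size contract", {
  tg1 <- make_toy_genome(small_spec(5))
  tg2 <- make_toy_genome(small_spec(5))
  expect_identical(as.character(tg1$nuclear), as.character(tg2$nuclear))
  expect_identical(as.character(tg1$mt$sequence),
                   as.character(tg2$mt$sequence))
  expect_identical(as.data.frame(tg1$sva), as.data.frame(tg2$sva))

  expect_equal(length(tg1$nuclear), 2L)
  expect_equal(unname(Biostrings::width(tg1$nuclear)), c(30000L, 30000L))
  expect_equal(tg1$mt$length, 16559L)
  expect_equal(length(tg1$numt), 3L)
  expect_setequal(unique(tg1$repeats$class),
                  c("SINE", "LINE", "LTR", "Satellite"))
  expect_true(all(c("promoter", "exon", "intron", "3UTR", "TTS") %in%
                    tg1$genes$feature))
})

test_that("germline numt sequences match mtDNA exactly", {
  tg <- make_toy_genome(small_spec(6))
  doubled <- paste0(as.character(tg$mt$sequence),
                    as.character(tg$mt$sequence))
  for (i in seq_along(tg$numt)) {
    ch <- as.character(GenomicRanges::seqnames(tg$numt))[i]
    planted <- substring(as.character(tg$nuclear[[ch]]),
                         GenomicRanges::start(tg$numt)[i],
                         GenomicRanges::end(tg$numt)[i])
    expect_equal(planted,
                 substring(doubled, tg$numt$mt_start0[i] + 1,
                           tg$numt$mt_start0[i] + tg$numt$mt_len[i]))
  }
})

test_that("requested features exceeding capacity raise an informative error", {
  expect_error(
    make_toy_genome(toy_genome_spec(n_chroms = 1L, chrom_length = 3000L,
                                    n_germline_sva = 40L)),
    "capacity")
})

test_that("planted de novo events are re-extractable; null plant is identity", {
  tg <- make_toy_genome(small_spec(7))
  ev0 <- plant_de_novo_events(tg, n_sva = 0, n_numt = 0, seed = 2)
  expect_identical(as.character(ev0$senescent), as.character(tg$nuclear))
  expect_equal(nrow(ev0$truth), 0L)

  ev <- plant_de_novo_events(tg, n_sva = 4, n_numt = 6,
                             params = list(mt_len_range = c(50, 130)),
                             seed = 2)
  expect_equal(nrow(ev$truth), 10L)
  doubled <- paste0(as.character(tg$mt$sequence),
                    as.character(tg$mt$sequence))
  for (i in seq_len(nrow(ev$truth))) {
    tt <- ev$truth[i, ]
    got <- substring(as.character(ev$senescent[[tt$chrom]]),
                     tt$sen_start, tt$sen_end)
    expect_equal(got, tt$ins_seq)
    if (tt$kind == "de_novo_numt") {
      expect_equal(tt$ins_seq, substring(doubled, tt$mt_start0 + 1,
                                         tt$mt_start0 + tt$mt_len))
      # engineered junction microhomology: reference bases left of the
      # insertion equal the segment's first h bases
      h <- tt$microhomology_len
      if (h > 0) {
        ref <- as.character(tg$nuclear[[tt$chrom]])
        expect_equal(substring(ref, tt$ins_at - h, tt$ins_at - 1),
                     substring(tt$ins_seq, 1, h))
      }
    } else {
      expect_match(tt$ins_seq, "^(CCCTCT)+")
    }
  }
  # driver genome lacks every event sequence at its locus
  for (i in seq_len(nrow(ev$truth))) {
    tt <- ev$truth[i, ]
    ref_piece <- substring(as.character(tg$nuclear[[tt$chrom]]),
                           tt$ins_at, tt$ins_at + nchar(tt$ins_seq) - 1)
    expect_false(ref_piece == tt$ins_seq)
  }
  # truth BED round-trip
  tmp <- withr::local_tempfile()
  write_truth(ev$truth, tmp)
  rt <- read_truth(tmp)
  expect_equal(rt$ins_at, ev$truth$ins_at)
  expect_equal(rt$kind, ev$truth$kind)
  expect_equal(rt$mt_len, ev$truth$mt_len)
})

test_that("repeat_target_bias = 1 places SVA insertions inside repeats", {
  tg <- make_toy_genome(small_spec(8))
  ev <- plant_de_novo_events(tg, n_sva = 5, n_numt = 0,
                             params = list(repeat_target_bias = 1.0),
                             seed = 3)
  tt <- ev$truth
  pts <- GenomicRanges::GRanges(tt$chrom,
                                IRanges::IRanges(tt$ins_at, tt$ins_at))
  expect_true(all(IRanges::overlapsAny(pts, tg$repeats,
                                       ignore.strand = TRUE)))
})

test_that("simulate_wgs meets the read-count contract and is deterministic", {
  tg <- make_toy_genome(toy_genome_spec(n_chroms = 3L,
                                        chrom_length = 50000L, seed = 9))
  r1 <- simulate_wgs(tg$nuclear, mt = NULL, coverage = 1, seed = 4)
  expect_equal(length(r1), 1000L)  # 1x over 150 kb at 150 nt
  expect_true(all(Biostrings::width(r1) == 150L))
  r2 <- simulate_wgs(tg$nuclear, mt = NULL, coverage = 1, seed = 4)
  expect_identical(as.character(r1), as.character(r2))

  # mtDNA drawn at mt_copy_number-fold relative depth
  rmt <- simulate_wgs(tg$nuclear, tg$mt, coverage = 1,
                      mt_copy_number = 20, seed = 4)
  n_mt <- sum(grepl("\\|MT\\|", names(rmt)))
  expect_equal(n_mt, round(20 * tg$mt$length / 150), tolerance = 0.02)
})

test_that("RDA simulation: perfect subtraction leaves only de novo loci", {
  tg <- make_toy_genome(small_spec(10))
  ev <- plant_de_novo_events(tg, n_sva = 3, n_numt = 0, seed = 5)
  tt <- ev$truth
  germ <- tg$sva
  g5 <- ifelse(as.character(GenomicRanges::strand(germ)) == "-",
               GenomicRanges::end(germ), GenomicRanges::start(germ))
  loci <- rbind(
    data.frame(chrom = as.character(GenomicRanges::seqnames(germ)),
               pos5 = ev$ref_to_sen(
                 as.character(GenomicRanges::seqnames(germ)), g5),
               strand = as.character(GenomicRanges::strand(germ)),
               is_de_novo = FALSE),
    data.frame(chrom = tt$chrom, pos5 = tt$sen_start, strand = "+",
               is_de_novo = TRUE))
  reads <- simulate_rda(ev$senescent, loci, subtraction_efficiency = 1.0,
                        amplification = 3, seed = 6)
  expect_gt(length(reads), 0)
  # every read derives from a de novo locus amplicon
  expect_true(all(grepl("^rda_", names(reads))))
  fl <- parse_amplicons(reads)
  ok <- fl[fl$status == "ok", ]
  expect_gt(nrow(ok), 0)
  # each parsed flank is the 80 nt immediately upstream of a de novo SVA
  for (fs in unique(ok$flank_seq)) {
    hit <- any(vapply(seq_len(nrow(tt)), function(i) {
      up <- substring(as.character(ev$senescent[[tt$chrom[i]]]),
                      tt$sen_start[i] - 80, tt$sen_start[i] - 1)
      identical(fs, up)
    }, logical(1)))
    expect_true(hit)
  }
  # zero de novo loci + perfect subtraction -> empty output
  r0 <- simulate_rda(ev$senescent, loci[!loci$is_de_novo, ],
                     subtraction_efficiency = 1.0, seed = 6)
  expect_equal(length(r0), 0L)
})

test_that("AluScan emits amplicons only for convergent pairs within range", {
  set.seed(41)
  g <- c(chr1 = rand_dna(12000))
  alus <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(1000, 2300, 9000), width = 300),
    strand = c("+", "-", "-"))
  reads <- simulate_aluscan(Biostrings::DNAStringSet(g), alus,
                            max_amplicon = 5000)
  expect_gt(length(reads), 0)
  # pair 1-2 amplifies (1 kb apart); pair 1-3 does not (span > 5 kb)
  spans <- as.integer(sub(".*\\|chr1\\|(\\d+)_.*", "\\1", names(reads)))
  expect_true(all(spans >= 1275 & spans <= 2324))
  reads2 <- simulate_aluscan(
    Biostrings::DNAStringSet(g),
    GenomicRanges::GRanges("chr1",
                           IRanges::IRanges(c(500, 9000), width = 300),
                           strand = c("+", "-")),
    max_amplicon = 5000)
  expect_equal(length(reads2), 0L)
})
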