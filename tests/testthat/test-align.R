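# The exact / near-exact aligner against brute-force enumeration.

test_that("align_exact recovers planted identities on both strands", {
  set.seed(31)
  tgt <- c(chr1 = rand_dna(10000))
  q <- substring(tgt, 101, 220)
  p <- align_exact(q, tgt, min_len = 20)
  expect_equal(nrow(p), 1L)
  expect_equal(p$tStart, 100L)
  expect_equal(p$tEnd, 220L)
  expect_equal(p$matches, 120L)
  expect_equal(p$strand, "+")

  pr <- align_exact(rc(q), tgt, min_len = 20)
  expect_equal(pr$strand, "-")
  expect_equal(pr$tStart, 100L)
  expect_equal(pr$tEnd, 220L)
})

test_that("align_exact equals brute-force substring enumeration", {
  for (seed in 1:6) {
    set.seed(seed)
    targets <- list(chrA = rand_dna(1500), chrB = rand_dna(1200))
    # query stitched from target pieces so multiple matches exist
    q <- paste0(substring(targets$chrA, 300, 345), rand_dna(20),
                rc(substring(targets$chrB, 700, 760)), rand_dna(15),
                substring(targets$chrA, 900, 930))
    got <- align_exact(q, unlist(targets), min_len = 12)
    want <- brute_align_exact(q, targets, min_len = 12)
    expect_equal(got[, c("tName", "strand", "qStart", "qEnd", "tStart",
                         "tEnd")],
                 want, ignore_attr = TRUE)
  }
})

test_that("planted 40-mers are recovered at planted coordinates, no extras", {
  set.seed(33)
  tgt <- rand_dna(10000)
  starts <- sort(sample(seq(1, 9000, by = 180), 50))
  kmers <- substring(tgt, starts, starts + 39)
  for (i in sample(seq_along(starts), 10)) {
    p <- align_exact(kmers[i], c(chr1 = tgt), min_len = 25)
    p <- p[p$strand == "+", ]
    expect_true((starts[i] - 1) %in% p$tStart)
    # every reported hit is a true exact occurrence
    for (j in seq_len(nrow(p)))
      expect_equal(substring(tgt, p$tStart[j] + 1, p$tEnd[j]), kmers[i])
  }
})

test_that("align_exact is invariant under reverse-complementing the target", {
  set.seed(34)
  tgt <- rand_dna(3000)
  q <- substring(tgt, 1001, 1100)
  a <- align_exact(q, c(chr = tgt), min_len = 30)
  b <- align_exact(q, c(chr = rc(tgt)), min_len = 30)
  expect_equal(nrow(a), nrow(b))
  # coordinates transform: tStart' = len - tEnd, strand flips
  expect_equal(sort(b$tStart), sort(3000 - a$tEnd))
  expect_setequal(b$strand, chartr("+-", "-+", a$strand))
})

test_that("circular alignment spans the origin and respects rotation", {
  set.seed(35)
  s <- rand_dna(2000)
  circ <- circular_genome(s, id = "MT")
  q <- paste0(substring(s, 1951, 2000), substring(s, 1, 50))
  p <- align_exact(q, circ, min_len = 20)
  expect_equal(nrow(p), 1L)
  expect_equal(p$tStart, 1950L)
  expect_equal(p$tEnd, 2050L)  # runs past the origin
  expect_equal(p$tSize, 2000L)

  # rotating the circular sequence by k shifts coordinates modulo L
  k <- 500
  rot <- circular_genome(paste0(substring(s, k + 1), substring(s, 1, k)),
                         id = "MT")
  pk <- align_exact(q, rot, min_len = 20)
  expect_equal((pk$tStart + k) %% 2000, p$tStart %% 2000)
})

test_that("align_near brackets the identity threshold exactly", {
  set.seed(36)
  tgt <- c(chr1 = rand_dna(8000))
  q <- substring(tgt, 501, 700)  # 200-mer
  expect_equal(nrow(align_near(q, tgt, min_identity = 0.95)), 1L)

  put_mm <- function(q, k) {
    ch <- strsplit(q, "")[[1]]
    idx <- seq(5, 195, length.out = k)
    ch[idx] <- vapply(ch[idx], function(b)
      setdiff(c("A", "C", "G", "T"), b)[1], character(1))
    paste(ch, collapse = "")
  }
  expect_equal(nrow(align_near(put_mm(q, 9), tgt, 0.95)), 1L)   # 95.5%
  expect_equal(nrow(align_near(put_mm(q, 11), tgt, 0.95)), 0L)  # 94.5%
  expect_equal(nrow(align_near(rand_dna(200), tgt, 0.95)), 0L)
  # superset of align_exact full-length hits at identity 1
  expect_equal(nrow(align_near(q, tgt, 1.0)), 1L)
})

test_that("batched read scanning agrees with per-read align_exact", {
  set.seed(37)
  mt <- circular_genome(rand_dna(4000), id = "MT")
  nuc <- rand_dna(5000)
  mtc <- as.character(mt$sequence)
  reads <- c(
    pure_nuc = substring(nuc, 101, 250),
    chimera = make_chimera(nuc, mtc, 60, 300, 60, 30),
    chimera_rc = rc(make_chimera(nuc, mtc, 40, 3950, 80, 30)),  # origin
    pure_mt = substring(mtc, 11, 160)
  )
  batch <- scan_reads(Biostrings::DNAStringSet(reads), mt, min_mt_len = 30)
  for (id in names(reads)) {
    single <- scan_read(reads[[id]], mt, min_mt_len = 30)
    bb <- batch[batch$read_id == id, , drop = FALSE]
    expect_equal(nrow(bb), nrow(single), info = id)
    if (nrow(single) > 0 && !any(bb$full_read)) {
      expect_equal(bb$r_start, single$r_start, info = id)
      expect_equal(bb$r_end, single$r_end, info = id)
      expect_equal(bb$mt_start0, single$mt_start0, info = id)
    }
  }
  expect_equal(sum(batch$full_read), 1L)
})
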