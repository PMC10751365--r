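# Synthetic toy genomes with planted germline features and de novo
# spike-in events. The generator defines the study conditions the
# detection pipelines are validated against: 150 nt reads, mtDNA-derived
# insertions up to a few hundred nt with junction microhomology, SVA
# insertions carrying the 5' (CCCTCT)n hexamer (30-50 units) and a target
# site duplication, and a germline/de-novo partition between a
# "proliferating" (reference) and a "senescent" sample genome.

MT_LENGTH_DEFAULT <- 16559L

# Fixed synthetic consensus sequences for repeat classes and SVA
# subfamilies. These are synthetic stand-ins (not DFAM sequences) generated
# once under an internal constant seed so they are identical across
# sessions; SVA subfamilies get distinct 5' 200-mers so subfamily queries
# are separable. Real consensus FASTA may be substituted via config.
element_consensus <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cons <- with_seed(987123L, {
      sva <- stats::setNames(
        vapply(1:6, function(i) random_dna(300, gc = 0.55), character(1)),
        paste0("SVA_", LETTERS[1:6]))
      list(SVA = sva,
           SINE = random_dna(300, gc = 0.52),   # Alu-like
           LINE = random_dna(600, gc = 0.40),
           LTR = random_dna(400, gc = 0.45),
           Satellite = strrep(random_dna(25, gc = 0.40), 8),
           DNA = random_dna(250, gc = 0.42))
    })
    cache <<- cons
    cons
  }
})

#' Specification of a toy genome
#'
#' Counts of planted germline features and background composition for
#' [make_toy_genome()]. All planted features are non-overlapping; the seed
#' fully determines the output.
#'
#' @param n_chroms,chrom_length number and length (nt) of nuclear
#'   chromosomes.
#' @param gc_fraction background GC content.
#' @param mt_length circular mtDNA length (nt).
#' @param n_germline_sva,n_germline_numt,n_alu,n_line,n_ltr,n_satellite
#'   counts of planted germline features.
#' @param n_genes number of annotated gene models (annotation only; the
#'   underlying sequence is background).
#' @param seed integer RNG seed.
#' @return a `toy_genome_spec` list.
#' @export
toy_genome_spec <- function(n_chroms = 2L, chrom_length = 50000L,
                            gc_fraction = 0.41,
                            mt_length = MT_LENGTH_DEFAULT,
                            n_germline_sva = 20L, n_germline_numt = 5L,
                            n_alu = 20L, n_line = 6L, n_ltr = 6L,
                            n_satellite = 3L, n_genes = 5L, seed = 1L) {
  spec <- list(n_chroms = as.integer(n_chroms),
               chrom_length = as.integer(chrom_length),
               gc_fraction = gc_fraction, mt_length = as.integer(mt_length),
               n_germline_sva = as.integer(n_germline_sva),
               n_germline_numt = as.integer(n_germline_numt),
               n_alu = as.integer(n_alu), n_line = as.integer(n_line),
               n_ltr = as.integer(n_ltr),
               n_satellite = as.integer(n_satellite),
               n_genes = as.integer(n_genes), seed = as.integer(seed))
  stopifnot(all(vapply(spec, function(x) x >= 0, logical(1))))
  class(spec) <- "toy_genome_spec"
  spec
}

# Human-like mtDNA feature map scaled to length L: D-Loop plus the 13
# protein-coding genes and 2 rRNAs, with the residue assigned to tRNA
# blocks spread between genes.
build_mt_gene_map <- function(L, mt_id = "MT") {
  base <- c("D-Loop" = 1122L, "MT-RNR1" = 954L, "MT-RNR2" = 1559L,
            "MT-ND1" = 956L, "MT-ND2" = 1042L, "MT-CO1" = 1542L,
            "MT-CO2" = 684L, "MT-ATP8" = 207L, "MT-ATP6" = 681L,
            "MT-CO3" = 784L, "MT-ND3" = 346L, "MT-ND4L" = 297L,
            "MT-ND4" = 1378L, "MT-ND5" = 1812L, "MT-ND6" = 525L,
            "MT-CYB" = 1141L)
  lens <- pmax(1L, as.integer(round(base * L / 16559)))
  names(lens) <- names(base)
  gap_total <- L - sum(lens)
  if (gap_total < 0) { lens["MT-RNR2"] <- lens["MT-RNR2"] + gap_total
    gap_total <- 0L }
  n_gap <- length(lens)
  gaps <- rep(gap_total %/% n_gap, n_gap)
  gaps[seq_len(gap_total %% n_gap)] <- gaps[seq_len(gap_total %% n_gap)] + 1L
  starts <- integer(n_gap); pos <- 1L
  feats <- list()
  for (i in seq_along(lens)) {
    feats[[length(feats) + 1L]] <-
      data.frame(name = names(lens)[i], start = pos, end = pos + lens[i] - 1L)
    pos <- pos + lens[i]
    if (gaps[i] > 0) {
      feats[[length(feats) + 1L]] <-
        data.frame(name = "MT-TRNA", start = pos, end = pos + gaps[i] - 1L)
      pos <- pos + gaps[i]
    }
  }
  df <- do.call(rbind, feats)
  GenomicRanges::GRanges(mt_id, IRanges::IRanges(df$start, df$end),
                         name = df$name, score = 0)
}

# Sample non-overlapping feature positions on random chromosomes, keeping
# `margin` nt clearance from previously occupied intervals.
sample_sites <- function(n, widths, chrom_lens, occupied, margin = 150L,
                         max_tries = 2000L) {
  chroms <- names(chrom_lens)
  out <- data.frame(chrom = character(0), start = integer(0),
                    end = integer(0))
  for (i in seq_len(n)) {
    w <- widths[i]
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      ch <- sample(chroms, 1, prob = chrom_lens)
      if (chrom_lens[[ch]] < w + 2L * margin) next
      s <- sample.int(chrom_lens[[ch]] - w - margin, 1) + margin
      cand <- IRanges::IRanges(s - margin, s + w - 1L + margin)
      occ <- occupied[[ch]]
      if (length(occ) == 0 ||
          !any(IRanges::overlapsAny(cand, occ))) {
        occupied[[ch]] <- c(occ, IRanges::IRanges(s, s + w - 1L))
        out <- rbind(out, data.frame(chrom = ch, start = s,
                                     end = s + w - 1L))
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("cannot place feature of width ", w,
           ": requested features exceed genome capacity; ",
           "minimum total chromosome length required is about ",
           sum(widths) * 3 + 2 * margin * n, " nt")
  }
  list(sites = out, occupied = occupied)
}

#' Generate a toy genome with annotated germline features
#'
#' Builds random nuclear chromosomes and a circular mtDNA, then plants
#' non-overlapping germline features by overwriting background sequence:
#' annotated SVAs (with hexamer head), numts (exact mtDNA substrings,
#' possibly origin-spanning), and repeats (SINE/Alu with exact primer ends
#' and 2% body divergence per copy, LINE, LTR, Satellite). Gene models
#' (promoter/exon/intron/3UTR/TTS) are annotation-only. Deterministic for a
#' fixed seed.
#'
#' @param spec a [toy_genome_spec()].
#' @return a list with elements `nuclear` (DNAStringSet), `mt`
#'   (circular_genome), `mt_genes`, `sva`, `numt`, `repeats`, `genes`
#'   (GRanges annotations) and `spec`.
#' @export
make_toy_genome <- function(spec = toy_genome_spec()) {
  stopifnot(inherits(spec, "toy_genome_spec"))
  cons <- element_consensus()
  with_seed(spec$seed, {
    mt_seq <- random_dna(spec$mt_length, gc = 0.44)
    mt <- circular_genome(mt_seq, id = "MT")
    chrom_lens <- stats::setNames(rep(spec$chrom_length, spec$n_chroms),
                                  paste0("chr", seq_len(spec$n_chroms)))
    chroms <- lapply(chrom_lens, random_dna, gc = spec$gc_fraction)
    occupied <- stats::setNames(
      rep(list(IRanges::IRanges()), spec$n_chroms), names(chrom_lens))

    plant <- function(sites, seqs) {
      for (i in seq_len(nrow(sites))) {
        ch <- sites$chrom[i]
        substr(chroms[[ch]], sites$start[i], sites$end[i]) <<- seqs[i]
      }
    }

    # annotated SVAs: hexamer run + subfamily consensus
    sva_sub <- sample(names(cons$SVA), spec$n_germline_sva, replace = TRUE)
    sva_nhex <- if (spec$n_germline_sva > 0)
      sample(30:50, spec$n_germline_sva, replace = TRUE) else integer(0)
    sva_strand <- if (spec$n_germline_sva > 0)
      sample(c("+", "-"), spec$n_germline_sva, replace = TRUE,
             prob = c(0.7, 0.3)) else character(0)
    sva_seqs <- vapply(seq_len(spec$n_germline_sva), function(i) {
      s <- paste0(strrep("CCCTCT", sva_nhex[i]), cons$SVA[[sva_sub[i]]])
      if (sva_strand[i] == "-") revcomp(s) else s
    }, character(1))
    r <- sample_sites(spec$n_germline_sva, nchar(sva_seqs), chrom_lens,
                      occupied)
    sva_sites <- r$sites; occupied <- r$occupied
    plant(sva_sites, sva_seqs)
    sva_gr <- GenomicRanges::GRanges(
      sva_sites$chrom, IRanges::IRanges(sva_sites$start, sva_sites$end),
      strand = sva_strand, name = sva_sub, score = 0)
    sva_gr$subfamily <- sva_sub
    sva_gr$hexamer_n <- sva_nhex

    # germline numts: exact mtDNA substrings (may span origin)
    numt_len <- if (spec$n_germline_numt > 0)
      sample(100:600, spec$n_germline_numt, replace = TRUE) else integer(0)
    numt_mt_start0 <- if (spec$n_germline_numt > 0)
      sample.int(spec$mt_length, spec$n_germline_numt) - 1L else integer(0)
    doubled <- paste0(mt_seq, mt_seq)
    numt_seqs <- vapply(seq_len(spec$n_germline_numt), function(i)
      substring(doubled, numt_mt_start0[i] + 1L,
                numt_mt_start0[i] + numt_len[i]), character(1))
    r <- sample_sites(spec$n_germline_numt, numt_len, chrom_lens, occupied)
    numt_sites <- r$sites; occupied <- r$occupied
    plant(numt_sites, numt_seqs)
    numt_gr <- GenomicRanges::GRanges(
      numt_sites$chrom, IRanges::IRanges(numt_sites$start, numt_sites$end),
      name = paste0("germline_numt_", seq_len(spec$n_germline_numt)),
      score = 0)
    numt_gr$mt_start0 <- numt_mt_start0
    numt_gr$mt_len <- numt_len

    # repeats: Alu-like SINEs keep exact 25 nt primer ends, body diverges
    rep_rows <- list()
    plant_repeats <- function(class, n, maker) {
      if (n == 0) return(invisible())
      seqs <- vapply(seq_len(n), function(i) maker(), character(1))
      r <- sample_sites(n, nchar(seqs), chrom_lens, occupied)
      occupied <<- r$occupied
      st <- sample(c("+", "-"), n, replace = TRUE)
      seqs_pl <- ifelse(st == "-", revcomp(seqs), seqs)
      plant(r$sites, seqs_pl)
      rep_rows[[class]] <<- GenomicRanges::GRanges(
        r$sites$chrom, IRanges::IRanges(r$sites$start, r$sites$end),
        strand = st, name = class, score = 0, class = class)
      invisible()
    }
    alu_maker <- function() {
      s <- cons$SINE
      head_ <- substring(s, 1, 25)
      tail_ <- substring(s, nchar(s) - 24, nchar(s))
      body <- mutate_dna(substring(s, 26, nchar(s) - 25), 0.02)
      paste0(head_, body, tail_)
    }
    plant_repeats("SINE", spec$n_alu, alu_maker)
    plant_repeats("LINE", spec$n_line,
                  function() mutate_dna(cons$LINE, 0.03))
    plant_repeats("LTR", spec$n_ltr, function() mutate_dna(cons$LTR, 0.03))
    plant_repeats("Satellite", spec$n_satellite,
                  function() cons$Satellite)
    repeats_gr <- if (length(rep_rows))
      sort_gr(do.call(c_gr, unname(rep_rows))) else
        GenomicRanges::GRanges(name = character(0), score = numeric(0),
                               class = character(0))

    # gene models (annotation only): promoter/exons/introns/3UTR/TTS.
    # Genes may overlap planted repeats (annotation layers are
    # independent), so they keep their own non-overlap tracker.
    gene_rows <- list()
    if (spec$n_genes > 0) {
      glen <- sample(1500:3000, spec$n_genes, replace = TRUE)
      occupied_genes <- stats::setNames(
        rep(list(IRanges::IRanges()), spec$n_chroms), names(chrom_lens))
      r <- sample_sites(spec$n_genes, glen + 2200L, chrom_lens,
                        occupied_genes, margin = 50L)
      for (i in seq_len(spec$n_genes)) {
        tss <- r$sites$start[i] + 1100L
        gend <- tss + glen[i] - 1L
        gid <- paste0("gene", i)
        ex_n <- 3L
        ex_b <- round(seq(tss, gend - 300L, length.out = 2 * ex_n + 1))
        feats <- data.frame(
          feature = c("promoter",
                      rep(c("exon", "intron"), ex_n)[-(2 * ex_n)],
                      "3UTR", "TTS"),
          start = c(tss - 1000L, ex_b[seq_len(2 * ex_n - 1)],
                    gend - 299L, gend - 99L),
          end = c(tss + 100L, ex_b[seq_len(2 * ex_n - 1) + 1L] - 1L,
                  gend, gend + 1000L))
        gene_rows[[gid]] <- GenomicRanges::GRanges(
          r$sites$chrom[i], IRanges::IRanges(feats$start, feats$end),
          strand = "+", name = paste0(gid, ":", feats$feature), score = 0,
          feature = feats$feature, gene_id = gid)
      }
    }
    genes_gr <- if (length(gene_rows)) sort_gr(do.call(c_gr, unname(gene_rows)))
      else GenomicRanges::GRanges(name = character(0), score = numeric(0),
                                  feature = character(0),
                                  gene_id = character(0))

    nuclear <- Biostrings::DNAStringSet(unlist(chroms))
    names(nuclear) <- names(chrom_lens)
    list(nuclear = nuclear, mt = mt,
         mt_genes = build_mt_gene_map(spec$mt_length, mt$id),
         sva = sva_gr, numt = numt_gr, repeats = repeats_gr,
         genes = genes_gr, spec = spec)
  })
}

#' Write toy-genome FASTA and annotation BED files
#'
#' @param tg result of [make_toy_genome()].
#' @param outdir output directory (created if absent).
#' @return invisibly, the directory.
#' @export
write_toy_genome <- function(tg, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(tg$nuclear, file.path(outdir, "nuclear.fa"))
  mt_set <- Biostrings::DNAStringSet(tg$mt$sequence)
  names(mt_set) <- tg$mt$id
  write_fasta(mt_set, file.path(outdir, "mt.fa"))
  write_bed(tg$sva, file.path(outdir, "sva.bed"))
  write_bed(tg$numt, file.path(outdir, "numt.bed"))
  rep_gr <- tg$repeats
  rep_gr$name <- paste0(rep_gr$class, "_", seq_along(rep_gr))
  write_bed(rep_gr, file.path(outdir, "repeats.bed"))
  write_bed(tg$genes, file.path(outdir, "genes.bed"))
  write_bed(tg$mt_genes, file.path(outdir, "mt_genes.bed"))
  invisible(outdir)
}

default_event_params <- function() {
  list(mt_len_range = c(40L, 400L), microhomology_range = c(0L, 5L),
       tsd_range = c(4L, 20L), trunc_range = c(0L, 50L),
       hexamer_range = c(30L, 50L), repeat_target_bias = 0)
}

#' Plant de novo SVA and numt events into a senescent copy of the genome
#'
#' The proliferating genome (from [make_toy_genome()]) is the reference;
#' events are inserted only into the returned senescent genome. Each numt
#' is an exact mtDNA substring (length from `params$mt_len_range`, may span
#' the origin) inserted at a site whose left-adjacent reference bases match
#' the segment's first `microhomology_len` bases (sampled from
#' `params$microhomology_range`), so the junction carries genuine
#' microhomology without modifying either sequence. Each SVA is a
#' (CCCTCT)n hexamer run (n from `params$hexamer_range`) plus a possibly
#' 5'-truncated subfamily consensus, inserted with a target site
#' duplication (`params$tsd_range`). `params$repeat_target_bias` is the
#' probability that an SVA insertion lands inside an annotated repeat.
#' Insertion points keep >= 150 nt clearance from annotated features so
#' that planted events are not removed by the callers' annotation filters
#' by construction.
#'
#' @param tg result of [make_toy_genome()].
#' @param n_sva,n_numt numbers of de novo events.
#' @param params list overriding [default_event_params()] entries.
#' @param seed integer RNG seed.
#' @return list with `senescent` (DNAStringSet), `truth` (data.frame, one
#'   row per event), `ref_to_sen` (vectorized coordinate lift function) and
#'   the input `tg`.
#' @export
plant_de_novo_events <- function(tg, n_sva = 0L, n_numt = 0L,
                                 params = list(), seed = 1L) {
  p <- utils::modifyList(default_event_params(), params)
  cons <- element_consensus()
  mt_seq <- as.character(tg$mt$sequence)
  doubled <- paste0(mt_seq, mt_seq)
  L <- tg$mt$length
  chrom_chr <- stats::setNames(as.character(tg$nuclear), names(tg$nuclear))
  chrom_lens <- nchar(chrom_chr)
  occupied <- lapply(stats::setNames(names(chrom_chr), names(chrom_chr)),
                     function(ch) {
    feats <- suppressWarnings(c(GenomicRanges::granges(tg$sva),
                                GenomicRanges::granges(tg$numt),
                                GenomicRanges::granges(tg$repeats)))
    f <- feats[GenomicRanges::seqnames(feats) == ch]
    IRanges::ranges(f)
  })

  events <- list()
  with_seed(seed, {
    sample_range <- function(rg) if (rg[1] == rg[2]) rg[1] else
      sample(seq(rg[1], rg[2]), 1)

    free_site <- function(w = 1L, inside_repeat = FALSE) {
      for (try in seq_len(5000L)) {
        if (inside_repeat && length(tg$repeats) > 0) {
          ri <- sample.int(length(tg$repeats), 1)
          ch <- as.character(GenomicRanges::seqnames(tg$repeats)[ri])
          pos <- sample(seq(GenomicRanges::start(tg$repeats)[ri] + 10L,
                            GenomicRanges::end(tg$repeats)[ri] - 10L), 1)
          occupied[[ch]] <<- c(occupied[[ch]],
                               IRanges::IRanges(pos, pos + w))
          return(list(chrom = ch, pos = pos))
        }
        ch <- sample(names(chrom_lens), 1, prob = chrom_lens)
        pos <- sample(seq(200L, chrom_lens[[ch]] - 200L), 1)
        cand <- IRanges::IRanges(pos - 150L, pos + w + 150L)
        if (!any(IRanges::overlapsAny(cand, occupied[[ch]]))) {
          occupied[[ch]] <<- c(occupied[[ch]], IRanges::IRanges(pos, pos + w))
          return(list(chrom = ch, pos = pos))
        }
      }
      stop("cannot place de novo event: genome too crowded")
    }

    for (i in seq_len(n_sva)) {
      sub <- sample(names(cons$SVA), 1)
      nhex <- sample_range(p$hexamer_range)
      trunc <- sample_range(p$trunc_range)
      tsd <- sample_range(p$tsd_range)
      body <- substring(cons$SVA[[sub]], trunc + 1L)
      sva_seq <- paste0(strrep("CCCTCT", nhex), body)
      inside <- stats::runif(1) < p$repeat_target_bias
      site <- free_site(w = tsd, inside_repeat = inside)
      ch <- site$chrom; pos <- site$pos
      tsd_seq <- substring(chrom_chr[[ch]], pos, pos + tsd - 1L)
      events[[length(events) + 1L]] <- list(
        kind = "de_novo_sva", chrom = ch,
        ins_at = pos + tsd, ins_seq = paste0(sva_seq, tsd_seq),
        subfamily = sub, hexamer_n = nhex, truncation_5p = trunc,
        tsd_len = tsd, mt_start0 = NA_integer_, mt_len = NA_integer_,
        microhomology_len = NA_integer_)
    }

    for (i in seq_len(n_numt)) {
      h <- sample_range(p$microhomology_range)
      mt_len <- sample_range(p$mt_len_range)
      placed <- FALSE
      for (try in seq_len(500L)) {
        mt_start0 <- sample.int(L, 1) - 1L
        seg <- substring(doubled, mt_start0 + 1L, mt_start0 + mt_len)
        if (h == 0L) {
          site <- free_site(); ch <- site$chrom; pos <- site$pos
          placed <- TRUE
        } else {
          pre <- substring(seg, 1L, h)
          # sites whose h left-adjacent bases equal the segment prefix
          ok <- FALSE
          for (ch_try in sample(names(chrom_lens))) {
            hp <- Biostrings::start(Biostrings::matchPattern(
              pre, Biostrings::DNAString(chrom_chr[[ch_try]])))
            hp <- hp + h  # insertion point just after the matched prefix
            hp <- hp[hp > 200L & hp < chrom_lens[[ch_try]] - 200L]
            hp <- sample(hp)
            for (pp in hp) {
              cand <- IRanges::IRanges(pp - 150L, pp + 150L)
              if (!any(IRanges::overlapsAny(cand, occupied[[ch_try]]))) {
                occupied[[ch_try]] <- c(occupied[[ch_try]],
                                        IRanges::IRanges(pp, pp + 1L))
                ch <- ch_try; pos <- pp; ok <- TRUE
                break
              }
            }
            if (ok) break
          }
          if (!ok) next
          placed <- TRUE
        }
        if (placed) {
          events[[length(events) + 1L]] <- list(
            kind = "de_novo_numt", chrom = ch, ins_at = pos, ins_seq = seg,
            subfamily = NA_character_, hexamer_n = NA_integer_,
            truncation_5p = NA_integer_, tsd_len = NA_integer_,
            mt_start0 = mt_start0, mt_len = mt_len, microhomology_len = h)
          break
        }
      }
      if (!placed) stop("cannot place de novo numt with microhomology ", h)
    }
  })

  truth <- if (length(events))
    do.call(rbind, lapply(events, as.data.frame,
                          stringsAsFactors = FALSE)) else
    data.frame(kind = character(0), chrom = character(0),
               ins_at = integer(0), ins_seq = character(0),
               subfamily = character(0), hexamer_n = integer(0),
               truncation_5p = integer(0), tsd_len = integer(0),
               mt_start0 = integer(0), mt_len = integer(0),
               microhomology_len = integer(0))
  truth <- truth[order(truth$chrom, truth$ins_at), , drop = FALSE]
  rownames(truth) <- NULL
  truth$event_id <- sprintf("ev%03d", seq_len(nrow(truth)))

  # build senescent chromosomes and senescent coordinates of inserts
  sen <- chrom_chr
  truth$sen_start <- rep(NA_integer_, nrow(truth))
  truth$sen_end <- rep(NA_integer_, nrow(truth))
  for (ch in names(chrom_chr)) {
    idx <- which(truth$chrom == ch)
    if (length(idx) == 0) next
    pieces <- character(0)
    prev <- 1L; offset <- 0L
    for (i in idx) {
      at <- truth$ins_at[i]
      pieces <- c(pieces, substring(chrom_chr[[ch]], prev, at - 1L),
                  truth$ins_seq[i])
      truth$sen_start[i] <- at + offset
      truth$sen_end[i] <- at + offset + nchar(truth$ins_seq[i]) - 1L
      offset <- offset + nchar(truth$ins_seq[i])
      prev <- at
    }
    pieces <- c(pieces, substring(chrom_chr[[ch]], prev))
    sen[[ch]] <- paste(pieces, collapse = "")
  }

  ref_to_sen <- function(chrom, pos) {
    mapply(function(ch, pp) {
      idx <- truth$chrom == ch & truth$ins_at <= pp
      pp + sum(nchar(truth$ins_seq[idx]))
    }, chrom, pos, USE.NAMES = FALSE)
  }

  senescent <- Biostrings::DNAStringSet(sen)
  names(senescent) <- names(chrom_chr)
  list(senescent = senescent, truth = truth, ref_to_sen = ref_to_sen,
       genome = tg)
}

#' Serialize / read a truth table as tagged BED
#'
#' One BED line per planted event at its reference insertion point, with
#' event parameters as `key=value` tags in the name field (the inserted
#' sequence itself is not serialized).
#'
#' @param truth truth data.frame from [plant_de_novo_events()].
#' @param path file path.
#' @export
write_truth <- function(truth, path) {
  tagcols <- c("kind", "event_id", "subfamily", "hexamer_n",
               "truncation_5p", "tsd_len", "mt_start0", "mt_len",
               "microhomology_len", "sen_start", "sen_end")
  tags <- vapply(seq_len(nrow(truth)), function(i) {
    kv <- vapply(tagcols, function(cc) paste0(cc, "=", truth[[cc]][i]),
                 character(1))
    paste(kv[!grepl("=NA$", kv)], collapse = ";")
  }, character(1))
  lines <- paste(truth$chrom, truth$ins_at - 1L, truth$ins_at, tags, 0, "+",
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  gr <- read_bed(path)
  tags <- strsplit(gr$name, ";", fixed = TRUE)
  parse_tag <- function(tag, key) {
    hit <- grep(paste0("^", key, "="), tag, value = TRUE)
    if (length(hit)) sub("^[^=]+=", "", hit[1]) else NA_character_
  }
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    ins_at = GenomicRanges::end(gr),
    kind = vapply(tags, parse_tag, character(1), key = "kind"),
    event_id = vapply(tags, parse_tag, character(1), key = "event_id"),
    stringsAsFactors = FALSE)
  for (cc in c("hexamer_n", "truncation_5p", "tsd_len", "mt_start0",
               "mt_len", "microhomology_len", "sen_start", "sen_end"))
    df[[cc]] <- as.integer(vapply(tags, parse_tag, character(1), key = cc))
  df$subfamily <- vapply(tags, parse_tag, character(1), key = "subfamily")
  df
}
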