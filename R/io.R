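# Standard-format I/O: FASTA/FASTQ through Biostrings, BED6 and PSL
# through thin validating parsers. BED is read and written 0-based
# half-open; internally intervals live in GRanges (1-based closed).

#' Circular genome container
#'
#' A single circular sequence (mitochondrial DNA here). Alignment against a
#' circular genome is performed on a doubled linearization; reported target
#' start positions are reduced modulo the genome length, so an interval may
#' end past the origin (end > length) when it spans it.
#'
#' @param sequence a `DNAString`, character scalar, or single-sequence
#'   `DNAStringSet`.
#' @param id sequence identifier.
#' @return an object of class `circular_genome` with fields `id`,
#'   `sequence` (`DNAString`) and `length`.
#' @export
circular_genome <- function(sequence, id = "MT") {
  if (inherits(sequence, "DNAStringSet")) {
    stopifnot(length(sequence) == 1L)
    if (!is.null(names(sequence))) id <- names(sequence)[1]
    sequence <- sequence[[1]]
  }
  if (is.character(sequence)) sequence <- Biostrings::DNAString(sequence)
  structure(list(id = id, sequence = sequence,
                 length = length(sequence)),
            class = "circular_genome")
}

#' @export
print.circular_genome <- function(x, ...) {
  cat("circular_genome '", x$id, "' of length ", x$length, " nt\n", sep = "")
  invisible(x)
}

#' Read FASTA / FASTQ files
#'
#' @param path file path.
#' @return a named `DNAStringSet`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- tryCatch(Biostrings::readDNAStringSet(path, format = "fasta"),
                error = function(e) stop("malformed FASTA '", path, "': ",
                                         conditionMessage(e)))
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

#' @rdname read_fasta
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- tryCatch(Biostrings::readDNAStringSet(path, format = "fastq"),
                error = function(e) stop("malformed FASTQ '", path, "': ",
                                         conditionMessage(e)))
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

#' Write sequences as FASTA or FASTQ
#'
#' FASTQ is written phred+33 with a constant quality (the simulators are
#' error-free by default, so per-base qualities carry no information).
#'
#' @param seqs a `DNAStringSet` (named).
#' @param path output file.
#' @param quality_char quality character applied to every base.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(as_dna_set(seqs), path, format = "fasta")
  invisible(path)
}

#' @rdname write_fasta
#' @export
write_fastq <- function(seqs, path, quality_char = "I") {
  seqs <- as_dna_set(seqs)
  qual <- Biostrings::BStringSet(vapply(Biostrings::width(seqs), function(w)
    strrep(quality_char, w), character(1)))
  Biostrings::writeXStringSet(seqs, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Read a BED file into a GRanges
#'
#' Accepts BED3 to BED6, tab-separated, 0-based half-open. Extra key=value
#' tags in the name column are preserved verbatim. Malformed lines raise an
#' error naming the file, line number and offending field.
#'
#' @param path file path.
#' @return a `GRanges` with `name` and `score` metadata columns.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  idx <- which(keep)
  if (length(idx) == 0L) return(GenomicRanges::GRanges(name = character(0),
                                                       score = numeric(0)))
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  n <- lengths(fields)
  if (any(n < 3L)) {
    bad <- idx[which(n < 3L)[1]]
    stop("malformed BED '", path, "' line ", bad,
         ": fewer than 3 tab-separated fields")
  }
  get_col <- function(i, default = NA_character_) {
    vapply(fields, function(f) if (length(f) >= i) f[i] else default,
           character(1))
  }
  chrom <- get_col(1)
  start <- suppressWarnings(as.integer(get_col(2)))
  end <- suppressWarnings(as.integer(get_col(3)))
  for (fld in list(list("start", start), list("end", end))) {
    if (anyNA(fld[[2]])) {
      bad <- idx[which(is.na(fld[[2]]))[1]]
      stop("malformed BED '", path, "' line ", bad,
           ": non-integer field '", fld[[1]], "'")
    }
  }
  if (any(start < 0 | end <= start)) {
    bad <- idx[which(start < 0 | end <= start)[1]]
    stop("malformed BED '", path, "' line ", bad,
         ": field 'start'/'end' violates 0 <= start < end")
  }
  nm <- get_col(4); nm[is.na(nm)] <- "."
  sc <- suppressWarnings(as.numeric(get_col(5))); sc[is.na(sc)] <- 0
  st <- get_col(6); st[is.na(st) | !st %in% c("+", "-")] <- "*"
  GenomicRanges::GRanges(chrom,
                         IRanges::IRanges(start + 1L, end),
                         strand = st, name = nm, score = sc)
}

#' Write a GRanges as BED6 (0-based half-open, tab-separated)
#'
#' @param gr a `GRanges`; `name`/`score` metadata columns are used when
#'   present.
#' @param path output file.
#' @export
write_bed <- function(gr, path) {
  nm <- if (!is.null(gr$name)) as.character(gr$name) else
    if (!is.null(names(gr))) names(gr) else rep(".", length(gr))
  nm[is.na(nm) | !nzchar(nm)] <- "."
  sc <- if (!is.null(gr$score)) gr$score else rep(0, length(gr))
  st <- as.character(GenomicRanges::strand(gr))
  st[st == "*"] <- "."
  lines <- paste(as.character(GenomicRanges::seqnames(gr)),
                 GenomicRanges::start(gr) - 1L,
                 GenomicRanges::end(gr),
                 nm, sc, st, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

psl_columns <- c("matches", "misMatches", "repMatches", "nCount",
                 "qNumInsert", "qBaseInsert", "tNumInsert", "tBaseInsert",
                 "strand", "qName", "qSize", "qStart", "qEnd",
                 "tName", "tSize", "tStart", "tEnd",
                 "blockCount", "blockSizes", "qStarts", "tStarts")

#' Read / write PSL alignment files
#'
#' The 21-column PSL dialect (headerless, or with the standard `psLayout`
#' header which is skipped). All coordinate fields follow the PSL 0-based
#' convention. Returns a data.frame with one row per alignment.
#'
#' @param path file path.
#' @return `read_psl`: a data.frame with the 21 PSL columns.
#' @export
read_psl <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- nzchar(lines) &
    !grepl("^(psLayout|match\\b|\\s|-)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) return(empty_psl())
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  n <- lengths(fields)
  if (any(n != 21L)) {
    bad <- idx[which(n != 21L)[1]]
    stop("malformed PSL '", path, "' line ", bad, ": expected 21 fields, got ",
         n[which(n != 21L)[1]])
  }
  m <- do.call(rbind, fields)
  df <- as.data.frame(m, stringsAsFactors = FALSE)
  names(df) <- psl_columns
  int_cols <- setdiff(psl_columns,
                      c("strand", "qName", "tName",
                        "blockSizes", "qStarts", "tStarts"))
  for (cc in int_cols) {
    v <- suppressWarnings(as.integer(df[[cc]]))
    if (anyNA(v)) {
      bad <- idx[which(is.na(v))[1]]
      stop("malformed PSL '", path, "' line ", bad,
           ": non-integer field '", cc, "'")
    }
    df[[cc]] <- v
  }
  validate_psl(df, context = path, lines = idx)
  df
}

#' @rdname read_psl
#' @param psl a PSL data.frame as returned by the aligners or `read_psl`.
#' @export
write_psl <- function(psl, path) {
  stopifnot(is.data.frame(psl), identical(names(psl), psl_columns))
  lines <- do.call(paste, c(unname(as.list(psl)), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

empty_psl <- function() {
  df <- as.data.frame(matrix(nrow = 0, ncol = 21))
  names(df) <- psl_columns
  for (cc in setdiff(psl_columns, c("strand", "qName", "tName",
                                    "blockSizes", "qStarts", "tStarts")))
    df[[cc]] <- integer(0)
  for (cc in c("strand", "qName", "tName", "blockSizes", "qStarts",
               "tStarts"))
    df[[cc]] <- character(0)
  df
}
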