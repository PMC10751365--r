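# Small shared helpers: reproducible RNG scoping, random sequence
# generation, and string/sequence conversions used across modules.

#' Evaluate code under a fixed RNG seed without disturbing the caller's RNG
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Random DNA string with a given GC fraction
#'
#' @param n length in nucleotides.
#' @param gc target GC fraction in [0, 1].
#' @return a character scalar over {A,C,G,T}.
#' @keywords internal
random_dna <- function(n, gc = 0.41) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Reverse complement of character DNA
#' @param x character vector of DNA strings.
#' @return character vector.
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Coerce common sequence inputs to a named DNAStringSet.
as_dna_set <- function(x) {
  if (inherits(x, "DNAStringSet")) return(x)
  if (inherits(x, "DNAString")) return(Biostrings::DNAStringSet(x))
  if (inherits(x, "circular_genome")) {
    s <- Biostrings::DNAStringSet(x$sequence)
    names(s) <- x$id
    return(s)
  }
  if (is.character(x)) {
    s <- Biostrings::DNAStringSet(x)
    if (is.null(names(s))) names(s) <- paste0("seq", seq_along(s))
    return(s)
  }
  stop("cannot interpret object of class '", class(x)[1], "' as sequences")
}

# Substitute random bases at a given per-base rate; used to model
# sequencing error and repeat-copy divergence.
mutate_dna <- function(x, rate) {
  if (rate <= 0) return(x)
  ch <- strsplit(x, "")[[1]]
  hit <- which(stats::runif(length(ch)) < rate)
  for (i in hit) {
    ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  }
  paste(ch, collapse = "")
}
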