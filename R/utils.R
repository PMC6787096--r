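#' Reverse-complement DNA strings
#'
#' Vectorised reverse complement over plain character vectors.
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Generate random DNA sequences
#'
#' @param n number of sequences.
#' @param width sequence length in nt.
#' @return character vector of `n` sequences of length `width`.
#' @export
random_dna <- function(n, width) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(c("A", "C", "G", "T"), n * width, replace = TRUE),
              nrow = n)
  apply(m, 1L, paste0, collapse = "")
}

## stop unless every character is A/C/G/T
assert_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    stop(sprintf("%s contains non-ACGT characters: %s", what,
                 paste(utils::head(x[bad], 3L), collapse = ", ")),
         call. = FALSE)
  }
  invisible(TRUE)
}

assert_scalar_number <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("%s must be a single number", what), call. = FALSE)
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
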