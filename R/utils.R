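#' @useDynLib flcdnakit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm rbinom runif rnbinom rgamma rgeom dnbinom
#'   uniroot median setNames
#' @importFrom utils write.table read.table head combn
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' @param seq character scalar over A/C/G/T/N.
#' @return The reverse complement, same alphabet.
#' @export
revcomp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Translate a coding sequence
#'
#' Translates complete codons of `cds` with the standard genetic code;
#' stops are rendered as `*`. Trailing partial codons are dropped.
#'
#' @param cds DNA string, length >= 3.
#' @return Amino-acid string.
#' @export
translate_cds <- function(cds) {
  n <- nchar(cds) - nchar(cds) %% 3L
  codons <- substring(cds, seq(1L, n - 2L, by = 3L), seq(3L, n, by = 3L))
  paste(unname(GENETIC_CODE_TABLE[codons]), collapse = "")
}

GENETIC_CODE_TABLE <- local({
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
})

STOP_CODONS <- c("TAA", "TAG", "TGA")

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Round half up
#'
#' Commercial ("half-up") rounding, the convention used in printed summary
#' tables; base [round()] rounds half to even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded to `digits` decimals, ties rounded upward.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

# split a string into characters
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
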