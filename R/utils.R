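#' @import data.table
#' @importFrom stats quantile optimize pchisq pt pnorm qnorm pgamma qgamma
#'   dnbinom pbinom dbinom rnbinom setNames runif
#' @importFrom utils write.table read.table head
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1L)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over plain character vectors. `N` maps to `N`.
#'
#' @param x character vector of sequences over A/C/G/T/N.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

check_dna <- function(x, what = "sequence", allow_n = TRUE) {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  bad <- !grepl(pat, x)
  if (any(bad)) {
    stop(sprintf("%s contains non-%s symbols (first offender: '%s')",
                 what, if (allow_n) "ACGTN" else "ACGT",
                 x[which(bad)[1L]]), call. = FALSE)
  }
  invisible(x)
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x >= 0 && x == floor(x)
}

stopifnot_named <- function(x, what) {
  if (is.null(names(x)) || any(!nzchar(names(x))) || anyDuplicated(names(x)))
    stop(sprintf("%s must have unique non-empty names", what), call. = FALSE)
  invisible(x)
}
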