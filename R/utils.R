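# Small shared helpers: seeded RNG scoping, sequence utilities.

#' Evaluate an expression under a local RNG seed
#'
#' All stochastic operations in the package funnel their randomness
#' through this helper so that a single integer seed determines every
#' simulated object, and callers' RNG state is left untouched.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Reverse complement of a nucleotide string
#' @param x character scalar (A/C/G/T/N).
#' @return character scalar.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Random nucleotide string
#' @keywords internal
random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substring by 0-based half-open interval
substr0 <- function(x, begin, end) substr(x, begin + 1L, end)

#' Sequence identity between two strings (edit-distance based)
#'
#' 1 - d / max(nchar), with d the Levenshtein distance.
#' @param a,b character scalars.
#' @return numeric in [0, 1].
#' @export
seq_identity <- function(a, b) {
  if (nchar(a) == 0 && nchar(b) == 0) return(1)
  1 - cpp_edit_distance(a, b) / max(nchar(a), nchar(b))
}

# draw a read length from a log-normal fitted so that the 1st percentile
# sits at `min_len`; hard truncation at min_len
draw_read_lengths <- function(n, mean_len, min_len) {
  if (min_len >= mean_len) return(rep(as.integer(mean_len), n))
  # place the 1st percentile at min_len: meanlog - z*sdlog = log(min) with
  # meanlog = log(mean) - sdlog^2/2, i.e. sdlog^2/2 + z*sdlog - r = 0
  z <- 2.326
  r <- log(mean_len / min_len)
  sdlog <- max(0.05, -z + sqrt(z^2 + 2 * r))
  meanlog <- log(mean_len) - sdlog^2 / 2
  len <- rlnorm(n, meanlog, sdlog)
  len[len < min_len] <- min_len
  as.integer(round(len))
}
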