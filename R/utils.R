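#' @useDynLib bgcmine, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats as.dist cutree hclust runif setNames
#' @importFrom utils read.delim write.table head combn modifyList
NULL

# Run `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards; generators therefore never leak global state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Deterministic child seeds below 2^31, derived from one parent seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Round half away from zero
#'
#' Decimal rounding in which ties go up (2.5 -> 3, 26.825 -> 26.83) rather
#' than to even as in [base::round()]. Used for printed percentages.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

assert_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a fraction in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, ...)
}
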