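#' @useDynLib dwtmotif, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats uniroot optimize rnorm runif rmultinom setNames
#' @importFrom stats coef logLik rgamma simulate predict
#' @importFrom graphics image plot
#' @importFrom utils head tail write.table read.table
NULL

DNA_LETTERS <- c("A", "C", "G", "T")

#' Numerically stable log-sum-exp
#'
#' @param x numeric vector of log-space values.
#' @return `log(sum(exp(x)))` computed without overflow.
#' @keywords internal
logsumexp <- function(x) {
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Encode A,C,G,T,N -> 0,1,2,3,4 (0-based for the C++ kernels).
encode_seq <- function(s) {
  x <- chartr("acgtn", "ACGTN", s)
  v <- match(strsplit(x, "", fixed = TRUE)[[1]], c(DNA_LETTERS, "N")) - 1L
  if (anyNA(v)) {
    bad <- which(is.na(v))[1]
    stop("invalid sequence character '", substr(x, bad, bad),
         "' at position ", bad, " (only A,C,G,T,N allowed)")
  }
  v
}

decode_seq <- function(v) {
  paste(c(DNA_LETTERS, "N")[v + 1L], collapse = "")
}

# Reverse complement of an encoded sequence; N (4) maps to N.
revcomp_enc <- function(v) {
  comp <- c(3L, 2L, 1L, 0L, 4L)
  rev(comp[v + 1L])
}

#' Reverse complement of a DNA string (A,C,G,T,N)
#' @param s character string.
#' @return reverse-complemented string.
#' @keywords internal
revcomp <- function(s) decode_seq(revcomp_enc(encode_seq(s)))

# Evaluate `code` under a temporary RNG state seeded with `seed`; the
# caller's RNG state is restored afterwards. A NULL seed runs as-is.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
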