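#' Dirichlet prior specification for motif counts
#'
#' The motif models place a symmetric Dirichlet prior with pseudocount
#' `lambda` per letter on each single-position distribution, and a symmetric
#' Dirichlet with pseudocount `lambda/4` per dinucleotide on each
#' position-pair distribution. The 1:4 ratio is forced: it is the unique
#' choice under which the dinucleotide prior marginalizes to the
#' mononucleotide prior, so that pair and column marginal likelihoods are
#' mutually consistent. The default `lambda = 1/2` is Jeffreys' prior;
#' results are insensitive for `0 < lambda <= 1`.
#'
#' @param lambda positive pseudocount per letter, in `(0, 1]`.
#' @return object of class `dwt_prior` with fields `lambda` and `lambda_di`.
#' @export
#' @examples
#' dwt_prior()       # Jeffreys, lambda = 1/2
#' dwt_prior(1)$lambda_di  # 0.25
dwt_prior <- function(lambda = 0.5) {
  if (!is.numeric(lambda) || length(lambda) != 1L || !is.finite(lambda) ||
      lambda <= 0 || lambda > 1)
    stop("lambda must be a single number in (0, 1]")
  structure(list(lambda = lambda, lambda_di = lambda / 4),
            class = "dwt_prior")
}

as_prior <- function(prior) {
  if (inherits(prior, "dwt_prior")) prior else dwt_prior(prior)
}

#' Marginal log-probability of one alignment column
#'
#' Log of the Dirichlet-multinomial marginal likelihood of the letter counts
#' observed in a single motif column: the integral over the unknown column
#' distribution w under a symmetric Dirichlet(lambda) prior,
#' \deqn{P(S_i) = \frac{\Gamma(4\lambda)}{\Gamma(n+4\lambda)}
#'   \prod_\alpha \frac{\Gamma(n_\alpha+\lambda)}{\Gamma(\lambda)}.}
#' Counts may be fractional (EM produces soft counts); everything is
#' evaluated through `lgamma`, never through `gamma` itself.
#'
#' @param counts numeric vector of 4 non-negative letter counts (A,C,G,T).
#' @param prior a [dwt_prior()] or a bare lambda value.
#' @return the natural-log marginal probability.
#' @export
#' @examples
#' column_log_prob(c(1, 0, 0, 0))          # log(1/4)
#' column_log_prob(c(2, 0, 0, 0))          # log(1/8)
column_log_prob <- function(counts, prior = dwt_prior()) {
  prior <- as_prior(prior)
  if (length(counts) != 4L || any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be 4 finite non-negative numbers")
  la <- prior$lambda
  n <- sum(counts)
  lgamma(4 * la) - lgamma(n + 4 * la) + sum(lgamma(counts + la)) - 4 * lgamma(la)
}

#' Marginal log-probability of a pair of alignment columns
#'
#' Dirichlet-multinomial marginal likelihood of the 4x4 table of joint
#' dinucleotide counts at a pair of positions, under a symmetric
#' Dirichlet(lambda/4) prior over the 16 dinucleotide probabilities.
#'
#' @param counts 4x4 numeric matrix of non-negative pair counts; rows index
#'   the letter at the first position, columns the letter at the second.
#' @inheritParams column_log_prob
#' @return the natural-log marginal probability.
#' @export
pair_log_prob <- function(counts, prior = dwt_prior()) {
  prior <- as_prior(prior)
  if (length(counts) != 16L || any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be a 4x4 table of finite non-negative numbers")
  ld <- prior$lambda_di
  n <- sum(counts)
  lgamma(16 * ld) - lgamma(n + 16 * ld) +
    sum(lgamma(counts + ld)) - 16 * lgamma(ld)
}

#' Evidence ratio for dependency between two motif positions
#'
#' The log Bayes factor comparing a joint (dependent) model of two columns
#' to the independent product of the column marginals:
#' `log R_ij = log P(S_i, S_j) - log P(S_i) - log P(S_j)`.
#' For large n, `R_ij` is approximately `exp(n I_ij)` with `I_ij` the
#' empirical mutual information of the two columns. A single observation
#' carries no dependency evidence (`log R = 0` at n = 1).
#'
#' @param pair_counts 4x4 matrix of joint counts for the position pair.
#' @inheritParams column_log_prob
#' @return the natural-log evidence ratio (symmetric in the two positions).
#' @export
dependency_log_ratio <- function(pair_counts, prior = dwt_prior()) {
  prior <- as_prior(prior)
  pair_counts <- matrix(pair_counts, 4, 4)
  pair_log_prob(pair_counts, prior) -
    column_log_prob(rowSums(pair_counts), prior) -
    column_log_prob(colSums(pair_counts), prior)
}

#' Empirical mutual information of a pair-count table
#'
#' Plug-in mutual information (natural log) of the joint letter frequencies
#' in a 4x4 count table. Used as a diagnostic: for large n the dependency
#' evidence satisfies `log R_ij ~ n * I_ij`.
#'
#' @param pair_counts 4x4 matrix of non-negative counts with `sum >= 2`.
#' @return mutual information in nats.
#' @export
mutual_information <- function(pair_counts) {
  pair_counts <- matrix(pair_counts, 4, 4)
  n <- sum(pair_counts)
  if (n < 2) stop("mutual information needs a total count of at least 2")
  p <- pair_counts / n
  pr <- rowSums(p)
  pc <- colSums(p)
  nz <- p > 0
  sum(p[nz] * (log(p[nz]) - log(outer(pr, pc))[nz]))
}

# ---- pair-count tensors -----------------------------------------------------

# A pair-count tensor is a 4 x 4 x l x l array T with T[a,b,i,j] the
# (possibly fractional) number of sites carrying letters (a,b) at positions
# (i,j), filled for all i != j with the symmetry T[a,b,i,j] == T[b,a,j,i].

empty_pair_tensor <- function(l) {
  array(0, dim = c(4, 4, l, l))
}

# Tensor of exact pair counts for a set of encoded sites (integer matrix,
# l rows x m columns, values 0..3) with per-site weights.
pair_tensor_from_sites <- function(sites, weights = NULL) {
  sites <- as.matrix(sites)
  l <- nrow(sites)
  m <- ncol(sites)
  if (is.null(weights)) weights <- rep(1, m)
  marg <- matrix(0, 4, l)
  tens <- cpp_accumulate_counts(empty_pair_tensor(l), sites, weights, marg)
  tens
}

# Column-count matrix (4 x l) implied by a pair tensor, averaging the
# (identical up to round-off) marginals over partner positions.
tensor_marginals <- function(tensor) {
  l <- dim(tensor)[3]
  if (l == 1L) stop("pair tensor needs l >= 2")
  marg <- matrix(0, 4, l)
  for (i in seq_len(l)) {
    js <- setdiff(seq_len(l), i)
    acc <- rowSums(sapply(js, function(j) rowSums(tensor[, , i, j])))
    marg[, i] <- acc / length(js)
  }
  marg
}

# Verify the structural invariants of a pair tensor: swap symmetry and
# marginal consistency across partner positions.
check_pair_tensor <- function(tensor, tol = 1e-6) {
  l <- dim(tensor)[3]
  n <- sum(tensor[, , 1, 2])
  scale <- max(1, n)
  for (i in seq_len(l)) for (j in seq_len(l)) {
    if (i == j) next
    if (max(abs(tensor[, , i, j] - t(tensor[, , j, i]))) > tol * scale)
      stop("pair tensor violates swap symmetry at positions (", i, ",", j, ")")
  }
  for (i in seq_len(l)) {
    ref <- NULL
    for (j in setdiff(seq_len(l), i)) {
      m <- rowSums(tensor[, , i, j])
      if (is.null(ref)) ref <- m
      else if (max(abs(m - ref)) > tol * scale)
        stop("pair tensor marginals for position ", i,
             " are inconsistent across partners (pair ", i, ",", j, ")")
    }
  }
  invisible(TRUE)
}

# log R matrix (l x l, zero diagonal) of a pair tensor.
dependency_matrix <- function(tensor, prior = dwt_prior()) {
  prior <- as_prior(prior)
  l <- dim(tensor)[3]
  colp <- vapply(seq_len(l), function(i) {
    js <- setdiff(seq_len(l), i)
    column_log_prob(rowSums(tensor[, , i, js[1]]), prior)
  }, numeric(1))
  logR <- matrix(0, l, l)
  for (i in seq_len(l - 1)) for (j in (i + 1):l) {
    v <- pair_log_prob(tensor[, , i, j], prior) - colp[i] - colp[j]
    logR[i, j] <- v
    logR[j, i] <- v
  }
  logR
}
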