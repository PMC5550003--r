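# Motif model objects. All three kinds share one internal layout so the
# same scoring kernels serve them:
#   counts  4 x l marginal letter counts (possibly fractional)
#   logw    4 x l predictive log-probabilities log[(n_a + lambda)/(n + 4 lambda)]
#   tensor  4 x 4 x l x l pair counts (DWT: all pairs; ADJ: adjacent only)
#   delta   per-pair augmentation log-ratios used by the scoring kernels
#   logR    dependency evidence matrix; log_D its spanning-tree sum (DWT)
# kind codes for the C++ kernels: 0 = PSWM, 1 = ADJ, 2 = DWT.

as_site_matrix <- function(sites) {
  if (is.matrix(sites)) {
    storage.mode(sites) <- "integer"
    return(sites)
  }
  enc <- lapply(sites, encode_seq)
  lens <- lengths(enc)
  if (length(unique(lens)) != 1L)
    stop("all sites must have the same length (got lengths ",
         paste(unique(lens), collapse = ","), ")")
  matrix(unlist(enc), nrow = lens[1])
}

# delta[a,b,i,j]: change in log R_ij when one site with letters (a,b) at
# (i,j) is added to the counts. Because 16*lambda_di = 4*lambda, the pair
# and column normalizers cancel to a single log(n + 4 lambda) term.
build_delta <- function(tensor, marg, n, lambda, adjacent_only = FALSE) {
  l <- ncol(marg)
  ld <- lambda / 4
  delta <- array(0, dim = c(4, 4, l, l))
  lc <- log(marg + lambda)   # 4 x l
  lnorm <- log(n + 4 * lambda)
  for (i in seq_len(l - 1)) {
    jmax <- if (adjacent_only) i + 1L else l
    for (j in (i + 1):jmax) {
      if (j > l) next
      d <- log(tensor[, , i, j] + ld) + lnorm -
        outer(lc[, i], lc[, j], `+`)
      delta[, , i, j] <- d
      delta[, , j, i] <- t(d)
    }
  }
  delta
}

new_motif_model <- function(kind, counts, tensor, lambda, name) {
  l <- ncol(counts)
  n <- sum(counts[, 1])
  if (l > 1 && max(abs(colSums(counts) - n)) > 1e-9 * max(1, n))
    stop("marginal counts must have the same total at every position")
  logw <- log(sweep(counts + lambda, 2, rep(n + 4 * lambda, l), `/`))
  obj <- list(kind = kind, l = l, n = n, lambda = lambda,
              counts = counts, logw = logw, tensor = tensor,
              name = name)
  if (kind == "dwt") {
    obj$logR <- dependency_matrix(tensor, lambda)
    obj$log_D <- if (l >= 2) tree_logdet(obj$logR)$log_D else 0
    obj$delta <- build_delta(tensor, counts, n, lambda)
  } else if (kind == "adj") {
    obj$logR <- matrix(0, l, l)
    obj$log_D <- 0
    obj$delta <- build_delta(tensor, counts, n, lambda, adjacent_only = TRUE)
  } else {
    obj$logR <- matrix(0, l, l)
    obj$log_D <- 0
    obj$delta <- array(0, dim = c(4, 4, l, l))
  }
  class(obj) <- c(paste0(kind, "_model"), "motif_model")
  obj
}

#' Position-specific weight matrix model
#'
#' A PSWM is specified by its 4 x l matrix of (possibly fractional) letter
#' counts plus the Dirichlet pseudocount; predictive probabilities per
#' position are `(n_a + lambda) / (n + 4 lambda)`.
#'
#' @param counts 4 x l numeric matrix of letter counts, rows ordered
#'   A, C, G, T (an l x 4 matrix is transposed when unambiguous), or a
#'   character vector / l x m integer matrix of aligned sites.
#' @param lambda Dirichlet pseudocount per letter (default 1/2, Jeffreys).
#' @param name optional model identifier.
#' @return object of class `pswm_model`.
#' @export
pswm_model <- function(counts, lambda = 0.5, name = "motif") {
  lambda <- as_prior(lambda)$lambda
  if (is.character(counts)) counts <- site_count_matrix(counts)
  counts <- as.matrix(counts)
  if (nrow(counts) != 4 && ncol(counts) == 4) counts <- t(counts)
  if (nrow(counts) != 4) stop("counts must be a 4 x l matrix (rows A,C,G,T)")
  if (any(counts < 0) || any(!is.finite(counts))) stop("counts must be finite and >= 0")
  rownames(counts) <- DNA_LETTERS
  new_motif_model("pswm", counts, NULL, lambda, name)
}

#' Marginal count matrix of a set of aligned sites
#'
#' @param sites character vector of equal-length sequences or an encoded
#'   integer site matrix (l x m).
#' @return 4 x l count matrix (rows A,C,G,T).
#' @export
site_count_matrix <- function(sites) {
  m <- as_site_matrix(sites)
  counts <- vapply(seq_len(nrow(m)), function(i)
    tabulate(m[i, ] + 1L, nbins = 4L), numeric(4))
  rownames(counts) <- DNA_LETTERS
  counts
}

#' Dinucleotide weight tensor model
#'
#' A DWT model is completely specified by the `16 l (l-1) / 2` pair counts
#' (plus the prior): for every pair of positions `(i, j)` the number of
#' sites carrying each of the 16 letter combinations. Its predictive
#' probability for a new segment is the PSWM predictive on the marginal
#' counts times a ratio of spanning-tree determinants that carries all
#' pairwise-dependency information (and is identically 1 when no
#' dependency evidence is present).
#'
#' @param x either a 4 x 4 x l x l pair-count array (entry `[a,b,i,j]` is
#'   the count of letter pair (a,b) at positions (i,j)), a character
#'   vector of aligned sites, or an l x m encoded site matrix.
#' @inheritParams pswm_model
#' @return object of class `dwt_model`, with cached dependency matrix
#'   `logR` and spanning-tree log-determinant `log_D`.
#' @export
dwt_model <- function(x, lambda = 0.5, name = "motif") {
  lambda <- as_prior(lambda)$lambda
  if (is.array(x) && length(dim(x)) == 4L) {
    tensor <- x
  } else {
    tensor <- pair_tensor_from_sites(as_site_matrix(x))
  }
  l <- dim(tensor)[3]
  if (l < 2) stop("a DWT model needs l >= 2")
  check_pair_tensor(tensor)
  counts <- tensor_marginals(tensor)
  rownames(counts) <- DNA_LETTERS
  new_motif_model("dwt", counts, tensor, lambda, name)
}

#' Adjacent-dependency (ADJ) motif model
#'
#' Restriction of the DWT in which only dependencies between adjacent
#' positions are allowed; the chain 1-2-...-l is then the unique spanning
#' tree and the predictive factorizes as a first-order Markov chain of
#' Dirichlet-marginal conditionals `P(s_i | s_{i-1})`.
#'
#' @inheritParams dwt_model
#' @return object of class `adj_model`.
#' @export
adj_model <- function(x, lambda = 0.5, name = "motif") {
  lambda <- as_prior(lambda)$lambda
  if (is.array(x) && length(dim(x)) == 4L) tensor <- x
  else tensor <- pair_tensor_from_sites(as_site_matrix(x))
  l <- dim(tensor)[3]
  if (l < 2) stop("an ADJ model needs l >= 2")
  # marginal consistency along the chain only: an ADJ model may be built
  # from a file that stores just the adjacent pair counts
  n <- sum(tensor[, , 1, 2])
  counts <- matrix(0, 4, l)
  for (i in seq_len(l - 1)) counts[, i] <- rowSums(tensor[, , i, i + 1])
  counts[, l] <- colSums(tensor[, , l - 1, l])
  if (l > 2) for (i in 2:(l - 1)) {
    alt <- colSums(tensor[, , i - 1, i])
    if (max(abs(alt - counts[, i])) > 1e-6 * max(1, n))
      stop("adjacent pair counts have inconsistent marginals at position ", i)
  }
  # keep only adjacent pairs populated
  keep <- empty_pair_tensor(l)
  for (i in seq_len(l - 1)) {
    keep[, , i, i + 1] <- tensor[, , i, i + 1]
    keep[, , i + 1, i] <- tensor[, , i + 1, i]
  }
  rownames(counts) <- DNA_LETTERS
  new_motif_model("adj", counts, keep, lambda, name)
}

#' Marginalize a motif model to its PSWM
#'
#' @param model a fitted or constructed motif model.
#' @return the `pswm_model` with the same marginal counts and prior.
#' @export
as_pswm <- function(model) {
  stopifnot(inherits(model, "motif_model"))
  pswm_model(model$counts, model$lambda, name = model$name)
}

kind_code <- function(model) {
  switch(model$kind, pswm = 0L, adj = 1L, dwt = 2L,
         stop("unknown model kind"))
}

#' Background (0th-order) sequence model
#'
#' @param x either a vector of 4 letter frequencies (A,C,G,T; normalized
#'   internally) or a character vector of sequences whose pooled letter
#'   frequencies (N excluded) define the background.
#' @return object of class `background_model` with fields `b` and `logb`.
#' @export
background_model <- function(x = c(0.25, 0.25, 0.25, 0.25)) {
  if (is.character(x)) {
    enc <- unlist(lapply(x, encode_seq))
    tab <- tabulate(enc[enc < 4L] + 1L, nbins = 4L)
    if (sum(tab) == 0) stop("sequences contain no A,C,G,T letters")
    b <- tab / sum(tab)
    if (any(b == 0)) b <- (tab + 0.5) / sum(tab + 2)   # keep log finite
  } else {
    if (length(x) != 4L || any(x <= 0)) stop("need 4 positive frequencies")
    b <- x / sum(x)
  }
  structure(list(b = setNames(b, DNA_LETTERS), logb = log(b)),
            class = "background_model")
}

#' Predictive log-probability of binding-site segments under a motif model
#'
#' For a PSWM this is the product of per-position Dirichlet-marginal
#' predictives; for the DWT it is that product times the ratio of
#' spanning-tree determinants `D(R(s,S)) / D(R(S))`, where `R(s,S)` is the
#' dependency matrix after adding the scored segment (with weight 1) to
#' the pair counts; for the ADJ model it is the first-order chain of pair
#' conditionals. All three are exactly normalized over the `4^l` possible
#' segments. `N` letters are permitted and contribute nothing (their
#' positions and pairs are marginalized out, so values are comparable to a
#' background that also skips those positions).
#'
#' @param model a `pswm_model`, `adj_model` or `dwt_model`.
#' @param sites character vector of length-l sequences, or an encoded
#'   l x m integer matrix (0..3 = ACGT, 4 = N).
#' @return numeric vector of natural-log probabilities.
#' @export
predictive_logprob <- function(model, sites) {
  stopifnot(inherits(model, "motif_model"))
  m <- as_site_matrix(sites)
  if (nrow(m) != model$l)
    stop("sites have length ", nrow(m), " but the model has l = ", model$l)
  cpp_score_sites(m, model$logw, model$delta, model$logR,
                  kind_code(model), model$log_D)
}

#' Binding energy of single segments
#'
#' The effective binding energy (in units of kT) of a length-l segment is
#' the log-odds of the segment under the motif model versus the background,
#' `E(s) = log P(s|M) - log P(s|B)`. `N` positions contribute 0 to both
#' terms (ratio-neutral missing data).
#'
#' @inheritParams predictive_logprob
#' @param background a [background_model()].
#' @return numeric vector of energies in kT.
#' @export
segment_energy <- function(model, sites, background = background_model()) {
  m <- as_site_matrix(sites)
  lp <- predictive_logprob(model, m)
  bg <- apply(m, 2, function(col) sum(background$logb[col[col < 4L] + 1L]))
  lp - bg
}

#' Total binding energy and per-segment energy profile of a sequence
#'
#' Enumerates every length-l segment on the forward strand and on the
#' reverse complement (so `L_S = 2 (|S| - l + 1)` segments) and combines
#' their energies into the total binding energy
#' `E(S) = log sum_s exp(E(s))` by log-sum-exp. Reverse-strand offsets
#' refer to the forward-strand leftmost base of the site (1-based).
#'
#' @inheritParams segment_energy
#' @param sequence a single sequence (character string).
#' @param pad number of `N` letters to append on each side before scanning
#'   (0 = none); sequences shorter than l are an error unless padded to
#'   at least l.
#' @return object of class `energy_profile`: list with `segments`
#'   (data.frame offset/strand/energy), `total` (E(S)) and `L_S`.
#' @export
score_sequence <- function(model, sequence, background = background_model(),
                           pad = 0L) {
  enc <- encode_seq(sequence)
  if (pad > 0L) enc <- c(rep(4L, pad), enc, rep(4L, pad))
  if (length(enc) < model$l)
    stop("sequence shorter than the motif (", length(enc), " < ", model$l,
         "); use pad")
  Ef <- cpp_scan_energies(enc, model$logw, model$delta, model$logR,
                          kind_code(model), model$log_D, background$logb)
  Er <- cpp_scan_energies(revcomp_enc(enc), model$logw, model$delta,
                          model$logR, kind_code(model), model$log_D,
                          background$logb)
  K <- length(Ef)
  # reverse-strand segment k (1-based on the revcomp) starts at forward
  # position L - l + 2 - k; report forward-strand leftmost base
  segs <- data.frame(
    offset = c(seq_len(K), length(enc) - model$l + 2L - seq_len(K)),
    strand = rep(c("+", "-"), each = K),
    energy = c(Ef, Er),
    stringsAsFactors = FALSE)
  structure(list(segments = segs, total = logsumexp(segs$energy),
                 L_S = 2L * K, l = model$l, pad = pad),
            class = "energy_profile")
}

#' @export
print.energy_profile <- function(x, ...) {
  cat("energy profile:", x$L_S, "segments (both strands), E(S) =",
      format(x$total, digits = 6), "\n")
  best <- x$segments[which.max(x$segments$energy), ]
  cat("best segment: offset", best$offset, "strand", best$strand,
      "E =", format(best$energy, digits = 6), "\n")
  invisible(x)
}

# Internal batch scorer: energies of both strands for a list of encoded
# sequences under a model; returns list of numeric vectors c(Ef, Er).
scan_energies_enc <- function(model, enc_list, background) {
  kind <- kind_code(model)
  lapply(enc_list, function(enc) {
    c(cpp_scan_energies(enc, model$logw, model$delta, model$logR, kind,
                        model$log_D, background$logb),
      cpp_scan_energies(revcomp_enc(enc), model$logw, model$delta,
                        model$logR, kind, model$log_D, background$logb))
  })
}

#' Total binding energies of many sequences
#'
#' @inheritParams score_sequence
#' @param sequences character vector of sequences.
#' @return numeric vector of total binding energies E(S).
#' @export
sequence_energies <- function(model, sequences,
                              background = background_model(), pad = 0L) {
  enc <- lapply(sequences, function(s) {
    v <- encode_seq(s)
    if (pad > 0L) v <- c(rep(4L, pad), v, rep(4L, pad))
    if (length(v) < model$l)
      stop("sequence shorter than the motif; use pad")
    v
  })
  vapply(scan_energies_enc(model, enc, background), logsumexp, numeric(1))
}

#' @export
print.motif_model <- function(x, ...) {
  cat(toupper(x$kind), "motif model '", x$name, "': l = ", x$l,
      ", n = ", format(x$n, digits = 6), ", lambda = ", x$lambda, "\n",
      sep = "")
  cat("consensus:", paste(DNA_LETTERS[apply(x$counts, 2, which.max)],
                          collapse = ""), "\n")
  if (x$kind == "dwt") {
    P <- edge_posteriors(x$logR)
    top <- which(P == max(P), arr.ind = TRUE)[1, ]
    cat("strongest dependency: positions (", top[1], ",", top[2], "), P = ",
        format(max(P), digits = 4), "\n", sep = "")
  }
  invisible(x)
}
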