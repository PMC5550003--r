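# EM motif inference under the thermodynamic sampling likelihood.
#
# The probability of sampling a bound sequence S from a large background
# pool is proportional to exp(E(S)) + L_S exp(E0), with E(S) the
# log-sum-exp of segment energies over both strands, L_S the number of
# segments, and E0 the non-specific binding energy; the TF concentration
# cancels. The log-likelihood maximized by EM (up to an additive constant
# independent of the model) is
#   L = sum_S log[(exp(E(S)) + L_S exp(E0)) / (1 + exp(E0))].

#' Dataset log-likelihood of the thermodynamic sampling model
#'
#' @param energies numeric vector of total binding energies E(S), one per
#'   sequence.
#' @param L_S integer vector of segment counts per sequence (both strands).
#' @param E0 non-specific binding energy (kT).
#' @return the log-likelihood (additive constant dropped), log-sum-exp safe.
#' @export
dataset_log_likelihood <- function(energies, L_S, E0) {
  if (length(energies) == 0L) stop("empty dataset")
  if (any(!is.finite(energies))) stop("non-finite energies")
  b <- log(L_S) + E0
  num <- pmax(energies, b) + log1p(exp(-abs(energies - b)))
  log_denom <- pmax(E0, 0) + log1p(exp(-abs(E0)))   # log(1 + e^E0)
  sum(num - log_denom)
}

#' Optimize the non-specific binding energy
#'
#' Finds the root of the stationarity condition
#' `sum_S [ L_S / (exp(E(S)) + L_S exp(E0)) - 1 / (1 + exp(E0)) ] = 0`
#' (the bracketed factor of the likelihood derivative; the `exp(E0)`
#' prefactor never vanishes at finite E0) by bracketing on `[-50, 50]`
#' and `uniroot`. If the condition has no sign change in the bracket, the
#' bracket end with the higher likelihood is returned with a warning; the
#' degenerate case where the condition vanishes identically returns 0.
#'
#' @inheritParams dataset_log_likelihood
#' @param bracket search interval for E0.
#' @return the optimal E0.
#' @export
optimize_E0 <- function(energies, L_S, bracket = c(-50, 50)) {
  if (any(!is.finite(energies))) stop("non-finite energies")
  n <- length(energies)
  logLS <- log(L_S)
  g <- function(E0) {
    # L_S/(e^E + L_S e^E0) = exp(log L_S - logsumexp(E, log L_S + E0))
    b <- logLS + E0
    t1 <- sum(exp(logLS - pmax(energies, b) - log1p(exp(-abs(energies - b)))))
    t1 - n / (1 + exp(E0))
  }
  # The condition decays to 0 as E0 -> +Inf, so a naive two-point bracket
  # always "finds" a spurious root at the top. Scan a grid for genuine
  # sign changes and keep the stationary point with the best likelihood.
  grid <- seq(bracket[1], bracket[2], length.out = 101L)
  gv <- vapply(grid, g, numeric(1))
  if (max(abs(gv)) < 1e-12 * max(1, n)) return(0)   # identically stationary
  cross <- which(gv[-length(gv)] * gv[-1] < 0)
  cand <- vapply(cross, function(k)
    uniroot(g, c(grid[k], grid[k + 1L]), tol = 1e-10)$root, numeric(1))
  cand <- c(cand, bracket)
  if (length(cross) == 0L)
    warning("no stationary E0 in bracket; returning the better endpoint")
  Lv <- vapply(cand, function(e) dataset_log_likelihood(energies, L_S, e),
               numeric(1))
  cand[which.max(Lv)]
}

#' Per-segment binding posteriors
#'
#' Probability that the TF is bound at each specific segment of a
#' sequence: `P_b(s) = exp(E(s)) / (exp(E(S)) + L_S exp(E0))`. Their sum
#' over segments is the sequence-level binding probability `P_b(S) <= 1`.
#'
#' @param segment_energies numeric vector of per-segment energies E(s).
#' @param E0 non-specific binding energy.
#' @return numeric vector of per-segment posteriors.
#' @export
site_posteriors <- function(segment_energies, E0) {
  ES <- logsumexp(segment_energies)
  logZ <- logsumexp(c(ES, log(length(segment_energies)) + E0))
  exp(segment_energies - logZ)
}

# One posterior-weighted pair-count update over all sequences.
# enc_f / enc_r: encoded forward / revcomp sequences; post: per-sequence
# vectors of segment posteriors ordered (forward offsets, reverse offsets).
update_pair_counts <- function(enc_f, enc_r, post, l, wmarg) {
  tens <- empty_pair_tensor(l)
  for (k in seq_along(enc_f)) {
    K <- length(enc_f[[k]]) - l + 1L
    p <- post[[k]]
    cpp_accumulate_scan(tens, enc_f[[k]], p[seq_len(K)], wmarg, l)
    cpp_accumulate_scan(tens, enc_r[[k]], p[K + seq_len(K)], wmarg, l)
  }
  tens
}

#' Fit a motif model to bound sequences by expectation maximization
#'
#' Infers a DWT, ADJ, or PSWM motif from a set of sequences enriched for
#' binding sites of one TF (e.g. ChIP-seq peak sequences), starting from
#' an initial PSWM. The same EM loop serves all three model kinds so their
#' performance can be compared on equal footing. Each iteration (i) scores
#' every length-l segment of every sequence on both strands under the
#' current model, (ii) re-optimizes the non-specific energy E0,
#' (iii) computes per-segment binding posteriors, and (iv) replaces the
#' model's pair counts with the posterior-weighted dinucleotide counts
#' (reverse-strand sites contribute reverse-complemented letters).
#' Iteration 0 scores with the initial PSWM alone (equivalent to a DWT
#' with no dependency evidence), so no initial pair counts are needed.
#'
#' @param sequences character vector of input sequences (A,C,G,T,N), or a
#'   named vector; all at least as long as the motif unless `pad > 0`.
#' @param init initial PSWM: a `pswm_model` or a 4 x l count matrix.
#' @param kind motif model kind to fit: `"dwt"`, `"adj"` or `"pswm"`.
#' @param lambda Dirichlet pseudocount per letter.
#' @param tol relative convergence tolerance: stop when
#'   `|dL| < tol * |L|`.
#' @param max_iter maximum EM iterations.
#' @param restarts number of EM starts; starts beyond the first perturb
#'   the initial PSWM counts (column-wise Dirichlet resampling) and the
#'   best final likelihood wins.
#' @param seed RNG seed for restart perturbations (and nothing else).
#' @param pad number of N letters appended to each side of every sequence
#'   before scanning (used for short reads, e.g. SELEX; 0 for peaks).
#' @param background a [background_model()]; default: 0th-order letter
#'   frequencies of `sequences`.
#' @param verbose print the likelihood trace while fitting.
#' @return object of class `dwt_fit`: the fitted `model`, `E0`, the
#'   per-iteration `trace` (iter, logLik, E0), predicted `sites`
#'   (data.frame seq_id, offset, strand, energy, posterior), `background`,
#'   convergence flag, and the call.
#' @seealso [predict.dwt_fit()], [summary.dwt_fit()], [build_dilogo()]
#' @export
dwt_em <- function(sequences, init, kind = c("dwt", "adj", "pswm"),
                   lambda = 0.5, tol = 1e-6, max_iter = 200L,
                   restarts = 1L, seed = NULL, pad = 0L,
                   background = NULL, verbose = FALSE) {
  kind <- match.arg(kind)
  if (inherits(init, "pswm_model")) init_counts <- init$counts
  else init_counts <- pswm_model(init, lambda)$counts
  l <- ncol(init_counts)
  if (is.null(background)) background <- background_model(unname(sequences))
  ids <- names(sequences) %||% paste0("seq_", seq_along(sequences))
  enc_f <- lapply(unname(sequences), function(s) {
    v <- encode_seq(s)
    if (pad > 0L) v <- c(rep(4L, pad), v, rep(4L, pad))
    v
  })
  if (any(lengths(enc_f) < l))
    stop("motif (l = ", l, ") longer than the shortest sequence; use pad")
  enc_r <- lapply(enc_f, revcomp_enc)

  perturb <- function(counts) {
    apply(counts, 2, function(cc) {
      a <- cc + 0.5
      g <- rgamma(4, shape = a * 4)   # concentrated Dirichlet around cc/n
      sum(cc) * g / sum(g)
    })
  }

  run_one <- function(counts0) {
    model <- pswm_model(counts0, lambda)
    trace <- data.frame(iter = integer(), logLik = numeric(), E0 = numeric())
    best <- NULL
    L_prev <- -Inf
    for (it in seq_len(max_iter + 1L) - 1L) {
      seg <- scan_energies_enc(model, enc_f, background)
      ES <- vapply(seg, logsumexp, numeric(1))
      LS <- lengths(seg)
      E0 <- suppressWarnings(optimize_E0(ES, LS))
      L <- dataset_log_likelihood(ES, LS, E0)
      trace <- rbind(trace, data.frame(iter = it, logLik = L, E0 = E0))
      if (verbose) message(sprintf("iter %3d  L = %.6f  E0 = %.4f", it, L, E0))
      post <- lapply(seg, site_posteriors, E0 = E0)
      if (is.null(best) || L > best$logLik)
        best <- list(model = model, E0 = E0, logLik = L, post = post,
                     seg = seg, iter = it)
      if (is.finite(L_prev) && abs(L - L_prev) < tol * abs(L)) break
      L_prev <- L
      wmarg <- exp(model$logw)
      tens <- update_pair_counts(enc_f, enc_r, post, l, wmarg)
      if (sum(tens[, , 1, 2]) <= 0)
        stop("EM collapse: all binding posteriors are zero")
      model <- switch(kind,
                      dwt = dwt_model(tens, lambda),
                      adj = adj_model(tens, lambda),
                      pswm = pswm_model(tensor_marginals(tens), lambda))
    }
    best$trace <- trace
    best
  }

  starts <- list(init_counts)
  if (restarts > 1L) {
    extra <- with_seed(seed, lapply(seq_len(restarts - 1L),
                                    function(i) perturb(init_counts)))
    starts <- c(starts, extra)
  }
  runs <- lapply(starts, run_one)
  best <- runs[[which.max(vapply(runs, `[[`, numeric(1), "logLik"))]]

  # predicted sites: best posterior segment table
  sites <- do.call(rbind, lapply(seq_along(best$seg), function(k) {
    e <- best$seg[[k]]
    K <- length(e) / 2L
    Lseq <- length(enc_f[[k]])
    p <- best$post[[k]]
    data.frame(seq_id = ids[k],
               offset = c(seq_len(K), Lseq - l + 2L - seq_len(K)),
               strand = rep(c("+", "-"), each = K),
               energy = e, posterior = p, stringsAsFactors = FALSE)
  }))
  structure(list(model = best$model, kind = kind, E0 = best$E0,
                 logLik = best$logLik, trace = best$trace, sites = sites,
                 background = background, converged =
                   nrow(best$trace) <= max_iter, iterations = best$iter,
                 pad = pad, call = match.call()),
            class = "dwt_fit")
}

#' @export
print.dwt_fit <- function(x, ...) {
  cat("EM-fitted", toupper(x$kind), "motif (l =", x$model$l, ")\n")
  cat("log-likelihood:", format(x$logLik, digits = 8),
      " E0:", format(x$E0, digits = 4),
      " iterations:", x$iterations, "\n")
  print(x$model)
  invisible(x)
}

#' @method logLik dwt_fit
#' @export
logLik.dwt_fit <- function(object, ...) {
  structure(object$logLik, class = "logLik",
            df = NA_integer_, nobs = length(unique(object$sites$seq_id)))
}

#' @method coef dwt_fit
#' @export
coef.dwt_fit <- function(object, ...) {
  # marginal predictive probabilities w[a, i]
  exp(object$model$logw)
}

#' Summarize a fitted motif model
#'
#' @param object a `dwt_fit`.
#' @param n_edges how many of the strongest dependencies to report.
#' @param ... unused.
#' @return a `summary.dwt_fit` with consensus, likelihood, E0 and (for
#'   DWT fits) the top edge posteriors.
#' @method summary dwt_fit
#' @export
summary.dwt_fit <- function(object, n_edges = 5L, ...) {
  m <- object$model
  out <- list(kind = object$kind, l = m$l, n_eff = m$n,
              logLik = object$logLik, E0 = object$E0,
              iterations = object$iterations,
              consensus = paste(DNA_LETTERS[apply(m$counts, 2, which.max)],
                                collapse = ""))
  if (object$kind == "dwt") {
    P <- edge_posteriors(m$logR)
    idx <- which(upper.tri(P), arr.ind = TRUE)
    ord <- order(P[idx], decreasing = TRUE)
    top <- head(ord, n_edges)
    out$edges <- data.frame(i = idx[top, 1], j = idx[top, 2],
                            posterior = P[idx][top])
  }
  class(out) <- "summary.dwt_fit"
  out
}

#' @export
print.summary.dwt_fit <- function(x, ...) {
  cat(toupper(x$kind), "motif fit: l =", x$l,
      " effective sites =", format(x$n_eff, digits = 5), "\n")
  cat("consensus:", x$consensus, "\n")
  cat("log-likelihood:", format(x$logLik, digits = 8),
      " E0:", format(x$E0, digits = 4), "\n")
  if (!is.null(x$edges)) {
    cat("strongest dependencies (edge posteriors):\n")
    print(x$edges, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Predict binding energies for new sequences
#'
#' @param object a `dwt_fit`.
#' @param newdata character vector of sequences.
#' @param type `"energy"` for total E(S) per sequence, `"profile"` for a
#'   list of per-segment [score_sequence()] profiles.
#' @param pad N-padding per side (defaults to the fit's setting).
#' @param ... unused.
#' @return numeric vector of energies, or list of `energy_profile`s.
#' @method predict dwt_fit
#' @export
predict.dwt_fit <- function(object, newdata, type = c("energy", "profile"),
                            pad = object$pad, ...) {
  type <- match.arg(type)
  if (type == "energy")
    sequence_energies(object$model, newdata, object$background, pad = pad)
  else
    lapply(newdata, function(s)
      score_sequence(object$model, s, object$background, pad = pad))
}

#' Sample binding sites from a fitted motif model
#'
#' Draws sites from the model's exact predictive distribution by full
#' enumeration of the `4^l` segments (supported for `l <= 8`).
#'
#' @param object a `dwt_fit`.
#' @param nsim number of sites.
#' @param seed RNG seed.
#' @param ... unused.
#' @return character vector of `nsim` sampled sites.
#' @method simulate dwt_fit
#' @export
simulate.dwt_fit <- function(object, nsim = 1, seed = NULL, ...) {
  m <- object$model
  if (m$l > 8L) stop("exact predictive sampling supported for l <= 8 only")
  sites <- all_sites_matrix(m$l)
  p <- exp(predictive_logprob(m, sites))
  idx <- with_seed(seed, sample.int(ncol(sites), nsim, replace = TRUE,
                                    prob = p))
  apply(sites[, idx, drop = FALSE], 2, decode_seq)
}

# l x 4^l matrix of all length-l sites (encoded 0..3)
all_sites_matrix <- function(l) {
  g <- as.matrix(expand.grid(rep(list(0:3), l)))
  storage.mode(g) <- "integer"
  t(g)
}

#' Plot the dependency structure of a fitted motif
#'
#' Draws the lower-triangle lattice of pairwise dependency posteriors
#' (base graphics); for non-DWT fits, plots the information-content
#' profile instead.
#'
#' @param x a `dwt_fit`.
#' @param ... passed to `image`.
#' @method plot dwt_fit
#' @export
plot.dwt_fit <- function(x, ...) {
  m <- x$model
  if (x$kind == "dwt") {
    P <- edge_posteriors(m$logR)
    image(seq_len(m$l), seq_len(m$l), t(P)[, rev(seq_len(m$l))],
          col = grDevices::hcl.colors(64, "Reds", rev = TRUE),
          xlab = "position j", ylab = "position i", axes = FALSE,
          main = "pairwise dependency posteriors", ...)
    graphics::axis(1, at = seq_len(m$l))
    graphics::axis(2, at = seq_len(m$l), labels = rev(seq_len(m$l)))
    graphics::box()
  } else {
    w <- exp(m$logw)
    ic <- 2 + colSums(ifelse(w > 0, w * log2(w), 0))
    graphics::barplot(ic, names.arg = seq_len(m$l),
                      xlab = "position", ylab = "information (bits)")
  }
  invisible(x)
}
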