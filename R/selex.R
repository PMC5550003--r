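# HT-SELEX enrichment likelihoods. A dataset is a list of per-round count
# tables; selection is modeled as sampling sequences in proportion to
# exp(beta * E(S)), with beta a fitted 'temperature' relating model
# energies to observed round-to-round enrichment.

#' Assemble an HT-SELEX dataset from per-round count tables
#'
#' @param rounds list (in round order, `T >= 2` elements) of data.frames
#'   with columns `sequence` and `count` (non-negative integers).
#' @return object of class `selex_dataset`: list with `rounds` (tables),
#'   `totals` N(t), and the union of observed sequences.
#' @export
selex_dataset <- function(rounds) {
  if (length(rounds) < 2L) stop("need at least two selection rounds")
  rounds <- lapply(rounds, function(r) {
    r <- as.data.frame(r)
    if (!all(c("sequence", "count") %in% names(r)))
      stop("each round needs columns 'sequence' and 'count'")
    if (any(r$count < 0) || any(r$count != round(r$count)))
      stop("counts must be non-negative integers")
    r[r$count > 0, c("sequence", "count")]
  })
  structure(list(rounds = rounds,
                 totals = vapply(rounds, function(r) sum(r$count), numeric(1)),
                 sequences = unique(unlist(lapply(rounds, `[[`, "sequence")))),
            class = "selex_dataset")
}

#' Score SELEX reads with N-padding
#'
#' SELEX reads are short (~20 nt) and can be shorter than the motif; each
#' read is padded with `floor(l/2)` N letters on both sides before the
#' total binding energy is computed (N positions are ratio-neutral, see
#' [segment_energy()]).
#'
#' @param model a motif model.
#' @param sequences character vector of reads.
#' @param background a [background_model()].
#' @return named numeric vector of total binding energies E(S).
#' @export
pad_and_score <- function(model, sequences, background = background_model()) {
  if (any(nchar(sequences) == 0)) stop("empty sequence")
  e <- sequence_energies(model, sequences, background,
                         pad = model$l %/% 2L)
  names(e) <- sequences
  e
}

#' Selection log-likelihood of an HT-SELEX dataset
#'
#' Under selection proportional to `exp(E(S))`, the probability that one
#' sequence selected from the round-t pool is S equals
#' `exp(E(S)) f_t(S) / sum_S' f_t(S') exp(E(S'))`; the dataset
#' log-likelihood `L(E)` sums `n_{t+1}(S)` times this log-probability over
#' all consecutive round pairs. `L0` is the analogous likelihood for
#' selection-free resampling (`log f_t(S)`). Sequences entering at round
#' t+1 that were unseen at round t receive the pseudo-frequency
#' `1/(N(t)+U)` (U = number of distinct sequences across both rounds) so
#' both likelihoods stay finite; the normalizing average is always over
#' the observed round-t pool.
#'
#' @param energies named numeric vector of energies E(S) covering every
#'   sequence in the dataset (names = sequences).
#' @param dataset a [selex_dataset()].
#' @return list with `L` (= L(E)), `L0`, and `dL = L - L0`.
#' @export
selection_log_likelihood <- function(energies, dataset) {
  stopifnot(inherits(dataset, "selex_dataset"))
  Tn <- length(dataset$rounds)
  L <- 0; L0 <- 0
  for (t in seq_len(Tn - 1L)) {
    rt <- dataset$rounds[[t]]
    rt1 <- dataset$rounds[[t + 1L]]
    Nt <- sum(rt$count)
    ft <- setNames(rt$count / Nt, rt$sequence)
    U <- length(unique(c(rt$sequence, rt1$sequence)))
    Et <- energies[rt$sequence]
    if (anyNA(Et)) stop("missing energies for some round-", t, " sequences")
    logZ <- logsumexp(log(ft) + Et)    # log <e^E>_t over the observed pool
    f_at <- ft[rt1$sequence]
    f_at[is.na(f_at)] <- 1 / (Nt + U)
    E1 <- energies[rt1$sequence]
    if (anyNA(E1)) stop("missing energies for some round-", t + 1, " sequences")
    L <- L + sum(rt1$count * (E1 + log(f_at) - logZ))
    L0 <- L0 + sum(rt1$count * log(f_at))
  }
  list(L = L, L0 = L0, dL = L - L0)
}

#' Log-likelihood gain of tempered selection
#'
#' Evaluates `dL(E, beta) = L(E, beta) - L0 = sum_t N(t+1) (beta <E>_{t+1}
#' - log <exp(beta E)>_t)`, with `<.>_t` the count-weighted average over
#' the round-t pool. `dL` is concave in beta (a cumulant generating
#' function enters with a minus sign) and `dL(E, 0) = 0`; at `beta = 1` it
#' equals `L(E) - L0` from [selection_log_likelihood()].
#'
#' @inheritParams selection_log_likelihood
#' @param beta selection temperature, `>= 0`.
#' @return the log-likelihood difference dL.
#' @export
temperature_dL <- function(energies, dataset, beta) {
  stopifnot(inherits(dataset, "selex_dataset"), beta >= 0)
  Tn <- length(dataset$rounds)
  dL <- 0
  for (t in seq_len(Tn - 1L)) {
    rt <- dataset$rounds[[t]]
    rt1 <- dataset$rounds[[t + 1L]]
    N1 <- sum(rt1$count)
    Ebar1 <- sum(rt1$count * energies[rt1$sequence]) / N1
    logavg <- logsumexp(log(rt$count / sum(rt$count)) +
                          beta * energies[rt$sequence])
    dL <- dL + N1 * (beta * Ebar1 - logavg)
  }
  dL
}

#' Fit the selection temperature of an HT-SELEX dataset
#'
#' Maximizes the concave `dL(E, beta)` over `beta` in `[0, beta_max]` by
#' golden-section search, and reports the per-sequence gain `dL/N` with
#' `N = sum_{t=2..T} N(t)` (selected sequences only). If dL is still
#' increasing at `beta_max` the bound is returned with a warning; a flat
#' dL (constant energies) returns `beta = 0` by convention.
#'
#' @inheritParams selection_log_likelihood
#' @param beta_max upper end of the search bracket.
#' @param tol absolute tolerance of the golden-section search.
#' @return object of class `selex_fit`: list with `beta`, `dL`,
#'   `dL_per_seq`, and `N`.
#' @export
fit_temperature <- function(energies, dataset, beta_max = 5, tol = 1e-8) {
  f <- function(b) temperature_dL(energies, dataset, b)
  # golden-section maximization on [0, beta_max]
  gr <- (sqrt(5) - 1) / 2
  a <- 0; b <- beta_max
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  while (b - a > tol) {
    if (f1 < f2) {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- f(x2)
    } else {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- f(x1)
    }
  }
  beta <- (a + b) / 2
  dbest <- f(beta)
  if (dbest <= f(0) + 1e-12) { beta <- 0; dbest <- 0 }   # flat or decreasing
  if (beta_max - beta < 10 * tol)
    warning("dL still increasing at beta_max = ", beta_max)
  N <- sum(dataset$totals[-1])
  structure(list(beta = beta, dL = dbest, dL_per_seq = dbest / N, N = N),
            class = "selex_fit")
}

#' @export
print.selex_fit <- function(x, ...) {
  cat("SELEX temperature fit: beta =", format(x$beta, digits = 5),
      " dL/N =", format(x$dL_per_seq, digits = 5),
      " (N =", x$N, "selected sequences)\n")
  invisible(x)
}

#' Energy-binned round-to-round enrichment
#'
#' Diagnostic for the tempered selection model: stratifies sequences into
#' energy bins and tabulates `log[f_{t+1}(E) / f_t(E)]` per bin; under
#' ideal selection this is linear in E with slope beta. Bins empty in
#' either round are dropped.
#'
#' @inheritParams selection_log_likelihood
#' @param t index of the earlier round of the consecutive pair.
#' @param bin_width energy bin width (kT).
#' @return data.frame with `E_mid`, `f_t`, `f_t1`, `log_enrichment`.
#' @export
energy_bin_enrichment <- function(energies, dataset, t = 1L, bin_width = 1) {
  stopifnot(inherits(dataset, "selex_dataset"))
  rt <- dataset$rounds[[t]]
  rt1 <- dataset$rounds[[t + 1L]]
  brk <- function(e) floor(e / bin_width)
  tab <- function(r) {
    b <- brk(energies[r$sequence])
    tapply(r$count / sum(r$count), b, sum)
  }
  ft <- tab(rt); ft1 <- tab(rt1)
  bins <- intersect(names(ft), names(ft1))
  bins <- bins[ft[bins] > 0 & ft1[bins] > 0]
  data.frame(E_mid = (as.numeric(bins) + 0.5) * bin_width,
             f_t = as.numeric(ft[bins]), f_t1 = as.numeric(ft1[bins]),
             log_enrichment = log(as.numeric(ft1[bins] / ft[bins])))
}
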