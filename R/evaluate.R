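# Benchmarking: composition-matched decoy sequences, precision-recall /
# average precision, and the randomized-dependency control.

#' Generate composition-matched decoy sequences
#'
#' For each source sequence, emits `m` decoys of identical length. The
#' default sampler is a first-order Markov chain fitted to the pooled
#' dinucleotide frequencies of the source set, which matches the sources'
#' dinucleotide composition in expectation. `method = "shuffle"` instead
#' performs an exact per-sequence dinucleotide-preserving shuffle
#' (random Eulerian walk on the dinucleotide multigraph), preserving each
#' sequence's dinucleotide counts exactly.
#'
#' @param sequences character vector of source sequences (>= 2 bp each).
#' @param m decoys per source sequence.
#' @param seed RNG seed; the same seed reproduces the same decoys.
#' @param method `"markov"` (default) or `"shuffle"`.
#' @return character vector of `m * length(sequences)` decoys.
#' @export
generate_decoys <- function(sequences, m = 4L, seed = NULL,
                            method = c("markov", "shuffle")) {
  method <- match.arg(method)
  if (m < 1L) stop("m must be >= 1")
  enc <- lapply(sequences, function(s) {
    v <- encode_seq(s)
    v[v < 4L]                           # N dropped from composition fitting
  })
  if (any(lengths(enc) < 2L)) stop("source sequences must be at least 2 bp")
  with_seed(seed, {
    if (method == "markov") {
      trans <- matrix(0, 4, 4)
      first <- numeric(4)
      for (v in enc) {
        first[v[1] + 1L] <- first[v[1] + 1L] + 1
        tt <- table(factor(head(v, -1L), levels = 0:3),
                    factor(tail(v, -1L), levels = 0:3))
        trans <- trans + tt
      }
      trans <- trans + 1e-9              # guard all-zero rows
      trans <- trans / rowSums(trans)
      first <- (first + 1e-9) / sum(first + 1e-9)
      out <- unlist(lapply(rep(lengths(enc), each = m), function(L) {
        x <- integer(L)
        x[1] <- sample.int(4L, 1L, prob = first) - 1L
        for (i in seq_len(L - 1L))
          x[i + 1L] <- sample.int(4L, 1L, prob = trans[x[i] + 1L, ]) - 1L
        decode_seq(x)
      }))
    } else {
      out <- unlist(lapply(enc, function(v)
        replicate(m, decode_seq(euler_shuffle(v)))))
    }
  })
  out
}

# Exact dinucleotide-preserving shuffle (Altschul-Erikson): pick random
# last-exit edges forming a tree into the terminal letter, then walk a
# random Eulerian path over the remaining transition multiset.
euler_shuffle <- function(v) {
  L <- length(v)
  if (L <= 2L) return(v)
  edges <- split(tail(v, -1L), factor(head(v, -1L), levels = 0:3))
  last <- v[L]
  verts <- which(lengths(edges) > 0L) - 1L
  repeat {   # rejection-sample last-exit edges until they form an in-tree
    lastexit <- rep(NA_integer_, 4)
    for (a in verts) if (a != last) {
      e <- edges[[a + 1L]]
      lastexit[a + 1L] <- e[sample.int(length(e), 1L)]
    }
    ok <- TRUE
    for (a in verts) {
      if (a == last) next
      seen <- a; cur <- a
      repeat {
        cur <- lastexit[cur + 1L]
        if (is.na(cur)) { ok <- FALSE; break }
        if (cur == last) break
        if (cur %in% seen) { ok <- FALSE; break }
        seen <- c(seen, cur)
      }
      if (!ok) break
    }
    if (ok) break
  }
  pools <- edges
  for (a in verts) {
    p <- pools[[a + 1L]]
    if (a != last) {
      p <- p[-match(lastexit[a + 1L], p)]
      pools[[a + 1L]] <- c(p[sample.int(length(p))], lastexit[a + 1L])
    } else {
      pools[[a + 1L]] <- p[sample.int(length(p))]
    }
  }
  ptr <- rep(1L, 4)
  out <- integer(L)
  out[1] <- v[1]
  cur <- v[1]
  for (i in 2:L) {
    nxt <- pools[[cur + 1L]][ptr[cur + 1L]]
    ptr[cur + 1L] <- ptr[cur + 1L] + 1L
    out[i] <- nxt
    cur <- nxt
  }
  out
}

#' Precision-recall curve and average precision
#'
#' Sweeps all distinct score thresholds `E_c`; at each, the predicted
#' positive set is every item with score strictly greater than `E_c`
#' (ties enter and leave together), precision is the fraction of
#' predicted positives that are labeled positive and recall the fraction
#' of positives predicted. Average precision is the step-wise area
#' `sum_k dRecall_k * Precision_k`, which is invariant under strictly
#' monotone transformations of the scores.
#'
#' @param scores numeric vector of finite scores (higher = more likely
#'   positive).
#' @param labels logical vector (TRUE = positive) aligned with `scores`.
#' @return list with `curve` (data.frame threshold, precision, recall)
#'   and `average_precision`.
#' @export
precision_recall <- function(scores, labels) {
  if (any(!is.finite(scores))) stop("scores must be finite")
  labels <- as.logical(labels)
  npos <- sum(labels); nneg <- sum(!labels)
  if (npos == 0L || nneg == 0L) stop("need both positive and negative labels")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  grp <- cumsum(!duplicated(s))            # tie groups share a threshold
  tp <- tapply(y, grp, sum)
  nn <- tapply(rep(1L, length(y)), grp, sum)
  ctp <- cumsum(tp); cn <- cumsum(nn)
  precision <- ctp / cn
  recall <- ctp / npos
  ap <- sum(diff(c(0, recall)) * precision)
  list(curve = data.frame(threshold = s[!duplicated(s)],
                          precision = as.numeric(precision),
                          recall = as.numeric(recall)),
       average_precision = as.numeric(ap))
}

#' Random train/test split of a sequence set
#'
#' @param sequences character vector (optionally named).
#' @param seed RNG seed (same seed, same split).
#' @param frac fraction assigned to the training set.
#' @return list with `train` and `test`.
#' @export
benchmark_split <- function(sequences, seed = NULL, frac = 0.5) {
  n <- length(sequences)
  if (n < 2L) stop("need at least 2 sequences")
  idx <- with_seed(seed, sample.int(n, floor(n * frac)))
  list(train = sequences[idx], test = sequences[-idx])
}

#' Randomized-dependency control for a DWT model
#'
#' Destroys pairwise dependencies while preserving marginals: the model's
#' pair counts are marginalized to a PSWM, `n` sites are sampled
#' independently per position from the PSWM predictive, and a fresh DWT is
#' built from the sampled sites. Edge posteriors of the rebuilt model,
#' stratified by adjacency, quantify how much apparent dependency arises
#' from sampling noise alone.
#'
#' @param model a `dwt_model` (or `dwt_fit`).
#' @param seed RNG seed.
#' @param n number of sites to sample (default: the model's effective
#'   count, rounded).
#' @return list with `control_model`, `posteriors` (matrix), and
#'   `summary` (data.frame: adjacency class, number of pairs, max
#'   posterior, fraction above 0.9).
#' @export
randomized_dependency_control <- function(model, seed = NULL, n = NULL) {
  if (inherits(model, "dwt_fit")) model <- model$model
  stopifnot(inherits(model, "dwt_model"))
  n <- n %||% max(2L, round(model$n))
  if (n < 2) stop("need n >= 2 sampled sites")
  w <- exp(model$logw)                    # predictive marginals, cols sum 1
  l <- model$l
  sites <- with_seed(seed, vapply(seq_len(l), function(i)
    sample.int(4L, n, replace = TRUE, prob = w[, i]) - 1L,
    integer(n)))
  ctrl <- dwt_model(t(sites), model$lambda, name = paste0(model$name, "_ctrl"))
  P <- edge_posteriors(ctrl$logR)
  idx <- which(upper.tri(P), arr.ind = TRUE)
  adj <- abs(idx[, 1] - idx[, 2]) == 1L
  p <- P[idx]
  list(control_model = ctrl, posteriors = P,
       summary = data.frame(
         class = c("adjacent", "distal"),
         n_pairs = c(sum(adj), sum(!adj)),
         max_posterior = c(max(p[adj]), max(p[!adj])),
         frac_above_0.9 = c(mean(p[adj] > 0.9), mean(p[!adj] > 0.9))))
}
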