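# Shared fixtures and independent oracles for the suite.

# random symmetric log-weight matrix with zero diagonal
random_logR <- function(l, range = c(-20, 20)) {
  A <- matrix(0, l, l)
  A[upper.tri(A)] <- runif(l * (l - 1) / 2, range[1], range[2])
  A + t(A)
}

# brute-force edge posteriors by Pruefer enumeration (independent of the
# Laplacian-inverse implementation)
bf_edge_posteriors <- function(logR) {
  l <- nrow(logR)
  stopifnot(l <= 6)
  codes <- as.matrix(expand.grid(rep(list(seq_len(l)), max(l - 2, 0))))
  if (l == 2) codes <- matrix(integer(0), 1, 0)
  ws <- apply(codes, 1, function(code) {
    e <- dwtmotif:::pruefer_edges(as.integer(code), l)
    sum(logR[cbind(e[1, ], e[2, ])])
  })
  tot <- dwtmotif:::logsumexp(ws)
  P <- matrix(0, l, l)
  for (k in seq_along(ws)) {
    e <- dwtmotif:::pruefer_edges(as.integer(codes[k, ]), l)
    w <- exp(ws[k] - tot)
    for (c in seq_len(l - 1)) {
      P[e[1, c], e[2, c]] <- P[e[1, c], e[2, c]] + w
      P[e[2, c], e[1, c]] <- P[e[2, c], e[1, c]] + w
    }
  }
  P
}

# random site matrix (l x n, encoded 0..3)
random_sites <- function(l, n) {
  matrix(sample(0:3, l * n, replace = TRUE), l, n)
}

# outer-product pair tensor with given marginal profile (4 x l, columns
# summing to n)
outer_tensor <- function(marg, n) {
  l <- ncol(marg)
  tens <- dwtmotif:::empty_pair_tensor(l)
  for (i in seq_len(l - 1)) for (j in (i + 1):l) {
    tens[, , i, j] <- outer(marg[, i], marg[, j]) / max(n, .Machine$double.eps)
    tens[, , j, i] <- t(tens[, , i, j])
  }
  tens
}

# a small strongly coupled planted model for quick tests
quick_coupled <- function(l = 5, coupling = 0.85) {
  cop <- matrix((1 - coupling) / 3, 4, 4)
  diag(cop) <- coupling
  planted_model(l, matrix(0.25, 4, l),
                data.frame(parent = 1L, child = l),
                list(cop))
}

all_sites <- function(l) dwtmotif:::all_sites_matrix(l)
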