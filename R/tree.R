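#' Log of the weighted spanning-tree sum via the matrix-tree theorem
#'
#' For a symmetric non-negative weight matrix `R` (given as `logR`, with a
#' zero diagonal by convention), the sum over all spanning trees of the
#' complete graph on `l` nodes of the product of edge weights equals any
#' principal minor determinant of the graph Laplacian
#' `L = diag(rowSums(R)) - R` (generalized Kirchhoff matrix-tree theorem).
#'
#' Weights are supplied in log space because the evidence ratios that arise
#' in motif models span hundreds of orders of magnitude. Stability is
#' handled by uniform rescaling: with `c = max(logR)` every weight is
#' divided by `exp(c)`, the minor determinant of the rescaled Laplacian is
#' computed by pivoted LU, and the exactly compensating term `(l-1)*c` is
#' added back (every spanning tree has `l-1` edges, so scaling all weights
#' by `exp(-c)` scales the tree sum by `exp(-(l-1)c)`).
#'
#' @param logR symmetric l x l matrix of log edge weights, `l >= 2`;
#'   the diagonal is ignored.
#' @param drop index of the row/column to delete for the minor (any choice
#'   gives the same value; exposed for testing).
#' @return list with `log_D` (log of the tree sum), `log_scale` (the
#'   rescaling offset already folded into `log_D`) and `l`.
#' @export
#' @examples
#' m <- matrix(0, 4, 4)            # all weights 1
#' tree_logdet(m)$log_D            # log(16): Cayley, 4^2 spanning trees
tree_logdet <- function(logR, drop = nrow(logR)) {
  l <- nrow(logR)
  if (is.null(l) || l < 2L || ncol(logR) != l)
    stop("logR must be a square matrix with l >= 2")
  if (max(abs(logR - t(logR))) > 1e-8 * max(1, max(abs(logR))))
    stop("logR must be symmetric")
  log_D <- cpp_tree_logdet(logR, drop - 1L)
  if (is.nan(log_D)) {
    cmax <- max(logR[row(logR) != col(logR)])
    Rp <- exp(pmax(logR - cmax, -745))
    diag(Rp) <- 0
    M <- (diag(rowSums(Rp)) - Rp)[-drop, -drop, drop = FALSE]
    stop("matrix-tree determinant is non-positive (catastrophic ",
         "cancellation); reciprocal condition number ",
         format(tryCatch(rcond(M), error = function(e) NA_real_)))
  }
  cmax <- max(logR[row(logR) != col(logR)])
  if (!is.finite(cmax)) cmax <- 0
  list(log_D = log_D, log_scale = (l - 1) * cmax, l = l)
}

# Decode a Pruefer sequence (values in 1..l, length l-2) into the 2 x (l-1)
# edge matrix of the labeled tree it encodes.
pruefer_edges <- function(code, l) {
  degree <- rep(1L, l)
  for (v in code) degree[v] <- degree[v] + 1L
  edges <- matrix(0L, 2, l - 1)
  k <- 1L
  ptr <- which(degree == 1L)[1]
  leaf <- ptr
  for (v in code) {
    edges[, k] <- c(leaf, v); k <- k + 1L
    degree[v] <- degree[v] - 1L
    if (degree[v] == 1L && v < ptr) {
      leaf <- v
    } else {
      ptr <- ptr + 1L
      while (degree[ptr] != 1L) ptr <- ptr + 1L
      leaf <- ptr
    }
  }
  u <- which(degree == 1L & seq_len(l) != leaf)
  edges[, l - 1] <- c(leaf, u[length(u)])
  edges
}

#' Brute-force spanning-tree sum by Pruefer enumeration
#'
#' Exact test oracle for [tree_logdet()]: enumerates all `l^(l-2)` labeled
#' spanning trees of the complete graph through their Pruefer sequences and
#' accumulates the log-sum-exp of the tree log-weights. Refuses `l > 7`.
#'
#' @inheritParams tree_logdet
#' @return log of the exact spanning-tree sum.
#' @export
brute_force_tree_sum <- function(logR) {
  l <- nrow(logR)
  if (l < 2L) stop("need l >= 2")
  if (l > 7L) stop("brute-force enumeration refused for l > 7")
  if (l == 2L) return(logR[1, 2])
  codes <- as.matrix(expand.grid(rep(list(seq_len(l)), l - 2L)))
  w <- apply(codes, 1, function(code) {
    e <- pruefer_edges(as.integer(code), l)
    sum(logR[cbind(e[1, ], e[2, ])])
  })
  logsumexp(w)
}

#' Posterior probabilities of direct dependencies (edge posteriors)
#'
#' Under the uniform mixture over spanning-tree factorizations, the
#' posterior probability that the factorization contains a direct
#' dependency between positions i and j is the weighted fraction of
#' spanning trees containing edge (i,j),
#' `P(i,j) = R_ij * d log D(R) / d R_ij`. It is computed in one O(l^3)
#' solve through the effective-resistance identity on the inverse of the
#' Laplacian minor, not by finite differences. The posteriors of all pairs
#' sum to `l - 1`, the number of edges in any spanning tree.
#'
#' @inheritParams tree_logdet
#' @return symmetric l x l matrix of edge posteriors (zero diagonal).
#' @export
#' @examples
#' lR <- matrix(0, 3, 3)
#' lR[1, 2] <- lR[2, 1] <- log(2)
#' edge_posteriors(lR)  # P(1,2) = 4/5, P(1,3) = P(2,3) = 3/5
edge_posteriors <- function(logR) {
  l <- nrow(logR)
  if (l < 2L) stop("need l >= 2")
  P <- cpp_edge_posteriors(logR)
  if (nrow(P) == 1L || anyNA(P))
    stop("singular Laplacian minor in edge_posteriors")
  P
}
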