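# Seed-deterministic generators for study-condition data: tree-structured
# site samplers, background embedding (ChIP-seq-peak-like sequences), and
# multi-round SELEX selection.

#' Define a planted tree-structured site model
#'
#' The generative model behind the synthetic fixtures: a forest of
#' pairwise dependencies over the l motif positions. Each root position
#' carries a marginal distribution; every other position is sampled from a
#' conditional table given its parent's letter (ancestral sampling).
#'
#' @param l motif length.
#' @param marginals 4 x l matrix of per-position letter probabilities used
#'   for root/independent positions (columns sum to 1).
#' @param edges optional data.frame with columns `parent`, `child`, and
#'   coupling tables: `conditionals` must then be a list (one 4 x 4
#'   row-stochastic matrix per edge, rows = parent letter).
#' @param conditionals list of 4 x 4 conditional tables aligned with
#'   `edges` rows.
#' @return object of class `planted_model`.
#' @export
planted_model <- function(l, marginals, edges = NULL, conditionals = NULL) {
  marginals <- as.matrix(marginals)
  stopifnot(nrow(marginals) == 4, ncol(marginals) == l,
            all(abs(colSums(marginals) - 1) < 1e-9))
  if (!is.null(edges)) {
    edges <- as.data.frame(edges)
    stopifnot(all(c("parent", "child") %in% names(edges)),
              length(conditionals) == nrow(edges))
    for (cc in conditionals)
      stopifnot(all(dim(cc) == c(4, 4)), all(abs(rowSums(cc) - 1) < 1e-9))
    # forest check: each child appears once, no cycles
    if (anyDuplicated(edges$child)) stop("each position may have one parent")
    g <- as.list(rep(NA_integer_, l))
    for (k in seq_len(nrow(edges))) g[[edges$child[k]]] <- edges$parent[k]
    for (v in seq_len(l)) {
      seen <- integer(0); cur <- v
      while (!is.na(g[[cur]])) {
        if (cur %in% seen) stop("dependency edges contain a cycle")
        seen <- c(seen, cur); cur <- g[[cur]]
      }
    }
  }
  structure(list(l = l, marginals = marginals, edges = edges,
                 conditionals = conditionals),
            class = "planted_model")
}

#' Sample binding sites from a planted model
#'
#' @param planted a [planted_model()].
#' @param n number of sites.
#' @param seed RNG seed.
#' @return character vector of n length-l sites.
#' @export
sample_sites <- function(planted, n, seed = NULL) {
  stopifnot(inherits(planted, "planted_model"), n >= 1)
  l <- planted$l
  with_seed(seed, {
    sites <- matrix(0L, l, n)
    parent_of <- rep(NA_integer_, l)
    cond_of <- vector("list", l)
    if (!is.null(planted$edges)) {
      for (k in seq_len(nrow(planted$edges))) {
        ch <- planted$edges$child[k]
        parent_of[ch] <- planted$edges$parent[k]
        cond_of[[ch]] <- planted$conditionals[[k]]
      }
    }
    # topological order: roots first, then children
    order_pos <- integer(0)
    remaining <- seq_len(l)
    while (length(remaining) > 0) {
      ready <- remaining[is.na(parent_of[remaining]) |
                           parent_of[remaining] %in% order_pos]
      if (length(ready) == 0) stop("cyclic dependency structure")
      order_pos <- c(order_pos, ready)
      remaining <- setdiff(remaining, ready)
    }
    for (i in order_pos) {
      if (is.na(parent_of[i])) {
        sites[i, ] <- sample.int(4L, n, replace = TRUE,
                                 prob = planted$marginals[, i]) - 1L
      } else {
        pa <- sites[parent_of[i], ]
        cond <- cond_of[[i]]
        for (a in 0:3) {
          idx <- which(pa == a)
          if (length(idx))
            sites[i, idx] <- sample.int(4L, length(idx), replace = TRUE,
                                        prob = cond[a + 1L, ]) - 1L
        }
      }
    }
    apply(sites, 2, decode_seq)
  })
}

#' Embed sites in background sequences (synthetic peaks)
#'
#' Emulates ChIP-seq peak sequences: each site is placed at a uniform
#' random offset and strand inside a sequence sampled letter-by-letter
#' from the background model. Returns the sequences together with the
#' ground-truth coordinates for recovery scoring.
#'
#' @param sites character vector of length-l sites.
#' @param peak_length total length of each output sequence (>= l).
#' @param background a [background_model()].
#' @param seed RNG seed.
#' @return list with `sequences` (named character vector) and `truth`
#'   (data.frame id, offset (1-based), strand).
#' @export
embed_in_background <- function(sites, peak_length,
                                background = background_model(),
                                seed = NULL) {
  l <- unique(nchar(sites))
  stopifnot(length(l) == 1L, peak_length >= l)
  n <- length(sites)
  with_seed(seed, {
    offs <- sample.int(peak_length - l + 1L, n, replace = TRUE)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    seqs <- vapply(seq_len(n), function(k) {
      bgv <- sample.int(4L, peak_length, replace = TRUE,
                        prob = background$b) - 1L
      site <- encode_seq(sites[k])
      if (strand[k] == "-") site <- revcomp_enc(site)
      bgv[offs[k]:(offs[k] + l - 1L)] <- site
      decode_seq(bgv)
    }, character(1))
    names(seqs) <- sprintf("peak_%04d", seq_len(n))
    list(sequences = seqs,
         truth = data.frame(id = names(seqs), offset = offs,
                            strand = strand, stringsAsFactors = FALSE))
  })
}

#' Simulate multi-round SELEX selection
#'
#' Round 1 draws from the initial pool; each later round draws
#' multinomially with probabilities proportional to
#' `f_t(S) * exp(beta0 * E(S))`, i.e. tempered selection on the supplied
#' energies.
#'
#' @param energies named numeric vector: the binding energies E(S) of the
#'   distinct pool sequences (names = sequences).
#' @param pool_freq initial pool frequencies (aligned with `energies`;
#'   default uniform).
#' @param beta0 true selection temperature.
#' @param rounds number of rounds T (>= 2).
#' @param draws sequences sampled per round.
#' @param seed RNG seed.
#' @return a [selex_dataset()].
#' @export
simulate_selex <- function(energies, pool_freq = NULL, beta0 = 0.3,
                           rounds = 3L, draws = 1e4, seed = NULL) {
  stopifnot(rounds >= 2L, !is.null(names(energies)))
  m <- length(energies)
  pool_freq <- pool_freq %||% rep(1 / m, m)
  with_seed(seed, {
    tabs <- vector("list", rounds)
    cnt <- as.vector(rmultinom(1, draws, pool_freq))
    tabs[[1]] <- data.frame(sequence = names(energies), count = cnt)
    for (t in 2:rounds) {
      f <- cnt / sum(cnt)
      wlog <- log(ifelse(f > 0, f, 0)) + beta0 * energies
      p <- exp(wlog - logsumexp(wlog[f > 0]))
      p[f == 0] <- 0
      cnt <- as.vector(rmultinom(1, draws, p))
      tabs[[t]] <- data.frame(sequence = names(energies), count = cnt)
    }
    selex_dataset(tabs)
  })
}

#' Standard synthetic fixture suite
#'
#' Four planted l = 10 motifs separating the model kinds: `null`
#' (independent positions), `one_edge` (a single distal coupling 2-9),
#' `two_edge` (distal 2-9 plus adjacent 3-4), and `chain` (first-order
#' chain over positions 4-8). In the coupled fixtures the coupled
#' positions carry uniform marginals: all of their information lives in
#' the pairwise dependency (letter agreement with the partner), which is
#' the regime that cleanly separates dependency-aware models from the
#' PSWM while leaving the PSWM a solid consensus core at the remaining
#' positions.
#'
#' @param coupling probability that a child copies its parent's letter
#'   (remainder spread evenly over the other letters); the 0.9 default
#'   is the strong-coupling condition.
#' @param strength of the informative (uncoupled) consensus positions:
#'   probability of the consensus letter.
#' @return named list of [planted_model()]s.
#' @export
fixture_suite <- function(coupling = 0.9, strength = 0.85) {
  l <- 10L
  cons <- encode_seq("TGACGTCATG") + 1L   # consensus letter index per position
  marg <- matrix((1 - strength) / 3, 4, l)
  for (i in seq_len(l)) marg[cons[i], i] <- strength
  # coupled positions: no marginal information at all
  weak <- rep(0.25, 4)
  cop <- matrix((1 - coupling) / 3, 4, 4)
  diag(cop) <- coupling
  mk <- function(edges, conds, weak_pos) {
    mm <- marg
    for (i in weak_pos) mm[, i] <- weak
    planted_model(l, mm, edges, conds)
  }
  list(
    null = planted_model(l, marg),
    one_edge = mk(data.frame(parent = 2L, child = 9L), list(cop),
                  weak_pos = c(2L, 9L)),
    two_edge = mk(data.frame(parent = c(2L, 3L), child = c(9L, 4L)),
                  list(cop, cop), weak_pos = c(2L, 3L, 4L, 9L)),
    chain = mk(data.frame(parent = 4:7, child = 5:8),
               rep(list(cop), 4), weak_pos = 4:8)
  )
}

#' Expected pair-count tensor of a planted model
#'
#' Exact joint letter distributions implied by the planted forest, scaled
#' by `n`: useful as an oracle for dependency recovery.
#'
#' @inheritParams sample_sites
#' @param n total count to scale the joint probabilities by.
#' @return 4 x 4 x l x l pair-count array.
#' @export
planted_pair_tensor <- function(planted, n = 1) {
  l <- planted$l
  # joint over all positions via enumeration is exponential; instead use
  # the forest structure: positions in different components are
  # independent; within a component joints follow the tree.
  marg <- matrix(0, 4, l)
  parent_of <- rep(NA_integer_, l)
  cond_of <- vector("list", l)
  if (!is.null(planted$edges)) {
    for (k in seq_len(nrow(planted$edges))) {
      ch <- planted$edges$child[k]
      parent_of[ch] <- planted$edges$parent[k]
      cond_of[[ch]] <- planted$conditionals[[k]]
    }
  }
  roots <- which(is.na(parent_of))
  for (r in roots) marg[, r] <- planted$marginals[, r]
  # joint of each node with every ancestor in its component
  joint <- array(NA_real_, dim = c(4, 4, l, l))   # [a,b,i,j] for i ancestor? use symmetric fill
  comp_of <- seq_len(l)
  pending <- which(!is.na(parent_of))
  while (length(pending)) {
    ready <- pending[!is.na(marg[1, parent_of[pending]])]
    for (ch in ready) {
      pa <- parent_of[ch]
      J <- sweep(cond_of[[ch]], 1, marg[, pa], `*`)
      # J[a,b] = P(parent = a, child = b)
      marg[, ch] <- colSums(J)
      joint[, , pa, ch] <- J
      joint[, , ch, pa] <- t(J)
      # chain joints through the parent for deeper ancestors
      for (anc in seq_len(l)) {
        if (anc %in% c(pa, ch)) next
        if (!all(is.na(joint[, , anc, pa]))) {
          Janc <- joint[, , anc, pa]          # P(anc = x, pa = a)
          Jac <- Janc %*% cond_of[[ch]]       # P(anc = x, ch = b)
          joint[, , anc, ch] <- Jac
          joint[, , ch, anc] <- t(Jac)
        }
      }
      comp_of[ch] <- comp_of[pa]
    }
    pending <- setdiff(pending, ready)
  }
  tens <- empty_pair_tensor(l)
  for (i in seq_len(l - 1)) for (j in (i + 1):l) {
    J <- joint[, , i, j]
    if (all(is.na(J))) J <- outer(marg[, i], marg[, j])
    tens[, , i, j] <- n * J
    tens[, , j, i] <- n * t(J)
  }
  tens
}
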