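# Dilogos: a sequence-logo generalization for pairwise-dependency motif
# models. A dilogo stacks (i) the familiar information-content logo of
# the marginals, (ii) an acyclic graph of the strongest direct
# dependencies, (iii) the full lower-triangle lattice of pairwise
# dependency posteriors, and (iv) per-dependent-position conditional
# logos, one row per parent letter.

#' Build the dilogo description of a DWT model
#'
#' Computes the marginal predictive probabilities, the full lattice of
#' edge posteriors, a loop-free set of dependencies chosen greedily from
#' the highest posterior downward (Kruskal-style, yielding a spanning
#' forest; edges below `min_posterior` are flagged for display pruning
#' only), and for every selected edge the conditional letter probabilities
#' `P(s_child | s_parent)`. Each tree component is rooted at its position
#' of highest marginal information content and edges are oriented away
#' from the root, so conserved anchor positions act as parents.
#'
#' @param model a `dwt_model` or `dwt_fit`.
#' @param min_posterior display threshold for dependency arrows and
#'   conditional logos.
#' @return object of class `dilogo_spec`: list with `marginals` (4 x l),
#'   `lattice` (l x l posterior matrix), `edges` (data.frame child,
#'   parent, posterior, display), and `conditionals` (list of 4 x 4
#'   row-stochastic tables named `"child|parent"`, rows = parent letter).
#' @export
build_dilogo <- function(model, min_posterior = 0.5) {
  if (inherits(model, "dwt_fit")) model <- model$model
  stopifnot(inherits(model, "dwt_model"))
  l <- model$l
  if (l < 2) stop("dilogos need l >= 2")
  w <- exp(model$logw)
  P <- edge_posteriors(model$logR)
  idx <- which(upper.tri(P), arr.ind = TRUE)
  ord <- order(P[idx], decreasing = TRUE)
  comp <- seq_len(l)
  sel <- matrix(0L, 0, 2)
  post <- numeric(0)
  for (k in ord) {   # greedy loop-free selection over all pairs
    i <- idx[k, 1]; j <- idx[k, 2]
    if (comp[i] != comp[j]) {
      sel <- rbind(sel, c(i, j))
      post <- c(post, P[i, j])
      comp[comp == comp[j]] <- comp[i]
    }
  }
  # orient: root components at max information content
  ic <- 2 + colSums(ifelse(w > 0, w * log2(w), 0))
  adj <- vector("list", l)
  for (k in seq_len(nrow(sel))) {
    adj[[sel[k, 1]]] <- c(adj[[sel[k, 1]]], sel[k, 2])
    adj[[sel[k, 2]]] <- c(adj[[sel[k, 2]]], sel[k, 1])
  }
  parent <- rep(NA_integer_, l)
  visited <- rep(FALSE, l)
  for (root in order(ic, decreasing = TRUE)) {
    if (visited[root]) next
    queue <- root; visited[root] <- TRUE
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (u in adj[[v]]) if (!visited[u]) {
        visited[u] <- TRUE
        parent[u] <- v
        queue <- c(queue, u)
      }
    }
  }
  edges <- data.frame(child = integer(0), parent = integer(0),
                      posterior = numeric(0))
  for (k in seq_len(nrow(sel))) {
    i <- as.integer(sel[k, 1]); j <- as.integer(sel[k, 2])
    ch <- if (isTRUE(parent[i] == j)) i else j
    pa <- if (ch == i) j else i
    edges <- rbind(edges, data.frame(child = ch, parent = pa,
                                     posterior = post[k]))
  }
  edges$display <- edges$posterior >= min_posterior
  ld <- model$lambda / 4
  conds <- lapply(seq_len(nrow(edges)), function(k) {
    ch <- edges$child[k]; pa <- edges$parent[k]
    tab <- t(model$tensor[, , ch, pa])    # rows = parent letter
    tab <- (tab + ld) / (model$counts[, pa] + 4 * ld)
    dimnames(tab) <- list(parent = DNA_LETTERS, child = DNA_LETTERS)
    tab
  })
  names(conds) <- sprintf("%d|%d", edges$child, edges$parent)
  structure(list(marginals = w, lattice = P, edges = edges,
                 conditionals = conds, min_posterior = min_posterior,
                 name = model$name),
            class = "dilogo_spec")
}

#' @export
print.dilogo_spec <- function(x, ...) {
  l <- ncol(x$marginals)
  cat("dilogo spec for '", x$name, "' (l = ", l, ")\n", sep = "")
  shown <- x$edges[x$edges$display, ]
  if (nrow(shown)) {
    cat("dependencies shown (posterior >= ", x$min_posterior, "):\n", sep = "")
    for (k in seq_len(nrow(shown)))
      cat(sprintf("  %d -> %d  (P = %.3f)\n", shown$parent[k],
                  shown$child[k], shown$posterior[k]))
  } else cat("no dependency reaches the display threshold\n")
  invisible(x)
}

svg_letter_colors <- c(A = "#109648", C = "#255C99", G = "#F7B32B",
                       T = "#D62839")

# one information-scaled letter stack at x, base y, cell width cw,
# full height H (= 2 bits)
svg_stack <- function(probs, x, ybase, cw, H) {
  ic <- 2 + sum(ifelse(probs > 0, probs * log2(probs), 0))
  h_total <- H * ic / 2
  ord <- order(probs)                     # draw small first, tall on top
  y <- ybase
  out <- character(0)
  for (a in ord) {
    h <- h_total * probs[a]
    if (h < 1e-3) next
    y <- y - h
    out <- c(out, sprintf(
      paste0("<text x=\"0\" y=\"0\" font-family=\"monospace\" ",
             "font-size=\"10\" font-weight=\"bold\" fill=\"%s\" ",
             "transform=\"translate(%.4f,%.4f) scale(%.4f,%.4f)\">%s</text>"),
      svg_letter_colors[a], x + 0.1 * cw, y + h,
      cw / 8, h / 8, DNA_LETTERS[a]))
  }
  out
}

#' Render a dilogo to SVG
#'
#' Pure function of the spec: the same `dilogo_spec` always yields a
#' byte-identical file. The SVG contains, top to bottom, the marginal
#' logo (stack height = 2 - H(w_i) bits), the dependency arrows, the
#' lower-triangle posterior lattice (one cell per position pair, red
#' intensity = posterior), and one 4-row conditional logo block per
#' displayed dependent position (rows labeled by the parent letter).
#'
#' @param spec a [build_dilogo()] result.
#' @param path output file path (`.svg`).
#' @return `path`, invisibly.
#' @export
render_dilogo <- function(spec, path) {
  stopifnot(inherits(spec, "dilogo_spec"))
  l <- ncol(spec$marginals)
  cw <- 24; H <- 60                       # cell width, full stack height
  mx <- 40                                # left margin
  logo_y <- 20 + H
  arrow_h <- 50
  lat_y0 <- logo_y + arrow_h + 20
  cell <- 16
  lat_h <- l * cell
  shown <- spec$edges[spec$edges$display, , drop = FALSE]
  cond_h <- if (nrow(shown)) 30 + nrow(shown) * 4 * 34 else 0
  width <- mx + l * cw + 40
  height <- lat_y0 + lat_h + 30 + cond_h + 20
  out <- c(sprintf(
    paste0("<svg xmlns=\"http://www.w3.org/2000/svg\" width=\"%d\" ",
           "height=\"%d\" viewBox=\"0 0 %d %d\">"),
    width, height, width, height),
    sprintf("<title>dilogo %s</title>", spec$name))
  # marginal logo
  for (i in seq_len(l)) {
    out <- c(out, svg_stack(spec$marginals[, i], mx + (i - 1) * cw,
                            logo_y, cw, H))
    out <- c(out, sprintf(
      paste0("<text x=\"%.4f\" y=\"%d\" font-size=\"8\" ",
             "text-anchor=\"middle\">%d</text>"),
      mx + (i - 0.5) * cw, logo_y + 12, i))
  }
  # dependency arrows (quadratic arcs parent -> child)
  for (k in seq_len(nrow(shown))) {
    x1 <- mx + (shown$parent[k] - 0.5) * cw
    x2 <- mx + (shown$child[k] - 0.5) * cw
    ymid <- logo_y + 18 + 14 * abs(shown$parent[k] - shown$child[k]) / l
    out <- c(out, sprintf(
      paste0("<path d=\"M %.4f %d Q %.4f %.4f %.4f %d\" fill=\"none\" ",
             "stroke=\"#333333\" stroke-width=\"1.2\"/>"),
      x1, logo_y + 16, (x1 + x2) / 2, ymid + 18, x2, logo_y + 16),
      sprintf(
        paste0("<circle cx=\"%.4f\" cy=\"%d\" r=\"2.2\" ",
               "fill=\"#333333\"/>"), x2, logo_y + 16))
  }
  # posterior lattice, lower triangle (row i, col j for j < i)
  for (i in seq_len(l)) for (j in seq_len(l)) {
    if (j >= i) next
    p <- spec$lattice[i, j]
    out <- c(out, sprintf(
      paste0("<rect class=\"lattice\" x=\"%.4f\" y=\"%.4f\" width=\"%d\" ",
             "height=\"%d\" fill=\"#CC0000\" fill-opacity=\"%.4f\" ",
             "stroke=\"#999999\" stroke-width=\"0.4\"/>"),
      mx + (j - 1) * cell, lat_y0 + (i - 1) * cell, cell, cell, p))
  }
  for (i in seq_len(l))
    out <- c(out, sprintf(
      paste0("<text x=\"%.4f\" y=\"%.4f\" font-size=\"7\" ",
             "text-anchor=\"middle\">%d</text>"),
      mx + (i - 0.5) * cell, lat_y0 + lat_h + 10, i))
  # conditional logos, one block per displayed edge
  y0 <- lat_y0 + lat_h + 30
  for (k in seq_len(nrow(shown))) {
    key <- sprintf("%d|%d", shown$child[k], shown$parent[k])
    tab <- spec$conditionals[[key]]
    out <- c(out, sprintf(
      paste0("<text x=\"%d\" y=\"%.4f\" font-size=\"9\">P(pos %d | ",
             "pos %d)</text>"),
      mx, y0 + 10, shown$child[k], shown$parent[k]))
    for (a in 1:4) {
      yb <- y0 + 18 + a * 34
      out <- c(out, sprintf(
        paste0("<text x=\"%d\" y=\"%.4f\" font-size=\"9\" ",
               "fill=\"%s\">%s</text>"),
        mx - 14, yb - 8, svg_letter_colors[a], DNA_LETTERS[a]))
      out <- c(out, svg_stack(tab[a, ], mx, yb, cw, 30))
    }
    y0 <- y0 + 30 + 4 * 34
  }
  out <- c(out, "</svg>")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(out, con, sep = "\n")
  invisible(path)
}

#' Write the dilogo spec as structured text blocks
#'
#' TSV sidecar with `#MARGINALS`, `#LATTICE`, `#EDGES` and `#CONDITIONAL`
#' blocks for downstream use.
#'
#' @inheritParams render_dilogo
#' @param path output text file.
#' @return `path`, invisibly.
#' @export
write_dilogo_spec <- function(spec, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  l <- ncol(spec$marginals)
  fmt <- function(x) sprintf("%.12g", x)
  writeLines(sprintf("#DILOGO name=%s l=%d", spec$name, l), con)
  writeLines("#MARGINALS", con)
  for (a in 1:4)
    writeLines(paste(c(DNA_LETTERS[a], fmt(spec$marginals[a, ])),
                     collapse = "\t"), con)
  writeLines("#LATTICE", con)
  for (i in seq_len(l))
    writeLines(paste(fmt(spec$lattice[i, ]), collapse = "\t"), con)
  writeLines("#EDGES\tchild\tparent\tposterior\tdisplay", con)
  for (k in seq_len(nrow(spec$edges)))
    writeLines(sprintf("edge\t%d\t%d\t%s\t%d", spec$edges$child[k],
                       spec$edges$parent[k], fmt(spec$edges$posterior[k]),
                       as.integer(spec$edges$display[k])), con)
  for (k in seq_along(spec$conditionals)) {
    writeLines(sprintf("#CONDITIONAL %s", names(spec$conditionals)[k]), con)
    tab <- spec$conditionals[[k]]
    for (a in 1:4)
      writeLines(paste(c(DNA_LETTERS[a], fmt(tab[a, ])), collapse = "\t"),
                 con)
  }
  invisible(path)
}
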