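# File formats: FASTA input, and the package's plain-text PSWM / DWT
# model files. Coordinates in all user-facing tables are 1-based
# inclusive; model files round-trip through 12-significant-digit decimals.

#' Read sequences from a FASTA file
#'
#' Accepts wrapped or unwrapped records, case-insensitively; sequences are
#' uppercased and must contain only A, C, G, T, N.
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  for (k in seq_along(seqs)) {
    if (nchar(seqs[k]) == 0L)
      stop("empty FASTA record '", names(seqs)[k], "'")
    bad <- regmatches(seqs[k], regexpr("[^ACGTN]", seqs[k]))
    if (length(bad) && nchar(bad))
      stop("record '", names(seqs)[k], "' contains invalid character '",
           bad, "'")
  }
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param sequences named character vector.
#' @param path output file.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path, width = 70L) {
  ids <- names(sequences) %||% paste0("seq_", seq_along(sequences))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (k in seq_along(sequences)) {
    writeLines(paste0(">", ids[k]), con)
    s <- sequences[[k]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

fmt12 <- function(x) sprintf("%.12g", x)

#' Write a PSWM count matrix file
#'
#' Plain text: a `#PSWM` header carrying `lambda` and `name`, then l rows
#' of 4 counts ordered A C G T.
#'
#' @param model a `pswm_model` (or any motif model; marginal counts are
#'   written).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pswm <- function(model, path) {
  stopifnot(inherits(model, "motif_model"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("#PSWM length=%d lambda=%s name=%s",
                     model$l, fmt12(model$lambda), model$name), con)
  for (i in seq_len(model$l))
    writeLines(paste(fmt12(model$counts[, i]), collapse = " "), con)
  invisible(path)
}

parse_header <- function(line, tag) {
  if (!startsWith(line, paste0("#", tag)))
    stop("expected a #", tag, " header, got: ", line)
  kv <- regmatches(line, gregexpr("[a-zA-Z_]+=[^ ]+", line))[[1]]
  vals <- sub("^[a-zA-Z_]+=", "", kv)
  names(vals) <- sub("=.*$", "", kv)
  vals
}

#' Read a PSWM count matrix file
#'
#' @param path file written by [write_pswm()] (or any `#PSWM` file).
#' @return a `pswm_model`.
#' @export
read_pswm <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- parse_header(lines[1], "PSWM")
  rows <- lapply(lines[-1], function(x) as.numeric(strsplit(trimws(x),
                                                            "[ \t]+")[[1]]))
  if (any(lengths(rows) != 4L)) stop("PSWM rows must have 4 counts")
  counts <- t(do.call(rbind, rows))
  if (!is.na(hdr["length"]) && as.integer(hdr["length"]) != ncol(counts))
    stop("PSWM header length disagrees with the number of rows")
  pswm_model(counts,
             lambda = if (is.na(hdr["lambda"])) 0.5
                      else as.numeric(hdr["lambda"]),
             name = if (is.na(hdr["name"])) "motif" else hdr["name"])
}

#' Write a DWT model file
#'
#' Whitespace-delimited text: a header
#' `#DWT length=<l> lambda=<lambda> name=<id>`, then one line per
#' `(i, j, a, b)` with `i < j` (1-based positions): `i j a b count` —
#' `16 l (l-1) / 2` lines in total, counts formatted with 12 significant
#' digits so that read/write round-trips are bit-exact at that precision.
#'
#' @param model a `dwt_model` or `adj_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dwt <- function(model, path) {
  stopifnot(inherits(model, c("dwt_model", "adj_model")))
  con <- file(path, open = "wt")
  on.exit(close(con))
  tag <- if (inherits(model, "adj_model")) "ADJ" else "DWT"
  writeLines(sprintf("#%s length=%d lambda=%s name=%s",
                     tag, model$l, fmt12(model$lambda), model$name), con)
  l <- model$l
  if (tag == "ADJ") {
    pairs <- cbind(seq_len(l - 1L), seq_len(l - 1L) + 1L)
  } else {
    pairs <- do.call(rbind, lapply(seq_len(l - 1L), function(i)
      cbind(i, (i + 1L):l)))
  }
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    for (a in 1:4) for (b in 1:4)
      writeLines(sprintf("%d %d %s %s %s", i, j, DNA_LETTERS[a],
                         DNA_LETTERS[b], fmt12(model$tensor[a, b, i, j])),
                 con)
  }
  invisible(path)
}

#' Read a DWT (or ADJ) model file
#'
#' Validates completeness of the pair list and marginal consistency of
#' the pair counts (every position's letter totals must agree across all
#' partner positions) before constructing the model.
#'
#' @param path file written by [write_dwt()].
#' @return a `dwt_model` (header `#DWT`) or `adj_model` (header `#ADJ`).
#' @export
read_dwt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  tag <- if (startsWith(lines[1], "#ADJ")) "ADJ" else "DWT"
  hdr <- parse_header(lines[1], tag)
  l <- as.integer(hdr["length"])
  if (is.na(l) || l < 2) stop("missing or invalid length in header")
  lambda <- if (is.na(hdr["lambda"])) 0.5 else as.numeric(hdr["lambda"])
  name <- if (is.na(hdr["name"])) "motif" else unname(hdr["name"])
  toks <- strsplit(trimws(lines[-1]), "[ \t]+")
  if (any(lengths(toks) != 5L)) stop("DWT lines must be: i j a b count")
  i <- as.integer(vapply(toks, `[`, "", 1))
  j <- as.integer(vapply(toks, `[`, "", 2))
  a <- match(vapply(toks, `[`, "", 3), DNA_LETTERS)
  b <- match(vapply(toks, `[`, "", 4), DNA_LETTERS)
  cnt <- as.numeric(vapply(toks, `[`, "", 5))
  if (anyNA(i) || anyNA(j) || anyNA(a) || anyNA(b) || anyNA(cnt))
    stop("malformed DWT line(s)")
  if (any(i >= j) || any(i < 1) || any(j > l)) stop("invalid position pair")
  if (any(cnt < 0)) stop("negative counts")
  tens <- empty_pair_tensor(l)
  for (k in seq_along(i)) {
    tens[a[k], b[k], i[k], j[k]] <- cnt[k]
    tens[b[k], a[k], j[k], i[k]] <- cnt[k]
  }
  expected <- if (tag == "ADJ") 16L * (l - 1L) else 16L * l * (l - 1L) / 2L
  if (length(i) != expected)
    stop("expected ", expected, " pair-count lines, found ", length(i))
  if (tag == "ADJ") {
    adj_model(tens, lambda, name)
  } else {
    ok <- tryCatch(check_pair_tensor(tens), error = function(e) e)
    if (inherits(ok, "error"))
      stop("pair counts in ", path, " are inconsistent: ",
           conditionMessage(ok))
    dwt_model(tens, lambda, name)
  }
}
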