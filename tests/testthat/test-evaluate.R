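# Decoy generation, precision-recall, and the randomized control.

test_that("average precision: worked example and edge cases", {
  pr <- precision_recall(c(3, 2, 1, 0), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(pr$average_precision, 5 / 6, tolerance = 1e-12)
  # perfect separation
  expect_equal(precision_recall(c(5, 4, 1, 0),
                                c(TRUE, TRUE, FALSE, FALSE))$average_precision,
               1)
  # worst ranking: positives last
  expect_equal(precision_recall(c(0, 1, 5, 4),
                                c(TRUE, TRUE, FALSE, FALSE))$average_precision,
               mean(c(1 / 3, 2 / 4)))
  expect_error(precision_recall(c(1, 2), c(TRUE, TRUE)), "both")
})

test_that("ties enter the predicted-positive set together", {
  # two tied at the top: one positive, one negative
  pr <- precision_recall(c(2, 2, 1), c(TRUE, FALSE, TRUE))
  expect_equal(pr$curve$precision, c(1 / 2, 2 / 3))
  expect_equal(pr$average_precision, 0.5 * 0.5 + 0.5 * 2 / 3)
})

test_that("AP is invariant under monotone score transformations", {
  set.seed(91)
  sc <- rnorm(200)
  lab <- runif(200) < plogis(sc)
  a1 <- precision_recall(sc, lab)$average_precision
  expect_equal(precision_recall(exp(sc), lab)$average_precision, a1)
  expect_equal(precision_recall(10 * sc - 3, lab)$average_precision, a1)
})

test_that("random scores give AP near the positive fraction", {
  set.seed(92)
  aps <- replicate(50, precision_recall(
    runif(2500), rep(c(TRUE, FALSE), c(500, 2000)))$average_precision)
  expect_lt(abs(mean(aps) - 0.2), 0.03)
})

test_that("Markov decoys match length and pooled dinucleotide composition", {
  set.seed(93)
  src <- vapply(1:100, function(i)
    paste(sample(c("A", "C", "G", "T"), 80, TRUE,
                 prob = c(.4, .1, .2, .3)), collapse = ""), character(1))
  dec <- generate_decoys(src, m = 1, seed = 17)
  expect_equal(nchar(dec), nchar(src))
  dinuc <- function(seqs) {
    v <- unlist(lapply(seqs, function(s) {
      e <- dwtmotif:::encode_seq(s)
      head(e, -1) * 4 + tail(e, -1)
    }))
    tabulate(v + 1, 16)
  }
  o <- dinuc(src); d <- dinuc(dec)
  expect_gt(suppressWarnings(chisq.test(rbind(o, d))$p.value), 0.001)
  # determinism
  expect_identical(dec, generate_decoys(src, m = 1, seed = 17))
  # homopolymer sources give homopolymer decoys
  expect_equal(generate_decoys(c("AAAAA", "AAAAAA"), m = 2, seed = 1),
               c("AAAAA", "AAAAA", "AAAAAA", "AAAAAA"))
})

test_that("Euler shuffle preserves each sequence's dinucleotide counts", {
  set.seed(94)
  dinuc_tab <- function(s) {
    e <- dwtmotif:::encode_seq(s)
    tabulate(head(e, -1) * 4 + tail(e, -1) + 1, 16)
  }
  for (r in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
    d <- generate_decoys(s, m = 1, seed = r, method = "shuffle")
    expect_equal(dinuc_tab(d), dinuc_tab(s))
    expect_equal(substr(d, 1, 1), substr(s, 1, 1))   # Euler path endpoints
    expect_equal(substr(d, 60, 60), substr(s, 60, 60))
  }
})

test_that("benchmark split is an exact seed-stable partition", {
  seqs <- paste0("s", 1:1000)
  sp <- benchmark_split(seqs, seed = 3)
  expect_length(sp$train, 500)
  expect_length(sp$test, 500)
  expect_setequal(c(sp$train, sp$test), seqs)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_identical(sp, benchmark_split(seqs, seed = 3))
})

test_that("randomized control removes dependencies but keeps marginals", {
  planted <- quick_coupled(6, coupling = 0.9)
  m <- dwt_model(sample_sites(planted, 400, seed = 95))
  # the original coupled model has a confident planted edge
  expect_gt(edge_posteriors(m$logR)[1, 6], 0.99)
  ctrl <- randomized_dependency_control(m, seed = 96)
  expect_identical(
    ctrl$posteriors,
    randomized_dependency_control(m, seed = 96)$posteriors)
  # marginals preserved within sampling noise
  w0 <- exp(m$logw); w1 <- exp(ctrl$control_model$logw)
  expect_lt(max(abs(w0 - w1)), 4 * sqrt(0.25 / 400) + 0.02)
  expect_s3_class(ctrl$summary, "data.frame")
})

test_that("held-out AP: DWT never trails PSWM badly, beats it under coupling", {
  set.seed(97)
  planted <- quick_coupled(6, coupling = 0.9)
  bg <- background_model(c(.3, .2, .2, .3))
  diffs <- numeric(3)
  for (r in 1:3) {
    sites <- sample_sites(planted, 200, seed = 300 + r)
    peaks <- embed_in_background(sites, 60, bg, seed = 400 + r)$sequences
    sp <- benchmark_split(peaks, seed = r)
    dm <- dwt_model(sample_sites(planted, 200, seed = 500 + r))
    pm <- as_pswm(dm)
    test <- sp$test
    dec <- generate_decoys(unname(test), m = 4, seed = 600 + r)
    labs <- rep(c(TRUE, FALSE), c(length(test), length(dec)))
    apd <- precision_recall(c(sequence_energies(dm, test, bg),
                              sequence_energies(dm, dec, bg)),
                            labs)$average_precision
    app <- precision_recall(c(sequence_energies(pm, test, bg),
                              sequence_energies(pm, dec, bg)),
                            labs)$average_precision
    diffs[r] <- apd - app
  }
  expect_gte(min(diffs), -0.02)
  expect_gt(mean(diffs), 0)
})
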