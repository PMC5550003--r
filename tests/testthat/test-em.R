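# EM motif inference: likelihood, E0 optimization, posteriors, updates.

test_that("dataset log-likelihood matches direct arithmetic", {
  # E(S) = 0, L_S = 1: numerator equals denominator for any E0
  expect_equal(dataset_log_likelihood(rep(0, 5), rep(1, 5), 0.7), 0)
  expect_equal(dataset_log_likelihood(rep(0, 5), rep(1, 5), -3), 0)
  # E0 -> -inf limit: sum of E(S)
  E <- c(1, 2, 3)
  expect_equal(dataset_log_likelihood(E, rep(10, 3), -200), sum(E),
               tolerance = 1e-10)
  # closed-form toy
  E0 <- 0
  expect_equal(dataset_log_likelihood(E, rep(10, 3), E0),
               sum(log((exp(E) + 10 * exp(E0)) / (1 + exp(E0)))),
               tolerance = 1e-10)
  expect_error(dataset_log_likelihood(numeric(0), integer(0), 0), "empty")
})

test_that("E0 optimizer finds the likelihood maximum", {
  # degenerate: E(S) = log L_S makes every E0 stationary; convention 0
  expect_equal(optimize_E0(log(c(10, 20)), c(10, 20)), 0)
  # grid-search oracle on random instances
  set.seed(41)
  for (r in 1:5) {
    E <- runif(20, -2, 8)
    LS <- sample(50:200, 20, replace = TRUE)
    E0 <- suppressWarnings(optimize_E0(E, LS))
    Lbest <- dataset_log_likelihood(E, LS, E0)
    grid <- seq(-50, 50, length.out = 100001)
    Lgrid <- max(vapply(grid, function(e)
      dataset_log_likelihood(E, LS, e), numeric(1)))
    expect_gte(Lbest, Lgrid - 1e-5)
    # local optimality
    expect_gte(Lbest, dataset_log_likelihood(E, LS, min(E0 + 0.01, 50)) - 1e-9)
    expect_gte(Lbest, dataset_log_likelihood(E, LS, max(E0 - 0.01, -50)) - 1e-9)
  }
  # single sequence, L_S > exp(E): non-specific binding dominates and
  # the optimum sits at the top of the bracket (condition still ~ 0)
  E0 <- suppressWarnings(optimize_E0(5, 200))
  g <- function(e) 200 / (exp(5) + 200 * exp(e)) - 1 / (1 + exp(e))
  expect_lt(abs(g(E0)), 1e-8)
  expect_gte(dataset_log_likelihood(5, 200, E0),
             dataset_log_likelihood(5, 200, E0 + 0.01) - 1e-10)
  expect_gte(dataset_log_likelihood(5, 200, E0),
             dataset_log_likelihood(5, 200, E0 - 0.01) - 1e-10)
  # strong signal (exp(E) > L_S): likelihood is maximized at the lower
  # bracket end, no interior maximum
  e0 <- suppressWarnings(optimize_E0(5, 100))
  expect_equal(e0, -50)
})

test_that("site posteriors follow the occupancy formula", {
  # toy: E = {0, log 3}, L_S = 2, E0 = 0 -> posteriors 1/6, 3/6
  p <- site_posteriors(c(0, log(3)), 0)
  expect_equal(p, c(1 / 6, 3 / 6), tolerance = 1e-12)
  # sum equals sequence-level binding probability
  E <- c(0.3, -1, 2)
  E0 <- 0.5
  ES <- dwtmotif:::logsumexp(E)
  expect_equal(sum(site_posteriors(E, E0)),
               exp(ES) / (exp(ES) + 3 * exp(E0)), tolerance = 1e-12)
  # E0 -> -inf with one dominant site: posterior -> 1
  p <- site_posteriors(c(10, 0, 0), -200)
  expect_equal(p[1], 1, tolerance = 1e-4)
})

test_that("pair-count updates are posterior-weighted indicator tensors", {
  l <- 3
  enc <- list(dwtmotif:::encode_seq("ACGT"))   # two offsets per strand
  encr <- lapply(enc, dwtmotif:::revcomp_enc)
  wm <- matrix(0.25, 4, l)
  # posterior 1 on the first forward segment ACG
  post <- list(c(1, 0, 0, 0))
  tens <- dwtmotif:::update_pair_counts(enc, encr, post, l, wm)
  expect_equal(tens[1, 2, 1, 2], 1)   # A at 1, C at 2
  expect_equal(tens[2, 3, 2, 3], 1)   # C at 2, G at 3
  expect_equal(sum(tens[, , 1, 2]), 1)
  # zero posteriors give the zero tensor
  z <- dwtmotif:::update_pair_counts(enc, encr, list(rep(0, 4)), l, wm)
  expect_equal(sum(z), 0)
  # convex combination of two segments
  post <- list(c(0.25, 0.75, 0, 0))
  t2 <- dwtmotif:::update_pair_counts(enc, encr, post, l, wm)
  expect_equal(t2[1, 2, 1, 2], 0.25)   # ACG with weight 1/4
  expect_equal(t2[2, 3, 1, 2], 0.75)   # CGT with weight 3/4
  # reverse-strand segments contribute reverse-complemented letters
  post <- list(c(0, 0, 1, 0))          # first reverse offset: revcomp = ACGT -> ACG
  t3 <- dwtmotif:::update_pair_counts(enc, encr, post, l, wm)
  expect_equal(t3[1, 2, 1, 2], 1)
  # mass conservation: same total for every pair
  post <- list(runif(4))
  t4 <- dwtmotif:::update_pair_counts(enc, encr, post, l, wm)
  totals <- c(sum(t4[, , 1, 2]), sum(t4[, , 1, 3]), sum(t4[, , 2, 3]))
  expect_equal(totals, rep(sum(post[[1]]), 3), tolerance = 1e-12)
})

test_that("N positions are soft-imputed from the model marginals", {
  l <- 2
  enc <- list(c(0L, 4L))               # AN
  encr <- lapply(enc, dwtmotif:::revcomp_enc)
  wm <- cbind(c(0.25, 0.25, 0.25, 0.25), c(0.7, 0.1, 0.1, 0.1))
  tens <- dwtmotif:::update_pair_counts(enc, encr, list(c(1, 0)), l, wm)
  expect_equal(tens[1, , 1, 2], wm[, 2], ignore_attr = TRUE)
  expect_equal(sum(tens[, , 1, 2]), 1, tolerance = 1e-12)
})

test_that("EM improves the likelihood and returns the best state", {
  suite <- fixture_suite()
  sites <- sample_sites(suite$one_edge, 120, seed = 61)
  peaks <- embed_in_background(sites, 60, background_model(), seed = 62)
  init <- pswm_model(site_count_matrix(sample_sites(suite$one_edge, 60,
                                                    seed = 63)))
  for (kind in c("pswm", "adj", "dwt")) {
    fit <- dwt_em(peaks$sequences, init, kind = kind, seed = 1,
                  max_iter = 40)
    expect_s3_class(fit, "dwt_fit")
    expect_equal(fit$model$l, 10)
    # the returned state is the best seen, and beats the initial model
    expect_equal(fit$logLik, max(fit$trace$logLik))
    expect_gt(fit$logLik, fit$trace$logLik[1])
    if (kind == "pswm") {
      # The count-replacement M-step uses the Dirichlet predictive, not
      # the bare ML update, so monotonicity is only guaranteed in the
      # large-count regime; at this deliberately tiny fixture only the
      # PSWM trace is reliably monotone. All three kinds are checked at
      # study scale in the acceptance suite.
      expect_gte(min(diff(fit$trace$logLik)), -1e-6)
    }
  }
})

test_that("EM reaches a fixed point: converged counts stop moving", {
  suite <- fixture_suite()
  sites <- sample_sites(suite$null, 150, seed = 64)
  init <- pswm_model(site_count_matrix(sites))
  fit <- dwt_em(sites, init, kind = "pswm", tol = 1e-14, max_iter = 80)
  # one further iteration from the converged counts changes them
  # negligibly relative to the effective site mass
  fit2 <- dwt_em(sites, fit$model$counts, kind = "pswm", max_iter = 1)
  expect_lt(max(abs(fit2$model$counts - fit$model$counts)),
            1e-8 * max(1, fit$model$n))
})

test_that("restarts and seeds are reproducible", {
  suite <- fixture_suite()
  sites <- sample_sites(suite$null, 60, seed = 65)
  peaks <- embed_in_background(sites, 40, background_model(), seed = 66)
  init <- pswm_model(site_count_matrix(sites))
  f1 <- dwt_em(peaks$sequences, init, kind = "pswm", restarts = 2,
               seed = 9, max_iter = 10)
  f2 <- dwt_em(peaks$sequences, init, kind = "pswm", restarts = 2,
               seed = 9, max_iter = 10)
  expect_equal(f1$logLik, f2$logLik)
  expect_equal(f1$model$counts, f2$model$counts)
})

test_that("errors: motif longer than sequences without padding", {
  init <- pswm_model(matrix(1, 4, 12))
  expect_error(dwt_em(c("ACGTACGT"), init, kind = "pswm"), "pad")
})

test_that("fit methods: coef, logLik, predict, summary, simulate", {
  sites <- sample_sites(quick_coupled(5, 0.9), 150, seed = 71)
  fit <- dwt_em(sites, pswm_model(site_count_matrix(sites)), kind = "dwt",
                max_iter = 5)
  w <- coef(fit)
  expect_equal(unname(colSums(w)), rep(1, 5), tolerance = 1e-9)
  expect_true(is.finite(as.numeric(logLik(fit))))
  e <- predict(fit, c("ACGTACG", "TTTTTTT"))
  expect_length(e, 2)
  s <- summary(fit)
  expect_s3_class(s, "summary.dwt_fit")
  expect_equal(nchar(s$consensus), 5)
  sims <- simulate(fit, nsim = 50, seed = 2)
  expect_length(sims, 50)
  expect_true(all(nchar(sims) == 5))
  expect_identical(sims, simulate(fit, nsim = 50, seed = 2))
})
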