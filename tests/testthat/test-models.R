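# PSWM / ADJ / DWT predictive probabilities and binding energies.

test_that("PSWM predictive matches the closed form", {
  l <- 4
  m0 <- pswm_model(matrix(0, 4, l))          # prior only
  s <- matrix(0L, l, 1)
  expect_equal(predictive_logprob(m0, s), l * log(1 / 4))
  cnt <- matrix(0, 4, l); cnt[1, ] <- 2      # counts (2,0,0,0) everywhere
  m2 <- pswm_model(cnt)
  expect_equal(predictive_logprob(m2, s), l * log(0.625))
  expect_error(predictive_logprob(m2, matrix(0L, 3, 1)), "length")
})

test_that("all three model kinds are exactly normalized", {
  set.seed(21)
  for (l in c(3, 5)) {
    sites <- random_sites(l, 50)
    grid <- all_sites(l)
    for (model in list(pswm_model(site_count_matrix(sites)),
                       adj_model(sites), dwt_model(sites))) {
      expect_equal(sum(exp(predictive_logprob(model, grid))), 1,
                   tolerance = 1e-9)
    }
  }
  # normalization also holds for strongly coupled training sites
  coupled <- dwt_model(sample_sites(quick_coupled(4), 300, seed = 3))
  expect_equal(sum(exp(predictive_logprob(coupled, all_sites(4)))), 1,
               tolerance = 1e-9)
})

test_that("DWT reduces exactly to the PSWM when no dependency evidence exists", {
  # n = 0: zero tensor
  l <- 4
  z <- dwtmotif:::empty_pair_tensor(l)
  expect_equal(predictive_logprob(dwt_model(z), all_sites(l)),
               predictive_logprob(pswm_model(matrix(0, 4, l)), all_sites(l)),
               tolerance = 1e-12)
  # uniform-marginal outer products at n <= 1 (delta vanishes identically)
  for (n in c(0.25, 1)) {
    marg <- matrix(n / 4, 4, l)
    tens <- outer_tensor(marg, n)
    expect_equal(predictive_logprob(dwt_model(tens), all_sites(l)),
                 predictive_logprob(pswm_model(marg), all_sites(l)),
                 tolerance = 1e-10)
  }
})

test_that("one-site DWT model scores its own site above single mismatches", {
  site <- "ACGT"
  m <- dwt_model(site)
  own <- predictive_logprob(m, site)
  for (i in 1:4) for (a in c("A", "C", "G", "T")) {
    mut <- site
    substr(mut, i, i) <- a
    if (mut == site) next
    expect_gt(own, predictive_logprob(m, mut))
  }
})

test_that("ADJ equals DWT at l = 2 and factorizes as a chain", {
  set.seed(22)
  sites <- random_sites(2, 30)
  expect_equal(predictive_logprob(adj_model(sites), all_sites(2)),
               predictive_logprob(dwt_model(sites), all_sites(2)),
               tolerance = 1e-10)
  # chain factorization: P(s1) * prod P(s_i | s_{i-1})
  sites5 <- random_sites(5, 40)
  am <- adj_model(sites5)
  tens <- dwtmotif:::pair_tensor_from_sites(sites5)
  marg <- site_count_matrix(sites5)
  n <- 40; lam <- 0.5; ld <- lam / 4
  s <- c(2L, 0L, 3L, 1L, 2L)
  manual <- log((marg[s[1] + 1, 1] + lam) / (n + 4 * lam))
  for (i in 2:5) {
    manual <- manual +
      log((tens[s[i - 1] + 1, s[i] + 1, i - 1, i] + ld) /
            (marg[s[i - 1] + 1, i - 1] + 4 * ld))
  }
  expect_equal(predictive_logprob(am, matrix(s, 5)), unname(manual),
               tolerance = 1e-10)
})

test_that("N letters are ratio-neutral in predictives and energies", {
  m <- dwt_model(sample_sites(quick_coupled(4), 100, seed = 5))
  bg <- background_model()
  # all-N segment: energy exactly 0
  expect_equal(segment_energy(m, "NNNN", bg), 0)
  # an N at one position: the other positions still contribute
  eN <- segment_energy(m, "ANNN", bg)
  expect_true(is.finite(eN))
  # for the PSWM part alone, N equals dropping the position
  p <- as_pswm(m)
  expect_equal(predictive_logprob(p, "ANNN"), m$logw[1, 1],
               ignore_attr = TRUE)
})

test_that("sequence energies enumerate both strands with log-sum-exp total", {
  m <- dwt_model(sample_sites(quick_coupled(4), 100, seed = 6))
  bg <- background_model()
  prof <- score_sequence(m, "ACGTACGTACG", bg)
  K <- 11 - 4 + 1
  expect_equal(prof$L_S, 2 * K)
  expect_equal(prof$total, dwtmotif:::logsumexp(prof$segments$energy),
               tolerance = 1e-10)
  expect_gte(prof$total, max(prof$segments$energy))
  # reverse-complement consistency: same segment multiset, same E(S)
  expect_equal(score_sequence(m, dwtmotif:::revcomp("ACGTACGTACG"), bg)$total,
               prof$total, tolerance = 1e-10)
  # |S| = l: exactly one segment per strand
  p1 <- score_sequence(m, "ACGT", bg)
  expect_equal(p1$L_S, 2L)
  expect_error(score_sequence(m, "AC", bg), "shorter")
  expect_equal(score_sequence(m, "AC", bg, pad = 2)$L_S, 2L * 3L)
})

test_that("a palindromic site on a palindromic model doubles the strand sum", {
  # ACGT is its own reverse complement
  m <- pswm_model(site_count_matrix(c("ACGT", "ACGT")))
  bg <- background_model()
  prof <- score_sequence(m, "ACGT", bg)
  e <- segment_energy(m, "ACGT", bg)
  expect_equal(prof$total, e + log(2), tolerance = 1e-10)
})

test_that("DWT beats PSWM on held-out coupled sites", {
  set.seed(30)
  planted <- quick_coupled(5, coupling = 0.9)
  wins <- 0
  for (r in 1:10) {
    train <- sample_sites(planted, 500, seed = 100 + r)
    test <- sample_sites(planted, 200, seed = 900 + r)
    dm <- dwt_model(train)
    pm <- pswm_model(site_count_matrix(train))
    gain <- mean(predictive_logprob(dm, test)) -
      mean(predictive_logprob(pm, test))
    wins <- wins + (gain > 0)
  }
  expect_gte(wins, 9)
})

test_that("cached model quantities are consistent", {
  sites <- sample_sites(quick_coupled(5), 200, seed = 8)
  m <- dwt_model(sites)
  expect_equal(m$log_D, tree_logdet(m$logR)$log_D, tolerance = 1e-9)
  expect_equal(m$logR, dwtmotif:::dependency_matrix(m$tensor, m$lambda),
               tolerance = 1e-10)
  marg <- dwtmotif:::tensor_marginals(m$tensor)
  expect_equal(unname(m$counts), unname(marg), tolerance = 1e-9)
})

test_that("background model validates and fits letter frequencies", {
  b <- background_model(c("AACCGGTT", "AATT"))
  expect_equal(sum(b$b), 1)
  expect_equal(unname(b$b["A"]), 4 / 12)
  expect_error(background_model(c(1, 2, 3)), "4 positive")
  expect_error(background_model(c(-1, 1, 1, 1)), "positive")
})
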