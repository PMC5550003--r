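# Dirichlet-marginal column and pair probabilities, and the dependency
# evidence ratio.

test_that("column marginal matches hand-derived values", {
  expect_equal(column_log_prob(c(0, 0, 0, 0)), 0)
  expect_equal(column_log_prob(c(1, 0, 0, 0)), log(1 / 4))
  # sequential predictive: (1/4) * (1 + 1/2)/(1 + 2)
  expect_equal(column_log_prob(c(2, 0, 0, 0)), log(1 / 8))
  # direct log-gamma evaluation at lambda = 1
  lam <- 1
  expect_equal(column_log_prob(c(2, 1, 0, 0), lam),
               lgamma(4) - lgamma(3 + 4) + lgamma(3) + lgamma(2) +
                 2 * lgamma(1) - 4 * lgamma(1))
  expect_error(column_log_prob(c(-1, 0, 0, 0)), "non-negative")
})

test_that("pair marginal matches hand-derived values", {
  z <- matrix(0, 4, 4)
  expect_equal(pair_log_prob(z), 0)
  one <- z; one[1, 1] <- 1
  expect_equal(pair_log_prob(one), log(1 / 16))
  two <- z; two[1, 1] <- 2
  # Gamma(2)/Gamma(3) * (9/8)(1/8) with lambda' = 1/8
  expect_equal(pair_log_prob(two), log(0.0234375))
})

test_that("dependency evidence is zero for one observation, log 1.5 for two", {
  one <- matrix(0, 4, 4); one[1, 1] <- 1
  expect_equal(dependency_log_ratio(one), 0)
  two <- matrix(0, 4, 4); two[1, 1] <- 2
  expect_equal(dependency_log_ratio(two), log(1.5))
  # relabeling invariance: AA/CC coupling equals AC/CA coupling
  a <- matrix(0, 4, 4); a[1, 1] <- 1; a[2, 2] <- 1
  b <- matrix(0, 4, 4); b[1, 2] <- 1; b[2, 1] <- 1
  expect_equal(dependency_log_ratio(a), dependency_log_ratio(b))
})

test_that("column marginal is exchangeable under letter relabeling", {
  set.seed(42)
  for (r in 1:20) {
    cc <- rexp(4) * 10
    p <- sample(4)
    expect_equal(column_log_prob(cc), column_log_prob(cc[p]))
  }
})

test_that("chain rule: unit increment multiplies by the predictive", {
  set.seed(7)
  lam <- 0.5
  for (r in 1:100) {
    cc <- rexp(4) * runif(1, 0, 50)
    a <- sample(4, 1)
    inc <- cc; inc[a] <- inc[a] + 1
    expect_equal(column_log_prob(inc, lam) - column_log_prob(cc, lam),
                 log((cc[a] + lam) / (sum(cc) + 4 * lam)),
                 tolerance = 1e-10)
  }
})

test_that("log R approximates n * mutual information at large n", {
  # perfectly coupled two-state columns
  n <- 1e4
  tab <- matrix(0, 4, 4); tab[1, 1] <- n / 2; tab[2, 2] <- n / 2
  expect_equal(mutual_information(tab), log(2))
  lR <- dependency_log_ratio(tab)
  expect_lt(abs(lR / (n * log(2)) - 1), 0.05)
  # independent product counts carry no mutual information
  ind <- outer(c(4, 3, 2, 1), c(1, 1, 1, 1)) * 10
  expect_equal(mutual_information(ind), 0)
})

test_that("independent observations drive logR/n to zero", {
  marg <- c(0.4, 0.3, 0.2, 0.1)
  prev <- Inf
  for (n in c(10, 100, 1000, 10000)) {
    tab <- outer(marg, rev(marg)) * n
    lR <- dependency_log_ratio(tab)
    # logR stays O(log n) (BIC-like penalty), so logR/n shrinks to 0
    expect_lt(abs(lR), 10 * log(n) + 10)
    expect_lt(abs(lR) / n, prev)
    prev <- abs(lR) / n
  }
  expect_lt(prev, 0.005)
})

test_that("dependency matrix is symmetric and zero on integer n <= 1", {
  set.seed(11)
  sites <- random_sites(5, 30)
  tens <- dwtmotif:::pair_tensor_from_sites(sites)
  lR <- dwtmotif:::dependency_matrix(tens)
  expect_equal(lR, t(lR))
  # one site: outer-product counts at n = 1, no dependency evidence
  one <- dwtmotif:::pair_tensor_from_sites(random_sites(4, 1))
  expect_equal(max(abs(dwtmotif:::dependency_matrix(one))), 0)
  # n = 0
  zero <- dwtmotif:::empty_pair_tensor(4)
  expect_equal(max(abs(dwtmotif:::dependency_matrix(zero))), 0)
})

test_that("pair tensors from sites satisfy swap symmetry and marginal consistency", {
  set.seed(12)
  sites <- random_sites(6, 40)
  tens <- dwtmotif:::pair_tensor_from_sites(sites)
  expect_silent(dwtmotif:::check_pair_tensor(tens))
  marg <- dwtmotif:::tensor_marginals(tens)
  expect_equal(marg, site_count_matrix(sites), ignore_attr = TRUE)
  expect_equal(unname(colSums(marg)), rep(40, 6))
})

test_that("prior is validated and the 1:4 mono/di ratio enforced", {
  expect_equal(dwt_prior(1)$lambda_di, 0.25)
  expect_error(dwt_prior(0), "in \\(0, 1\\]")
  expect_error(dwt_prior(1.5), "in \\(0, 1\\]")
})
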