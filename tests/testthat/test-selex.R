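# HT-SELEX selection likelihoods and temperature fitting.

toy_dataset <- function() {
  selex_dataset(list(data.frame(sequence = c("AA", "CC"), count = c(5, 5)),
                     data.frame(sequence = c("AA", "CC"), count = c(1, 3))))
}

test_that("selection likelihood matches the two-sequence worked example", {
  ds <- toy_dataset()
  E <- setNames(c(0, log(3)), c("AA", "CC"))
  sel <- selection_log_likelihood(E, ds)
  # P(AA) = 1/4, P(CC) = 3/4 under selection from a half-half pool
  expect_equal(sel$L, log(1 / 4) + 3 * log(3 / 4), tolerance = 1e-12)
  expect_equal(sel$L0, 4 * log(1 / 2), tolerance = 1e-12)
  expect_lte(sel$L, 0)
})

test_that("constant energies make selection indistinguishable from resampling", {
  ds <- toy_dataset()
  E <- setNames(c(2.2, 2.2), c("AA", "CC"))
  sel <- selection_log_likelihood(E, ds)
  expect_equal(sel$L, sel$L0, tolerance = 1e-12)
  expect_equal(temperature_dL(E, ds, 3.1), 0, tolerance = 1e-12)
  ft <- fit_temperature(E, ds)
  expect_equal(ft$beta, 0)
  expect_equal(ft$dL_per_seq, 0)
})

test_that("tempered dL at beta = 1 equals L - L0, and dL(0) = 0", {
  set.seed(81)
  for (r in 1:5) {
    pool <- setNames(rnorm(50), paste0("s", 1:50))
    ds <- simulate_selex(pool, beta0 = 0.5, rounds = 3, draws = 2000,
                         seed = 100 + r)
    sel <- selection_log_likelihood(pool, ds)
    expect_equal(temperature_dL(pool, ds, 1), sel$dL, tolerance = 1e-9)
    expect_equal(temperature_dL(pool, ds, 0), 0)
  }
})

test_that("dL is concave in beta and the fit matches a dense grid", {
  set.seed(82)
  pool <- setNames(rnorm(100, 0, 2), paste0("s", 1:100))
  ds <- simulate_selex(pool, beta0 = 0.4, rounds = 3, draws = 5000, seed = 7)
  bgrid <- seq(0, 2, by = 0.01)
  dl <- vapply(bgrid, function(b) temperature_dL(pool, ds, b), numeric(1))
  expect_true(all(diff(dl, differences = 2) <= 1e-6 * max(abs(dl))))
  ft <- fit_temperature(pool, ds)
  expect_lt(abs(ft$beta - bgrid[which.max(dl)]), 0.011)
  expect_gte(ft$dL, max(dl) - 1e-6)
  expect_gte(ft$dL_per_seq, 0)
})

test_that("simulated selection recovers the true temperature", {
  set.seed(83)
  pool <- setNames(rnorm(300, 0, 2), paste0("s", 1:300))
  hits <- 0
  for (r in 1:5) {
    ds <- simulate_selex(pool, beta0 = 0.3, rounds = 3, draws = 1e4,
                         seed = 200 + r)
    b <- fit_temperature(pool, ds)$beta
    hits <- hits + (b >= 0.25 && b <= 0.35)
  }
  expect_gte(hits, 4)
})

test_that("padding rules: floor(l/2) N per side, all-N scores log L_S", {
  m <- dwt_model(sample_sites(quick_coupled(12), 100, seed = 9))
  bg <- background_model()
  # a 20-mer with l = 12: padded length 32, 21 offsets per strand
  e <- pad_and_score(m, paste(rep("A", 20), collapse = ""), bg)
  prof <- score_sequence(m, paste(rep("A", 20), collapse = ""), bg,
                         pad = 6)
  expect_equal(prof$L_S, 2 * 21)
  expect_equal(unname(e), prof$total)
  # all-N sequence: every segment neutral
  eN <- pad_and_score(m, paste(rep("N", 20), collapse = ""), bg)
  expect_equal(unname(eN), log(2 * 21), tolerance = 1e-10)
  # reads shorter than the motif become scorable through padding
  e8 <- pad_and_score(m, "ACGTACGT", bg)
  expect_true(is.finite(e8))
})

test_that("energy-binned enrichment has slope ~ beta under ideal selection", {
  set.seed(84)
  pool <- setNames(rnorm(500, 0, 2), paste0("s", 1:500))
  ds <- simulate_selex(pool, beta0 = 1, rounds = 2, draws = 1e5, seed = 31)
  tab <- energy_bin_enrichment(pool, ds, bin_width = 0.5)
  fitl <- lm(log_enrichment ~ E_mid, data = tab, weights = f_t)
  expect_lt(abs(coef(fitl)[2] - 1), 0.1)
  # no selection: slope ~ 0
  ds0 <- simulate_selex(pool, beta0 = 0, rounds = 2, draws = 1e5, seed = 32)
  tab0 <- energy_bin_enrichment(pool, ds0, bin_width = 0.5)
  expect_lt(abs(coef(lm(log_enrichment ~ E_mid, data = tab0,
                        weights = f_t))[2]), 0.05)
})

test_that("dataset validation rejects malformed rounds", {
  expect_error(selex_dataset(list(data.frame(sequence = "A", count = 1))),
               "two")
  expect_error(selex_dataset(list(data.frame(sequence = "A", count = -1),
                                  data.frame(sequence = "A", count = 1))),
               "non-negative")
})
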