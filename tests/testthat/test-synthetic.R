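test_that("ancestral sampling is reproducible and matches its generator", {
  net <- reference_network()
  a <- sample_binary(net, 200, seed = 5)
  b <- sample_binary(net, 200, seed = 5)
  expect_identical(a, b)
  expect_false(identical(a, sample_binary(net, 200, seed = 6)))
  # degenerate CPTs propagate deterministically
  g <- dag(c("a", "b"), rbind(c("a", "b")))
  z <- bayes_net(g, list(cpt("a", prob = 0), cpt("b", "a", c(1, 0))))
  expect_true(all(sample_binary(z, 50, seed = 1) == 0L))
  # marginal frequency close to the root's CPT entry (binomial SE ~ 0.0015)
  big <- sample_binary(net, 100000, seed = 9)
  expect_lt(abs(mean(big[, "fatigue"]) - 0.647), 0.005)
})

test_that("empirical conditional frequencies converge to the CPTs", {
  net <- reference_network()
  X <- sample_binary(net, 100000, seed = 21)
  # P(anxiety | fatigue present) estimated by simple stratified frequency
  est <- mean(X[X[, "fatigue"] == 1L, "anxiety"])
  expect_lt(abs(est - 0.331), 0.01)
  est0 <- mean(X[X[, "fatigue"] == 0L, "anxiety"])
  expect_lt(abs(est0 - 0.086), 0.01)
})

test_that("NRS expansion is the exact inverse of dichotomization", {
  net <- reference_network()
  B <- sample_binary(net, 300, seed = 2)
  cfg <- generator_config(n_patients = 300L)
  S <- expand_to_nrs(B, cfg, seed = 3)
  expect_true(all(S >= 0L & S <= 10L))
  expect_true(all(S[B == 1L] >= 4L))
  expect_true(all(S[B == 0L] <= 3L))
  expect_identical(dichotomize(S), B)
  expect_identical(expand_to_nrs(B, cfg, seed = 3), S)
  # ranges crossing the threshold are rejected at config time
  expect_error(generator_config(nrs_absent_range = c(0L, 5L)),
               "threshold")
  expect_error(generator_config(nrs_present_range = c(3L, 10L)),
               "threshold")
})

test_that("missingness injection reproduces the survey counts", {
  cfg <- generator_config()
  expect_identical(cfg$missing_composition, c(18L, 6L, 2L))
  expect_identical(sum(cfg$missing_composition * 1:3), 36L)
  net <- reference_network()
  S <- expand_to_nrs(sample_binary(net, 532, seed = 4), cfg, seed = 5)
  M <- inject_missing(S, cfg, seed = 6)
  expect_identical(sum(is.na(M)), 36L)
  miss_per_row <- rowSums(is.na(M))
  expect_identical(sum(miss_per_row > 0L), 26L)
  expect_true(all(miss_per_row <= 3L))
  expect_identical(as.integer(table(factor(miss_per_row[miss_per_row > 0],
                                           levels = 1:3))),
                   c(18L, 6L, 2L))
  # observed cells unchanged
  expect_identical(M[!is.na(M)], S[!is.na(M)])
  # no-missingness config is the identity
  cfg0 <- generator_config(missing_rows = 0L, missing_cells_total = 0L)
  expect_identical(inject_missing(S, cfg0, seed = 1), S)
  # infeasible requests fail cleanly
  expect_error(generator_config(missing_rows = 5L,
                                missing_cells_total = 20L), "1-3")
  expect_error(inject_missing(S[1:10, ], cfg, seed = 1), "rows")
})

test_that("the end-to-end survey simulator has the documented shape", {
  sim <- simulate_survey(seed = 17)
  expect_identical(dim(sim$scores), c(532L, 11L))
  expect_identical(colnames(sim$scores), symptom_labels())
  expect_identical(sum(is.na(sim$scores)), 36L)
  expect_identical(sum(!is.na(sim$scores)), 532L * 11L - 36L)
  # latent truth is recovered wherever scores are observed
  obs <- !is.na(sim$scores)
  expect_identical(dichotomize(ifelse(obs, sim$scores, 0L))[obs] == 1L,
                   sim$binary[obs] == 1L)
})

test_that("symptom CSV round-trips including missing cells", {
  sim <- simulate_survey(seed = 8)
  path <- withr::local_tempfile(fileext = ".csv")
  write_symptom_csv(sim$scores, path)
  back <- read_symptom_csv(path)
  expect_identical(back, sim$scores)
  header <- readLines(path, n = 1L)
  expect_match(header, "fatigue")
})
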