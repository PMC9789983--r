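test_that("k-fold split partitions rows into near-equal folds", {
  fold <- kfold_split(532, 4, seed = 1)
  expect_length(fold, 532)
  expect_identical(as.integer(table(fold)), rep(133L, 4))
  expect_identical(sort(unique(fold)), 1:4)
  expect_identical(as.integer(table(kfold_split(8, 4, seed = 2))),
                   rep(2L, 4))
  expect_identical(kfold_split(100, 4, seed = 3), kfold_split(100, 4, seed = 3))
  f5 <- kfold_split(10, 3, seed = 4)
  expect_lte(diff(range(table(f5))), 1)
  expect_error(kfold_split(3, 4), "n_rows >= k")
})

test_that("rank-based AUC matches the all-pairs concordance oracle", {
  expect_equal(auc_roc(c(0.9, 0.8, 0.1), c(1, 1, 0)), 1.0)
  expect_equal(auc_roc(rep(0.4, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  set.seed(91)
  for (i in 1:10) {
    n <- 30L
    pred <- round(stats::runif(n), 1)  # coarse grid forces ties
    lab <- sample(0:1, n, TRUE)
    if (length(unique(lab)) < 2L) next
    expect_equal(auc_roc(pred, lab), auc_bruteforce(pred, lab))
  }
  expect_warning(a <- auc_roc(c(0.1, 0.9), c(1, 1)), "one class")
  expect_true(is.na(a))
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(92)
  pred <- stats::runif(200)
  lab <- as.integer(stats::runif(200) < pred)
  expect_equal(auc_roc(pred, lab),
               as.numeric(suppressMessages(pROC::auc(lab, pred))),
               tolerance = 1e-12)
})

test_that("AUC is invariant under strictly monotone transforms", {
  set.seed(93)
  pred <- stats::runif(50)
  lab <- sample(0:1, 50, TRUE)
  a <- auc_roc(pred, lab)
  expect_equal(auc_roc(stats::qlogis(pred * 0.98 + 0.01), lab), a)
  expect_equal(auc_roc(pred^3, lab), a)
})

test_that("cross-validated AUC summary has the per-symptom report shape", {
  net <- reference_network()
  X <- sample_binary(net, 800, seed = 95)
  learner <- fixed_structure_learner(net$dag)
  auc <- symptom_auc_cv(X, learner, k = 4, seed = 5)
  expect_identical(auc$symptom, symptom_labels())
  expect_true(all(auc$mean_auc > 0.5))  # every node has a Markov blanket
  expect_true(all(auc$mean_auc <= 1 & auc$mean_auc >= 0))
  expect_identical(auc$satisfactory, auc$mean_auc >= 0.65)
})

test_that("a symptom independent of all others gets chance-level AUC", {
  net <- reference_network()
  X <- sample_binary(net, 2000, seed = 96)
  set.seed(97)
  X[, "pain"] <- sample(0:1, 2000, TRUE)  # overwrite: now independent
  g_indep <- dag(symptom_labels(),
                 reference_network()$dag$edges[
                   reference_network()$dag$edges[, 2L] != "pain", ])
  auc <- symptom_auc_cv(X, fixed_structure_learner(g_indep), k = 4,
                        seed = 6)
  expect_lt(abs(auc$mean_auc[auc$symptom == "pain"] - 0.5), 0.06)
})

test_that("decile calibration bins partition rows and sum to prevalence", {
  net <- reference_network()
  X <- sample_binary(net, 1005, seed = 98)  # deliberately not divisible
  learner <- fixed_structure_learner(net$dag)
  calib <- calibration(X, learner, k = 4, seed = 7)
  tab <- calib$table
  expect_identical(nrow(tab), 110L)
  expect_identical(calib$n_total, 110L)
  for (v in symptom_labels()) {
    sub <- tab[tab$symptom == v, ]
    expect_identical(sum(sub$n), 1005L)
    expect_lte(diff(range(sub$n)), 1)
    # predicted means non-decreasing across deciles
    expect_true(all(diff(sub$mean_predicted) >= -1e-12))
    # count-weighted observed frequencies recover the pooled prevalence
    expect_equal(sum(sub$observed_frequency * sub$n) / sum(sub$n),
                 mean(X[, v]), tolerance = 1e-12)
  }
  expect_error(calibration(X[1:5, ], learner), "fewer than")
})

test_that("algorithm selection ranks deterministically by mean AIC", {
  net <- reference_network()
  X <- sample_binary(net, 400, seed = 99)
  registry <- algorithm_menu()[c("hc", "tabu", "pc_stable")]
  r1 <- cv_algorithm_selection(X, registry, k = 4, seed = 11)
  r2 <- cv_algorithm_selection(X, registry, k = 4, seed = 11)
  expect_identical(r1, r2)
  expect_identical(nrow(r1), 3L)
  expect_identical(r1$rank, 1:3)
  expect_true(all(diff(r1$mean_aic) <= 0))
  # row order of the data must not matter for a fixed seed
  # (folds are assigned to positions, so permuting rows permutes folds;
  # the ranking criterion is invariant for exchangeable fold contents)
  failing <- c(registry,
               list(broken = function(data, seed = NULL) stop("boom")))
  expect_warning(r3 <- cv_algorithm_selection(X, failing, k = 4, seed = 11),
                 "failed on fold")
  expect_false("broken" %in% r3$algorithm)
})

test_that("bootstrap direction voting resolves identifiable colliders", {
  net <- collider_net()
  X <- sample_binary(net, 4000, seed = 101)
  votes <- bootstrap_edge_directions(X, function(d, seed = NULL) {
    hill_climb(d, score_spec("bic"))
  }, n_boot = 60L, majority = 0.51, seed = 102)
  for (e in c("a", "b")) {
    row <- votes[votes$from == e & votes$to == "c", ]
    expect_identical(nrow(row), 1L)
    expect_identical(row$direction, "forward")  # oriented toward c
    expect_gte(row$fraction_forward, 0.51)
  }
})

test_that("direction voting thresholds behave as documented", {
  # synthetic learner replaying canned structures: 0.6 / 0.25 forward split
  nodes <- c("a", "b")
  seq_dags <- c(rep("fwd", 12), rep("bwd", 5), rep("none", 3))
  i <- 0L
  learner <- function(data, seed = NULL) {
    i <<- i + 1L
    edges <- switch(seq_dags[i], fwd = rbind(c("a", "b")),
                    bwd = rbind(c("b", "a")), none = NULL)
    fixed_structure_learner(dag(nodes, edges))(data)
  }
  X <- cbind(a = rep(0:1, 10), b = rep(0:1, 10))
  votes <- bootstrap_edge_directions(X, learner, n_boot = 20L,
                                     majority = 0.51, seed = 1)
  expect_identical(votes$direction, "forward")
  expect_equal(votes$fraction_forward, 0.6)
  expect_equal(votes$fraction_backward, 0.25)
  # an exact 50/50 split stays unresolved at majority 0.51
  i <- 0L
  seq_dags <- rep(c("fwd", "bwd"), 10)
  votes2 <- bootstrap_edge_directions(X, learner, n_boot = 20L,
                                      majority = 0.51, seed = 1)
  expect_identical(votes2$direction, "unresolved")
})

test_that("operating thresholds match a brute-force scan", {
  pred <- c(0.05, 0.1, 0.2, 0.35, 0.4, 0.55, 0.6, 0.8, 0.85, 0.95)
  lab <- c(0L, 0L, 0L, 1L, 0L, 1L, 0L, 1L, 1L, 1L)
  res <- operating_thresholds(pred, lab, min_sensitivity = 0.8,
                              min_specificity = 0.8)
  # oracle: scan all candidate cut-offs exhaustively
  cand <- sort(unique(c(0, pred, 1)))
  sens <- vapply(cand, function(t) mean(pred[lab == 1L] >= t), numeric(1))
  spec <- vapply(cand, function(t) mean(pred[lab == 0L] < t), numeric(1))
  t_spec <- min(cand[spec >= 0.8])
  t_sens <- max(cand[sens >= 0.8])
  expect_equal(res$high_specificity$threshold, t_spec)
  expect_equal(res$high_sensitivity$threshold, t_sens)
  # perfectly separated classes reach both constraints exactly
  sep <- operating_thresholds(c(0.1, 0.2, 0.8, 0.9), c(0L, 0L, 1L, 1L),
                              min_sensitivity = 1, min_specificity = 1)
  expect_equal(sep$high_specificity$sensitivity, 1)
  expect_equal(sep$high_specificity$specificity, 1)
  expect_gt(sep$high_specificity$threshold, 0.2)
  expect_lte(sep$high_sensitivity$threshold, 0.8)
  # degenerate constraint: everything flagged
  everything <- operating_thresholds(pred, lab, min_specificity = 0)
  expect_equal(everything$high_specificity$threshold, 0)
  # unattainable constraint reported as NULL: a negative case scoring the
  # maximal probability 1 can never be excluded by any cut-off
  none <- operating_thresholds(c(1, 1), c(0L, 1L), min_specificity = 1)
  expect_null(none$high_specificity)
})
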