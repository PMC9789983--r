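make_independent_coins <- function(n, seed) {
  set.seed(seed)
  cbind(a = sample(0:1, n, TRUE), b = sample(0:1, n, TRUE))
}

test_that("hill climbing leaves independent coins unconnected", {
  X <- make_independent_coins(10000, seed = 31)
  res <- hill_climb(X)
  expect_equal(nrow(res$dag$edges), 0L)
  expect_gte(res$score, aic_score(X, dag(colnames(X))))
})

test_that("hill climbing recovers a strong pairwise dependence", {
  g <- dag(c("a", "b"), rbind(c("a", "b")))
  net <- bayes_net(g, list(cpt("a", prob = 0.5),
                           cpt("b", "a", c(0.9, 0.1))))
  X <- sample_binary(net, 10000, seed = 32)
  res <- hill_climb(X)
  expect_identical(dag_skeleton(res$dag), "a--b")  # either orientation
})

test_that("tabu search never returns a worse structure than hill climbing", {
  net <- reference_network()
  for (seed in c(41, 42)) {
    X <- sample_binary(net, 2000, seed = seed)
    hc <- hill_climb(X)
    tb <- tabu_search(X)
    expect_gte(tb$score + 1e-9, hc$score)
    expect_true(is_acyclic(tb$dag))
    expect_equal(tb$score, aic_score(X, tb$dag))
  }
})

test_that("restarted hill climbing never scores below the single climb", {
  net <- reference_network()
  X <- sample_binary(net, 1000, seed = 43)
  hc <- hill_climb(X)
  hr <- hill_climb_restarts(X, restarts = 3L, seed = 7)
  expect_gte(hr$score + 1e-9, hc$score)
  # same seed, same result
  hr2 <- hill_climb_restarts(X, restarts = 3L, seed = 7)
  expect_equal(hr$dag$edges, hr2$dag$edges)
})

test_that("G-squared statistic matches hand arithmetic and is symmetric", {
  d <- cbind(x = c(rep(1L, 40), rep(0L, 60)),
             y = c(rep(1L, 30), rep(0L, 10), rep(1L, 10), rep(0L, 50)))
  # hand: cells (30,10,10,50), margins 40/60 both ways, N = 100
  E <- outer(c(40, 60), c(40, 60)) / 100
  O <- matrix(c(30, 10, 10, 50), 2, byrow = TRUE)
  oracle <- 2 * sum(O * log(O / E))
  res <- g2_test(d, "x", "y")
  expect_equal(res$statistic, oracle)
  expect_identical(res$dof, 1L)
  sym <- g2_test(d, "y", "x")
  expect_equal(sym$statistic, res$statistic)
  # invariant to relabelling present/absent
  flip <- 1L - d
  colnames(flip) <- colnames(d)
  expect_equal(g2_test(flip, "x", "y")$statistic, res$statistic)
  # dof formula with one conditioning variable
  d3 <- cbind(d, z = rep(c(0L, 1L), 50))
  expect_identical(g2_test(d3, "x", "y", "z")$dof, 2L)
  # duplicated variable: overwhelming dependence
  dd <- cbind(a = d[, "x"], b = d[, "x"])
  expect_lt(g2_test(dd, "a", "b")$p_value, 1e-10)
})

test_that("PC-stable prunes marginal and conditional independences", {
  X <- make_independent_coins(5000, seed = 51)
  res <- pc_stable(X)
  expect_equal(nrow(res$dag$edges), 0L)
  net <- chain_net()
  Xc <- sample_binary(net, 10000, seed = 52)
  resc <- pc_stable(Xc)
  expect_setequal(dag_skeleton(resc$dag), c("a--b", "b--c"))
  expect_true(is_acyclic(resc$dag))
})

test_that("blanket-based learners recover a chain skeleton", {
  net <- chain_net()
  X <- sample_binary(net, 10000, seed = 53)
  for (learn in list(grow_shrink, iamb, inter_iamb)) {
    res <- learn(X)
    expect_setequal(dag_skeleton(res$dag), c("a--b", "b--c"))
    expect_true(is_acyclic(res$dag))
  }
})

test_that("hybrid search honours its restriction and finds colliders", {
  net <- collider_net()
  X <- sample_binary(net, 10000, seed = 54)
  res <- mmhc(X)
  expect_true(all(c("a--c", "b--c") %in% dag_skeleton(res$dag)))
  # restriction contract: a full restriction reduces to plain hill climb
  hc <- hill_climb(X)
  full <- matrix(TRUE, 3, 3)
  res_full <- hill_climb(X, restrict = full)
  expect_equal(res_full$dag$edges, hc$dag$edges)
  # nothing outside the discovered skeleton can appear
  skel <- symptomBN:::pc_skeleton(X, 0.05)
  allowed <- skel$adj | t(skel$adj)
  for (r in seq_len(nrow(res$dag$edges))) {
    expect_true(allowed[res$dag$edges[r, 1L], res$dag$edges[r, 2L]])
  }
})

test_that("the algorithm registry has nine working, acyclic learners", {
  menu <- algorithm_menu()
  expect_length(menu, 9L)
  expect_true("tabu" %in% names(menu))
  set.seed(60)
  X <- matrix(sample(0:1, 200 * 5, TRUE), ncol = 5,
              dimnames = list(NULL, paste0("v", 1:5)))
  for (nm in names(menu)) {
    res <- menu[[nm]](X, seed = 1L)
    expect_s3_class(res, "learned_structure")
    expect_true(is_acyclic(res$dag), label = paste(nm, "acyclic"))
  }
})
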