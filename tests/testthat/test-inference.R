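test_that("CPT fitting reproduces count ratios and Laplace smoothing", {
  d <- cbind(parent = c(rep(1L, 40), rep(0L, 20)),
             child = c(rep(1L, 10), rep(0L, 30), rep(1L, 5), rep(0L, 15)))
  g <- dag(c("parent", "child"), rbind(c("parent", "child")))
  mle <- fit_cpts(d, g, smoothing_alpha = 0)
  expect_equal(mle$cpts$child$prob, c(10 / 40, 5 / 20))
  lap <- fit_cpts(d, g, smoothing_alpha = 1)
  expect_equal(lap$cpts$child$prob, c(11 / 42, 6 / 22))
  # unseen parent configuration at alpha = 0 becomes 0.5 and is flagged
  d0 <- cbind(parent = rep(1L, 10), child = rep(1L, 10))
  m0 <- fit_cpts(d0, g, smoothing_alpha = 0)
  expect_equal(m0$cpts$child$prob[2L], 0.5)
  expect_match(attr(m0, "unseen_configs"), "child")
  expect_error(fit_cpts(d, dag(c("a", "b"))), "disagree")
})

test_that("CPT estimates tighten as the sample grows", {
  net <- reference_network()
  err <- vapply(c(1000L, 10000L, 100000L), function(n) {
    X <- sample_binary(net, n, seed = 71)
    fitted <- fit_cpts(X, net$dag)
    max(unlist(lapply(net$dag$nodes, function(v) {
      abs(fitted$cpts[[v]]$prob - net$cpts[[v]]$prob)
    })))
  }, numeric(1))
  expect_true(all(diff(err) < 0))
})

test_that("queries reproduce the published conditional probabilities", {
  net <- reference_network()
  expect_equal(query(net, "lack_of_appetite",
                     c(fatigue = 1, dysphagia = 1))$probability, 0.800)
  expect_equal(query(net, "fatigue")$probability, 0.647)
  expect_equal(query(net, "anxiety", c(fatigue = 1))$probability, 0.331)
  # Bayes reversal on the two-node fragment, hand-derived:
  # P(F | A+) = 0.647 * 0.331 / (0.647 * 0.331 + 0.353 * 0.086)
  two <- two_node_net()
  expect_equal(query(two, "fatigue", c(anxiety = 1))$probability,
               0.647 * 0.331 / (0.647 * 0.331 + 0.353 * 0.086),
               tolerance = 1e-12)
})

test_that("queries validate their inputs", {
  net <- two_node_net()
  expect_error(query(net, "anxiety", c(anxiety = 1)), "target")
  expect_error(query(net, "headache"), "unknown target")
  expect_error(query(net, "anxiety", c(fatigue = 2)), "0 or 1")
  g <- dag(c("a", "b"), rbind(c("a", "b")))
  z <- bayes_net(g, list(cpt("a", prob = 1), cpt("b", "a", c(0.5, 0.5))))
  expect_error(query(z, "b", c(a = 0)), "probability zero")
})

test_that("variable elimination equals joint enumeration on random queries", {
  net <- reference_network()
  j <- enumerate_joint(net)
  set.seed(81)
  for (i in 1:100) {
    target <- sample(net$dag$nodes, 1L)
    n_ev <- sample(0:5, 1L)
    ev_nodes <- sample(setdiff(net$dag$nodes, target), n_ev)
    ev <- stats::setNames(sample(0:1, n_ev, TRUE), ev_nodes)
    jj <- j
    for (v in ev_nodes) jj <- jj[jj[[v]] == ev[[v]], , drop = FALSE]
    oracle <- sum(jj$prob[jj[[target]] == 1L]) / sum(jj$prob)
    expect_equal(query(net, target, ev)$probability, oracle,
                 tolerance = 1e-9)
  }
})

test_that("conditioning on exactly the parents returns the CPT entry", {
  net <- reference_network()
  for (v in net$dag$nodes) {
    cp <- net$cpts[[v]]
    p <- length(cp$parents)
    cfg <- symptomBN:::parent_config_matrix(p)
    for (r in seq_len(nrow(cfg))) {
      ev <- stats::setNames(cfg[r, ], cp$parents)
      expect_equal(query(net, v, ev)$probability, cp$prob[r],
                   tolerance = 1e-9)
    }
  }
})

test_that("law of total probability holds for random evidence extensions", {
  net <- reference_network()
  set.seed(82)
  for (i in 1:10) {
    target <- sample(net$dag$nodes, 1L)
    extra <- sample(setdiff(net$dag$nodes, target), 1L)
    base_nodes <- sample(setdiff(net$dag$nodes, c(target, extra)), 2L)
    ev <- stats::setNames(sample(0:1, 2L, TRUE), base_nodes)
    p_reduced <- query(net, target, ev)$probability
    p_ext <- vapply(0:1, function(val) {
      query(net, target, c(ev, stats::setNames(val, extra)))$probability
    }, numeric(1))
    w <- vapply(0:1, function(val) {
      query(net, extra, ev)$probability * val +
        (1 - query(net, extra, ev)$probability) * (1 - val)
    }, numeric(1))
    expect_equal(sum(p_ext * w), p_reduced, tolerance = 1e-9)
  }
})

test_that("predicting from all others equals the enumeration oracle", {
  net <- reference_network()
  set.seed(83)
  for (i in 1:25) {
    row <- stats::setNames(sample(0:1, 11L, TRUE), net$dag$nodes)
    target <- sample(net$dag$nodes, 1L)
    ev <- row[setdiff(net$dag$nodes, target)]
    oracle <- enum_query(net, target, ev)
    expect_equal(predict_from_others(net, row, target), oracle,
                 tolerance = 1e-9)
    expect_equal(query(net, target, ev)$probability, oracle,
                 tolerance = 1e-9)
  }
})

test_that("non-blanket evidence does not move the prediction", {
  net <- reference_network()
  # markov blanket of pain: parents only (no children)
  expect_length(dag_children(net$dag, "pain"), 0L)
  ev_parents <- c(fatigue = 1L, sleeping_problems = 0L)
  p_parents <- query(net, "pain", ev_parents)$probability
  # canonical parent order (sleeping_problems, fatigue): config -+ is row 3
  expect_equal(p_parents, net$cpts$pain$prob[3L])
  ev_more <- c(ev_parents, constipation = 1L, nausea = 0L)
  expect_equal(query(net, "pain", ev_more)$probability, p_parents,
               tolerance = 1e-9)
})

test_that("zero-probability evidence falls back to the marginal", {
  # d = 1 deterministically whatever its parents do, so observing d = 0 is
  # impossible — and d sits in the Markov blanket of the target c
  g <- dag(c("a", "c", "d"), rbind(c("c", "d"), c("a", "d")))
  net <- bayes_net(g, list(cpt("a", prob = 0.6), cpt("c", prob = 0.3),
                           cpt("d", c("a", "c"), c(1, 1, 1, 1))))
  row <- c(a = 1L, d = 0L)
  expect_warning(p <- predict_from_others(net, row, "c"),
                 "zero-probability")
  expect_equal(p, 0.3)
})
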