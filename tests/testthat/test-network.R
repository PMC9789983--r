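test_that("CPT construction validates shape, range and parent lists", {
  expect_error(cpt("a", c("b", "c"), c(0.5, 0.5)), "expected 4")
  expect_error(cpt("a", "b", c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(cpt("a", "a", c(0.5, 0.5)), "own parent")
  cp <- cpt("a", c("b", "c"), c(0.9, 0.6, 0.4, 0.05))
  expect_s3_class(cp, "symptom_cpt")
  # entry order: ++, +-, -+, -- with the first parent most significant
  expect_equal(symptomBN:::cpt_lookup(cp, rbind(c(1L, 0L))), 0.6)
  expect_equal(symptomBN:::cpt_lookup(cp, rbind(c(0L, 1L))), 0.4)
})

test_that("network construction rejects CPTs that disagree with the DAG", {
  g <- dag(c("a", "b"), rbind(c("a", "b")))
  expect_error(bayes_net(g, list(cpt("a", prob = 0.5),
                                 cpt("b", prob = 0.5))),
               "disagree")
  expect_error(bayes_net(g, list(cpt("a", prob = 0.5))), "one CPT per")
  # parent order different from canonical is accepted and re-ordered
  g2 <- dag(c("a", "b", "c"), rbind(c("a", "c"), c("b", "c")))
  cp_swapped <- cpt("c", c("b", "a"), c(0.9, 0.4, 0.6, 0.05))
  net <- bayes_net(g2, list(cpt("a", prob = 0.5), cpt("b", prob = 0.5),
                            cp_swapped))
  expect_identical(net$cpts$c$parents, c("a", "b"))
  # entry for (a=1, b=0) must equal the original (b=0, a=1) entry
  expect_equal(symptomBN:::cpt_lookup(net$cpts$c, rbind(c(1L, 0L))), 0.6)
})

test_that("joint probability is the product of CPT entries", {
  net <- two_node_net()
  expect_equal(joint_probability(net, c(fatigue = 1, anxiety = 1)),
               0.647 * 0.331)
  expect_equal(joint_probability(net, c(fatigue = 0, anxiety = 1)),
               0.353 * 0.086)
  expect_error(joint_probability(net, c(fatigue = 1)), "missing node")
  # a zero CPT entry makes the matching assignment impossible
  g <- dag(c("a", "b"), rbind(c("a", "b")))
  z <- bayes_net(g, list(cpt("a", prob = 0.5), cpt("b", "a", c(0, 0.5))))
  expect_equal(joint_probability(z, c(a = 1, b = 1)), 0)
})

test_that("joint distributions are normalized for random networks", {
  for (seed in 1:5) {
    net <- random_net(n_nodes = 6L, seed = seed)
    j <- enumerate_joint(net)
    expect_equal(nrow(j), 64L)
    expect_lt(abs(sum(j$prob) - 1), 1e-9)
  }
  expect_lt(abs(sum(enumerate_joint(reference_network())$prob) - 1), 1e-9)
  big <- dag(paste0("n", 1:25))
  net_big <- bayes_net(big, lapply(paste0("n", 1:25),
                                   function(v) cpt(v, prob = 0.5)))
  expect_error(enumerate_joint(net_big), "query\\(\\)")
})

test_that("the reference network matches its published parameterization", {
  net <- reference_network()
  expect_length(net$dag$nodes, 11L)
  expect_equal(nrow(net$dag$edges), 19L)
  expect_identical(dag_children(net$dag, "fatigue"),
                   c("pain", "sleeping_problems", "dry_mouth",
                     "lack_of_appetite", "nausea", "shortness_of_breath",
                     "anxiety"))
  expect_equal(net$cpts$fatigue$prob, 0.647)
  expect_equal(net$cpts$anxiety$prob, c(0.331, 0.086))
  # canonical parent order: dry_mouth before anxiety
  expect_identical(net$cpts$depressed_mood$parents,
                   c("dry_mouth", "anxiety"))
  expect_equal(net$cpts$depressed_mood$prob, c(0.789, 0.229, 0.764, 0.089))
  expect_identical(dag_parents(net$dag, "dysphagia"),
                   c("dry_mouth", "nausea"))
  expect_true(is_acyclic(net$dag))
})

test_that("JSON serialization round-trips a network exactly", {
  net <- reference_network()
  path <- withr::local_tempfile(fileext = ".json")
  bn_to_json(net, path)
  back <- bn_from_json(path)
  expect_identical(back$dag$nodes, net$dag$nodes)
  expect_equal(back$dag$edges, net$dag$edges)
  for (v in net$dag$nodes) {
    expect_identical(back$cpts[[v]]$parents, net$cpts[[v]]$parents)
    expect_equal(back$cpts[[v]]$prob, net$cpts[[v]]$prob)
  }
  txt <- bn_to_json(net)
  # parents are serialized in canonical order (dysphagia precedes fatigue)
  expect_match(as.character(txt), "dysphagia=1,fatigue=0", fixed = TRUE)
})
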