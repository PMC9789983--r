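# Shared fixtures: tiny hand-parameterized networks and random generators.

# fatigue -> anxiety, the two-node fragment with the published entries
two_node_net <- function() {
  g <- dag(c("fatigue", "anxiety"), rbind(c("fatigue", "anxiety")))
  bayes_net(g, list(cpt("fatigue", prob = 0.647),
                    cpt("anxiety", "fatigue", c(0.331, 0.086))))
}

# chain a -> b -> c with strong effects
chain_net <- function(p_a = 0.5, hi = 0.9, lo = 0.1) {
  g <- dag(c("a", "b", "c"), rbind(c("a", "b"), c("b", "c")))
  bayes_net(g, list(cpt("a", prob = p_a),
                    cpt("b", "a", c(hi, lo)),
                    cpt("c", "b", c(hi, lo))))
}

# collider a -> c <- b with independent causes
collider_net <- function() {
  g <- dag(c("a", "b", "c"), rbind(c("a", "c"), c("b", "c")))
  bayes_net(g, list(cpt("a", prob = 0.5), cpt("b", prob = 0.5),
                    cpt("c", c("a", "b"), c(0.9, 0.6, 0.4, 0.05))))
}

# a random DAG + CPTs over n generic nodes (for property sweeps)
random_net <- function(n_nodes = 5L, edge_prob = 0.4, seed = 1L) {
  set.seed(seed)
  nodes <- paste0("v", seq_len(n_nodes))
  edges <- NULL
  for (i in seq_len(n_nodes - 1L)) {
    for (j in seq(i + 1L, n_nodes)) {
      if (stats::runif(1) < edge_prob) edges <- rbind(edges, c(nodes[i], nodes[j]))
    }
  }
  g <- dag(nodes, edges)
  cpts <- lapply(nodes, function(v) {
    pa <- dag_parents(g, v)
    cpt(v, pa, stats::runif(2^length(pa), 0.05, 0.95))
  })
  bayes_net(g, cpts)
}

# conditional probability from a full joint enumeration (oracle path)
enum_query <- function(net, target, evidence = NULL) {
  j <- enumerate_joint(net)
  ev <- unlist(evidence)
  for (v in names(ev)) j <- j[j[[v]] == ev[[v]], , drop = FALSE]
  sum(j$prob[j[[target]] == 1L]) / sum(j$prob)
}

# learner that returns a fixed known structure (for evaluating the true
# model without a search step)
fixed_structure_learner <- function(g) {
  function(data, seed = NULL) {
    symptomBN:::new_learned_structure("fixed", g, NA_real_, 0L, 0L)
  }
}

# all-pairs concordance AUC oracle (independent of the rank formula)
auc_bruteforce <- function(predicted, labels) {
  pos <- which(labels == 1L)
  neg <- which(labels == 0L)
  total <- 0
  for (i in pos) {
    for (j in neg) {
      total <- total + (predicted[i] > predicted[j]) +
        0.5 * (predicted[i] == predicted[j])
    }
  }
  total / (length(pos) * length(neg))
}
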