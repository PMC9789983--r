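#' Conditional probability table for a binary symptom node
#'
#' Stores only P(child = present | parent configuration); the complement
#' gives P(absent), so normalization is exact by construction. Entries are
#' ordered with the first parent as the most significant "bit" and
#' present (1) before absent (0): for two parents the order is
#' \code{++, +-, -+, --}, matching the conventional presentation of
#' conditional probabilities per simultaneous symptom.
#'
#' @param child Child node name.
#' @param parents Character vector of parent names (possibly empty), in the
#'   order the probability entries refer to.
#' @param prob Numeric vector of length \code{2^length(parents)} of
#'   probabilities of the child being present, in the order above. For a
#'   root node, a single marginal probability.
#' @return Object of class \code{symptom_cpt}.
#' @examples
#' cpt("anxiety", "fatigue", c(0.331, 0.086))  # P(anx | fat+), P(anx | fat-)
#' @export
cpt <- function(child, parents = character(0), prob) {
  parents <- as.character(parents)
  prob <- as.numeric(prob)
  if (length(prob) != 2^length(parents)) {
    stop("cpt for ", child, ": expected ", 2^length(parents),
         " entries for ", length(parents), " parent(s), got ", length(prob))
  }
  if (anyNA(prob) || any(prob < 0) || any(prob > 1)) {
    stop("cpt for ", child, ": probabilities must lie in [0, 1]")
  }
  if (child %in% parents) stop("cpt for ", child, ": child cannot be its own parent")
  if (anyDuplicated(parents)) stop("cpt for ", child, ": duplicate parents")
  structure(list(child = child, parents = parents, prob = prob),
            class = "symptom_cpt")
}

# All parent configurations in CPT entry order: 2^p x p matrix of 1/0,
# first parent most significant, present-first. p = 0 gives a 1 x 0 matrix.
parent_config_matrix <- function(p) {
  if (p == 0L) return(matrix(integer(0), nrow = 1L, ncol = 0L))
  # expand.grid varies its first column fastest; the CPT convention wants
  # the LAST parent fastest, so reverse the columns after expansion.
  cfg <- as.matrix(expand.grid(rep(list(c(1L, 0L)), p)))[, p:1, drop = FALSE]
  dimnames(cfg) <- NULL
  cfg
}

# Row index into cpt$prob for parent value rows (n x p matrix of 0/1).
cpt_config_index <- function(values, p) {
  if (p == 0L) return(rep(1L, max(1L, NROW(values))))
  values <- matrix(as.integer(values), ncol = p)
  as.integer(1L + (1L - values) %*% 2L^((p - 1L):0))
}

# Vectorized P(child = 1 | parent rows): values is n x p matrix of 0/1.
cpt_lookup <- function(cp, values) {
  cp$prob[cpt_config_index(values, length(cp$parents))]
}

#' Assemble a discrete Bayesian network from a DAG and CPTs
#'
#' Validates that the CPT set matches the DAG exactly: one CPT per node,
#' and each CPT's parent list equal (as a set) to the node's parents in the
#' DAG. CPT parents are re-ordered to canonical node order internally.
#'
#' @param g A \code{symptom_dag}.
#' @param cpts List of \code{symptom_cpt} objects, one per node.
#' @return Object of class \code{symptom_bn} with elements \code{dag} and
#'   \code{cpts} (named list, in node order).
#' @export
bayes_net <- function(g, cpts) {
  stopifnot(inherits(g, "symptom_dag"))
  names(cpts) <- vapply(cpts, function(x) x$child, character(1))
  if (!setequal(names(cpts), g$nodes) || length(cpts) != length(g$nodes)) {
    stop("need exactly one CPT per DAG node")
  }
  cpts <- cpts[g$nodes]
  for (v in g$nodes) {
    cp <- cpts[[v]]
    if (!inherits(cp, "symptom_cpt")) stop("cpts must be symptom_cpt objects")
    pa <- dag_parents(g, v)
    if (!setequal(cp$parents, pa)) {
      stop("CPT parents for ", v, " (", paste(cp$parents, collapse = ","),
           ") disagree with DAG parents (", paste(pa, collapse = ","), ")")
    }
    if (!identical(cp$parents, pa)) {
      cpts[[v]] <- reorder_cpt(cp, pa)
    }
  }
  structure(list(dag = g, cpts = cpts), class = "symptom_bn")
}

# Permute a CPT's parent axis order without changing the distribution.
reorder_cpt <- function(cp, new_parents) {
  p <- length(cp$parents)
  cfg_new <- parent_config_matrix(p)                 # configs in new order
  perm <- match(cp$parents, new_parents)
  idx_old <- cpt_config_index(cfg_new[, perm, drop = FALSE], p)
  cpt(cp$child, new_parents, cp$prob[idx_old])
}

#' Joint probability of a full assignment under a Bayesian network
#'
#' The network factorization: the product over nodes of the CPT entry for
#' the node's value given its parents' assigned values.
#'
#' @param net A \code{symptom_bn}.
#' @param assignment Named vector (or list) of 0/1 values covering every
#'   node.
#' @return The joint probability, a scalar in [0, 1].
#' @export
joint_probability <- function(net, assignment) {
  stopifnot(inherits(net, "symptom_bn"))
  assignment <- unlist(assignment)
  missing_nodes <- setdiff(net$dag$nodes, names(assignment))
  if (length(missing_nodes) > 0L) {
    stop("assignment is missing node(s): ",
         paste(missing_nodes, collapse = ", "))
  }
  vals <- as.integer(assignment[net$dag$nodes])
  if (anyNA(vals) || any(!vals %in% c(0L, 1L))) {
    stop("assignment values must be 0 (absent) or 1 (present)")
  }
  names(vals) <- net$dag$nodes
  prod(vapply(net$dag$nodes, function(v) {
    cp <- net$cpts[[v]]
    p1 <- cpt_lookup(cp, matrix(vals[cp$parents], nrow = 1L))
    if (vals[v] == 1L) p1 else 1 - p1
  }, numeric(1)))
}

#' Enumerate the full joint distribution of a network
#'
#' Brute-force table of all \code{2^n} assignments; feasible for the 11-node
#' symptom networks this package targets and used as the exact-inference
#' oracle against which variable elimination is checked.
#'
#' @param net A \code{symptom_bn}.
#' @param max_nodes Guard on network size (default 20).
#' @return data.frame with one 0/1 column per node plus a \code{prob}
#'   column; probabilities sum to 1.
#' @export
enumerate_joint <- function(net, max_nodes = 20L) {
  stopifnot(inherits(net, "symptom_bn"))
  nodes <- net$dag$nodes
  n <- length(nodes)
  if (n > max_nodes) {
    stop("network has ", n, " nodes (> ", max_nodes,
         "); use query() for exact inference instead")
  }
  grid <- as.matrix(expand.grid(rep(list(c(0L, 1L)), n)))
  colnames(grid) <- nodes
  prob <- rep(1, nrow(grid))
  for (v in nodes) {
    cp <- net$cpts[[v]]
    p1 <- cpt_lookup(cp, grid[, cp$parents, drop = FALSE])
    prob <- prob * ifelse(grid[, v] == 1L, p1, 1 - p1)
  }
  out <- as.data.frame(grid)
  out$prob <- prob
  out
}

#' Reference symptom network
#'
#' The 11-node discrete Bayesian network over the Utrecht Symptom Diary
#' symptoms, with structure and conditional probability tables transcribed
#' from the published conditional-probability table of the original
#' 532-patient advanced-cancer survey model. Fatigue is the only root node
#' and has seven children. This network parameterizes the synthetic-data
#' generator and serves as the ground truth for recovery tests.
#'
#' Note: the source publication's running text gives 79.8% for depressed
#' mood given anxiety present and dry mouth present, while its table prints
#' 78.9% for the same configuration (and 76.4% for dry mouth absent); the
#' tabulated values are used here.
#'
#' @return A \code{symptom_bn} with 11 nodes and 19 edges.
#' @examples
#' net <- reference_network()
#' length(dag_children(net$dag, "fatigue"))  # 7
#' @export
reference_network <- function() {
  spec <- list(
    list("fatigue", character(0), 0.647),
    list("anxiety", "fatigue", c(0.331, 0.086)),
    list("sleeping_problems", c("fatigue", "anxiety"),
         c(0.635, 0.414, 0.563, 0.183)),
    list("pain", c("fatigue", "sleeping_problems"),
         c(0.544, 0.376, 0.400, 0.138)),
    list("dry_mouth", c("fatigue", "sleeping_problems"),
         c(0.627, 0.478, 0.450, 0.228)),
    list("dysphagia", c("dry_mouth", "nausea"),
         c(0.542, 0.330, 0.313, 0.058)),
    list("lack_of_appetite", c("fatigue", "dysphagia"),
         c(0.800, 0.564, 0.810, 0.244)),
    list("constipation", c("dysphagia", "lack_of_appetite"),
         c(0.787, 0.500, 0.568, 0.339)),
    list("nausea", c("fatigue", "depressed_mood"),
         c(0.301, 0.095, 0.040, 0.013)),
    list("shortness_of_breath", c("fatigue", "dry_mouth"),
         c(0.361, 0.160, 0.059, 0.022)),
    list("depressed_mood", c("anxiety", "dry_mouth"),
         c(0.789, 0.764, 0.229, 0.089)))
  edges <- do.call(rbind, lapply(spec, function(s) {
    if (length(s[[2]]) == 0L) return(NULL)
    cbind(s[[2]], s[[1]])
  }))
  g <- dag(symptom_labels(), edges)
  cpts <- lapply(spec, function(s) cpt(s[[1]], s[[2]], s[[3]]))
  bayes_net(g, cpts)
}

#' Serialize a Bayesian network to JSON
#'
#' The document holds \code{nodes}, \code{edges} and one CPT per node with
#' explicit parent-configuration keys such as
#' \code{"fatigue=1,dysphagia=0"} (root nodes use the key \code{"(root)"}).
#'
#' @param net A \code{symptom_bn}.
#' @param file Optional path to write to.
#' @return JSON text (invisibly when written to a file).
#' @export
bn_to_json <- function(net, file = NULL) {
  stopifnot(inherits(net, "symptom_bn"))
  cpts <- lapply(net$cpts, function(cp) {
    p <- length(cp$parents)
    cfg <- parent_config_matrix(p)
    keys <- if (p == 0L) "(root)" else {
      apply(cfg, 1L, function(v) {
        paste(paste0(cp$parents, "=", v), collapse = ",")
      })
    }
    list(parents = cp$parents,
         p_present = as.list(setNames(cp$prob, keys)))
  })
  doc <- list(nodes = net$dag$nodes,
              edges = apply(net$dag$edges, 1L, function(e) {
                list(from = e[[1]], to = e[[2]])
              }),
              cpts = cpts)
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                          pretty = TRUE)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' Read a Bayesian network from JSON
#'
#' Inverse of \code{\link{bn_to_json}}.
#'
#' @param file Path to a JSON file, or a JSON string.
#' @return A \code{symptom_bn}.
#' @export
bn_from_json <- function(file) {
  doc <- jsonlite::fromJSON(file, simplifyVector = FALSE)
  nodes <- unlist(doc$nodes)
  edges <- if (length(doc$edges) > 0L) {
    do.call(rbind, lapply(doc$edges, function(e) c(e$from, e$to)))
  } else NULL
  g <- dag(nodes, edges)
  cpts <- lapply(names(doc$cpts), function(v) {
    entry <- doc$cpts[[v]]
    parents <- as.character(unlist(entry$parents))
    p <- length(parents)
    prob <- numeric(2^p)
    cfg <- parent_config_matrix(p)
    keys <- if (p == 0L) "(root)" else {
      apply(cfg, 1L, function(vals) {
        paste(paste0(parents, "=", vals), collapse = ",")
      })
    }
    got <- unlist(entry$p_present)
    if (!setequal(names(got), keys)) {
      stop("CPT for ", v, ": configuration keys do not match parents")
    }
    cpt(v, parents, as.numeric(got[keys]))
  })
  bayes_net(g, cpts)
}

#' @export
print.symptom_bn <- function(x, ...) {
  cat("Discrete Bayesian network:", length(x$dag$nodes), "binary nodes,",
      nrow(x$dag$edges), "edges\n")
  for (v in x$dag$nodes) {
    cp <- x$cpts[[v]]
    if (length(cp$parents) == 0L) {
      cat(sprintf("  %s (root): P(present) = %.3f\n", v, cp$prob))
    } else {
      cat(sprintf("  %s | %s: %s\n", v, paste(cp$parents, collapse = ", "),
                  paste(sprintf("%.3f", cp$prob), collapse = " ")))
    }
  }
  invisible(x)
}
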