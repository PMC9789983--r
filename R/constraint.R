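# Constraint-based structure learning: G^2 conditional-independence test,
# PC-stable skeleton discovery, Markov-blanket learners (grow-shrink, IAMB,
# interleaved IAMB) and the shared orientation/extension machinery that
# turns a partially directed graph into a DAG deterministically.

#' G-squared conditional-independence test for binary variables
#'
#' Likelihood-ratio test of \eqn{x \perp y \mid Z}: the 2x2 table of x and
#' y is formed within every configuration of the conditioning set and
#' \eqn{G^2 = 2 \sum O \log(O/E)} accumulated over strata, with expected
#' counts from the within-stratum margins. Strata with a zero margin
#' contribute nothing and reduce the degrees of freedom accordingly (each
#' full stratum contributes 1 df).
#'
#' @param data Complete integer 0/1 matrix with named columns.
#' @param x,y Column names.
#' @param conditioning_set Character vector of column names (may be empty).
#' @return List with \code{statistic}, \code{dof} and \code{p_value}.
#' @export
g2_test <- function(data, x, y, conditioning_set = character(0)) {
  data <- as_binary_matrix(data)
  if (nrow(data) == 0L) stop("empty dataset")
  xi <- data[, x]
  yi <- data[, y]
  q <- length(conditioning_set)
  stratum <- if (q == 0L) rep(1L, nrow(data)) else {
    cpt_config_index(data[, conditioning_set, drop = FALSE], q)
  }
  # cell code: stratum-major, then x, then y
  code <- (stratum - 1L) * 4L + xi * 2L + yi + 1L
  counts <- tabulate(code, nbins = 4L * 2L^q)
  dim(counts) <- c(4L, 2L^q)
  stat <- 0
  dof <- 0L
  for (s in seq_len(ncol(counts))) {
    tab <- matrix(counts[, s], 2L, 2L)   # rows y, cols x
    ntot <- sum(tab)
    if (ntot == 0L) next
    rs <- rowSums(tab)
    cs <- colSums(tab)
    nzr <- sum(rs > 0L)
    nzc <- sum(cs > 0L)
    d <- (nzr - 1L) * (nzc - 1L)
    if (d <= 0L) next
    dof <- dof + d
    E <- outer(rs, cs) / ntot
    keep <- tab > 0L
    stat <- stat + 2 * sum(tab[keep] * log(tab[keep] / E[keep]))
  }
  p_value <- if (dof == 0L) 1 else stats::pchisq(stat, df = dof,
                                                 lower.tail = FALSE)
  list(statistic = stat, dof = dof, p_value = p_value)
}

pair_key <- function(x, y) paste(sort(c(x, y)), collapse = "|")

# deterministic list of subsets of `pool` of size l (canonical order)
subsets_of_size <- function(pool, l) {
  if (l == 0L) return(list(character(0)))
  if (length(pool) < l) return(list())
  cmb <- utils::combn(pool, l, simplify = FALSE)
  cmb
}

# PC-stable skeleton: level-wise conditional-independence pruning using a
# per-level snapshot of the adjacency sets (order-independent). Returns the
# undirected adjacency matrix and the separating sets found.
pc_skeleton <- function(data, alpha = 0.05, max_cond = Inf) {
  nodes <- colnames(data)
  n <- length(nodes)
  adj <- matrix(TRUE, n, n, dimnames = list(nodes, nodes))
  diag(adj) <- FALSE
  sepsets <- new.env(parent = emptyenv())
  l <- 0L
  repeat {
    snapshot <- adj
    any_testable <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j || !adj[i, j]) next
        x <- nodes[i]; y <- nodes[j]
        pool <- nodes[snapshot[i, ] & nodes != y]
        if (length(pool) < l) next
        any_testable <- TRUE
        for (S in subsets_of_size(pool, l)) {
          res <- g2_test(data, x, y, S)
          if (res$p_value > alpha) {
            adj[i, j] <- adj[j, i] <- FALSE
            assign(pair_key(x, y), S, envir = sepsets)
            break
          }
        }
      }
    }
    l <- l + 1L
    if (!any_testable || l > max_cond) break
  }
  list(adj = adj, sepsets = sepsets, nodes = nodes)
}

# Orient v-structures on an undirected skeleton given separating sets:
# x - z - y with x, y non-adjacent becomes x -> z <- y when z is not in
# sepset(x, y). `M` is a signed matrix: M[i,j] TRUE means i -> j directed;
# undirected edges remain symmetric in `adj`. Conflicting orientations are
# resolved first-come in canonical order.
orient_vstructures <- function(adj, sepsets, nodes,
                               find_sep = NULL) {
  n <- length(nodes)
  dir_ <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  for (zi in seq_len(n)) {
    nb <- which(adj[zi, ])
    if (length(nb) < 2L) next
    for (a in seq_along(nb)) {
      for (b in seq_along(nb)) {
        if (a >= b) next
        xi <- nb[a]; yi <- nb[b]
        if (adj[xi, yi]) next
        key <- pair_key(nodes[xi], nodes[yi])
        S <- if (exists(key, envir = sepsets, inherits = FALSE)) {
          get(key, envir = sepsets)
        } else if (!is.null(find_sep)) {
          find_sep(nodes[xi], nodes[yi])
        } else NULL
        if (is.null(S)) next
        if (!(nodes[zi] %in% S)) {
          # collider, unless an opposite arrow is already committed
          if (!dir_[zi, xi]) dir_[xi, zi] <- TRUE
          if (!dir_[zi, yi]) dir_[yi, zi] <- TRUE
        }
      }
    }
  }
  dir_
}

# Meek rules 1-3: propagate orientations implied by acyclicity and by not
# creating new v-structures. adj is the symmetric skeleton, dir_ the
# committed arrows.
meek_rules <- function(adj, dir_) {
  n <- nrow(adj)
  undirected <- function(i, j) adj[i, j] && !dir_[i, j] && !dir_[j, i]
  changed <- TRUE
  while (changed) {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j || !undirected(i, j)) next
        # R1: k -> i, k not adjacent to j  =>  i -> j
        for (k in seq_len(n)) {
          if (k != j && dir_[k, i] && !adj[k, j]) {
            dir_[i, j] <- TRUE; changed <- TRUE; break
          }
        }
        if (!undirected(i, j)) next
        # R2: directed path i -> k -> j with i - j undirected => i -> j
        for (k in seq_len(n)) {
          if (k != i && k != j && dir_[i, k] && dir_[k, j]) {
            dir_[i, j] <- TRUE; changed <- TRUE; break
          }
        }
        if (!undirected(i, j)) next
        # R3: i - k -> j and i - l -> j, k,l non-adjacent => i -> j
        ks <- which(vapply(seq_len(n), function(k) {
          k != i && k != j && undirected(i, k) && dir_[k, j]
        }, logical(1)))
        if (length(ks) >= 2L) {
          for (a in seq_along(ks)) {
            for (b in seq_along(ks)) {
              if (a < b && !adj[ks[a], ks[b]]) {
                dir_[i, j] <- TRUE; changed <- TRUE
              }
            }
          }
        }
      }
    }
  }
  dir_
}

# Deterministic consistent extension of a partially directed graph to a
# DAG (Dor & Tarsi's algorithm); any edge the algorithm cannot place (the
# PDAG admits no consistent extension, e.g. after conflicting collider
# orientations) falls back to canonical-order orientation skipping
# cycle-creating arrows.
extend_to_dag <- function(adj, dir_, nodes) {
  n <- length(nodes)
  A <- adj
  D <- dir_
  live <- rep(TRUE, n)
  out <- dir_
  repeat {
    if (!any(live)) break
    placed <- FALSE
    for (i in which(live)) {
      # sink: no outgoing directed edges among live nodes
      if (any(D[i, live])) next
      und <- which(live & A[i, ] & !D[i, ] & !D[, i])
      nb <- which(live & A[i, ])
      ok <- all(vapply(und, function(u) all(A[u, setdiff(nb, u)]), logical(1)))
      if (!ok) next
      out[und, i] <- TRUE
      live[i] <- FALSE
      A[i, live] <- A[live, i] <- FALSE
      D[i, ] <- D[, i] <- FALSE
      placed <- TRUE
      break
    }
    if (!placed) break
  }
  if (any(live)) {
    # fallback for the unplaced remainder: canonical order, avoid cycles
    und_idx <- which(adj & !out & !t(out), arr.ind = TRUE)
    und_idx <- und_idx[und_idx[, 1L] < und_idx[, 2L], , drop = FALSE]
    for (r in seq_len(nrow(und_idx))) {
      i <- und_idx[r, 1L]; j <- und_idx[r, 2L]
      if (out[i, j] || out[j, i]) next
      if (!path_exists(out, j, i)) out[i, j] <- TRUE else out[j, i] <- TRUE
    }
  }
  # final safety: drop any arrow that closes a cycle (processed canonically)
  final <- matrix(FALSE, n, n)
  idx <- which(out, arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1L]; j <- idx[r, 2L]
    if (!path_exists(final, j, i)) final[i, j] <- TRUE
  }
  adjacency_to_dag(final, nodes)
}

finalize_constraint_dag <- function(data, skel, algorithm, alpha) {
  nodes <- skel$nodes
  find_sep <- function(x, y) {
    # search for a separating set among the smaller current neighbourhood
    nx <- nodes[skel$adj[x, ]]
    ny <- nodes[skel$adj[y, ]]
    pool <- if (length(nx) <= length(ny)) setdiff(nx, y) else setdiff(ny, x)
    for (l in 0:length(pool)) {
      for (S in subsets_of_size(pool, l)) {
        if (g2_test(data, x, y, S)$p_value > alpha) return(S)
      }
    }
    NULL
  }
  dir_ <- orient_vstructures(skel$adj, skel$sepsets, nodes,
                             find_sep = find_sep)
  dir_ <- meek_rules(skel$adj, dir_)
  g <- extend_to_dag(skel$adj, dir_, nodes)
  g
}

#' PC-stable structure learning
#'
#' Order-independent level-wise skeleton discovery with the G-squared
#' conditional-independence test, v-structure orientation from separating
#' sets, Meek-rule propagation, and a deterministic consistent extension to
#' a DAG (canonical node order breaks all remaining ties).
#'
#' @param data Complete integer 0/1 matrix with named columns.
#' @param alpha Significance level for the independence tests
#'   (default 0.05).
#' @param score Score reported for the returned DAG (default AIC).
#' @return A \code{learned_structure}.
#' @export
pc_stable <- function(data, alpha = 0.05, score = score_spec("aic")) {
  data <- as_binary_matrix(data)
  stopifnot(alpha > 0, alpha < 1)
  skel <- pc_skeleton(data, alpha)
  g <- finalize_constraint_dag(data, skel, "pc_stable", alpha)
  new_learned_structure("pc_stable", g, network_score(data, g, score),
                        NA_integer_, NA_integer_)
}

# -- Markov-blanket discovery ------------------------------------------------

mb_grow_shrink <- function(data, x, alpha, strategy = c("gs", "iamb",
                                                        "inter_iamb")) {
  strategy <- match.arg(strategy)
  nodes <- colnames(data)
  S <- character(0)
  shrink <- function(S) {
    repeat {
      dropped <- FALSE
      for (y in S) {
        if (g2_test(data, x, y, setdiff(S, y))$p_value > alpha) {
          S <- setdiff(S, y)
          dropped <- TRUE
          break
        }
      }
      if (!dropped) return(S)
    }
  }
  if (strategy == "gs") {
    repeat {
      added <- FALSE
      for (y in setdiff(nodes, c(x, S))) {
        if (g2_test(data, x, y, S)$p_value <= alpha) {
          S <- c(S, y)
          added <- TRUE
        }
      }
      if (!added) break
    }
    S <- shrink(S)
  } else {
    repeat {
      cand <- setdiff(nodes, c(x, S))
      if (length(cand) == 0L) break
      pv <- vapply(cand, function(y) g2_test(data, x, y, S)$p_value,
                   numeric(1))
      best <- cand[which.min(pv)]
      if (min(pv) > alpha) break
      S <- c(S, best)
      if (strategy == "inter_iamb") S <- shrink(S)
    }
    S <- shrink(S)
  }
  S
}

# Blanket-based learner: MB discovery per node, AND-rule symmetry
# correction, neighbour identification within blankets, then the shared
# orientation machinery.
blanket_learner <- function(data, alpha, strategy, label,
                            score = score_spec("aic")) {
  data <- as_binary_matrix(data)
  stopifnot(alpha > 0, alpha < 1)
  nodes <- colnames(data)
  n <- length(nodes)
  mb <- lapply(nodes, function(x) mb_grow_shrink(data, x, alpha, strategy))
  names(mb) <- nodes
  # symmetry: y in MB(x) AND x in MB(y)
  for (x in nodes) mb[[x]] <- mb[[x]][vapply(mb[[x]], function(y) {
    x %in% mb[[y]]
  }, logical(1))]
  adj <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  sepsets <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    x <- nodes[i]
    for (j in seq_len(n)) {
      if (j <= i) next
      y <- nodes[j]
      if (!(y %in% mb[[x]])) next
      bx <- setdiff(mb[[x]], y)
      by <- setdiff(mb[[y]], x)
      pool <- if (length(bx) <= length(by)) bx else by
      separated <- FALSE
      for (l in 0:length(pool)) {
        for (S in subsets_of_size(pool, l)) {
          if (g2_test(data, x, y, S)$p_value > alpha) {
            separated <- TRUE
            assign(pair_key(x, y), S, envir = sepsets)
            break
          }
        }
        if (separated) break
      }
      if (!separated) adj[i, j] <- adj[j, i] <- TRUE
    }
  }
  skel <- list(adj = adj, sepsets = sepsets, nodes = nodes)
  g <- finalize_constraint_dag(data, skel, label, alpha)
  new_learned_structure(label, g, network_score(data, g, score),
                        NA_integer_, NA_integer_)
}

#' Grow-shrink structure learning
#'
#' Markov-blanket discovery by the grow-shrink heuristic, neighbourhood
#' identification inside the blankets, and the shared deterministic
#' orientation/extension machinery.
#'
#' @inheritParams pc_stable
#' @return A \code{learned_structure}.
#' @export
grow_shrink <- function(data, alpha = 0.05, score = score_spec("aic")) {
  blanket_learner(data, alpha, "gs", "gs", score)
}

#' IAMB structure learning
#'
#' Incremental-association Markov-blanket discovery (greedy forward
#' addition of the most associated variable, then backward shrinking),
#' followed by the shared neighbourhood/orientation machinery.
#'
#' @inheritParams pc_stable
#' @return A \code{learned_structure}.
#' @export
iamb <- function(data, alpha = 0.05, score = score_spec("aic")) {
  blanket_learner(data, alpha, "iamb", "iamb", score)
}

#' Interleaved IAMB structure learning
#'
#' IAMB with a shrink pass interleaved after every forward addition, which
#' reduces false positives entering the blanket.
#'
#' @inheritParams pc_stable
#' @return A \code{learned_structure}.
#' @export
inter_iamb <- function(data, alpha = 0.05, score = score_spec("aic")) {
  blanket_learner(data, alpha, "inter_iamb", "inter_iamb", score)
}

# -- hybrid learners ---------------------------------------------------------

#' Hybrid structure learning (constraint-restricted score search)
#'
#' Candidate adjacencies are discovered constraint-based (the PC-stable
#' skeleton at \code{alpha}); greedy hill climbing (or tabu search) then
#' optimizes the score over edges permitted by that restriction, in the
#' spirit of max-min hill climbing. No edge outside the discovered
#' neighbourhoods can appear in the output.
#'
#' @inheritParams pc_stable
#' @param spec A \code{score_spec} for the search phase (default AIC).
#' @param search \code{"hc"} or \code{"tabu"}.
#' @param ... Passed to the search routine.
#' @return A \code{learned_structure}.
#' @export
mmhc <- function(data, alpha = 0.05, spec = score_spec("aic"),
                 search = c("hc", "tabu"), ...) {
  data <- as_binary_matrix(data)
  search <- match.arg(search)
  skel <- pc_skeleton(data, alpha)
  restrict <- skel$adj | t(skel$adj)
  res <- if (search == "hc") {
    hill_climb(data, spec, restrict = restrict, ...)
  } else {
    tabu_search(data, spec, restrict = restrict, ...)
  }
  label <- if (search == "hc") "mmhc" else "tabu_restricted"
  res$algorithm <- label
  res
}
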