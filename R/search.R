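# Score-based structure search: greedy hill climbing and tabu search over
# single-edge additions, deletions and reversals. Everything is
# deterministic for a fixed seed: candidate moves are enumerated in
# canonical edge order and score ties go to the earliest move.

new_learned_structure <- function(algorithm, g, score, iterations,
                                  moves_evaluated) {
  structure(list(algorithm = algorithm, dag = g, score = score,
                 diagnostics = list(iterations = iterations,
                                    moves_evaluated = moves_evaluated)),
            class = "learned_structure")
}

#' @export
print.learned_structure <- function(x, ...) {
  cat("Learned structure [", x$algorithm, "], score ",
      format(x$score), ", ", nrow(x$dag$edges), " edges\n", sep = "")
  invisible(x)
}

# TRUE if a directed path u ~> v exists in adjacency matrix A (A[i,j] means
# an edge i -> j).
path_exists <- function(A, u, v) {
  if (u == v) return(TRUE)
  frontier <- which(A[u, ])
  seen <- logical(nrow(A))
  while (length(frontier) > 0L) {
    if (v %in% frontier) return(TRUE)
    seen[frontier] <- TRUE
    frontier <- which(colSums(A[frontier, , drop = FALSE]) > 0 & !seen)
  }
  FALSE
}

adjacency_to_dag <- function(A, nodes) {
  idx <- which(A, arr.ind = TRUE)
  edges <- if (nrow(idx) > 0L) {
    ord <- order(idx[, 1L], idx[, 2L])
    cbind(nodes[idx[ord, 1L]], nodes[idx[ord, 2L]])
  } else NULL
  dag(nodes, edges)
}

dag_to_adjacency <- function(g) {
  n <- length(g$nodes)
  A <- matrix(FALSE, n, n, dimnames = list(g$nodes, g$nodes))
  if (nrow(g$edges) > 0L) {
    A[cbind(match(g$edges[, 1L], g$nodes), match(g$edges[, 2L], g$nodes))] <- TRUE
  }
  A
}

graph_hash <- function(A) {
  idx <- which(A)
  paste(idx, collapse = ",")
}

# Core local search. tabu_len = 0 gives plain greedy hill climbing that
# stops at the first local optimum; tabu_len >= 1 keeps searching through
# worsening moves, forbidding the last tabu_len visited structures, and
# returns the best structure encountered. `restrict` is an optional logical
# matrix of permitted directed edges.
local_search <- function(data, spec, start = NULL, tabu_len = 0L,
                         max_iter = 200L, restrict = NULL, cache = NULL) {
  nodes <- colnames(data)
  n <- length(nodes)
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  if (is.null(restrict)) {
    restrict <- matrix(TRUE, n, n)
  }
  diag(restrict) <- FALSE
  A <- if (is.null(start)) matrix(FALSE, n, n) else dag_to_adjacency(start)
  dimnames(A) <- list(nodes, nodes)

  fam <- function(child_i, parents_i) {
    family_score(data, nodes[child_i], nodes[sort(parents_i)], spec, cache)
  }
  node_scores <- vapply(seq_len(n), function(j) fam(j, which(A[, j])),
                        numeric(1))
  current <- sum(node_scores)
  best <- current
  best_A <- A
  tabu <- character(0)
  if (tabu_len > 0L) tabu <- graph_hash(A)
  moves_evaluated <- 0L
  iter <- 0L
  stall <- 0L
  max_stall <- max(tabu_len, 1L)

  while (iter < max_iter) {
    iter <- iter + 1L
    best_move <- NULL
    best_delta <- -Inf
    consider <- function(kind, i, j, delta, move_A) {
      moves_evaluated <<- moves_evaluated + 1L
      if (delta <= best_delta) return()
      if (tabu_len > 0L) {
        h <- graph_hash(move_A)
        if (h %in% tabu && current + delta <= best) return()  # aspiration
      }
      best_delta <<- delta
      best_move <<- list(kind = kind, i = i, j = j, A = move_A)
    }
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j) next
        if (!A[i, j] && !A[j, i]) {
          if (restrict[i, j] && !path_exists(A, j, i)) {
            pa <- which(A[, j])
            delta <- fam(j, c(pa, i)) - node_scores[j]
            A2 <- A; A2[i, j] <- TRUE
            consider("add", i, j, delta, A2)
          }
        } else if (A[i, j]) {
          pa <- which(A[, j])
          delta_del <- fam(j, setdiff(pa, i)) - node_scores[j]
          A2 <- A; A2[i, j] <- FALSE
          consider("delete", i, j, delta_del, A2)
          if (restrict[j, i]) {
            A2[i, j] <- FALSE
            if (!path_exists(A2, i, j)) {
              pa_i <- which(A[, i])
              delta <- delta_del + fam(i, c(pa_i, j)) - node_scores[i]
              A3 <- A2; A3[j, i] <- TRUE
              consider("reverse", i, j, delta, A3)
            }
          }
        }
      }
    }
    if (is.null(best_move)) break
    if (tabu_len == 0L && best_delta <= 1e-12) break
    # apply the move
    A <- best_move$A
    j <- best_move$j
    node_scores[j] <- fam(j, which(A[, j]))
    if (best_move$kind == "reverse") {
      i <- best_move$i
      node_scores[i] <- fam(i, which(A[, i]))
    }
    current <- sum(node_scores)
    if (tabu_len > 0L) {
      tabu <- c(tabu, graph_hash(A))
      if (length(tabu) > tabu_len) tabu <- tabu[-1L]
    }
    if (current > best + 1e-12) {
      best <- current
      best_A <- A
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (tabu_len > 0L && stall >= max_stall) break
      if (tabu_len == 0L) break  # greedy never accepts non-improving moves
    }
  }
  list(A = best_A, score = best, iterations = iter,
       moves_evaluated = moves_evaluated, nodes = nodes)
}

#' Greedy hill-climbing structure learning
#'
#' Starts from the empty graph and repeatedly applies the single-edge
#' addition, deletion or reversal that most improves the decomposable
#' network score, stopping at a local optimum. Deterministic: ties are
#' broken by canonical edge order.
#'
#' @param data Complete integer 0/1 matrix with named columns.
#' @param spec A \code{score_spec} (default AIC).
#' @param max_iter Iteration cap (default 200).
#' @param seed Unused by plain hill climbing (kept for a uniform learner
#'   signature).
#' @param restrict Optional logical matrix of permitted directed edges
#'   (rows = from, cols = to), as produced by constraint-based
#'   neighbourhood discovery.
#' @param start Optional \code{symptom_dag} to start from (default empty).
#' @return A \code{learned_structure}.
#' @export
hill_climb <- function(data, spec = score_spec("aic"), max_iter = 200L,
                       seed = NULL, restrict = NULL, start = NULL) {
  data <- as_binary_matrix(data)
  res <- local_search(data, spec, start = start, tabu_len = 0L,
                      max_iter = max_iter, restrict = restrict)
  new_learned_structure("hc", adjacency_to_dag(res$A, res$nodes), res$score,
                        res$iterations, res$moves_evaluated)
}

#' Hill climbing with random restarts
#'
#' Runs plain hill climbing, then repeatedly perturbs the best structure
#' found (a seeded sequence of random legal edge flips) and re-climbs,
#' keeping the best-scoring local optimum over all restarts.
#'
#' @inheritParams hill_climb
#' @param restarts Number of perturb-and-reclimb rounds (default 5).
#' @param perturb Number of random edge flips per restart (default 8).
#' @param seed Integer seed driving the perturbations.
#' @return A \code{learned_structure}.
#' @export
hill_climb_restarts <- function(data, spec = score_spec("aic"),
                                restarts = 5L, perturb = 8L,
                                max_iter = 200L, seed = 1L,
                                restrict = NULL) {
  data <- as_binary_matrix(data)
  nodes <- colnames(data)
  n <- length(nodes)
  cache <- new.env(parent = emptyenv())
  res <- local_search(data, spec, tabu_len = 0L, max_iter = max_iter,
                      restrict = restrict, cache = cache)
  best <- res
  total_iter <- res$iterations
  total_moves <- res$moves_evaluated
  local_seed(seed)
  full <- if (is.null(restrict)) matrix(TRUE, n, n) else restrict
  diag(full) <- FALSE
  for (r in seq_len(restarts)) {
    A <- best$A
    for (m in seq_len(perturb)) {
      i <- sample.int(n, 1L)
      j <- sample.int(n, 1L)
      if (i == j) next
      if (A[i, j]) {
        A[i, j] <- FALSE
      } else if (!A[j, i] && full[i, j]) {
        if (!path_exists(A, j, i)) A[i, j] <- TRUE
      }
    }
    start <- adjacency_to_dag(A, nodes)
    res <- local_search(data, spec, start = start, tabu_len = 0L,
                        max_iter = max_iter, restrict = restrict,
                        cache = cache)
    total_iter <- total_iter + res$iterations
    total_moves <- total_moves + res$moves_evaluated
    if (res$score > best$score + 1e-12) best <- res
  }
  new_learned_structure("hc_restarts", adjacency_to_dag(best$A, nodes),
                        best$score, total_iter, total_moves)
}

#' Tabu-search structure learning
#'
#' Hill climbing that escapes local optima: at an optimum it accepts the
#' best non-tabu worsening move, keeping the last \code{tabu_len} visited
#' structures forbidden (with the usual aspiration exception for moves that
#' beat the best score seen). Returns the best structure encountered, so
#' its score is never below plain hill climbing's.
#'
#' @inheritParams hill_climb
#' @param tabu_len Length of the tabu list (default 10).
#' @return A \code{learned_structure}.
#' @export
tabu_search <- function(data, spec = score_spec("aic"), tabu_len = 10L,
                        max_iter = 200L, seed = NULL, restrict = NULL) {
  data <- as_binary_matrix(data)
  stopifnot(tabu_len >= 1L)
  res <- local_search(data, spec, tabu_len = tabu_len, max_iter = max_iter,
                      restrict = restrict)
  new_learned_structure("tabu", adjacency_to_dag(res$A, res$nodes),
                        res$score, res$iterations, res$moves_evaluated)
}
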