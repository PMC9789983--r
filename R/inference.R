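#' Fit conditional probability tables on a fixed structure
#'
#' Maximum-likelihood (or Laplace-smoothed) CPT estimation:
#' \eqn{(n(child{=}1, pa) + \alpha) / (n(pa) + 2\alpha)}. With
#' \code{smoothing_alpha = 0} an unobserved parent configuration gets the
#' uninformative entry 0.5 and is flagged in the returned diagnostics;
#' inside cross-validated evaluation a default of 1 (Laplace) is used so
#' held-out rows with unseen configurations receive finite, non-degenerate
#' predictions.
#'
#' @param data Complete integer 0/1 matrix with named columns.
#' @param g A \code{symptom_dag} over the data columns.
#' @param smoothing_alpha Additive smoothing pseudo-count (default 0 =
#'   maximum likelihood).
#' @return A \code{symptom_bn}; attribute \code{"unseen_configs"} lists any
#'   parent configurations never observed (only possible at
#'   \code{smoothing_alpha = 0}).
#' @export
fit_cpts <- function(data, g, smoothing_alpha = 0) {
  data <- as_binary_matrix(data)
  stopifnot(inherits(g, "symptom_dag"), smoothing_alpha >= 0)
  if (!setequal(g$nodes, colnames(data))) {
    stop("DAG nodes and data columns disagree")
  }
  unseen <- character(0)
  cpts <- lapply(g$nodes, function(v) {
    pa <- dag_parents(g, v)
    counts <- family_counts(data, v, pa)
    n_pa <- colSums(counts)
    prob <- (counts[1L, ] + smoothing_alpha) / (n_pa + 2 * smoothing_alpha)
    zero <- n_pa == 0
    if (any(zero) && smoothing_alpha == 0) {
      prob[zero] <- 0.5
      unseen <<- c(unseen, paste0(v, "[config ", which(zero), "]"))
    }
    cpt(v, pa, prob)
  })
  net <- bayes_net(g, cpts)
  attr(net, "unseen_configs") <- unseen
  net
}

# -- factors for variable elimination ---------------------------------------
# A factor is a list(vars, prob) where prob has length 2^length(vars),
# indexed like CPT entries: first variable most significant, value 1 before
# value 0.

cpt_to_factor <- function(cp) {
  vars <- c(cp$child, cp$parents)
  p <- length(cp$parents)
  cfg <- parent_config_matrix(length(vars))   # includes child as first var
  child_val <- cfg[, 1L]
  idx <- cpt_config_index(cfg[, -1L, drop = FALSE], p)
  prob <- ifelse(child_val == 1L, cp$prob[idx], 1 - cp$prob[idx])
  list(vars = vars, prob = prob)
}

factor_reduce <- function(f, var, value) {
  i <- match(var, f$vars)
  if (is.na(i)) return(f)
  k <- length(f$vars)
  cfg <- parent_config_matrix(k)
  keep <- cfg[, i] == value
  list(vars = f$vars[-i], prob = f$prob[keep])
}

factor_product <- function(f, g) {
  vars <- union(f$vars, g$vars)
  k <- length(vars)
  cfg <- parent_config_matrix(k)
  fi <- cpt_config_index(cfg[, match(f$vars, vars), drop = FALSE],
                         length(f$vars))
  gi <- cpt_config_index(cfg[, match(g$vars, vars), drop = FALSE],
                         length(g$vars))
  list(vars = vars, prob = f$prob[fi] * g$prob[gi])
}

factor_marginalize <- function(f, var) {
  i <- match(var, f$vars)
  if (is.na(i)) return(f)
  k <- length(f$vars)
  cfg <- parent_config_matrix(k)
  out_vars <- f$vars[-i]
  idx <- cpt_config_index(cfg[, -i, drop = FALSE], k - 1L)
  # tapply groups by sorted unique idx = 1..2^(k-1), the target order
  prob <- as.vector(tapply(f$prob, idx, sum))
  list(vars = out_vars, prob = prob)
}

#' Exact conditional query by variable elimination
#'
#' Computes P(target = present | evidence) exactly. Evidence variables are
#' clamped by factor reduction; the remaining non-target variables are
#' summed out in reverse topological order (a deterministic elimination
#' order; with 11 binary nodes performance is immaterial, reproducibility
#' is the point).
#'
#' @param net A \code{symptom_bn}.
#' @param target Node name (must not appear in the evidence).
#' @param evidence Named vector/list of 0/1 values for a subset of the
#'   other nodes (may be empty).
#' @return List of class \code{query_result}: \code{target},
#'   \code{evidence}, \code{probability}.
#' @examples
#' net <- reference_network()
#' query(net, "lack_of_appetite", c(fatigue = 1, dysphagia = 1))
#' @export
query <- function(net, target, evidence = NULL) {
  stopifnot(inherits(net, "symptom_bn"))
  nodes <- net$dag$nodes
  if (!(target %in% nodes)) stop("unknown target node: ", target)
  ev <- unlist(evidence)
  if (length(ev) > 0L) {
    if (is.null(names(ev)) || any(names(ev) == "")) {
      stop("evidence must be a named vector of 0/1 values")
    }
    if (anyDuplicated(names(ev))) stop("node assigned twice in evidence")
    bad <- setdiff(names(ev), nodes)
    if (length(bad) > 0L) stop("unknown evidence node(s): ",
                               paste(bad, collapse = ", "))
    if (target %in% names(ev)) stop("target cannot appear in the evidence")
    if (!all(ev %in% c(0, 1))) stop("evidence values must be 0 or 1")
  }
  factors <- lapply(net$cpts, cpt_to_factor)
  for (v in names(ev)) {
    factors <- lapply(factors, factor_reduce, var = v, value = as.integer(ev[[v]]))
  }
  elim <- rev(topological_order(net$dag))
  elim <- elim[!(elim %in% c(target, names(ev)))]
  for (v in elim) {
    has_v <- vapply(factors, function(f) v %in% f$vars, logical(1))
    if (!any(has_v)) next
    merged <- Reduce(factor_product, factors[has_v])
    merged <- factor_marginalize(merged, v)
    factors <- c(factors[!has_v], list(merged))
  }
  final <- Reduce(factor_product, factors)
  # final is a factor over the target only (constants have 0 vars)
  if (length(final$vars) == 0L) stop("internal error: target eliminated")
  i <- match(target, final$vars)
  k <- length(final$vars)
  cfg <- parent_config_matrix(k)
  p1 <- sum(final$prob[cfg[, i] == 1L])
  p0 <- sum(final$prob[cfg[, i] == 0L])
  z <- p1 + p0
  if (z <= 0) {
    stop("evidence has probability zero under the network: ",
         paste(paste0(names(ev), "=", ev), collapse = ", "))
  }
  structure(list(target = target, evidence = ev, probability = p1 / z),
            class = "query_result")
}

#' @export
print.query_result <- function(x, ...) {
  ev <- if (length(x$evidence) == 0L) "(none)" else {
    paste(paste0(names(x$evidence), "=", x$evidence), collapse = ", ")
  }
  cat(sprintf("P(%s = present | %s) = %.4f (%s%%)\n", x$target, ev,
              x$probability, format_percent(x$probability)))
  invisible(x)
}

#' Predict one symptom from all the others
#'
#' The model's per-patient prediction: P(target = present | the observed
#' presence/absence of the other 10 symptoms). Equivalent to a
#' variable-elimination query with full evidence, which reduces to the
#' target's Markov blanket. If the evidence restricted to the target's
#' Markov blanket has probability zero under the network (possible only
#' with unsmoothed CPTs), the target's marginal probability is returned
#' instead and the fallback is counted in the \code{"fallbacks"} attribute
#' rather than failing a whole evaluation fold; impossible evidence outside
#' the blanket cannot influence the blanket ratio and is ignored.
#'
#' @param net A \code{symptom_bn}.
#' @param row Named 0/1 vector (or single-row matrix) covering every node.
#' @param target Node to predict.
#' @return Predicted probability (scalar).
#' @export
predict_from_others <- function(net, row, target) {
  if (is.matrix(row)) row <- row[1L, ]
  nodes <- net$dag$nodes
  missing_nodes <- setdiff(setdiff(nodes, target), names(row))
  if (length(missing_nodes) > 0L) {
    stop("row is missing node(s): ", paste(missing_nodes, collapse = ", "))
  }
  full <- matrix(0L, 1L, length(nodes), dimnames = list(NULL, nodes))
  keep <- intersect(names(row), nodes)
  full[1L, keep] <- as.integer(row[keep])  # target slot is ignored
  as.numeric(predict_matrix(net, full, target))
}

# Vectorized P(target = 1 | all other columns), one value per data row.
# Only factors containing the target (its CPT and its children's CPTs)
# matter once everything else is observed.
predict_matrix <- function(net, data, target) {
  nodes <- net$dag$nodes
  kids <- dag_children(net$dag, target)
  n <- nrow(data)
  num1 <- rep(1, n)  # joint factor with target = 1
  num0 <- rep(1, n)  # target = 0
  for (v in c(target, kids)) {
    cp <- net$cpts[[v]]
    vals <- function(tval) {
      pa <- cp$parents
      if (length(pa) == 0L) {
        m <- matrix(integer(0), nrow = n, ncol = 0L)
      } else {
        m <- data[, pa, drop = FALSE]
        if (target %in% pa) m[, pa == target] <- tval
      }
      p1 <- cpt_lookup(cp, m)
      obs <- if (v == target) rep(tval, n) else data[, v]
      ifelse(obs == 1L, p1, 1 - p1)
    }
    num1 <- num1 * vals(1L)
    num0 <- num0 * vals(0L)
  }
  z <- num1 + num0
  out <- num1 / z
  bad <- z <= 0
  if (any(bad)) {
    marg <- query(net, target)$probability
    out[bad] <- marg
    attr(out, "fallbacks") <- sum(bad)
    warning(sum(bad), " row(s) had zero-probability evidence for ", target,
            "; marginal probability substituted")
  }
  out
}

format_percent <- function(p) {
  formatC(round_half_away(100 * p, 1), format = "f", digits = 1)
}
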