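#' Network score specification
#'
#' All scores are decomposable (a sum over per-node family scores) and
#' follow the higher-is-better convention. \code{aic} is log-likelihood
#' minus the number of free parameters (one per CPT entry for binary
#' variables, i.e. \code{2^|parents|} per node), so the structure with the
#' highest AIC is the one with the lowest estimated prediction error. The
#' textbook \code{-2 loglik + 2 p} form is \code{-2 *} this value.
#' \code{bic} uses a \code{log(n)/2} multiplier on the parameter count.
#'
#' @param kind One of \code{"loglik"}, \code{"aic"}, \code{"bic"}.
#' @return A \code{score_spec} object.
#' @export
score_spec <- function(kind = c("aic", "bic", "loglik")) {
  kind <- match.arg(kind)
  structure(list(kind = kind), class = "score_spec")
}

# Counts for a family (child, parents): 2 x 2^p matrix, rows child = 1/0,
# columns in CPT configuration order (first parent most significant,
# present before absent).
family_counts <- function(data, child, parents) {
  p <- length(parents)
  ci <- data[, child]
  if (p == 0L) {
    n1 <- sum(ci)
    return(matrix(c(n1, length(ci) - n1), nrow = 2L))
  }
  pv <- data[, parents, drop = FALSE]
  idx <- cpt_config_index(pv, p)               # 1..2^p
  code <- (idx - 1L) * 2L + (1L - ci) + 1L     # child present first
  counts <- tabulate(code, nbins = 2L^(p + 1L))
  matrix(counts, nrow = 2L)
}

#' Family log-likelihood
#'
#' The maximized multinomial log-likelihood contribution of one node given
#' its parent set: \eqn{\sum_{c,pa} n(c,pa) \log(n(c,pa)/n(pa))}, with
#' \eqn{0 \log 0 = 0}.
#'
#' @param data Complete integer 0/1 matrix with named columns.
#' @param child Child column name.
#' @param parents Character vector of parent column names (may be empty).
#' @return Scalar log-likelihood (non-positive).
#' @export
family_loglik <- function(data, child, parents = character(0)) {
  data <- as_binary_matrix(data)
  counts <- family_counts(data, child, parents)
  n_pa <- colSums(counts)
  keep <- counts > 0
  sum(counts[keep] * log(counts[keep] /
                           rep(n_pa, each = 2L)[as.vector(keep)]))
}

# family score under a spec, with memoisation via `cache` (an environment)
family_score <- function(data, child, parents, spec, cache = NULL) {
  key <- paste0(child, "|", paste(sort(parents), collapse = ","))
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  ll <- family_loglik(data, child, parents)
  val <- switch(spec$kind,
                loglik = ll,
                aic = ll - 2^length(parents),
                bic = ll - 2^length(parents) * log(nrow(data)) / 2)
  if (!is.null(cache)) cache[[key]] <- val
  val
}

#' AIC score of a DAG on a binary dataset
#'
#' Decomposable network AIC in the higher-is-better convention:
#' \eqn{\sum_v \mathrm{loglik}(v \mid pa(v)) - \sum_v 2^{|pa(v)|}}.
#'
#' @param data Complete integer 0/1 matrix with named columns.
#' @param g A \code{symptom_dag} whose nodes are the data columns.
#' @return Scalar score; higher means lower estimated prediction error.
#' @export
aic_score <- function(data, g) {
  network_score(data, g, score_spec("aic"))
}

#' Score a DAG on a binary dataset
#'
#' @param data Complete integer 0/1 matrix with named columns.
#' @param g A \code{symptom_dag}.
#' @param spec A \code{score_spec} (default AIC).
#' @return Scalar decomposable network score (higher is better).
#' @export
network_score <- function(data, g, spec = score_spec("aic")) {
  data <- as_binary_matrix(data)
  stopifnot(inherits(g, "symptom_dag"))
  if (!setequal(g$nodes, colnames(data))) {
    stop("DAG nodes and data columns disagree")
  }
  sum(vapply(g$nodes, function(v) {
    family_score(data, v, dag_parents(g, v), spec)
  }, numeric(1)))
}

#' Held-out log-likelihood of a fitted network
#'
#' Average-free total log-likelihood of new rows under a fitted network;
#' rows whose probability is zero under the model contribute \code{-Inf}
#' unless the CPTs were smoothed.
#'
#' @param net A \code{symptom_bn}.
#' @param data Integer 0/1 matrix of held-out rows.
#' @return Scalar log-likelihood.
#' @export
heldout_loglik <- function(net, data) {
  data <- as_binary_matrix(data)
  stopifnot(inherits(net, "symptom_bn"))
  total <- 0
  for (v in net$dag$nodes) {
    cp <- net$cpts[[v]]
    p1 <- cpt_lookup(cp, data[, cp$parents, drop = FALSE])
    pr <- ifelse(data[, v] == 1L, p1, 1 - p1)
    total <- total + sum(log(pr))
  }
  total
}
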