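#' k-nearest-neighbour imputation of 0-10 symptom scores
#'
#' Replaces every missing cell by the rounded mean score of the k nearest
#' rows that observe that column. The distance between two rows is the
#' root-mean-square difference over the columns observed in both,
#' \eqn{d(i,j) = \sqrt{\sum_{c \in S_{ij}} (x_{ic}-x_{jc})^2 / |S_{ij}|}},
#' which normalizes for how many columns the two rows share. Rows that
#' share no observed column are at infinite distance. Distance ties are
#' broken by row index, the neighbour mean is rounded half away from zero
#' to an integer and clamped to 0-10. Observed cells are never altered, and
#' imputation of one cell never uses another imputed cell.
#'
#' @param scores Integer matrix of 0-10 scores with \code{NA} for missing
#'   cells.
#' @param k Number of neighbours (default 5).
#' @return Complete integer score matrix.
#' @export
knn_impute <- function(scores, k = 5L) {
  stopifnot(is.matrix(scores), k >= 1L)
  if (!anyNA(scores)) return(scores)
  obs <- !is.na(scores)
  if (any(rowSums(obs) == 0L)) {
    stop("row(s) with all cells missing cannot be imputed: ",
         paste(which(rowSums(obs) == 0L), collapse = ", "))
  }
  n <- nrow(scores)
  need <- which(rowSums(!obs) > 0L)
  out <- scores
  X <- scores
  X[!obs] <- 0L
  for (i in need) {
    # shared-column RMS distance from row i to every other row
    oi <- obs[i, ]
    shared <- obs %*% oi                       # count of shared columns
    diff2 <- (t(t(X) - X[i, ]))^2
    diff2[!obs] <- 0
    diff2[, !oi] <- 0
    ss <- rowSums(diff2)
    d <- ifelse(shared > 0, sqrt(ss / pmax(shared, 1L)), Inf)
    d[i] <- Inf
    for (j in unname(which(!obs[i, ]))) {
      cand <- which(obs[, j] & is.finite(d))
      if (length(cand) < k) {
        stop("fewer than k = ", k, " candidate neighbours observe column '",
             colnames(scores)[j], "' for row ", i)
      }
      ord <- cand[order(d[cand], cand)]        # tie-break by row index
      nn <- ord[seq_len(k)]
      val <- round_half_away(mean(scores[nn, j]))
      out[i, j] <- as.integer(min(10L, max(0L, val)))
    }
  }
  out
}

#' Dichotomize symptom scores at the clinically relevant cut-off
#'
#' A score at or above the threshold (default 4, the conventional
#' clinically relevant cut-off for 0-10 symptom-assessment scales) becomes
#' 1 (present), anything below becomes 0 (absent).
#'
#' @param scores Complete integer score matrix (impute first).
#' @param threshold Integer cut-off in 1-10 (default 4).
#' @return Integer 0/1 matrix of the same shape.
#' @export
dichotomize <- function(scores, threshold = 4L) {
  stopifnot(is.matrix(scores))
  threshold <- as.integer(threshold)
  stopifnot(threshold >= 1L, threshold <= 10L)
  if (anyNA(scores)) {
    stop("scores contain missing cells; run knn_impute() first")
  }
  out <- matrix(as.integer(scores >= threshold), nrow = nrow(scores),
                dimnames = dimnames(scores))
  out
}

#' Per-symptom prevalence of clinically relevant scores
#'
#' @param binary Integer 0/1 matrix.
#' @return Named numeric vector: for each column, the proportion of rows
#'   with the symptom present.
#' @export
prevalence <- function(binary) {
  binary <- as_binary_matrix(binary)
  if (nrow(binary) == 0L) stop("empty dataset")
  colMeans(binary)
}

# round half away from zero (so 0.5 -> 1, -0.5 -> -1), per digit position
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}
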