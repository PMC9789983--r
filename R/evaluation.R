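#' Fold assignment for k-fold cross-validation
#'
#' Seeded shuffle of the row indices followed by a contiguous split into
#' folds whose sizes differ by at most one. Folds are not stratified.
#'
#' @param n_rows Number of rows.
#' @param k Number of folds (default 4).
#' @param seed Integer RNG seed.
#' @return Integer vector of length \code{n_rows} with fold labels 1..k.
#' @export
kfold_split <- function(n_rows, k = 4L, seed = 1L) {
  stopifnot(n_rows >= k, k >= 2L)
  local_seed(seed)
  perm <- sample.int(n_rows)
  sizes <- rep(n_rows %/% k, k)
  extra <- n_rows %% k
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  fold <- integer(n_rows)
  fold[perm] <- rep(seq_len(k), times = sizes)
  fold
}

#' Cross-validated algorithm selection by mean AIC
#'
#' For each registered algorithm and each fold, a structure is learned on
#' the training portion and its AIC computed; the algorithms are ranked by
#' mean AIC over folds (highest first: the lowest estimated prediction
#' error). The held-out log-likelihood of each fold's fitted model
#' (Laplace-smoothed CPTs) is also reported. An algorithm that fails on any
#' fold is excluded from the ranking with a warning.
#'
#' @param data Complete integer 0/1 matrix with named columns.
#' @param registry Named list of learners, as from
#'   \code{\link{algorithm_menu}}.
#' @param k Number of folds (default 4).
#' @param seed Integer RNG seed (drives the fold split and any learner
#'   randomness).
#' @param aic_on \code{"train"} (default) scores each learned structure on
#'   its training fold; \code{"test"} reports mean held-out log-likelihood
#'   as the ranking criterion instead.
#' @return data.frame with one row per algorithm: \code{algorithm},
#'   \code{mean_aic}, \code{sd_aic}, \code{mean_heldout_loglik},
#'   \code{rank}; ordered by the ranking criterion, best first.
#' @export
cv_algorithm_selection <- function(data, registry = algorithm_menu(),
                                   k = 4L, seed = 1L,
                                   aic_on = c("train", "test")) {
  data <- as_binary_matrix(data)
  aic_on <- match.arg(aic_on)
  fold <- kfold_split(nrow(data), k, seed)
  seeds <- derive_seeds(seed, length(registry) * k)
  rows <- list()
  for (ai in seq_along(registry)) {
    name <- names(registry)[ai]
    aics <- numeric(k)
    hls <- numeric(k)
    failed <- FALSE
    for (f in seq_len(k)) {
      train <- data[fold != f, , drop = FALSE]
      test <- data[fold == f, , drop = FALSE]
      res <- tryCatch({
        ls <- registry[[ai]](train, seed = seeds[(ai - 1L) * k + f])
        aics[f] <- aic_score(train, ls$dag)
        net <- fit_cpts(train, ls$dag, smoothing_alpha = 1)
        hls[f] <- heldout_loglik(net, test)
        TRUE
      }, error = function(e) {
        warning("algorithm '", name, "' failed on fold ", f, ": ",
                conditionMessage(e))
        FALSE
      })
      if (!isTRUE(res)) { failed <- TRUE; break }
    }
    if (failed) next
    rows[[name]] <- data.frame(algorithm = name, mean_aic = mean(aics),
                               sd_aic = stats::sd(aics),
                               mean_heldout_loglik = mean(hls))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  crit <- if (aic_on == "train") out$mean_aic else out$mean_heldout_loglik
  out <- out[order(-crit), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Rank-based AUC-ROC
#'
#' Mann-Whitney formulation: the probability that a randomly chosen
#' positive row is ranked above a randomly chosen negative row, with ties
#' counting one half.
#'
#' @param predicted Numeric vector of predicted probabilities (any
#'   monotone score works: AUC is rank-based).
#' @param labels Integer 0/1 vector of true classes.
#' @return AUC in [0, 1]; \code{NA} with a warning if only one class is
#'   present.
#' @export
auc_roc <- function(predicted, labels) {
  stopifnot(length(predicted) == length(labels))
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    warning("AUC undefined: only one class present")
    return(NA_real_)
  }
  r <- rank(predicted, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Pooled held-out predictions: per fold, learn a structure on the training
# rows (via `learner`), fit Laplace-smoothed CPTs, and predict each held-out
# row's value for every symptom from the other ten. Returns a matrix of
# predictions aligned with `data`, plus the per-row fold labels.
cv_predictions <- function(data, learner, k = 4L, seed = 1L,
                           smoothing_alpha = 1) {
  data <- as_binary_matrix(data)
  fold <- kfold_split(nrow(data), k, seed)
  seeds <- derive_seeds(seed, k)
  pred <- matrix(NA_real_, nrow(data), ncol(data),
                 dimnames = dimnames(data))
  for (f in seq_len(k)) {
    train <- data[fold != f, , drop = FALSE]
    test_idx <- which(fold == f)
    ls <- learner(train, seed = seeds[f])
    net <- fit_cpts(train, ls$dag, smoothing_alpha = smoothing_alpha)
    for (v in colnames(data)) {
      pred[test_idx, v] <- predict_matrix(net, data[test_idx, , drop = FALSE],
                                          v)
    }
  }
  list(predictions = pred, fold = fold)
}

#' Cross-validated per-symptom AUC
#'
#' Per fold, a structure is learned and CPTs fitted on the training rows;
#' each held-out row's probability of each symptom is predicted from the
#' other ten symptoms. Per symptom, the AUC is computed within each fold
#' and summarized as mean and SD over folds, with the satisfactory flag at
#' mean AUC >= 0.65.
#'
#' @param data Complete integer 0/1 matrix with named columns.
#' @param learner Function \code{(data, seed)} returning a
#'   \code{learned_structure} (e.g. an entry of
#'   \code{\link{algorithm_menu}}).
#' @param k Number of folds (default 4).
#' @param seed Integer RNG seed.
#' @param satisfactory Mean-AUC threshold for the flag (default 0.65).
#' @param cv Optional precomputed result of the internal cross-validated
#'   prediction pass, to share work with \code{\link{calibration}}.
#' @return data.frame with one row per symptom: \code{symptom},
#'   \code{mean_auc}, \code{sd_auc}, \code{satisfactory}.
#' @export
symptom_auc_cv <- function(data, learner, k = 4L, seed = 1L,
                           satisfactory = 0.65, cv = NULL) {
  data <- as_binary_matrix(data)
  if (is.null(cv)) cv <- cv_predictions(data, learner, k, seed)
  out <- lapply(colnames(data), function(v) {
    aucs <- vapply(seq_len(k), function(f) {
      idx <- cv$fold == f
      suppressWarnings(auc_roc(cv$predictions[idx, v], data[idx, v]))
    }, numeric(1))
    data.frame(symptom = v, mean_auc = mean(aucs, na.rm = TRUE),
               sd_auc = stats::sd(aucs, na.rm = TRUE),
               satisfactory = mean(aucs, na.rm = TRUE) >= satisfactory)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Decile calibration of cross-validated predictions
#'
#' Pools the held-out predictions of all folds; per symptom, rows are
#' sorted by predicted probability (stable sort, row-index tie-break) and
#' split into 10 bins of near-equal count. Each bin compares the mean
#' predicted probability with the observed symptom frequency; a bin is
#' accurate when the absolute difference is at most \code{tolerance}
#' (default 0.10, i.e. ten percentage points).
#'
#' @inheritParams symptom_auc_cv
#' @param n_bins Number of probability bins (default 10).
#' @param tolerance Maximum accurate |predicted - observed| (default 0.10).
#' @return List of class \code{calibration_table}: \code{table} (one row
#'   per symptom per decile: mean predicted, observed frequency, count,
#'   accurate flag), \code{n_accurate}, \code{n_total}.
#' @export
calibration <- function(data, learner, k = 4L, seed = 1L, n_bins = 10L,
                        tolerance = 0.10, cv = NULL) {
  data <- as_binary_matrix(data)
  if (nrow(data) < n_bins) stop("fewer than ", n_bins, " pooled rows")
  if (is.null(cv)) cv <- cv_predictions(data, learner, k, seed)
  rows <- list()
  for (v in colnames(data)) {
    p <- cv$predictions[, v]
    ord <- order(p, seq_along(p))          # stable, row-index tie-break
    sizes <- rep(length(p) %/% n_bins, n_bins)
    extra <- length(p) %% n_bins
    if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    bin_of <- rep(seq_len(n_bins), times = sizes)
    for (b in seq_len(n_bins)) {
      idx <- ord[bin_of == b]
      mp <- mean(p[idx])
      obs <- mean(data[idx, v])
      rows[[length(rows) + 1L]] <- data.frame(
        symptom = v, decile = b, n = length(idx), mean_predicted = mp,
        observed_frequency = obs, accurate = abs(mp - obs) <= tolerance)
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(table = tab, n_accurate = sum(tab$accurate),
                 n_total = nrow(tab), tolerance = tolerance),
            class = "calibration_table")
}

#' @export
print.calibration_table <- function(x, ...) {
  cat("Decile calibration: ", x$n_accurate, "/", x$n_total,
      " comparisons accurate (|predicted - observed| <= ", x$tolerance,
      ")\n", sep = "")
  invisible(x)
}

#' Bootstrap edge-direction voting
#'
#' Resamples rows with replacement, relearns the structure on each
#' replicate, and tallies how often each directed edge appears. An
#' undirected adjacency is resolved to a direction when that direction's
#' fraction over replicates reaches the majority threshold.
#'
#' @param data Complete integer 0/1 matrix with named columns.
#' @param learner Function \code{(data, seed)} returning a
#'   \code{learned_structure}.
#' @param n_boot Number of bootstrap replicates (default 10000; desk-scale
#'   analyses use a few hundred).
#' @param majority Fraction required to resolve a direction, in (0.5, 1]
#'   (default 0.51).
#' @param seed Integer RNG seed.
#' @return data.frame with one row per adjacency ever observed:
#'   \code{from}, \code{to} (the canonical lower node first),
#'   \code{fraction_forward}, \code{fraction_backward} (of all
#'   replicates), \code{direction} (\code{"forward"}, \code{"backward"} or
#'   \code{"unresolved"}).
#' @export
bootstrap_edge_directions <- function(data, learner, n_boot = 10000L,
                                      majority = 0.51, seed = 1L) {
  data <- as_binary_matrix(data)
  stopifnot(n_boot >= 1L, majority > 0.5, majority <= 1)
  nodes <- colnames(data)
  local_seed(seed)
  row_seeds <- derive_seeds(seed, n_boot)
  counts <- new.env(parent = emptyenv())
  for (b in seq_len(n_boot)) {
    idx <- sample.int(nrow(data), replace = TRUE)
    ls <- learner(data[idx, , drop = FALSE], seed = row_seeds[b])
    if (nrow(ls$dag$edges) == 0L) next
    for (r in seq_len(nrow(ls$dag$edges))) {
      key <- paste0(ls$dag$edges[r, 1L], ">", ls$dag$edges[r, 2L])
      counts[[key]] <- (if (is.null(counts[[key]])) 0L else counts[[key]]) + 1L
    }
  }
  keys <- ls(counts)
  if (length(keys) == 0L) {
    return(data.frame(from = character(0), to = character(0),
                      fraction_forward = numeric(0),
                      fraction_backward = numeric(0),
                      direction = character(0)))
  }
  parts <- strsplit(keys, ">", fixed = TRUE)
  from <- vapply(parts, `[[`, character(1), 1L)
  to <- vapply(parts, `[[`, character(1), 2L)
  i <- match(from, nodes); j <- match(to, nodes)
  lo <- ifelse(i < j, from, to)
  hi <- ifelse(i < j, to, from)
  pair <- paste0(lo, "--", hi)
  out <- lapply(unique(pair), function(pk) {
    sel <- pair == pk
    a <- lo[sel][1L]; b <- hi[sel][1L]
    fwd_key <- paste0(a, ">", b)
    bwd_key <- paste0(b, ">", a)
    n_fwd <- if (is.null(counts[[fwd_key]])) 0L else counts[[fwd_key]]
    n_bwd <- if (is.null(counts[[bwd_key]])) 0L else counts[[bwd_key]]
    f_fwd <- n_fwd / n_boot
    f_bwd <- n_bwd / n_boot
    dirn <- if (f_fwd >= majority) "forward" else if (f_bwd >= majority) {
      "backward"
    } else "unresolved"
    data.frame(from = a, to = b, fraction_forward = f_fwd,
               fraction_backward = f_bwd, direction = dirn)
  })
  out <- do.call(rbind, out)
  out[order(match(out$from, nodes), match(out$to, nodes)), , drop = FALSE]
}

#' Operating thresholds from an empirical ROC curve
#'
#' Scans every candidate probability cut-off (rows classified positive at
#' predicted >= cut-off) and returns two clinically motivated operating
#' points: the lowest cut-off whose specificity reaches
#' \code{min_specificity} (few false positives, for time-limited
#' assessment) and the highest cut-off whose sensitivity reaches
#' \code{min_sensitivity} (few false negatives, when time allows).
#'
#' @param predicted Numeric predicted probabilities.
#' @param labels Integer 0/1 true classes (both classes must be present).
#' @param min_sensitivity Sensitivity constraint (default 0.9).
#' @param min_specificity Specificity constraint (default 0.9).
#' @return List with \code{high_specificity} and \code{high_sensitivity},
#'   each either a list \code{(threshold, sensitivity, specificity)} or
#'   \code{NULL} when the constraint is unattainable.
#' @export
operating_thresholds <- function(predicted, labels, min_sensitivity = 0.9,
                                 min_specificity = 0.9) {
  labels <- as.integer(labels)
  if (sum(labels == 1L) == 0L || sum(labels == 0L) == 0L) {
    stop("both classes must be present")
  }
  cand <- sort(unique(c(0, predicted, 1)))
  stats_at <- function(t) {
    pos <- predicted >= t
    c(sens = sum(pos & labels == 1L) / sum(labels == 1L),
      spec = sum(!pos & labels == 0L) / sum(labels == 0L))
  }
  m <- vapply(cand, stats_at, numeric(2))
  ok_spec <- which(m["spec", ] >= min_specificity)
  ok_sens <- which(m["sens", ] >= min_sensitivity)
  pick <- function(i) {
    if (length(i) == 0L) return(NULL)
    list(threshold = cand[i], sensitivity = unname(m["sens", i]),
         specificity = unname(m["spec", i]))
  }
  list(high_specificity = pick(if (length(ok_spec)) min(ok_spec) else integer(0)),
       high_sensitivity = pick(if (length(ok_sens)) max(ok_sens) else integer(0)))
}
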