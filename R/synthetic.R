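#' Configuration for the synthetic symptom-survey generator
#'
#' Defaults reproduce the shape of the reference survey: 532 returned
#' questionnaires, 26 of them with 1 to 3 missing scores for a total of 36
#' missing cells, scores on a 0-10 numeric rating scale with the clinically
#' relevant cut-off at >= 4. Present symptoms receive integer scores from
#' \code{nrs_present_range}, absent symptoms from \code{nrs_absent_range};
#' because the two ranges sit on opposite sides of the cut-off,
#' dichotomizing a generated dataset recovers the underlying binary matrix
#' exactly.
#'
#' @param n_patients Number of rows to generate (default 532).
#' @param nrs_present_range Integer score interval for present symptoms
#'   (default \code{c(4, 10)}).
#' @param nrs_absent_range Integer score interval for absent symptoms
#'   (default \code{c(0, 3)}).
#' @param missing_rows Number of rows that receive missing cells
#'   (default 26).
#' @param missing_cells_total Total number of missing cells (default 36).
#' @param missing_composition Optional integer vector \code{c(ones, twos,
#'   threes)}: how many affected rows have 1, 2 and 3 missing cells. The
#'   default for 26 rows / 36 cells is \code{c(18, 6, 2)}; otherwise the
#'   feasible composition with the fewest 3-cell rows is chosen.
#' @param threshold Dichotomization cut-off (default 4).
#' @return A \code{generator_config} list.
#' @export
generator_config <- function(n_patients = 532L,
                             nrs_present_range = c(4L, 10L),
                             nrs_absent_range = c(0L, 3L),
                             missing_rows = 26L,
                             missing_cells_total = 36L,
                             missing_composition = NULL,
                             threshold = 4L) {
  stopifnot(n_patients >= 1L, length(nrs_present_range) == 2L,
            length(nrs_absent_range) == 2L)
  if (any(c(nrs_present_range, nrs_absent_range) < 0L) ||
      any(c(nrs_present_range, nrs_absent_range) > 10L)) {
    stop("NRS ranges must lie within 0-10")
  }
  if (nrs_absent_range[2L] >= threshold || nrs_present_range[1L] < threshold) {
    stop("NRS ranges must not overlap the dichotomization threshold (",
         threshold, "): absent range must stay below it, present range at ",
         "or above it")
  }
  if (is.null(missing_composition)) {
    missing_composition <- solve_missing_composition(missing_rows,
                                                     missing_cells_total)
  } else {
    missing_composition <- as.integer(missing_composition)
    stopifnot(length(missing_composition) == 3L,
              all(missing_composition >= 0L))
    if (sum(missing_composition) != missing_rows ||
        sum(missing_composition * 1:3) != missing_cells_total) {
      stop("missing_composition inconsistent with missing_rows/",
           "missing_cells_total")
    }
  }
  structure(list(n_patients = as.integer(n_patients),
                 nrs_present_range = as.integer(nrs_present_range),
                 nrs_absent_range = as.integer(nrs_absent_range),
                 missing_rows = as.integer(missing_rows),
                 missing_cells_total = as.integer(missing_cells_total),
                 missing_composition = missing_composition,
                 threshold = as.integer(threshold)),
            class = "generator_config")
}

# Rows with 1..3 missing cells: a + b + c = rows, a + 2b + 3c = cells.
# The survey default (26, 36) uses (18, 6, 2); any other request takes the
# feasible solution with the fewest 3-cell rows.
solve_missing_composition <- function(rows, cells) {
  rows <- as.integer(rows); cells <- as.integer(cells)
  if (rows == 0L) {
    if (cells != 0L) stop("missing_cells_total must be 0 when missing_rows is 0")
    return(c(0L, 0L, 0L))
  }
  if (cells < rows || cells > 3L * rows) {
    stop("missing_cells_total must lie in [missing_rows, 3*missing_rows] ",
         "so each affected row has 1-3 missing cells")
  }
  if (rows == 26L && cells == 36L) return(c(18L, 6L, 2L))
  extra <- cells - rows            # b + 2c = extra
  c3 <- max(0L, extra - rows)      # need b = extra - 2*c3 <= rows - c3
  b <- extra - 2L * c3
  a <- rows - b - c3
  c(a, b, c3)
}

#' Ancestral sampling from a discrete Bayesian network
#'
#' Visits nodes in topological order and draws each from its CPT given the
#' already-sampled parent values; fully reproducible for a fixed seed.
#'
#' @param net A \code{symptom_bn}.
#' @param n Number of rows to draw.
#' @param seed Integer RNG seed.
#' @return Integer 0/1 matrix with \code{n} rows and one column per node
#'   (columns in canonical node order).
#' @export
sample_binary <- function(net, n, seed = 1L) {
  stopifnot(inherits(net, "symptom_bn"), n >= 1L)
  nodes <- net$dag$nodes
  out <- matrix(0L, nrow = n, ncol = length(nodes),
                dimnames = list(NULL, nodes))
  local_seed(seed)
  for (v in topological_order(net$dag)) {
    cp <- net$cpts[[v]]
    p1 <- cpt_lookup(cp, out[, cp$parents, drop = FALSE])
    out[, v] <- as.integer(stats::runif(n) < p1)
  }
  out
}

#' Expand a binary presence/absence matrix to 0-10 NRS scores
#'
#' Present cells receive a uniform integer draw from the configured present
#' range, absent cells from the absent range. Because the two ranges lie on
#' opposite sides of the dichotomization threshold,
#' \code{dichotomize(expand_to_nrs(B))} recovers \code{B} exactly.
#'
#' @param binary Integer 0/1 matrix (symptom columns).
#' @param config A \code{generator_config}.
#' @param seed Integer RNG seed.
#' @return Integer score matrix of the same shape.
#' @export
expand_to_nrs <- function(binary, config = generator_config(), seed = 1L) {
  binary <- as_binary_matrix(binary)
  local_seed(seed)
  n_cells <- length(binary)
  pr <- config$nrs_present_range
  ar <- config$nrs_absent_range
  present_draw <- sample(seq(pr[1L], pr[2L]), n_cells, replace = TRUE)
  absent_draw <- sample(seq(ar[1L], ar[2L]), n_cells, replace = TRUE)
  out <- ifelse(binary == 1L, present_draw, absent_draw)
  out <- matrix(as.integer(out), nrow = nrow(binary),
                dimnames = dimnames(binary))
  out
}

#' Inject survey-style missingness into a complete score matrix
#'
#' Selects \code{missing_rows} distinct rows uniformly at random, assigns
#' each a burden of 1-3 missing cells according to the configured
#' composition, and blanks uniformly chosen columns in those rows. The
#' mechanism is missing completely at random.
#'
#' @param scores Complete integer score matrix.
#' @param config A \code{generator_config}.
#' @param seed Integer RNG seed.
#' @return The matrix with \code{missing_cells_total} cells set to
#'   \code{NA}.
#' @export
inject_missing <- function(scores, config = generator_config(), seed = 1L) {
  stopifnot(is.matrix(scores))
  if (anyNA(scores)) stop("input matrix already contains missing cells")
  comp <- config$missing_composition
  n_aff <- sum(comp)
  if (n_aff == 0L) return(scores)
  if (nrow(scores) < n_aff) {
    stop("dataset has ", nrow(scores), " rows; cannot affect ", n_aff)
  }
  local_seed(seed)
  rows <- sample(nrow(scores), n_aff)
  burdens <- rep(1:3, times = comp)
  for (i in seq_along(rows)) {
    cols <- sample(ncol(scores), burdens[i])
    scores[rows[i], cols] <- NA_integer_
  }
  scores
}

#' Generate a complete synthetic symptom survey
#'
#' Convenience wrapper: ancestral-samples binary symptom states from a
#' network (by default the reference network), expands them to 0-10 scores
#' and injects survey-style missingness.
#'
#' @param config A \code{generator_config}.
#' @param net Generating network (default \code{reference_network()}).
#' @param seed Integer RNG seed; sub-stages derive their own seeds from it.
#' @return List with \code{binary} (the latent truth), \code{scores} (the
#'   observed NRS matrix with missing cells) and the \code{config} used.
#' @export
simulate_survey <- function(config = generator_config(),
                            net = reference_network(), seed = 1L) {
  seeds <- derive_seeds(seed, 3L)
  binary <- sample_binary(net, config$n_patients, seed = seeds[1L])
  scores <- expand_to_nrs(binary, config, seed = seeds[2L])
  scores <- inject_missing(scores, config, seed = seeds[3L])
  list(binary = binary, scores = scores, config = config)
}

#' Write a symptom score matrix to CSV
#'
#' Header row of canonical symptom names; missing cells are left empty.
#'
#' @param x Integer matrix (scores or binary).
#' @param file Output path.
#' @return \code{file}, invisibly.
#' @export
write_symptom_csv <- function(x, file) {
  utils::write.csv(as.data.frame(x), file, row.names = FALSE, na = "")
  invisible(file)
}

#' Read a symptom score matrix from CSV
#'
#' Column names are canonicalized; the canonical 11 symptom columns must
#' all be present (extra columns are dropped with a warning).
#'
#' @param file CSV path.
#' @return Integer matrix with canonical symptom columns; empty cells
#'   become \code{NA}.
#' @export
read_symptom_csv <- function(file) {
  df <- utils::read.csv(file, check.names = FALSE)
  nm <- gsub("[. -]+", "_", tolower(trimws(names(df))))
  names(df) <- nm
  missing_cols <- setdiff(symptom_labels(), nm)
  if (length(missing_cols) > 0L) {
    stop("CSV is missing symptom column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  extra <- setdiff(nm, symptom_labels())
  if (length(extra) > 0L) {
    warning("dropping non-symptom column(s): ", paste(extra, collapse = ", "))
  }
  m <- as.matrix(df[symptom_labels()])
  storage.mode(m) <- "integer"
  rownames(m) <- NULL
  m
}

# -- internal helpers --------------------------------------------------------

# Seed the session RNG locally: restores the caller's RNG state on exit of
# the calling function.
local_seed <- function(seed, env = parent.frame()) {
  if (is.null(seed)) return(invisible(NULL))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  withr::defer({
    if (is.null(old)) {
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, envir = env)
  set.seed(as.integer(seed))
  invisible(NULL)
}

# Deterministic stream of sub-seeds below 2^31 from a master seed.
derive_seeds <- function(seed, n) {
  (as.numeric(seed) * 1103515245 + 12345 * seq_len(n)) %% 2147483647
}

as_binary_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  stopifnot(is.matrix(x))
  if (anyNA(x)) stop("binary matrix must be complete (no missing cells)")
  if (!all(x %in% c(0L, 1L))) stop("binary matrix values must be 0 or 1")
  storage.mode(x) <- "integer"
  x
}
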