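#' Conditional-probability report of a fitted network
#'
#' One row per node per parent configuration, in the presentation style of
#' clinical symptom-network reports: parent nodes are labelled "main
#' symptoms" with +/- states, the child is the "predicted simultaneous
#' symptom", and the probability of its presence is given as a percentage
#' rounded half away from zero to one decimal.
#'
#' @param net A \code{symptom_bn}.
#' @return data.frame with columns \code{main_symptoms} (e.g.
#'   \code{"fatigue+, dysphagia-"}; \code{"-"} for a root node),
#'   \code{simultaneous_symptom} and \code{probability_pct}.
#' @export
cpt_report <- function(net) {
  stopifnot(inherits(net, "symptom_bn"))
  rows <- list()
  for (v in net$dag$nodes) {
    cp <- net$cpts[[v]]
    p <- length(cp$parents)
    cfg <- parent_config_matrix(p)
    for (r in seq_len(nrow(cfg))) {
      main <- if (p == 0L) "-" else {
        paste(paste0(cp$parents, ifelse(cfg[r, ] == 1L, "+", "-")),
              collapse = ", ")
      }
      rows[[length(rows) + 1L]] <- data.frame(
        main_symptoms = main, simultaneous_symptom = v,
        probability_pct = round_half_away(100 * cp$prob[r], 1))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Symptom-prediction flow-chart from a starting symptom
#'
#' For a chosen start symptom (by default the node with the most children
#' — the network hub), lists each child with its probability of being
#' present when the start symptom is present versus absent, the shape of a
#' two-branch bedside prediction chart.
#'
#' @param net A \code{symptom_bn}.
#' @param start Start node; default picks the node with the largest number
#'   of children (earliest in canonical order on ties).
#' @return List of class \code{symptom_flowchart}: \code{start} and
#'   \code{children} (data.frame with \code{symptom},
#'   \code{pct_if_present}, \code{pct_if_absent}). A start node without
#'   children yields an empty chart with a notice attribute.
#' @export
flowchart <- function(net, start = NULL) {
  stopifnot(inherits(net, "symptom_bn"))
  if (is.null(start)) {
    n_children <- vapply(net$dag$nodes, function(v) {
      length(dag_children(net$dag, v))
    }, integer(1))
    start <- net$dag$nodes[which.max(n_children)]
  }
  stopifnot(start %in% net$dag$nodes)
  kids <- dag_children(net$dag, start)
  if (length(kids) == 0L) {
    out <- structure(list(start = start,
                          children = data.frame(symptom = character(0),
                                                pct_if_present = numeric(0),
                                                pct_if_absent = numeric(0))),
                     class = "symptom_flowchart")
    attr(out, "notice") <- paste0("node '", start, "' has no children")
    return(out)
  }
  children <- do.call(rbind, lapply(kids, function(ch) {
    p1 <- query(net, ch, stats::setNames(1L, start))$probability
    p0 <- query(net, ch, stats::setNames(0L, start))$probability
    data.frame(symptom = ch,
               pct_if_present = round_half_away(100 * p1, 1),
               pct_if_absent = round_half_away(100 * p0, 1))
  }))
  structure(list(start = start, children = children),
            class = "symptom_flowchart")
}

#' @export
print.symptom_flowchart <- function(x, ...) {
  cat("Symptom prediction flow-chart, start =", x$start, "\n")
  if (nrow(x$children) == 0L) {
    cat("  (no children)\n")
  } else {
    for (r in seq_len(nrow(x$children))) {
      cat(sprintf("  %-20s %5.1f%% if present, %5.1f%% if absent\n",
                  x$children$symptom[r], x$children$pct_if_present[r],
                  x$children$pct_if_absent[r]))
    }
  }
  invisible(x)
}

#' Calibration plot for one symptom
#'
#' Mean predicted probability against observed frequency per decile, with
#' the identity line of perfect calibration.
#'
#' @param calib A \code{calibration_table}.
#' @param symptom Symptom to plot.
#' @param file Optional PNG path; when given the plot is written there.
#' @return Invisibly, the plotted decile table.
#' @export
plot_calibration <- function(calib, symptom, file = NULL) {
  stopifnot(inherits(calib, "calibration_table"))
  tab <- calib$table[calib$table$symptom == symptom, , drop = FALSE]
  if (nrow(tab) == 0L) stop("no calibration rows for ", symptom)
  if (!is.null(file)) {
    grDevices::png(file, width = 640, height = 640)
    on.exit(grDevices::dev.off())
  }
  graphics::plot(tab$mean_predicted, tab$observed_frequency,
                 xlim = c(0, 1), ylim = c(0, 1), pch = 19,
                 xlab = "Mean predicted probability",
                 ylab = "Observed frequency",
                 main = paste("Calibration:", symptom))
  graphics::abline(0, 1)
  invisible(tab)
}

#' Run the full symptom-network analysis pipeline
#'
#' End to end: load (or synthesize) a score dataset, impute missing scores
#' by k-nearest neighbours, dichotomize at the clinically relevant
#' cut-off, select the structure-learning algorithm by cross-validated
#' AIC, relearn on the full data with the winner, fit CPTs, and produce
#' the conditional-probability report, flow-chart, AUC and calibration
#' evaluations. All artifacts are written under \code{output_dir} and
#' stamped with the configuration hash and seed.
#'
#' @param config Named list (or path to a YAML file holding one) with
#'   entries: \code{input} (CSV path) or \code{synthetic = TRUE};
#'   \code{seed} (default 1); \code{k_impute} (default 5);
#'   \code{threshold} (default 4); \code{k_folds} (default 4);
#'   \code{algorithm} (name in the registry, or \code{"auto"} for
#'   CV-selection, the default); \code{n_patients} (synthetic size,
#'   default 532); \code{plots} (default TRUE).
#' @param output_dir Directory for the artifact bundle.
#' @return List with the fitted \code{network}, \code{aic_ranking},
#'   \code{auc}, \code{calibration}, \code{cpt_report}, \code{flowchart}
#'   and the resolved \code{config}; files are written as a side effect.
#' @export
run_pipeline <- function(config = list(synthetic = TRUE),
                         output_dir = tempfile("symptom_pipeline_")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(synthetic = FALSE, input = NULL, seed = 1L,
                   k_impute = 5L, threshold = 4L, k_folds = 4L,
                   algorithm = "auto", n_patients = 532L, plots = TRUE)
  config <- utils::modifyList(defaults, config)
  if (!isTRUE(config$synthetic)) {
    if (is.null(config$input)) stop("config needs 'input' or synthetic = TRUE")
    if (!file.exists(config$input)) stop("input file not found: ",
                                         config$input)
  }
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  note <- function(...) {
    msg <- paste0(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  cfg_hash <- substr(digest_config(config), 1L, 12L)
  note("config hash ", cfg_hash, ", seed ", config$seed)

  scores <- if (isTRUE(config$synthetic)) {
    gen <- generator_config(n_patients = config$n_patients,
                            threshold = config$threshold)
    simulate_survey(gen, seed = config$seed)$scores
  } else {
    read_symptom_csv(config$input)
  }
  note("rows: ", nrow(scores), ", missing cells: ", sum(is.na(scores)))
  imputed <- knn_impute(scores, k = config$k_impute)
  note("imputed ", sum(is.na(scores)), " cells (k = ", config$k_impute, ")")
  binary <- dichotomize(imputed, threshold = config$threshold)

  registry <- algorithm_menu()
  if (identical(config$algorithm, "auto")) {
    ranking <- cv_algorithm_selection(binary, registry, k = config$k_folds,
                                      seed = config$seed)
    winner <- ranking$algorithm[1L]
  } else {
    if (!config$algorithm %in% names(registry)) {
      stop("unknown algorithm '", config$algorithm, "'")
    }
    ranking <- cv_algorithm_selection(binary,
                                      registry[config$algorithm],
                                      k = config$k_folds,
                                      seed = config$seed)
    winner <- config$algorithm
  }
  note("selected algorithm: ", winner)
  learner <- registry[[winner]]
  ls_full <- learner(binary, seed = config$seed)
  net <- fit_cpts(binary, ls_full$dag, smoothing_alpha = 0)

  cv <- cv_predictions(binary, learner, k = config$k_folds,
                       seed = config$seed)
  auc <- symptom_auc_cv(binary, learner, k = config$k_folds,
                        seed = config$seed, cv = cv)
  calib <- calibration(binary, learner, k = config$k_folds,
                       seed = config$seed, cv = cv)
  report <- cpt_report(net)
  chart <- flowchart(net)

  # artifact bundle
  stamp <- c(sprintf("# config_hash: %s", cfg_hash),
             sprintf("# seed: %s", config$seed))
  write_stamped_csv <- function(df, file) {
    path <- file.path(output_dir, file)
    con <- file(path, "w")
    writeLines(stamp, con)
    utils::write.csv(df, con, row.names = FALSE)
    close(con)
  }
  bn_to_json(net, file.path(output_dir, "network.json"))
  dag_to_dot(net$dag, file.path(output_dir, "network.dot"))
  write_stamped_csv(ranking, "aic_ranking.csv")
  write_stamped_csv(auc, "auc_table.csv")
  write_stamped_csv(calib$table, "calibration.csv")
  write_stamped_csv(report, "cpt_report.csv")
  jsonlite::write_json(list(start = chart$start, children = chart$children),
                       file.path(output_dir, "flowchart.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  if (isTRUE(config$plots)) {
    dir.create(file.path(output_dir, "calibration"), showWarnings = FALSE)
    for (v in unique(calib$table$symptom)) {
      plot_calibration(calib, v,
                       file.path(output_dir, "calibration",
                                 paste0(v, ".png")))
    }
  }
  writeLines(c(stamp, log_lines), file.path(output_dir, "pipeline.log"))
  invisible(list(network = net, aic_ranking = ranking, auc = auc,
                 calibration = calib, cpt_report = report,
                 flowchart = chart, config = config,
                 output_dir = output_dir))
}

# stable hash of the configuration list (no external digest dependency:
# serialize deterministically and fold into hex)
digest_config <- function(config) {
  txt <- paste(deparse(config[order(names(config))]), collapse = "")
  bytes <- utf8ToInt(txt)
  h <- c(17, 31, 73, 127)
  for (i in seq_along(bytes)) {
    j <- (i - 1L) %% 4L + 1L
    h[j] <- (h[j] * 131 + bytes[i]) %% 4294967291
  }
  paste(sprintf("%08x", as.integer(h %% 2147483647)), collapse = "")
}
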