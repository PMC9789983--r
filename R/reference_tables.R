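#' Published per-symptom AUC of the reference survey model
#'
#' The cross-validated predictive performance reported for the original
#' 532-patient advanced-cancer survey model: mean AUC-ROC over four folds
#' and its SD, per predicted symptom. Shipped so reports can juxtapose new
#' results with the reference model and so the satisfactory-performance
#' rule (mean AUC >= 0.65) can be applied to the published values.
#'
#' @param satisfactory Threshold for the satisfactory flag (default 0.65).
#' @return data.frame with \code{symptom}, \code{mean_auc}, \code{sd_auc},
#'   \code{satisfactory}.
#' @export
reference_auc_table <- function(satisfactory = 0.65) {
  out <- data.frame(
    symptom = symptom_labels(),
    mean_auc = c(0.60, 0.60, 0.66, 0.70, 0.70, 0.65, 0.75, 0.65, 0.64,
                 0.70, 0.78),
    sd_auc = c(0.07, 0.08, 0.10, 0.09, 0.05, 0.03, 0.04, 0.12, 0.10,
               0.08, 0.01))
  out$satisfactory <- out$mean_auc >= satisfactory
  out
}

#' Published symptom prevalences of the reference survey cohort
#'
#' Proportion of the original 532 patients with a clinically relevant
#' score (>= 4) per symptom. Used as the reference point for checking that
#' the marginal distribution implied by \code{\link{reference_network}}
#' reproduces the cohort it was estimated from.
#'
#' @return Named numeric vector of proportions, canonical symptom order.
#' @export
reference_prevalence <- function() {
  stats::setNames(
    c(195, 209, 241, 111, 274, 265, 64, 99, 344, 131, 161) / 532,
    symptom_labels())
}
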