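#' Registry of the nine structure-learning algorithms
#'
#' The menu spans the three algorithm families used for automated Bayesian
#' network learning: score-based (hill climbing, hill climbing with random
#' restarts, tabu search), constraint-based (PC-stable, grow-shrink, IAMB,
#' interleaved IAMB) and hybrid (MMHC-style constraint-restricted hill
#' climbing and skeleton-restricted tabu search). Every entry is a function
#' \code{function(data, seed)} returning a \code{learned_structure}.
#'
#' @param spec A \code{score_spec} used by the score-based and hybrid
#'   searches and for reporting (default AIC).
#' @param alpha Significance level for the constraint-based tests
#'   (default 0.05).
#' @return Named list of 9 learner functions.
#' @examples
#' menu <- algorithm_menu()
#' names(menu)
#' @export
algorithm_menu <- function(spec = score_spec("aic"), alpha = 0.05) {
  list(
    hc = function(data, seed = NULL) hill_climb(data, spec),
    hc_restarts = function(data, seed = 1L) {
      hill_climb_restarts(data, spec, seed = if (is.null(seed)) 1L else seed)
    },
    tabu = function(data, seed = NULL) tabu_search(data, spec),
    pc_stable = function(data, seed = NULL) pc_stable(data, alpha, spec),
    gs = function(data, seed = NULL) grow_shrink(data, alpha, spec),
    iamb = function(data, seed = NULL) iamb(data, alpha, spec),
    inter_iamb = function(data, seed = NULL) inter_iamb(data, alpha, spec),
    mmhc = function(data, seed = NULL) mmhc(data, alpha, spec, "hc"),
    tabu_restricted = function(data, seed = NULL) {
      mmhc(data, alpha, spec, "tabu")
    })
}
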