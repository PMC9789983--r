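#' Canonical symptom vocabulary
#'
#' The eleven symptoms of the Utrecht Symptom Diary (the Dutch adaptation of
#' the Edmonton Symptom Assessment System), in their fixed listing order.
#' All tie-breaking and ordering in this package refers to this order, so
#' that every run of every algorithm is reproducible.
#'
#' @return Character vector of the 11 canonical symptom names.
#' @examples
#' symptom_labels()
#' @export
symptom_labels <- function() {
  c("pain", "sleeping_problems", "dry_mouth", "dysphagia",
    "lack_of_appetite", "constipation", "nausea", "shortness_of_breath",
    "fatigue", "anxiety", "depressed_mood")
}

#' Display names for the canonical symptoms
#'
#' @return Named character vector mapping canonical names to display labels
#'   (e.g. \code{"dry_mouth"} to \code{"Dry mouth"}).
#' @export
symptom_display_names <- function() {
  c(pain = "Pain", sleeping_problems = "Sleeping problems",
    dry_mouth = "Dry mouth", dysphagia = "Dysphagia",
    lack_of_appetite = "Lack of appetite", constipation = "Constipation",
    nausea = "Nausea", shortness_of_breath = "Shortness of breath",
    fatigue = "Fatigue", anxiety = "Anxiety",
    depressed_mood = "Depressed mood")
}

#' Canonicalize symptom names
#'
#' Lookups are case-insensitive and tolerant of spaces/hyphens, so
#' \code{"Dry mouth"}, \code{"dry-mouth"} and \code{"DRY_MOUTH"} all resolve
#' to \code{"dry_mouth"}. Unknown names raise an error.
#'
#' @param x Character vector of symptom names in any accepted spelling.
#' @return Character vector of canonical names.
#' @export
canonical_symptom <- function(x) {
  key <- gsub("[ -]+", "_", tolower(trimws(as.character(x))))
  known <- symptom_labels()
  bad <- setdiff(unique(key), known)
  if (length(bad) > 0L) {
    stop("unknown symptom name(s): ", paste(bad, collapse = ", "),
         "; expected one of: ", paste(known, collapse = ", "))
  }
  key
}

# Order a set of node names canonically: symptom labels first in USD order,
# anything else (generic variable names in tests) alphabetically after.
canonical_node_order <- function(nodes) {
  known <- symptom_labels()
  in_known <- nodes[match(known, nodes, nomatch = 0L)]
  rest <- sort(setdiff(nodes, known))
  c(in_known, rest)
}
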