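# Bundled experimental outcome panels from the SlitOR25/SlitOR31
# single-sensillum validation screens: each predicted binder, suspected
# decoy and potential non-binder that was synthesized and tested, with
# its experimental outcome. Activity labels enter the package as data;
# the electrophysiology itself is outside its scope.

#' Bundled single-sensillum validation panels
#'
#' Returns the experimentally tested selection for one receptor: 19
#' predicted binders, 3 suspected decoys and 5 potential non-binders for
#' SlitOR25 (2 binders active), and 17/3/5 for SlitOR31 (1 binder
#' active). Molecules whose identity was not individually reported carry
#' generic ids.
#'
#' @param receptor `"SlitOR25"` or `"SlitOR31"`.
#' @return A data.frame with columns `molecule`, `prediction`
#'   (`binder`/`suspected_decoy`/`potential_nonbinder`) and `active`
#'   (0/1).
#' @seealso [evaluate_predictions()]
#' @export
#' @examples
#' panel <- ssr_panel("SlitOR25")
#' table(panel$prediction, panel$active)
ssr_panel <- function(receptor = c("SlitOR25", "SlitOR31")) {
  receptor <- match.arg(receptor)
  file <- system.file("extdata",
                      paste0(tolower(receptor), "_ssr_panel.csv"),
                      package = "orscreen", mustWork = TRUE)
  utils::read.csv(file, stringsAsFactors = FALSE)
}

#' Evaluate a validation panel
#'
#' Convenience wrapper collapsing a panel's triage classes into the
#' binder / non-binder-or-decoy dichotomy and scoring the predictions
#' against the experimental outcomes.
#'
#' @param panel a data.frame as returned by [ssr_panel()].
#' @return A [evaluate_predictions()] result.
#' @export
evaluate_panel <- function(panel) {
  stopifnot(all(c("molecule", "prediction", "active") %in% names(panel)))
  pred <- stats::setNames(
    ifelse(panel$prediction == "binder", "binder", "nonbinder_or_decoy"),
    panel$molecule)
  obs <- stats::setNames(panel$active, panel$molecule)
  evaluate_predictions(pred, obs)
}
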