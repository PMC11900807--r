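# Triage of a screened library: per-receptor partition into potential
# binders (top fraction, decoys removed), globally suspected decoys
# (promiscuous top-rankers), and potential non-binders (bottom fraction),
# plus evaluation of workflow predictions against experimental outcomes.

#' Triage ranked screening results
#'
#' Four-step partition. (1) Per receptor, the top set is the best
#' `k = max(1, round(top_fraction * N))` molecules. (2) Each molecule's
#' promiscuity frequency is the share of `decoy_receptors` whose top set
#' contains it; molecules with frequency at or above
#' `promiscuity_threshold` (inclusive) are suspected decoys, a global
#' label. (3) A receptor's potential binders are its top set minus the
#' decoys. (4) Its potential non-binders are the worst
#' `floor(bottom_fraction * N)` molecules by rank. Everything else is
#' unclassified for that receptor.
#'
#' @param ranked named list of [rank_scores()] results (one per receptor)
#'   over a common molecule universe.
#' @param top_fraction top fraction called binders (default 0.06).
#' @param promiscuity_threshold inclusive decoy frequency threshold
#'   (default 0.7).
#' @param bottom_fraction bottom fraction called non-binders
#'   (default 0.45).
#' @param decoy_receptors receptor ids over which the decoy frequency is
#'   computed (default: all of `ranked`); typically the non-pheromonal
#'   receptors.
#' @return An object of class `triage_result`: `potential_binders` and
#'   `potential_nonbinders` (named lists of molecule id vectors, per
#'   receptor), `suspected_decoys` (character vector),
#'   `decoy_frequency` (named numeric over the whole universe) and
#'   `parameters`.
#' @export
triage <- function(ranked, top_fraction = 0.06, promiscuity_threshold = 0.7,
                   bottom_fraction = 0.45, decoy_receptors = names(ranked)) {
  if (!length(ranked)) stop("need at least one ranked list")
  stopifnot(top_fraction > 0, top_fraction <= 1,
            promiscuity_threshold >= 0, promiscuity_threshold <= 1,
            bottom_fraction >= 0, bottom_fraction <= 1)
  if (is.null(names(ranked)))
    names(ranked) <- vapply(ranked, `[[`, "", "receptor_id")
  universe <- sort(ranked[[1]]$order)
  for (r in ranked)
    if (!identical(sort(r$order), universe))
      stop("ranked lists cover different molecule universes")
  if (!all(decoy_receptors %in% names(ranked)))
    stop("unknown decoy receptor(s): ",
         paste(setdiff(decoy_receptors, names(ranked)), collapse = ", "))
  n <- length(universe)
  k <- top_k(top_fraction, n)
  top_sets <- lapply(ranked, function(r) r$order[seq_len(k)])

  freq <- rowSums(matrix(vapply(decoy_receptors, function(rc)
    universe %in% top_sets[[rc]], logical(n)), nrow = n)) / length(decoy_receptors)
  names(freq) <- universe
  decoys <- universe[freq >= promiscuity_threshold]

  n_bottom <- floor(bottom_fraction * n)
  binders <- lapply(top_sets, function(ts) setdiff(ts, decoys))
  nonbinders <- lapply(ranked, function(r)
    if (n_bottom > 0) r$order[seq.int(n - n_bottom + 1L, n)] else character())

  structure(list(potential_binders = binders,
                 potential_nonbinders = nonbinders,
                 suspected_decoys = decoys,
                 decoy_frequency = freq,
                 parameters = list(top_fraction = top_fraction,
                                   promiscuity_threshold = promiscuity_threshold,
                                   bottom_fraction = bottom_fraction,
                                   decoy_receptors = decoy_receptors,
                                   n_molecules = n, top_k = k)),
            class = "triage_result")
}

#' @export
print.triage_result <- function(x, ...) {
  p <- x$parameters
  cat(sprintf("triage_result: %d receptors, %d molecules (top %d, bottom %d)\n",
              length(x$potential_binders), p$n_molecules, p$top_k,
              floor(p$bottom_fraction * p$n_molecules)))
  cat(sprintf("  suspected decoys (freq >= %.2f over %d receptors): %d\n",
              p$promiscuity_threshold, length(p$decoy_receptors),
              length(x$suspected_decoys)))
  for (r in names(x$potential_binders))
    cat(sprintf("  %s: %d potential binders\n", r, length(x$potential_binders[[r]])))
  invisible(x)
}

#' Write per-receptor triage tables
#'
#' One CSV per receptor (molecule, class, rank, score, decoy_frequency)
#' plus a global decoy list CSV.
#'
#' @param result a [triage()] result.
#' @param ranked the ranked lists the triage was computed from.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_triage_csv <- function(result, ranked, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(names(ranked)))
    names(ranked) <- vapply(ranked, `[[`, "", "receptor_id")
  for (rc in names(result$potential_binders)) {
    r <- ranked[[rc]]
    cls <- rep("unclassified", length(r$order))
    cls[r$order %in% result$suspected_decoys] <- "suspected_decoy"
    cls[r$order %in% result$potential_binders[[rc]]] <- "potential_binder"
    cls[r$order %in% result$potential_nonbinders[[rc]]] <- "potential_nonbinder"
    utils::write.csv(
      data.frame(molecule = r$order, class = cls,
                 rank = unname(r$rank[r$order]),
                 score = unname(r$scores[r$order]),
                 decoy_frequency = unname(result$decoy_frequency[r$order])),
      file.path(dir, paste0("triage_", rc, ".csv")), row.names = FALSE)
  }
  utils::write.csv(
    data.frame(molecule = result$suspected_decoys,
               frequency = unname(result$decoy_frequency[result$suspected_decoys])),
    file.path(dir, "suspected_decoys.csv"), row.names = FALSE)
  invisible(dir)
}

#' Evaluate workflow predictions against experimental outcomes
#'
#' Contingency of predicted binders versus experimentally active
#' molecules. Precision is reported as a percentage; undefined ratios
#' (zero denominators) are reported as `NA`, never as 0.
#'
#' @param predicted named vector mapping molecule id to `"binder"` or
#'   `"nonbinder_or_decoy"`.
#' @param observed named vector of experimental outcomes
#'   (`"active"`/`"inactive"`, logical, or 0/1) over the same molecules.
#' @return An object of class `prediction_evaluation` with `counts`
#'   (TP, FP, TN, FN), `precision` (%), `accuracy`, `tpr`, `fpr`.
#' @export
#' @examples
#' pred <- setNames(rep(c("binder", "nonbinder_or_decoy"), c(4, 4)),
#'                  paste0("m", 1:8))
#' obs <- setNames(c(1, 1, 0, 0, 0, 0, 0, 0), paste0("m", 1:8))
#' evaluate_predictions(pred, obs)
evaluate_predictions <- function(predicted, observed) {
  if (is.null(names(predicted)) || is.null(names(observed)))
    stop("predicted and observed must be named by molecule id")
  if (!setequal(names(predicted), names(observed)))
    stop("predicted and observed cover different molecule sets")
  bad <- setdiff(unique(predicted), c("binder", "nonbinder_or_decoy"))
  if (length(bad)) stop("unknown prediction label(s): ", paste(bad, collapse = ", "))
  obs <- as_active(observed)[names(predicted)]
  pred <- predicted == "binder"
  tp <- sum(pred & obs); fp <- sum(pred & !obs)
  tn <- sum(!pred & !obs); fn <- sum(!pred & obs)
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  structure(list(counts = c(TP = tp, FP = fp, TN = tn, FN = fn),
                 precision = 100 * ratio(tp, tp + fp),
                 accuracy = (tp + tn) / length(pred),
                 tpr = ratio(tp, tp + fn),
                 fpr = ratio(fp, fp + tn)),
            class = "prediction_evaluation")
}

#' @export
print.prediction_evaluation <- function(x, ...) {
  cat("prediction_evaluation\n")
  cat(sprintf("  TP %d  FP %d  TN %d  FN %d\n", x$counts["TP"], x$counts["FP"],
              x$counts["TN"], x$counts["FN"]))
  cat(sprintf("  precision %s%%  accuracy %.3f  TPR %s  FPR %s\n",
              format(round(x$precision, 1)), x$accuracy,
              format(round(x$tpr, 3)), format(round(x$fpr, 3))))
  invisible(x)
}
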