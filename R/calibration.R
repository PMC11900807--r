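# Calibration of scoring functions against an experimental activity
# panel: ROC/AUC per receptor, enrichment factors over a fraction grid,
# optimal top-fraction by TPR/FPR ratio, and the derived non-binder
# fraction.

#' Construct a receptor x molecule activity matrix
#'
#' Experimental activity labels for a panel of molecules tested on a set
#' of receptors. Labels may be given directly or derived from p-values
#' (active iff `p < p_threshold`, strict).
#'
#' @param labels logical matrix (receptors x molecules, TRUE = active)
#'   with dimnames, or `NULL` if `p_values` is given.
#' @param receptor_class named character vector tagging each receptor as
#'   `"pheromone_receptor"` or `"non_pheromonal"`; defaults to
#'   `"non_pheromonal"` for all.
#' @param p_values optional numeric matrix of p-values, same shape.
#' @param p_threshold activity threshold on p-values (default 0.001).
#' @return An object of class `activity_matrix`.
#' @export
activity_matrix <- function(labels = NULL, receptor_class = NULL,
                            p_values = NULL, p_threshold = 0.001) {
  if (is.null(labels)) {
    if (is.null(p_values)) stop("either labels or p_values must be given")
    stopifnot(is.matrix(p_values), !is.null(dimnames(p_values)))
    if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
      stop("p-values must lie in [0, 1]")
    labels <- p_values < p_threshold
  }
  stopifnot(is.matrix(labels), is.logical(labels), !is.null(dimnames(labels)))
  if (anyNA(labels)) stop("missing activity labels")
  receptors <- rownames(labels)
  if (is.null(receptor_class))
    receptor_class <- stats::setNames(rep("non_pheromonal", length(receptors)),
                                      receptors)
  bad <- setdiff(unique(receptor_class), c("pheromone_receptor", "non_pheromonal"))
  if (length(bad)) stop("unknown receptor class: ", paste(bad, collapse = ", "))
  miss <- setdiff(receptors, names(receptor_class))
  if (length(miss)) stop("no class tag for receptor(s): ", paste(miss, collapse = ", "))
  structure(list(labels = labels,
                 receptor_class = receptor_class[receptors],
                 p_values = p_values, p_threshold = p_threshold),
            class = "activity_matrix")
}

#' @export
print.activity_matrix <- function(x, ...) {
  cat(sprintf("activity_matrix: %d receptors x %d molecules, %d active pairs\n",
              nrow(x$labels), ncol(x$labels), sum(x$labels)))
  invisible(x)
}

#' Read an activity panel from CSV
#'
#' Long format with header columns `receptor`, `molecule` and either
#' `label` (`active`/`inactive`) or `p_value`. An optional `class` column
#' (or a separate `classes` data.frame/CSV with columns `receptor`,
#' `class`) tags pheromone receptors.
#'
#' @param path CSV path.
#' @param classes optional data.frame or CSV path with columns `receptor`
#'   and `class`.
#' @param p_threshold p-value activity threshold when labels are derived.
#' @return An [activity_matrix()].
#' @export
read_activity_csv <- function(path, classes = NULL, p_threshold = 0.001) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("receptor", "molecule") %in% names(tab)))
    stop("activity CSV needs columns receptor, molecule")
  receptors <- sort(unique(tab$receptor))
  molecules <- sort(unique(tab$molecule))
  if ("label" %in% names(tab)) {
    m <- matrix(NA, length(receptors), length(molecules),
                dimnames = list(receptors, molecules))
    m[cbind(tab$receptor, tab$molecule)] <- as_active(tab$label)
    act <- activity_matrix(labels = m, p_threshold = p_threshold)
  } else if ("p_value" %in% names(tab)) {
    m <- matrix(NA_real_, length(receptors), length(molecules),
                dimnames = list(receptors, molecules))
    m[cbind(tab$receptor, tab$molecule)] <- tab$p_value
    act <- activity_matrix(p_values = m, p_threshold = p_threshold)
  } else stop("activity CSV needs a label or p_value column")
  cls <- NULL
  if ("class" %in% names(tab))
    cls <- tab[!duplicated(tab$receptor), c("receptor", "class")]
  if (!is.null(classes)) {
    if (is.character(classes)) classes <- utils::read.csv(classes, stringsAsFactors = FALSE)
    cls <- classes
  }
  if (!is.null(cls))
    act <- activity_matrix(labels = act$labels,
                           receptor_class = stats::setNames(cls$class, cls$receptor),
                           p_values = act$p_values, p_threshold = p_threshold)
  act
}

# extract the labels relevant to one ranked list (molecule intersection)
ranked_labels <- function(ranked, labels) {
  act <- as_active(labels)
  if (is.null(names(act))) stop("labels must be named by molecule id")
  act <- act[names(act) %in% ranked$order]
  if (!length(act)) stop("no labelled molecules among the ranked set")
  act
}

#' ROC AUC of a ranking against activity labels
#'
#' Area under the ROC curve, computed as the Mann-Whitney statistic: the
#' fraction of (active, inactive) pairs in which the active molecule has
#' the better (more negative) score, with ties credited 0.5. Only
#' molecules present in `labels` contribute; the ranking's scores are
#' used so that score ties are handled exactly.
#'
#' @param ranked a [rank_scores()] result.
#' @param labels named activity labels (`"active"`/`"inactive"`, logical,
#'   or 0/1) for (a subset of) the ranked molecules.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(ranked, labels) {
  stopifnot(inherits(ranked, "ranked_list"))
  act <- ranked_labels(ranked, labels)
  n1 <- sum(act); n0 <- sum(!act)
  if (n1 == 0 || n0 == 0)
    stop("AUC undefined: need at least one active and one inactive molecule")
  s <- ranked$scores[names(act)]
  r <- rank(s)  # ascending: best (most negative) = smallest rank, ties averaged
  (sum(r[!act]) - n0 * (n0 + 1) / 2) / (n1 * n0)
}

# top-set size for a fraction of N molecules (round half up, at least 1)
top_k <- function(fraction, n) max(1L, as.integer(round_half_up(fraction * n)))

#' Enrichment factor at a top fraction
#'
#' `EF = (actives in top k / k) / (total actives / N)` with
#' `k = max(1, round(fraction * N))` (round half up).
#'
#' @inheritParams roc_auc
#' @param fraction top fraction in `(0, 1]`.
#' @return EF (non-negative; at most `1/ (actives/N)`).
#' @export
enrichment_factor <- function(ranked, labels, fraction) {
  stopifnot(inherits(ranked, "ranked_list"), fraction > 0, fraction <= 1)
  act <- ranked_labels(ranked, labels)
  if (!sum(act)) stop("EF undefined with zero actives")
  ids <- ranked$order[ranked$order %in% names(act)]
  n <- length(ids)
  k <- top_k(fraction, n)
  hit <- sum(act[ids[seq_len(k)]])
  (hit / k) / (sum(act) / n)
}

#' Optimal top-fraction threshold by TPR/FPR ratio
#'
#' For each grid fraction, the top `k = max(1, round(fraction * N))`
#' molecules are called binders; TPR and FPR follow. A zero FPR is
#' replaced by the continuity correction `0.5 / n_inactive` so the ratio
#' stays finite while preserving ordering. Returns the fraction
#' maximizing TPR/FPR (smallest fraction on ties).
#'
#' @inheritParams roc_auc
#' @param grid candidate fractions; default 1% to 100% in 1% steps.
#' @return A list with `fraction` and `ratio`.
#' @export
optimal_top_fraction <- function(ranked, labels, grid = seq(0.01, 1, by = 0.01)) {
  stopifnot(inherits(ranked, "ranked_list"), length(grid) > 0,
            all(grid > 0 & grid <= 1))
  act <- ranked_labels(ranked, labels)
  n1 <- sum(act); n0 <- sum(!act)
  if (n1 == 0 || n0 == 0)
    stop("TPR/FPR undefined: need at least one active and one inactive molecule")
  ids <- ranked$order[ranked$order %in% names(act)]
  n <- length(ids)
  grid <- sort(grid)
  ratio <- vapply(grid, function(f) {
    k <- top_k(f, n)
    top <- ids[seq_len(k)]
    tpr <- sum(act[top]) / n1
    fpr <- sum(!act[top]) / n0
    if (fpr == 0) fpr <- 0.5 / n0
    tpr / fpr
  }, 0)
  best <- which.max(ratio)  # first max = smallest fraction on ties
  list(fraction = grid[best], ratio = ratio[best])
}

# first rank (1-based) at which TPR reaches 1, i.e. the rank of the
# worst-ranked active molecule, restricted to labelled molecules
tpr1_rank <- function(ranked, labels) {
  act <- ranked_labels(ranked, labels)
  ids <- ranked$order[ranked$order %in% names(act)]
  max(which(act[ids]))
}

#' Calibrate scoring functions against an activity panel
#'
#' Computes, for every (receptor, method) score table, the ROC AUC, the
#' maximum enrichment factor over the fraction grid, and the optimal
#' top-fraction by TPR/FPR ratio; summarizes medians within receptor
#' classes; and derives the two workflow thresholds: the chosen top
#' fraction (median of per-receptor optima over the designated receptor
#' class, for the best-performing method) and the non-binder fraction
#' (median over the same receptors of the first rank at which TPR reaches
#' 1, divided by the number of ranked molecules).
#'
#' @param tables list of [score_table()]s covering every receptor of
#'   `activity` for every method present.
#' @param activity an [activity_matrix()].
#' @param grid fraction grid (default 1%..100% in 1% steps).
#' @param threshold_class receptor class used to derive the workflow
#'   thresholds; pheromone receptors are excluded by default.
#' @return An object of class `calibration_report`: `per_receptor`
#'   data.frame (receptor, method, class, auc, max_ef, optimal_fraction),
#'   `summary` data.frame of class x method medians, `best_method` (by
#'   median AUC within `threshold_class`), `best_method_by_ef`,
#'   `chosen_top_fraction` and `nonbinder_fraction`.
#' @export
calibrate <- function(tables, activity, grid = seq(0.01, 1, by = 0.01),
                      threshold_class = "non_pheromonal") {
  stopifnot(inherits(activity, "activity_matrix"))
  receptors <- rownames(activity$labels)
  methods <- unique(vapply(tables, `[[`, "", "method"))
  key <- vapply(tables, function(t) paste(t$receptor_id, t$method), "")
  need <- as.vector(outer(receptors, methods, paste))
  miss <- setdiff(need, key)
  if (length(miss))
    stop("missing score table(s) for: ", paste(miss, collapse = "; "))

  rows <- lapply(tables[match(need, key)], function(tab) {
    ranked <- rank_scores(tab)
    labs <- activity$labels[tab$receptor_id, ]
    opt <- optimal_top_fraction(ranked, labs, grid)
    data.frame(receptor = tab$receptor_id, method = tab$method,
               class = unname(activity$receptor_class[tab$receptor_id]),
               auc = roc_auc(ranked, labs),
               max_ef = max(vapply(grid, function(f)
                 enrichment_factor(ranked, labs, f), 0)),
               optimal_fraction = opt$fraction,
               tpr1_rank = tpr1_rank(ranked, labs),
               n_ranked = sum(names(as_active(labs)) %in% ranked$order),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  rownames(per) <- NULL

  summ <- do.call(rbind, lapply(split(per, list(per$class, per$method), drop = TRUE),
    function(d) data.frame(class = d$class[1], method = d$method[1],
                           median_auc = median_mid(d$auc),
                           median_max_ef = median_mid(d$max_ef),
                           stringsAsFactors = FALSE)))
  rownames(summ) <- NULL

  thr <- per[per$class %in% threshold_class, , drop = FALSE]
  if (!nrow(thr)) thr <- per  # no receptor of that class: use all
  s_thr <- summ[summ$class %in% unique(thr$class), , drop = FALSE]
  best <- s_thr$method[which.max(s_thr$median_auc)]
  best_ef <- s_thr$method[which.max(s_thr$median_max_ef)]
  tb <- thr[thr$method == best, , drop = FALSE]
  structure(list(per_receptor = per, summary = summ,
                 best_method = best, best_method_by_ef = best_ef,
                 chosen_top_fraction = median_mid(tb$optimal_fraction),
                 nonbinder_fraction = median_mid(tb$tpr1_rank / tb$n_ranked),
                 grid = grid, threshold_class = threshold_class),
            class = "calibration_report")
}

#' @export
print.calibration_report <- function(x, ...) {
  cat("calibration_report\n")
  cat("  median AUC / max EF by class and method:\n")
  print(x$summary, row.names = FALSE)
  cat(sprintf("  best method (median AUC): %s; by median max EF: %s\n",
              x$best_method, x$best_method_by_ef))
  cat(sprintf("  chosen top fraction: %.3f; non-binder fraction: %.3f\n",
              x$chosen_top_fraction, x$nonbinder_fraction))
  invisible(x)
}

#' Serialize a calibration report
#'
#' Writes the report as JSON and, optionally, the per-receptor AUC matrix
#' (receptors x methods) as CSV.
#'
#' @param report a [calibrate()] result.
#' @param json_path output JSON path.
#' @param auc_csv_path optional CSV path for the AUC matrix.
#' @return `json_path`, invisibly.
#' @export
write_calibration <- function(report, json_path, auc_csv_path = NULL) {
  jsonlite::write_json(unclass(report[c("per_receptor", "summary", "best_method",
                                        "best_method_by_ef", "chosen_top_fraction",
                                        "nonbinder_fraction")]),
                       json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(auc_csv_path)) {
    per <- report$per_receptor
    m <- stats::reshape(per[, c("receptor", "method", "auc")],
                        direction = "wide", idvar = "receptor",
                        timevar = "method")
    names(m) <- sub("^auc\\.", "", names(m))
    utils::write.csv(m, auc_csv_path, row.names = FALSE)
  }
  invisible(json_path)
}
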