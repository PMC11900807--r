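# Binding-pocket descriptor regression of receptor tuning breadth: an
# ordinary-least-squares model predicting each receptor's number of
# active molecules from cavity descriptors (volume, SASA, hydrophobicity,
# polarity, ...). Descriptors are produced externally by cavity-analysis
# tools and consumed here as data.

#' Count active molecules per receptor
#'
#' Tuning breadth of each receptor: the number of panel molecules it
#' responds to. When the activity matrix carries p-values, a molecule is
#' active iff `p < p_threshold` (strict); otherwise the stored labels are
#' used.
#'
#' @param activity an [activity_matrix()].
#' @param p_threshold p-value threshold (default 0.001).
#' @return Named integer vector, receptor -> active-molecule count.
#' @export
count_actives <- function(activity, p_threshold = 0.001) {
  stopifnot(inherits(activity, "activity_matrix"))
  m <- if (!is.null(activity$p_values)) {
    if (anyNA(activity$p_values)) stop("missing p-values")
    activity$p_values < p_threshold
  } else activity$labels
  rs <- rowSums(m)
  stats::setNames(as.integer(rs), rownames(m))
}

#' Fit the pocket-descriptor tuning model
#'
#' Ordinary least squares regressing per-receptor active-molecule counts
#' on named binding-pocket descriptors. Reported metrics are in-sample:
#' Pearson correlation between fitted and observed counts, and RMSE in
#' molecule-count units (denominator `n`). An optional leave-one-out
#' cross-validation adds out-of-sample counterparts.
#'
#' @param descriptors data.frame with a `receptor` column (or rownames)
#'   and one numeric column per descriptor.
#' @param counts named numeric vector, receptor -> active count (see
#'   [count_actives()]).
#' @param variables descriptor column names to use.
#' @param loo also compute leave-one-out predictions (default `FALSE`).
#' @return An object of class `tuning_model`: `variables`,
#'   `coefficients` (incl. intercept), `fitted`, `pearson_r`, `rmse`,
#'   `n`, and `pearson_r_loo`/`rmse_loo` when `loo = TRUE`.
#' @export
fit_tuning_model <- function(descriptors, counts, variables, loo = FALSE) {
  stopifnot(is.data.frame(descriptors), length(variables) >= 1)
  if (anyDuplicated(variables))
    stop("duplicated variable(s): ",
         paste(unique(variables[duplicated(variables)]), collapse = ", "))
  if (!"receptor" %in% names(descriptors)) {
    descriptors$receptor <- rownames(descriptors)
  }
  miss <- setdiff(variables, names(descriptors))
  if (length(miss)) stop("descriptor column(s) not found: ", paste(miss, collapse = ", "))
  rec <- as.character(descriptors$receptor)
  if (is.null(names(counts)) || !all(rec %in% names(counts)))
    stop("counts must be named and cover every receptor of the descriptor table")
  y <- counts[rec]
  X <- descriptors[, variables, drop = FALSE]
  if (any(vapply(X, anyNA, TRUE)) || anyNA(y)) stop("missing values in modeled columns")
  n <- length(y)
  if (n <= length(variables) + 1)
    stop("need more receptors than variables + 1 (n = ", n, ")")
  if (stats::var(y) == 0) stop("constant response: correlation undefined")

  dat <- cbind(data.frame(.count = as.numeric(y)), X)
  fit <- stats::lm(.count ~ ., data = dat)
  if (fit$rank < length(variables) + 1) {
    dropped <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear or constant column(s): ",
         paste(dropped, collapse = ", "))
  }
  fitted <- stats::setNames(stats::fitted(fit), rec)
  out <- list(variables = variables,
              coefficients = stats::coef(fit),
              fitted = fitted,
              observed = stats::setNames(as.numeric(y), rec),
              pearson_r = stats::cor(fitted, y),
              rmse = sqrt(mean((fitted - y)^2)),
              n = n)
  if (loo) {
    pred <- vapply(seq_len(n), function(i) {
      f <- stats::lm(.count ~ ., data = dat[-i, , drop = FALSE])
      stats::predict(f, newdata = dat[i, , drop = FALSE])
    }, 0)
    out$pearson_r_loo <- stats::cor(pred, y)
    out$rmse_loo <- sqrt(mean((pred - y)^2))
  }
  structure(out, class = "tuning_model")
}

#' @export
print.tuning_model <- function(x, ...) {
  cat(sprintf("tuning_model: %d receptors, variables: %s\n",
              x$n, paste(x$variables, collapse = " + ")))
  cat(sprintf("  in-sample pearson r = %.3f, RMSE = %.3f molecules\n",
              x$pearson_r, x$rmse))
  if (!is.null(x$pearson_r_loo))
    cat(sprintf("  leave-one-out r = %.3f, RMSE = %.3f\n",
                x$pearson_r_loo, x$rmse_loo))
  invisible(x)
}

#' Compare tuning models across descriptor subsets
#'
#' Fits [fit_tuning_model()] for each variable subset and tabulates the
#' in-sample fit quality.
#'
#' @inheritParams fit_tuning_model
#' @param variable_sets named list of character vectors of descriptor
#'   names.
#' @return data.frame with columns `model`, `n_variables`, `pearson_r`,
#'   `rmse`.
#' @export
compare_tuning_models <- function(descriptors, counts, variable_sets) {
  rows <- lapply(names(variable_sets), function(nm) {
    fit <- fit_tuning_model(descriptors, counts, variable_sets[[nm]])
    data.frame(model = nm, n_variables = length(fit$variables),
               pearson_r = fit$pearson_r, rmse = fit$rmse,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
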