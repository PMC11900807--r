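# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# round-half-up; round() in R rounds half to even, which moves top-set
# boundaries (e.g. round(0.5) == 0), so threshold cuts use this instead
round_half_up <- function(x) floor(x + 0.5)

# normalize an activity label vector to logical (TRUE = active).
# Accepts logical, 0/1 numeric, or character "active"/"inactive".
as_active <- function(labels) {
  nm <- names(labels)
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) stop("numeric labels must be 0/1")
    return(stats::setNames(labels == 1, nm))
  }
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels)
    bad <- setdiff(unique(labels), c("active", "inactive"))
    if (length(bad)) stop("unknown activity labels: ", paste(bad, collapse = ", "))
    return(stats::setNames(labels == "active", nm))
  }
  stop("labels must be logical, 0/1 or 'active'/'inactive'")
}

assert_ids <- function(ids, what = "id") {
  if (anyNA(ids) || any(!nzchar(ids))) stop(what, " values must be non-empty")
  if (any(grepl("[[:space:]]", ids))) stop(what, " values must not contain whitespace")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) stop("duplicate ", what, ": ", paste(dup, collapse = ", "))
  invisible(ids)
}

# median with midpoint-of-two convention (stats::median already does this
# for even counts; wrapped for a single documented point of truth)
median_mid <- function(x) stats::median(x)
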