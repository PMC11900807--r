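# Docking-score ingestion and ligand-efficiency rescoring.
#
# Raw docking scores (Vinardo-style, kcal/mol-like, more negative =
# stronger predicted binding) are consumed from delimited tables or
# smina-style logs. Rescoring divides the raw score by a function of the
# heavy-atom count to correct the size bias of empirical scoring
# functions:
#   LE   = s / HA
#   LEln = s / (1 + ln HA)
#   LESA = s / HA^(2/3)

SCORE_METHODS <- c("vinardo_raw", "LE", "LEln", "LESA")

#' Construct a per-receptor score table
#'
#' @param receptor_id receptor identifier.
#' @param scores named numeric vector, molecule id -> docking score
#'   (more negative = better).
#' @param method scoring method tag; raw docking output is
#'   `"vinardo_raw"`.
#' @return An object of class `score_table`.
#' @export
score_table <- function(receptor_id, scores, method = "vinardo_raw") {
  method <- match.arg(method, SCORE_METHODS)
  stopifnot(is.numeric(scores), length(scores) > 0)
  assert_ids(names(scores), "molecule id")
  if (any(!is.finite(scores))) stop("all scores must be finite")
  structure(list(receptor_id = as.character(receptor_id),
                 method = method, scores = scores),
            class = "score_table")
}

#' @export
print.score_table <- function(x, ...) {
  cat(sprintf("score_table: receptor %s, method %s, %d molecules (best %.3f)\n",
              x$receptor_id, x$method, length(x$scores), min(x$scores)))
  invisible(x)
}

#' Parse docking scores into per-receptor tables
#'
#' Two dialects are supported. `"table"`: delimited files with header
#' columns `receptor`, `molecule`, `score`; duplicate (receptor, molecule)
#' rows keep the most negative score with a warning. `"smina_log"`:
#' smina/Vina-style text logs in which each molecule's section is
#' introduced by a line `Ligand: <id>` followed by the standard
#' `mode | affinity ...` pose table; the first pose row (best affinity) is
#' kept. A log file without `Ligand:` markers is treated as a single
#' molecule named after the file (without extension).
#'
#' @param paths character vector of file paths.
#' @param dialect `"table"` or `"smina_log"`.
#' @param receptor_id receptor id to use for `smina_log` files that do not
#'   encode one; defaults to `"receptor"`.
#' @return A named list of [score_table()] objects (method
#'   `"vinardo_raw"`), one per receptor.
#' @export
parse_scores <- function(paths, dialect = c("table", "smina_log"),
                         receptor_id = "receptor") {
  dialect <- match.arg(dialect)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) stop("file not found: ", paste(missing, collapse = ", "))
  rows <- if (dialect == "table") {
    do.call(rbind, lapply(paths, parse_score_table_file))
  } else {
    do.call(rbind, lapply(paths, parse_smina_log_file, receptor_id = receptor_id))
  }
  if (!nrow(rows)) stop("no parseable scores found")
  dup <- duplicated(rows[, c("receptor", "molecule")])
  if (any(dup)) {
    warning(sum(dup), " duplicate (receptor, molecule) score(s); keeping the most negative")
    rows <- rows[order(rows$receptor, rows$molecule, rows$score), ]
    rows <- rows[!duplicated(rows[, c("receptor", "molecule")]), ]
  }
  tabs <- lapply(split(rows, rows$receptor), function(d)
    score_table(d$receptor[1], stats::setNames(d$score, d$molecule)))
  tabs[order(names(tabs))]
}

parse_score_table_file <- function(path) {
  sep <- if (grepl("\\.tsv$|\\.txt$", path)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  miss <- setdiff(c("receptor", "molecule", "score"), names(tab))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))
  score <- suppressWarnings(as.numeric(tab$score))
  if (anyNA(score)) {
    bad <- which(is.na(score))[1]
    stop("non-numeric score in ", path, " at data row ", bad,
         " (molecule ", tab$molecule[bad], ")")
  }
  data.frame(receptor = as.character(tab$receptor),
             molecule = as.character(tab$molecule),
             score = score, stringsAsFactors = FALSE)
}

parse_smina_log_file <- function(path, receptor_id) {
  lines <- readLines(path, warn = FALSE)
  lig_at <- grep("^\\s*Ligand:\\s*\\S+", lines)
  ids <- if (length(lig_at)) {
    sub("^\\s*Ligand:\\s*(\\S+).*$", "\\1", lines[lig_at])
  } else {
    tools::file_path_sans_ext(basename(path))
  }
  starts <- if (length(lig_at)) lig_at else 1L
  ends <- c(starts[-1] - 1L, length(lines))
  aff <- mapply(function(s, e) {
    block <- lines[s:e]
    # first data row of the pose table: "   1   -6.725   0.000   0.000"
    hit <- grep("^\\s*1\\s+-?[0-9.]+", block, value = TRUE)
    if (!length(hit)) return(NA_real_)
    as.numeric(strsplit(trimws(hit[1]), "\\s+")[[1]][2])
  }, starts, ends)
  if (anyNA(aff))
    stop("no parseable affinity in ", path, " for: ",
         paste(ids[is.na(aff)], collapse = ", "))
  data.frame(receptor = receptor_id, molecule = ids, score = aff,
             stringsAsFactors = FALSE)
}

#' Ligand-efficiency rescoring of a docking-score table
#'
#' Divides each raw score by a function of the molecule's heavy-atom
#' count: `LE = s/HA`, `LEln = s/(1 + ln HA)` (natural log),
#' `LESA = s/HA^(2/3)`. The molecule set is preserved.
#'
#' @param table a [score_table()] with method `"vinardo_raw"`.
#' @param library an `or_library` with `heavy_atoms` populated, covering
#'   every molecule of the table.
#' @param method `"LE"`, `"LEln"` or `"LESA"`.
#' @return A new [score_table()] with the rescored values.
#' @export
rescore <- function(table, library, method = c("LE", "LEln", "LESA")) {
  method <- match.arg(method)
  stopifnot(inherits(table, "score_table"))
  if (table$method != "vinardo_raw")
    stop("rescore() expects a raw score table, got method ", table$method)
  ha <- stats::setNames(library$heavy_atoms, library$id)[names(table$scores)]
  if (anyNA(ha))
    stop("molecules missing from library: ",
         paste(names(table$scores)[is.na(ha)], collapse = ", "))
  if (any(ha < 1)) stop("heavy-atom count below 1")
  s <- table$scores
  out <- switch(method,
                LE   = s / ha,
                LEln = s / (1 + log(ha)),
                LESA = s / ha^(2 / 3))
  score_table(table$receptor_id, out, method)
}

#' Rank a score table best-first
#'
#' Ascending sort by score (most negative first); ties are broken by
#' lexicographic molecule id so that threshold cuts are reproducible.
#'
#' @param table a [score_table()].
#' @return An object of class `ranked_list` with elements `receptor_id`,
#'   `method`, `order` (molecule ids, best first), `rank` (named 1-based
#'   ranks) and `scores` (named, sorted).
#' @export
rank_scores <- function(table) {
  stopifnot(inherits(table, "score_table"))
  if (!length(table$scores)) stop("empty score table")
  o <- order(table$scores, names(table$scores), method = "radix")
  ids <- names(table$scores)[o]
  structure(list(receptor_id = table$receptor_id, method = table$method,
                 order = ids,
                 rank = stats::setNames(seq_along(ids), ids),
                 scores = table$scores[o]),
            class = "ranked_list")
}

#' @export
print.ranked_list <- function(x, ...) {
  cat(sprintf("ranked_list: receptor %s, method %s, %d molecules; top: %s\n",
              x$receptor_id, x$method, length(x$order),
              paste(utils::head(x$order, 3), collapse = ", ")))
  invisible(x)
}

#' Write a multi-method rescored score table to CSV
#'
#' One row per (receptor, molecule) with the raw score, each requested
#' rescored value and the per-method rank.
#'
#' @param raw_tables named list of raw [score_table()]s (one per receptor).
#' @param library descriptor-populated `or_library`.
#' @param path output CSV path.
#' @param methods rescoring methods to include alongside the raw score.
#' @return The written data.frame, invisibly.
#' @export
write_rescored_csv <- function(raw_tables, library, path,
                               methods = c("LE", "LEln", "LESA")) {
  rows <- lapply(raw_tables, function(tab) {
    d <- data.frame(receptor = tab$receptor_id, molecule = names(tab$scores),
                    vinardo_raw = unname(tab$scores), stringsAsFactors = FALSE)
    d$rank_vinardo_raw <- rank_scores(tab)$rank[d$molecule]
    for (m in methods) {
      rt <- rescore(tab, library, m)
      d[[m]] <- unname(rt$scores[d$molecule])
      d[[paste0("rank_", m)]] <- rank_scores(rt)$rank[d$molecule]
    }
    d
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}

#' Read a rescored CSV back into per-receptor score tables
#'
#' @param path CSV written by [write_rescored_csv()].
#' @param method which score column to load.
#' @return Named list of [score_table()]s.
#' @export
read_rescored_csv <- function(path, method = "vinardo_raw") {
  method <- match.arg(method, SCORE_METHODS)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!method %in% names(tab)) stop("no column ", method, " in ", path)
  lapply(split(tab, tab$receptor), function(d)
    score_table(d$receptor[1], stats::setNames(d[[method]], d$molecule), method))
}
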