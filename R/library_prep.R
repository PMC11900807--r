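# Library preparation: loading molecule libraries, physicochemical
# descriptors, the odorant-likeness filter.
#
# Chemistry is delegated to Open Babel through ChemmineOB/ChemmineR:
# canonical SMILES, molecular weight and the atomic-contribution
# (Crippen-type) logP come from one batched format conversion; heavy-atom
# and heteroatom counts are read off the molfile atom block.

#' Physicochemical filter limits for odorant-likeness
#'
#' Bounds used to retain volatile, odorant-like molecules. Defaults are
#' the published screening values: molecular weight at most 400 g/mol, at
#' most 25 heavy atoms, at most 10 heteroatoms, and calculated logP
#' between -1 and 7. All bounds are inclusive.
#'
#' @param mw_max maximum molecular weight (g/mol).
#' @param heavy_atoms_max maximum number of non-hydrogen atoms.
#' @param heteroatoms_max maximum number of non-carbon, non-hydrogen atoms.
#' @param logp_min,logp_max inclusive bounds on calculated logP.
#' @return An object of class `filter_limits`.
#' @export
#' @examples
#' filter_limits()
#' filter_limits(mw_max = 300)
filter_limits <- function(mw_max = 400, heavy_atoms_max = 25,
                          heteroatoms_max = 10, logp_min = -1, logp_max = 7) {
  stopifnot(is.numeric(mw_max), is.numeric(heavy_atoms_max),
            is.numeric(heteroatoms_max), is.numeric(logp_min),
            is.numeric(logp_max))
  if (logp_min >= logp_max) stop("logp_min must be below logp_max")
  if (mw_max < 0 || heavy_atoms_max < 0 || heteroatoms_max < 0)
    stop("max limits must be non-negative")
  structure(list(mw_max = mw_max, heavy_atoms_max = heavy_atoms_max,
                 heteroatoms_max = heteroatoms_max,
                 logp_min = logp_min, logp_max = logp_max),
            class = "filter_limits")
}

#' @export
print.filter_limits <- function(x, ...) {
  cat("odorant-likeness filter limits:\n")
  cat(sprintf("  mw <= %g g/mol, heavy atoms <= %g, heteroatoms <= %g, logP in [%g, %g]\n",
              x$mw_max, x$heavy_atoms_max, x$heteroatoms_max,
              x$logp_min, x$logp_max))
  invisible(x)
}

# --- Open Babel helpers -----------------------------------------------------

# Batch canonicalisation + MW + logP through one in-process conversion.
# Returns a data.frame(id, canonical, mw, logp); molecules the parser
# rejects are absent from the result. The parser stops a batch at the
# first rejected molecule, so ids missing after the batch pass are
# retried one at a time.
ob_can_props <- function(smiles, ids) {
  res <- ob_can_props_batch(smiles, ids)
  missing <- which(!ids %in% res$id)
  if (length(missing)) {
    retried <- lapply(missing, function(i)
      ob_can_props_batch(smiles[i], ids[i]))
    res <- rbind(res, do.call(rbind, retried))
    res <- res[order(match(res$id, ids)), , drop = FALSE]
    rownames(res) <- NULL
  }
  res
}

ob_can_props_batch <- function(smiles, ids) {
  stopifnot(length(smiles) == length(ids))
  src <- paste0(paste(smiles, ids), collapse = "\n")
  out <- tryCatch(ChemmineOB::convertFormat(
    "SMI", "CAN", paste0(src, "\n"),
    options = data.frame(names = "append", args = "MW logP")),
    error = function(e) "")
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(data.frame(id = character(), canonical = character(),
                      mw = numeric(), logp = numeric()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  can <- vapply(parts, `[`, "", 1L)
  rest <- strsplit(trimws(vapply(parts, function(p) p[2] %||% "", "")), "[[:space:]]+")
  ok <- lengths(rest) == 3L
  data.frame(id = vapply(rest[ok], `[`, "", 1L),
             canonical = can[ok],
             mw = as.numeric(vapply(rest[ok], `[`, "", 2L)),
             logp = as.numeric(vapply(rest[ok], `[`, "", 3L)),
             stringsAsFactors = FALSE)
}

# Heavy-atom / heteroatom counts from the molfile atom block.
sdf_atom_counts <- function(smiles, ids) {
  sdf <- ChemmineR::smiles2sdf(stats::setNames(smiles, ids))
  counts <- lapply(ChemmineR::cid(sdf), function(cid) {
    ab <- ChemmineR::atomblock(sdf[[cid]])
    el <- sub("_.*$", "", rownames(ab))
    c(heavy = sum(el != "H"), hetero = sum(!el %in% c("C", "H")))
  })
  m <- do.call(rbind, counts)
  data.frame(id = ChemmineR::cid(sdf), heavy_atoms = as.integer(m[, "heavy"]),
             heteroatoms = as.integer(m[, "hetero"]), stringsAsFactors = FALSE)
}

# Crude heavy-atom count used only to pick the largest fragment of a
# multi-fragment (salt/mixture) SMILES; exact counts come later from the
# parsed structure.
approx_heavy_count <- function(smi) {
  n_br <- lengths(regmatches(smi, gregexpr("\\[[^]]*\\]", smi)))
  rest <- gsub("\\[[^]]*\\]", "", smi)
  n_two <- lengths(regmatches(rest, gregexpr("Cl|Br|Si", rest)))
  rest <- gsub("Cl|Br|Si", "", rest)
  n_one <- lengths(regmatches(rest, gregexpr("[BCNOPSFI]|[bcnops]", rest)))
  n_br + n_two + n_one
}

# Keep the largest fragment of dotted SMILES (ties: first). Returns the
# possibly stripped vector; strips are reported via message().
strip_fragments <- function(smiles, ids) {
  dotted <- grepl(".", smiles, fixed = TRUE)
  if (!any(dotted)) return(smiles)
  smiles[dotted] <- vapply(smiles[dotted], function(s) {
    frags <- strsplit(s, ".", fixed = TRUE)[[1]]
    frags[which.max(approx_heavy_count(frags))]
  }, "", USE.NAMES = FALSE)
  message("kept largest fragment for ", sum(dotted), " multi-fragment molecule(s): ",
          paste(utils::head(ids[dotted], 5L), collapse = ", "),
          if (sum(dotted) > 5L) ", ..." else "")
  smiles
}

# --- loading ----------------------------------------------------------------

#' Load a molecule library
#'
#' Reads a molecule library from a delimited SMILES table (columns `id`
#' and `smiles`; comma- or tab-separated, with header) or an SDF (V2000)
#' file. Entries whose structure cannot be parsed are skipped with a
#' warning and counted in the `n_skipped` attribute; duplicate ids are an
#' error. Multi-fragment SMILES are reduced to their largest fragment.
#'
#' @param path path to the library file.
#' @param format `"smiles_table"` or `"sdf"`.
#' @return A data.frame of class `or_library` with columns `id`, `smiles`
#'   and (initially `NA`) descriptor columns `mw`, `heavy_atoms`,
#'   `heteroatoms`, `logp`. Attribute `n_skipped` counts unparseable
#'   entries. Use [compute_descriptors()] to populate the descriptors.
#' @seealso [compute_descriptors()], [physchem_filter()]
#' @export
load_library <- function(path, format = c("smiles_table", "sdf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "smiles_table") {
    sep <- if (grepl("\\.tsv$|\\.txt$", path)) "\t" else ","
    tab <- utils::read.table(path, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE, comment.char = "",
                             quote = "\"")
    miss <- setdiff(c("id", "smiles"), names(tab))
    if (length(miss)) stop("missing required column(s): ", paste(miss, collapse = ", "))
    ids <- as.character(tab$id)
    smiles <- as.character(tab$smiles)
  } else {
    sdf <- ChemmineR::read.SDFset(path)
    ok <- ChemmineR::validSDF(sdf)
    if (any(!ok)) warning(sum(!ok), " invalid SDF record(s) skipped")
    sdf <- sdf[ok]
    ids <- ChemmineR::sdfid(sdf)
    smiles <- unname(as.character(ChemmineR::sdf2smiles(sdf)))
  }
  assert_ids(ids)
  smiles <- strip_fragments(smiles, ids)
  parsed <- ob_can_props(smiles, ids)
  skipped <- setdiff(ids, parsed$id)
  if (length(skipped))
    warning(length(skipped), " unparseable molecule(s) skipped: ",
            paste(utils::head(skipped, 10L), collapse = ", "))
  keep <- ids %in% parsed$id
  lib <- data.frame(id = ids[keep], smiles = smiles[keep],
                    mw = NA_real_, heavy_atoms = NA_integer_,
                    heteroatoms = NA_integer_, logp = NA_real_,
                    stringsAsFactors = FALSE)
  class(lib) <- c("or_library", "data.frame")
  attr(lib, "n_skipped") <- length(skipped)
  lib
}

#' Compute physicochemical descriptors
#'
#' Populates molecular weight (standard-atomic-weight sum over the neutral
#' molecule, g/mol), heavy-atom count, heteroatom count (any atom that is
#' neither carbon nor hydrogen), and the atomic-contribution (Crippen-type)
#' calculated logP for every molecule of a library.
#'
#' @param x an `or_library` data.frame (from [load_library()] or built in
#'   code with columns `id` and `smiles`), or a character vector of SMILES
#'   (optionally named; unnamed vectors get ids `m1`, `m2`, ...).
#' @return The library with descriptor columns filled in.
#' @export
#' @examples
#' \donttest{
#' lib <- compute_descriptors(c(ethanol = "CCO", benzene = "c1ccccc1"))
#' lib[, c("id", "mw", "heavy_atoms", "heteroatoms")]
#' }
compute_descriptors <- function(x) {
  if (is.character(x)) {
    ids <- names(x) %||% paste0("m", seq_along(x))
    if (is.null(names(x))) names(ids) <- NULL
    x <- data.frame(id = ids, smiles = unname(x), stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(x), all(c("id", "smiles") %in% names(x)))
  assert_ids(x$id)
  smiles <- strip_fragments(as.character(x$smiles), x$id)
  props <- ob_can_props(smiles, x$id)
  bad <- setdiff(x$id, props$id)
  if (length(bad)) stop("unparseable SMILES for: ", paste(bad, collapse = ", "))
  counts <- sdf_atom_counts(smiles, x$id)
  i1 <- match(x$id, props$id)
  i2 <- match(x$id, counts$id)
  x$mw <- props$mw[i1]
  x$logp <- props$logp[i1]
  x$heavy_atoms <- counts$heavy_atoms[i2]
  x$heteroatoms <- counts$heteroatoms[i2]
  if (!inherits(x, "or_library")) class(x) <- c("or_library", class(x))
  x
}

#' Canonical SMILES
#'
#' @param smiles character vector of SMILES.
#' @return Canonical SMILES; `NA` for unparseable input.
#' @export
canonical_smiles <- function(smiles) {
  ids <- paste0("q", seq_along(smiles))
  res <- ob_can_props(smiles, ids)
  res$canonical[match(ids, res$id)]
}

# --- filtering --------------------------------------------------------------

#' Apply the odorant-likeness physicochemical filter
#'
#' Partitions a descriptor-populated library into molecules satisfying all
#' inclusive bounds of `limits` and rejected molecules annotated with
#' every violated bound (`mw`, `heavy_atoms`, `heteroatoms`, `logp_low`,
#' `logp_high`).
#'
#' @param records an `or_library` with descriptors populated
#'   (see [compute_descriptors()]).
#' @param limits a [filter_limits()] object.
#' @return A list with elements `passing` (an `or_library`) and `rejected`
#'   (a data.frame with an additional comma-separated `reasons` column).
#' @export
physchem_filter <- function(records, limits = filter_limits()) {
  stopifnot(is.data.frame(records), inherits(limits, "filter_limits"))
  need <- c("mw", "heavy_atoms", "heteroatoms", "logp")
  if (any(vapply(records[need], anyNA, TRUE)))
    stop("records lack descriptors; run compute_descriptors() first")
  viol <- cbind(
    mw          = records$mw > limits$mw_max,
    heavy_atoms = records$heavy_atoms > limits$heavy_atoms_max,
    heteroatoms = records$heteroatoms > limits$heteroatoms_max,
    logp_low    = records$logp < limits$logp_min,
    logp_high   = records$logp > limits$logp_max)
  pass <- rowSums(viol) == 0L
  rejected <- records[!pass, , drop = FALSE]
  rejected$reasons <- apply(viol[!pass, , drop = FALSE], 1L, function(v)
    paste(colnames(viol)[v], collapse = ","))
  passing <- records[pass, , drop = FALSE]
  class(passing) <- class(records)
  list(passing = passing, rejected = rejected)
}
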