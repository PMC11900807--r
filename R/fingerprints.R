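# Morgan-type circular fingerprints and Tanimoto similarity.
#
# The fingerprint is an ECFP-style iterative neighborhood hash computed on
# the molecular graph (atom block + bond block of the parsed structure).
# Atom environments of radius 0..radius are hashed into a fixed-length bit
# vector. The hash combines sorted (bond order, neighbor id) pairs, so the
# result is invariant to atom input order; SMILES are canonicalised first
# so that different writings of one molecule give identical bits.

FP_PRIME <- 16777213  # largest prime below 2^24; keeps products exact in doubles

fp_hash2 <- function(h, v) (h * 1000003 + v) %% FP_PRIME

# bit positions (1-based) for one molecule
fp_bits_graph <- function(elem, bonds, radius, n_bits) {
  n <- length(elem)
  nbr <- vector("list", n)
  ord <- vector("list", n)
  if (nrow(bonds)) {
    for (k in seq_len(nrow(bonds))) {
      a <- bonds[k, 1L]; b <- bonds[k, 2L]; o <- bonds[k, 3L]
      nbr[[a]] <- c(nbr[[a]], b); ord[[a]] <- c(ord[[a]], o)
      nbr[[b]] <- c(nbr[[b]], a); ord[[b]] <- c(ord[[b]], o)
    }
  }
  # initial invariant: element, heavy degree, sum of bond orders
  ecode <- vapply(elem, function(e) sum(utf8ToInt(e)), 0)
  ids <- vapply(seq_len(n), function(a)
    fp_hash2(fp_hash2(ecode[a], length(nbr[[a]])), sum(ord[[a]])), 0)
  all_ids <- ids
  if (radius > 0) for (r in seq_len(radius)) {
    ids <- vapply(seq_len(n), function(a) {
      h <- fp_hash2(ids[a], r)
      if (length(nbr[[a]])) {
        key <- ord[[a]] * FP_PRIME + ids[nbr[[a]]]
        for (v in sort(key)) h <- fp_hash2(h, v %% FP_PRIME + v %/% FP_PRIME)
      }
      h
    }, 0)
    all_ids <- c(all_ids, ids)
  }
  unique(all_ids %% n_bits) + 1
}

#' Morgan-type circular fingerprints
#'
#' Computes radius-2, 2048-bit (by default) circular substructure
#' fingerprints for a set of molecules. Identical molecules written as
#' different SMILES give identical fingerprints; the computation is fully
#' deterministic.
#'
#' @param x an `or_library` data.frame (columns `id`, `smiles`) or a
#'   character vector of SMILES (optionally named).
#' @param radius neighborhood radius (2 corresponds to the common
#'   "Morgan2"/ECFP4 setting).
#' @param n_bits fingerprint length in bits (at least 8).
#' @return A binary integer matrix with one row per molecule (rownames =
#'   ids) and `n_bits` columns.
#' @export
#' @examples
#' \donttest{
#' fps <- morgan_fp(c(a = "CCO", b = "OCC", c = "c1ccccc1"))
#' identical(fps["a", ], fps["b", ])  # TRUE: same molecule
#' tanimoto(fps["a", ], fps["c", ])
#' }
morgan_fp <- function(x, radius = 2, n_bits = 2048) {
  if (n_bits < 8) stop("n_bits must be at least 8")
  if (radius < 0) stop("radius must be non-negative")
  if (is.character(x)) {
    ids <- names(x) %||% paste0("m", seq_along(x))
    x <- data.frame(id = ids, smiles = unname(x), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("id", "smiles") %in% names(x)))
  assert_ids(x$id)
  can <- canonical_smiles(as.character(x$smiles))
  if (anyNA(can))
    stop("unparseable SMILES for: ", paste(x$id[is.na(can)], collapse = ", "))
  sdf <- ChemmineR::smiles2sdf(stats::setNames(can, x$id))
  fps <- matrix(0L, nrow = nrow(x), ncol = n_bits,
                dimnames = list(x$id, NULL))
  for (cid in ChemmineR::cid(sdf)) {
    mol <- sdf[[cid]]
    ab <- ChemmineR::atomblock(mol)
    elem <- sub("_.*$", "", rownames(ab))
    bb <- ChemmineR::bondblock(mol)
    bonds <- if (length(bb) && nrow(bb)) {
      m <- matrix(as.integer(as.matrix(bb[, 1:3, drop = FALSE])), ncol = 3)
      m[m[, 3] < 1 | m[, 3] > 4, 3] <- 1L  # defensive: clamp odd bond codes
      m
    } else matrix(integer(), ncol = 3)
    # drop explicit hydrogens if any
    keep <- elem != "H"
    if (!all(keep)) {
      idx <- cumsum(keep)
      bonds <- bonds[keep[bonds[, 1]] & keep[bonds[, 2]], , drop = FALSE]
      bonds[, 1] <- idx[bonds[, 1]]; bonds[, 2] <- idx[bonds[, 2]]
      elem <- elem[keep]
    }
    fps[cid, fp_bits_graph(elem, bonds, radius, n_bits)] <- 1L
  }
  fps
}

#' Tanimoto similarity between two binary fingerprints
#'
#' `|a AND b| / |a OR b|`. By convention two all-zero vectors have
#' similarity 1 (identical, featureless).
#'
#' @param a,b binary vectors of equal length.
#' @return Similarity in `[0, 1]`.
#' @export
#' @examples
#' tanimoto(c(1, 1, 1, 0), c(0, 1, 1, 1))  # 2 shared / 4 union = 0.5
tanimoto <- function(a, b) {
  if (length(a) != length(b)) stop("fingerprint length mismatch")
  a <- as.logical(a); b <- as.logical(b)
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

# Pairwise Tanimoto similarity matrix for a 0/1 fingerprint matrix
# (rows = molecules); used by the chemical-space module.
tanimoto_matrix <- function(fps) {
  m <- fps %*% t(fps)                 # intersections
  on <- rowSums(fps)
  un <- outer(on, on, "+") - m        # unions
  s <- ifelse(un == 0, 1, m / un)
  dimnames(s) <- list(rownames(fps), rownames(fps))
  s
}
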