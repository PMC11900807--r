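# shared fixtures and independent oracles

# brute-force pairwise AUC oracle: fraction of (active, inactive) pairs
# where the active has the more negative score; ties count 0.5
auc_pairwise_oracle <- function(scores, active) {
  a <- scores[active]; i <- scores[!active]
  conc <- 0
  for (x in a) for (y in i)
    conc <- conc + if (x < y) 1 else if (x == y) 0.5 else 0
  conc / (length(a) * length(i))
}

# ranked list straight from a named score vector
make_ranked <- function(scores, receptor = "R1", method = "vinardo_raw") {
  rank_scores(score_table(receptor, scores, method))
}

# random labelled score instance (possibly with score ties)
random_instance <- function(n, ties = TRUE) {
  pool <- if (ties) round(stats::rnorm(n), 1) else stats::rnorm(n)
  scores <- stats::setNames(pool, paste0("m", seq_len(n)))
  n_act <- sample(seq_len(n - 1), 1)
  active <- stats::setNames(rep(FALSE, n), names(scores))
  active[sample(names(scores), n_act)] <- TRUE
  list(scores = scores, active = active)
}

# block fingerprints: families with disjoint on-bit blocks
block_fps <- function(n, block, n_bits = 256, prefix = "m", bits_on = 20,
                      seed = 99) {
  m <- matrix(0L, n, n_bits,
              dimnames = list(paste0(prefix, sprintf("%02d", seq_len(n))), NULL))
  withr::with_seed(seed, for (i in seq_len(n)) m[i, sample(block, bits_on)] <- 1L)
  m
}

# hand-counted descriptor oracle: molecular formulas worked out on paper,
# MW from 2021 IUPAC standard atomic weights
descriptor_oracle <- data.frame(
  id = c("ethanol", "eugenol", "benzene", "acetophenone", "limonene",
         "hexanal", "ethyl_acetate", "linalool", "sulcatone", "benzyl_formate"),
  smiles = c("CCO", "COc1cc(CC=C)ccc1O", "c1ccccc1", "CC(=O)c1ccccc1",
             "CC1=CCC(CC1)C(=C)C", "CCCCCC=O", "CCOC(C)=O",
             "CC(C)=CCCC(C)(O)C=C", "CC(C)=CCCC(C)=O", "O=COCc1ccccc1"),
  heavy = c(3L, 12L, 6L, 9L, 10L, 7L, 6L, 11L, 9L, 10L),
  hetero = c(1L, 2L, 0L, 1L, 0L, 1L, 2L, 1L, 1L, 2L),
  mw = c(46.07, 164.20, 78.11, 120.15, 136.23, 100.16, 88.11, 154.25,
         126.20, 136.15),
  stringsAsFactors = FALSE)

# deterministic ranked lists over a shared universe where each
# receptor's top ranks can be pinned: `tops[[r]]` lists molecule ids
# forced best-first; unpinned molecules rank by reverse id order, so low
# ids sit at the bottom unless pinned
pinned_ranked <- function(n_rec, ids, tops) {
  base <- stats::setNames(-1 - 0.001 * seq_along(ids), ids)
  stats::setNames(lapply(seq_len(n_rec), function(i) {
    s <- base
    top <- tops[[i]]
    s[top] <- -100 + seq_along(top)  # far ahead of everything else
    make_ranked(s, receptor = paste0("R", i))
  }), paste0("R", seq_len(n_rec)))
}
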