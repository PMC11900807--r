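make_lib <- function(ids, ha) data.frame(id = ids, smiles = "x",
                                         heavy_atoms = as.integer(ha))

test_that("score tables parse from delimited files and group by receptor", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("receptor,molecule,score", "R1,m1,-6.0", "R1,m2,-4.5",
               "R2,m1,-3.0"), path)
  tabs <- parse_scores(path)
  expect_named(tabs, c("R1", "R2"))
  expect_equal(tabs$R1$scores, c(m1 = -6.0, m2 = -4.5))
  expect_equal(tabs$R1$method, "vinardo_raw")
})

test_that("duplicate score rows keep the most negative with a warning", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("receptor,molecule,score", "R1,m1,-6.0", "R1,m1,-7.1"), path)
  expect_warning(tabs <- parse_scores(path), "duplicate")
  expect_equal(tabs$R1$scores[["m1"]], -7.1)
})

test_that("malformed score files raise located errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("receptor,molecule,score", "R1,m1,abc"), path)
  expect_error(parse_scores(path), "non-numeric")
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines("receptor,molecule", path2)
  expect_error(parse_scores(path2), "score")
})

test_that("smina-style logs yield the best pose affinity per molecule", {
  path <- withr::local_tempfile(fileext = ".log")
  writeLines(c(
    "Ligand: molA",
    "mode |   affinity | dist from best mode",
    "-----+------------+---------------------",
    "   1       -6.725      0.000      0.000",
    "   2       -6.100      1.902      2.504",
    "Ligand: molB",
    "mode |   affinity | dist from best mode",
    "-----+------------+---------------------",
    "   1       -4.210      0.000      0.000"), path)
  tabs <- parse_scores(path, "smina_log", receptor_id = "R7")
  expect_equal(tabs$R7$scores, c(molA = -6.725, molB = -4.21))
})

test_that("rescoring applies the ligand-efficiency formulas exactly", {
  lib <- make_lib(c("m1", "m2", "m3"), c(12, 1, 8))
  tab <- score_table("R1", c(m1 = -6.0, m2 = -5.0, m3 = -8.0))
  expect_equal(rescore(tab, lib, "LE")$scores[["m1"]], -0.5)
  expect_equal(rescore(tab, lib, "LEln")$scores[["m2"]], -5.0)  # ln 1 = 0
  expect_equal(rescore(tab, lib, "LESA")$scores[["m3"]], -2.0)  # 8^(2/3) = 4
  expect_setequal(names(rescore(tab, lib, "LE")$scores), names(tab$scores))
})

test_that("rescoring validates its inputs", {
  lib <- make_lib("m1", 12)
  tab <- score_table("R1", c(m1 = -6, mX = -2))
  expect_error(rescore(tab, lib, "LE"), "mX")
  le <- rescore(score_table("R1", c(m1 = -6)), lib, "LE")
  expect_error(rescore(le, lib, "LE"), "raw")
})

test_that("rescoring preserves ranks within equal heavy-atom strata and
           is strictly increasing in heavy atoms for fixed raw score", {
  # same HA: order preserved
  lib <- make_lib(paste0("m", 1:4), rep(10, 4))
  tab <- score_table("R1", stats::setNames(c(-9, -7, -5, -3), paste0("m", 1:4)))
  for (m in c("LE", "LEln", "LESA"))
    expect_equal(rank_scores(rescore(tab, lib, m))$order,
                 rank_scores(tab)$order)
  # mixed HA: a large weak binder loses its raw-rank advantage
  lib2 <- make_lib(c("big", "small"), c(25, 5))
  tab2 <- score_table("R1", c(big = -6, small = -4))
  expect_equal(rank_scores(tab2)$order, c("big", "small"))
  expect_equal(rank_scores(rescore(tab2, lib2, "LE"))$order, c("small", "big"))
  # monotone size penalty
  for (m in c("LE", "LEln", "LESA")) {
    vals <- vapply(2:25, function(ha)
      rescore(score_table("R", c(m1 = -6)), make_lib("m1", ha), m)$scores[[1]], 0)
    expect_true(all(diff(vals) > 0))
  }
})

test_that("ranking sorts best-first with deterministic id tie-breaks", {
  r <- rank_scores(score_table("R1", c(m1 = -3, m2 = -9, m3 = -5)))
  expect_equal(r$order, c("m2", "m3", "m1"))
  expect_equal(r$rank[["m1"]], 3L)
  tie <- rank_scores(score_table("R1", c(mb = -4, ma = -4)))
  expect_equal(tie$order, c("ma", "mb"))
  single <- rank_scores(score_table("R1", c(only = -2)))
  expect_equal(single$rank[["only"]], 1L)
})

test_that("parse -> rescore -> write -> re-read reproduces identical ranks", {
  lib <- make_lib(paste0("m", 1:20), sample(4:25, 20, TRUE))
  tabs <- list(R1 = score_table("R1",
    stats::setNames(round(-runif(20, 2, 9), 3), lib$id)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_rescored_csv(tabs, lib, path)
  for (m in c("LE", "LEln", "LESA")) {
    direct <- rank_scores(rescore(tabs$R1, lib, m))
    reread <- rank_scores(read_rescored_csv(path, m)$R1)
    expect_equal(reread$order, direct$order)
  }
})
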