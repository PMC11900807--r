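test_that("roc_auc reproduces worked examples and rejects degenerate labels", {
  r4 <- make_ranked(c(m1 = -9, m2 = -8, m3 = -2, m4 = -1))
  lab <- c(m1 = "active", m2 = "active", m3 = "inactive", m4 = "inactive")
  expect_equal(roc_auc(r4, lab), 1)
  rev_lab <- c(m1 = "inactive", m2 = "inactive", m3 = "active", m4 = "active")
  expect_equal(roc_auc(r4, rev_lab), 0)
  r <- make_ranked(c(a = -9, b = -5, c = -4, d = -1))
  expect_equal(roc_auc(r, c(a = "active", b = "inactive",
                            c = "active", d = "inactive")), 0.75)
  expect_error(roc_auc(r4, c(m1 = "active", m2 = "active",
                             m3 = "active", m4 = "active")), "undefined")
})

test_that("roc_auc equals the brute-force pairwise oracle on random instances", {
  withr::with_seed(42, {
    for (i in 1:300) {
      inst <- random_instance(sample(3:50, 1))
      expect_equal(roc_auc(make_ranked(inst$scores), inst$active),
                   auc_pairwise_oracle(inst$scores, inst$active))
    }
  })
})

test_that("roc_auc of a reversed ranking is the complement when tie-free", {
  withr::with_seed(11, {
    for (i in 1:25) {
      inst <- random_instance(sample(4:40, 1), ties = FALSE)
      a <- roc_auc(make_ranked(inst$scores), inst$active)
      b <- roc_auc(make_ranked(-inst$scores), inst$active)
      expect_equal(a + b, 1)
    }
  })
})

test_that("roc_auc agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(5, {
    for (i in 1:10) {
      inst <- random_instance(30)
      ours <- roc_auc(make_ranked(inst$scores), inst$active)
      ref <- as.numeric(pROC::auc(pROC::roc(
        response = inst$active, predictor = inst$scores,
        direction = ">", levels = c(FALSE, TRUE), quiet = TRUE)))
      expect_equal(ours, ref)
    }
  })
})

test_that("enrichment factor counts actives in the top fraction", {
  scores <- stats::setNames(-(100:1) / 10, paste0("m", 1:100))
  r <- make_ranked(scores)
  lab <- stats::setNames(rep(FALSE, 100), names(scores))
  lab[r$order[c(1:5, 30, 40, 50, 60, 70)]] <- TRUE  # 10 actives, 5 in top 10
  expect_equal(enrichment_factor(r, lab, 0.10), 5)
  lab2 <- stats::setNames(rep(FALSE, 100), names(scores))
  lab2[r$order[1:10]] <- TRUE
  expect_equal(enrichment_factor(r, lab2, 0.10), 10)  # maximal = 1/fraction
  lab3 <- stats::setNames(rep(FALSE, 100), names(scores))
  lab3[r$order[seq(5, 100, by = 10)]] <- TRUE  # exactly uniform spread
  expect_equal(enrichment_factor(r, lab3, 0.5), 1)
  expect_error(enrichment_factor(r, lab3 & FALSE, 0.1), "zero actives")
})

test_that("EF at fraction 1 is exactly 1 for any labels", {
  withr::with_seed(21, {
    for (i in 1:50) {
      inst <- random_instance(sample(3:60, 1))
      expect_equal(enrichment_factor(make_ranked(inst$scores),
                                     inst$active, 1), 1)
    }
  })
})

test_that("optimal top fraction maximizes the corrected TPR/FPR ratio", {
  scores <- stats::setNames(-(10:1), paste0("m", 1:10))
  r <- make_ranked(scores)
  lab <- stats::setNames(rep(FALSE, 10), names(scores))
  lab[r$order[1:2]] <- TRUE
  # at 20%: TPR 1, FPR 0 -> corrected 0.5/8, ratio 16; checked by hand
  opt <- optimal_top_fraction(r, lab, seq(0.1, 1, 0.1))
  expect_equal(opt$fraction, 0.2)
  expect_equal(opt$ratio, 16)
  # actives at the two worst ranks: only the full list reaches them
  lab2 <- stats::setNames(rep(FALSE, 10), names(scores))
  lab2[r$order[9:10]] <- TRUE
  expect_equal(optimal_top_fraction(r, lab2, seq(0.1, 1, 0.1))$fraction, 1)
  expect_equal(optimal_top_fraction(r, lab, 0.3)$fraction, 0.3)
})

synthetic_panel <- function(n_rec = 5, n_mol = 60, seed = 8, perfect = FALSE) {
  withr::with_seed(seed, {
    ids <- paste0("m", seq_len(n_mol))
    labels <- matrix(FALSE, n_rec, n_mol,
                     dimnames = list(paste0("R", seq_len(n_rec)), ids))
    tabs <- list()
    for (r in rownames(labels)) {
      act <- sample(ids, 6)
      labels[r, act] <- TRUE
      s <- stats::setNames(rnorm(n_mol, -4), ids)
      s[act] <- s[act] - if (perfect) 100 else 1.5
      tabs[[length(tabs) + 1]] <- score_table(r, s)
    }
    list(tabs = tabs, activity = activity_matrix(labels = labels))
  })
}

test_that("calibrate reports per-receptor metrics and class medians", {
  p <- synthetic_panel(perfect = TRUE)
  rep <- calibrate(p$tabs, p$activity, grid = seq(0.05, 1, 0.05))
  expect_s3_class(rep, "calibration_report")
  expect_equal(nrow(rep$per_receptor), 5)
  expect_equal(rep$summary$median_auc, 1)  # perfect separation everywhere
  expect_true(all(rep$per_receptor$max_ef <= 60 / 6))
  expect_error(calibrate(p$tabs[-1], p$activity), "missing")
})

test_that("workflow thresholds are medians of per-receptor quantities", {
  # engineered panel: optimal fractions 4%, 6%, 8% and TPR=1 ranks 40/45/50
  n <- 100
  ids <- paste0("m", sprintf("%03d", 1:n))
  labels <- matrix(FALSE, 3, n, dimnames = list(c("Ra", "Rb", "Rc"), ids))
  tabs <- list()
  specs <- list(Ra = c(4, 40), Rb = c(6, 45), Rc = c(8, 50))
  for (r in names(specs)) {
    k <- specs[[r]][1]; worst <- specs[[r]][2]
    s <- stats::setNames(-(n:1) / 10, ids)   # m001 best ... m100 worst
    # actives fill ranks 1..k plus one straggler at rank `worst`, so the
    # corrected TPR/FPR ratio peaks exactly at fraction k% and TPR first
    # reaches 1 at `worst`
    act <- ids[c(seq_len(k), worst)]
    labels[r, act] <- TRUE
    tabs[[length(tabs) + 1]] <- score_table(r, s)
  }
  rep <- calibrate(tabs, activity_matrix(labels = labels),
                   grid = seq(0.01, 1, 0.01))
  expect_equal(rep$chosen_top_fraction, 0.06)
  expect_equal(rep$nonbinder_fraction, 0.45)
})

test_that("pheromone receptors are excluded from threshold derivation", {
  p <- synthetic_panel(n_rec = 4)
  cls <- stats::setNames(c("pheromone_receptor", rep("non_pheromonal", 3)),
                         paste0("R", 1:4))
  act <- activity_matrix(labels = p$activity$labels, receptor_class = cls)
  rep <- calibrate(p$tabs, act)
  expect_setequal(unique(rep$summary$class),
                  c("pheromone_receptor", "non_pheromonal"))
  non <- rep$per_receptor[rep$per_receptor$class == "non_pheromonal" &
                          rep$per_receptor$method == rep$best_method, ]
  expect_equal(rep$chosen_top_fraction, median(non$optimal_fraction))
})

test_that("p-value activity matrices derive labels at the strict threshold", {
  p <- matrix(c(0.0005, 0.01, 0.2, 0.001), 1, 4,
              dimnames = list("R1", paste0("m", 1:4)))
  act <- activity_matrix(p_values = p)
  expect_equal(unname(act$labels["R1", ]), c(TRUE, FALSE, FALSE, FALSE))
  act05 <- activity_matrix(p_values = p, p_threshold = 0.05)
  expect_equal(sum(act05$labels), 3)
})

test_that("activity panels round-trip through CSV", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("receptor,molecule,label", "R1,m1,active", "R1,m2,inactive",
               "R2,m1,inactive", "R2,m2,active"), path)
  act <- read_activity_csv(path)
  expect_equal(dim(act$labels), c(2L, 2L))
  expect_true(act$labels["R1", "m1"])
  expect_false(act$labels["R2", "m1"])
})
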