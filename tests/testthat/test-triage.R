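test_that("the promiscuity threshold is inclusive at exactly 0.7", {
  withr::with_seed(3, {
    ids <- paste0("m", sprintf("%03d", 1:100))
    # d1 pinned into the top set of exactly 7 of 10 receptors, d2 in 1
    tops <- lapply(1:10, function(i)
      c(if (i <= 7) "m001", if (i == 1) "m002"))
    ranked <- pinned_ranked(10, ids, tops)
    tr <- triage(ranked, top_fraction = 0.06, promiscuity_threshold = 0.7)
    expect_equal(tr$decoy_frequency[["m001"]], 0.7)
    expect_true("m001" %in% tr$suspected_decoys)      # inclusive boundary
    expect_false("m002" %in% tr$suspected_decoys)     # frequency 0.1
    expect_true("m002" %in% tr$potential_binders$R1)  # still a binder there
    expect_false("m001" %in% unlist(tr$potential_binders))
  })
})

test_that("bottom-fraction non-binders are the worst ranks", {
  withr::with_seed(4, {
    ids <- paste0("m", sprintf("%03d", 1:100))
    ranked <- pinned_ranked(1, ids, list(character()))
    tr <- triage(ranked, bottom_fraction = 0.45)
    nb <- tr$potential_nonbinders$R1
    expect_length(nb, 45)
    expect_setequal(nb, ranked$R1$order[56:100])
    expect_length(intersect(tr$potential_binders$R1, nb), 0)
  })
})

test_that("raising the promiscuity threshold never shrinks binder sets", {
  withr::with_seed(5, {
    sim <- simulate_screen(screen_sim_config(n_receptors = 8,
                                             n_molecules = 150, seed = 12))
    ranked <- lapply(lapply(sim$tables, rescore, library = sim$library,
                            method = "LE"), rank_scores)
    prev <- NULL
    for (thr in c(0.2, 0.5, 0.7, 0.9, 1.0)) {
      tr <- triage(ranked, promiscuity_threshold = thr)
      sizes <- lengths(tr$potential_binders)
      if (!is.null(prev)) expect_true(all(sizes >= prev))
      prev <- sizes
      expect_true(all(sizes <= tr$parameters$top_k))
      expect_true(all(tr$decoy_frequency[tr$suspected_decoys] >= thr))
    }
  })
})

test_that("a single receptor yields degenerate 0/1 frequencies", {
  withr::with_seed(6, {
    ids <- paste0("m", 1:50)
    ranked <- pinned_ranked(1, ids, list(character()))
    tr <- triage(ranked, top_fraction = 0.1, promiscuity_threshold = 1)
    expect_setequal(unique(tr$decoy_frequency), c(0, 1))
    # decoys are exactly the top set; binder set is emptied
    expect_setequal(tr$suspected_decoys, ranked$R1$order[1:5])
    expect_length(tr$potential_binders$R1, 0)
  })
})

test_that("planted promiscuous decoys are recovered at 95%+ sensitivity", {
  hits <- vapply(1:5, function(s) {
    sim <- simulate_screen(screen_sim_config(decoy_effect = 0.8, seed = s))
    ranked <- lapply(lapply(sim$tables, rescore, library = sim$library,
                            method = "LE"), rank_scores)
    tr <- triage(ranked)
    # the strong scoring artefact plants them in essentially every top set
    expect_gte(min(tr$decoy_frequency[sim$decoys]), 0.7)
    mean(sim$decoys %in% tr$suspected_decoys)
  }, 0)
  expect_gte(mean(hits), 0.95)
})

test_that("triage validates universes and inputs", {
  r1 <- make_ranked(c(a = -3, b = -2), receptor = "R1")
  r2 <- make_ranked(c(a = -3, c = -2), receptor = "R2")
  expect_error(triage(list(R1 = r1, R2 = r2)), "universe")
  expect_error(triage(list()), "at least one")
  expect_error(triage(list(R1 = r1), decoy_receptors = "R9"), "unknown")
})

test_that("prediction evaluation reproduces the published panel arithmetic", {
  # broadly tuned receptor: 19 predicted binders of which 2 active,
  # 8 predicted non-binders/decoys all inactive
  ev25 <- evaluate_panel(ssr_panel("SlitOR25"))
  expect_equal(unname(ev25$counts), c(2L, 17L, 8L, 0L),
               ignore_attr = TRUE)
  expect_gte(ev25$precision, 10)
  expect_equal(ev25$precision, 100 * 2 / 19, tolerance = 1e-12)
  expect_equal(ev25$accuracy, 10 / 27, tolerance = 1e-12)
  # narrowly tuned receptor: 17 predicted binders of which 1 active
  ev31 <- evaluate_panel(ssr_panel("SlitOR31"))
  expect_equal(ev31$precision, 100 / 17, tolerance = 1e-12)
  expect_equal(round(ev31$precision), 6)
  expect_equal(ev31$accuracy, 9 / 25, tolerance = 1e-12)
})

test_that("undefined ratios are reported as absent, never zero", {
  pred <- stats::setNames(rep("nonbinder_or_decoy", 4), paste0("m", 1:4))
  obs <- stats::setNames(c(0, 0, 1, 0), paste0("m", 1:4))
  ev <- evaluate_predictions(pred, obs)
  expect_true(is.na(ev$precision))
  expect_equal(ev$accuracy, 0.75)
  expect_error(evaluate_predictions(pred, obs[-1]), "different molecule sets")
})
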