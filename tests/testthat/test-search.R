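test_that("candidate clades are counted correctly", {
  balanced <- parse_newick(
    "(((A:1,B:1):1,(C:1,D:1):1):1,((E:1,F:1):1,(G:1,H:1):1):1);")
  expect_length(candidate_clades(balanced, 4), 2)
  expect_length(candidate_clades(balanced, 2), 6)

  caterpillar <- parse_newick(
    "(A:1,(B:1,(C:1,(D:1,(E:1,(F:1,(G:1,H:1):1):1):1):1):1):1);")
  expect_length(candidate_clades(caterpillar, 4), 4)

  expect_length(candidate_clades(balanced, 100), 0)
  expect_warning(candidate_clades(balanced, 3, k = 3), "poorly determined")
  # preorder order is deterministic
  expect_equal(candidate_clades(caterpillar, 4),
               sort(candidate_clades(caterpillar, 4)))
})

test_that("branch regimes follow the most recent rootward shift, stem excluded", {
  tr <- parse_newick("(((A:1,B:1):1,C:1):1,((D:1,E:1):1,F:1):1);")
  ab <- ape::getMRCA(tr, c("A", "B"))
  abc <- ape::getMRCA(tr, c("A", "C"))
  asg <- regime_assignment(tr, c(abc, ab))   # regime 1 outer, 2 nested
  expect_equal(unname(asg[as.character(abc)]), 0L)  # stem of outer shift
  expect_equal(unname(asg[as.character(ab)]), 1L)   # nested stem: outer regime
  a <- which(tr$tip.label == "A")
  expect_equal(unname(asg[as.character(a)]), 2L)
  c_ <- which(tr$tip.label == "C")
  expect_equal(unname(asg[as.character(c_)]), 1L)
  f <- which(tr$tip.label == "F")
  expect_equal(unname(asg[as.character(f)]), 0L)
  expect_length(asg, 2 * 6 - 2)
})

test_that("a near-whole-tree candidate is penalty-dominated when matrices agree", {
  # strong common structure: the split model refits (almost) the same matrix
  # twice, so the AIC difference approaches the pure parameter penalty
  set.seed(31)
  tr <- sim_yule(40, 1, seed = 31)
  sim <- sim_divergences(tr, integer(0), list(equicorr(3, 0.6)), seed = 32)
  D <- sim$divergences
  cand <- candidate_clades(tr, 10)
  big <- cand[which.max(covshift:::.tip_counts(tr)[cand])]
  ev <- evaluate_candidate(big, D, tr)
  expect_lt(ev$delta_aic, 0)
  expect_gt(ev$delta_aic, -2 * 3 - 10)  # close to -2 * delta m, minus noise
})

test_that("a single fixed candidate under the null rarely improves AIC", {
  set.seed(37)
  hits <- 0
  for (r in 1:20) {
    tr <- sim_yule(64, 1, seed = 500 + r)
    sim <- sim_divergences(tr, integer(0), list(equicorr(3, 0.5)),
                           seed = 600 + r)
    cand <- candidate_clades(tr, 10)[1]
    ev <- evaluate_candidate(cand, sim$divergences, tr)
    if (!is.null(ev) && ev$delta_aic > 0) hits <- hits + 1
  }
  expect_lt(hits / 20, 0.5)
})

test_that("a strongly contrasting planted clade yields a positive improvement", {
  Rin <- equicorr(3, 0.8)
  Rout <- flip_sign(Rin, 1)
  tr <- sim_yule(128, 1, seed = 41)
  planted <- choose_clade(tr, 32)
  sim <- sim_divergences(tr, planted, list(Rout, Rin), seed = 42)
  ev <- evaluate_candidate(planted, sim$divergences, tr)
  expect_gt(ev$delta_aic, 0)
  m <- greedy_search(tr, sim$divergences)
  expect_true(planted %in% m$shift_nodes)
  expect_lt(m$aic, m$base_aic)
})

test_that("greedy search output is deterministic and AIC-bounded", {
  tr <- sim_yule(64, 1, seed = 43)
  sim <- sim_divergences(tr, integer(0), list(equicorr(3, 0.5)), seed = 44)
  m1 <- greedy_search(tr, sim$divergences)
  m2 <- greedy_search(tr, sim$divergences)
  expect_identical(serialize(m1, NULL), serialize(m2, NULL))
  expect_lte(m1$aic, m1$base_aic)
  # every branch assigned exactly one regime; aic identity holds
  expect_length(m1$assignment, 2 * 64 - 2)
  expect_equal(m1$aic, 2 * m1$n_params - 2 * m1$loglik)
})

test_that("permuting trait columns permutes matrices and leaves AIC unchanged", {
  Rin <- equicorr(3, 0.8)
  Rout <- flip_sign(Rin, 1)
  tr <- sim_yule(96, 1, seed = 47)
  planted <- choose_clade(tr, 28)
  sim <- sim_divergences(tr, planted, list(Rout, Rin), seed = 48)
  D <- sim$divergences
  perm <- c(3, 1, 2)
  m1 <- greedy_search(tr, D)
  m2 <- greedy_search(tr, D[, perm])
  expect_equal(m1$aic, m2$aic, tolerance = 1e-9)
  expect_equal(m1$shift_nodes, m2$shift_nodes)
  for (id in names(m1$matrices))
    expect_equal(unname(m2$matrices[[id]]),
                 unname(m1$matrices[[id]][perm, perm]), tolerance = 1e-12)
})

test_that("empty retention returns the base model", {
  # two regimes with identical matrices: no real shift to find
  tr <- sim_yule(24, 1, seed = 53)
  sim <- sim_divergences(tr, integer(0), list(diag(3)), seed = 54)
  m <- greedy_search(tr, sim$divergences, min_size = 25)  # no candidates
  expect_length(m$shift_nodes, 0)
  expect_equal(m$aic, m$base_aic)
  expect_equal(m$loglik, m$base_loglik)
  expect_equal(names(m$matrices), "0")
})

test_that("fit reports are written as machine-readable JSON", {
  tr <- sim_yule(32, 1, seed = 57)
  sim <- sim_divergences(tr, integer(0), list(equicorr(3, 0.4)), seed = 58)
  m <- greedy_search(tr, sim$divergences)
  f <- withr::local_tempfile(fileext = ".json")
  write_fit_report(m, f)
  rep <- jsonlite::read_json(f)
  expect_equal(rep$n_regimes, m$n_regimes)
  expect_equal(rep$aic, m$aic, tolerance = 1e-12)
  expect_named(rep$mean_abs_correlation, names(m$matrices))
})
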