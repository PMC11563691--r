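test_that("Yule simulation is reproducible and well-formed", {
  t1 <- sim_yule(50, 1, seed = 7)
  t2 <- sim_yule(50, 1, seed = 7)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_false(identical(ape::write.tree(t1),
                         ape::write.tree(sim_yule(50, 1, seed = 8))))
  expect_equal(nrow(t1$edge), 98)           # 2n - 2 branches
  expect_true(ape::is.binary(t1))
  expect_true(ape::is.ultrametric(t1, tol = 1e-8))
})

test_that("Yule tree height grows like log(n)/birth rate", {
  heights <- vapply(1:60, function(r) {
    max(ape::node.depth.edgelength(sim_yule(40, 2, seed = 900 + r)))
  }, numeric(1))
  # E[height] ~ sum_{j=2}^{n} 1/(lambda j) ~ log(n)/lambda; loose band
  expected <- sum(1 / (2 * (2:40)))
  expect_gt(mean(heights), 0.5 * expected)
  expect_lt(mean(heights), 2 * expected)
})

test_that("simulated increments follow the regime matrix and accumulate to tips", {
  R <- equicorr(3, 0.6)
  tr <- sim_yule(1500, 1, seed = 71)
  sim <- sim_divergences(tr, integer(0), list(R), seed = 72)
  expect_equal(nrow(sim$divergences), 2 * 1500 - 2)
  emp <- cov_to_corr(shrunk_covariance(sim$divergences, 0))
  expect_lt(max(abs(emp - R)), 0.05)
  expect_lt(max(abs(apply(sim$divergences, 2, sd) - 1)), 0.05)

  # tip values are exact root-to-tip sums of the returned increments
  par <- rep(0L, 1500 + tr$Nnode)
  par[tr$edge[, 2]] <- tr$edge[, 1]
  for (tip in c(1, 500, 1500)) {
    v <- tip; acc <- rep(0, 3)
    while (v != 1501) { acc <- acc + sim$divergences[as.character(v), ]; v <- par[v] }
    expect_equal(unname(acc), unname(sim$traits[tr$tip.label[tip], ]),
                 tolerance = 1e-12)
  }
})

test_that("identical seeds reproduce the simulation exactly", {
  tr <- sim_yule(30, 1, seed = 73)
  shift <- choose_clade(tr, 10)
  mats <- list(equicorr(3, 0.2), equicorr(3, 0.7))
  s1 <- sim_divergences(tr, shift, mats, seed = 74)
  s2 <- sim_divergences(tr, shift, mats, seed = 74)
  expect_identical(s1, s2)
  expect_false(identical(s1$traits,
                         sim_divergences(tr, shift, mats, seed = 75)$traits))
  expect_error(sim_divergences(tr, shift, list(equicorr(3, .2)), seed = 1),
               "one matrix per regime")
  bad <- matrix(-0.8, 3, 3); diag(bad) <- 1
  expect_error(sim_divergences(tr, integer(0), list(bad), seed = 1),
               "positive definite")
})

test_that("per-trait tip variance equals the root-to-tip branch count under V = I", {
  tr <- parse_newick("((A:1,B:1):1,C:2);")   # A,B: 2 branches; C: 1
  tips <- vapply(1:400, function(r) {
    sim_divergences(tr, integer(0), list(diag(2)), seed = 2000 + r)$traits[, 1]
  }, numeric(3))
  v <- apply(tips, 1, var)
  expect_equal(unname(v[c("A", "B")]), c(2, 2), tolerance = 0.35)
  expect_equal(unname(v["C"]), 1, tolerance = 0.25)
})

test_that("time-scaled increments scale variance with branch length", {
  tr <- parse_newick("(A:9,B:1);")
  incs <- vapply(1:400, function(r) {
    sim_divergences(tr, integer(0), list(diag(1)), seed = 3000 + r,
                    scale_by_time = TRUE)$divergences[, 1]
  }, numeric(2))
  expect_equal(var(incs["1", ]) / var(incs["2", ]), 9, tolerance = 0.35 * 9)
})

test_that("choose_clade picks the nearest-size clade deterministically", {
  tr <- parse_newick(
    "(((A:1,B:1):1,(C:1,D:1):1):1,((E:1,F:1):1,(G:1,H:1):1):1);")
  nd <- choose_clade(tr, 4)
  expect_equal(unname(covshift:::.tip_counts(tr)[nd]), 4L)
  expect_identical(choose_clade(tr, 4), choose_clade(tr, 4))
})

test_that("recovery experiments return a machine-readable table", {
  expect_equal(nrow(recovery_experiment(16, diag(3), NULL, replicates = 0)), 0)
  tab <- recovery_experiment(32, equicorr(3, 0.5), NULL, replicates = 2,
                             seed = 81)
  expect_equal(nrow(tab), 2)
  expect_true(all(c("replicate", "planted_nodes", "shift_nodes", "n_shifts",
                    "recovered", "contains_planted", "delta_aic") %in%
                    names(tab)))
  expect_true(all(tab$delta_aic >= 0))   # final AIC never exceeds base

  Rin <- equicorr(3, 0.8)
  tab2 <- recovery_experiment(64, list(flip_sign(Rin, 1), Rin), 16,
                              replicates = 2, seed = 83)
  expect_type(tab2$contains_planted, "logical")
})
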