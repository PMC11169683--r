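test_that("the ground-truth model is valid and hits the published prior bands", {
  tr <- default_truth()
  expect_length(validate_network(tr$network), 0)
  for (cpt in tr$cpts) {
    expect_true(all(cpt$prob >= 0))
    expect_equal(unname(rowSums(cpt$prob)), rep(1, nrow(cpt$prob)),
                 tolerance = 1e-12)
  }
  # exact marginals (by inference, not sampling) within +/- 0.05 of the
  # published prior rates
  expect_true(abs(query(tr, "ERR")[["skill"]] - 0.375) <= 0.05)
  expect_true(abs(query(tr, "CO")[["yes"]] - 0.496) <= 0.05)
  expect_true(abs(query(tr, "PF")[["yes"]] - 0.598) <= 0.05)
  expect_true(abs(query(tr, "IS")[["yes"]] - 0.576) <= 0.05)
  expect_true(abs(query(tr, "OC")[["yes"]] - 0.253) <= 0.05)
  # routine violations more likely than exceptional ones
  vio <- query(tr, "VIO")
  expect_gt(vio[["routine"]], vio[["exceptional"]])
})

test_that("ancestral sampling is seed-deterministic down to the written file", {
  tr <- default_truth()
  d1 <- sample_incidents(tr, 40, seed = 123)
  d2 <- sample_incidents(tr, 40, seed = 123)
  expect_identical(d1$records, d2$records)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_case_db(d1, f1); write_case_db(d2, f2)
  expect_identical(readLines(f1), readLines(f2))
  d3 <- sample_incidents(tr, 40, seed = 124)
  expect_false(identical(d1$records, d3$records))
})

test_that("degenerate CPTs force every sampled record to the same assignment", {
  net <- chain_network()
  bn <- make_bn(net, list(A = cbind(yes = 1, no = 0),
                          B = cbind(yes = c(0, 0), no = c(1, 1)),
                          C = cbind(yes = c(1, 1), no = c(0, 0))))
  db <- simulate(bn, nsim = 25, seed = 5)
  expect_true(all(db$records$A == "yes"))
  expect_true(all(db$records$B == "no"))
  expect_true(all(db$records$C == "yes"))
})

test_that("sampling frequencies concentrate around the exact marginals", {
  tr <- default_truth()
  tr$cpts$RM$prob[1, ] <- c(0.2, 0.8)
  db <- sample_incidents(tr, 10000, seed = 7)
  expect_lt(abs(mean(db$records$RM == "yes") - 0.2), 0.012)  # 3 sigma binomial
  # every node state within its own 3 sigma band at n = 10000
  for (code in c("OC", "IS", "CO", "ERR", "VIO")) {
    p <- query(tr, code)
    for (s in names(p)) {
      phat <- mean(db$records[[code]] == s)
      expect_lt(abs(phat - p[[s]]), 3 * sqrt(p[[s]] * (1 - p[[s]]) / 10000) + 1e-12)
    }
  }
})

test_that("sampled records carry labels from the packaged phase distribution", {
  tr <- default_truth()
  db <- sample_incidents(tr, 500, seed = 8)
  ref <- phase_error_counts()
  expect_true(all(db$records$phase %in% ref$phase))
  expect_true(all(db$records$error_type %in% ref$error_type))
  # the most common label should be the modal reference row at n = 500
  tab <- summarize_phases(db)
  expect_equal(tab$error_type[which.max(tab$count)],
               "wrong data transfer or setting")
})

test_that("the frozen 81-incident fixture regenerates from its published seed", {
  frozen <- synthetic_cases()
  fresh <- sample_incidents(default_truth(), 81, seed = 42)
  expect_identical(frozen$records, fresh$records)
  expect_equal(nrow(frozen$records), 81)
})

test_that("CPT recovery is exact in expectation and improves with sample size", {
  tr <- default_truth()
  expect_error(recovery_experiment(tr, 0), "positive")
  rep5k <- recovery_experiment(tr, 5000, alpha = 1, seed = 11)
  expect_true(all(rep5k$rows$tv >= 0 & rep5k$rows$tv <= 1))
  # abundant rows (>= 1000 observations) recover within TV 0.05
  big <- rep5k$rows$n_obs >= 1000
  expect_true(any(big))
  expect_lt(max(rep5k$rows$tv[big]), 0.05)
  # estimation error decreases with n for matched seeds (allow one inversion
  # in five); compared on mean TV over all rows, which is the summary that is
  # comparable across sample sizes (the >= 50-observation row set itself
  # grows with n)
  worse <- vapply(1:5, function(s) {
    small <- recovery_experiment(tr, 200, alpha = 1, seed = s)$mean_tv
    large <- recovery_experiment(tr, 5000, alpha = 1, seed = s)$mean_tv
    large > small
  }, TRUE)
  expect_lte(sum(worse), 1)
})

test_that("recovery from a uniform-CPT truth stays near uniform", {
  net <- hfacs_network()
  tables <- lapply(net$nodes$code, function(code) {
    k <- length(net$states[[code]])
    nc <- prod(lengths(net$states[bnhfacs:::parents_of(net, code)]))
    matrix(1 / k, nc, k)
  })
  names(tables) <- net$nodes$code
  tr <- make_bn(net, tables)
  rep <- recovery_experiment(tr, 5000, alpha = 1, seed = 3)
  expect_lt(rep$mean_tv, 0.05)
  big <- rep$rows$n_obs >= 1000
  expect_lt(max(rep$rows$tv[big]), 0.05)
})
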