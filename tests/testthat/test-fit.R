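test_that("smoothed maximum-likelihood CPT estimation follows the counting formula", {
  # four incidents, IS always "yes": with alpha = 0 every observed row is exact
  db <- as_case_db(toy_records(list(list(IS = "yes"), list(IS = "yes"),
                                    list(IS = "yes", RM = "yes"),
                                    list(IS = "yes"))))
  fit0 <- hfacs_bn(db, alpha = 0)
  obs <- !fit0$cpts$IS$unobserved
  expect_true(all(fit0$cpts$IS$prob[obs, "yes"] == 1))

  # root node: 3 of 4 records "yes", alpha = 1 -> (3+1)/(4+2) = 2/3
  db2 <- as_case_db(toy_records(list(list(RM = "yes"), list(RM = "yes"),
                                     list(RM = "yes"), list())))
  fit1 <- hfacs_bn(db2, alpha = 1)
  expect_equal(unname(fit1$cpts$RM$prob[1, "yes"]), 2 / 3)
  # and with alpha = 0 the root marginal equals the empirical frequency exactly
  fit0b <- hfacs_bn(db2, alpha = 0)
  expect_identical(unname(fit0b$cpts$RM$prob[1, "yes"]), 3 / 4)
  expect_equal(query(fit0b, "RM")[["yes"]], 3 / 4)
})

test_that("unobserved parent configurations fall back to uniform under pure MLE", {
  db <- as_case_db(toy_records(list(list(ERR = "skill"))))
  fit <- hfacs_bn(db, alpha = 0)
  unobs <- fit$cpts$ERR$unobserved
  expect_true(any(unobs))
  expect_true(all(fit$cpts$ERR$prob[unobs, ] == 1 / 4))
  expect_gt(length(fit$provenance$unobserved_configs), 0)
})

test_that("every fitted CPT row is a proper distribution", {
  db <- synthetic_cases()
  for (a in c(0, 0.5, 1)) {
    fit <- hfacs_bn(db, alpha = a)
    for (cpt in fit$cpts) {
      expect_true(all(cpt$prob >= 0))
      expect_equal(unname(rowSums(cpt$prob)), rep(1, nrow(cpt$prob)),
                   tolerance = 1e-12)
      expect_equal(nrow(cpt$prob),
                   prod(lengths(fit$network$states[cpt$parents])))
    }
  }
})

test_that("smoothing pulls every row toward uniform as alpha grows", {
  db <- synthetic_cases()
  dist_to_uniform <- function(fit) max(vapply(fit$cpts, function(cpt)
    max(abs(cpt$prob - 1 / ncol(cpt$prob))), 1))
  d <- vapply(c(1, 10, 1e4), function(a) dist_to_uniform(hfacs_bn(db, alpha = a)), 1)
  expect_true(all(diff(d) < 0))
  expect_lt(d[3], 1e-2)
})

test_that("degenerate inputs are rejected", {
  db <- synthetic_cases()
  empty <- db
  empty$records <- db$records[0, ]
  expect_error(hfacs_bn(empty), "empty")
  expect_error(hfacs_bn(db, alpha = -1), "alpha")
})

test_that("authored models are validated and serialization round-trips exactly", {
  expect_error(make_bn(chain_network(), list(A = cbind(0.5, 0.6),
                                             B = cbind(c(1, 1), c(0, 0)),
                                             C = cbind(c(1, 1), c(0, 0)))),
               "sum to 1")
  fit <- hfacs_bn(synthetic_cases(), alpha = 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_bn_json(fit, path)
  back <- read_bn_json(path)
  for (code in names(fit$cpts)) {
    expect_identical(unname(back$cpts[[code]]$prob),
                     unname(fit$cpts[[code]]$prob))
    expect_identical(back$cpts[[code]]$parents, fit$cpts[[code]]$parents)
  }
  expect_identical(back$network$nodes, fit$network$nodes)
})

test_that("model methods expose coefficients, likelihood and predictions", {
  fit <- hfacs_bn(synthetic_cases(), alpha = 1)
  cf <- coef(fit)
  expect_named(cf, fit$network$nodes$code)
  expect_equal(dim(cf$ERR), c(8, 4))
  expect_lt(as.numeric(logLik(fit)), 0)
  pm <- predict(fit)
  expect_equal(nrow(pm), sum(lengths(fit$network$states)))
  agg <- tapply(pm$probability, pm$node, sum)
  expect_equal(as.vector(agg), rep(1, 12), tolerance = 1e-9)
  expect_output(print(fit), "Layered Bayesian network")
  expect_output(print(summary(fit)), "Prior marginal")
})
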