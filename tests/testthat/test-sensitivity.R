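test_that("the sensitivity kernel implements the truncated relative change", {
  expect_equal(relative_sensitivity(0.624, 0.571), (0.624 - 0.571) / 0.571)
  expect_equal(bnhfacs:::round_half_up(relative_sensitivity(0.624, 0.571), 2), 0.09)
  expect_equal(relative_sensitivity(0.4, 0.4), 0)      # no change
  expect_equal(relative_sensitivity(0.2, 0.5), 0)      # negative change truncated
  expect_equal(relative_sensitivity(0, 0), 0)
  expect_error(relative_sensitivity(0.3, 0), "undefined")
})

test_that("presentation rounding is half-up, full precision is kept internally", {
  expect_equal(bnhfacs:::round_half_up(0.125, 2), 0.13)
  expect_equal(bnhfacs:::round_half_up(0.004999, 2), 0)
  s <- sensitivity(default_truth(), "RM", "IS")
  expect_gt(abs(s - round(s, 2)), 0)  # the raw value is not pre-rounded
})

test_that("pairwise sensitivity validates the query against the network", {
  bn <- default_truth()
  expect_error(sensitivity(bn, "ERR", "VIO"), "binary")
  expect_error(sensitivity(bn, "CO", "IS"), "level")
  expect_error(sensitivity(bn, "RM", "ERR", "none"), "occurrence state")
  expect_gte(sensitivity(bn, "RM", "ERR", "skill"), 0)
})

test_that("the matrix has the layered fill pattern and matches single calls", {
  bn <- hfacs_bn(synthetic_cases(), alpha = 1)
  sm <- sensitivity_matrix(bn)
  expect_equal(colnames(sm), c("RM", "OC", "OP", "IS", "PIO", "FCP", "SV",
                               "CO", "PF", "EF"))
  expect_equal(rownames(sm), c("IS", "PIO", "FCP", "SV", "CO", "PF", "EF",
                               "SBE", "DE", "PE", "RV", "EV"))
  filled <- attr(sm, "filled")
  # level-3 rows only under the level-4 columns; bottom rows under all ten
  expect_true(all(filled["IS", c("RM", "OC", "OP")]))
  expect_false(any(filled["IS", c("IS", "PIO", "FCP", "SV", "CO", "PF", "EF")]))
  expect_true(all(filled["SBE", ]))
  expect_true(all(filled["RV", ]))
  expect_false(any(filled["CO", c("CO", "PF", "EF")]))
  # cellwise agreement with the scalar operation
  rows <- attr(sm, "rows")
  for (cell in list(c("RM", "IS"), c("OC", "PF"), c("CO", "SBE"), c("EF", "EV"))) {
    i <- match(cell[2], rownames(sm))
    expect_identical(sm[cell[2], cell[1]],
                     sensitivity(bn, cell[1], rows$node[i], rows$state[i]))
  }
  expect_true(all(sm[filled] >= 0, na.rm = TRUE))
})

test_that("a lower node with constant CPT rows is insensitive to everything", {
  net <- hfacs_network()
  bn <- random_bn(net, seed = 12)
  # make ERR's distribution identical across all parent configurations
  row <- bn$cpts$ERR$prob[1, , drop = FALSE]
  bn$cpts$ERR$prob <- row[rep(1, nrow(bn$cpts$ERR$prob)), , drop = FALSE]
  sm <- sensitivity_matrix(bn)
  for (r in c("SBE", "DE", "PE")) {
    vals <- sm[r, attr(sm, "filled")[r, ]]
    expect_equal(unname(vals), rep(0, length(vals)), tolerance = 1e-9)
  }
})

test_that("sensitivities from random fitted models are always non-negative", {
  for (seed in c(101, 102)) {
    db <- sample_incidents(random_bn(seed = seed), 300, seed = seed)
    sm <- sensitivity_matrix(hfacs_bn(db, alpha = 1))
    expect_true(all(sm[attr(sm, "filled")] >= 0, na.rm = TRUE))
  }
})

test_that("overall scores are the group means over error and violation states", {
  bn <- hfacs_bn(synthetic_cases(), alpha = 1)
  sm <- sensitivity_matrix(bn)
  ov <- overall_sensitivity(sm)
  expect_equal(ov$factor, colnames(sm))
  for (j in seq_len(ncol(sm))) {
    expect_equal(ov$errors[j], mean(sm[c("SBE", "DE", "PE"), j]))
    expect_equal(ov$violations[j], mean(sm[c("RV", "EV"), j]))
  }
  # hand-checked means on injected values
  stub <- sm
  stub[c("SBE", "DE", "PE"), "RM"] <- c(0.3, 0.6, 0.0)
  stub[c("RV", "EV"), "RM"] <- c(0.25, 0.0)
  ov2 <- overall_sensitivity(stub)
  expect_equal(ov2$errors[ov2$factor == "RM"], 0.3)
  expect_equal(ov2$violations[ov2$factor == "RM"], 0.125)
  stub[c("SBE", "DE", "PE"), "OC"] <- 0
  expect_equal(overall_sensitivity(stub)$errors[2], 0)
})

test_that("matrix export mirrors the on-screen layout in wide and long form", {
  bn <- hfacs_bn(synthetic_cases(), alpha = 1)
  sm <- sensitivity_matrix(bn)
  wide <- withr::local_tempfile(fileext = ".csv")
  write_sensitivity_csv(sm, wide)
  tab <- utils::read.csv(wide, check.names = FALSE,
                         colClasses = "character")
  expect_equal(nrow(tab), 12)
  expect_equal(tab$factor, rownames(sm))
  expect_equal(tab[tab$factor == "IS", "PF"], "")  # structurally empty
  expect_match(tab[tab$factor == "SBE", "CO"], "^[0-9]+\\.[0-9]{2}$")

  long <- withr::local_tempfile(fileext = ".csv")
  write_sensitivity_csv(sm, long, long = TRUE)
  tl <- utils::read.csv(long)
  expect_equal(nrow(tl), sum(attr(sm, "filled")))
  expect_true(all(tl$status %in% c("ok", "undefined")))
})
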