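test_that("a valid toy CSV reads into a validated case database", {
  rec <- toy_records(list(list(ERR = "skill"),
                          list(VIO = "routine", CO = "yes"),
                          list(RM = "yes")))
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(rec, path, row.names = FALSE)
  db <- read_case_db(path)
  expect_s3_class(db, "hfacs_cases")
  expect_equal(nrow(db$records), 3)
  expect_equal(db$records$ERR[1], "skill")
})

test_that("state strings are normalized case-insensitively and trimmed", {
  rec <- toy_records(list(list(ERR = "skill")))
  rec$ERR <- " Skill "
  rec$CO <- "YES"
  db <- as_case_db(rec)
  expect_equal(db$records$ERR, "skill")
  expect_equal(db$records$CO, "yes")
})

test_that("structural problems are hard errors naming the culprit", {
  rec <- toy_records(list(list(ERR = "skill"), list(CO = "yes")))
  expect_error(as_case_db(rec[, setdiff(names(rec), "PF")]), "PF")

  bad <- rec; bad$ERR[2] <- "slip"
  expect_error(as_case_db(bad), "slip.*ERR|ERR.*slip")

  dup <- rec; dup$incident_id <- c("I001", "I001")
  expect_error(as_case_db(dup), "duplicate")
})

test_that("missing cells follow the strict/drop policy", {
  rec <- toy_records(list(list(ERR = "skill"), list(CO = "yes")))
  rec$SV[2] <- ""
  expect_error(as_case_db(rec, missing = "strict"), "empty")
  expect_warning(db <- as_case_db(rec, missing = "drop"), "dropped")
  expect_equal(nrow(db$records), 1)
  expect_equal(db$records$incident_id, "I001")
})

test_that("write -> read round-trips the database", {
  db <- synthetic_cases()
  path <- withr::local_tempfile(fileext = ".csv")
  write_case_db(db, path)
  back <- read_case_db(path)
  expect_identical(back$records, db$records)
})

test_that("frequency summary matches hand counts", {
  # incident 1: ERR=skill only; incident 2: VIO=routine + CO
  db <- as_case_db(toy_records(list(list(ERR = "skill"),
                                    list(VIO = "routine", CO = "yes"))))
  fr <- summarize_frequencies(db)
  expect_equal(fr$total_occurrences, 3)
  expect_equal(as.vector(fr$per_incident[c("1", "2")]), c(1, 1))
  lev1 <- fr$levels$proportion[fr$levels$level == 1]
  expect_equal(lev1, 2 / 3)
  expect_equal(fr$factors$count[fr$factors$factor == "ERR:skill"], 1)

  # a fully loaded incident counts all 12 nodes as occurrences
  all_on <- as.list(setNames(rep("yes", 10),
                             c("RM","OC","OP","IS","PIO","FCP","SV","CO","PF","EF")))
  all_on$ERR <- "skill"; all_on$VIO <- "routine"
  db2 <- as_case_db(toy_records(list(all_on)))
  fr2 <- summarize_frequencies(db2)
  expect_equal(fr2$total_occurrences, 12)
  expect_equal(names(fr2$per_incident), "12")
})

test_that("an all-absent database reports zero occurrences and NA proportions", {
  db <- as_case_db(toy_records(list(list(), list())))
  fr <- summarize_frequencies(db)
  expect_equal(fr$total_occurrences, 0)
  expect_true(all(is.na(fr$levels$proportion)))
  expect_error(summarize_frequencies(as_case_db(toy_records(list(list()))[0, ])),
               "empty")
})

test_that("frequency totals are invariant under record order and partition by level", {
  db <- synthetic_cases()
  fr <- summarize_frequencies(db)
  shuffled <- db
  shuffled$records <- db$records[rev(seq_len(nrow(db$records))), ]
  rownames(shuffled$records) <- NULL
  fr2 <- summarize_frequencies(shuffled)
  expect_equal(fr2$total_occurrences, fr$total_occurrences)
  expect_equal(sort(fr2$factors$count), sort(fr$factors$count))
  expect_equal(sum(fr$levels$count), fr$total_occurrences)
  expect_equal(sum(fr$levels$proportion), 1, tolerance = 1e-9)
  expect_equal(sum(fr$per_incident), fr$n_incidents)
})

test_that("phase summaries group annotated and unannotated records", {
  db <- synthetic_cases()
  tab <- summarize_phases(db)
  expect_equal(sum(tab$count), 81)
  expect_equal(sum(tab$ratio), 1)

  plain <- db
  plain$records$phase <- NA_character_
  plain$records$error_type <- NA_character_
  tab2 <- summarize_phases(plain)
  expect_equal(nrow(tab2), 1)
  expect_equal(tab2$phase, "unspecified")
  expect_equal(tab2$count, 81)
})

test_that("the packaged phase/error-type reference table is intact", {
  tab <- phase_error_counts()
  expect_equal(nrow(tab), 16)
  expect_equal(sum(tab$count), 81)
  expect_equal(tab$count[tab$phase == "treatment planning" &
                           tab$error_type == "wrong data transfer or setting"], 17)
})
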