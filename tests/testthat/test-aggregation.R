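test_that("guarding score is the sum of present-codes across raters", {
  expect_identical(guarding_score(c(1, 1, 1, 0)), 3L)
  expect_identical(guarding_score(c(0, 0, 0, 0)), 0L)
  expect_identical(guarding_score(c(1, 1, 1, 1)), 4L)
  expect_error(guarding_score(numeric(0)), "no ratings")
  expect_error(guarding_score(c(1, 2)), "0 or 1")
  # incomplete panel: raw sum by default, rescaled under the opt-in flag
  expect_identical(guarding_score(c(1, 1, 0)), 2L)
  expect_identical(guarding_score(c(1, 1, 0), rescale_to = 4), 3L)
})

test_that("self-efficacy median retains half-integers", {
  expect_equal(self_efficacy_median(c(2, 2, 3, 3)), 2.5)
  expect_equal(self_efficacy_median(c(1, 1, 1, 1)), 1)
  expect_equal(self_efficacy_median(c(1, 2, 3)), 2)
  expect_equal(self_efficacy_median(c("low", "medium", "high", "high")), 2.5)
  expect_equal(self_efficacy_median(c(2, 2, 3, 3), rounding = "floor"), 2)
  expect_equal(self_efficacy_median(c(2, 2, 3, 3), rounding = "ceiling"), 3)
  expect_error(self_efficacy_median(character(0)), "no ratings")
  expect_error(self_efficacy_median(c(0, 2)), "codes")
})

test_that("aggregates are invariant to rater order", {
  set.seed(31)
  for (i in 1:25) {
    g <- sample(0:1, 4, replace = TRUE)
    s <- sample(1:3, 4, replace = TRUE)
    p <- sample(4)
    expect_identical(guarding_score(g), guarding_score(g[p]))
    expect_identical(self_efficacy_median(s), self_efficacy_median(s[p]))
  }
})

test_that("assemble_records applies the inclusion rule", {
  tt <- toy_tables()
  rec <- assemble_records(tt$instances, tt$ratings)
  # i3 has no self-report at all -> excluded; i2/i4 qualify on distress alone
  expect_setequal(rec$instance_id, c("i1", "i2", "i4"))
  expect_equal(rec$guarding[rec$instance_id == "i1"], 3L)
  expect_equal(rec$self_efficacy[rec$instance_id == "i1"], 2.5)
  expect_equal(rec$guarding[rec$instance_id == "i2"], 0L)
  # no duplicates, one record per qualifying instance
  expect_false(anyDuplicated(rec$instance_id) > 0)
})

test_that("assemble_records validates its inputs", {
  tt <- toy_tables()
  bad <- tt$ratings
  bad$instance_id[1] <- "ghost"
  expect_error(assemble_records(tt$instances, bad), "ghost")
  oor <- tt$instances
  oor$pain[1] <- 11
  expect_error(assemble_records(oor, tt$ratings), "out of range")
})

test_that("every cohort record satisfies the inclusion rule", {
  co <- small_cohort(seed = 64)
  rec <- assemble_records(co$instances, co$ratings)
  expect_lte(nrow(rec), nrow(co$instances))
  expect_true(all(!is.na(rec$pain) | !is.na(rec$anxiety) |
                    !is.na(rec$distress)))
  expect_true(all(rec$guarding >= 0 & rec$guarding <= 4))
  expect_true(all(rec$self_efficacy %in% c(1, 1.5, 2, 2.5, 3)))
})
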