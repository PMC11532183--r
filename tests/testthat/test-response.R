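test_that("per-pair classification follows the congruous-change rule", {
  # published study case 1: stage 4->3, ECA 8.6->6.3, EnC 1.56->1.38
  c1 <- classify_pair(list(stage_pre = "F4", stage_post = "F3",
                           eca_pre_pct = 8.6, eca_post_pct = 6.3,
                           enc_pre = 1.56, enc_post = 1.38))
  expect_identical(c1$histo, "stage_decrease")
  expect_identical(c1$ai, "responder")
  expect_true(c1$congruous_with_histo)
  # published validation case 1: stage 2->3, ECA up but EnC down
  c2 <- classify_pair(list(stage_pre = "F2", stage_post = "F3",
                           eca_pre_pct = 3.48, eca_post_pct = 5.06,
                           enc_pre = 0.99, enc_post = 0.74))
  expect_identical(c2$histo, "stage_increase")
  expect_identical(c2$ai, "not_conclusive")
  expect_false(c2$congruous_with_histo)
  # identical pre/post: zero deltas break congruity
  c3 <- classify_pair(list(stage_pre = "F3", stage_post = "F3",
                           eca_pre_pct = 5, eca_post_pct = 5,
                           enc_pre = 1, enc_post = 1))
  expect_identical(c3$histo, "no_change")
  expect_identical(c3$ai, "not_conclusive")
  expect_true(is.na(c3$congruous_with_histo))
  # F1 sub-stages are ordered: 1a -> 2 is an increase
  c4 <- classify_pair(list(stage_pre = "1a", stage_post = "2",
                           eca_pre_pct = 2.0, eca_post_pct = 2.7,
                           enc_pre = 0.86, enc_post = 0.95))
  expect_identical(c4$histo, "stage_increase")
  expect_identical(c4$ai, "non_responder")
})

test_that("swapping pre and post mirrors the calls", {
  set.seed(19)
  for (i in 1:20) {
    rec <- list(stage_pre = sample(stage_levels(), 1),
                stage_post = sample(stage_levels(), 1),
                eca_pre_pct = runif(1, 1, 12),
                eca_post_pct = runif(1, 1, 12),
                enc_pre = runif(1, 0.5, 2), enc_post = runif(1, 0.5, 2))
    swp <- rec[c(2, 1, 4, 3, 6, 5)]
    names(swp) <- names(rec)
    a <- classify_pair(rec); b <- classify_pair(swp)
    expect_identical(b$ai, switch(a$ai, responder = "non_responder",
                                  non_responder = "responder",
                                  not_conclusive = "not_conclusive"))
    expect_identical(b$histo,
                     switch(a$histo, stage_decrease = "stage_increase",
                            stage_increase = "stage_decrease",
                            no_change = "no_change"))
  }
})

test_that("every pair maps to exactly one AI category and shares sum to 100", {
  pairs <- load_paired_fixtures("both")
  calls <- classify_pairs(pairs)
  expect_identical(nrow(calls), 17L)
  expect_true(all(calls$ai %in% c("responder", "non_responder",
                                  "not_conclusive")))
  rep <- summarize_cohort(pairs)
  expect_equal(sum(rep$ai_counts), rep$n_pairs)
  expect_equal(sum(rep$histo_counts), rep$n_pairs)
  expect_lte(abs(sum(rep$ai_percent) - 100), 2)     # integer rounding slack
  expect_lte(abs(sum(rep$histo_percent) - 100), 2)
})

test_that("cohort summaries reproduce the published treatment percentages", {
  study <- summarize_cohort(load_paired_fixtures("study"))
  expect_identical(study$n_pairs, 9L)
  expect_equal(study$histo_change_percent, 56)
  expect_equal(study$ai_any_change_percent, 100)
  expect_equal(study$pct_ai_decrease_among_histo_unchanged, 75)
  expect_equal(study$pct_ai_increase_among_histo_unchanged, 25)
  expect_equal(study$pct_congruous_among_histo_changed, 80)

  valid <- summarize_cohort(load_paired_fixtures("validation"))
  expect_identical(valid$n_pairs, 8L)
  expect_equal(valid$histo_change_percent, 50)
  expect_equal(valid$ai_any_change_percent, 100)
  expect_equal(valid$pct_ai_decrease_among_histo_unchanged, 50)
  expect_equal(valid$pct_congruous_among_histo_changed, 50)

  pooled <- summarize_cohort(load_paired_fixtures("both"))
  expect_equal(unname(pooled$histo_percent["stage_decrease"]), 29)
  expect_equal(unname(pooled$histo_percent["no_change"]), 47)
  expect_equal(unname(pooled$histo_percent["stage_increase"]), 24)
  expect_equal(unname(pooled$ai_percent["responder"]), 53)
  expect_equal(unname(pooled$ai_percent["not_conclusive"]), 24)
  expect_equal(pooled$ai_congruous_change_percent, 76)
  expect_equal(pooled$histo_change_percent, 53)
})

test_that("single-pair cohorts hit the trivial shares", {
  one <- load_paired_fixtures("study")[1, ]
  rep <- summarize_cohort(one)
  expect_equal(unname(rep$ai_percent["responder"]), 100)
  expect_error(summarize_cohort(load_paired_fixtures("study")[0, ]),
               "at least one")
})

test_that("weight outcome applies the strict >10% loss rule", {
  expect_true(weight_outcome(-12))
  expect_false(weight_outcome(-10))   # exactly 10% is not 'more than'
  expect_true(is.na(weight_outcome(NA_real_)))
  study <- load_paired_fixtures("study")
  wo <- weight_outcome(study$weight_change_pct)
  expect_identical(study$patient_id[which(wo)], c(2L, 6L))
  valid <- load_paired_fixtures("validation")
  expect_false(any(weight_outcome(valid$weight_change_pct), na.rm = TRUE))
  # both flagged patients are AI responders; histopathology sees only one
  rep <- summarize_cohort(study)
  expect_equal(rep$weight$n_outcome_positive, 2L)
  expect_equal(rep$weight$ai_responder_share_percent, 100)
  expect_equal(rep$weight$histo_decrease_share_percent, 50)
})

test_that("response heatmap grid matches the per-case calls", {
  pairs <- load_paired_fixtures("both")
  hm <- render_response_heatmap(pairs)
  expect_identical(dim(hm$grid), c(17L, 3L))
  calls <- classify_pairs(pairs)
  histo_col <- c(stage_decrease = "green", no_change = "yellow",
                 stage_increase = "red")[calls$histo]
  expect_identical(unname(hm$grid[, "histo"]), unname(histo_col))
  expect_identical(unname(hm$grid[, "eca"]),
                   ifelse(calls$d_eca < 0, "green",
                          ifelse(calls$d_eca > 0, "red", "yellow")))
  # a pure responder row is all green
  hm1 <- render_response_heatmap(load_paired_fixtures("study")[1, ])
  expect_identical(unname(hm1$grid[1, ]), rep("green", 3))
  # PNG writing round-trips the cell colors
  f <- tempfile(fileext = ".png")
  render_response_heatmap(pairs, path = f)
  expect_true(file.exists(f))
  img <- png::readPNG(f)
  expect_identical(dim(img)[2], 3L * 24L + 4L * 2L)
})
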