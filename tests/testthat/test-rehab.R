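test_that("swallow timing applies the strict 3 s and 15 s clinical rules", {
  fs <- 100
  # single clean burst of 1.5 s starting at t = 0.5 s
  env <- numeric(5 * fs)
  env[(0.5 * fs):(2 * fs)] <- 1
  set.seed(1)
  x <- env * rnorm(length(env))
  tm <- swallow_timing(x, fs)
  expect_true(tm$assessable)
  expect_true(tm$safety_ok)
  expect_true(tm$effectiveness_ok)
  expect_lt(tm$onset_to_opening, 3)

  # burst train spanning 16 s: ineffective
  env2 <- numeric(17 * fs)
  env2[(1 * fs):(2 * fs)] <- 1
  env2[(15 * fs):(16 * fs)] <- 1
  x2 <- env2 * rnorm(length(env2))
  tm2 <- swallow_timing(x2, fs)
  expect_false(tm2$effectiveness_ok)

  # boundary behavior: both rules are strict inequalities on the measured
  # times, and a burst reaching the 15 s mark fails
  env3 <- numeric(16 * fs)
  env3[(14 * fs):(15 * fs)] <- 1
  tm3 <- swallow_timing(env3, fs)
  expect_gte(tm3$total_duration, 15)
  expect_identical(tm3$effectiveness_ok, tm3$total_duration < 15)
  expect_false(tm3$effectiveness_ok)
  expect_false(tm3$safety_ok)  # first peak beyond 3 s too

  # flat signal: not assessable, no exception
  tm4 <- swallow_timing(rnorm(5 * fs, 0, 1), fs)
  expect_false(tm4$assessable)

  # a synthetic swallow event passes both rules
  ev <- synthesize_event("swallow", 333, 1.5, seed = 2)
  tm5 <- swallow_timing(ev$az, 333)
  expect_true(tm5$safety_ok && tm5$effectiveness_ok)
})

test_that("behavior flags combine confidence and timing rules", {
  preds <- tibble::tibble(
    behavior = rep(c("swallowing", "drinking", "talking"), each = 4),
    confidence = c(rep(0.9, 4), rep(0.9, 4), rep(0.9, 4)))
  fl <- behavior_flags(preds)
  expect_true(all(fl$status == "normal"))

  low <- preds
  low$confidence[low$behavior == "talking"] <- 0.2
  fl2 <- behavior_flags(low)
  expect_equal(fl2$status[fl2$behavior == "talking"], "abnormal")

  timings <- tibble::tibble(behavior = "swallowing", safety_ok = TRUE,
                            effectiveness_ok = FALSE)
  fl3 <- behavior_flags(preds, timings)
  expect_equal(fl3$status[fl3$behavior == "swallowing"], "abnormal")

  missing <- preds[preds$behavior != "drinking", ]
  fl4 <- behavior_flags(missing)
  expect_equal(fl4$status[fl4$behavior == "drinking"], "not_assessable")
  expect_error(rehab_level(fl4), "assessable")
})

test_that("the eight-level mapping is a monotone bijection", {
  combos <- expand.grid(s = c("normal", "abnormal"),
                        d = c("normal", "abnormal"),
                        t = c("normal", "abnormal"),
                        stringsAsFactors = FALSE)
  levels_seen <- integer(8)
  for (i in seq_len(8)) {
    fl <- tibble::tibble(behavior = c("swallowing", "drinking", "talking"),
                         status = c(combos$s[i], combos$d[i], combos$t[i]))
    lv <- rehab_level(fl)
    levels_seen[i] <- lv$level
    n_abn <- sum(fl$status == "abnormal")
    # monotone in the abnormal count: count k occupies a fixed level band
    expect_true(lv$level > n_abn * 0 )
    if (n_abn == 0) expect_equal(lv$level, 1)
    if (n_abn == 1) expect_true(lv$level %in% 2:4)
    if (n_abn == 2) expect_true(lv$level %in% 5:7)
    if (n_abn == 3) expect_equal(lv$level, 8)
  }
  expect_setequal(levels_seen, 1:8)  # bijection over the 2^3 combinations

  all_ok <- tibble::tibble(behavior = c("swallowing", "drinking", "talking"),
                           status = rep("normal", 3))
  expect_equal(rehab_level(all_ok)$roman, "I")
  all_bad <- all_ok
  all_bad$status <- "abnormal"
  expect_equal(rehab_level(all_bad)$roman, "VIII")
  # severity priority: abnormal swallowing outranks drinking outranks talking
  mk <- function(s, d, t) {
    tibble::tibble(behavior = c("swallowing", "drinking", "talking"),
                   status = c(s, d, t))
  }
  expect_lt(rehab_level(mk("normal", "normal", "abnormal"))$level,
            rehab_level(mk("normal", "abnormal", "normal"))$level)
  expect_lt(rehab_level(mk("normal", "abnormal", "normal"))$level,
            rehab_level(mk("abnormal", "normal", "normal"))$level)
})
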