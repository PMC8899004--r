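test_that("partition coefficient equals the delta-R1 ratio", {
  expect_equal(partition_coefficient(1000, 500, 1600, 300),
               (1 / 500 - 1 / 1000) / (1 / 300 - 1 / 1600),
               tolerance = 1e-12)
  expect_equal(round(partition_coefficient(1000, 500, 1600, 300), 4), 0.3692)
  # identical delta R1 in myocardium and blood
  expect_equal(partition_coefficient(1000, 500, 1000, 500), 1)
  expect_error(partition_coefficient(1000, 500, 1600, 1600),
               "post-contrast")
  expect_error(partition_coefficient(1000, -5, 1600, 300), "positive")
})

test_that("ECV is 100(1-hct)*lambda", {
  expect_equal(round(ecv_percent(1000, 500, 1600, 300, 0.42), 1), 21.4)
  expect_equal(ecv_percent(1000, 500, 1000, 500, 0.40), 60)
  expect_equal(ecv_percent(1000, 500, 1600, 300, 0),
               100 * partition_coefficient(1000, 500, 1600, 300))
  # closed form holds for random valid inputs
  set.seed(2)
  for (i in 1:50) {
    pre_m <- runif(1, 900, 1100); post_m <- runif(1, 350, 650)
    pre_b <- runif(1, 1500, 1700); post_b <- runif(1, 250, 400)
    hct <- runif(1, 0.3, 0.5)
    expect_equal(
      ecv_percent(pre_m, post_m, pre_b, post_b, hct),
      100 * (1 - hct) * partition_coefficient(pre_m, post_m, pre_b, post_b),
      tolerance = 1e-12
    )
  }
})

test_that("MI/HF exclusion conserves counts and validates flags", {
  d <- data.frame(id = letters[1:6],
                  mi_history = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
                  hf_history = c(FALSE, TRUE, FALSE, FALSE, FALSE, TRUE))
  sp <- apply_exclusions(d)
  expect_equal(nrow(sp$included), 3L)
  expect_equal(nrow(sp$included) + nrow(sp$excluded), nrow(d))
  expect_setequal(sp$excluded$id, c("a", "b", "f"))

  none <- data.frame(id = 1:3, mi_history = FALSE, hf_history = FALSE)
  expect_equal(nrow(apply_exclusions(none)$included), 3L)
  all_f <- data.frame(id = 1:3, mi_history = TRUE, hf_history = FALSE)
  expect_equal(nrow(apply_exclusions(all_f)$included), 0L)

  bad <- data.frame(id = "x", mi_history = NA, hf_history = FALSE)
  expect_error(apply_exclusions(bad), "x")
})

test_that("quartile threshold uses linear interpolation and guards input", {
  expect_equal(quartile_threshold(1:8, 0.75), 6.25)
  expect_equal(quartile_threshold(rep(3.3, 10), 0.75), 3.3)
  expect_error(quartile_threshold(1:3, 0.75), "at least 4")
  # ~25% exceed the 0.75 threshold in a large continuous sample
  set.seed(6)
  x <- rnorm(10000)
  thr <- quartile_threshold(x, 0.75)
  expect_equal(mean(x > thr), 0.25, tolerance = 0.01)
})

test_that("case status follows the strict top-quartile union rule", {
  d <- data.frame(
    id = c("case_both", "ctrl", "at_thr", "ecv_only", "t1_only"),
    ecv = c(29.4, 25.6, 28.8, 30.1, 25.0),
    native_t1 = c(1014, 957, 1006, 1000, 1012),
    stringsAsFactors = FALSE
  )
  asg <- assign_case_status(d, thresholds = list(ecv = 28.8,
                                                 native_t1 = 1006))
  st <- asg$status
  expect_equal(st$status,
               c("case", "control", "control", "case", "case"))
  expect_equal(st$category[st$id == "case_both"], "both")
  expect_equal(st$category[st$id == "at_thr"], "none")  # strict inequality
  expect_equal(st$category[st$id == "ecv_only"], "ecv_only")
  expect_equal(st$category[st$id == "t1_only"], "t1_only")
  d2 <- asg$decomposition
  expect_equal(unname(d2["ecv_only"] + d2["t1_only"] + d2["both"]),
               unname(d2["cases"]))
  expect_equal(unname(d2["cases"] + d2["controls"]), nrow(d))
})

test_that("ECV is derived from T1 values when not supplied", {
  d <- data.frame(
    id = c("a", "b"),
    ecv = c(NA, 30),
    native_t1 = c(1000, 1000),
    t1_myo_pre = c(1000, NA), t1_myo_post = c(500, NA),
    t1_blood_pre = c(1600, NA), t1_blood_post = c(300, NA),
    hct = c(0.42, NA), stringsAsFactors = FALSE
  )
  asg <- assign_case_status(d, thresholds = list(ecv = 25, native_t1 = 2000))
  expect_equal(asg$status$ecv[1],
               ecv_percent(1000, 500, 1600, 300, 0.42))
  expect_equal(asg$status$ecv[2], 30)
  expect_error(
    assign_case_status(data.frame(id = "x", ecv = NA, native_t1 = 1000),
                       thresholds = list(ecv = 25, native_t1 = 2000)),
    "x")
})

test_that("decomposition conservation holds on random cohorts", {
  set.seed(13)
  for (i in 1:5) {
    n <- sample(50:200, 1)
    d <- data.frame(id = seq_len(n), ecv = rnorm(n, 27, 2),
                    native_t1 = rnorm(n, 980, 35))
    asg <- assign_case_status(d)
    dc <- asg$decomposition
    expect_equal(unname(dc["ecv_only"] + dc["t1_only"] + dc["both"]),
                 unname(dc["cases"]))
    expect_equal(unname(dc["cases"] + dc["controls"]), n)
    # roughly a quarter to a half are cases under the union rule
    expect_gt(dc[["cases"]] / n, 0.2)
    expect_lt(dc[["cases"]] / n, 0.55)
  }
})

test_that("perfectly correlated ECV and T1 leave no single-marker cases", {
  set.seed(21)
  z <- rnorm(400)
  d <- data.frame(id = seq_along(z), ecv = 26 + 2 * z,
                  native_t1 = 980 + 30 * z)
  asg <- assign_case_status(d)
  expect_equal(unname(asg$decomposition["ecv_only"]), 0L)
  expect_equal(unname(asg$decomposition["t1_only"]), 0L)
})
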