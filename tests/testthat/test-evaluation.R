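test_that("background sampling is seeded, bounded and respects exclusions", {
  stack <- make_test_stack(5, 5, vars = "x", seed = 2)
  expect_error(sample_background(stack, 26, seed = 1), "only 25")

  b1 <- sample_background(stack, 10, seed = 3)
  b2 <- sample_background(stack, 10, seed = 3)
  expect_identical(b1, b2)

  # exhaustive check on the 5x5 grid: excluded cells never drawn
  excl <- data.frame(lon = c(0.5, 2.5), lat = c(4.5, 2.5))  # cells (1,1),(3,3)
  for (s in 1:25) {
    b <- sample_background(stack, 23, seed = s, exclude = excl)
    expect_false(any(b$row == 1 & b$col == 1))
    expect_false(any(b$row == 3 & b$col == 3))
  }
})

test_that("AUC matches hand-computed and exhaustive pairwise values", {
  expect_equal(compute_auc(c(0.9, 0.7), c(0.8, 0.1)), 0.75)
  expect_equal(compute_auc(c(0.9, 0.8), c(0.2, 0.1)), 1.0)
  expect_equal(compute_auc(c(0.5, 0.5), c(0.5, 0.5)), 0.5)  # all ties

  set.seed(14)
  for (rep in 1:20) {
    pres <- round(runif(sample(2:50, 1)), 2)   # rounding forces ties
    bg <- round(runif(sample(2:50, 1)), 2)
    expect_equal(compute_auc(pres, bg), auc_pairwise_oracle(pres, bg))
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(15)
  pres <- rnorm(40, 1); bg <- rnorm(60)
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = c(rep(1, 40), rep(0, 60)), predictor = c(pres, bg),
    direction = "<", quiet = TRUE)))
  expect_equal(compute_auc(pres, bg), ref, tolerance = 1e-12)
})

test_that("class-free scores give AUC near one half", {
  set.seed(16)
  expect_equal(compute_auc(runif(1e4), runif(1e4)), 0.5, tolerance = 0.02)
})

test_that("accuracy counts the confusion matrix at a threshold", {
  expect_equal(compute_acc(c(0.9, 0.4), c(0.2, 0.6), 0.5), 0.5)
  expect_equal(compute_acc(c(0.9, 0.8), c(0.2, 0.1), 0.5), 1.0)
  # threshold 0: everything predicted present
  expect_equal(compute_acc(c(0.9, 0.4, 0.3), c(0.2, 0.6), 0),
               3 / 5)
})

test_that("partial-ROC ratio is ~1 under the null and >1 with signal", {
  set.seed(17)
  null_ratio <- partial_roc_ratio(runif(1000), runif(1000),
                                  n_boot = 200, seed = 18)
  expect_equal(null_ratio, 1.0, tolerance = 0.1)

  strong <- partial_roc_ratio(runif(100, 0.8, 1), runif(500, 0, 0.5),
                              n_boot = 50, seed = 19)
  expect_gt(strong, 1.5)

  expect_error(partial_roc_ratio(0.5, runif(10)), "at least 2")
})

test_that("tiny partial-ROC case equals a numeric-integration oracle", {
  pres <- c(0.9, 0.6, 0.4)
  bg <- c(0.8, 0.5, 0.3, 0.2, 0.1)
  got <- elnm:::partial_roc_ratio_once(pres, bg, omission_e = 0.10)

  # oracle: dense numeric integration of the interpolated ROC polyline
  th <- sort(unique(c(pres, bg, -Inf)), decreasing = TRUE)
  tpr <- c(0, sapply(th, function(t) mean(pres >= t)))
  fpr <- c(0, sapply(th, function(t) mean(bg >= t)))
  curve_fun <- approxfun(fpr, tpr, ties = max)
  sens0 <- 0.9
  x0 <- min(fpr[tpr >= sens0])
  i_above <- which(tpr >= sens0)
  x_at <- approx(tpr[c(min(i_above) - 1, min(i_above))],
                 fpr[c(min(i_above) - 1, min(i_above))], xout = sens0)$y
  x0 <- min(x0, x_at, na.rm = TRUE)
  xs <- seq(x0, 1, length.out = 20001)
  model_area <- sum(diff(xs) * (curve_fun(xs)[-1] + curve_fun(xs)[-20001]) / 2)
  oracle <- model_area / ((1 - x0^2) / 2)
  expect_equal(got, oracle, tolerance = 1e-3)
})

test_that("consensus selects, weights and averages as specified", {
  m_hi <- as_suit_map(matrix(1, 3, 3))
  m_lo <- as_suit_map(matrix(0, 3, 3))
  ev <- function(id, auc) structure(
    list(model_id = id, acc = 0.5, auc = auc, proc_ratio = 1,
         n_presence = 10, n_background = 100, seed = 1L),
    class = "evaluation_result")

  # score-proportional weights 0.75 / 0.25 -> cellwise 0.75
  cons <- weighted_elitist_consensus(list(m_hi, m_lo),
                                     list(ev("a", 0.75), ev("b", 0.25)),
                                     top_k = 2)
  expect_true(all(cons$values == 0.75))
  expect_equal(vapply(cons$provenance, `[[`, numeric(1), "weight"),
               c(0.75, 0.25))

  # top_k = 1 returns the best model exactly
  best <- weighted_elitist_consensus(list(m_hi, m_lo),
                                     list(ev("a", 0.9), ev("b", 0.2)),
                                     top_k = 1)
  expect_identical(best$values, m_hi$values)

  # identical inputs: consensus equals them under any weighting
  same <- weighted_elitist_consensus(list(m_hi, m_hi),
                                     list(ev("a", 0.9), ev("b", 0.3)),
                                     top_k = 2, weighting = "equal")
  expect_equal(same$values, m_hi$values)

  expect_warning(weighted_elitist_consensus(list(m_hi), list(ev("a", 0.9)),
                                            top_k = 5), "clamped")
})

test_that("consensus is a convex combination cellwise", {
  set.seed(20)
  maps <- lapply(1:5, function(i) as_suit_map(matrix(runif(36), 6, 6)))
  evs <- lapply(1:5, function(i) structure(
    list(model_id = paste0("m", i), acc = 0.5, auc = runif(1), proc_ratio = 1,
         n_presence = 5, n_background = 50, seed = 1L),
    class = "evaluation_result"))
  cons <- weighted_elitist_consensus(maps, evs, top_k = 3)
  sel_ids <- vapply(cons$provenance, `[[`, character(1), "model_id")
  sel <- maps[match(sel_ids, paste0("m", 1:5))]
  lo <- Reduce(pmin, lapply(sel, `[[`, "values"))
  hi <- Reduce(pmax, lapply(sel, `[[`, "values"))
  expect_true(all(cons$values >= lo - 1e-12 & cons$values <= hi + 1e-12))
})

test_that("fixed-sensitivity threshold picks the right order statistic", {
  vals <- c(0.2, 0.3, 0.4, 0.5, 0.6, 0.65, 0.7, 0.8, 0.9, 1.0)
  map <- as_suit_map(matrix(seq(0, 1, length.out = 25), 5, 5))

  out <- fixed_sensitivity_threshold(map, vals, s = 0.10)
  expect_equal(out$omission_threshold, 0.3)
  expect_equal(sum(vals < out$omission_threshold), 1)   # one occurrence omitted
  expect_true(all(out$values[map$values < 0.3] == 0))
  expect_identical(out$values[map$values >= 0.3], map$values[map$values >= 0.3])

  # s -> 0 keeps every occurrence
  out0 <- fixed_sensitivity_threshold(map, vals, s = 0)
  expect_equal(out0$omission_threshold, 0.2)

  # all-equal occurrence suitabilities: nothing omitted
  oute <- fixed_sensitivity_threshold(map, rep(0.4, 8), s = 0.10)
  expect_equal(oute$omission_threshold, 0.4)
})

test_that("thresholding omits at most the nominal fraction of occurrences", {
  set.seed(23)
  for (rep in 1:100) {
    n <- sample(5:80, 1)
    vals <- runif(n)
    map <- as_suit_map(matrix(runif(100), 10, 10))
    for (s in c(0.05, 0.10, 0.25)) {
      out <- fixed_sensitivity_threshold(map, vals, s = s)
      expect_lte(mean(vals < out$omission_threshold), s)
    }
  }
})
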