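test_that("R^2 and RMSE follow their definitions", {
  y <- c(0, 1, 2)
  expect_equal(fit_metrics(y, y), c(r2 = 1, rmse = 0))
  expect_equal(fit_metrics(y, rep(mean(y), 3))[["r2"]], 0)
  m <- fit_metrics(c(0, 1, 2), c(0, 1, 1))
  expect_equal(m[["r2"]], 0.5)
  expect_equal(m[["rmse"]], sqrt(1 / 3), tolerance = 1e-10)
  expect_error(fit_metrics(rep(1, 5), rnorm(5)), "variance")
  set.seed(2)
  a <- rnorm(50); b <- a + rnorm(50, 0, 0.3)
  expect_equal(unname(fit_metrics(a, b)), unname(metrics_oracle(a, b)),
               tolerance = 1e-12)
})

test_that("condition labels encode the study design", {
  cds <- study_conditions()
  expect_length(cds, 6)
  expect_setequal(names(cds), c("EGEC-M", "EGEC-N", "EGMC-M", "EGMC-N",
                                "MGEC-M", "MGEC-N"))
  ctrl <- condition_label("measured", "measured", "M")
  expect_true(ctrl$control)
  expect_false(cds[["EGEC-M"]]$control)
})

test_that("the fully measured control condition is exact for model M", {
  sub <- fix_subject(11)
  tr <- fix_trial(11, 1)
  res <- run_condition(sub, tr, condition_label("measured", "measured", "M"))
  expect_equal(res$r2, rep(1, 3))
  expect_equal(res$rmse, rep(0, 3))
})

test_that("estimates equal to the measured channels reproduce the control", {
  sub <- fix_subject(11)
  tr <- fix_trial(11, 1)
  est <- tibble::tibble(
    sample = seq_len(tr$n),
    est_grf_ap = 100 * tr$data$grf_ap / tr$bw,
    est_grf_v = 100 * tr$data$grf_v / tr$bw,
    est_cop_ap = tr$data$cop_ap
  )
  res <- run_condition(sub, tr, condition_label("estimated", "estimated", "M"),
                       estimates = est)
  expect_equal(res$r2, rep(1, 3), tolerance = 1e-9)
  expect_equal(res$rmse, rep(0, 3), tolerance = 1e-7)
})

test_that("condition wiring: COP source changes results, GRF inputs untouched", {
  sub <- fix_subject(11)
  tr <- fix_trial(11, 1)
  est <- tibble::tibble(
    sample = seq_len(tr$n),
    est_grf_ap = 100 * tr$data$grf_ap / tr$bw,
    est_grf_v = 100 * tr$data$grf_v / tr$bw,
    est_cop_ap = tr$data$cop_ap + 10 # 1 cm COP bias
  )
  mgec <- run_condition(sub, tr, condition_label("measured", "estimated", "M"),
                        estimates = est)
  expect_gt(mgec$rmse[mgec$joint == "ankle"], 0)
  # estimated-GRF-only condition with perfect GRF estimates stays exact
  egmc <- run_condition(sub, tr, condition_label("estimated", "measured", "M"),
                        estimates = est)
  expect_equal(egmc$rmse, rep(0, 3), tolerance = 1e-7)
  expect_error(run_condition(sub, tr, condition_label("estimated", "estimated", "M")),
               "needs ground-reaction estimates")
  expect_error(run_condition(sub, tr, condition_label("estimated", "estimated", "M"),
                             estimates = est[, 1:3]),
               "cop_ap")
})

test_that("Friedman test matches the hand-worked rank computation", {
  m <- matrix(rep(1:3, each = 3), 3) # every block ranks the treatments 1,2,3
  ft <- friedman_test(m)
  expect_equal(ft$chi2, 6)
  expect_equal(ft$df, 2)
  # complete ties
  ft0 <- friedman_test(matrix(1, 4, 3))
  expect_equal(ft0$chi2, 0)
  expect_equal(ft0$p_value, 1)
  # label symmetry
  set.seed(3)
  d <- matrix(rnorm(15), 5, 3)
  expect_equal(friedman_test(d)$chi2, friedman_test(d[, c(3, 1, 2)])$chi2)
  expect_error(friedman_test(matrix(1:4, 4, 1)), "2 treatments")
  # agrees with the base implementation on tie-free data
  expect_equal(friedman_test(d)$chi2,
               unname(stats::friedman.test(d)$statistic))
})

test_that("Dunn-Bonferroni obeys its adjustment bounds", {
  set.seed(4)
  d2 <- matrix(rnorm(12), 6, 2)
  out2 <- dunn_bonferroni(d2)
  expect_equal(nrow(out2), 1)
  expect_equal(out2$p_adjusted, out2$p_value) # single comparison
  d4 <- matrix(rnorm(24), 6, 4)
  out4 <- dunn_bonferroni(d4)
  expect_equal(nrow(out4), 6)
  expect_true(all(out4$p_adjusted >= out4$p_value))
  expect_true(all(out4$p_adjusted <= 1))
  same <- dunn_bonferroni(matrix(rep(1:6, 3), 6, 3))
  expect_false(any(same$significant))
})

test_that("condition summaries have the 6 x 3 study layout", {
  set.seed(5)
  grid <- expand.grid(subject = paste0("S", 1:2), trial = 1:2,
                      joint = c("hip", "knee", "ankle"),
                      condition = names(study_conditions()),
                      stringsAsFactors = FALSE)
  res <- tibble::as_tibble(grid)
  res$model <- sub(".*-", "", res$condition)
  res$r2 <- runif(nrow(res), 0.5, 1)
  res$rmse <- runif(nrow(res), 0.02, 0.2)
  s <- summarize_conditions(res)
  expect_equal(nrow(s$r2), 6)
  expect_equal(names(s$r2), c("condition", "hip", "knee", "ankle"))
  expect_equal(nrow(s$rmse), 6)
  expect_equal(nrow(s$long), 2 * 2 * 3 * 6)
  # single result per cell: mean = value, sd = 0
  one <- res[res$subject == "S1" & res$trial == 1, ]
  s1 <- summarize_conditions(one)
  expect_true(all(s1$cells$r2_sd == 0))
  expect_equal(sort(s1$cells$r2_mean), sort(one$r2))
})

test_that("within- and between-subject statistics run on cohort-shaped results", {
  set.seed(6)
  grid <- expand.grid(subject = paste0("S", 1:3), trial = 1:4,
                      joint = c("hip", "knee", "ankle"),
                      condition = names(study_conditions()),
                      stringsAsFactors = FALSE)
  res <- tibble::as_tibble(grid)
  res$rmse <- runif(nrow(res), 0.02, 0.2) +
    0.1 * (res$condition == "EGEC-M") # one clearly worse condition
  res$r2 <- 1 - res$rmse
  st <- condition_statistics(res, "rmse")
  expect_equal(nrow(st$within), 3 * 3)
  expect_equal(nrow(st$between), 3)
  expect_true(all(st$between$df == 5))
  expect_length(st$posthoc, 3)
  expect_equal(nrow(st$posthoc[[1]]), choose(6, 2))
})
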