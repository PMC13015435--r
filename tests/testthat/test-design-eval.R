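separable_fixture <- function() {
  # 10 binders with low PoC, 90 non-binders with high PoC at one dose
  poc <- tibble::tibble(
    compound_id = paste0("C", 1:100), kinase_id = "K1",
    percent_control = c(runif(10, 2, 15), runif(90, 60, 100)))
  truth <- tibble::tibble(
    compound_id = paste0("C", 1:100), kinase_id = "K1",
    kd_nM = c(runif(10, 1, 500), rep(NA, 90)))
  list(poc = poc, truth = truth)
}

test_that("threshold grid obeys its confusion-count invariants", {
  set.seed(8)
  fx <- separable_fixture()
  grid <- threshold_metrics(fx$poc, fx$truth, goal_kd = 1000)
  expect_true(all(grid$tp + grid$fn == 10))
  expect_true(all(grid$tn + grid$fp == 90))
  expect_true(all(diff(grid$sensitivity) >= 0))
  expect_true(all(diff(grid$specificity) <= 0))
  called <- grid$tp + grid$fp > 0
  expect_equal((grid$precision * (grid$tp + grid$fp))[called],
               grid$tp[called], tolerance = 1e-12)
  # separable data: some cutoff is perfect
  expect_true(any(grid$fp == 0 & grid$fn == 0))

  # cutoff 1 calls (almost) nothing; a cutoff above every PoC calls all
  expect_equal(grid$sensitivity[grid$cutoff == 1], 0)
  full <- threshold_metrics(fx$poc, fx$truth, goal_kd = 1000, cutoffs = 101)
  expect_equal(full$sensitivity, 1)
  expect_equal(full$specificity, 0)

  expect_error(threshold_metrics(fx$poc, fx$truth, goal_kd = -1), "positive")
  expect_error(threshold_metrics(rbind(fx$poc, fx$poc[1, ]), fx$truth, 1000),
               "one percent-control")
})

test_that("optimal cutoff maximises its objective and breaks ties low", {
  set.seed(9)
  fx <- separable_fixture()
  grid <- threshold_metrics(fx$poc, fx$truth, goal_kd = 1000)
  best <- optimal_cutoff(grid)
  expect_equal(best$objective_value, max(grid$sensitivity + grid$specificity - 1))
  # smallest perfect cutoff returned under ties
  perfect <- grid$cutoff[grid$fp == 0 & grid$fn == 0]
  expect_equal(best$cutoff, min(perfect))

  bf1 <- optimal_cutoff(grid, "f1")
  expect_equal(bf1$f1, max(grid$f1, na.rm = TRUE))
  bfp <- optimal_cutoff(grid, "min_fp_at_fn_ceiling", fn_ceiling = 0)
  expect_equal(bfp$fn, 0)
  expect_equal(bfp$fp, min(grid$fp[grid$fn == 0]))

  # degenerate grid: all PoC identical -> constant objective, smallest cutoff
  same <- fx$poc
  same$percent_control <- 50
  g2 <- threshold_metrics(same, fx$truth, goal_kd = 1000, cutoffs = c(60, 70, 80))
  expect_equal(optimal_cutoff(g2)$cutoff, 60)
})

test_that("two-vs-four agreement recovers known perturbations", {
  base <- tibble::tibble(
    compound_id = paste0("C", 1:200), kinase_id = "K1",
    log10_kd_median = runif(200, 0, 4), censor = "none")
  base$kd_nM <- 10^base$log10_kd_median
  same <- compare_two_vs_four(base, base)
  expect_equal(same$r_squared, 1)
  expect_equal(same$mse, 0)
  expect_equal(same$censor_disagreements, 0)

  set.seed(12)
  noisy <- base
  noisy$log10_kd_median <- base$log10_kd_median + rnorm(200, 0, 0.1)
  pert <- compare_two_vs_four(noisy, base)
  expect_equal(pert$mse, 0.01, tolerance = 0.35)

  cens <- base
  cens$censor[1:5] <- "above_range"
  cc <- compare_two_vs_four(cens, base)
  expect_equal(cc$censor_disagreements, 5)
  expect_equal(cc$n, 195)

  expect_error(compare_two_vs_four(base[1:2, ], base[1:2, ]), "fewer than 3")
})

test_that("binder-classification F1 matches closed forms", {
  # planted confusion: TP = 8, FP = 2, FN = 2
  est <- tibble::tibble(
    compound_id = paste0("C", 1:14), kinase_id = "K1",
    kd_nM = c(rep(10, 8), rep(10, 2), rep(5000, 2), rep(5000, 2)),
    censor = "none")
  truth <- tibble::tibble(
    compound_id = paste0("C", 1:14), kinase_id = "K1",
    kd_nM = c(rep(10, 8), rep(NA, 2), rep(10, 2), rep(NA, 2)))
  expect_equal(f1_binder_classification(est, truth), 0.8)

  perfect <- est
  perfect$kd_nM <- truth$kd_nM
  perfect$kd_nM[is.na(perfect$kd_nM)] <- 1e6
  expect_equal(f1_binder_classification(perfect, truth), 1)

  allneg <- est
  allneg$kd_nM <- 1e6
  expect_equal(f1_binder_classification(allneg, truth), 0)

  nopos <- f1_binder_classification(allneg, truth[0, ])
  expect_true(is.na(nopos))
  expect_match(attr(nopos, "reason"), "no positives")
})
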