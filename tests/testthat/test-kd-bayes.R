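fast_mcmc <- function(...) {
  model_config(n_draws = 400, n_warmup = 300, n_chains = 2, seed = 33L, ...)
}

test_that("noiseless four-point curves recover Kd (least-squares oracle)", {
  doses <- c(12.5, 100, 1000, 10000)
  cur <- curve_tbl(hill_curve(100), doses = doses)
  # independent nonlinear least-squares oracle on the same curve
  skip_if_not_installed("minpack.lm")
  or <- minpack.lm::nlsLM(
    percent_control ~ 100 / (1 + (concentration_nM / 10^lk)^h),
    data = cur, start = list(lk = 3, h = 1.5))
  expect_equal(unname(coef(or)["lk"]), 2, tolerance = 1e-6)

  est <- fit_curves(cur, config = fast_mcmc())
  expect_lt(abs(est$log10_kd_median - 2), 0.05)
  expect_equal(est$censor, "none")

  estm <- fit_curves(cur, config = model_config(sampler = "map"))
  expect_lt(abs(estm$log10_kd_median - 2), 0.05)
  expect_gt(estm$hill_median, 0.9)
  expect_lt(estm$hill_median, 1.1)
})

test_that("flat curves are censored above the tested range", {
  cur <- curve_tbl(c(100, 100, 100, 100))
  for (cfg in list(fast_mcmc(), model_config(sampler = "map"))) {
    est <- fit_curves(cur, config = cfg)
    expect_equal(est$censor, "above_range")
  }
})

test_that("estimates are scale-equivariant in concentration", {
  cur <- curve_tbl(hill_curve(300, h = 1.2))
  cfg <- model_config(sampler = "map")
  e1 <- fit_curves(cur, config = cfg)
  cur10 <- cur
  cur10$concentration_nM <- cur10$concentration_nM * 10
  e2 <- fit_curves(cur10, config = cfg)
  expect_equal(e2$log10_kd_median - e1$log10_kd_median, 1, tolerance = 0.02)
})

test_that("posterior point estimate is monotone in uniform PoC shifts", {
  cfg <- model_config(sampler = "map")
  base <- hill_curve(500, h = 1)
  kd_at <- function(shift) {
    fit_curves(curve_tbl(pmax(base - shift, 0)), config = cfg)$log10_kd_median
  }
  kds <- vapply(c(0, 10, 20, 30), kd_at, numeric(1))
  expect_true(all(diff(kds) <= 1e-6))
})

test_that("two-dose fits agree with four-dose fits but are less certain", {
  cur <- curve_tbl(hill_curve(100))
  cfg <- fast_mcmc()
  e4 <- fit_curves(cur, config = cfg)
  e2 <- fit_two_dose(cur, c(100, 10000), config = cfg)
  expect_lt(abs(e2$log10_kd_median - 2), 0.2)
  # overlapping intervals on the same generative truth
  expect_lt(max(e2$log10_kd_lo, e4$log10_kd_lo),
            min(e2$log10_kd_hi, e4$log10_kd_hi))
  # two-dose no more certain than four-dose
  expect_gte(e2$log10_kd_hi - e2$log10_kd_lo,
             (e4$log10_kd_hi - e4$log10_kd_lo) * 0.9)

  # both tested doses far below Kd: no information, censored or unbounded
  weak <- curve_tbl(hill_curve(5000))
  ew <- fit_two_dose(weak, c(12.5, 100), config = cfg)
  expect_true(ew$censor == "above_range" || ew$log10_kd_hi > 4)

  expect_error(fit_two_dose(cur, c(50, 10000), config = cfg), "not present")
})

test_that("discordant curves are excluded and weak_low curves flagged", {
  tab <- dplyr::bind_rows(
    curve_tbl(c(20, 70, 80, 90), kinase = "K1"),
    curve_tbl(c(100, 98, 97, 30), kinase = "K2"),
    curve_tbl(hill_curve(100), kinase = "K3"))
  qc <- classify_curves(tab)
  est <- fit_curves(tab, qc_labels = qc, config = model_config(sampler = "map"))
  expect_false("K1" %in% est$kinase_id)
  expect_equal(est$quality_flag[est$kinase_id == "K2"], "weak_low")
  expect_equal(est$quality_flag[est$kinase_id == "K3"], "")
  expect_error(fit_curves(tab[0, ]), "empty")
})

test_that("affinity_matrix materialises the grid with reason-coded gaps", {
  est <- tibble::tibble(
    compound_id = rep(c("C1", "C2", "C3"), each = 2),
    kinase_id = rep(c("K1", "K2"), 3),
    kd_nM = c(10, 20, 30, 40, 50, 1e6),
    censor = c(rep("none", 5), "above_range"))
  am <- affinity_matrix(est)
  expect_equal(sum(!is.na(am$kd)), 5)
  expect_equal(am$censor["C3", "K2"], "above_range")
  expect_true(is.na(am$kd["C3", "K2"]))

  expect_error(affinity_matrix(est[c(1, 1, 2), ]), "duplicate")

  path <- withr::local_tempfile(fileext = ".csv")
  write_affinity_matrix(am, path)
  back <- read_affinity_matrix(path)
  expect_equal(back$kd, am$kd)
  expect_equal(back$censor, am$censor)
})
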