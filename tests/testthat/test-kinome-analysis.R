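make_cov_matrix <- function() {
  # 4 compounds x 3 kinases with known counts at each threshold
  planted_matrix(list(
    C1 = c(K1 = 10, K2 = 500, K3 = NA),
    C2 = c(K1 = 50, K2 = 2000, K3 = NA),
    C3 = c(K1 = 90, K2 = NA, K3 = 150),
    C4 = c(K1 = 5000, K2 = NA, K3 = NA)))
}

test_that("coverage counts are exact, monotone in tau, threshold-checked", {
  am <- make_cov_matrix()
  cov100 <- coverage(am, 100)
  expect_equal(cov100$per_kinase$n_compounds, c(3L, 0L, 0L))
  expect_equal(cov100$per_compound$n_kinases, c(1L, 1L, 1L, 0L))
  cov1u <- coverage(am, 1000)
  expect_true(all(cov1u$per_kinase$n_compounds >= cov100$per_kinase$n_compounds))
  covhi <- coverage(am, 1e9)
  expect_equal(sum(covhi$per_kinase$n_compounds), sum(!is.na(am$kd)))
  covlo <- coverage(am, 1)
  expect_true(all(covlo$per_kinase$n_compounds == 0))
  expect_error(coverage(am, -5), "positive")
})

test_that("promiscuous kinase rules handle thresholds and rank ties", {
  counts <- tibble::tibble(kinase_id = paste0("K", 1:5),
                           n_compounds = c(40L, 33L, 10L, 33L, 2L))
  cov <- structure(list(per_kinase = counts,
                        per_compound = tibble::tibble(), tau_nM = 100),
                   class = "coverage_table")
  expect_equal(promiscuous_kinases(cov, "count", threshold = 33)$kinase_id,
               c("K1", "K2", "K4"))
  # top-2 ranks with a tie at rank 2 keeps both tied kinases
  expect_equal(sort(promiscuous_kinases(cov, "top_ranks", k = 2)$kinase_id),
               c("K1", "K2", "K4"))
  empty <- structure(list(per_kinase = counts[0, ],
                          per_compound = tibble::tibble(), tau_nM = 100),
                     class = "coverage_table")
  expect_equal(nrow(promiscuous_kinases(empty)), 0)
})

test_that("group comparison is Welch's t-test with sane edge behaviour", {
  same <- c(1, 2, 3, 4, 1, 2, 3, 4)
  g <- rep(c("a", "b"), each = 4)
  r <- group_compare(same, g)
  expect_equal(r$p_value, 1, tolerance = 1e-9)
  expect_lt(abs(r$t), 1e-9)

  jitter <- c(0, 0.01, 0, 0.01, 10, 10.01, 10, 10.01)
  r2 <- group_compare(jitter, g)
  expect_lt(r2$p_value, 1e-6)
  # matches stats::t.test directly
  tt <- t.test(jitter[1:4], jitter[5:8])
  expect_equal(r2$p_value, tt$p.value)

  expect_error(group_compare(1:4, c("a", "a", "a", "a")), "two groups")
  expect_error(group_compare(1:3, c("a", "a", "b")), "two members")
})

test_that("a planted dark-kinase deficit is detected with high power", {
  set.seed(11)
  rejections <- vapply(1:60, function(i) {
    dark <- c(rnorm(50, 8, 5))
    illum <- c(rnorm(400, 15, 5))
    group_compare(c(dark, illum),
                  rep(c("dark", "illuminated"), c(50, 400)))$p_value < 0.001
  }, logical(1))
  expect_gte(mean(rejections), 0.95)
})

test_that("type-II enrichment uses the library composition as its null", {
  types <- tibble::tibble(
    compound_id = paste0("C", 1:100),
    inhibitor_type = rep(c("II", "I", "I", "I", "I", "I", "I", "I", "I", "I"), 10))
  # kinase bound by 40 all-type-II binders vs a 10% type-II library
  binders <- tibble::tibble(kinase_id = "Khot",
                            compound_id = paste0("C", seq(1, 100, 10))[1:10])
  binders <- dplyr::bind_rows(binders,
    tibble::tibble(kinase_id = "Knull", compound_id = paste0("C", 1:10)))
  res <- type2_enrichment(binders, types)
  hot <- res[res$kinase_id == "Khot", ]
  expect_equal(hot$n_type2, 10L)
  expect_lt(hot$p_value, 1e-8)
  nul <- res[res$kinase_id == "Knull", ]
  expect_gte(nul$p_value, 0.5)

  # kinase with no typed binders is skipped with a reason
  types2 <- types
  types2$inhibitor_type[1:10] <- "unknown"
  b2 <- tibble::tibble(kinase_id = "Kskip", compound_id = paste0("C", 1:10))
  r2 <- type2_enrichment(b2, types2)
  expect_equal(r2$skipped_reason, "no typed binders")
})

test_that("enrichment p-values are super-uniform under the null", {
  set.seed(21)
  types <- tibble::tibble(compound_id = paste0("C", 1:200),
                          inhibitor_type = sample(rep(c("II", "I"), c(40, 160))))
  pvals <- vapply(1:500, function(i) {
    b <- tibble::tibble(kinase_id = "K",
                        compound_id = sample(types$compound_id, 30))
    type2_enrichment(b, types)$p_value
  }, numeric(1))
  for (alpha in c(0.05, 0.1, 0.25)) {
    expect_lte(mean(pvals <= alpha), alpha + 3 * sqrt(alpha * (1 - alpha) / 500))
  }
})

test_that("assigned-target ranks use competition ranking and flag censoring", {
  am <- planted_matrix(list(
    C1 = c(K1 = 10, K2 = 100, K3 = 900),   # assigned K1 -> rank 1
    C2 = c(K1 = 10, K2 = 100, K3 = 900),   # assigned K3 -> rank 3
    C3 = c(K1 = 10, K2 = 100, K3 = 900),   # assigned K2 -> rank 2
    C4 = c(K1 = 5, K2 = 400, K3 = NA),     # assigned K3 censored -> flagged
    C5 = c(K1 = 50, K2 = 60, K3 = 70)))    # assigned target off-panel
  assigned <- tibble::tibble(
    compound_id = c("C1", "C2", "C3", "C4", "C5"),
    kinase_id = c("K1", "K3", "K2", "K3", "KX"))
  r <- assigned_target_rank(am, assigned)
  ranks <- setNames(r$ranks$best_rank, r$ranks$compound_id)
  expect_equal(ranks[c("C1", "C2", "C3")], c(C1 = 1L, C2 = 3L, C3 = 2L))
  expect_equal(ranks[["C4"]], 3L) # 2 finite kinases + 1
  expect_true(r$ranks$flagged[r$ranks$compound_id == "C4"])
  expect_equal(r$excluded$reason, "assigned target not in panel")
  expect_equal(mean(r$ranks$best_rank == 1), 0.25)

  curve <- top_n_curve(r, n_max = 3)
  expect_equal(curve$fraction, c(0.25, 0.5, 1)) # C4 sits at rank 3 flagged
  # permuting non-assigned kinase labels leaves ranks unchanged
  am2 <- am
  colnames(am2$kd) <- colnames(am2$censor) <- colnames(am2$hill) <-
    c("K1", "K3", "K2")[match(colnames(am$kd), c("K1", "K2", "K3"))]
  am2$kinases <- colnames(am2$kd)
  r1 <- assigned_target_rank(am, assigned[assigned$compound_id == "C1", ])
  r2 <- assigned_target_rank(am2, assigned[assigned$compound_id == "C1", ])
  expect_equal(r1$ranks$best_rank, r2$ranks$best_rank)
})

test_that("selectivity trend separates frontier and mean behaviour", {
  years <- rep(2000:2009, each = 5)
  flat <- rep(0.3, 50)
  tr <- selectivity_trend(flat, years)
  expect_equal(tr$slope, c(0, 0), tolerance = 1e-12)

  # rising frontier, flat centre
  set.seed(5)
  pim <- rep(0.3, 50)
  frontier <- seq_along(2000:2009) * 0.02 + 0.3
  pim[seq(1, 50, 5)] <- frontier
  tr2 <- selectivity_trend(pim, years)
  expect_equal(tr2$slope[tr2$fit == "yearly_max"], 0.02, tolerance = 1e-9)
  expect_lt(abs(tr2$slope[tr2$fit == "all"]), 0.01)

  # single compound per year: the two fits coincide
  tr3 <- selectivity_trend(c(0.1, 0.5, 0.2), 2001:2003)
  expect_equal(tr3$slope[1], tr3$slope[2])

  expect_error(selectivity_trend(c(0.1, 0.2), c(2001, 2001)), "3 distinct")
})
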