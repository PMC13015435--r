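test_that("TAS binning follows the affinity thresholds", {
  expect_equal(tas_from_kd(50000), 10L)
  expect_equal(tas_from_kd(5000), 3L)
  expect_equal(tas_from_kd(500), 2L)
  expect_equal(tas_from_kd(50), 1L)
  # half-open, lower-inclusive boundaries
  expect_equal(tas_from_kd(c(100, 1000, 10000)), c(2L, 3L, 10L))
  expect_equal(tas_from_kd(NA, censored_above = TRUE), 10L)
  expect_error(tas_from_kd(-5), "positive")

  # step function, non-increasing in affinity
  kd <- sort(10^runif(200, -1, 5.5))
  expect_true(all(diff(tas_from_kd(kd)) >= 0))
})

test_that("partition index normalises and matches closed forms", {
  expect_equal(unname(partition_index(c(K1 = 10))), 1)
  expect_equal(unname(partition_index(c(A = 5, B = 5, C = 5, D = 5))),
               rep(0.25, 4))
  expect_equal(unname(partition_index(c(A = 1, B = 9))), c(0.9, 0.1))

  none <- partition_index(c(A = NA_real_, B = NA_real_))
  expect_length(none, 0)
  expect_equal(attr(none, "reason"), "no finite affinities")

  set.seed(3)
  for (i in 1:25) {
    kds <- setNames(10^runif(8, 0, 4), paste0("K", 1:8))
    kds[sample(8, 2)] <- NA
    pi <- partition_index(kds)
    expect_equal(sum(pi), 1, tolerance = 1e-9)
    # invariant to rescaling all Kd of the compound
    expect_equal(pi, partition_index(kds * 7.3))
  }
})

test_that("engagement follows the occupancy closed form", {
  expect_equal(engagement(100, 1, 100), 50)
  expect_equal(engagement(100, 2.7, 100), 50)
  expect_equal(engagement(1000, 1, 100), 100 / 11)
  expect_lt(engagement(1e9, 1, 100), 1e-4)
})

test_that("CATDS_most-potent matches symmetry and worked closed forms", {
  expect_equal(as.numeric(catds_most_potent(c(K1 = 10))), 1)
  expect_equal(as.numeric(catds_most_potent(c(A = 50, B = 50))), 0.5)
  m <- c(A = 20, B = 20, C = 20, D = 20)
  expect_equal(as.numeric(catds_most_potent(m)), 0.25)

  # Kd {10, 100} nM, h = 1, evaluated at 10 nM
  v <- catds_most_potent(c(A = 10, B = 100))
  expect_equal(as.numeric(v), 50 / (50 + 100 / 11), tolerance = 1e-12)
  expect_equal(attr(v, "ref_kinase"), "A")

  # tie broken lexicographically
  tie <- catds_most_potent(c(Z = 10, B = 10))
  expect_equal(attr(tie, "ref_kinase"), "B")
  expect_true(attr(tie, "tie"))

  # second target approaching Kd_ref strictly decreases CATDS (h = 1)
  vals <- vapply(c(1e5, 1e4, 1e3, 1e2, 10),
                 function(k2) as.numeric(catds_most_potent(c(A = 10, B = k2))),
                 numeric(1))
  expect_true(all(diff(vals) < 0))

  # relabeling invariance
  kds <- c(K1 = 10, K2 = 250, K3 = 4000)
  rl <- setNames(kds, c("X9", "X2", "X5"))
  expect_equal(as.numeric(catds_most_potent(kds)),
               as.numeric(catds_most_potent(rl)))
})

test_that("selectivity records and the probe filter pick the planted set", {
  am <- planted_matrix(list(
    probeA = c(K1 = 10, K2 = 50000),        # potent, selective -> probe
    weakB = c(K1 = 150, K2 = 200000),       # best Kd above 100 nM -> fail
    promC = c(K1 = 20, K2 = 25, K3 = 30),   # potent but unselective -> fail
    tieD = c(K1 = 10, K2 = 10),             # tie: not a single target -> fail
    soloE = c(K3 = 99)))                    # single-target, potent -> probe
  sel <- selectivity_table(am)
  expect_equal(sort(chemical_probe_filter(sel)), c("probeA", "soloE"))
  expect_equal(sel$pi_max[sel$compound_id == "soloE"], 1)
  expect_equal(sel$catds_most_potent[sel$compound_id == "tieD"], 0.5)
  expect_equal(sel$ref_kinase[sel$compound_id == "probeA"], "K1")
})

test_that("tas_table covers estimated pairs and codes censored ones", {
  am <- planted_matrix(list(C1 = c(K1 = 50, K2 = NA)),
                       censor = list(c("none", "above_range")))
  tt <- tas_table(am)
  expect_equal(nrow(tt), 2)
  expect_equal(tt$tas[tt$kinase_id == "K1"], 1L)
  expect_equal(tt$tas[tt$kinase_id == "K2"], 10L)
})
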