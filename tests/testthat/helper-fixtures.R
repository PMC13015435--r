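# Shared fixtures: small configs and hand-planted affinity matrices.

pair_key_test <- function(a, b) paste(a, b, sep = "\r")

block_matrix <- function() {
  # two blocks of kinases with internally consistent, mutually reversed
  # affinity rank orders across 12 compounds
  set.seed(14)
  base <- sort(runif(12, 0, 4))
  kd <- sapply(1:6, function(j) {
    if (j <= 3) 10^(base + rnorm(12, 0, 0.05)) else
      10^(rev(base) + rnorm(12, 0, 0.05))
  })
  dimnames(kd) <- list(paste0("C", 1:12), paste0("K", 1:6))
  est <- tidyr::expand_grid(compound_id = rownames(kd),
                            kinase_id = colnames(kd))
  est$kd_nM <- kd[cbind(est$compound_id, est$kinase_id)]
  affinity_matrix(est)
}

tiny_config <- function(...) {
  generator_config(n_compounds = 6, n_kinases = 10, seed = 42L, ...)
}

# affinity matrix from a named list: compound -> named kd vector (nM)
planted_matrix <- function(kds, hills = NULL, censor = NULL) {
  rows <- lapply(names(kds), function(cp) {
    v <- kds[[cp]]
    tibble::tibble(compound_id = cp, kinase_id = names(v), kd_nM = unname(v))
  })
  est <- dplyr::bind_rows(rows)
  if (!is.null(hills)) {
    est$hill_median <- unlist(hills, use.names = FALSE)
  }
  if (!is.null(censor)) {
    est$censor <- unlist(censor, use.names = FALSE)
  } else {
    est$censor <- ifelse(is.na(est$kd_nM), "above_range", "none")
  }
  affinity_matrix(est)
}

# a 4-point curve tibble at the standard doses
curve_tbl <- function(poc, compound = "C1", kinase = "K1",
                      doses = c(12.5, 100, 1000, 10000)) {
  tibble::tibble(compound_id = compound, kinase_id = kinase,
                 concentration_nM = doses, percent_control = poc)
}

# noiseless percent-control values from the Hill form
hill_curve <- function(kd, h = 1, doses = c(12.5, 100, 1000, 10000)) {
  100 / (1 + (doses / kd)^h)
}
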