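#' Kinome coverage at an affinity threshold
#'
#' Counts, at threshold `tau_nM`, how many compounds bind each kinase and
#' how many kinases each compound binds (Kd <= tau; censored and missing
#' pairs count as non-binding).
#'
#' @param x An [affinity_matrix()].
#' @param tau_nM Positive affinity threshold in nM.
#' @return A list of class `coverage_table` with tibbles `per_kinase`
#'   (`kinase_id`, `n_compounds`) and `per_compound` (`compound_id`,
#'   `n_kinases`) and the threshold `tau_nM`.
#' @export
coverage <- function(x, tau_nM) {
  stopifnot(inherits(x, "affinity_matrix"))
  if (length(x$kd) == 0) stop("matrix nonempty required", call. = FALSE)
  if (!is.numeric(tau_nM) || tau_nM <= 0) {
    stop("tau_nM must be positive", call. = FALSE)
  }
  hit <- !is.na(x$kd) & x$kd <= tau_nM
  structure(list(
    per_kinase = tibble::tibble(kinase_id = x$kinases,
                                n_compounds = as.integer(colSums(hit))),
    per_compound = tibble::tibble(compound_id = x$compounds,
                                  n_kinases = as.integer(rowSums(hit))),
    tau_nM = tau_nM
  ), class = "coverage_table")
}

#' Identify promiscuous kinases
#'
#' Either all kinases bound by at least `threshold` compounds at the
#' coverage threshold (`rule = "count"`), or the kinases occupying the top
#' `k` competition ranks of the per-kinase count, with ties at the last
#' rank included (`rule = "top_ranks"`).
#'
#' @param cov A [coverage()] result (conventionally at tau = 100 nM).
#' @param rule `"count"` or `"top_ranks"`.
#' @param threshold Minimum compound count for `rule = "count"`.
#' @param k Number of ranks for `rule = "top_ranks"`.
#' @return Tibble `kinase_id`, `n_compounds` of the qualifying kinases,
#'   ordered by decreasing count.
#' @export
promiscuous_kinases <- function(cov, rule = c("count", "top_ranks"),
                                threshold = 33, k = 15) {
  stopifnot(inherits(cov, "coverage_table"))
  rule <- match.arg(rule)
  pk <- cov$per_kinase
  if (nrow(pk) == 0 || all(pk$n_compounds == 0)) {
    return(pk[0, ])
  }
  if (rule == "count") {
    out <- pk[pk$n_compounds >= threshold, ]
  } else {
    r <- rank(-pk$n_compounds, ties.method = "min")
    out <- pk[r <= k, ]
  }
  dplyr::arrange(out, dplyr::desc(.data$n_compounds), .data$kinase_id)
}

#' Welch's two-sample comparison of a per-entity statistic
#'
#' Runs Welch's unequal-variance t-test between exactly two groups of a
#' supplied statistic (e.g. inhibitor counts per kinase split by DFG-out
#' structure availability, or per dark-kinase status).
#'
#' @param values Numeric vector.
#' @param groups Vector with exactly two distinct values, aligned with
#'   `values`; each group needs at least two members.
#' @return One-row tibble: group names, group means, `t`, `df`, `p_value`.
#' @export
group_compare <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- as.character(groups[keep])
  lev <- sort(unique(groups))
  if (length(lev) != 2) stop("exactly two groups required", call. = FALSE)
  if (any(table(groups) < 2)) {
    stop("each group needs at least two members", call. = FALSE)
  }
  tt <- stats::t.test(values[groups == lev[1]], values[groups == lev[2]],
                      var.equal = FALSE)
  tibble::tibble(group1 = lev[1], group2 = lev[2],
                 mean1 = unname(tt$estimate[1]), mean2 = unname(tt$estimate[2]),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value)
}

#' Per-kinase enrichment of type-II inhibitors among binders
#'
#' For each kinase, tests whether the number of type-II inhibitors among
#' its (type-labelled) binders exceeds the expectation under draws from the
#' library's type composition, via a one-sided exact binomial tail.
#' Compounds typed `"unknown"` are excluded both from the library
#' composition and from the binder counts. Kinases with no typed binders
#' are skipped (reported with a reason). P-values are reported raw and
#' Benjamini-Hochberg adjusted across kinases.
#'
#' @param binders Tibble `kinase_id`, `compound_id` of binding pairs (e.g.
#'   Kd <= 100 nM).
#' @param compound_types Tibble `compound_id`, `inhibitor_type` describing
#'   the whole library (types `I`, `II`, `other`, `unknown`).
#' @return Tibble `kinase_id`, `n_typed`, `n_type2`, `expected`,
#'   `p_value`, `p_adj`, `skipped_reason`.
#' @export
type2_enrichment <- function(binders, compound_types) {
  assert_columns(binders, c("kinase_id", "compound_id"), what = "binders")
  assert_columns(compound_types, c("compound_id", "inhibitor_type"),
                 what = "compound_types")
  lib <- compound_types[compound_types$inhibitor_type != "unknown", ]
  if (nrow(lib) == 0) stop("no typed compounds in the library", call. = FALSE)
  p0 <- mean(lib$inhibitor_type == "II")
  b <- dplyr::left_join(binders, compound_types, by = "compound_id")
  if (anyNA(b$inhibitor_type)) {
    stop("every binder needs a type label (use 'unknown' if unavailable)",
         call. = FALSE)
  }
  b <- b[b$inhibitor_type != "unknown", ]
  res <- lapply(unique(binders$kinase_id), function(kn) {
    sub <- b[b$kinase_id == kn, ]
    n <- nrow(sub)
    if (n == 0) {
      return(tibble::tibble(kinase_id = kn, n_typed = 0L, n_type2 = 0L,
                            expected = NA_real_, p_value = NA_real_,
                            skipped_reason = "no typed binders"))
    }
    x <- sum(sub$inhibitor_type == "II")
    p <- stats::binom.test(x, n, p = p0, alternative = "greater")$p.value
    tibble::tibble(kinase_id = kn, n_typed = n, n_type2 = as.integer(x),
                   expected = n * p0, p_value = p,
                   skipped_reason = NA_character_)
  })
  out <- dplyr::bind_rows(res)
  out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  out[, c("kinase_id", "n_typed", "n_type2", "expected",
          "p_value", "p_adj", "skipped_reason")]
}

#' Rank of each compound's assigned target(s) in its affinity profile
#'
#' For every compound with at least one assayed assigned target and at
#' least one finite Kd, reports the best competition rank (1 = lowest Kd;
#' ties share the minimum rank) achieved by any assigned target. An
#' assigned target censored above the range while other kinases bind gets
#' rank `n_finite + 1` and is flagged. Compounds whose assigned targets
#' are all absent from the panel are excluded with a reason.
#'
#' @param x An [affinity_matrix()].
#' @param assigned Tibble `compound_id`, `kinase_id` of assigned targets
#'   (one row per assignment).
#' @return A list of class `target_rank_table` with tibbles `ranks`
#'   (`compound_id`, `best_rank`, `n_finite`, `flagged`) and `excluded`
#'   (`compound_id`, `reason`).
#' @export
assigned_target_rank <- function(x, assigned) {
  stopifnot(inherits(x, "affinity_matrix"))
  assert_columns(assigned, c("compound_id", "kinase_id"), what = "assigned")
  ranks <- list()
  excluded <- list()
  for (cp in intersect(unique(assigned$compound_id), x$compounds)) {
    tg <- assigned$kinase_id[assigned$compound_id == cp]
    tg_in <- intersect(tg, x$kinases)
    if (length(tg_in) == 0) {
      excluded[[cp]] <- tibble::tibble(compound_id = cp,
                                       reason = "assigned target not in panel")
      next
    }
    kds <- x$kd[cp, ]
    fin <- which(is.finite(kds))
    if (length(fin) == 0) {
      excluded[[cp]] <- tibble::tibble(compound_id = cp,
                                       reason = "no finite Kd")
      next
    }
    r <- rank(kds[fin], ties.method = "min")
    tg_fin <- intersect(tg_in, names(kds)[fin])
    if (length(tg_fin) > 0) {
      best <- min(r[tg_fin])
      flag <- FALSE
    } else {
      best <- length(fin) + 1L
      flag <- TRUE
    }
    ranks[[cp]] <- tibble::tibble(compound_id = cp, best_rank = as.integer(best),
                                  n_finite = length(fin), flagged = flag)
  }
  structure(list(ranks = dplyr::bind_rows(ranks),
                 excluded = dplyr::bind_rows(excluded)),
            class = "target_rank_table")
}

#' Cumulative fraction of compounds whose assigned target is in the top N
#'
#' @param rank_table An [assigned_target_rank()] result.
#' @param n_max Largest N to tabulate.
#' @param status Optional named vector (compound_id -> stratum label) to
#'   stratify the curve, e.g. by approval status.
#' @return Tibble `stratum`, `N`, `fraction`.
#' @export
top_n_curve <- function(rank_table, n_max = 10, status = NULL) {
  stopifnot(inherits(rank_table, "target_rank_table"))
  r <- rank_table$ranks
  if (nrow(r) == 0) stop("no ranked compounds", call. = FALSE)
  r$stratum <- if (is.null(status)) "all" else
    as.character(status[r$compound_id])
  dplyr::bind_rows(lapply(split(r, r$stratum), function(s) {
    tibble::tibble(stratum = s$stratum[1], N = seq_len(n_max),
                   fraction = vapply(seq_len(n_max),
                                     function(n) mean(s$best_rank <= n),
                                     numeric(1)))
  }))
}

#' Selectivity-over-time trend
#'
#' Fits two ordinary least-squares lines of maximum partition index on
#' first-publication year: one to all compounds, one to the per-year
#' maxima (the frontier of best-achieved selectivity). Reports both slopes
#' with 95% confidence intervals and whether zero lies inside each.
#'
#' @param pi_max Numeric vector of per-compound PI_max values.
#' @param first_pub_year Integer vector of years, aligned with `pi_max`.
#' @return Tibble `fit` (`"all"` / `"yearly_max"`), `slope`, `ci_lo`,
#'   `ci_hi`, `zero_in_ci`, `n`.
#' @export
selectivity_trend <- function(pi_max, first_pub_year) {
  stopifnot(length(pi_max) == length(first_pub_year))
  keep <- is.finite(pi_max) & is.finite(first_pub_year)
  pi_max <- pi_max[keep]
  year <- first_pub_year[keep]
  if (length(unique(year)) < 3) {
    stop("need at least 3 distinct years", call. = FALSE)
  }
  fit_line <- function(yv, xv, label) {
    mod <- stats::lm(yv ~ xv)
    # constant responses give a zero-residual fit; the CI is then [0, 0]
    ci <- tryCatch(suppressWarnings(stats::confint(mod)[2, ]),
                   error = function(e) c(NA, NA))
    tibble::tibble(fit = label, slope = unname(stats::coef(mod)[2]),
                   ci_lo = ci[1], ci_hi = ci[2],
                   zero_in_ci = !is.na(ci[1]) && ci[1] <= 0 && ci[2] >= 0,
                   n = length(yv))
  }
  ymax <- tapply(pi_max, year, max)
  yrs <- as.numeric(names(ymax))
  dplyr::bind_rows(fit_line(pi_max, year, "all"),
                   fit_line(as.numeric(ymax), yrs, "yearly_max"))
}
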