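#' Confusion metrics of single-dose screening over a cutoff grid
#'
#' Evaluates calling a pair a binder whenever its single-dose percent
#' control falls below a cutoff, against a reference affinity truth
#' (binder iff Kd < `goal_kd`; censored/missing Kd counts as non-binder),
#' across a grid of cutoffs.
#'
#' @param single_dose_poc Tibble `compound_id`, `kinase_id`,
#'   `percent_control` with one reading per pair at the screening dose.
#' @param truth_kd Tibble `compound_id`, `kinase_id`, `kd_nM` (`NA` for
#'   non-binders).
#' @param goal_kd Positive Kd threshold (nM) defining a true binder.
#' @param cutoffs Percent-control cutoffs to scan (default integers 1-99).
#' @param screening_dose_nM Optional metadata recorded on the result.
#' @return Tibble of class `threshold_grid`: `cutoff`, `tp`, `fp`, `tn`,
#'   `fn`, `sensitivity`, `specificity`, `precision`, `f1`.
#' @export
threshold_metrics <- function(single_dose_poc, truth_kd, goal_kd,
                              cutoffs = 1:99, screening_dose_nM = NA_real_) {
  assert_columns(single_dose_poc,
                 c("compound_id", "kinase_id", "percent_control"),
                 what = "single_dose_poc")
  assert_columns(truth_kd, c("compound_id", "kinase_id", "kd_nM"),
                 what = "truth_kd")
  if (!is.numeric(goal_kd) || goal_kd <= 0) {
    stop("goal_kd must be positive", call. = FALSE)
  }
  key <- pair_key(single_dose_poc$compound_id, single_dose_poc$kinase_id)
  if (anyDuplicated(key) > 0) {
    stop("one percent-control value per pair required", call. = FALSE)
  }
  tk <- truth_kd$kd_nM[match(key, pair_key(truth_kd$compound_id,
                                           truth_kd$kinase_id))]
  truth <- !is.na(tk) & tk < goal_kd
  poc <- single_dose_poc$percent_control
  rows <- lapply(cutoffs, function(ct) {
    pred <- poc < ct
    tp <- sum(pred & truth); fp <- sum(pred & !truth)
    fn <- sum(!pred & truth); tn <- sum(!pred & !truth)
    tibble::tibble(
      cutoff = ct, tp = tp, fp = fp, tn = tn, fn = fn,
      sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
      precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
      f1 = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "goal_kd") <- goal_kd
  attr(out, "screening_dose_nM") <- screening_dose_nM
  class(out) <- c("threshold_grid", class(out))
  out
}

#' Pick the optimal cutoff from a threshold grid
#'
#' Maximises the chosen objective over the grid: Youden's J
#' (sensitivity + specificity - 1, the default), F1, or
#' `"min_fp_at_fn_ceiling"` (fewest false positives among cutoffs whose
#' false negatives do not exceed `fn_ceiling` -- the objective implied by
#' screening scenarios that trade fewer false positives at equal false
#' negatives). Ties return the smallest cutoff.
#'
#' @param grid A [threshold_metrics()] result.
#' @param objective One of `"youden"`, `"f1"`, `"min_fp_at_fn_ceiling"`.
#' @param fn_ceiling Maximum tolerated false negatives (only for the
#'   FP-minimising objective; defaults to the grid's minimum achievable
#'   FN).
#' @return One-row tibble: the selected row of the grid plus `objective`
#'   and `objective_value`.
#' @export
optimal_cutoff <- function(grid, objective = c("youden", "f1",
                                               "min_fp_at_fn_ceiling"),
                           fn_ceiling = NULL) {
  stopifnot(inherits(grid, "threshold_grid"), nrow(grid) > 0)
  objective <- match.arg(objective)
  if (objective == "min_fp_at_fn_ceiling") {
    if (is.null(fn_ceiling)) fn_ceiling <- min(grid$fn)
    ok <- grid$fn <= fn_ceiling
    if (!any(ok)) stop("no cutoff satisfies the FN ceiling", call. = FALSE)
    score <- ifelse(ok, -grid$fp, -Inf)
  } else if (objective == "youden") {
    score <- grid$sensitivity + grid$specificity - 1
  } else {
    score <- grid$f1
  }
  score[is.na(score)] <- -Inf
  best <- which(score == max(score))
  pick <- best[which.min(grid$cutoff[best])]
  out <- grid[pick, ]
  out$objective <- objective
  out$objective_value <- score[pick]
  out
}

#' Agreement between two-dose and four-dose Kd estimates
#'
#' Computes the squared Pearson correlation (R^2) and mean squared error of
#' log10 Kd between the two estimate sets, and counts pairs whose
#' censoring status disagrees. With `pairs = "co_finite"` the statistics
#' run over pairs uncensored in both sets; with `pairs = "all"` they run
#' over every shared pair using the posterior medians regardless of
#' censoring, so that a design which mislocates non-binders (for example
#' one lacking the top assay concentration) is penalised for it.
#'
#' @param two_dose_est,four_dose_est `kd_estimates` tibbles on the same
#'   pairs (from [fit_two_dose()] and [fit_curves()]).
#' @param pairs `"co_finite"` (default) or `"all"`.
#' @return One-row tibble: `r_squared`, `mse`, `n`,
#'   `censor_disagreements`.
#' @export
compare_two_vs_four <- function(two_dose_est, four_dose_est,
                                pairs = c("co_finite", "all")) {
  pairs <- match.arg(pairs)
  need <- c("compound_id", "kinase_id", "log10_kd_median", "censor")
  assert_columns(two_dose_est, need, what = "two_dose_est")
  assert_columns(four_dose_est, need, what = "four_dose_est")
  j <- dplyr::inner_join(two_dose_est, four_dose_est,
                         by = c("compound_id", "kinase_id"),
                         suffix = c("_2", "_4"))
  cof <- if (pairs == "co_finite") {
    j$censor_2 == "none" & j$censor_4 == "none"
  } else {
    rep(TRUE, nrow(j))
  }
  if (sum(cof) < 3) stop("fewer than 3 comparable pairs", call. = FALSE)
  l2 <- j$log10_kd_median_2[cof]
  l4 <- j$log10_kd_median_4[cof]
  tibble::tibble(
    r_squared = stats::cor(l2, l4)^2,
    mse = mean((l2 - l4)^2),
    n = sum(cof),
    censor_disagreements = sum(j$censor_2 != j$censor_4)
  )
}

#' F1 score of binder classification from Kd estimates
#'
#' Predicted binder iff the estimated Kd is below `threshold_nM` and not
#' censored above the range; true binder iff the reference Kd is finite
#' and below `threshold_nM`.
#'
#' @param estimates `kd_estimates` tibble.
#' @param truth_kd Tibble `compound_id`, `kinase_id`, `kd_nM` (`NA` =
#'   non-binder).
#' @param threshold_nM Binder definition (default 1 uM).
#' @return F1 as a numeric scalar; `NA` with a `reason` attribute when no
#'   positives exist on either side.
#' @export
f1_binder_classification <- function(estimates, truth_kd,
                                     threshold_nM = 1000) {
  assert_columns(estimates, c("compound_id", "kinase_id", "kd_nM", "censor"),
                 what = "estimates")
  assert_columns(truth_kd, c("compound_id", "kinase_id", "kd_nM"),
                 what = "truth_kd")
  key <- pair_key(estimates$compound_id, estimates$kinase_id)
  tk <- truth_kd$kd_nM[match(key, pair_key(truth_kd$compound_id,
                                           truth_kd$kinase_id))]
  truth <- !is.na(tk) & tk < threshold_nM
  pred <- estimates$censor != "above_range" & !is.na(estimates$kd_nM) &
    estimates$kd_nM < threshold_nM
  tp <- sum(pred & truth); fp <- sum(pred & !truth); fn <- sum(!pred & truth)
  if (tp + fp + fn == 0) {
    return(structure(NA_real_, reason = "no positives predicted or true"))
  }
  2 * tp / (2 * tp + fp + fn)
}
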