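#' Configuration of the hierarchical dose-response model
#'
#' Fixes the priors, sampler settings and censoring bounds of the Bayesian
#' hierarchical Hill model used by [fit_curves()] and [fit_two_dose()].
#' The defaults are weakly informative: log10 Kd uniform on
#' \[-0.5, 6.5\] log10 nM (about 0.3 nM to 3 mM, spanning the assay's four
#' decades with margin), Hill slopes log-normal centred at 1 with total sd
#' 0.35 on the log scale split equally between compound-level and
#' within-compound variation, and a global half-normal(10) observation sd.
#'
#' @param log10_kd_prior Uniform prior interval for log10 Kd (log10 nM).
#' @param hill_prior_mu,hill_prior_sd Centre and total sd of the
#'   log-normal Hill-slope prior (log scale); compound-level partial
#'   pooling splits the sd between levels.
#' @param obs_sd_prior Half-normal scale of the global observation sd
#'   (percent-control units).
#' @param sampler `"mcmc"` (random-walk Metropolis within Gibbs, the
#'   default) or `"map"` (per-curve MAP + Laplace interval, a fast
#'   deterministic mode for bulk runs).
#' @param n_draws,n_warmup,n_chains MCMC size settings.
#' @param seed Integer seed; determines the draws.
#' @param censor_low_nM,censor_high_nM Tested concentration range; point
#'   estimates whose posterior mass falls outside it are flagged as
#'   censored rather than silently extrapolated.
#' @param upper_clip Upper truncation bound of the observation model
#'   (maximum reportable percent control).
#' @param rhat_threshold Estimates with split-Rhat above this are flagged
#'   `nonconverged` (retained, not dropped).
#' @return A validated list of class `model_config`.
#' @export
model_config <- function(log10_kd_prior = c(-0.5, 6.5),
                         hill_prior_mu = 0,
                         hill_prior_sd = 0.35,
                         obs_sd_prior = 10,
                         sampler = c("mcmc", "map"),
                         n_draws = 1000,
                         n_warmup = 500,
                         n_chains = 4,
                         seed = 1L,
                         censor_low_nM = 12.5,
                         censor_high_nM = 10000,
                         upper_clip = 140,
                         rhat_threshold = 1.1) {
  sampler <- match.arg(sampler)
  stopifnot(length(log10_kd_prior) == 2, diff(log10_kd_prior) > 0,
            hill_prior_sd > 0, obs_sd_prior > 0,
            n_draws >= 10, n_warmup >= 10, n_chains >= 1,
            censor_low_nM > 0, censor_low_nM < censor_high_nM,
            upper_clip > 100)
  structure(list(log10_kd_prior = as.numeric(log10_kd_prior),
                 hill_prior_mu = hill_prior_mu,
                 hill_prior_sd = hill_prior_sd,
                 obs_sd_prior = obs_sd_prior,
                 sampler = sampler,
                 n_draws = as.integer(n_draws),
                 n_warmup = as.integer(n_warmup),
                 n_chains = as.integer(n_chains),
                 seed = as.integer(seed),
                 censor_low_nM = censor_low_nM,
                 censor_high_nM = censor_high_nM,
                 upper_clip = upper_clip,
                 rhat_threshold = rhat_threshold),
            class = "model_config")
}

# Above-range: the point estimate (or the whole interval) falls beyond the
# top tested concentration -- such pairs are treated as non-binding
# downstream. Below-range: only when the whole interval lies below the
# lowest tested dose; a potent median with an interval reaching into the
# tested range is still data-constrained and is reported unflagged.
.censor_state <- function(median, lo_q, hi_q, config) {
  log_hi <- log10(config$censor_high_nM)
  log_lo <- log10(config$censor_low_nM)
  dplyr::case_when(
    lo_q > log_hi | median > log_hi ~ "above_range",
    hi_q < log_lo ~ "below_range",
    .default = "none"
  )
}

#' Fit the hierarchical Hill model to dose-response curves
#'
#' Estimates, for every (compound, kinase) curve, the posterior of log10 Kd
#' and the Hill slope under a truncated-normal observation model whose mean
#' follows the competition-binding Hill form
#' PoC = 100 / (1 + (c / Kd)^h). Hill slopes are partially pooled per
#' compound and the observation sd is pooled globally. Estimates whose
#' posterior mass lies outside the tested concentration range are flagged
#' `above_range` / `below_range`; they are reported, not extrapolated.
#'
#' Curves labelled `discordant` in `qc_labels` are excluded (they are
#' technical artifacts); curves labelled `weak_low` are fitted but flagged
#' as low quality. qPCR dropouts should be removed beforehand with
#' [exclude_dropouts()].
#'
#' @param curves Long measurement tibble (`compound_id`, `kinase_id`,
#'   `concentration_nM`, `percent_control`).
#' @param qc_labels Optional output of [classify_curves()].
#' @param config A [model_config()].
#' @return A tibble of class `kd_estimates` with one row per fitted pair:
#'   `kd_nM`, `log10_kd_median`, `log10_kd_lo`, `log10_kd_hi` (95%
#'   interval), `hill_median`, `censor`, `rhat`, `ess`, `quality_flag`.
#' @export
fit_curves <- function(curves, qc_labels = NULL, config = model_config()) {
  assert_columns(curves, c("compound_id", "kinase_id", "concentration_nM",
                           "percent_control"), what = "curves")
  if (nrow(curves) == 0) stop("empty input", call. = FALSE)

  weak_pairs <- character(0)
  if (!is.null(qc_labels)) {
    assert_columns(qc_labels, c("compound_id", "kinase_id", "label"),
                   what = "qc_labels")
    disc <- qc_labels[qc_labels$label == "discordant", ]
    if (nrow(disc) > 0) {
      curves <- curves[!(pair_key(curves$compound_id, curves$kinase_id) %in%
                           pair_key(disc$compound_id, disc$kinase_id)), ]
    }
    weak <- qc_labels[qc_labels$label == "weak_low", ]
    weak_pairs <- pair_key(weak$compound_id, weak$kinase_id)
    if (nrow(curves) == 0) stop("no curves left after QC exclusion", call. = FALSE)
  }

  key <- pair_key(curves$compound_id, curves$kinase_id)
  curve_f <- factor(key, levels = unique(key))
  curve <- as.integer(curve_f)
  first <- match(levels(curve_f), key)
  compound_id <- curves$compound_id[first]
  kinase_id <- curves$kinase_id[first]
  comp_f <- factor(compound_id, levels = unique(compound_id))

  dat <- list(y = curves$percent_control,
              logc = log(curves$concentration_nM),
              curve = curve,
              comp = as.integer(comp_f),
              n_curve = nlevels(curve_f),
              n_comp = nlevels(comp_f))

  if (config$sampler == "mcmc") {
    chains <- lapply(seq_len(config$n_chains), function(ch) {
      .run_chain(dat, config, chain_seed = config$seed + 7919L * ch)
    })
    th_all <- do.call(rbind, lapply(chains, `[[`, "theta"))
    et_all <- do.call(rbind, lapply(chains, `[[`, "eta"))
    med <- apply(th_all, 2, stats::median)
    lo_q <- apply(th_all, 2, stats::quantile, probs = 0.025, names = FALSE)
    hi_q <- apply(th_all, 2, stats::quantile, probs = 0.975, names = FALSE)
    hill_med <- exp(apply(et_all, 2, stats::median))
    mlist <- coda::mcmc.list(lapply(chains, function(ch) coda::mcmc(ch$theta)))
    rhat <- tryCatch(
      coda::gelman.diag(mlist, autoburnin = FALSE, multivariate = FALSE)$psrf[, 1],
      error = function(e) rep(NA_real_, dat$n_curve))
    ess <- tryCatch(as.numeric(coda::effectiveSize(mlist)),
                    error = function(e) rep(NA_real_, dat$n_curve))
  } else {
    idx <- split(seq_along(dat$y), dat$curve)
    fits <- lapply(idx, function(i) .fit_map_curve(dat$y[i], dat$logc[i], config))
    med <- unname(vapply(fits, `[[`, numeric(1), "theta"))
    lo_q <- unname(vapply(fits, `[[`, numeric(1), "theta_lo"))
    hi_q <- unname(vapply(fits, `[[`, numeric(1), "theta_hi"))
    hill_med <- unname(vapply(fits, `[[`, numeric(1), "hill"))
    rhat <- rep(NA_real_, dat$n_curve)
    ess <- rep(NA_real_, dat$n_curve)
  }

  censor <- .censor_state(med, lo_q, hi_q, config)
  flag <- rep("", dat$n_curve)
  flag[pair_key(compound_id, kinase_id) %in% weak_pairs] <- "weak_low"
  bad <- !is.na(rhat) & rhat > config$rhat_threshold
  flag[bad] <- trimws(paste(flag[bad], "nonconverged"))

  out <- tibble::tibble(
    compound_id = compound_id,
    kinase_id = kinase_id,
    kd_nM = 10^med,
    log10_kd_median = med,
    log10_kd_lo = lo_q,
    log10_kd_hi = hi_q,
    hill_median = hill_med,
    censor = censor,
    rhat = rhat,
    ess = ess,
    quality_flag = flag
  )
  class(out) <- c("kd_estimates", class(out))
  out
}

#' Fit the model using only two of the assay concentrations
#'
#' Restricts every curve to the selected dose pair and refits the same
#' hierarchical model, emulating a cheaper two-concentration screening
#' design. Intervals are expected to widen; the censoring contract is
#' unchanged.
#'
#' @param curves Long measurement tibble.
#' @param dose_pair Two concentrations (nM) present in the data.
#' @inheritParams fit_curves
#' @return A `kd_estimates` tibble as from [fit_curves()].
#' @export
fit_two_dose <- function(curves, dose_pair, qc_labels = NULL,
                         config = model_config()) {
  stopifnot(length(dose_pair) == 2)
  present <- dose_pair %in% unique(curves$concentration_nM)
  if (!all(present)) {
    stop(sprintf("dose(s) %s not present in the data",
                 paste(dose_pair[!present], collapse = ", ")), call. = FALSE)
  }
  sub <- curves[curves$concentration_nM %in% dose_pair, ]
  fit_curves(sub, qc_labels = qc_labels, config = config)
}

#' Assemble Kd estimates into a compounds x kinases affinity matrix
#'
#' Materialises the affinity grid behind all downstream selectivity and
#' coverage analyses. Pairs censored above the tested range are stored as
#' missing-with-reason (their `kd_nM` cell is `NA` and the `censor` matrix
#' records why); pairs never estimated are reason-coded `not_estimated`.
#'
#' `estimates` may be a full [fit_curves()] result or any tibble with
#' `compound_id`, `kinase_id` and `kd_nM` (plus optional `hill_median` and
#' `censor`), which makes planted matrices easy to construct.
#'
#' @param estimates Tibble keyed uniquely by (compound_id, kinase_id).
#' @return An object of class `affinity_matrix`: a list with numeric
#'   matrices `kd` (nM) and `hill`, a character matrix `censor`, and the
#'   `compounds` / `kinases` dimension names.
#' @export
affinity_matrix <- function(estimates) {
  assert_columns(estimates, c("compound_id", "kinase_id", "kd_nM"),
                 what = "estimates")
  key <- pair_key(estimates$compound_id, estimates$kinase_id)
  if (anyDuplicated(key) > 0) {
    d <- estimates[duplicated(key), ][1, ]
    stop(sprintf("duplicate estimate for pair (%s, %s)",
                 d$compound_id, d$kinase_id), call. = FALSE)
  }
  compounds <- unique(estimates$compound_id)
  kinases <- unique(estimates$kinase_id)
  kd <- matrix(NA_real_, length(compounds), length(kinases),
               dimnames = list(compounds, kinases))
  hill <- kd
  censor <- matrix("not_estimated", length(compounds), length(kinases),
                   dimnames = list(compounds, kinases))
  ij <- cbind(match(estimates$compound_id, compounds),
              match(estimates$kinase_id, kinases))
  cens <- if ("censor" %in% names(estimates)) estimates$censor else
    rep("none", nrow(estimates))
  kd[ij] <- ifelse(cens == "above_range", NA_real_, estimates$kd_nM)
  hill[ij] <- if ("hill_median" %in% names(estimates))
    estimates$hill_median else 1
  censor[ij] <- cens
  structure(list(kd = kd, hill = hill, censor = censor,
                 compounds = compounds, kinases = kinases),
            class = "affinity_matrix")
}

#' @export
print.affinity_matrix <- function(x, ...) {
  cat(sprintf("affinity_matrix: %d compounds x %d kinases, %d finite Kd, %d censored above\n",
              length(x$compounds), length(x$kinases),
              sum(!is.na(x$kd)), sum(x$censor == "above_range")))
  invisible(x)
}

#' Write / read an affinity matrix as a long CSV
#'
#' The long form (`compound_id`, `kinase_id`, `kd_nM`, `hill`, `censor`)
#' round-trips losslessly through [read_affinity_matrix()].
#'
#' @param x An `affinity_matrix`.
#' @param path CSV path.
#' @return `write_affinity_matrix()` returns `path` invisibly;
#'   `read_affinity_matrix()` returns an `affinity_matrix`.
#' @export
write_affinity_matrix <- function(x, path) {
  stopifnot(inherits(x, "affinity_matrix"))
  long <- tidyr::expand_grid(compound_id = x$compounds, kinase_id = x$kinases)
  ij <- cbind(match(long$compound_id, x$compounds),
              match(long$kinase_id, x$kinases))
  long$kd_nM <- x$kd[ij]
  long$hill <- x$hill[ij]
  long$censor <- x$censor[ij]
  long <- long[long$censor != "not_estimated" | !is.na(long$kd_nM), ]
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_affinity_matrix
#' @export
read_affinity_matrix <- function(path) {
  long <- utils::read.csv(path)
  assert_columns(long, c("compound_id", "kinase_id", "kd_nM", "hill", "censor"),
                 what = basename(path))
  # censored-above rows carry NA kd in the file; restore via the censor code
  est <- tibble::tibble(compound_id = long$compound_id,
                        kinase_id = long$kinase_id,
                        kd_nM = long$kd_nM,
                        hill_median = long$hill,
                        censor = long$censor)
  affinity_matrix(est)
}
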