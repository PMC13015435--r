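#' Convert dissociation constants to target affinity spectrum (TAS) bins
#'
#' TAS summarises per-pair binding evidence as an ordinal bin: Kd above
#' 10 uM maps to TAS 10 (non-binding), 1-10 uM to TAS 3, 100 nM-1 uM to
#' TAS 2, and below 100 nM to TAS 1. Bins are half-open and
#' lower-inclusive, so Kd = 100 nM is TAS 2 and Kd = 1 uM is TAS 3.
#' Pairs censored above the tested range map to TAS 10.
#'
#' The strongest bin is bounded at 100 nM, the conventional TAS-1 boundary
#' consistent with the TAS-2 bin starting there; assay descriptions
#' sometimes quote the lowest tested concentration (12.5 nM) instead,
#' leaving 12.5-100 nM unassigned, which this implementation deliberately
#' closes.
#'
#' @param kd_nM Numeric vector of dissociation constants (nM); must be
#'   positive.
#' @param censored_above Logical vector (recycled); `TRUE` forces TAS 10.
#' @return Integer vector with values in \{1, 2, 3, 10\}.
#' @export
#' @examples
#' tas_from_kd(c(50, 500, 5000, 50000))
tas_from_kd <- function(kd_nM, censored_above = FALSE) {
  censored_above <- rep_len(censored_above, length(kd_nM))
  if (any(!censored_above & (!is.finite(kd_nM) | kd_nM <= 0))) {
    stop("kd_nM must be positive (or censored above)", call. = FALSE)
  }
  out <- rep(10L, length(kd_nM))
  ok <- !censored_above
  out[ok & kd_nM < 10000] <- 3L
  out[ok & kd_nM < 1000] <- 2L
  out[ok & kd_nM < 100] <- 1L
  out
}

#' Partition index of one compound across its kinase targets
#'
#' The partition index PI_i = (1/Kd_i) / sum_j (1/Kd_j) is the fraction of
#' a compound bound to kinase i in a theoretical situation in which all
#' kinases are present in excess. A perfectly selective compound has
#' PI_max = 1; a promiscuous one has PI_max far below 1. Censored-above and
#' missing pairs are excluded from the sum (non-binder semantics).
#'
#' @param kds Named numeric vector of Kd values (nM) for one compound;
#'   `NA` entries are treated as non-binding.
#' @return Named numeric vector of PI values over the finite entries,
#'   summing to 1. If no entry is finite, a zero-length vector with
#'   attribute `reason = "no finite affinities"`.
#' @export
partition_index <- function(kds) {
  fin <- is.finite(kds) & kds > 0
  if (!any(fin)) {
    return(structure(stats::setNames(numeric(0), character(0)),
                     reason = "no finite affinities"))
  }
  inv <- 1 / kds[fin]
  inv / sum(inv)
}

#' Predicted target engagement at a given free-compound concentration
#'
#' E_i = 100 / (1 + (Kd_i / conc)^h_i), the percent of kinase i predicted
#' to be occupied at concentration `conc`. Used with `conc` equal to the
#' Kd of the compound's most potent target to compute
#' [catds_most_potent()].
#'
#' @param kd_i,hill_i,conc Positive numerics (vectors recycle).
#' @return Engagement values in (0, 100).
#' @export
engagement <- function(kd_i, hill_i, conc) {
  stopifnot(all(kd_i > 0), all(hill_i > 0), all(conc > 0))
  100 / (1 + exp(hill_i * (log(kd_i) - log(conc))))
}

#' Concentration- and target-dependent selectivity of the most potent target
#'
#' CATDS_most-potent = E_ref / sum_i E_i: the share of a compound's total
#' predicted target engagement attributable to its most potent target,
#' with every engagement evaluated at a free-compound concentration equal
#' to that target's Kd. Equals 1 for a single-target compound and 1/m for
#' m equally potent targets.
#'
#' Ties for the lowest Kd are broken by lexicographic kinase id (recorded
#' in the `tie` attribute). Missing Hill slopes default to 1.
#'
#' @param kds Named numeric Kd vector (nM) for one compound; `NA` entries
#'   are treated as non-binding and excluded.
#' @param hills Optional named numeric vector of Hill slopes aligned with
#'   `kds`.
#' @return A numeric value in (0, 1] with attribute `ref_kinase` (and
#'   `tie = TRUE` if the reference was tie-broken), or `NA` with a
#'   `reason` attribute when no Kd is finite.
#' @export
catds_most_potent <- function(kds, hills = NULL) {
  fin <- is.finite(kds) & kds > 0
  if (!any(fin)) {
    return(structure(NA_real_, reason = "no finite affinities"))
  }
  kds <- kds[fin]
  h <- if (is.null(hills)) rep(1, length(kds)) else {
    hh <- hills[names(kds)]
    hh[!is.finite(hh) | hh <= 0] <- 1
    hh
  }
  candidates <- names(kds)[kds == min(kds)]
  ref <- sort(candidates)[1]
  e <- engagement(kds, h, conc = kds[[ref]])
  out <- unname(e[[ref]] / sum(e))
  attr(out, "ref_kinase") <- ref
  if (length(candidates) > 1) attr(out, "tie") <- TRUE
  out
}

#' Per-compound selectivity records from an affinity matrix
#'
#' Computes, for every compound with at least one finite Kd, the partition
#' index vector's maximum (`pi_max`) and argmax, CATDS_most-potent with its
#' reference kinase, the minimum Kd, and the chemical-probe flag (minimum
#' Kd below 100 nM and CATDS_most-potent above 0.5, attributed to a single
#' kinase). Compounds with no finite Kd get `NA` metrics.
#'
#' @param x An [affinity_matrix()].
#' @return A tibble of class `selectivity_records` with one row per
#'   compound.
#' @export
selectivity_table <- function(x) {
  stopifnot(inherits(x, "affinity_matrix"))
  rows <- lapply(x$compounds, function(cp) {
    kds <- x$kd[cp, ]
    hills <- x$hill[cp, ]
    pi <- partition_index(kds)
    if (length(pi) == 0) {
      return(tibble::tibble(compound_id = cp, n_targets = 0L,
                            pi_max = NA_real_, pi_max_kinase = NA_character_,
                            catds_most_potent = NA_real_,
                            ref_kinase = NA_character_, min_kd_nM = NA_real_,
                            probe = FALSE))
    }
    catds <- catds_most_potent(kds, hills)
    fin <- kds[is.finite(kds)]
    ref <- attr(catds, "ref_kinase")
    single_ref <- sum(fin == min(fin)) == 1
    tibble::tibble(
      compound_id = cp,
      n_targets = length(pi),
      pi_max = max(pi),
      pi_max_kinase = names(pi)[which.max(pi)],
      catds_most_potent = as.numeric(catds),
      ref_kinase = ref,
      min_kd_nM = min(fin),
      probe = min(fin) < 100 && as.numeric(catds) > 0.5 && single_ref
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("selectivity_records", class(out))
  out
}

#' Compounds meeting the chemical-probe definition
#'
#' A chemical probe here is a compound whose lowest Kd is below 100 nM and
#' whose CATDS_most-potent exceeds 0.5 for a single target (the minimum Kd
#' is attained by exactly one kinase).
#'
#' @param records A [selectivity_table()] result.
#' @return Character vector of compound ids.
#' @export
chemical_probe_filter <- function(records) {
  assert_columns(records, c("compound_id", "probe"), what = "records")
  records$compound_id[records$probe]
}

#' Per-pair TAS table from an affinity matrix
#'
#' @param x An [affinity_matrix()].
#' @return A tibble `compound_id`, `kinase_id`, `tas` covering every
#'   estimated pair (censored-above pairs get TAS 10; never-estimated
#'   cells are omitted).
#' @export
tas_table <- function(x) {
  stopifnot(inherits(x, "affinity_matrix"))
  long <- tidyr::expand_grid(compound_id = x$compounds, kinase_id = x$kinases)
  ij <- cbind(match(long$compound_id, x$compounds),
              match(long$kinase_id, x$kinases))
  kd <- x$kd[ij]
  cens <- x$censor[ij]
  keep <- cens != "not_estimated"
  long <- long[keep, ]
  long$tas <- tas_from_kd(ifelse(is.na(kd[keep]), 1, kd[keep]),
                          censored_above = cens[keep] == "above_range")
  long
}
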