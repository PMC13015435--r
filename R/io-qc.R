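#' Read a scanMAX-style long table of percent-of-control measurements
#'
#' Reads a CSV with columns `compound_id`, `kinase_id`, `concentration_nM`,
#' `percent_control` and optionally `batch`, validates it, and returns the
#' set of dose-response curves as a long tibble sorted by pair and
#' ascending concentration. Malformed rows (non-numeric percent control or
#' concentration, non-positive concentration, negative percent control) are
#' reported with their file line numbers; duplicated
#' (pair, concentration) measurements are an error naming the pair.
#'
#' @param path CSV file path.
#' @return A tibble with one row per measurement.
#' @export
read_scanmax_table <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  assert_columns(raw, c("compound_id", "kinase_id", "concentration_nM",
                        "percent_control"), what = basename(path))
  conc <- suppressWarnings(as.numeric(raw$concentration_nM))
  poc <- suppressWarnings(as.numeric(raw$percent_control))
  bad <- which(is.na(conc) | is.na(poc) | conc <= 0 | poc < 0)
  if (length(bad) > 0) {
    stop(sprintf("malformed rows at line(s): %s",
                 paste(utils::head(bad + 1L, 20), collapse = ", ")),
         call. = FALSE) # +1 for the header line
  }
  tab <- tibble::tibble(
    compound_id = raw$compound_id,
    kinase_id = raw$kinase_id,
    concentration_nM = conc,
    percent_control = poc,
    batch = if ("batch" %in% names(raw)) raw$batch else NA_character_
  )
  key <- pair_key(tab$compound_id, tab$kinase_id)
  dup <- duplicated(paste(key, tab$concentration_nM))
  if (any(dup)) {
    p <- tab[which(dup)[1], ]
    stop(sprintf("duplicate measurement for pair (%s, %s) at %g nM",
                 p$compound_id, p$kinase_id, p$concentration_nM),
         call. = FALSE)
  }
  dplyr::arrange(tab, .data$compound_id, .data$kinase_id,
                 .data$concentration_nM)
}

#' Remove listed qPCR-dropout measurements
#'
#' Dropouts are assay points reported as 100% control (no binding) caused
#' by amplification failure rather than true non-binding; vendors supply
#' them as a list of (compound, kinase, concentration) triples, and they
#' must be excluded before inference. A curve that loses all of its points
#' is removed entirely (with a message). Triples absent from the data
#' produce a warning, not an error.
#'
#' @param curves Long measurement tibble as from [read_scanmax_table()].
#' @param dropout_list Data frame with columns `compound_id`, `kinase_id`,
#'   `concentration_nM`.
#' @return The filtered tibble.
#' @export
exclude_dropouts <- function(curves, dropout_list) {
  assert_columns(dropout_list,
                 c("compound_id", "kinase_id", "concentration_nM"),
                 what = "dropout_list")
  if (nrow(dropout_list) == 0) return(curves)
  key <- function(d) paste(pair_key(d$compound_id, d$kinase_id),
                           d$concentration_nM)
  hit <- key(curves) %in% key(dropout_list)
  n_absent <- nrow(dropout_list) - sum(key(dropout_list) %in% key(curves))
  if (n_absent > 0) {
    warning(sprintf("%d dropout triple(s) not present in the data", n_absent),
            call. = FALSE)
  }
  kept <- curves[!hit, ]
  lost <- setdiff(unique(pair_key(curves$compound_id, curves$kinase_id)),
                  unique(pair_key(kept$compound_id, kept$kinase_id)))
  if (length(lost) > 0) {
    message(sprintf("%d curve(s) lost all points to dropouts and were removed",
                    length(lost)))
  }
  kept
}

qc_classes <- c("non_binding", "binding", "weak_high", "weak_low", "discordant")

#' Classify a single dose-response curve into the five QC classes
#'
#' Applies the five-class scheme used to vet competition-binding
#' dose-response curves against the conventional hit cutoff (35% control by
#' default):
#'
#' * `discordant` -- some reading below the cutoff is followed, at a higher
#'   concentration, by a reading above the cutoff that is at least two-fold
#'   higher than a preceding value (a technical artifact; tested first
#'   because true binding requires all measurements to be concordant);
#' * `non_binding` -- no reading below the cutoff;
#' * `binding` -- two or more readings below the cutoff;
#' * `weak_high` -- exactly one reading below the cutoff and a negative
#'   dose-response trend with p < `p_thresh` (ordinary least squares of
#'   percent control on log10 concentration, two-sided slope p-value);
#' * `weak_low` -- exactly one reading below the cutoff otherwise (usually
#'   curves where only the top concentration falls below the cutoff).
#'
#' Single-point curves are classified by the cutoff alone: `non_binding` at
#' or above it, `weak_low` below it.
#'
#' @param percent_control,concentration_nM Numeric vectors of equal length.
#' @param cutoff Percent-control hit cutoff (default 35).
#' @param p_thresh Trend-test p-value threshold (default 0.1).
#' @return A list with elements `label` (one of
#'   `r paste(qc_classes, collapse = ", ")`) and `p_value` (trend-test
#'   p-value when computed, otherwise `NA`).
#' @export
classify_curve <- function(percent_control, concentration_nM,
                           cutoff = 35, p_thresh = 0.1) {
  stopifnot(length(percent_control) == length(concentration_nM),
            length(percent_control) >= 1)
  ord <- order(concentration_nM)
  poc <- percent_control[ord]
  conc <- concentration_nM[ord]
  n <- length(poc)
  below <- poc < cutoff

  if (n >= 2) {
    prev_min <- cummin(poc)[-n]
    prev_any_below <- cumsum(below)[-n] > 0
    later <- poc[-1]
    if (any(later > cutoff & later >= 2 * prev_min & prev_any_below)) {
      return(list(label = "discordant", p_value = NA_real_))
    }
  }
  if (!any(below)) return(list(label = "non_binding", p_value = NA_real_))
  if (sum(below) >= 2) return(list(label = "binding", p_value = NA_real_))

  # exactly one reading below the cutoff: trend test
  p <- NA_real_
  slope <- NA_real_
  if (n >= 3) {
    fit <- stats::lm(poc ~ log10(conc))
    sm <- summary(fit)$coefficients
    if (nrow(sm) == 2 && !is.na(sm[2, 4])) {
      slope <- sm[2, 1]
      p <- sm[2, 4]
    }
  }
  label <- if (!is.na(p) && slope < 0 && p < p_thresh) "weak_high" else "weak_low"
  list(label = label, p_value = p)
}

#' Classify every curve in a long measurement table
#'
#' @param curves Long tibble as from [read_scanmax_table()].
#' @inheritParams classify_curve
#' @return A tibble with one row per (compound_id, kinase_id) pair and
#'   columns `label` and `p_value`.
#' @export
classify_curves <- function(curves, cutoff = 35, p_thresh = 0.1) {
  assert_columns(curves, c("compound_id", "kinase_id", "concentration_nM",
                           "percent_control"), what = "curves")
  key <- pair_key(curves$compound_id, curves$kinase_id)
  idx <- split(seq_len(nrow(curves)), factor(key, levels = unique(key)))
  res <- lapply(idx, function(i) {
    classify_curve(curves$percent_control[i], curves$concentration_nM[i],
                   cutoff = cutoff, p_thresh = p_thresh)
  })
  first <- vapply(idx, `[`, integer(1), 1L)
  tibble::tibble(
    compound_id = curves$compound_id[first],
    kinase_id = curves$kinase_id[first],
    label = vapply(res, `[[`, character(1), "label"),
    p_value = vapply(res, `[[`, numeric(1), "p_value")
  )
}

#' Summarise QC labels
#'
#' Computes the overall class fractions (always reporting all five classes,
#' summing to one) and the per-kinase and per-compound discordant rates,
#' which surface systematic batch effects when discordance concentrates on
#' a few assay plates.
#'
#' @param labels Output of [classify_curves()].
#' @return A list of class `qc_summary` with tibbles `class_fractions`,
#'   `discordant_by_kinase` and `discordant_by_compound`.
#' @export
qc_summary <- function(labels) {
  assert_columns(labels, c("compound_id", "kinase_id", "label"),
                 what = "labels")
  if (nrow(labels) == 0) stop("empty label set", call. = FALSE)
  counts <- table(factor(labels$label, levels = qc_classes))
  class_fractions <- tibble::tibble(
    label = qc_classes,
    n = as.integer(counts),
    fraction = as.numeric(counts) / nrow(labels)
  )
  by_rate <- function(g) {
    dplyr::summarise(dplyr::group_by(labels, .data[[g]]),
                     n_curves = dplyr::n(),
                     discordant_rate = mean(.data$label == "discordant"),
                     .groups = "drop")
  }
  structure(list(class_fractions = class_fractions,
                 discordant_by_kinase = by_rate("kinase_id"),
                 discordant_by_compound = by_rate("compound_id")),
            class = "qc_summary")
}

#' @export
print.qc_summary <- function(x, ...) {
  cat("QC class fractions:\n")
  print(x$class_fractions)
  worst <- dplyr::arrange(x$discordant_by_kinase,
                          dplyr::desc(.data$discordant_rate))
  cat("\nHighest per-kinase discordant rates:\n")
  print(utils::head(worst, 5))
  invisible(x)
}
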