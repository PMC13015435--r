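# Internal helpers shared across modules.

# Deterministic largest-remainder allocation of n items to named categories
# with the given weights. Guarantees sum(counts) == n.
quota_counts <- function(n, weights) {
  stopifnot(n >= 0, all(weights >= 0), sum(weights) > 0)
  prop <- weights / sum(weights)
  base <- floor(prop * n)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- prop * n - base
    top <- order(frac, decreasing = TRUE)[seq_len(rem)]
    base[top] <- base[top] + 1
  }
  stats::setNames(as.integer(base), names(weights))
}

# Expand quota counts into a label vector of length n (unshuffled).
quota_labels <- function(n, weights) {
  counts <- quota_counts(n, weights)
  rep(names(counts), times = counts)
}

# Truncated-normal sampler via inverse CDF; sd = 0 degenerates to clipping.
rnorm_trunc <- function(n, mean, sd, lower, upper) {
  if (sd <= 0) {
    return(pmin(pmax(mean, lower), upper))
  }
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

# Mean percent-of-control of the competition-binding Hill curve.
# conc and kd in nM; h dimensionless. PoC = 100 / (1 + (conc / kd)^h).
hill_poc <- function(conc, kd, h) {
  100 / (1 + exp(h * (log(conc) - log(kd))))
}

# Recursively drop S3 classes so configs serialise as plain lists.
strip_classes <- function(x) {
  if (is.list(x)) lapply(unclass(x), strip_classes) else x
}

pair_key <- function(compound_id, kinase_id) {
  paste(compound_id, kinase_id, sep = "\r")
}

assert_columns <- function(df, cols, what = "table") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}
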