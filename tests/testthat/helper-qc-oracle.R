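# Independent, deliberately literal re-statement of the five curve-class
# rules, used as the brute-force oracle for classify_curve().
oracle_classify <- function(poc, conc, cutoff = 35, p_thresh = 0.1) {
  ord <- order(conc)
  poc <- poc[ord]
  conc <- conc[ord]
  n <- length(poc)
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i < k && j < k &&
            poc[i] < cutoff && poc[k] > cutoff && poc[k] >= 2 * poc[j]) {
          return("discordant")
        }
      }
    }
  }
  n_below <- sum(poc < cutoff)
  if (n_below == 0) return("non_binding")
  if (n_below >= 2) return("binding")
  if (n >= 3) {
    fit <- summary(lm(poc ~ log10(conc)))$coefficients
    if (fit[2, 1] < 0 && fit[2, 4] < p_thresh) return("weak_high")
  }
  "weak_low"
}
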