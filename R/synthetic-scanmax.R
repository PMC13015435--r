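#' Configuration for the synthetic scanMAX-like data generator
#'
#' Builds and validates the configuration object that fully determines a
#' synthetic kinome-profiling dataset: library and panel sizes, assay
#' concentrations, the latent affinity distribution, the observation-noise
#' model, and the rates of the two technical artifacts that competition
#' binding panels exhibit in practice (qPCR dropouts reported as 100, and
#' discordant curves in which displacement does not increase with
#' concentration).
#'
#' The default concentrations are the four used by multi-dose scanMAX
#' profiling (12.5 nM, 100 nM, 1 uM, 10 uM), collected in two batches:
#' 10 uM and 100 nM in the first batch, 1 uM and 12.5 nM in the second.
#'
#' @param n_compounds,n_kinases Library and panel sizes.
#' @param doses Assay concentrations in nM; strictly positive and distinct.
#' @param binder_fraction Probability that a compound-kinase pair is a true
#'   binder (has a finite dissociation constant).
#' @param log10_kd_range Interval (log10 nM) from which binder log10 Kd
#'   values are drawn uniformly.
#' @param hill_mu,hill_sigma Meanlog and sdlog of the log-normal Hill-slope
#'   distribution (`hill_mu = 0` centres slopes at 1).
#' @param noise_sd Additive Gaussian observation noise, percent-control
#'   units, truncated to `[0, upper_clip]`.
#' @param upper_clip Maximum reportable percent-control value. Real panels
#'   report values above 100; the default cap is 140.
#' @param dropout_rate Per-measurement probability of a qPCR dropout
#'   (value replaced by exactly 100).
#' @param discordant_rate Per-curve probability of injecting a discordant
#'   artifact (one higher-concentration reading inflated above the hit
#'   cutoff and to at least twice a lower-concentration reading).
#' @param batch_map Named character vector mapping `as.character(dose)` to a
#'   batch label. Defaults to the two-batch structure above when `doses` is
#'   the default set, otherwise a single batch.
#' @param seed Integer seed; fully determines the generated dataset.
#' @param clinical_status_weights,kinase_category_weights Relative sizes of
#'   the compound clinical-status categories (approved / clinical / tool)
#'   and kinase categories (WT / mutant / non_mammalian). Defaults mirror a
#'   192-compound library (44/98/50) and a 468-kinase panel (406/59/3).
#' @param inhibitor_type_weights Relative library composition of inhibitor
#'   binding-mode types (I / II / other / unknown).
#' @param dark_fraction Fraction of kinases flagged as understudied
#'   ("dark").
#' @param dfg_out_fraction Fraction of kinases with a reported DFG-out
#'   structure.
#' @param pub_year_range Range of first-publication years for compounds.
#' @param kinome_groups Labels for sequence-based kinome groups.
#'
#' @return A validated list of class `generator_config`.
#' @export
#' @examples
#' cfg <- generator_config(n_compounds = 4, n_kinases = 6, seed = 7)
#' truth <- sample_ground_truth(cfg)
#' head(truth$pairs)
generator_config <- function(n_compounds = 24,
                             n_kinases = 50,
                             doses = c(12.5, 100, 1000, 10000),
                             binder_fraction = 0.15,
                             log10_kd_range = c(0, 4),
                             hill_mu = 0,
                             hill_sigma = 0.35,
                             noise_sd = 5,
                             upper_clip = 140,
                             dropout_rate = 0.003,
                             discordant_rate = 0.02,
                             batch_map = NULL,
                             seed = 1L,
                             clinical_status_weights = c(approved = 44, clinical = 98, tool = 50),
                             kinase_category_weights = c(WT = 406, mutant = 59, non_mammalian = 3),
                             inhibitor_type_weights = c(I = 0.55, II = 0.15, other = 0.10, unknown = 0.20),
                             dark_fraction = 0.3,
                             dfg_out_fraction = 0.25,
                             pub_year_range = c(1995, 2020),
                             kinome_groups = c("TK", "TKL", "STE", "CK1", "AGC",
                                               "CAMK", "CMGC", "ATYPICAL", "OTHER")) {
  if (is.null(batch_map)) {
    if (setequal(doses, c(12.5, 100, 1000, 10000))) {
      batch_map <- c("10000" = "B1", "100" = "B1", "1000" = "B2", "12.5" = "B2")
    } else {
      batch_map <- stats::setNames(rep("B1", length(doses)), as.character(doses))
    }
  }
  cfg <- list(
    n_compounds = as.integer(n_compounds),
    n_kinases = as.integer(n_kinases),
    doses = sort(as.numeric(doses)),
    binder_fraction = binder_fraction,
    log10_kd_range = as.numeric(log10_kd_range),
    hill_mu = hill_mu,
    hill_sigma = hill_sigma,
    noise_sd = noise_sd,
    upper_clip = upper_clip,
    dropout_rate = dropout_rate,
    discordant_rate = discordant_rate,
    batch_map = batch_map,
    seed = as.integer(seed),
    clinical_status_weights = clinical_status_weights,
    kinase_category_weights = kinase_category_weights,
    inhibitor_type_weights = inhibitor_type_weights,
    dark_fraction = dark_fraction,
    dfg_out_fraction = dfg_out_fraction,
    pub_year_range = pub_year_range,
    kinome_groups = kinome_groups
  )
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
}

validate_generator_config <- function(cfg) {
  with(cfg, {
    if (n_compounds < 1 || n_kinases < 1) {
      stop("n_compounds and n_kinases must be positive", call. = FALSE)
    }
    if (any(doses <= 0) || anyDuplicated(doses) > 0) {
      stop("doses must be strictly positive and distinct", call. = FALSE)
    }
    if (binder_fraction < 0 || binder_fraction > 1) {
      stop("binder_fraction must lie in [0, 1]", call. = FALSE)
    }
    if (length(log10_kd_range) != 2 || diff(log10_kd_range) <= 0) {
      stop("log10_kd_range must be a non-empty increasing interval", call. = FALSE)
    }
    if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
    if (hill_sigma < 0) stop("hill_sigma must be >= 0", call. = FALSE)
    if (upper_clip <= 0) stop("upper_clip must be positive", call. = FALSE)
    if (dropout_rate < 0 || dropout_rate > 1 ||
        discordant_rate < 0 || discordant_rate > 1) {
      stop("dropout_rate and discordant_rate must lie in [0, 1]", call. = FALSE)
    }
    if (!all(as.character(doses) %in% names(batch_map))) {
      stop("batch_map must cover every dose", call. = FALSE)
    }
  })
  cfg
}

#' Sample the latent ground truth of a synthetic screen
#'
#' Draws, for every compound-kinase pair, a binder indicator, a true
#' dissociation constant (binders only; non-binders carry no finite Kd so
#' that downstream censoring logic is exercised) and a true Hill slope,
#' together with compound metadata (clinical status, assigned targets,
#' inhibitor type, first-publication year) and kinase metadata (category,
#' kinome group, dark flag, DFG-out-structure flag).
#'
#' Assigned targets are sampled from each compound's binder kinases with
#' probability weights proportional to `1 / sqrt(Kd)`, so the assigned
#' target is usually potent but not always the top-affinity target.
#'
#' @param config A [generator_config()].
#' @return A list of class `scanmax_truth` with tibbles `pairs`,
#'   `compounds` and `kinases`.
#' @export
sample_ground_truth <- function(config) {
  config <- validate_generator_config(config)
  set.seed(config$seed)

  compounds <- sprintf("CPD%04d", seq_len(config$n_compounds))
  kinases <- sprintf("KIN%04d", seq_len(config$n_kinases))

  grid <- tidyr::expand_grid(compound_id = compounds, kinase_id = kinases)
  n_pair <- nrow(grid)
  binder <- stats::runif(n_pair) < config$binder_fraction
  lk <- ifelse(binder,
               stats::runif(n_pair, config$log10_kd_range[1], config$log10_kd_range[2]),
               NA_real_)
  hill <- ifelse(binder,
                 exp(stats::rnorm(n_pair, config$hill_mu, config$hill_sigma)),
                 NA_real_)
  pairs <- tibble::tibble(
    compound_id = grid$compound_id,
    kinase_id = grid$kinase_id,
    binder = binder,
    true_log10_kd = lk,
    true_hill = hill
  )

  kinase_meta <- tibble::tibble(
    kinase_id = kinases,
    category = sample(quota_labels(config$n_kinases, config$kinase_category_weights)),
    group = sample(config$kinome_groups, config$n_kinases, replace = TRUE),
    dark = stats::runif(config$n_kinases) < config$dark_fraction,
    dfg_out_structure = stats::runif(config$n_kinases) < config$dfg_out_fraction
  )

  # assigned targets: 1 (80%) or 2 (20%) kinases drawn from the binder set
  assigned <- vapply(compounds, function(cp) {
    sub <- pairs[pairs$compound_id == cp & pairs$binder, ]
    if (nrow(sub) == 0) return(NA_character_)
    n_assign <- min(nrow(sub), 1L + stats::rbinom(1, 1, 0.2))
    w <- 1 / sqrt(10^sub$true_log10_kd)
    sel <- sample(sub$kinase_id, n_assign, prob = w / sum(w))
    paste(sort(sel), collapse = ";")
  }, character(1))

  compound_meta <- tibble::tibble(
    compound_id = compounds,
    clinical_status = sample(quota_labels(config$n_compounds, config$clinical_status_weights)),
    assigned_targets = unname(assigned),
    inhibitor_type = sample(quota_labels(config$n_compounds, config$inhibitor_type_weights)),
    first_pub_year = sample(seq(config$pub_year_range[1], config$pub_year_range[2]),
                            config$n_compounds, replace = TRUE)
  )

  structure(list(pairs = pairs, compounds = compound_meta, kinases = kinase_meta),
            class = "scanmax_truth")
}

#' Simulate percent-of-control measurements from a ground truth
#'
#' Generates one row per pair x dose. The mean response follows the
#' competition-binding Hill form, PoC = 100 / (1 + (c / Kd)^h); non-binders
#' have mean 100 at every dose. Additive Gaussian noise (sd `noise_sd`) is
#' truncated to `[0, upper_clip]`. Discordant artifacts are then injected
#' per curve at rate `discordant_rate` by post-hoc corruption: the
#' lowest-concentration reading is forced below the conventional 35%-control
#' hit cutoff and one higher-concentration reading is inflated above it (and
#' to at least twice the lowest preceding value), emulating the
#' batch-handling errors such panels show. Finally qPCR dropouts replace
#' individual readings with exactly 100 at rate `dropout_rate` (skipping
#' artifact-corrupted curves so the two artifacts do not cancel).
#'
#' The hidden-truth columns `dropout` and `discordant` record the injected
#' artifacts; [write_scanmax_fixture()] withholds them from the observed
#' bundle.
#'
#' @param truth A `scanmax_truth` from [sample_ground_truth()].
#' @param config The same [generator_config()] used to draw `truth`.
#' @return A tibble with columns `compound_id`, `kinase_id`,
#'   `concentration_nM`, `percent_control`, `batch`, `dropout`,
#'   `discordant`.
#' @export
simulate_percent_control <- function(truth, config) {
  config <- validate_generator_config(config)
  stopifnot(inherits(truth, "scanmax_truth"))
  set.seed(config$seed + 1L)

  pairs <- truth$pairs
  n_dose <- length(config$doses)
  tab <- tidyr::expand_grid(
    pair = seq_len(nrow(pairs)),
    concentration_nM = config$doses
  )
  tab$compound_id <- pairs$compound_id[tab$pair]
  tab$kinase_id <- pairs$kinase_id[tab$pair]
  kd <- 10^pairs$true_log10_kd[tab$pair]
  h <- pairs$true_hill[tab$pair]
  mu <- ifelse(pairs$binder[tab$pair],
               hill_poc(tab$concentration_nM, kd, h),
               100)
  tab$percent_control <- rnorm_trunc(nrow(tab), mu, config$noise_sd,
                                     0, config$upper_clip)
  tab$batch <- unname(config$batch_map[as.character(tab$concentration_nM)])
  tab$dropout <- FALSE
  tab$discordant <- FALSE

  # discordant artifacts, one curve at a time (curves are contiguous blocks)
  disc_curve <- which(stats::runif(nrow(pairs)) < config$discordant_rate)
  if (n_dose >= 2) {
    for (cv in disc_curve) {
      idx <- (cv - 1L) * n_dose + seq_len(n_dose) # ascending concentration
      poc <- tab$percent_control[idx]
      poc[1] <- stats::runif(1, 5, 30)
      k <- if (n_dose == 2) 2L else sample(2:n_dose, 1)
      m <- min(poc[seq_len(k - 1)])
      poc[k] <- max(2.2 * m, stats::runif(1, 40, 95))
      tab$percent_control[idx] <- poc
      tab$discordant[idx] <- TRUE
    }
  }

  eligible <- !tab$discordant
  drop <- eligible & stats::runif(nrow(tab)) < config$dropout_rate
  tab$percent_control[drop] <- 100
  tab$dropout[drop] <- TRUE

  tab$pair <- NULL
  tab[, c("compound_id", "kinase_id", "concentration_nM",
          "percent_control", "batch", "dropout", "discordant")]
}

#' Write a synthetic screen to vendor-like CSV files
#'
#' Writes the observed long table (without the hidden-truth artifact
#' columns), the compound and kinase metadata tables, the per-pair ground
#' truth, and the list of dropout measurements (the synthetic analogue of
#' the vendor-supplied dropout list). The observed table round-trips
#' losslessly through [read_scanmax_table()].
#'
#' @param table Output of [simulate_percent_control()].
#' @param truth Matching `scanmax_truth`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named character vector of file paths.
#' @export
write_scanmax_fixture <- function(table, truth, dir) {
  stopifnot(nrow(table) > 0, inherits(truth, "scanmax_truth"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create directory: ", dir, call. = FALSE)

  paths <- c(
    observed = file.path(dir, "observed.csv"),
    compounds = file.path(dir, "compounds.csv"),
    kinases = file.path(dir, "kinases.csv"),
    truth = file.path(dir, "truth.csv"),
    dropouts = file.path(dir, "dropouts.csv")
  )
  observed <- table[, c("compound_id", "kinase_id", "concentration_nM",
                        "percent_control", "batch")]
  utils::write.csv(observed, paths["observed"], row.names = FALSE)
  utils::write.csv(truth$compounds, paths["compounds"], row.names = FALSE)
  utils::write.csv(truth$kinases, paths["kinases"], row.names = FALSE)
  utils::write.csv(truth$pairs, paths["truth"], row.names = FALSE)
  dropouts <- table[table$dropout,
                    c("compound_id", "kinase_id", "concentration_nM")]
  utils::write.csv(dropouts, paths["dropouts"], row.names = FALSE)
  invisible(paths)
}
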