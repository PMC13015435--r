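#' End-to-end pipeline configuration
#'
#' Bundles the generator and model configurations with the QC, analysis,
#' design-evaluation and clustering parameters. A single `seed` propagates
#' to every stochastic stage (the generator and the sampler receive
#' deterministic offsets of it). The configuration round-trips losslessly
#' through YAML via [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param generator A [generator_config()].
#' @param model A [model_config()].
#' @param qc_cutoff,qc_p QC classification parameters.
#' @param tau_nM Coverage thresholds (nM).
#' @param goal_kd_nM Binder definition for design evaluation (nM).
#' @param dose_pair Two-dose design to evaluate (nM).
#' @param promiscuity_rule,promiscuity_threshold,promiscuity_k Promiscuous
#'   kinase rule (see [promiscuous_kinases()]).
#' @param cluster_k,min_overlap,linkage Clustering parameters.
#' @param seed Master seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(generator = generator_config(),
                            model = model_config(),
                            qc_cutoff = 35,
                            qc_p = 0.1,
                            tau_nM = c(100, 1000),
                            goal_kd_nM = 1000,
                            dose_pair = c(100, 10000),
                            promiscuity_rule = "top_ranks",
                            promiscuity_threshold = 33,
                            promiscuity_k = 15,
                            cluster_k = 9,
                            min_overlap = 10,
                            linkage = "average",
                            seed = 1L) {
  seed <- as.integer(seed)
  generator$seed <- seed
  model$seed <- seed + 1000L
  structure(list(generator = generator, model = model,
                 qc_cutoff = qc_cutoff, qc_p = qc_p,
                 tau_nM = tau_nM, goal_kd_nM = goal_kd_nM,
                 dose_pair = dose_pair,
                 promiscuity_rule = promiscuity_rule,
                 promiscuity_threshold = promiscuity_threshold,
                 promiscuity_k = promiscuity_k,
                 cluster_k = cluster_k, min_overlap = min_overlap,
                 linkage = linkage, seed = seed),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  plain <- strip_classes(config)
  # named atomic vectors must become YAML maps, not bare sequences
  for (f in c("batch_map", "clinical_status_weights",
              "kinase_category_weights", "inhibitor_type_weights")) {
    plain$generator[[f]] <- as.list(plain$generator[[f]])
  }
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  gen <- raw$generator
  gen$batch_map <- unlist(gen$batch_map)
  gen$clinical_status_weights <- unlist(gen$clinical_status_weights)
  gen$kinase_category_weights <- unlist(gen$kinase_category_weights)
  gen$inhibitor_type_weights <- unlist(gen$inhibitor_type_weights)
  generator <- do.call(generator_config, gen)
  model <- do.call(model_config, raw$model)
  rest <- raw[setdiff(names(raw), c("generator", "model"))]
  cfg <- do.call(pipeline_config,
                 c(list(generator = generator, model = model), rest))
  # pipeline_config re-derives the stage seeds from `seed`; restore as read
  cfg$generator$seed <- raw$generator$seed
  cfg$model$seed <- raw$model$seed
  cfg
}

.write_stage <- function(df, run_dir, name, log) {
  path <- file.path(run_dir, name)
  utils::write.csv(df, path, row.names = FALSE)
  log(sprintf("wrote %s (%d rows)", name, nrow(df)))
  path
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> QC -> fit -> selectivity metrics -> kinome
#' analysis -> design evaluation -> clustering on a synthetic screen,
#' writing every intermediate as a plain CSV under `run_dir` together with
#' a manifest (configuration, seed, package version, configuration hash).
#' Rerunning with the same configuration reproduces every output
#' byte-for-byte (the sampler is seeded). A stage failure halts the
#' pipeline with an error; the outputs of completed stages remain on disk.
#'
#' @param config A [pipeline_config()].
#' @param run_dir Output directory (created if needed).
#' @return Invisibly, the named vector of written file paths.
#' @export
run_pipeline <- function(config, run_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  log <- function(msg) {
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  paths <- character(0)

  log("stage simulate")
  truth <- sample_ground_truth(config$generator)
  tab <- simulate_percent_control(truth, config$generator)
  fixture <- write_scanmax_fixture(tab, truth, run_dir)
  paths <- c(paths, fixture)

  log("stage qc")
  observed <- read_scanmax_table(fixture[["observed"]])
  dropouts <- utils::read.csv(fixture[["dropouts"]])
  observed <- exclude_dropouts(observed, dropouts)
  qc <- classify_curves(observed, cutoff = config$qc_cutoff,
                        p_thresh = config$qc_p)
  paths <- c(qc = .write_stage(qc, run_dir, "qc_labels.csv", log), paths)
  qs <- qc_summary(qc)
  paths <- c(qc_summary = .write_stage(qs$class_fractions, run_dir,
                                       "qc_class_fractions.csv", log), paths)

  log("stage fit")
  est <- fit_curves(observed, qc_labels = qc, config = config$model)
  paths <- c(estimates = .write_stage(est, run_dir, "estimates.csv", log),
             paths)
  am <- affinity_matrix(est)
  paths <- c(matrix = write_affinity_matrix(am, file.path(run_dir, "affinity_matrix.csv")),
             paths)
  log("wrote affinity_matrix.csv")

  log("stage metrics")
  sel <- selectivity_table(am)
  paths <- c(selectivity = .write_stage(sel, run_dir, "selectivity.csv", log),
             paths)
  paths <- c(tas = .write_stage(tas_table(am), run_dir, "tas.csv", log), paths)

  log("stage analyze")
  for (tau in config$tau_nM) {
    cov <- coverage(am, tau)
    .write_stage(cov$per_kinase, run_dir,
                 sprintf("coverage_per_kinase_tau%g.csv", tau), log)
    .write_stage(cov$per_compound, run_dir,
                 sprintf("coverage_per_compound_tau%g.csv", tau), log)
  }
  cov100 <- coverage(am, 100)
  prom <- promiscuous_kinases(cov100, rule = config$promiscuity_rule,
                              threshold = config$promiscuity_threshold,
                              k = config$promiscuity_k)
  paths <- c(promiscuous = .write_stage(prom, run_dir, "promiscuous_kinases.csv", log),
             paths)
  kin <- truth$kinases
  counts <- cov100$per_kinase$n_compounds
  dark <- kin$dark[match(cov100$per_kinase$kinase_id, kin$kinase_id)]
  dfg <- kin$dfg_out_structure[match(cov100$per_kinase$kinase_id, kin$kinase_id)]
  comparisons <- dplyr::bind_rows(
    dplyr::mutate(group_compare(counts, ifelse(dark, "dark", "illuminated")),
                  comparison = "dark_vs_illuminated"),
    dplyr::mutate(group_compare(counts, ifelse(dfg, "dfg_out", "no_dfg_out")),
                  comparison = "dfg_out_vs_not"))
  paths <- c(groups = .write_stage(comparisons, run_dir, "group_comparisons.csv", log),
             paths)
  binders100 <- tas_table(am)
  binders100 <- binders100[binders100$tas == 1, c("kinase_id", "compound_id")]
  enr <- type2_enrichment(binders100,
                          truth$compounds[, c("compound_id", "inhibitor_type")])
  paths <- c(enrichment = .write_stage(enr, run_dir, "type2_enrichment.csv", log),
             paths)
  assigned <- tidyr::separate_rows(
    truth$compounds[!is.na(truth$compounds$assigned_targets),
                    c("compound_id", "assigned_targets")],
    "assigned_targets", sep = ";")
  names(assigned)[2] <- "kinase_id"
  ranks <- assigned_target_rank(am, assigned)
  paths <- c(ranks = .write_stage(ranks$ranks, run_dir, "assigned_target_ranks.csv", log),
             paths)
  trend <- selectivity_trend(
    sel$pi_max,
    truth$compounds$first_pub_year[match(sel$compound_id,
                                         truth$compounds$compound_id)])
  paths <- c(trend = .write_stage(trend, run_dir, "selectivity_trend.csv", log),
             paths)

  log("stage design")
  truth_kd_tbl <- tibble::tibble(
    compound_id = truth$pairs$compound_id,
    kinase_id = truth$pairs$kinase_id,
    kd_nM = 10^truth$pairs$true_log10_kd)
  grids <- list()
  for (dose in config$generator$doses) {
    sd_poc <- observed[observed$concentration_nM == dose,
                       c("compound_id", "kinase_id", "percent_control")]
    grid <- threshold_metrics(sd_poc, truth_kd_tbl, config$goal_kd_nM,
                              screening_dose_nM = dose)
    grid$screening_dose_nM <- dose
    grids[[as.character(dose)]] <- grid
  }
  all_grids <- dplyr::bind_rows(grids)
  paths <- c(thresholds = .write_stage(all_grids, run_dir, "threshold_grids.csv", log),
             paths)
  lookup <- dplyr::bind_rows(lapply(grids, function(g) {
    row <- optimal_cutoff(g)
    row$screening_dose_nM <- g$screening_dose_nM[1]
    row$goal_kd_nM <- config$goal_kd_nM
    row
  }))
  paths <- c(lookup = .write_stage(lookup, run_dir, "cutoff_lookup.csv", log),
             paths)
  est2 <- fit_two_dose(observed, config$dose_pair, qc_labels = qc,
                       config = config$model)
  paths <- c(two_dose = .write_stage(est2, run_dir, "estimates_two_dose.csv", log),
             paths)
  agree <- compare_two_vs_four(est2, est)
  agree$f1_multi_dose <- as.numeric(
    f1_binder_classification(est, truth_kd_tbl, config$goal_kd_nM))
  paths <- c(agreement = .write_stage(agree, run_dir, "two_vs_four_agreement.csv", log),
             paths)

  log("stage cluster")
  d <- spearman_distance(am, min_overlap = config$min_overlap)
  .write_stage(as.data.frame(d), run_dir, "spearman_distance.csv", log)
  k_eff <- min(config$cluster_k, sum(rowSums(is.na(d)) == 0))
  cl <- cluster_profiles(d, k = k_eff, linkage = config$linkage)
  labels_df <- tibble::tibble(kinase_id = names(cl$labels),
                              cluster = unname(cl$labels))
  paths <- c(clusters = .write_stage(labels_df, run_dir, "cluster_labels.csv", log),
             paths)
  groups_v <- stats::setNames(kin$group, kin$kinase_id)
  comp <- cluster_vs_group(cl$labels, groups_v)
  .write_stage(as.data.frame(comp$contingency), run_dir,
               "cluster_vs_group.csv", log)
  .write_stage(tibble::tibble(ari = comp$ari, n = comp$n, k = k_eff),
               run_dir, "cluster_agreement.csv", log)

  manifest <- list(
    package = "kinomescanr",
    version = as.character(utils::packageVersion("kinomescanr")),
    seed = config$seed,
    config_hash = rlang::hash(unclass(config)),
    config = strip_classes(config)
  )
  jsonlite::write_json(manifest, file.path(run_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(log_lines, file.path(run_dir, "log.txt"))
  invisible(paths)
}

#' Summarise a completed pipeline run
#'
#' Reads the stage outputs of a run directory and assembles a tabular
#' summary of the headline analyses: QC class fractions, coverage,
#' the PI_max distribution, the chemical-probe list, the single-dose
#' cutoff look-up, two-dose vs four-dose agreement, and cluster sizes.
#' Missing stage outputs are listed as absent rather than failing.
#' Regenerating the report for an unchanged run directory gives identical
#' output.
#'
#' @param run_dir Directory written by [run_pipeline()].
#' @return A list of class `pipeline_report` (also written to
#'   `report.txt` inside `run_dir`).
#' @export
pipeline_report <- function(run_dir) {
  get <- function(name) {
    p <- file.path(run_dir, name)
    if (file.exists(p)) utils::read.csv(p) else NULL
  }
  qc <- get("qc_class_fractions.csv")
  sel <- get("selectivity.csv")
  cov <- get("coverage_per_kinase_tau100.csv")
  lookup <- get("cutoff_lookup.csv")
  agree <- get("two_vs_four_agreement.csv")
  clusters <- get("cluster_labels.csv")

  sections <- list(
    qc_class_fractions = qc %||% "absent",
    coverage_per_kinase_tau100 = if (is.null(cov)) "absent" else
      summary(cov$n_compounds),
    pi_max_summary = if (is.null(sel)) "absent" else
      summary(sel$pi_max[is.finite(sel$pi_max)]),
    chemical_probes = if (is.null(sel)) "absent" else
      sel$compound_id[which(sel$probe == TRUE | sel$probe == "TRUE")],
    cutoff_lookup = lookup %||% "absent",
    two_vs_four_agreement = agree %||% "absent",
    cluster_sizes = if (is.null(clusters)) "absent" else
      as.data.frame(table(cluster = clusters$cluster))
  )
  out <- structure(sections, class = "pipeline_report")
  txt <- utils::capture.output(print(out))
  writeLines(txt, file.path(run_dir, "report.txt"))
  out
}

#' @export
print.pipeline_report <- function(x, ...) {
  for (nm in names(x)) {
    cat("==", nm, "==\n")
    print(x[[nm]])
    cat("\n")
  }
  invisible(x)
}
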