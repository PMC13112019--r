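# End-to-end orchestration: synthetic (or user-supplied) cohort -> group
# behavior comparison -> NBS -> CPM -> mediation, with flat-file outputs
# and a reproducibility manifest.

#' Welch two-sample comparison of the behavioral score
#'
#' Welch t-test of the behavior column between the two groups, with group
#' descriptives.
#'
#' @param manifest data.frame with at least the `group` and behavior
#'   columns.
#' @param behavior behavior column name (default `"wis"`).
#' @param group group column name (default `"group"`).
#' @return list with `t`, `df`, `p` and a `descriptives` data.frame
#'   (group, n, mean, sd).
#' @export
group_compare_behavior <- function(manifest, behavior = "wis", group = "group") {
  for (col in c(behavior, group)) {
    if (!col %in% names(manifest)) stop("manifest is missing column '", col, "'")
  }
  y <- manifest[[behavior]]
  g <- as.factor(manifest[[group]])
  if (nlevels(g) != 2) stop("need exactly two groups")
  if (anyNA(y)) stop("behavior column contains missing values")
  tt <- stats::t.test(y ~ g)
  desc <- do.call(rbind, lapply(levels(g), function(lev) {
    v <- y[g == lev]
    data.frame(group = lev, n = length(v), mean = mean(v), sd = stats::sd(v))
  }))
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       descriptives = desc)
}

#' Welch t-test from summary statistics
#'
#' Audit helper: computes the Welch t statistic, Satterthwaite degrees of
#' freedom and two-tailed p-value from per-group n, mean and SD alone, so
#' printed cohort tables can be checked without subject-level data.
#'
#' @param n1,mean1,sd1 first group summary.
#' @param n2,mean2,sd2 second group summary.
#' @return list with `t`, `df`, `p`.
#' @examples
#' welch_from_summary(25, 71.57, 16.25, 35, 107.07, 11.23)$p  # << 0.001
#' @export
welch_from_summary <- function(n1, mean1, sd1, n2, mean2, sd2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  se2 <- sd1^2 / n1 + sd2^2 / n2
  t <- (mean1 - mean2) / sqrt(se2)
  df <- se2^2 / ((sd1^2 / n1)^2 / (n1 - 1) + (sd2^2 / n2)^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Pipeline configuration
#'
#' Assembles the run configuration, either programmatically or from a
#' YAML file with the same field names.
#'
#' @param out_dir output directory for all stage artifacts.
#' @param seed global seed; stage seeds derive from it.
#' @param synth list of [cohort_spec()] arguments (the cohort seed is the
#'   global seed unless given); set `route = "timeseries"` (default) or
#'   `"matrix"`.
#' @param input optional list with `z_edges` (TSV path) and `manifest`
#'   (CSV path) to analyze user data instead of a synthetic cohort.
#' @param nbs list of [nbs_config()] arguments.
#' @param cpm list of [cpm_config()] arguments.
#' @param mediation list: `n_boot`, `standardize`, `exposures`
#'   (default hemoglobin and rdw).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, synth = list(), input = NULL,
                            nbs = list(), cpm = list(),
                            mediation = list()) {
  med <- utils::modifyList(list(n_boot = 1000L, standardize = FALSE,
                                exposures = c("hemoglobin", "rdw")),
                           mediation)
  structure(list(out_dir = out_dir, seed = as.integer(seed), synth = synth,
                 input = input, nbs = nbs, cpm = cpm, mediation = med),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file.
#' @return `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

validate_manifest <- function(manifest, need = c("subject_id", "group", "wis")) {
  missing <- setdiff(need, names(manifest))
  if (length(missing)) {
    stop("manifest is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  invisible(manifest)
}

#' Run the full analysis pipeline
#'
#' Stages, in order: cohort (synthetic generation or user input),
#' functional connectivity (when time series are present), behavioral
#' group comparison, NBS, CPM (cross-validation + permutation test +
#' degree table + group-wise evaluation), and mediation for each
#' configured exposure using the mean Fisher-z over the CPM consensus
#' positive network as mediator (patients only). Each stage writes flat
#' files under `out_dir`; a machine-readable run manifest records the
#' package version, seed and config hash. Outputs are deterministic given
#' the seed.
#'
#' @param config a [pipeline_config()] or path to a YAML file.
#' @return invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(config$seed, 6L)
  atlas <- tryCatch(load_atlas(), error = function(e) NULL)

  # -- stage: cohort ---------------------------------------------------------
  if (!is.null(config$input)) {
    for (f in c(config$input$z_edges, config$input$manifest)) {
      if (!file.exists(f)) stop("input file does not exist: ", f)
    }
    z <- as.matrix(utils::read.table(config$input$z_edges, sep = "\t"))
    dimnames(z) <- NULL
    manifest <- utils::read.csv(config$input$manifest, stringsAsFactors = FALSE)
    validate_manifest(manifest)
    cohort <- NULL
    n_regions <- as.integer(round((1 + sqrt(1 + 8 * ncol(z))) / 2))
    message("stage cohort: loaded ", nrow(z), " subjects from input files")
  } else {
    synth_args <- config$synth
    route <- synth_args$route %||% "timeseries"
    synth_args$route <- NULL
    if (is.null(synth_args$seed)) synth_args$seed <- config$seed
    spec <- do.call(cohort_spec, synth_args)
    cohort <- if (route == "timeseries") generate_timeseries_cohort(spec)
              else generate_matrix_cohort(spec)
    cohort <- generate_behavior(spec, cohort)
    cohort <- generate_hematology(spec, cohort)
    z <- cohort$z
    manifest <- cohort$manifest
    n_regions <- spec$n_regions
    write_cohort(list(z = z, manifest = manifest, ground_truth = spec,
                      timeseries = NULL) |>
                   structure(class = "synthetic_cohort"),
                 file.path(out, "cohort"))
    message("stage cohort: generated ", nrow(z), " subjects (", route,
            " route)")
  }
  validate_manifest(manifest)
  groups <- factor(manifest$group, levels = c("patient", "control"))
  if (anyNA(groups)) stop("manifest group column must be 'patient'/'control'")

  # -- stage: behavioral group comparison ------------------------------------
  beh <- group_compare_behavior(manifest)
  jsonlite::write_json(list(t = beh$t, df = beh$df, p = beh$p,
                            descriptives = beh$descriptives),
                       file.path(out, "behavior_group_test.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  message(sprintf("stage behavior: Welch t = %.2f, p = %.3g", beh$t, beh$p))

  # -- stage: NBS ------------------------------------------------------------
  nbs_args <- config$nbs
  if (is.null(nbs_args$seed)) nbs_args$seed <- seeds[[2]]
  nbs_cfg <- do.call(nbs_config, nbs_args)
  nbs_res <- run_nbs(z, groups, nbs_cfg, n_regions = n_regions)
  write_nbs_result(nbs_res, out, atlas = atlas)
  message("stage nbs: ", length(nbs_res$sizes), " component(s)",
          if (length(nbs_res$sizes))
            paste0(", largest ", nbs_res$sizes[1], " edges (corrected p = ",
                   signif(nbs_res$corrected_p[1], 3), ")") else "")

  # -- stage: CPM ------------------------------------------------------------
  cpm_args <- config$cpm
  if (is.null(cpm_args$seed)) cpm_args$seed <- seeds[[3]]
  cpm_cfg <- do.call(cpm_config, cpm_args)
  cpm_perm <- permutation_test(z, manifest$wis, cpm_cfg, groups = groups)
  model <- cpm_perm$model
  deg <- degree_table(model$consensus_positive, n_regions, atlas = atlas)
  strength_pos <- network_strength(z, model$consensus_positive)
  gw <- if (length(model$consensus_positive)) {
    groupwise_evaluation(strength_pos, manifest$wis, groups)
  } else NULL
  if (length(model$consensus_positive)) {
    write_edge_table(rep(1, length(model$consensus_positive)),
                     model$consensus_positive, n_regions,
                     file.path(out, "cpm_consensus_positive.tsv"),
                     atlas = atlas, value_name = "selected")
  }
  utils::write.csv(deg, file.path(out, "cpm_degree_table.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(subject_id = manifest$subject_id,
                              observed = manifest$wis,
                              model$predictions),
                   file.path(out, "cpm_predictions.csv"), row.names = FALSE)
  utils::write.table(as.data.frame(cpm_perm$null),
                     file.path(out, "cpm_null_r.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(
    performance_r = as.list(model$performance$r),
    performance_r_raw = as.list(model$performance$r_raw),
    permutation_p = as.list(cpm_perm$p),
    n_consensus_positive = length(model$consensus_positive),
    n_consensus_negative = length(model$consensus_negative),
    groupwise = gw,
    config = model$config[c("select_alpha", "cv", "k", "n_permutations",
                            "negative_r_to_zero")],
    seed = model$config$seed),
    file.path(out, "cpm_summary.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  message(sprintf(
    "stage cpm: positive r = %.3f (p = %.3g), consensus %d edge(s)",
    model$performance$r["positive"], cpm_perm$p["positive"],
    length(model$consensus_positive)))

  # -- stage: mediation ------------------------------------------------------
  med_results <- list()
  pat <- manifest$group == "patient"
  mediator <- if (length(model$consensus_positive)) {
    network_strength(z, model$consensus_positive) /
      length(model$consensus_positive)
  } else NULL
  covs <- manifest[, intersect(c("age", "sex", "brain_volume"),
                               names(manifest)), drop = FALSE]
  med_seeds <- derive_seeds(seeds[[4]], length(config$mediation$exposures))
  for (i in seq_along(config$mediation$exposures)) {
    exposure <- config$mediation$exposures[i]
    if (is.null(mediator)) {
      message("stage mediation: skipped (empty consensus network)")
      break
    }
    if (!exposure %in% names(manifest) || all(is.na(manifest[[exposure]][pat]))) {
      message("stage mediation: exposure ", exposure, " unavailable; skipped")
      next
    }
    res <- mediate(manifest[[exposure]][pat], mediator[pat],
                   manifest$wis[pat], covariates = covs[pat, , drop = FALSE],
                   n_boot = config$mediation$n_boot,
                   standardize = config$mediation$standardize,
                   seed = med_seeds[[i]])
    write_mediation_result(res, out, label = paste0("mediation_", exposure))
    med_results[[exposure]] <- res
    message(sprintf(
      "stage mediation (%s): indirect = %.3f, CI [%.3f, %.3f]",
      exposure, res$indirect, res$ci[1], res$ci[2]))
  }
  if (length(med_results) > 1) {
    fam <- vapply(med_results, function(r) r$paths["a", "p"], numeric(1))
    jsonlite::write_json(
      list(exposures = names(med_results), a_path_p = as.list(fam),
           a_path_p_fdr = as.list(fdr_adjust(fam))),
      file.path(out, "mediation_fdr.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }

  # -- run manifest ----------------------------------------------------------
  cfg_path <- file.path(out, "run_config.json")
  jsonlite::write_json(unclass(config), cfg_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  jsonlite::write_json(list(
    package = "connectopipe",
    version = as.character(utils::packageVersion("connectopipe")),
    seed = config$seed,
    config_hash = unname(tools::md5sum(cfg_path))),
    file.path(out, "run_manifest.json"), auto_unbox = TRUE, pretty = TRUE)

  invisible(list(cohort = cohort, behavior = beh, nbs = nbs_res,
                 cpm = model, cpm_permutation = cpm_perm,
                 mediation = med_results, out_dir = out))
}
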