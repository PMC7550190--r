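#' Pipeline configuration with study defaults
#'
#' Collects every tunable constant of the pipeline in one place. Thresholds
#' that have an established value keep it as the default: responsiveness
#' thresholds 0.2 (tectal) / 0.4 (RGC), minimum affinity-propagation
#' cluster size 5, minimum final cluster size 20 units (tectal) or 1% of
#' pixels (RGC), k = 10 (tectal) / 100 (RGC) nearest neighbors, penalty
#' grid 1e-5..1e-1, 1000 shuffles and 1000 null draws.
#'
#' @param seed Master RNG seed.
#' @param ... Overrides of any default field.
#' @return A `retinotype_config` list.
#' @export
retinotype_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = seed,
    sampling_rate = 2,
    kernel_variant = "nls_gcamp6s",
    tectal_threshold = 0.2,
    rgc_threshold = 0.4,
    ap_min_cluster = 5,
    tectal_min_final = 20,
    rgc_min_final_frac = 0.01,
    k_tectum = 10,
    k_rgc = 100,
    lambda_grid = lambda_grid_default(),
    n_shuffles = 1000,
    n_null_draws = 1000,
    n_rgc_per_cluster = 30,
    n_tectal_units = 200,
    rgc_noise_sigma = 0.05,
    tectal_noise_sigma = 0.1,
    out_dir = NULL)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("configuration error: unknown fields ",
         paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "retinotype_config")
}

config_hash <- function(cfg) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  yaml::write_yaml(unclass(cfg), f)
  unname(tools::md5sum(f))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage ", name, ": ", conditionMessage(e), call. = FALSE))
}

#' Run the full synthetic-data pipeline
#'
#' Simulate -> score -> cluster -> decompose, end to end on synthetic data
#' with known ground truth: builds the default protocol and regressors,
#' simulates RGC and tectal populations, scores and normalizes both,
#' clusters the RGC population (silhouette-selected threshold), forms the
#' RGC cluster average matrix, and fits the non-negative L1 decomposition
#' of every tectal unit. When `config$out_dir` is set, writes score,
#' label, and decomposition CSVs plus a YAML run manifest (config hash,
#' seed, versions).
#'
#' @param config A `retinotype_config`.
#' @return Invisible list with `regressors`, `rgc`, `tectum`,
#'   `rgc_scores`, `tectal_scores`, `clustering`, `rgc_matrix`,
#'   `decomposition`, `ground_truth`, `manifest`.
#' @export
run_full_pipeline <- function(config = retinotype_config()) {
  stopifnot(inherits(config, "retinotype_config"))
  reg <- stage("stimulus", {
    proto <- build_default_protocol(config$sampling_rate)
    kern <- make_kernel(config$kernel_variant, config$sampling_rate)
    build_regressors(proto, kern)
  })
  rgc <- stage("simulate_rgc", simulate_rgc_population(
    reg, n_per_cluster = config$n_rgc_per_cluster,
    noise_sigma = config$rgc_noise_sigma, seed = config$seed + 1L))
  tect <- stage("simulate_tectum", simulate_tectal_population(
    reg, n_units = config$n_tectal_units,
    noise_sigma = config$tectal_noise_sigma, seed = config$seed + 2L))
  rgc_sc <- stage("score_rgc", {
    sc <- score_population(rgc$trials, reg, presmooth = TRUE)
    norm <- normalize_scores(sc$scores)
    list(raw = sc, normalized = norm$scores, factors = norm$factors)
  })
  clus <- stage("cluster_rgc", cluster_scores(
    rgc_sc$normalized, mode = "rgc",
    max_score_threshold = config$rgc_threshold,
    min_cluster_size = config$ap_min_cluster))
  rgc_mat <- stage("rgc_matrix", rgc_cluster_matrix(
    clus$labels, rgc_sc$normalized, rgc$trials))
  tect_sc <- stage("score_tectum", {
    per_trial <- lapply(tect$trials, function(m)
      score_population(list(m), reg, presmooth = TRUE))
    sc <- score_population(tect$trials, reg, presmooth = TRUE)
    norm <- normalize_scores(sc$scores)
    f <- norm$factors[[1]]
    list(raw = sc, normalized = norm$scores, factors = norm$factors,
         trial_scores = lapply(per_trial, function(p) p$scores / f))
  })
  mean_trace <- Reduce(`+`, tect$trials) / length(tect$trials)
  decomp <- stage("decompose", decompose_units(
    tect_sc$normalized, rgc_mat, traces = mean_trace,
    trial_scores = tect_sc$trial_scores,
    lambda_grid = config$lambda_grid))
  manifest <- list(
    config_hash = config_hash(config),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("retinotype")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    n_rgc_units = nrow(rgc_sc$normalized),
    n_tectal_units = nrow(tect_sc$normalized),
    n_rgc_clusters = clus$model$n_clusters,
    distance_threshold = clus$threshold)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    w <- function(x, f) utils::write.csv(
      x, file.path(config$out_dir, f), row.names = FALSE)
    w(as.data.frame(rgc_sc$normalized), "rgc_scores.csv")
    w(data.frame(unit = seq_along(clus$labels), label = clus$labels),
      "rgc_labels.csv")
    w(as.data.frame(tect_sc$normalized), "tectal_scores.csv")
    w(decomp, "decomposition.csv")
    yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))
  }
  invisible(list(regressors = reg, rgc = rgc, tectum = tect,
                 rgc_scores = rgc_sc, tectal_scores = tect_sc,
                 clustering = clus, rgc_matrix = rgc_mat,
                 decomposition = decomp,
                 ground_truth = tect$ground_truth, manifest = manifest))
}
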