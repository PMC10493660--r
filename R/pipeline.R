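#' Run the full SCN analysis pipeline from a single configuration
#'
#' Orchestrates simulate/load -> homologue flip -> covariate residualization
#' -> density grid (optionally truncated by the reference group's
#' small-worldness) -> permutation comparison, writing result tables and a
#' reproducibility manifest to `out_dir`.
#'
#' `config` is a named list (or path to a YAML file with the same keys):
#' \describe{
#'   \item{simulate}{list of [scn_sim_config()] arguments; when present the
#'     dataset is generated and written under `out_dir/sim/`.}
#'   \item{thickness, covariates}{paths to TSV tables (used when `simulate`
#'     is absent).}
#'   \item{flip_subjects, homologues}{optional: path to a file with one
#'     subject id per line, and to a homologue-map TSV; listed subjects get
#'     their left/right ROI values swapped before analysis.}
#'   \item{grid}{list with `step` (default 0.01), `d_max` (0.47),
#'     `sigma_min` (`NULL` to skip sigma-bounded truncation), `sigma_n_random`.}
#'   \item{metrics, n_perm, alpha, seed}{passed to [scn_compare()]; defaults
#'     5000 permutations, alpha 0.05.}
#' }
#'
#' @param config named list or YAML file path.
#' @param out_dir output directory (overrides `config$out_dir`).
#' @return the manifest, invisibly.
#' @export
run_scn_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config)
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the yaml package")
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  out_dir <- out_dir %||% config$out_dir
  if (is.null(out_dir)) stop("config must provide out_dir")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  seed <- as.integer(config$seed %||% 1L)
  stage <- function(name, expr) {
    message(sprintf("[scnet] stage %s", name))
    tryCatch(force(expr),
             error = function(e)
               stop(sprintf("pipeline failed at stage '%s': %s", name,
                            conditionMessage(e)), call. = FALSE))
  }

  # validate referenced inputs before any computation
  if (is.null(config$simulate)) {
    for (key in c("thickness", "covariates")) {
      if (is.null(config[[key]]))
        stop("config must provide 'simulate' or paths 'thickness' and 'covariates'")
      if (!file.exists(config[[key]]))
        stop(sprintf("input file for '%s' not found: %s", key, config[[key]]))
    }
  }
  for (key in c("flip_subjects", "homologues"))
    if (!is.null(config[[key]]) && !file.exists(config[[key]]))
      stop(sprintf("input file for '%s' not found: %s", key, config[[key]]))

  if (!is.null(config$simulate)) {
    dataset <- stage("simulate", {
      sim_args <- config$simulate
      sim_args$seed <- NULL
      cfg <- do.call(scn_sim_config, c(sim_args, list(seed = seed)))
      scn_simulate(cfg)
    })
    write_scn_dataset(dataset, file.path(out_dir, "sim"))
    thickness <- dataset$thickness
    covariates <- dataset$covariates
  } else {
    thickness <- stage("load", read_thickness_tsv(config$thickness))
    covariates <- stage("load", read_covariates_tsv(config$covariates))
  }

  if (!is.null(config$flip_subjects)) {
    thickness <- stage("flip", {
      ids <- readLines(config$flip_subjects, warn = FALSE)
      ids <- ids[nzchar(ids)]
      map <- if (!is.null(config$homologues))
        read_homologue_map_tsv(config$homologues)
      else default_homologue_map(thickness$roi_labels)
      flip_homologues(thickness, ids, map)
    })
  }

  resid <- stage("residualize", residualize(thickness, covariates))
  dir.create(file.path(out_dir, "prep"), showWarnings = FALSE)
  write_thickness_tsv(resid, file.path(out_dir, "prep",
                                       "thickness_residualized.tsv"))

  gcfg <- config$grid %||% list()
  grid <- stage("grid", {
    g <- density_grid(length(resid$roi_labels),
                      d_max = gcfg$d_max %||% 0.47,
                      step = gcfg$step %||% 0.01)
    if (!is.null(gcfg$sigma_min)) {
      ref_cov <- scn_covariance(resid, group = levels(resid$group)[1])
      g <- sigma_bounded_dmax(ref_cov, g, sigma_min = gcfg$sigma_min,
                              n_random = gcfg$sigma_n_random %||% 100,
                              seed = seed)
    }
    g
  })

  cmp <- stage("infer", scn_compare(
    resid, grid = grid,
    metrics = config$metrics %||% c("eglob", "eloc", "cp", "lp",
                                    "degree", "betweenness",
                                    "nodal_efficiency"),
    n_perm = config$n_perm %||% 5000,
    alpha = config$alpha %||% 0.05,
    seed = seed,
    sigma_n_random = gcfg$sigma_n_random %||% 100,
    keep_null = "none"))

  dir.create(file.path(out_dir, "infer"), showWarnings = FALSE)
  res_path <- file.path(out_dir, "infer", "results.tsv")
  write.table(cmp$results, res_path, sep = "\t", quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8")

  # tidy global metric-versus-density curves: group, density, metric, value
  curves <- do.call(rbind, lapply(names(cmp$curves), function(g) {
    cm <- cmp$curves[[g]]
    keep <- colnames(cm)[colSums(!is.na(cm)) > 0]
    do.call(rbind, lapply(keep, function(m)
      data.frame(group = g, density = grid$densities, metric = m,
                 value = cm[, m], stringsAsFactors = FALSE)))
  }))
  curves_path <- file.path(out_dir, "infer", "global_curves.tsv")
  write.table(curves, curves_path, sep = "\t", quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8")

  outputs <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  outputs <- setdiff(outputs, file.path(out_dir, "manifest.json"))
  manifest <- list(
    package = "scnet",
    version = as.character(packageVersion("scnet")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config,
    density_grid = grid$densities,
    checksums = as.list(tools::md5sum(outputs)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
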