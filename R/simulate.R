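#' Configuration for the synthetic two-group thickness generator
#'
#' Defines a latent-factor model of inter-ROI structural covariance. ROIs are
#' split into `n_factors` contiguous communities; subject thickness for ROI i
#' is
#' \deqn{x_{si} = \mu_i + \sigma (\lambda_i z_{s f(i)} +
#'       \sqrt{1-\lambda_i^2}\,\epsilon_{si}) + \beta^T c_s}
#' with per-ROI baseline \eqn{\mu_i}, subject factor scores z, total
#' morphometric fluctuation \eqn{\sigma} (`noise_sd`, mm) and loading
#' \eqn{\lambda_i} on the correlation scale, so the within-community ROI-ROI
#' correlation is `factor_loading^2`. Group 2 subjects get `deficit_mm`
#' subtracted on the deficit ROIs (a localized thinning) and
#' `hub_loading_delta` added to the loadings of the planted hub ROIs (raising
#' those ROIs' covariance with their community, i.e. planting a nodal network
#' difference). A clinical pain score for group-2 subjects is constructed to
#' correlate `clinical_target_r` with the structural component of mean
#' deficit-ROI thickness.
#'
#' Defaults emulate a two-group cortical-thickness study: 45 subjects per
#' group, 360 atlas ROIs, a sensorimotor thickness deficit with a pain score
#' correlated at -0.533, demographics with age about 45 +/- 9 years,
#' education about 7.5 +/- 4.3 years and roughly one quarter female.
#'
#' @param n_per_group subjects per group (>= 4).
#' @param n_rois number of atlas ROIs (>= n_factors).
#' @param n_factors number of latent covariance communities.
#' @param factor_loading loading in `[0, 1]`; within-community correlation is
#'   its square.
#' @param noise_sd total subject-to-subject fluctuation per ROI, mm.
#' @param base_thickness_mean,base_thickness_sd across-ROI distribution of
#'   baseline mean thickness, mm.
#' @param covariate_betas named numeric (`age`, `gender`, `education`),
#'   mm per unit of the centered covariate.
#' @param planted_hub_rois ROI indices whose loading is raised in group 2.
#' @param hub_loading_delta loading increment for planted hubs
#'   (`factor_loading + hub_loading_delta` must stay below 1).
#' @param deficit_rois ROI indices thinned in group 2.
#' @param deficit_mm group-2 mean thickness deficit on those ROIs, mm (>= 0).
#' @param clinical_target_r target correlation between the clinical score and
#'   mean deficit-ROI (structural) thickness, in (-1, 1).
#' @param seed master seed; per-stage substreams are derived from it.
#' @param prop_female proportion of gender == 1 subjects.
#' @param age_mean,age_sd,age_range,education_mean,education_sd,education_range
#'   truncated-normal demographics.
#' @return an object of class `scn_sim_config`.
#' @export
scn_sim_config <- function(n_per_group = 45, n_rois = 360, n_factors = 6,
                           factor_loading = 0.6, noise_sd = 0.15,
                           base_thickness_mean = 2.5, base_thickness_sd = 0.25,
                           covariate_betas = c(age = -0.005, gender = 0.05,
                                               education = 0.002),
                           planted_hub_rois = 8L, hub_loading_delta = 0.25,
                           deficit_rois = c(8L, 9L), deficit_mm = 0.1,
                           clinical_target_r = -0.533, seed = 1L,
                           prop_female = 0.25,
                           age_mean = 45, age_sd = 9, age_range = c(18, 70),
                           education_mean = 7.5, education_sd = 4.3,
                           education_range = c(0, 20)) {
  covariate_betas <- unlist(covariate_betas)
  cfg <- list(n_per_group = as.integer(n_per_group),
              n_rois = as.integer(n_rois), n_factors = as.integer(n_factors),
              factor_loading = factor_loading, noise_sd = noise_sd,
              base_thickness_mean = base_thickness_mean,
              base_thickness_sd = base_thickness_sd,
              covariate_betas = covariate_betas,
              planted_hub_rois = as.integer(planted_hub_rois),
              hub_loading_delta = hub_loading_delta,
              deficit_rois = as.integer(deficit_rois),
              deficit_mm = deficit_mm,
              clinical_target_r = clinical_target_r,
              seed = as.integer(seed), prop_female = prop_female,
              age_mean = age_mean, age_sd = age_sd, age_range = age_range,
              education_mean = education_mean, education_sd = education_sd,
              education_range = education_range)
  class(cfg) <- "scn_sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  bad <- function(field, why)
    stop(sprintf("invalid generator config: %s %s", field, why), call. = FALSE)
  if (cfg$n_per_group < 4) bad("n_per_group", "must be >= 4")
  if (cfg$n_factors < 1) bad("n_factors", "must be >= 1")
  if (cfg$n_rois < cfg$n_factors) bad("n_rois", "must be >= n_factors")
  if (cfg$factor_loading < 0 || cfg$factor_loading > 1)
    bad("factor_loading", "must lie in [0, 1]")
  if (cfg$noise_sd <= 0) bad("noise_sd", "must be positive")
  if (cfg$deficit_mm < 0) bad("deficit_mm", "must be >= 0")
  if (abs(cfg$clinical_target_r) >= 1)
    bad("clinical_target_r", "must satisfy |r| < 1")
  if (length(cfg$planted_hub_rois) &&
      (min(cfg$planted_hub_rois) < 1 || max(cfg$planted_hub_rois) > cfg$n_rois))
    bad("planted_hub_rois", "indices must lie in 1..n_rois")
  if (length(cfg$deficit_rois) &&
      (min(cfg$deficit_rois) < 1 || max(cfg$deficit_rois) > cfg$n_rois))
    bad("deficit_rois", "indices must lie in 1..n_rois")
  if (cfg$factor_loading + cfg$hub_loading_delta >= 1)
    bad("hub_loading_delta", "factor_loading + hub_loading_delta must be < 1")
  if (cfg$factor_loading + cfg$hub_loading_delta < 0)
    bad("hub_loading_delta", "resulting loading must be >= 0")
  if (!all(c("age", "gender", "education") %in% names(cfg$covariate_betas)))
    bad("covariate_betas", "must name age, gender and education")
  if (cfg$prop_female < 0 || cfg$prop_female > 1)
    bad("prop_female", "must lie in [0, 1]")
  invisible(cfg)
}

rtrunc_norm <- function(n, mean, sd, range) {
  lo <- pnorm(range[1], mean, sd)
  hi <- pnorm(range[2], mean, sd)
  qnorm(lo + runif(n) * (hi - lo), mean, sd)
}

default_roi_labels <- function(n_rois) {
  if (n_rois %% 2 == 0) {
    h <- n_rois / 2
    c(sprintf("L_ROI%03d", seq_len(h)), sprintf("R_ROI%03d", seq_len(h)))
  } else {
    sprintf("ROI_%03d", seq_len(n_rois))
  }
}

#' Simulate a two-group ROI thickness dataset with known ground truth
#'
#' Draws a dataset under the model described in [scn_sim_config()]. All
#' randomness is controlled by the config's master seed through per-stage
#' substreams; identical configs give identical datasets.
#'
#' @param config an [scn_sim_config()].
#' @return an object of class `scn_dataset`: list with `thickness`
#'   (a [thickness_table()] with groups `group1` = control-like and `group2`
#'   carrying the planted effects), `covariates` (a [covariate_table()]),
#'   `clinical` (per group-2 subject `plp`, `pls` pain/sensation scores on a
#'   0-10-style scale and `months_since_amputation`), and `truth` (planted
#'   structure and generating parameters).
#' @export
scn_simulate <- function(config) {
  stopifnot(inherits(config, "scn_sim_config"))
  validate_sim_config(config)
  cfg <- config
  n <- cfg$n_per_group
  N <- cfg$n_rois
  ntot <- 2L * n
  subject_id <- sprintf("sub%03d", seq_len(ntot))
  group <- factor(rep(c("group1", "group2"), each = n),
                  levels = c("group1", "group2"))
  roi_labels <- default_roi_labels(N)

  # stage 1: fixed structure (ROI baselines and community assignment)
  set.seed(stage_seed(cfg$seed, 1L))
  mu <- rnorm(N, cfg$base_thickness_mean, cfg$base_thickness_sd)
  factor_of <- if (cfg$n_factors == 1L) rep(1L, N) else
    as.integer(cut(seq_len(N), breaks = cfg$n_factors, labels = FALSE))

  # stage 2: demographics
  set.seed(stage_seed(cfg$seed, 2L))
  age <- rtrunc_norm(ntot, cfg$age_mean, cfg$age_sd, cfg$age_range)
  gender <- rbinom(ntot, 1L, cfg$prop_female)
  education <- rtrunc_norm(ntot, cfg$education_mean, cfg$education_sd,
                           cfg$education_range)

  # stage 3: thickness = baseline + structural (factor) part + covariates
  set.seed(stage_seed(cfg$seed, 3L))
  z <- matrix(rnorm(ntot * cfg$n_factors), ntot, cfg$n_factors)
  eps <- matrix(rnorm(ntot * N), ntot, N)
  lam <- matrix(cfg$factor_loading, ntot, N, byrow = TRUE)
  if (length(cfg$planted_hub_rois) && cfg$hub_loading_delta != 0) {
    g2 <- which(group == "group2")
    lam[g2, cfg$planted_hub_rois] <- cfg$factor_loading + cfg$hub_loading_delta
  }
  structural <- cfg$noise_sd *
    (lam * z[, factor_of, drop = FALSE] + sqrt(1 - lam^2) * eps)
  betas <- cfg$covariate_betas
  cov_shift <- betas[["age"]] * (age - cfg$age_mean) +
    betas[["gender"]] * (gender - 0.5) +
    betas[["education"]] * (education - cfg$education_mean)
  values <- matrix(mu, ntot, N, byrow = TRUE) + structural + cov_shift
  if (length(cfg$deficit_rois) && cfg$deficit_mm > 0) {
    g2 <- which(group == "group2")
    values[g2, cfg$deficit_rois] <- values[g2, cfg$deficit_rois] - cfg$deficit_mm
  }

  # stage 4: clinical scores for group 2, targeting the requested correlation
  # with the structural component of mean deficit-ROI thickness
  set.seed(stage_seed(cfg$seed, 4L))
  g2 <- which(group == "group2")
  target_rois <- if (length(cfg$deficit_rois)) cfg$deficit_rois else seq_len(N)
  struct_mean <- rowMeans(structural[g2, target_rois, drop = FALSE])
  zst <- as.numeric(scale(struct_mean))
  r <- cfg$clinical_target_r
  plp_latent <- r * zst + sqrt(1 - r^2) * rnorm(n)
  plp <- 3.93 + 2.72 * plp_latent
  pls <- 6.73 + 2.90 * rnorm(n)
  months <- rtrunc_norm(n, 25.3, 16.7, c(1, 120))

  thickness <- thickness_table(values, group, subject_id, roi_labels)
  covariates <- covariate_table(data.frame(
    subject_id = subject_id, age = age, gender = gender,
    education = education, stringsAsFactors = FALSE))
  clinical <- data.frame(subject_id = subject_id[g2], plp = plp, pls = pls,
                         months_since_amputation = months,
                         stringsAsFactors = FALSE)
  truth <- list(planted_hub_rois = cfg$planted_hub_rois,
                deficit_rois = cfg$deficit_rois,
                deficit_mm = cfg$deficit_mm,
                hub_loading_delta = cfg$hub_loading_delta,
                factor_of = factor_of,
                clinical_target_r = cfg$clinical_target_r,
                config = unclass(cfg))
  structure(list(thickness = thickness, covariates = covariates,
                 clinical = clinical, truth = truth),
            class = "scn_dataset")
}

#' @export
print.scn_dataset <- function(x, ...) {
  cat("scn_dataset\n")
  print(x$thickness)
  cat(sprintf("  planted hubs: %s; deficit ROIs: %s (%.3g mm)\n",
              paste(x$truth$planted_hub_rois, collapse = ","),
              paste(x$truth$deficit_rois, collapse = ","),
              x$truth$deficit_mm))
  invisible(x)
}

#' Write a simulated dataset to a directory of TSV/JSON files
#'
#' Writes `thickness.tsv`, `covariates.tsv`, `clinical.tsv` and `truth.json`.
#' @param dataset an `scn_dataset`.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_scn_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "scn_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_thickness_tsv(dataset$thickness, file.path(dir, "thickness.tsv"))
  write_covariates_tsv(dataset$covariates, file.path(dir, "covariates.tsv"))
  write.table(dataset$clinical, file.path(dir, "clinical.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  jsonlite::write_json(dataset$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read back the ground-truth record written by [write_scn_dataset()]
#' @param path path to `truth.json`.
#' @export
read_scn_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' @importFrom stats pnorm
NULL
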