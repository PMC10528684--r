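#' Pipeline configuration
#'
#' Bundles the sub-configurations of the full analysis pipeline:
#' generation, feature extraction, cleaning, psychometric and regression
#' fitting, and screening.
#'
#' @param generator a [generator_config()]
#' @param cleaning a [cleaning_thresholds()]
#' @param quadtree a [quadtree_params()]
#' @param n_participants simulated observers
#' @param trials_per_participant trials per observer
#' @param observer an [observer_model()] used for every simulated
#'   participant
#' @param planted_violations named counts passed to
#'   [simulate_experiment()]
#' @param lambda_grid ridge penalty grid
#' @param tail_fraction screening tail
#' @param n_boot bootstrap resamples for psychometric CIs
#' @param seed global pipeline seed
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(generator = generator_config(),
                            cleaning = cleaning_thresholds(),
                            quadtree = quadtree_params(),
                            n_participants = 30L,
                            trials_per_participant = 100L,
                            observer = observer_model(),
                            planted_violations = integer(),
                            lambda_grid = 10^seq(-4, 2, length.out = 25L),
                            tail_fraction = 0.05,
                            n_boot = 199L,
                            seed = 1L) {
  structure(list(generator = generator, cleaning = cleaning,
                 quadtree = quadtree,
                 n_participants = as.integer(n_participants),
                 trials_per_participant = as.integer(trials_per_participant),
                 observer = observer,
                 planted_violations = planted_violations,
                 lambda_grid = lambda_grid,
                 tail_fraction = tail_fraction,
                 n_boot = as.integer(n_boot),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

write_json_out <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, pretty = TRUE)
  invisible(path)
}

strip_fits <- function(x) {
  # lm objects carry environments; drop them before serialization
  if (is.list(x)) {
    x$fit <- NULL
    lapply(x, function(el) if (is.list(el)) strip_fits(el) else el)
  } else x
}

#' Run the full analysis pipeline
#'
#' Executes, in order: sequence generation, feature extraction and
#' standardization, experiment simulation, participant cleaning,
#' agreement aggregation and psychometric fitting, polynomial agreement
#' regression, confound ANOVA, feature-to-score and feature-to-alpha
#' regressions with a ridge cross-check, and the two percentile screens
#' plus the Fréchet profile.  Every stage's outputs are written to
#' `out_dir` before the next stage starts, and a manifest records the
#' configuration, package version, per-file MD5 digests and timestamps.
#' Re-running with the same configuration and seed reproduces identical
#' outputs (manifest timestamps aside).
#'
#' @param cfg a [pipeline_config()]
#' @param out_dir output directory (created if missing)
#' @param write_images also write every generated image as PNG (default
#'   `FALSE`; the images are regenerable from the configuration)
#' @return the manifest list, invisibly
#' @export
run_pipeline <- function(cfg = pipeline_config(), out_dir,
                         write_images = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = strip_fits(lapply(cfg, unclass)),
                   package_version = as.character(utils::packageVersion("aesthseq")),
                   started = format(Sys.time(), tz = "UTC"),
                   stages = list())
  gen <- cfg$generator
  gen$rng_seed <- cfg$seed
  record <- function(stage, files) {
    manifest$stages[[stage]] <<- list(
      files = as.list(stats::setNames(unname(tools::md5sum(files)),
                                      basename(files))),
      timestamp = format(Sys.time(), tz = "UTC"))
    write_json_out(manifest, file.path(out_dir, "manifest.json"))
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      write_json_out(manifest, file.path(out_dir, "manifest.json"))
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  # simulate: sequences + scores ------------------------------------------
  seqs <- run_stage("simulate", generate_dataset(gen))
  cfg_path <- file.path(out_dir, "generator_config.json")
  write_generator_config(gen, cfg_path)
  if (write_images)
    for (s in seqs) write_sequence_png(s, file.path(out_dir, "images"))
  record("simulate", cfg_path)

  # extract-features -------------------------------------------------------
  feats <- run_stage("extract_features",
                     extract_feature_table(seqs, cfg$quadtree))
  feats_std <- standardize_features(feats, "zscore", "global")
  fpath <- file.path(out_dir, "features.csv")
  utils::write.csv(feats_std, fpath, row.names = FALSE, quote = FALSE)
  record("extract_features", fpath)

  # behavioral simulation + cleaning ---------------------------------------
  models <- rep(list(cfg$observer), cfg$n_participants)
  trials <- run_stage("simulate_experiment",
                      simulate_experiment(models, gen,
                                          cfg$trials_per_participant,
                                          cfg$planted_violations,
                                          rng_seed = cfg$seed + 1L))
  tpath <- file.path(out_dir, "trials.csv")
  write_trials(trials, tpath)
  cleaned <- run_stage("clean", clean_participants(trials, cfg$cleaning))
  kpath <- file.path(out_dir, "trials_clean.csv")
  write_trials(cleaned$trials, kpath)
  rpath <- file.path(out_dir, "cleaning_report.json")
  write_json_out(cleaned$report, rpath)
  record("clean", c(tpath, kpath, rpath))

  # psychometric ------------------------------------------------------------
  agg <- run_stage("aggregate", aggregate_agreement(cleaned$trials))
  apath <- file.path(out_dir, "agreement.csv")
  utils::write.csv(agg$folded, apath, row.names = FALSE, quote = FALSE)
  psy <- run_stage("fit_psychometric",
                   fit_psychometric(cleaned$trials, n_boot = cfg$n_boot,
                                    boot_seed = cfg$seed + 2L))
  ppath <- file.path(out_dir, "psychometric.json")
  write_json_out(list(threshold_mu = psy$threshold_mu, slope_s = psy$slope_s,
                      guess_gamma = psy$guess_gamma,
                      lapse_lambda = psy$lapse_lambda,
                      ci = psy$ci, ci_level = psy$ci_level,
                      loglik = psy$loglik, n_trials = psy$n_trials), ppath)
  record("fit_psychometric", c(apath, ppath))

  # polynomial + ANOVA ------------------------------------------------------
  poly <- run_stage("polynomial",
                    fit_polynomial_agreement(agg$folded))
  qpath <- file.path(out_dir, "polynomial.json")
  write_json_out(strip_fits(poly), qpath)
  labels <- stats::setNames(broad_category_labels(category_ids(gen$n_categories)),
                            category_ids(gen$n_categories))
  anv <- run_stage("anova",
                   anova_confounds(cleaned$trials,
                                   unname(labels[cleaned$trials$category_id])))
  npath <- file.path(out_dir, "anova.json")
  write_json_out(anv, npath)
  record("polynomial_anova", c(qpath, npath))

  # feature models -----------------------------------------------------------
  # features without spread (possible at very small image sizes, where the
  # quadtree statistics are constant) cannot enter the regressions
  usable <- names(which(vapply(feats_std[.FEATURE_NAMES], stats::sd,
                               numeric(1)) > 0))
  reg_score <- run_stage("model_features",
                         fit_feature_regression(feats_std, "aesthetic_score",
                                                features = usable))
  reg_alpha <- fit_feature_regression(feats_std, "alpha", features = usable)
  ridge <- fit_ridge(feats_std, "aesthetic_score",
                     split_seed = cfg$seed + 3L,
                     lambda_grid = cfg$lambda_grid, features = usable)
  vc <- variance_contribution(feats_std, "colorfulness", "aesthetic_score",
                              features = usable)
  mpath <- file.path(out_dir, "feature_models.json")
  write_json_out(list(score_model = strip_fits(reg_score),
                      alpha_model = strip_fits(reg_alpha),
                      ridge = unclass(ridge),
                      colorfulness_alone = vc), mpath)
  record("model_features", mpath)

  # screens -------------------------------------------------------------------
  stable <- run_stage("screen", stable_feature_sequences(
    feats_std, tail_fraction = cfg$tail_fraction))
  downturn <- aesthetic_downturn_sequences(
    seqs, tail_fraction = cfg$tail_fraction)
  fid <- frechet_profile(seqs, params = cfg$quadtree)
  spath <- file.path(out_dir, "screens.json")
  write_json_out(list(stable = unclass(stable),
                      downturn = unclass(downturn),
                      frechet_profile = fid), spath)
  record("screen", spath)

  manifest$finished <- format(Sys.time(), tz = "UTC")
  write_json_out(manifest, file.path(out_dir, "manifest.json"))
  invisible(manifest)
}
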