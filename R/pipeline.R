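# Config-driven orchestration of the pipeline stages with a manifest
# for reproducibility. Stage seeds are derived deterministically from
# the single global seed.

# schema: top-level keys allowed in a pipeline config
pipeline_schema <- c("seed", "preset", "resolution", "voxel", "noise_sd",
                     "n_links", "fit", "assemble", "refine", "report",
                     "weights", "xl_threshold", "xl_sigma", "xl_cap",
                     "conn_slack", "conn_sigma")

# presets: desk-scale search budgets vs the reference workflow's
pipeline_presets <- list(
  desk = list(fit = list(n_starts = 400, n_opt_steps = 220,
                         max_fits = 100),
              assemble = list(n_configs = 200, n_steps = 5000),
              refine = list(n_steps = 2000)),
  `paper-scale` = list(fit = list(n_starts = 10000, n_opt_steps = 100,
                                  max_fits = 10000),
                       assemble = list(n_configs = 10000, n_steps = 60000),
                       refine = list(n_steps = 20000)))

#' Load and validate a pipeline configuration
#'
#' YAML or JSON; unknown top-level keys are rejected with field-level
#' messages. Preset values (`desk` or `paper-scale`) provide defaults
#' that explicit config values override.
#'
#' @param path config file (`NULL` for the preset defaults alone).
#' @param preset `"desk"` or `"paper-scale"`.
#' @param overrides named list of config overrides.
#' @return validated config list.
#' @export
load_config <- function(path = NULL, preset = "desk", overrides = list()) {
  cfg <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config not found: ", path)
    cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
           else yaml::read_yaml(path)
    bad <- setdiff(names(cfg), pipeline_schema)
    if (length(bad))
      stop("invalid config key(s): ", paste(bad, collapse = ", "),
           "; allowed: ", paste(pipeline_schema, collapse = ", "))
  }
  if (!is.null(cfg$preset)) preset <- cfg$preset
  preset <- match.arg(preset, names(pipeline_presets))
  base <- list(seed = 1, preset = preset, resolution = 28, voxel = 4,
               noise_sd = 0.05, n_links = 60,
               weights = c(em = 60, xl = 1, conn = 1, clash = 0.1),
               xl_threshold = 30, xl_sigma = 3, xl_cap = 9,
               conn_slack = 5, conn_sigma = 3)
  base <- modifyList(base, pipeline_presets[[preset]])
  cfg <- modifyList(base, cfg)
  modifyList(cfg, overrides)
}

#' Run a pipeline stage
#'
#' Subcommands: `"simulate"` (write the standard synthetic fixture),
#' `"fit"` (per-body global fitting), `"assemble"` (Monte Carlo
#' recombination), `"refine"` (continuous refinement of the best
#' configuration), `"report"` (crosslink satisfaction, coverage, FSC,
#' difference-map summaries). Every stage writes its artifacts plus a
#' manifest (parameters, derived seeds, input checksums) under
#' `out_dir`; deterministic stages rerun bit-identically from the same
#' manifest inputs.
#'
#' @param command one of `simulate`, `fit`, `assemble`, `refine`,
#'   `report`, or `all`.
#' @param out_dir output directory (created if needed).
#' @param config config file path or a list from [load_config()].
#' @param seed overrides the config seed when given.
#' @param preset `"desk"` or `"paper-scale"`.
#' @return list of artifact paths, invisibly.
#' @export
run_pipeline <- function(command = c("all", "simulate", "fit", "assemble",
                                     "refine", "report"),
                         out_dir, config = NULL, seed = NULL,
                         preset = "desk") {
  command <- match.arg(command)
  cfg <- if (is.list(config)) config else load_config(config, preset)
  if (!is.null(seed)) cfg$seed <- seed
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- if (command == "all")
    c("simulate", "fit", "assemble", "refine", "report") else command
  artifacts <- list()
  for (st in stages)
    artifacts[[st]] <- do.call(paste0("stage_", st),
                               list(cfg = cfg, out_dir = out_dir))
  invisible(artifacts)
}

# internal: write a stage manifest
write_manifest <- function(stage, cfg, out_dir, inputs = character(),
                           outputs = character()) {
  man <- list(stage = stage, parameters = cfg,
              stage_seed = run_seed(cfg$seed, match(stage, c(
                "simulate", "fit", "assemble", "refine", "report")) * 100),
              inputs = as.list(tools::md5sum(inputs[file.exists(inputs)])),
              outputs = as.list(basename(outputs)),
              package_version = as.character(utils::packageVersion("rigidem")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  path <- file.path(out_dir, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA)
  path
}

stage_simulate <- function(cfg, out_dir) {
  fx <- elongator_like_fixture(seed = cfg$seed,
                               resolution = cfg$resolution,
                               voxel = cfg$voxel, noise_sd = cfg$noise_sd,
                               n_links = cfg$n_links)
  p_truth <- file.path(out_dir, "truth.pdb")
  p_full <- file.path(out_dir, "map_full.mrc")
  p_scaf <- file.path(out_dir, "map_scaffold.mrc")
  p_xl <- file.path(out_dir, "crosslinks.tsv")
  p_poses <- file.path(out_dir, "true_poses.json")
  write_structure(fx$truth$model, p_truth)
  write_density(fx$map_full, p_full)
  write_density(fx$map_scaffold, p_scaf)
  write_crosslink_table(fx$crosslinks, p_xl)
  jsonlite::write_json(fx$truth$poses_true, p_poses, auto_unbox = TRUE,
                       digits = NA)
  saveRDS(fx, file.path(out_dir, "fixture.rds"))
  write_manifest("simulate", cfg, out_dir,
                 outputs = c(p_truth, p_full, p_scaf, p_xl, p_poses))
  list(truth = p_truth, map_full = p_full, map_scaffold = p_scaf,
       crosslinks = p_xl)
}

# internal: load the fixture written by stage_simulate
pipeline_fixture <- function(out_dir) {
  p <- file.path(out_dir, "fixture.rds")
  if (!file.exists(p))
    stop("missing input: ", p, " (run the simulate stage first)")
  readRDS(p)
}

stage_fit <- function(cfg, out_dir) {
  fx <- pipeline_fixture(out_dir)
  fx$map_full$resolution <- cfg$resolution
  types <- unique(fx$truth$body_types)
  paths <- character(0)
  for (i in seq_along(types)) {
    ty <- types[i]
    body_name <- names(fx$truth$body_types)[
      fx$truth$body_types == ty & grepl("_1$", names(fx$truth$body_types))][1]
    bm <- body_model(fx$ref_model, fx$truth$bodies[[body_name]])
    lib <- global_fit(bm, fx$map_full,
                      n_starts = cfg$fit$n_starts,
                      n_opt_steps = cfg$fit$n_opt_steps,
                      seed = run_seed(cfg$seed, 200 + i),
                      max_fits = cfg$fit$max_fits)
    p <- file.path(out_dir, paste0("fits_", ty, ".tsv"))
    write_fit_library(lib, p)
    paths <- c(paths, p)
  }
  write_manifest("fit", cfg, out_dir,
                 inputs = file.path(out_dir, "fixture.rds"),
                 outputs = paths)
  paths
}

# internal: per-body libraries (copies share their type's library)
pipeline_libs <- function(fx, out_dir) {
  libs <- list()
  for (nm in names(fx$truth$body_types)) {
    ty <- fx$truth$body_types[[nm]]
    p <- file.path(out_dir, paste0("fits_", ty, ".tsv"))
    if (!file.exists(p)) stop("missing input: ", p,
                              " (run the fit stage first)")
    libs[[nm]] <- read_fit_library(p)
  }
  libs
}

stage_assemble <- function(cfg, out_dir) {
  fx <- pipeline_fixture(out_dir)
  libs <- pipeline_libs(fx, out_dir)
  configs <- sample_configurations(libs, fx$ref_model, fx$truth$bodies,
                                   fx$crosslinks,
                                   n_configs = cfg$assemble$n_configs,
                                   n_steps = cfg$assemble$n_steps,
                                   weights = cfg$weights,
                                   xl_threshold = cfg$xl_threshold,
                                   xl_sigma = cfg$xl_sigma,
                                   xl_cap = cfg$xl_cap,
                                   conn_slack = cfg$conn_slack,
                                   conn_sigma = cfg$conn_sigma,
                                   seed = run_seed(cfg$seed, 300))
  p_best <- file.path(out_dir, "best_configuration.json")
  write_configuration(configs[[1]], p_best)
  log <- data.frame(run = vapply(configs, function(cf) cf$run, 0L),
                    total = vapply(configs, function(cf) cf$score$total, 0))
  p_log <- file.path(out_dir, "assemble_runs.tsv")
  write.table(log, p_log, sep = "\t", quote = FALSE, row.names = FALSE)
  write_manifest("assemble", cfg, out_dir,
                 inputs = file.path(out_dir, "fixture.rds"),
                 outputs = c(p_best, p_log))
  list(best = p_best, log = p_log)
}

stage_refine <- function(cfg, out_dir) {
  fx <- pipeline_fixture(out_dir)
  fx$map_full$resolution <- cfg$resolution
  best <- read_configuration(file.path(out_dir, "best_configuration.json"))
  refined <- refine_continuous(best, fx$map_full, fx$ref_model,
                               fx$truth$bodies, fx$crosslinks,
                               n_steps = cfg$refine$n_steps,
                               weights = cfg$weights,
                               seed = run_seed(cfg$seed, 400))
  p_ref <- file.path(out_dir, "refined_configuration.json")
  write_configuration(refined, p_ref)
  model <- rebuild_full_model(refined, fx$ref_model, fx$truth$bodies)
  p_pdb <- file.path(out_dir, "refined_model.pdb")
  write_structure(model, p_pdb)
  write_manifest("refine", cfg, out_dir, outputs = c(p_ref, p_pdb))
  list(config = p_ref, model = p_pdb)
}

stage_report <- function(cfg, out_dir) {
  fx <- pipeline_fixture(out_dir)
  cfg_path <- file.path(out_dir, "refined_configuration.json")
  if (!file.exists(cfg_path))
    cfg_path <- file.path(out_dir, "best_configuration.json")
  config <- read_configuration(cfg_path)
  model <- rebuild_full_model(config, fx$ref_model, fx$truth$bodies)
  sat <- satisfaction_report(model, fx$crosslinks,
                             threshold = cfg$xl_threshold)
  net <- crosslink_network_summary(fx$crosslinks)
  beads <- coarse_grain(model)
  cover <- volume_coverage(fx$map_full, beads, radius_scale = 1.5)
  diff <- difference_map(fx$map_full, fx$map_scaffold)
  errs <- assignment_errors(config, fx$truth)
  rep <- list(satisfaction = sat[c("n_satisfied", "n_mapped", "fraction",
                                   "text")],
              network = net[c("n_inter", "n_intra", "n_dimeric")],
              volume_coverage = cover,
              max_centroid_error = max(errs$trans_err),
              difference_map_peak = as.numeric(
                which(diff$values == max(diff$values), arr.ind = TRUE)[1, ]))
  p <- file.path(out_dir, "report.json")
  jsonlite::write_json(rep, p, auto_unbox = TRUE, digits = NA)
  write_manifest("report", cfg, out_dir, outputs = p)
  p
}
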