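#' Experiment configuration for the staged pipeline
#'
#' Declarative description of a full end-to-end run: stimulus space,
#' trial construction, synthetic observer, network training and analysis.
#' Presets: `"reduced"` (the desk-scale developmental experiment) and
#' `"tiny"` (seconds-scale, for smoke tests and examples). `"full"`
#' matches the published protocol scale (13^3 x 10 images, (1500, 1000),
#' 200 epochs) and is cluster-sized; it is provided for completeness.
#'
#' @param scale `"tiny"`, `"reduced"` or `"full"`.
#' @param seed global seed; all stage seeds derive from it.
#' @return Nested config list of class `experiment_config`.
#' @export
experiment_config <- function(scale = c("tiny", "reduced", "full"),
                              seed = 1) {
  scale <- match.arg(scale)
  base <- switch(scale,
    tiny = list(
      stimulus = list(n_range = c(5, 12), k = 5,
                      size_range = c(2.6e5, 10.4e5) / 128,
                      spacing_range = c(0.8e7, 3.2e7) / 128,
                      instances = 3, canvas = 50, downscale_to = 25),
      trials = list(n_pairs = 40, quotas = protocol_ratio_quotas(),
                    observer = list(betas = c(side = 0, num = 2,
                                              size = 0.4, spacing = 0.3),
                                    gamma = 0.01,
                                    rt_model = list(meanlog = 6.6,
                                                    sdlog = 0.3)),
                    test_pairs = 60),
      dbn = list(arch = c(30, 20), young_epochs = 1, mature_epochs = 3),
      analysis = list(gamma_mode = "fixed", gamma = 0.01,
                      probe_indices = c(1, 2, 3), probe_instances = 2)),
    reduced = {
      rc <- reduced_experiment_config()
      list(
        stimulus = list(n_range = rc$n_range, k = rc$k,
                        size_range = rc$size_range,
                        spacing_range = rc$spacing_range,
                        instances = rc$train_instances,
                        canvas = rc$canvas,
                        downscale_to = rc$downscale_to),
        trials = list(n_pairs = 300, quotas = protocol_ratio_quotas(),
                      observer = list(betas = c(side = 0, num = 2,
                                                size = 0.4, spacing = 0.3),
                                      gamma = 0.01,
                                      rt_model = list(meanlog = 6.6,
                                                      sdlog = 0.3)),
                      test_pairs = rc$test_pairs),
        dbn = list(arch = rc$arch, young_epochs = rc$young_epochs,
                   mature_epochs = rc$mature_epochs),
        analysis = list(gamma_mode = "fixed", gamma = 0.01,
                        probe_indices = rc$probe_indices,
                        probe_instances = rc$probe_instances))
    },
    full = list(
      stimulus = list(n_range = c(7, 28), k = 13,
                      size_range = c(2.6e5, 10.4e5),
                      spacing_range = c(0.8e7, 3.2e7),
                      instances = 10, canvas = 200, downscale_to = 100),
      trials = list(n_pairs = 300, quotas = protocol_ratio_quotas(),
                    observer = list(betas = c(side = 0, num = 2,
                                              size = 0.4, spacing = 0.3),
                                    gamma = 0.01,
                                    rt_model = list(meanlog = 6.6,
                                                    sdlog = 0.3)),
                    test_pairs = 15200),
      dbn = list(arch = c(1500, 1000), young_epochs = 1,
                 mature_epochs = 200),
      analysis = list(gamma_mode = "fixed", gamma = 0.01,
                      probe_indices = c(1, 9, 13), probe_instances = 10)))
  base$scale <- scale
  base$seed <- seed
  class(base) <- "experiment_config"
  base
}

#' Validate an experiment configuration
#'
#' Checks every documented stage precondition (quota sums, integral bin
#' counts, level counts, positive epochs, gamma range) before any
#' computation runs.
#'
#' @param cfg an `experiment_config`.
#' @return `cfg` invisibly; stops with a validation error otherwise.
#' @export
validate_config <- function(cfg) {
  st <- cfg$stimulus
  if (st$k < 2) stop("config: need >= 2 levels per dimension",
                     call. = FALSE)
  if (any(st$n_range <= 0, st$size_range <= 0, st$spacing_range <= 0))
    stop("config: ranges must be positive", call. = FALSE)
  tr <- cfg$trials
  if (abs(sum(tr$quotas$fraction) - 1) > 1e-9)
    stop("config: quota fractions must sum to 1", call. = FALSE)
  cnt <- tr$quotas$fraction * tr$n_pairs
  if (any(abs(cnt - round(cnt)) > 1e-9))
    stop("config: quota fraction * n_pairs must be integral", call. = FALSE)
  g <- tr$observer$gamma
  if (g < 0 || g >= 1) stop("config: gamma must be in [0, 1)",
                            call. = FALSE)
  if (cfg$dbn$young_epochs < 1 || cfg$dbn$mature_epochs < 1)
    stop("config: epochs must be >= 1", call. = FALSE)
  if (any(cfg$analysis$probe_indices < 1 |
          cfg$analysis$probe_indices > st$k))
    stop("config: probe index out of range", call. = FALSE)
  invisible(cfg)
}

pipeline_stages <- function() {
  c("generate", "render", "pairs", "observer", "train", "task", "fit",
    "rsa", "report")
}

stage_seed <- function(cfg, name) {
  (cfg$seed * 1000L + match(name, pipeline_stages())) %% .Machine$integer.max
}

stage_path <- function(run_dir, ...) file.path(run_dir, ...)

require_artifact <- function(path, stage) {
  if (!file.exists(path))
    stop("run_stage(", stage, "): missing dependency artifact '", path,
         "'; run the upstream stage first", call. = FALSE)
  path
}

cheap_checksum <- function(txt) {
  sum(utf8ToInt(paste(txt, collapse = "\n")) *
        (seq_len(nchar(paste(txt, collapse = "\n"))) %% 97 + 1)) %%
    .Machine$integer.max
}

write_manifest <- function(run_dir, stage, cfg, outputs) {
  cfg_json <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  man_path <- stage_path(run_dir, "manifest.json")
  man <- if (file.exists(man_path))
    jsonlite::read_json(man_path) else
      list(config = jsonlite::fromJSON(cfg_json),
           config_checksum = cheap_checksum(cfg_json), stages = list())
  man$stages[[stage]] <- list(seed = stage_seed(cfg, stage),
                              outputs = as.list(outputs))
  jsonlite::write_json(man, man_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
}

#' Run one pipeline stage
#'
#' Stages: `generate` (stimulus grid + feature table), `render` (images;
#' ASCII PGM exports plus a run-time matrix artifact), `pairs`
#' (quota-based comparison pairs), `observer` (synthetic choices with
#' RTs), `train` (Young/Mature DBN checkpoints), `task` (network choices
#' on held-out pairs), `fit` (choice-GLM fits for observer and networks),
#' `rsa` (probe RDM + categorical relatedness), `report` (summary
#' tables). Outputs land under `run_dir`; a manifest records config,
#' checksum and per-stage seeds. Stages whose outputs already exist are
#' skipped (idempotent re-runs).
#'
#' @param name stage name.
#' @param cfg an `experiment_config` (validated before any compute).
#' @param run_dir run directory (created if needed).
#' @param force re-run even if outputs exist.
#' @return Invisible character vector of output paths.
#' @export
run_stage <- function(name, cfg, run_dir, force = FALSE) {
  name <- match.arg(name, pipeline_stages())
  validate_config(cfg)
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  out <- switch(name,
    generate = stage_generate(cfg, run_dir, force),
    render = stage_render(cfg, run_dir, force),
    pairs = stage_pairs(cfg, run_dir, force),
    observer = stage_observer(cfg, run_dir, force),
    train = stage_train(cfg, run_dir, force),
    task = stage_task(cfg, run_dir, force),
    fit = stage_fit(cfg, run_dir, force),
    rsa = stage_rsa(cfg, run_dir, force),
    report = report(run_dir))
  if (name != "report") write_manifest(run_dir, name, cfg, out)
  invisible(out)
}

#' Run the full pipeline
#' @inheritParams run_stage
#' @param stages stages to run, in order.
#' @return Invisible `run_dir`.
#' @export
run_pipeline <- function(cfg, run_dir, stages = pipeline_stages(),
                         force = FALSE) {
  for (s in stages) run_stage(s, cfg, run_dir, force = force)
  invisible(run_dir)
}

space_levels_of <- function(cfg) {
  st <- cfg$stimulus
  default_space_levels(st$n_range, st$size_range, st$spacing_range, st$k)
}

stage_generate <- function(cfg, run_dir, force) {
  out <- stage_path(run_dir, "stimuli.csv")
  if (file.exists(out) && !force) return(out)
  set.seed(stage_seed(cfg, "generate"))
  lv <- space_levels_of(cfg)
  grid <- build_full_grid(lv$numerosity, lv$size, lv$spacing,
                          cfg$stimulus$instances)
  write_stimulus_table(grid, out)
  out
}

read_grid <- function(run_dir) {
  g <- utils::read.csv(require_artifact(stage_path(run_dir, "stimuli.csv"),
                                        "render"))
  class(g) <- c("stimulus_grid", "data.frame")
  g
}

stage_render <- function(cfg, run_dir, force) {
  img_dir <- stage_path(run_dir, "images")
  mat_path <- stage_path(run_dir, "images.rds")
  if (file.exists(mat_path) && !force) return(c(img_dir, mat_path))
  grid <- read_grid(run_dir)
  set.seed(stage_seed(cfg, "render"))
  rendered <- render_grid_images(grid, cfg$stimulus$canvas,
                                 cfg$stimulus$downscale_to,
                                 measure_hull = TRUE)
  dir.create(img_dir, showWarnings = FALSE)
  # PGM exports of the first few images (full-resolution re-render)
  set.seed(stage_seed(cfg, "render"))
  for (i in seq_len(min(4, nrow(grid)))) {
    da <- render_dot_array(grid[i, , drop = FALSE],
                           canvas = cfg$stimulus$canvas)
    write_dot_array(da, file.path(img_dir, sprintf("stim_%04d", i)))
  }
  saveRDS(rendered, mat_path)
  c(img_dir, mat_path)
}

stage_pairs <- function(cfg, run_dir, force) {
  out <- stage_path(run_dir, "pairs.csv")
  if (file.exists(out) && !force) return(out)
  grid <- read_grid(run_dir)
  set.seed(stage_seed(cfg, "pairs"))
  p <- sample_comparison_pairs(grid, cfg$trials$n_pairs,
                               cfg$trials$quotas)
  p <- label_congruency(p)
  utils::write.csv(as.data.frame(p), out, row.names = FALSE)
  out
}

read_pairs <- function(run_dir, stage) {
  p <- utils::read.csv(require_artifact(stage_path(run_dir, "pairs.csv"),
                                        stage))
  class(p) <- c("trial_pairs", "data.frame")
  p
}

stage_observer <- function(cfg, run_dir, force) {
  out <- stage_path(run_dir, "choices_observer.csv")
  if (file.exists(out) && !force) return(out)
  p <- read_pairs(run_dir, "observer")
  ob <- cfg$trials$observer
  set.seed(stage_seed(cfg, "observer"))
  ch <- simulate_observer(p, ob$betas, ob$gamma, ob$rt_model)
  write_choice_data(ch, out)
  out
}

stage_train <- function(cfg, run_dir, force) {
  outs <- stage_path(run_dir, c("dbn_young.rds", "dbn_mature.rds"))
  if (all(file.exists(outs)) && !force) return(outs)
  imgs <- readRDS(require_artifact(stage_path(run_dir, "images.rds"),
                                   "train"))$images
  sd0 <- stage_seed(cfg, "train")
  for (stage in c("young", "mature")) {
    epochs <- if (stage == "young") cfg$dbn$young_epochs else
      cfg$dbn$mature_epochs
    model <- train_dbn(imgs, cfg$dbn$arch, epochs, seed = sd0,
                       label = stage)
    save_dbn(model, stage_path(run_dir, paste0("dbn_", stage)))
    curve <- attr(model$layers[[1]], "recon_curve")
    utils::write.csv(data.frame(epoch = seq_along(curve),
                                recon_error = curve),
                     stage_path(run_dir,
                                paste0("training_curve_", stage, ".csv")),
                     row.names = FALSE)
  }
  outs
}

stage_task <- function(cfg, run_dir, force) {
  outs <- stage_path(run_dir, c("choices_young.csv", "choices_mature.csv"))
  if (all(file.exists(outs)) && !force) return(outs)
  grid <- read_grid(run_dir)
  imgs <- readRDS(require_artifact(stage_path(run_dir, "images.rds"),
                                   "task"))$images
  set.seed(stage_seed(cfg, "task"))
  npair <- min(cfg$trials$test_pairs, nrow(grid) * (nrow(grid) - 1) %/% 2)
  idx <- sample.int(nrow(grid))
  ro_idx <- idx[seq_len(floor(length(idx) / 2))]
  te_idx <- setdiff(idx, ro_idx)
  ro_pairs <- sample_uniform_pairs(grid[ro_idx, , drop = FALSE],
                                   min(npair, length(ro_idx)^2 %/% 2))
  ro_pairs$left <- ro_idx[ro_pairs$left]
  ro_pairs$right <- ro_idx[ro_pairs$right]
  te_pairs <- sample_uniform_pairs(grid[te_idx, , drop = FALSE],
                                   min(npair, length(te_idx)^2 %/% 2))
  te_pairs$left <- te_idx[te_pairs$left]
  te_pairs$right <- te_idx[te_pairs$right]
  protocol <- readout_protocol()
  for (stage in c("young", "mature")) {
    model <- load_dbn(stage_path(run_dir, paste0("dbn_", stage)))
    cl <- encode(model, imgs[ro_pairs$left, , drop = FALSE])
    cr <- encode(model, imgs[ro_pairs$right, , drop = FALSE])
    ro <- train_readout(cl, cr, ro_pairs$correct_side, protocol)
    ch <- run_comparison_task(model, ro, te_pairs, imgs,
                              protocol = protocol, observer_id = stage)
    write_choice_data(ch, stage_path(run_dir,
                                     paste0("choices_", stage, ".csv")))
  }
  outs
}

read_choices <- function(path, stage) {
  ch <- utils::read.csv(require_artifact(path, stage))
  class(ch) <- c("choice_data", "data.frame")
  ch
}

stage_fit <- function(cfg, run_dir, force) {
  out <- stage_path(run_dir, "fits.json")
  if (file.exists(out) && !force) return(out)
  an <- cfg$analysis
  fits <- list()
  obs_path <- stage_path(run_dir, "choices_observer.csv")
  sources <- c(observer = obs_path,
               young = stage_path(run_dir, "choices_young.csv"),
               mature = stage_path(run_dir, "choices_mature.csv"))
  sources <- sources[file.exists(sources)]
  if (length(sources) == 0)
    stop("run_stage(fit): no choice datasets found", call. = FALSE)
  for (nm in names(sources)) {
    ch <- read_choices(sources[[nm]], "fit")
    if (!is.null(ch$response_time))
      ch <- filter_outlier_trials(ch)
    fit <- fit_choice_glm(ch, gamma_mode = an$gamma_mode,
                          gamma = an$gamma)
    v <- discrimination_vector(fit)
    fits[[nm]] <- list(
      coefficients = as.list(fit$coefficients), gamma = fit$gamma,
      deviance = fit$deviance, adj_r2 = fit$adj_r2,
      n_trials = fit$n_trials,
      magnitude = v$magnitude,
      projections = as.list(project_onto_axes(v)),
      angles = as.list(angles_to_axes(v)$angles))
  }
  jsonlite::write_json(fits, out, auto_unbox = TRUE, digits = NA)
  out
}

stage_rsa <- function(cfg, run_dir, force) {
  out <- stage_path(run_dir, "rsa.json")
  if (file.exists(out) && !force) return(out)
  an <- cfg$analysis
  lv <- space_levels_of(cfg)
  set.seed(stage_seed(cfg, "rsa"))
  probe <- build_probe_set(lv, an$probe_indices, an$probe_instances)
  rendered <- render_grid_images(probe, cfg$stimulus$canvas,
                                 cfg$stimulus$downscale_to,
                                 measure_hull = TRUE)
  cands <- categorical_rdms(probe, rendered$hull_area)
  res <- list()
  for (stage in c("young", "mature")) {
    ck <- stage_path(run_dir, paste0("dbn_", stage, ".rds"))
    if (!file.exists(ck)) next
    model <- load_dbn(stage_path(run_dir, paste0("dbn_", stage)))
    pat <- mean_activation_patterns(model, rendered$images,
                                    probe$condition)
    rdm <- model_rdm(pat)
    write_rdm(rdm, stage_path(run_dir, paste0("rdm_", stage, ".csv")))
    tau <- vapply(cands, kendall_tau_a, numeric(1), rdm_a = rdm)
    res[[stage]] <- list(tau = as.list(tau),
                         ranking = names(sort(tau, decreasing = TRUE)))
  }
  if (length(res) == 0)
    stop("run_stage(rsa): no trained checkpoints found", call. = FALSE)
  jsonlite::write_json(res, out, auto_unbox = TRUE, digits = NA)
  out
}

#' Summarize a pipeline run
#'
#' Builds CSV tables from the fit and RSA artifacts: one coefficient /
#' projection row per observer or network stage, and one tau row per
#' (stage, feature). Byte-identical on repeated calls.
#'
#' @param run_dir a run directory with `fits.json` (and optionally
#'   `rsa.json`).
#' @return Character vector of the table paths.
#' @export
report <- function(run_dir) {
  fits_path <- require_artifact(stage_path(run_dir, "fits.json"), "report")
  fits <- jsonlite::read_json(fits_path)
  coef_tab <- do.call(rbind, lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    data.frame(source = nm,
               beta_side = f$coefficients$side,
               beta_num = f$coefficients$num,
               beta_size = f$coefficients$size,
               beta_spacing = f$coefficients$spacing,
               gamma = f$gamma, adj_r2 = f$adj_r2,
               magnitude = f$magnitude,
               angle_numerosity = f$angles$numerosity,
               angle_total_perimeter = f$angles$total_perimeter)
  }))
  out1 <- stage_path(run_dir, "report_coefficients.csv")
  utils::write.csv(coef_tab, out1, row.names = FALSE)
  outs <- out1
  rsa_path <- stage_path(run_dir, "rsa.json")
  if (file.exists(rsa_path)) {
    rsa <- jsonlite::read_json(rsa_path)
    tau_tab <- do.call(rbind, lapply(names(rsa), function(stage)
      data.frame(stage = stage,
                 feature = names(rsa[[stage]]$tau),
                 tau = unlist(rsa[[stage]]$tau), row.names = NULL)))
    out2 <- stage_path(run_dir, "report_tau.csv")
    utils::write.csv(tau_tab, out2, row.names = FALSE)
    outs <- c(outs, out2)
  }
  outs
}
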