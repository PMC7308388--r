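#' Reduced-scale experiment configuration
#'
#' A desk-scale stand-in for the full 144-network study (which needs
#' 100x100 images, 65912 training stimuli and 200 epochs): 50x50 images
#' (rendered at 100 px then downscaled), numerosities 5-16 with 5 log
#' levels per dimension, Size/Spacing ranges scaled by 1/16 (the squared
#' linear scale factor, keeping areas proportional on the smaller canvas),
#' 16 training instances per grid point (2000 training images), a
#' (200, 100) architecture, Young = 1 vs Mature = 50 epochs, and 2000 test
#' pairs from held-out instances.
#'
#' @param n_range,k,size_range,spacing_range reduced stimulus space.
#' @param canvas,downscale_to render and network image sides (px).
#' @param train_instances,test_instances instances per grid point for the
#'   unsupervised training set and the held-out test set.
#' @param arch hidden layer sizes.
#' @param young_epochs,mature_epochs unsupervised epochs per stage.
#' @param readout_pairs,test_pairs pair counts for readout training and
#'   task testing.
#' @param probe_indices 1-based grid indices of the RSA probe levels.
#' @param probe_instances probe images per condition.
#' @return Config list.
#' @export
reduced_experiment_config <- function(n_range = c(5, 16), k = 5,
                                      size_range = c(2.6e5, 10.4e5) / 16,
                                      spacing_range = c(0.8e7, 3.2e7) / 16,
                                      canvas = 100, downscale_to = 50,
                                      train_instances = 16,
                                      test_instances = 6,
                                      arch = c(200, 100),
                                      young_epochs = 1, mature_epochs = 50,
                                      readout_pairs = 4000,
                                      test_pairs = 2000,
                                      probe_indices = c(1, 3, 5),
                                      probe_instances = 10) {
  as.list(environment())
}

#' Render the stimulus material for a reduced experiment
#'
#' Builds the reduced grid, renders unsupervised-training images, held-out
#' test-instance images, and the RSA probe images (with empirically
#' measured convex hulls). Shared across network seeds.
#'
#' @param cfg a [reduced_experiment_config()].
#' @return List: `levels`, `train_grid`/`train`, `test_grid`/`test`,
#'   `probe_grid`/`probe` (each `train`/`test`/`probe` a
#'   [render_grid_images()] result).
#' @export
prepare_experiment_stimuli <- function(cfg = reduced_experiment_config()) {
  lv <- default_space_levels(cfg$n_range, cfg$size_range,
                             cfg$spacing_range, cfg$k)
  train_grid <- build_full_grid(lv$numerosity, lv$size, lv$spacing,
                                cfg$train_instances)
  test_grid <- build_full_grid(lv$numerosity, lv$size, lv$spacing,
                               cfg$test_instances)
  test_grid$instance_id <- test_grid$instance_id + cfg$train_instances
  probe_grid <- build_probe_set(lv, cfg$probe_indices, cfg$probe_instances)
  list(
    levels = lv,
    train_grid = train_grid,
    train = render_grid_images(train_grid, cfg$canvas, cfg$downscale_to),
    test_grid = test_grid,
    test = render_grid_images(test_grid, cfg$canvas, cfg$downscale_to),
    probe_grid = probe_grid,
    probe = render_grid_images(probe_grid, cfg$canvas, cfg$downscale_to,
                               measure_hull = TRUE)
  )
}

#' Categorical RDMs for a probe grid
#'
#' One candidate RDM per feature: nominal (analytic) values for all
#' features except convex hull, which uses the mean empirically measured
#' hull area over each condition's rendered instances.
#'
#' @param probe_grid probe `stimulus_grid` with a `condition` column.
#' @param hull_area measured hull area per probe image (from
#'   [render_grid_images()] with `measure_hull = TRUE`).
#' @return Named list of `rdm`s over the probe conditions.
#' @export
categorical_rdms <- function(probe_grid, hull_area) {
  feats <- derive_features(as.data.frame(probe_grid))
  conds <- levels(probe_grid$condition)
  first <- match(conds, as.character(probe_grid$condition))
  per_cond <- function(v) v[first]
  out <- list(
    numerosity = per_cond(feats$n),
    size = per_cond(feats$size),
    spacing = per_cond(feats$spacing),
    isa = per_cond(feats$isa),
    tsa = per_cond(feats$tsa),
    fa = per_cond(feats$fa),
    sparsity = per_cond(feats$sparsity),
    coverage = per_cond(feats$coverage),
    total_perimeter = per_cond(feats$total_perimeter),
    convex_hull = as.vector(
      rowsum(hull_area, probe_grid$condition)[conds, ] /
        as.vector(table(probe_grid$condition)[conds]))
  )
  lapply(stats::setNames(names(out), names(out)), function(nm)
    categorical_rdm(out[[nm]], conds, nm))
}

#' Run the Young-vs-Mature developmental experiment at reduced scale
#'
#' For each network seed: trains a Young (1 epoch) and a Mature
#' (`mature_epochs`) DBN from the same initialization on the same images,
#' trains the identical linear readout protocol on each stage's frozen
#' codes, runs the comparison task on held-out pairs, fits the choice GLM
#' (guessing factor fixed at 0.01), and computes the stage's probe RDM and
#' its tau-A against the ten categorical feature models.
#'
#' @param n_seeds number of network initialization seeds.
#' @param cfg a [reduced_experiment_config()].
#' @param seed global seed (controls rendering, pair sampling and the
#'   per-network seed stream).
#' @param stimuli optional pre-rendered [prepare_experiment_stimuli()]
#'   result (rendered under `seed` if omitted).
#' @param verbose print per-seed progress.
#' @return List: `coefficients` (data.frame: seed, stage, beta_*, gamma,
#'   accuracy), `tau` (data.frame: seed, stage, feature, tau),
#'   `rdms` (list of per-stage RDM lists), `config`.
#' @export
run_development_experiment <- function(n_seeds = 12,
                                       cfg = reduced_experiment_config(),
                                       seed = 1, stimuli = NULL,
                                       verbose = FALSE) {
  set.seed(seed)
  if (is.null(stimuli)) stimuli <- prepare_experiment_stimuli(cfg)
  train_imgs <- stimuli$train$images
  test_imgs <- stimuli$test$images
  probe_imgs <- stimuli$probe$images

  ro_pairs <- sample_uniform_pairs(stimuli$train_grid, cfg$readout_pairs)
  te_pairs <- sample_uniform_pairs(stimuli$test_grid, cfg$test_pairs)
  cands <- categorical_rdms(stimuli$probe_grid, stimuli$probe$hull_area)
  protocol <- readout_protocol()

  coef_rows <- list()
  tau_rows <- list()
  rdms <- list(young = list(), mature = list())
  for (s in seq_len(n_seeds)) {
    net_seed <- seed * 1000L + s
    for (stage in c("young", "mature")) {
      epochs <- if (stage == "young") cfg$young_epochs else cfg$mature_epochs
      model <- train_dbn(train_imgs, cfg$arch, epochs, seed = net_seed,
                         label = paste0(stage, "_seed", s))
      cl <- encode(model, train_imgs[ro_pairs$left, , drop = FALSE])
      cr <- encode(model, train_imgs[ro_pairs$right, , drop = FALSE])
      ro <- train_readout(cl, cr, ro_pairs$correct_side, protocol)
      choices <- run_comparison_task(model, ro, te_pairs, test_imgs,
                                     protocol = protocol)
      fit <- fit_choice_glm(choices, gamma_mode = "fixed", gamma = 0.01)
      coef_rows[[length(coef_rows) + 1L]] <- data.frame(
        seed = s, stage = stage,
        beta_side = fit$coefficients[["side"]],
        beta_num = fit$coefficients[["num"]],
        beta_size = fit$coefficients[["size"]],
        beta_spacing = fit$coefficients[["spacing"]],
        gamma = fit$gamma, adj_r2 = fit$adj_r2,
        accuracy = mean(choices$correct))
      pat <- mean_activation_patterns(model, probe_imgs,
                                      stimuli$probe_grid$condition)
      rdm <- model_rdm(pat)
      rdms[[stage]][[s]] <- rdm
      tau <- vapply(cands, kendall_tau_a, numeric(1), rdm_a = rdm)
      tau_rows[[length(tau_rows) + 1L]] <- data.frame(
        seed = s, stage = stage, feature = names(tau), tau = unname(tau),
        row.names = NULL)
      if (verbose)
        message(sprintf("seed %d %s: beta_num=%.2f acc=%.3f top=%s",
                        s, stage, fit$coefficients[["num"]],
                        mean(choices$correct),
                        names(tau)[which.max(tau)]))
    }
  }
  list(coefficients = do.call(rbind, coef_rows),
       tau = do.call(rbind, tau_rows),
       rdms = rdms, config = cfg)
}

#' Summarize the developmental effect across seeds
#'
#' Counts, per seed, whether the qualitative developmental signatures
#' hold: the Mature numerosity coefficient exceeds the Young one, the
#' magnitudes of the Size and Spacing coefficients decrease, the Young
#' RDM correlates best with convex hull, and the Mature RDM places
#' numerosity within its top `mature_top` features.
#'
#' @param res a [run_development_experiment()] result.
#' @param mature_top rank numerosity must reach in the Mature RSA.
#' @return List of logical vectors (one element per seed):
#'   `num_increases`, `size_decreases`, `spacing_decreases`,
#'   `young_hull_top`, `mature_num_top`.
#' @export
developmental_effect_summary <- function(res, mature_top = 2) {
  co <- res$coefficients
  y <- co[co$stage == "young", ]
  m <- co[co$stage == "mature", ]
  y <- y[order(y$seed), ]; m <- m[order(m$seed), ]
  tau <- res$tau
  rank_of <- function(stage, s, feature) {
    tt <- tau[tau$stage == stage & tau$seed == s, ]
    match(feature, tt$feature[order(-tt$tau)])
  }
  seeds <- sort(unique(co$seed))
  list(
    num_increases = m$beta_num > y$beta_num,
    size_decreases = abs(m$beta_size) < abs(y$beta_size),
    spacing_decreases = abs(m$beta_spacing) < abs(y$beta_spacing),
    young_hull_top = vapply(seeds, function(s)
      rank_of("young", s, "convex_hull") == 1, logical(1)),
    mature_num_top = vapply(seeds, function(s)
      rank_of("mature", s, "numerosity") <= mature_top, logical(1))
  )
}
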