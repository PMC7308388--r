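#' RBM training hyperparameters
#'
#' Local defaults for contrastive-divergence training: learning rate 0.1
#' for the pixel layer (0.05 recommended for the second layer), momentum
#' 0.5 switching to 0.9 after epoch 5, weight decay 2e-4, mini-batch 125,
#' weights initialized N(0, 0.01^2), biases 0.
#'
#' @param learning_rate step size.
#' @param momentum_initial,momentum_final,momentum_switch_epoch momentum
#'   schedule (initial value up to and including the switch epoch).
#' @param weight_decay L2 penalty on weights (not biases).
#' @param batch_size mini-batch size.
#' @param init_sd sd of the Gaussian weight initialization.
#' @return List of class `rbm_hyper`.
#' @export
rbm_hyper <- function(learning_rate = 0.1, momentum_initial = 0.5,
                      momentum_final = 0.9, momentum_switch_epoch = 5,
                      weight_decay = 2e-4, batch_size = 125,
                      init_sd = 0.01) {
  stopifnot(learning_rate > 0, batch_size >= 1, weight_decay >= 0)
  structure(as.list(environment()), class = "rbm_hyper")
}

sigmoid <- function(x) 1 / (1 + exp(-x))

rbm_init <- function(n_visible, n_hidden, init_sd = 0.01) {
  structure(list(
    weights = matrix(stats::rnorm(n_visible * n_hidden, 0, init_sd),
                     n_visible, n_hidden),
    visible_bias = numeric(n_visible),
    hidden_bias = numeric(n_hidden),
    n_visible = n_visible, n_hidden = n_hidden
  ), class = "rbm")
}

#' Single CD-1 update on a mini-batch
#'
#' One contrastive-divergence step: hidden probabilities from the data,
#' a Bernoulli hidden sample, a mean-field visible reconstruction, hidden
#' probabilities of the reconstruction, and the gradient
#' `<v h>_data - <v h>_recon` applied with momentum and weight decay.
#' Uniform draws for the hidden sampling can be supplied explicitly
#' (`u`), which makes the update exactly reproducible by hand.
#'
#' @param rbm an `rbm` parameter set.
#' @param V batch matrix (rows = cases, values in `[0, 1]`).
#' @param lr learning rate.
#' @param momentum momentum coefficient for this update.
#' @param weight_decay L2 coefficient on weights.
#' @param state previous-update deltas (list `dW`, `db`, `dc`) or `NULL`.
#' @param u optional matrix of uniforms (same shape as the hidden
#'   probabilities) used to sample hidden states.
#' @return List: updated `rbm`, new momentum `state`, and the batch mean
#'   squared reconstruction error `recon_error`.
#' @export
rbm_cd1_step <- function(rbm, V, lr, momentum = 0, weight_decay = 0,
                         state = NULL, u = NULL) {
  nb <- nrow(V)
  h_prob0 <- sigmoid(sweep(V %*% rbm$weights, 2, rbm$hidden_bias, "+"))
  if (is.null(u)) u <- matrix(stats::runif(length(h_prob0)),
                              nrow(h_prob0), ncol(h_prob0))
  h0 <- (u < h_prob0) * 1
  v1 <- sigmoid(sweep(tcrossprod(h0, rbm$weights), 2,
                      rbm$visible_bias, "+"))
  h_prob1 <- sigmoid(sweep(v1 %*% rbm$weights, 2, rbm$hidden_bias, "+"))
  gW <- (crossprod(V, h_prob0) - crossprod(v1, h_prob1)) / nb
  gb <- colMeans(V - v1)
  gc <- colMeans(h_prob0 - h_prob1)
  if (is.null(state))
    state <- list(dW = 0 * rbm$weights, db = 0 * gb, dc = 0 * gc)
  state$dW <- momentum * state$dW + lr * (gW - weight_decay * rbm$weights)
  state$db <- momentum * state$db + lr * gb
  state$dc <- momentum * state$dc + lr * gc
  rbm$weights <- rbm$weights + state$dW
  rbm$visible_bias <- rbm$visible_bias + state$db
  rbm$hidden_bias <- rbm$hidden_bias + state$dc
  if (any(!is.finite(rbm$weights)))
    stop("rbm_cd1_step: weights diverged (NaN/Inf)", call. = FALSE)
  list(rbm = rbm, state = state, recon_error = mean((V - v1)^2))
}

#' Train a restricted Boltzmann machine with CD-1
#'
#' Mini-batch contrastive divergence over shuffled epochs. Data values must
#' lie in `[0, 1]` (binary pixels or activation probabilities).
#'
#' @param data matrix, rows = training cases.
#' @param n_hidden hidden layer size.
#' @param epochs training epochs; `0` returns the initialization.
#' @param hyper an [rbm_hyper()] list.
#' @param rbm optional pre-initialized `rbm` (for resuming training).
#' @param verbose print per-epoch reconstruction error.
#' @return An `rbm` with attribute `"recon_curve"` (mean reconstruction
#'   error per epoch).
#' @export
train_rbm_cd1 <- function(data, n_hidden, epochs, hyper = rbm_hyper(),
                          rbm = NULL, verbose = FALSE) {
  stopifnot(is.matrix(data))
  if (min(data) < 0 || max(data) > 1)
    stop("train_rbm_cd1: data must lie in [0, 1]", call. = FALSE)
  if (is.null(rbm))
    rbm <- rbm_init(ncol(data), n_hidden, hyper$init_sd)
  state <- NULL
  curve <- numeric(epochs)
  n <- nrow(data)
  start_epoch <- attr(rbm, "epochs_done") %||% 0L
  for (e in seq_len(epochs)) {
    mom <- if (start_epoch + e <= hyper$momentum_switch_epoch)
      hyper$momentum_initial else hyper$momentum_final
    ord <- sample.int(n)
    errs <- c()
    for (b in split(ord, ceiling(seq_along(ord) / hyper$batch_size))) {
      res <- rbm_cd1_step(rbm, data[b, , drop = FALSE], hyper$learning_rate,
                          mom, hyper$weight_decay, state)
      rbm <- res$rbm; state <- res$state
      errs <- c(errs, res$recon_error)
    }
    curve[e] <- mean(errs)
    if (verbose)
      message(sprintf("epoch %d: recon error %.5f", start_epoch + e,
                      curve[e]))
  }
  attr(rbm, "epochs_done") <- start_epoch + epochs
  attr(rbm, "recon_curve") <- c(attr(rbm, "recon_curve"), curve)
  rbm
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mean reconstruction error of an RBM on a dataset
#' @param rbm an `rbm`.
#' @param data matrix of cases in `[0, 1]`.
#' @return Mean squared mean-field reconstruction error.
#' @export
rbm_recon_error <- function(rbm, data) {
  h <- sigmoid(sweep(data %*% rbm$weights, 2, rbm$hidden_bias, "+"))
  v <- sigmoid(sweep(tcrossprod(h, rbm$weights), 2, rbm$visible_bias, "+"))
  mean((data - v)^2)
}

#' Train a two-layer deep belief network
#'
#' Greedy layerwise training: the first RBM learns the pixel statistics;
#' the second RBM is then trained on the first layer's hidden activation
#' probabilities. With `epochs = 1` the result is a "Young" network (one
#' pass through the data); prolonged training yields a "Mature" network.
#'
#' @param images matrix, rows = flattened images in `[0, 1]`.
#' @param arch integer pair `(h1, h2)`: hidden sizes of the two layers.
#' @param epochs unsupervised epochs applied to each layer.
#' @param hyper1,hyper2 [rbm_hyper()] settings per layer.
#' @param seed RNG seed controlling initialization and batch order; runs
#'   with the same seed, data and settings are bit-identical.
#' @param label optional stage label (e.g. `"young"`, `"mature"`).
#' @return Object of class `dbn`: list `layers` (two `rbm`s),
#'   `epochs_trained`, `seed`, `arch`, `label`.
#' @export
train_dbn <- function(images, arch, epochs,
                      hyper1 = rbm_hyper(learning_rate = 0.1),
                      hyper2 = rbm_hyper(learning_rate = 0.05),
                      seed = 1, label = NULL) {
  stopifnot(length(arch) == 2, all(arch >= 1))
  set.seed(seed)
  l1 <- train_rbm_cd1(images, arch[1], epochs, hyper1)
  h1 <- sigmoid(sweep(images %*% l1$weights, 2, l1$hidden_bias, "+"))
  l2 <- train_rbm_cd1(h1, arch[2], epochs, hyper2)
  structure(list(layers = list(l1, l2), epochs_trained = epochs,
                 seed = seed, arch = arch,
                 label = label %||% paste0("dbn_", arch[1], "x", arch[2])),
            class = "dbn")
}

#' Deterministic encoding through a DBN
#'
#' Feed-forward pass of activation *probabilities* (no sampling) through
#' both layers; the top-layer activations are the network's internal
#' representation of the stimulus.
#'
#' @param model a `dbn`.
#' @param images matrix of flattened images (rows) or a single vector.
#' @return Matrix of top-layer activations in `(0, 1)` (rows = images).
#' @export
encode <- function(model, images) {
  if (is.vector(images)) images <- matrix(images, 1)
  if (ncol(images) != model$layers[[1]]$n_visible)
    stop("encode: image size does not match the visible layer",
         call. = FALSE)
  h1 <- sigmoid(sweep(images %*% model$layers[[1]]$weights, 2,
                      model$layers[[1]]$hidden_bias, "+"))
  sigmoid(sweep(h1 %*% model$layers[[2]]$weights, 2,
                model$layers[[2]]$hidden_bias, "+"))
}

#' Readout training protocol
#'
#' Descriptor of the supervised stage. The same protocol object must be
#' used for every condition being compared (e.g. Young vs Mature), which
#' enforces structurally that differences in task performance come from
#' the frozen internal representations, not the readout.
#'
#' @param iterations full-batch gradient-descent iterations.
#' @param learning_rate step size.
#' @param init_seed seed for the readout weight initialization.
#' @param online if `TRUE`, a single per-trial (stochastic) pass in the
#'   order given - used for curriculum/hysteresis experiments.
#' @return List of class `readout_protocol`.
#' @export
readout_protocol <- function(iterations = 200, learning_rate = 0.1,
                             init_seed = 99, online = FALSE) {
  structure(list(iterations = iterations, learning_rate = learning_rate,
                 init_seed = init_seed, online = online),
            class = "readout_protocol")
}

#' Train the linear readout for the comparison task
#'
#' Softmax regression with two output units (choose left / choose right)
#' on the concatenated top-layer codes of the two stimuli in each pair,
#' trained by cross-entropy gradient descent. The DBN itself is never
#' modified. In `online` mode the classifier takes a single pass over the
#' trials in the order given, one gradient step per trial (the iterative
#' variant used for curriculum ordering experiments).
#'
#' @param codes_left,codes_right matrices of top-layer codes (rows =
#'   trials).
#' @param labels character vector, `"left"`/`"right"` = side with more
#'   dots.
#' @param protocol a [readout_protocol()].
#' @return Object of class `readout`: `weights` ((2*code dim + 1) x 2,
#'   first row = bias), `protocol`.
#' @export
train_readout <- function(codes_left, codes_right, labels,
                          protocol = readout_protocol()) {
  stopifnot(inherits(protocol, "readout_protocol"))
  X <- cbind(1, codes_left, codes_right)
  Y <- cbind(left = labels == "left", right = labels == "right") * 1
  set.seed(protocol$init_seed)
  W <- matrix(stats::rnorm(ncol(X) * 2, 0, 0.01), ncol(X), 2)
  lr <- protocol$learning_rate
  if (protocol$online) {
    for (i in seq_len(nrow(X))) {
      xi <- X[i, ]
      s <- drop(xi %*% W)
      p <- exp(s - max(s)); p <- p / sum(p)
      W <- W - lr * tcrossprod(xi, p - Y[i, ])
    }
  } else {
    n <- nrow(X)
    for (it in seq_len(protocol$iterations)) {
      S <- X %*% W
      S <- S - apply(S, 1, max)
      P <- exp(S); P <- P / rowSums(P)
      W <- W - (lr / n) * crossprod(X, P - Y)
    }
  }
  structure(list(weights = W, protocol = protocol), class = "readout")
}

readout_scores <- function(readout, codes_left, codes_right) {
  cbind(1, codes_left, codes_right) %*% readout$weights
}

#' Run the numerosity comparison task
#'
#' Encodes each test pair through the frozen DBN, applies the linear
#' readout, and records the argmax choice (ties broken by a seeded coin
#' flip). The result is a `choice_data` frame that feeds directly into
#' [fit_choice_glm()].
#'
#' @param model a `dbn`.
#' @param readout a trained `readout`. Its protocol must match `protocol`
#'   if one is supplied (guards Young/Mature comparability).
#' @param test_pairs `trial_pairs` whose `left`/`right` index into
#'   `images`; they must be disjoint from the readout's training images.
#' @param images matrix of flattened test images.
#' @param protocol optional protocol the readout is required to match.
#' @param observer_id label for the resulting dataset.
#' @return A `choice_data` data frame (no response times).
#' @export
run_comparison_task <- function(model, readout, test_pairs, images,
                                protocol = NULL,
                                observer_id = model$label) {
  if (!is.null(protocol) &&
      !identical(readout$protocol, protocol))
    stop("run_comparison_task: readout protocol differs from the required ",
         "protocol (conditions are not comparable)", call. = FALSE)
  cl <- encode(model, images[test_pairs$left, , drop = FALSE])
  cr <- encode(model, images[test_pairs$right, , drop = FALSE])
  s <- readout_scores(readout, cl, cr)
  d <- s[, 2] - s[, 1]
  tie <- d == 0
  d[tie] <- stats::runif(sum(tie)) - 0.5
  out <- as.data.frame(test_pairs)
  out$chosen_side <- ifelse(d > 0, "right", "left")
  out$correct <- out$chosen_side == out$correct_side
  out$observer_id <- observer_id
  class(out) <- c("choice_data", "data.frame")
  out
}

#' Order trials by task difficulty
#'
#' Difficulty is the closeness of the numerosity ratio to 1; easy trials
#' have large `|log2 r_num|`. Ties preserve the original row order.
#'
#' @param pairs `trial_pairs`.
#' @param mode `"easy_to_hard"`, `"hard_to_easy"` or `"shuffled"`.
#' @return Reordered `trial_pairs`.
#' @export
curriculum_order <- function(pairs, mode = c("easy_to_hard", "hard_to_easy",
                                             "shuffled")) {
  mode <- match.arg(mode)
  diff <- abs(log2(pairs$r_num))
  ord <- switch(mode,
    easy_to_hard = order(-diff, seq_len(nrow(pairs))),
    hard_to_easy = order(diff, seq_len(nrow(pairs))),
    shuffled = sample.int(nrow(pairs)))
  pairs[ord, , drop = FALSE]
}

#' Save / load a DBN checkpoint
#'
#' Checkpoints are run-time artifacts: an `.rds` array container plus a
#' JSON metadata sidecar (architecture, seed, epochs, label).
#'
#' @param model a `dbn`.
#' @param path path without extension.
#' @return `path`, invisibly (for `save_dbn`); a `dbn` (for `load_dbn`).
#' @export
save_dbn <- function(model, path) {
  saveRDS(model, paste0(path, ".rds"))
  jsonlite::write_json(list(arch = model$arch, seed = model$seed,
                            epochs = model$epochs_trained,
                            label = model$label),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_dbn
#' @export
load_dbn <- function(path) readRDS(paste0(path, ".rds"))
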