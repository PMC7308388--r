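test_that("a single CD-1 update matches the hand-computed oracle", {
  rbm <- structure(list(
    weights = matrix(c(0.1, -0.2, 0.3, 0.05), 2, 2),
    visible_bias = c(0.01, -0.01),
    hidden_bias = c(0.02, 0.03),
    n_visible = 2L, n_hidden = 2L), class = "rbm")
  V <- rbind(c(1, 0), c(0, 1))
  u <- rbind(c(0.4, 0.9), c(0.1, 0.6))
  lr <- 0.5; mom <- 0.9; wd <- 0.01
  prev <- list(dW = matrix(0.001, 2, 2), db = c(0.002, 0.002),
               dc = c(-0.001, 0.001))

  # oracle: scalar arithmetic, element by element
  sg <- function(x) 1 / (1 + exp(-x))
  hp0 <- matrix(0, 2, 2); h0 <- matrix(0, 2, 2)
  for (i in 1:2) for (j in 1:2)
    hp0[i, j] <- sg(V[i, 1] * rbm$weights[1, j] +
                    V[i, 2] * rbm$weights[2, j] + rbm$hidden_bias[j])
  for (i in 1:2) for (j in 1:2) h0[i, j] <- as.numeric(u[i, j] < hp0[i, j])
  v1 <- matrix(0, 2, 2)
  for (i in 1:2) for (k in 1:2)
    v1[i, k] <- sg(h0[i, 1] * rbm$weights[k, 1] +
                   h0[i, 2] * rbm$weights[k, 2] + rbm$visible_bias[k])
  hp1 <- matrix(0, 2, 2)
  for (i in 1:2) for (j in 1:2)
    hp1[i, j] <- sg(v1[i, 1] * rbm$weights[1, j] +
                    v1[i, 2] * rbm$weights[2, j] + rbm$hidden_bias[j])
  gW <- matrix(0, 2, 2)
  for (k in 1:2) for (j in 1:2)
    gW[k, j] <- (V[1, k] * hp0[1, j] + V[2, k] * hp0[2, j] -
                 v1[1, k] * hp1[1, j] - v1[2, k] * hp1[2, j]) / 2
  dW <- mom * prev$dW + lr * (gW - wd * rbm$weights)
  db <- mom * prev$db + lr * c(mean(V[, 1] - v1[, 1]),
                               mean(V[, 2] - v1[, 2]))
  dc <- mom * prev$dc + lr * c(mean(hp0[, 1] - hp1[, 1]),
                               mean(hp0[, 2] - hp1[, 2]))

  res <- rbm_cd1_step(rbm, V, lr, mom, wd, state = prev, u = u)
  expect_equal(res$rbm$weights, rbm$weights + dW, tolerance = 1e-15)
  expect_equal(res$rbm$visible_bias, rbm$visible_bias + db,
               tolerance = 1e-15)
  expect_equal(res$rbm$hidden_bias, rbm$hidden_bias + dc,
               tolerance = 1e-15)
  expect_equal(res$recon_error, mean((V - v1)^2), tolerance = 1e-15)
})

test_that("zero-epoch training returns the initialization unchanged", {
  X <- toy_prototypes(50)
  set.seed(40)
  trained <- train_rbm_cd1(X, 4, epochs = 0)
  set.seed(40)
  init <- numsense:::rbm_init(8, 4, 0.01)
  expect_equal(trained$weights, init$weights)
  expect_equal(trained$visible_bias, init$visible_bias)
})

test_that("CD-1 training reduces reconstruction error on structured data", {
  X <- toy_prototypes(500)
  set.seed(41)
  init <- numsense:::rbm_init(8, 6, 0.01)
  baseline <- rbm_recon_error(init, X)
  trained <- train_rbm_cd1(X, 6, epochs = 20,
                           hyper = rbm_hyper(batch_size = 50), rbm = init)
  expect_lt(rbm_recon_error(trained, X), baseline)
  curve <- attr(trained, "recon_curve")
  expect_length(curve, 20)
  expect_lt(curve[20], curve[1])
})

test_that("held-out reconstruction improves in most seeds (sign test)", {
  wins <- vapply(1:6, function(s) {
    X <- toy_prototypes(300, seed = 100 + s)
    hold <- toy_prototypes(100, seed = 200 + s)
    set.seed(s)
    init <- numsense:::rbm_init(8, 6, 0.01)
    before <- rbm_recon_error(init, hold)
    after <- rbm_recon_error(
      train_rbm_cd1(X, 6, epochs = 15, hyper = rbm_hyper(batch_size = 50),
                    rbm = init), hold)
    after < before
  }, logical(1))
  expect_gte(sum(wins), 5)
})

test_that("training diverges loudly rather than silently", {
  X <- toy_prototypes(100)
  expect_error(
    train_rbm_cd1(X - 2, 4, epochs = 1),
    "data must lie in")
})

test_that("dbn stacking, determinism and encode semantics", {
  X <- toy_prototypes(200)
  m1 <- train_dbn(X, c(6, 3), epochs = 2, seed = 42)
  m2 <- train_dbn(X, c(6, 3), epochs = 2, seed = 42)
  expect_identical(m1$layers, m2$layers)
  expect_equal(m1$layers[[1]]$n_hidden, m1$layers[[2]]$n_visible)

  codes <- encode(m1, X)
  expect_equal(dim(codes), c(200, 3))
  expect_true(all(codes > 0 & codes < 1))
  expect_identical(encode(m1, X[1, ]), encode(m1, X[1, ]))
  expect_error(encode(m1, numeric(5)), "does not match")

  # zero-weight network encodes everything as 0.5
  zero <- m1
  for (l in 1:2) {
    zero$layers[[l]]$weights[] <- 0
    zero$layers[[l]]$visible_bias[] <- 0
    zero$layers[[l]]$hidden_bias[] <- 0
  }
  expect_equal(unname(encode(zero, X[1, ])[1, ]), rep(0.5, 3))
})

test_that("the readout separates linearly separable codes", {
  sc <- separable_codes()
  ro <- train_readout(sc$left, sc$right, sc$labels,
                      readout_protocol(iterations = 2000))
  s <- numsense:::readout_scores(ro, sc$left, sc$right)
  pred <- ifelse(s[, 2] > s[, 1], "right", "left")
  expect_equal(mean(pred == sc$labels), 1.0)
})

test_that("swapping sides and labels mirrors the readout", {
  sc <- separable_codes(n = 100)
  proto <- readout_protocol(iterations = 500)
  ro1 <- train_readout(sc$left, sc$right, sc$labels, proto)
  swapped <- ifelse(sc$labels == "left", "right", "left")
  ro2 <- train_readout(sc$right, sc$left, swapped, proto)
  s1 <- numsense:::readout_scores(ro1, sc$left, sc$right)
  s2 <- numsense:::readout_scores(ro2, sc$right, sc$left)
  # the decision margins mirror (readout init noise keeps this approximate)
  expect_equal(s1[, 2] - s1[, 1], s2[, 1] - s2[, 2], tolerance = 0.05)
})

test_that("untrained and zero readouts perform at chance", {
  set.seed(43)
  g <- tiny_grid(2)
  imgs <- matrix(runif(nrow(g) * 16), nrow(g), 16)
  pairs <- sample_uniform_pairs(g, 300)
  model <- untrained_dbn(16, c(8, 4))
  zero_ro <- structure(list(weights = matrix(0, 2 * 4 + 1, 2),
                            protocol = readout_protocol()),
                       class = "readout")
  ch <- run_comparison_task(model, zero_ro, pairs, imgs)
  expect_equal(mean(ch$correct), 0.5, tolerance = 0.08)
  expect_s3_class(ch, "choice_data")

  sc <- separable_codes()
  ro0 <- train_readout(sc$left, sc$right, sc$labels,
                       readout_protocol(iterations = 0))
  s <- numsense:::readout_scores(ro0, sc$left, sc$right)
  pred <- ifelse(s[, 2] > s[, 1], "right", "left")
  expect_lt(abs(mean(pred == sc$labels) - 0.5), 0.15)
})

test_that("protocol identity across conditions is enforced", {
  set.seed(44)
  g <- tiny_grid(1)
  imgs <- matrix(runif(nrow(g) * 16), nrow(g), 16)
  pairs <- sample_uniform_pairs(g, 20)
  model <- untrained_dbn(16, c(8, 4))
  codes <- encode(model, imgs)
  pa <- readout_protocol(iterations = 10)
  pb <- readout_protocol(iterations = 20)
  ro <- train_readout(codes[pairs$left, ], codes[pairs$right, ],
                      pairs$correct_side, pa)
  expect_error(run_comparison_task(model, ro, pairs, imgs, protocol = pb),
               "not comparable")
})

test_that("curriculum ordering sorts by numerosity-ratio difficulty", {
  set.seed(45)
  p <- sample_uniform_pairs(tiny_grid(2), 60)
  diff <- abs(log2(p$r_num))
  easy <- curriculum_order(p, "easy_to_hard")
  expect_equal(abs(log2(easy$r_num[1])), max(diff))
  expect_equal(abs(log2(easy$r_num[60])), min(diff))
  hard <- curriculum_order(p, "hard_to_easy")
  expect_equal(abs(log2(hard$r_num)), rev(abs(log2(easy$r_num))))
  # ties keep their original order (stable sort)
  dup <- p[c(1, 1, 2, 2), ]
  expect_equal(curriculum_order(dup, "easy_to_hard")$left,
               dup$left[order(-abs(log2(dup$r_num)))])
  sh1 <- { set.seed(9); curriculum_order(p, "shuffled") }
  sh2 <- { set.seed(9); curriculum_order(p, "shuffled") }
  expect_identical(sh1, sh2)
  expect_error(curriculum_order(p, "random"), "arg")
})

test_that("checkpoints round-trip through save/load", {
  X <- toy_prototypes(100)
  m <- train_dbn(X, c(5, 3), epochs = 1, seed = 46, label = "young")
  path <- file.path(withr::local_tempdir(), "ckpt")
  save_dbn(m, path)
  back <- load_dbn(path)
  expect_equal(back$layers, m$layers)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(meta$label, "young")
  expect_equal(unlist(meta$arch), c(5, 3))
})
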