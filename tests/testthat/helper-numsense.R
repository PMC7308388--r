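# shared fixture builders (everything generated in code)

tiny_levels <- function() {
  default_space_levels(n_range = c(5, 10), size_range = c(2.6e5, 10.4e5) / 64,
                       spacing_range = c(0.8e7, 3.2e7) / 64, k = 3)
}

tiny_grid <- function(instances = 2) {
  lv <- tiny_levels()
  build_full_grid(lv$numerosity, lv$size, lv$spacing, instances)
}

# the full-protocol grid (no images rendered; nominal features only)
full_grid <- function(instances = 10) {
  lv <- default_space_levels()
  build_full_grid(lv$numerosity, lv$size, lv$spacing, instances)
}

# two-prototype binary toy dataset for RBM smoke training
toy_prototypes <- function(n = 500, seed = 7) {
  set.seed(seed)
  protos <- rbind(c(1, 1, 1, 1, 0, 0, 0, 0),
                  c(0, 0, 0, 0, 1, 1, 1, 1))
  idx <- sample(1:2, n, replace = TRUE)
  X <- protos[idx, ]
  flip <- matrix(runif(length(X)) < 0.05, nrow(X))
  X[flip] <- 1 - X[flip]
  X
}

# deterministic linearly separable "codes" for readout tests
separable_codes <- function(n = 200, d = 6, seed = 3) {
  set.seed(seed)
  lab <- rep(c("left", "right"), length.out = n)
  base <- matrix(runif(n * d, 0.2, 0.8), n, d)
  cl <- base
  cr <- base
  cl[lab == "left", 1] <- 0.95
  cl[lab == "left", 2] <- 0.05
  cr[lab == "right", 1] <- 0.95
  cr[lab == "right", 2] <- 0.05
  list(left = cl, right = cr, labels = lab)
}

# an untrained (random-weight) dbn for structural tests
untrained_dbn <- function(n_visible, arch = c(8, 4), seed = 11) {
  set.seed(seed)
  imgs <- matrix(runif(2 * n_visible), 2, n_visible)
  train_dbn(imgs, arch, epochs = 0, seed = seed)
}

# lower-triangle vector of a random symmetric dissimilarity matrix
random_rdm_acc <- function(k, seed) {
  set.seed(seed)
  runif(k * (k - 1) / 2)
}

# exhaustive pair-enumeration tau-A oracle
tau_a_oracle_acc <- function(x, y) {
  m <- length(x); conc <- 0; disc <- 0
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
    if (s > 0) conc <- conc + 1 else if (s < 0) disc <- disc + 1
  }
  (conc - disc) / (m * (m - 1) / 2)
}

new_rdm_for_test <- function(m, conditions = seq_len(nrow(m))) {
  numsense:::new_rdm(m, conditions, "test")
}

expect_rdm_valid <- function(rdm) {
  expect_s3_class(rdm, "rdm")
  expect_equal(diag(rdm$matrix), rep(0, nrow(rdm$matrix)),
               ignore_attr = TRUE)
  expect_lt(max(abs(rdm$matrix - t(rdm$matrix))), 1e-12)
}
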