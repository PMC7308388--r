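# independent brute-force tau-A oracle: explicit pair enumeration
tau_a_oracle <- function(x, y) {
  m <- length(x); conc <- 0; disc <- 0
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
    if (s > 0) conc <- conc + 1 else if (s < 0) disc <- disc + 1
  }
  (conc - disc) / (m * (m - 1) / 2)
}

random_rdm <- function(k, seed) {
  set.seed(seed)
  m <- matrix(0, k, k)
  m[lower.tri(m)] <- runif(k * (k - 1) / 2)
  m + t(m)
}

test_that("probe sets select grid levels by index", {
  lv <- default_space_levels()
  probe <- build_probe_set(lv, c(1, 9, 13), 10)
  expect_equal(nrow(probe), 270)
  expect_equal(nlevels(probe$condition), 27)
  expect_setequal(unique(probe$n), c(7, 18, 28))
  expect_equal(sort(unique(probe$spacing)),
               c(0.8e7, 0.8e7 * 4^(8 / 12), 3.2e7), tolerance = 1e-12)
  expect_equal(round(lv$numerosity[9]), 18)
  expect_equal(nrow(build_probe_set(lv, c(1, 9, 13), 1)), 27)
  expect_error(build_probe_set(lv, c(0, 9, 14)), "out of range")
})

test_that("mean activation patterns average codes within conditions", {
  model <- untrained_dbn(16, c(8, 5))
  set.seed(50)
  imgs <- matrix(runif(6 * 16), 6, 16)
  imgs[4, ] <- imgs[3, ]  # identical instances in condition b
  conds <- c("a", "a", "b", "b", "c", "c")
  pat <- mean_activation_patterns(model, imgs, conds)
  expect_equal(dim(pat), c(3, 5))
  codes <- encode(model, imgs)
  expect_equal(pat["b", ], codes[3, ], ignore_attr = TRUE)
  expect_equal(pat["a", ], (codes[1, ] + codes[2, ]) / 2,
               ignore_attr = TRUE)
  expect_error(mean_activation_patterns(model, imgs,
                                        factor(conds, levels = letters[1:4])),
               "empty condition")
})

test_that("model RDMs are 1 minus Pearson correlation", {
  p <- rbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8), c = c(4, 3, 2, 1))
  rdm <- model_rdm(p)
  expect_rdm_valid(rdm)
  expect_equal(rdm$matrix["a", "b"], 0)            # perfectly correlated
  expect_equal(rdm$matrix["a", "c"], 2)            # anticorrelated
  q <- rbind(x = c(0.1, 0.9, 0.4, 0.7), y = c(0.3, 0.2, 0.9, 0.5),
             z = c(0.8, 0.1, 0.2, 0.6))
  rdm2 <- model_rdm(q)
  for (i in 1:3) for (j in 1:3)
    expect_equal(rdm2$matrix[i, j], 1 - cor(q[i, ], q[j, ]))
  expect_error(model_rdm(rbind(c(1, 1, 1), c(1, 2, 3))), "zero-variance")
})

test_that("categorical RDMs are log-scale differences, scale invariant", {
  r <- categorical_rdm(c(a = 7, b = 28))
  expect_equal(r$matrix["a", "b"], 2)  # |log2 28 - log2 7|
  expect_equal(categorical_rdm(c(a = 5, b = 5))$matrix["a", "b"], 0)
  v <- c(a = 3, b = 11, c = 29)
  expect_equal(categorical_rdm(v * 17)$matrix, categorical_rdm(v)$matrix)
  expect_error(categorical_rdm(c(a = 1, b = -2)), "positive")
})

test_that("rank transform maps into [0,1] and is monotone invariant", {
  m <- random_rdm(6, 51)
  r <- rank_transform_rdm(new_rdm_for_test(m))
  expect_rdm_valid(r)
  lt <- r$matrix[lower.tri(r$matrix)]
  expect_equal(range(lt), c(0, 1))
  r2 <- rank_transform_rdm(new_rdm_for_test(m^3))  # monotone transform
  expect_equal(r$matrix, r2$matrix)
  flat <- rank_transform_rdm(new_rdm_for_test(0 * m + 1 - diag(6)))
  expect_equal(diff(range(flat$matrix[lower.tri(flat$matrix)])), 0)
})

test_that("kendall tau-A matches exhaustive enumeration", {
  expect_equal(kendall_tau_a(c(1, 2, 3, 4), c(1, 2, 3, 4)), 1)
  expect_equal(kendall_tau_a(c(1, 2, 3, 4), c(4, 3, 2, 1)), -1)
  expect_equal(kendall_tau_a(c(1, 2, 3, 4), c(1, 3, 2, 4)), 4 / 6)
  for (s in 1:10) {
    a <- random_rdm(8, 600 + s)
    b <- random_rdm(8, 700 + s)
    if (s %% 3 == 0) b[lower.tri(b)][1:5] <- a[lower.tri(a)][1:5] # ties
    b <- b * lower.tri(b); b <- b + t(b)
    expect_equal(kendall_tau_a(a[lower.tri(a)], b[lower.tri(b)]),
                 tau_a_oracle(a[lower.tri(a)], b[lower.tri(b)]))
  }
  ra <- new_rdm_for_test(random_rdm(4, 1), letters[1:4])
  rb <- new_rdm_for_test(random_rdm(4, 2), letters[2:5])
  expect_error(kendall_tau_a(ra, rb), "condition sets differ")
})

test_that("relatedness tests flag true structure and respect the null", {
  cand <- new_rdm_for_test(random_rdm(8, 52))
  reps <- lapply(1:8, function(i) {
    m <- cand$matrix + random_rdm(8, 1000 + i) * 0.01
    diag(m) <- 0
    new_rdm_for_test(m)
  })
  res <- relatedness_test(reps, list(true = cand), q = 0.01)
  expect_gt(res$tau, 0.9)
  expect_true(res$significant)
  # m = 1 candidate: BH reduces to the raw p-value
  expect_equal(res$p, res$p_bh)
  expect_error(relatedness_test(reps[1:3], list(true = cand)),
               ">= 5 replicates")
})

test_that("independent noise candidates are rarely significant", {
  false_pos <- vapply(1:100, function(run) {
    reps <- lapply(1:8, function(i) random_rdm(8, run * 100 + i))
    noise <- random_rdm(8, 99000 + run)
    suppressWarnings(
      relatedness_test(lapply(reps, new_rdm_for_test),
                       list(noise = new_rdm_for_test(noise)),
                       q = 0.01)$significant)
  }, logical(1))
  expect_lte(mean(false_pos), 0.05)
})

test_that("noise ceiling bounds behave as defined", {
  same <- lapply(1:4, function(i) new_rdm_for_test(random_rdm(7, 53)))
  nc <- noise_ceiling(same)
  expect_equal(unname(nc), c(1, 1))
  set.seed(54)
  for (i in 1:10) {
    reps <- lapply(1:5, function(j)
      random_rdm(6, sample.int(1e6, 1)))
    nc <- noise_ceiling(lapply(reps, new_rdm_for_test))
    expect_lte(nc[["lower"]], nc[["upper"]] + 1e-12)
  }
  two <- lapply(1:2, function(i) new_rdm_for_test(random_rdm(6, 60 + i)))
  nc2 <- noise_ceiling(two)
  lo_oracle <- mean(c(
    kendall_tau_a(two[[1]]$matrix[lower.tri(two[[1]]$matrix)],
                  two[[2]]$matrix[lower.tri(two[[2]]$matrix)]),
    kendall_tau_a(two[[2]]$matrix[lower.tri(two[[2]]$matrix)],
                  two[[1]]$matrix[lower.tri(two[[1]]$matrix)])))
  expect_equal(nc2[["lower"]], lo_oracle)
  expect_error(noise_ceiling(two[1]), ">= 2 replicates")
})

test_that("the RDM GLM recovers constructed coefficients", {
  p1 <- new_rdm_for_test(random_rdm(7, 55))
  p2 <- new_rdm_for_test(random_rdm(7, 56))
  target <- new_rdm_for_test(2 * p1$matrix + 3 * p2$matrix)
  beta <- rdm_glm_fit(target, list(a = p1, b = p2))
  expect_equal(unname(beta), c(2, 3), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(attr(beta, "intercept"), 0, tolerance = 1e-9)

  zero <- new_rdm_for_test(random_rdm(7, 57) * 0)
  expect_equal(unname(rdm_glm_fit(zero, list(a = p1, b = p2))), c(0, 0),
               tolerance = 1e-12, ignore_attr = TRUE)
  # order invariance
  b2 <- rdm_glm_fit(target, list(b = p2, a = p1))
  expect_equal(b2[["a"]], beta[["a"]], tolerance = 1e-9)
  expect_warning(rdm_glm_fit(target, list(a = p1, a2 = p1)), "collinear")
})

test_that("RDMs export with condition labels", {
  r <- new_rdm_for_test(random_rdm(4, 58), c("c1", "c2", "c3", "c4"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_rdm(r, path)
  back <- read.csv(path, row.names = 1)
  expect_equal(rownames(back), c("c1", "c2", "c3", "c4"))
  expect_equal(as.matrix(back), r$matrix, ignore_attr = TRUE)
})
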