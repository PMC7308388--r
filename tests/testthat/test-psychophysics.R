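sim_dataset <- function(n_pairs, betas, gamma, seed, rt_model = NULL) {
  set.seed(seed)
  p <- sample_uniform_pairs(full_grid(1), n_pairs)
  simulate_observer(p, betas, gamma, rt_model = rt_model)
}

test_that("RT outlier filter removes fast and slow trials per difficulty bin", {
  set.seed(30)
  p <- sample_comparison_pairs(full_grid(1), 100,
                               data.frame(lo = 0.5, hi = 0.6, fraction = 1))
  ch <- simulate_observer(p)
  ch$response_time <- runif(100, 400, 600)
  # direct mean/SD oracle: inject one extreme slow trial
  base <- ch$response_time[-1]
  ch$response_time[1] <- mean(ch$response_time) + 3 * sd(ch$response_time)
  keep_oracle <- ch$response_time <=
    mean(ch$response_time) + 2 * sd(ch$response_time)
  filtered <- filter_outlier_trials(ch)
  expect_equal(nrow(filtered), sum(keep_oracle))
  expect_equal(nrow(filtered), 99)
  expect_false(1 %in% which(filtered$response_time == ch$response_time[1]))

  # below presentation time
  ch$response_time[2] <- 100
  f2 <- filter_outlier_trials(ch, presentation_ms = 250)
  expect_equal(attr(f2, "removal_report")$n_fast, 1)

  ch$response_time <- NULL
  expect_warning(f3 <- filter_outlier_trials(ch), "skipped")
  expect_equal(nrow(f3), nrow(ch))
})

test_that("gamma = 0 reproduces an ordinary probit regression", {
  ch <- sim_dataset(3000, c(side = 0.1, num = 1.5, size = 0.3,
                            spacing = 0.2), gamma = 0, seed = 31)
  fit <- fit_choice_glm(ch, "fixed", gamma = 0)
  y <- as.numeric(ch$chosen_side == "right")
  ref <- glm(y ~ log2(ch$r_num) + log2(ch$r_size) + log2(ch$r_spacing),
             family = binomial("probit"))
  expect_equal(unname(fit$coefficients), unname(coef(ref)),
               tolerance = 1e-4)
  expect_equal(fit$deviance, deviance(ref), tolerance = 1e-6)
})

test_that("known observer parameters are recovered", {
  true <- c(side = 0, num = 2, size = 0.4, spacing = 0.3)
  ch <- sim_dataset(15200, true, gamma = 0.01, seed = 32)
  fit <- fit_choice_glm(ch, "fixed", gamma = 0.01)
  expect_equal(fit$gamma, 0.01)
  expect_lt(max(abs(fit$coefficients - true)), 0.1)
  expect_gt(fit$adj_r2, 0.3)
  expect_true(all(is.finite(fit$se)) && all(fit$se > 0))
})

test_that("random choices yield a non-significant numerosity coefficient", {
  ch <- sim_dataset(2000, c(side = 0, num = 0, size = 0, spacing = 0),
                    gamma = 0, seed = 33)
  fit <- fit_choice_glm(ch, "fixed", gamma = 0)
  z <- fit$coefficients[["num"]] / fit$se[["num"]]
  expect_gt(2 * pnorm(-abs(z)), 0.05)
})

test_that("deviance-grid gamma selection minimizes deviance on the grid", {
  ch <- sim_dataset(4000, c(side = 0, num = 2, size = 0.4, spacing = 0.3),
                    gamma = 0.05, seed = 34)
  grid <- seq(0, 0.1, by = 0.025)
  fit <- fit_choice_glm(ch, "grid", gamma_grid = grid)
  expect_true(fit$gamma %in% grid)
  devs <- vapply(grid, function(g)
    fit_choice_glm(ch, "fixed", gamma = g)$deviance, numeric(1))
  expect_equal(fit$gamma, grid[which.min(devs)])
})

test_that("discrimination vector geometry obeys the projection identity", {
  v <- discrimination_vector(c(num = 2, size = 0, spacing = 0))
  expect_equal(v$magnitude, 2)
  expect_equal(project_onto_axes(v, "numerosity")[["numerosity"]], 2)
  expect_equal(project_onto_axes(v, "tsa")[["tsa"]], 2 / sqrt(2))
  expect_equal(project_onto_axes(v, "spacing")[["spacing"]], 0)
  expect_equal(discrimination_vector(c(num = 1, size = 1,
                                       spacing = 0))$magnitude, sqrt(2))
  set.seed(35)
  for (i in 1:25) {
    v <- discrimination_vector(c(num = rnorm(1), size = rnorm(1),
                                 spacing = rnorm(1)))
    pr <- project_onto_axes(v, c("numerosity", "size", "spacing"))
    expect_equal(sum(pr^2), v$magnitude^2, tolerance = 1e-9)
  }
  bad <- matrix(c(2, 0, 0), 1, dimnames = list("x", NULL))
  expect_error(project_onto_axes(v, bad), "unit-norm")
})

test_that("angles to axes rank features by closeness", {
  v <- discrimination_vector(c(num = 1, size = 0, spacing = 0))
  a <- angles_to_axes(v)
  expect_equal(a$angles[["numerosity"]], 0)
  expect_equal(a$angles[["total_perimeter"]], acos(3 / sqrt(10)) * 180 / pi,
               tolerance = 1e-9)
  expect_equal(a$ranking[1], "numerosity")

  tp <- discrimination_vector(c(num = 3, size = 1, spacing = 0))
  expect_equal(angles_to_axes(tp)$angles[["total_perimeter"]], 0,
               tolerance = 1e-7)
  eq <- angles_to_axes(discrimination_vector(c(num = 1, size = 1,
                                               spacing = 1)),
                       c("numerosity", "size", "spacing"))
  expect_equal(diff(range(eq$angles)), 0, tolerance = 1e-9)
  expect_error(angles_to_axes(discrimination_vector(
    c(num = 0, size = 0, spacing = 0))), "zero vector")
})

test_that("weber fraction follows the adopted closed form", {
  expect_equal(weber_fraction(2), log(2) / (sqrt(2) * 2))
  expect_equal(weber_fraction(2), 0.2451, tolerance = 1e-3)
  expect_equal(weber_fraction(1), 2 * weber_fraction(2))
  expect_error(weber_fraction(-1), "undefined acuity")
})

test_that("group-level tests pick the right procedure and threshold", {
  set.seed(36)
  r <- group_level_stats(rnorm(20, 1), mu = 0, m = 5)
  expect_equal(r$threshold, 0.01)
  x <- rnorm(15)
  same <- group_level_stats(x, x, comparison = "paired")
  expect_false(same$significant)
  skewed <- rexp(30)^3
  r2 <- group_level_stats(skewed, mu = 0)
  expect_equal(r2$test, "wilcoxon")
  r3 <- group_level_stats(rnorm(20), rnorm(20) + 3,
                          comparison = "two_sample")
  expect_equal(r3$test, "mann-whitney")
  expect_true(r3$significant)
  expect_error(group_level_stats(1), ">= 2 observations")
})

test_that("one-sample test attains its nominal type-I error", {
  set.seed(37)
  rej <- vapply(1:1000, function(i)
    group_level_stats(rnorm(20), mu = 0)$significant, logical(1))
  rate <- mean(rej)
  ci <- 0.05 + c(-1, 1) * 2.58 * sqrt(0.05 * 0.95 / 1000)
  expect_gt(rate, ci[1])
  expect_lt(rate, ci[2])
})

test_that("coefficient recovery is unbiased (small replicate check)", {
  true <- c(side = 0, num = 2, size = 0.4, spacing = 0.3)
  est <- t(vapply(1:5, function(s) {
    ch <- sim_dataset(6000, true, gamma = 0.01, seed = 300 + s)
    fit_choice_glm(ch, "fixed", gamma = 0.01)$coefficients
  }, numeric(4)))
  bias <- colMeans(est) - true
  expect_lt(max(abs(bias[c("num", "size", "spacing")] /
                      true[c("num", "size", "spacing")])), 0.05)
})

test_that("fits serialize to JSON", {
  ch <- sim_dataset(2000, c(side = 0, num = 2, size = 0.4, spacing = 0.3),
                    gamma = 0.01, seed = 38)
  fit <- fit_choice_glm(ch)
  path <- withr::local_tempfile(fileext = ".json")
  write_glm_fit(fit, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$coefficients$num, fit$coefficients[["num"]])
  expect_equal(back$gamma, 0.01)
})
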