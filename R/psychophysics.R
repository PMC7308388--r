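#' Filter outlier trials by response time
#'
#' Removes trials whose response time is below the stimulus presentation
#' time, then, within each numerosity-ratio difficulty bin, trials slower
#' than the bin mean plus two standard deviations. Difficulty bins default
#' to the protocol's quota bins plus a catch-all `[0.9, 1)`.
#'
#' @param data `choice_data` with a `response_time` column (ms). Without
#'   response times the filter is skipped with a warning (network-generated
#'   choices carry no RTs).
#' @param presentation_ms stimulus presentation duration (default 250 ms).
#' @param bins `data.frame(lo, hi)` of min/max numerosity-ratio bins.
#' @return Filtered `choice_data`; attribute `"removal_report"` holds a list
#'   with counts `n_fast`, `n_slow`, `n_kept`.
#' @export
filter_outlier_trials <- function(data, presentation_ms = 250,
                                  bins = rbind(protocol_ratio_quotas()[, 1:2],
                                               data.frame(lo = 0.9, hi = 1))) {
  if (is.null(data$response_time)) {
    warning("filter_outlier_trials: no response times; filter skipped")
    attr(data, "removal_report") <- list(n_fast = 0, n_slow = 0,
                                         n_kept = nrow(data))
    return(data)
  }
  fast <- data$response_time < presentation_ms
  kept <- data[!fast, , drop = FALSE]
  ratio <- pmin(kept$r_num, 1 / kept$r_num)
  slow <- logical(nrow(kept))
  for (k in seq_len(nrow(bins))) {
    idx <- ratio >= bins$lo[k] & ratio < bins$hi[k]
    if (sum(idx) < 2) next
    rt <- kept$response_time[idx]
    slow[idx] <- rt > mean(rt) + 2 * stats::sd(rt)
  }
  out <- kept[!slow, , drop = FALSE]
  attr(out, "removal_report") <- list(n_fast = sum(fast),
                                      n_slow = sum(slow),
                                      n_kept = nrow(out))
  out
}

# negative log-likelihood and analytic gradient of the choice model
choice_nll <- function(beta, X, y, gamma) {
  eta <- drop(X %*% beta)
  p <- (1 - gamma) * (stats::pnorm(eta) - 0.5) + 0.5
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -sum(y * log(p) + (1 - y) * log(1 - p))
}

choice_nll_grad <- function(beta, X, y, gamma) {
  eta <- drop(X %*% beta)
  p <- (1 - gamma) * (stats::pnorm(eta) - 0.5) + 0.5
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  w <- (1 - gamma) * stats::dnorm(eta) * (y / p - (1 - y) / (1 - p))
  -drop(crossprod(X, w))
}

#' Fit the probit choice model with guessing factor
#'
#' Maximum-likelihood fit of
#' `P(choose right) = (1-gamma)*(pnorm(eta) - 1/2) + 1/2` with
#' `eta = b_side + b_num*log2(r_num) + b_size*log2(r_size) +
#' b_spacing*log2(r_spacing)`. The guessing factor is either held fixed
#' (protocol value 0.01) or chosen on a grid to minimize model deviance.
#' With `gamma = 0` this reduces to an ordinary probit GLM.
#'
#' @param data `choice_data` data frame (`chosen_side`, ratio columns).
#' @param gamma_mode `"fixed"` or `"grid"`.
#' @param gamma fixed guessing rate (used when `gamma_mode = "fixed"`).
#' @param gamma_grid candidate values for `"grid"` mode.
#' @return Object of class `glm_fit`: coefficients
#'   `(side, num, size, spacing)`, `gamma`, `deviance`, `null_deviance`,
#'   `adj_r2` (McFadden adjusted), `se`, `loglik`, `n_trials`.
#' @export
fit_choice_glm <- function(data, gamma_mode = c("fixed", "grid"),
                           gamma = 0.01,
                           gamma_grid = seq(0, 0.1, by = 0.005)) {
  gamma_mode <- match.arg(gamma_mode)
  y <- as.numeric(data$chosen_side == "right")
  X <- cbind(side = 1, num = log2(data$r_num),
             size = log2(data$r_size), spacing = log2(data$r_spacing))
  if (nrow(X) < ncol(X))
    stop("fit_choice_glm: fewer trials than coefficients", call. = FALSE)
  if (length(unique(X[, "num"])) < 2)
    stop("fit_choice_glm: need >= 2 distinct ratio values", call. = FALSE)

  fit_one <- function(g) {
    # plain probit fit as a starting point (exact when g = 0)
    start <- tryCatch(
      stats::coef(suppressWarnings(stats::glm.fit(
        X, y, family = stats::binomial("probit")))),
      error = function(e) rep(0, ncol(X)))
    start[!is.finite(start)] <- 0
    opt <- stats::optim(start, choice_nll, choice_nll_grad,
                        X = X, y = y, gamma = g, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-12))
    opt
  }
  if (gamma_mode == "fixed") {
    if (gamma < 0 || gamma >= 1)
      stop("fit_choice_glm: gamma must be in [0, 1)", call. = FALSE)
    opt <- fit_one(gamma)
    g <- gamma
  } else {
    fits <- lapply(gamma_grid, fit_one)
    best <- which.min(vapply(fits, `[[`, numeric(1), "value"))
    opt <- fits[[best]]
    g <- gamma_grid[best]
  }
  if (opt$convergence != 0)
    stop("fit_choice_glm: optimizer failed to converge (code ",
         opt$convergence, ")", call. = FALSE)
  beta <- opt$par
  names(beta) <- colnames(X)
  ll <- -opt$value
  # null model: side bias only, same gamma
  opt0 <- stats::optim(0, function(b) choice_nll(b, X[, 1, drop = FALSE],
                                                 y, g),
                       method = "Brent", lower = -10, upper = 10)
  ll0 <- -opt0$value
  k <- length(beta)
  H <- stats::optimHess(beta, choice_nll, choice_nll_grad,
                        X = X, y = y, gamma = g)
  se <- tryCatch(sqrt(diag(solve(H))), error = function(e)
    rep(NA_real_, k))
  names(se) <- names(beta)
  structure(list(
    coefficients = beta, gamma = g,
    deviance = 2 * opt$value, null_deviance = 2 * opt0$value,
    loglik = ll,
    adj_r2 = 1 - (ll - k) / ll0,
    se = se, n_trials = length(y)
  ), class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat("Probit choice model with guessing factor\n")
  cat(sprintf("  gamma = %.3f, n = %d, deviance = %.1f, adj R2 = %.3f\n",
              x$gamma, x$n_trials, x$deviance, x$adj_r2))
  print(round(rbind(estimate = x$coefficients, se = x$se), 4))
  invisible(x)
}

#' Discrimination vector of a fitted choice model
#'
#' The `(b_num, b_size, b_spacing)` coefficient vector in the orthonormal
#' log-stimulus space. Its direction reveals which stimulus dimensions
#' drive choices; its magnitude indexes discrimination acuity.
#'
#' @param fit a `glm_fit` (or a named numeric with `num`, `size`,
#'   `spacing`).
#' @return Object of class `discrimination_vector`: `components` and
#'   `magnitude`.
#' @export
discrimination_vector <- function(fit) {
  b <- if (inherits(fit, "glm_fit")) fit$coefficients else fit
  v <- c(num = unname(b[["num"]]), size = unname(b[["size"]]),
         spacing = unname(b[["spacing"]]))
  structure(list(components = v, magnitude = sqrt(sum(v^2))),
            class = "discrimination_vector")
}

as_vec3 <- function(v) {
  if (inherits(v, "discrimination_vector")) v$components else v
}

#' Project a discrimination vector onto feature axes
#'
#' Signed scalar projections `dot(v, axis)` onto unit feature axes; the
#' projection on a feature measures how much that feature contributes to
#' the observer's choices.
#'
#' @param v `discrimination_vector` or numeric 3-vector.
#' @param axes character feature names or a matrix from [feature_axes()].
#' @return Named numeric vector of projections.
#' @export
project_onto_axes <- function(v, axes = feature_axis_names()) {
  if (is.character(axes)) axes <- feature_axes(axes)
  nrm <- sqrt(rowSums(axes^2))
  if (any(abs(nrm - 1) > 1e-9))
    stop("project_onto_axes: axes must be unit-norm", call. = FALSE)
  drop(axes %*% as_vec3(v))
}

#' Angles between a discrimination vector and feature axes
#'
#' @inheritParams project_onto_axes
#' @return List with `angles` (degrees, named) and `ranking` (feature names
#'   ordered by increasing angle).
#' @export
angles_to_axes <- function(v, axes = feature_axis_names()) {
  vv <- as_vec3(v)
  if (sqrt(sum(vv^2)) == 0)
    stop("angles_to_axes: zero vector", call. = FALSE)
  if (is.character(axes)) axes <- feature_axes(axes)
  ang <- apply(axes, 1, function(a) angle_between(vv, a))
  list(angles = ang, ranking = names(sort(ang)))
}

#' Weber fraction from the numerosity coefficient
#'
#' Converts the numerosity coefficient of the choice model into a Weber
#' fraction under the equal-variance log-Gaussian discrimination model,
#' `w = ln(2) / (sqrt(2) * b_num)`: the convention equates
#' `pnorm(b_num * log2 r)` with `pnorm(ln(r) / (sqrt(2) * w))`. Smaller
#' `w` means finer number acuity. The conversion convention is a package
#' choice (see the methods vignette), not a claim about any external
#' source.
#'
#' @param fit a `glm_fit` or a positive number (`b_num`).
#' @return Weber fraction `w`.
#' @export
weber_fraction <- function(fit) {
  b <- if (inherits(fit, "glm_fit")) fit$coefficients[["num"]] else fit
  if (!is.finite(b) || b <= 0)
    stop("weber_fraction: undefined acuity (b_num <= 0)", call. = FALSE)
  log(2) / (sqrt(2) * b)
}

#' Group-level statistics with normality-gated tests
#'
#' One-sample and paired comparisons use a t-test when Shapiro-Wilk does
#' not reject normality at `alpha`, and a Wilcoxon signed-rank test
#' otherwise; two-sample unpaired comparisons use the Mann-Whitney U test.
#' P-value thresholds are Bonferroni-corrected for `m` comparisons.
#'
#' @param x numeric vector of per-observer values (e.g. coefficients or
#'   projections).
#' @param y optional second sample (paired or two-sample comparisons).
#' @param comparison `"one_sample"`, `"paired"` or `"two_sample"`.
#' @param mu null value for one-sample tests.
#' @param m number of comparisons in the family (Bonferroni).
#' @param alpha family-wise significance level.
#' @return `data.frame` row: test used, statistic, `p`, adjusted threshold
#'   `alpha/m`, and `significant`.
#' @export
group_level_stats <- function(x, y = NULL,
                              comparison = c("one_sample", "paired",
                                             "two_sample"),
                              mu = 0, m = 1, alpha = 0.05) {
  comparison <- match.arg(comparison)
  if (length(x) < 2)
    stop("group_level_stats: need >= 2 observations", call. = FALSE)
  thr <- alpha / m
  normal_ok <- function(v) {
    if (length(unique(v)) < 3) return(FALSE)
    stats::shapiro.test(v)$p.value > alpha
  }
  if (comparison == "one_sample") {
    if (normal_ok(x)) {
      tt <- stats::t.test(x, mu = mu)
      res <- c(test = "t", stat = unname(tt$statistic), p = tt$p.value)
    } else {
      wt <- suppressWarnings(stats::wilcox.test(x, mu = mu))
      res <- c(test = "wilcoxon", stat = unname(wt$statistic),
               p = wt$p.value)
    }
  } else if (comparison == "paired") {
    stopifnot(length(x) == length(y))
    d <- x - y
    if (all(d == 0)) {
      res <- c(test = "degenerate", stat = 0, p = 1)
    } else if (normal_ok(d)) {
      tt <- stats::t.test(x, y, paired = TRUE)
      res <- c(test = "t", stat = unname(tt$statistic), p = tt$p.value)
    } else {
      wt <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE))
      res <- c(test = "wilcoxon", stat = unname(wt$statistic),
               p = wt$p.value)
    }
  } else {
    wt <- suppressWarnings(stats::wilcox.test(x, y))
    res <- c(test = "mann-whitney", stat = unname(wt$statistic),
             p = wt$p.value)
  }
  data.frame(test = res[["test"]],
             statistic = as.numeric(res[["stat"]]),
             p = as.numeric(res[["p"]]),
             threshold = thr,
             significant = as.numeric(res[["p"]]) < thr)
}

#' Serialize a choice-model fit as JSON
#' @param fit `glm_fit`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_glm_fit <- function(fit, path) {
  jsonlite::write_json(list(
    coefficients = as.list(fit$coefficients),
    gamma = fit$gamma, deviance = fit$deviance,
    null_deviance = fit$null_deviance, adj_r2 = fit$adj_r2,
    se = as.list(fit$se), n_trials = fit$n_trials
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
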