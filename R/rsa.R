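#' Build the RSA probe set by grid index
#'
#' Selects one level per dimension by (1-based) index into the 13-level log
#' grids and takes the Cartesian product with fresh instances. The default
#' indices `(1, 9, 13)` reproduce the canonical probe levels - numerosity
#' (7, 18, 28), Size (2.60, 6.55, 10.40) x 1e5, Spacing (0.80, 2.02, 3.20)
#' x 1e7: the printed middle values match grid index 9 (0-based 8), not the
#' geometric midpoint (see the methods vignette).
#'
#' @param levels list from [default_space_levels()] (or any level grids).
#' @param level_indices integer indices into each grid (same triple used
#'   for all three dimensions, or a list of three index vectors).
#' @param instances images per condition.
#' @return A `stimulus_grid` with a `condition` label column
#'   (`n<su>_s<i>_p<j>` style labels shared by instances).
#' @export
build_probe_set <- function(levels = default_space_levels(),
                            level_indices = c(1, 9, 13),
                            instances = 10) {
  idx <- if (is.list(level_indices)) level_indices else
    list(level_indices, level_indices, level_indices)
  check <- function(i, g) {
    if (any(i < 1 | i > length(g)))
      stop("build_probe_set: level index out of range", call. = FALSE)
    g[i]
  }
  g <- build_full_grid(check(idx[[1]], levels$numerosity),
                       check(idx[[2]], levels$size),
                       check(idx[[3]], levels$spacing),
                       instances)
  g$condition <- interaction(
    paste0("n", g$n),
    paste0("s", match(g$size, sort(unique(g$size)))),
    paste0("p", match(g$spacing, sort(unique(g$spacing)))),
    sep = "_", drop = TRUE)
  g
}

#' Condition-mean activation patterns
#'
#' Encodes every probe image through the network and averages top-layer
#' activations over instances of the same feature combination.
#'
#' @param model a `dbn`.
#' @param images matrix of flattened probe images (rows align with
#'   `conditions`).
#' @param conditions factor/character of condition labels per image.
#' @return Matrix: one row per condition (rownames = labels), columns =
#'   top-layer units.
#' @export
mean_activation_patterns <- function(model, images, conditions) {
  conditions <- as.factor(conditions)
  if (any(table(conditions) == 0))
    stop("mean_activation_patterns: empty condition", call. = FALSE)
  codes <- encode(model, images)
  g <- rowsum(codes, conditions)
  g / as.vector(table(conditions))
}

new_rdm <- function(m, conditions, metric) {
  dimnames(m) <- list(conditions, conditions)
  diag(m) <- 0
  structure(list(matrix = m, conditions = as.character(conditions),
                 metric = metric), class = "rdm")
}

#' Representational dissimilarity matrix (1 - Pearson correlation)
#'
#' @param patterns matrix of condition-mean activation patterns (rows =
#'   conditions, rownames = labels).
#' @return An `rdm` (symmetric, zero diagonal).
#' @export
model_rdm <- function(patterns) {
  if (nrow(patterns) < 2)
    stop("model_rdm: need >= 2 patterns", call. = FALSE)
  v <- apply(patterns, 1, stats::sd)
  if (any(v == 0))
    stop("model_rdm: zero-variance pattern (correlation undefined)",
         call. = FALSE)
  new_rdm(1 - stats::cor(t(patterns)),
          rownames(patterns) %||% seq_len(nrow(patterns)),
          "1 - Pearson r")
}

#' Categorical model RDM from feature values
#'
#' Dissimilarity between two conditions is the absolute difference of
#' their feature values on a log scale, `|log2 f_i - log2 f_j|` - so the
#' RDM is invariant to rescaling the feature.
#'
#' @param values positive feature value per condition.
#' @param conditions labels (defaults to names of `values`).
#' @param name metric label stored in the RDM.
#' @return An `rdm`.
#' @export
categorical_rdm <- function(values, conditions = names(values),
                            name = "log feature distance") {
  if (any(values <= 0))
    stop("categorical_rdm: feature values must be positive", call. = FALSE)
  lv <- log2(values)
  new_rdm(abs(outer(lv, lv, "-")),
          conditions %||% seq_along(values), name)
}

#' Rank-transform an RDM for display
#'
#' Off-diagonal cells are replaced by their ranks (average ranks on ties)
#' and scaled into `[0, 1]`; any monotone transform of the input yields
#' the same output.
#'
#' @param rdm an `rdm`.
#' @return An `rdm` with transformed cells.
#' @export
rank_transform_rdm <- function(rdm) {
  m <- rdm$matrix
  lt <- lower.tri(m)
  r <- rank(m[lt])
  if (max(r) > min(r)) r <- (r - min(r)) / (max(r) - min(r)) else r <- r * 0
  m[lt] <- r
  m[upper.tri(m)] <- t(m)[upper.tri(m)]
  new_rdm(m, rdm$conditions, paste0(rdm$metric, " (rank)"))
}

rdm_lower <- function(rdm) {
  m <- if (inherits(rdm, "rdm")) rdm$matrix else rdm
  m[lower.tri(m)]
}

#' Kendall tau-A correlation between two RDMs
#'
#' `tau_A = (concordant - discordant) / (m*(m-1)/2)` over the `m`
#' lower-triangle cells; tied pairs count as neither concordant nor
#' discordant (they penalize the correlation, which makes tau-A the
#' appropriate statistic when candidate models predict tied
#' dissimilarities).
#'
#' @param rdm_a,rdm_b `rdm`s over the same condition set (numeric vectors
#'   are accepted for testing).
#' @return Correlation in `[-1, 1]`.
#' @export
kendall_tau_a <- function(rdm_a, rdm_b) {
  if (inherits(rdm_a, "rdm") && inherits(rdm_b, "rdm") &&
      !identical(rdm_a$conditions, rdm_b$conditions))
    stop("kendall_tau_a: condition sets differ", call. = FALSE)
  x <- if (is.numeric(rdm_a) && is.null(dim(rdm_a))) rdm_a else
    rdm_lower(rdm_a)
  y <- if (is.numeric(rdm_b) && is.null(dim(rdm_b))) rdm_b else
    rdm_lower(rdm_b)
  m <- length(x)
  dx <- sign(outer(x, x, "-"))
  dy <- sign(outer(y, y, "-"))
  s <- sum((dx * dy)[lower.tri(dx)])
  s / (m * (m - 1) / 2)
}

#' Relatedness of candidate RDMs to a set of replicate model RDMs
#'
#' For each candidate, computes tau-A against every replicate (seed) RDM,
#' runs a one-sided Wilcoxon signed-rank test of the tau values against
#' zero, and controls the false discovery rate across candidates by
#' Benjamini-Hochberg at `q`.
#'
#' @param model_rdms list of `rdm`s, one per seed/replicate (>= 5).
#' @param candidates named list of candidate `rdm`s.
#' @param q FDR level.
#' @return `data.frame`: candidate, mean tau, tau SE, `p`, `p_bh`,
#'   `significant`.
#' @export
relatedness_test <- function(model_rdms, candidates, q = 0.01) {
  if (length(model_rdms) < 5)
    stop("relatedness_test: need >= 5 replicates", call. = FALSE)
  taus <- sapply(candidates, function(cand)
    vapply(model_rdms, kendall_tau_a, numeric(1), rdm_b = cand))
  p <- apply(taus, 2, function(tv)
    suppressWarnings(stats::wilcox.test(tv, mu = 0,
                                        alternative = "greater"))$p.value)
  p_bh <- stats::p.adjust(p, "BH")
  data.frame(candidate = colnames(taus),
             tau = colMeans(taus),
             tau_se = apply(taus, 2, stats::sd) / sqrt(nrow(taus)),
             p = p, p_bh = p_bh,
             significant = p_bh < q,
             row.names = NULL)
}

#' Noise ceiling for RDM correlations
#'
#' Bounds on the best tau-A any model could achieve given replicate
#' variability: the upper bound averages each replicate's correlation with
#' the mean RDM including itself; the lower bound uses the leave-one-out
#' mean.
#'
#' @param model_rdms list of `rdm`s (>= 2 replicates).
#' @return Named numeric `c(lower =, upper =)` with `lower <= upper`.
#' @export
noise_ceiling <- function(model_rdms) {
  k <- length(model_rdms)
  if (k < 2)
    stop("noise_ceiling: need >= 2 replicates", call. = FALSE)
  mats <- lapply(model_rdms, rdm_lower)
  all_mean <- Reduce(`+`, mats) / k
  up <- mean(vapply(mats, function(m) kendall_tau_a(m, all_mean),
                    numeric(1)))
  lo <- mean(vapply(seq_len(k), function(i) {
    loo <- (all_mean * k - mats[[i]]) / (k - 1)
    kendall_tau_a(mats[[i]], loo)
  }, numeric(1)))
  c(lower = lo, upper = up)
}

#' Fit a GLM to an RDM with candidate RDMs as predictors
#'
#' Ordinary least squares of the vectorized lower triangle of the target
#' on the predictor triangles plus an intercept. Collinear predictors
#' trigger a rank-deficiency warning and a minimum-norm (pseudoinverse)
#' solution.
#'
#' @param target an `rdm`.
#' @param predictors named list of `rdm`s over the same conditions.
#' @return Named coefficient vector (excluding the intercept), with the
#'   intercept as attribute `"intercept"`.
#' @export
rdm_glm_fit <- function(target, predictors) {
  y <- rdm_lower(target)
  X <- cbind(intercept = 1,
             sapply(predictors, rdm_lower))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    warning("rdm_glm_fit: collinear predictors; minimum-norm solution")
    sv <- svd(X)
    pos <- sv$d > max(sv$d) * 1e-10
    beta <- sv$v[, pos] %*% ((crossprod(sv$u[, pos], y)) / sv$d[pos])
    beta <- drop(beta)
  } else {
    beta <- qr.coef(qx, y)
  }
  names(beta) <- colnames(X)
  out <- beta[-1]
  attr(out, "intercept") <- unname(beta[1])
  out
}

#' Write an RDM as CSV with condition labels
#' @param rdm an `rdm`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rdm <- function(rdm, path) {
  utils::write.csv(as.data.frame(rdm$matrix), path, row.names = TRUE)
  invisible(path)
}
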