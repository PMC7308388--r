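#' Ratio-bin oversampling quotas for the comparison protocol
#'
#' The human protocol oversamples difficult numerosity ratios: 10% of pairs
#' with min/max ratio in `[0.5, 0.6)`, 20% in `[0.6, 0.7)`, 30% in
#' `[0.7, 0.8)` and 40% in `[0.8, 0.9)`. Bins are half-open.
#'
#' @return `data.frame` with columns `lo`, `hi`, `fraction`.
#' @export
protocol_ratio_quotas <- function() {
  data.frame(lo = c(0.5, 0.6, 0.7, 0.8),
             hi = c(0.6, 0.7, 0.8, 0.9),
             fraction = c(0.1, 0.2, 0.3, 0.4))
}

pair_frame <- function(dataset, left, right) {
  p <- data.frame(
    left = left, right = right,
    n_left = dataset$n[left], n_right = dataset$n[right],
    r_num = dataset$n[right] / dataset$n[left],
    r_size = dataset$size[right] / dataset$size[left],
    r_spacing = dataset$spacing[right] / dataset$spacing[left]
  )
  p$correct_side <- ifelse(p$r_num > 1, "right", "left")
  class(p) <- c("trial_pairs", "data.frame")
  p
}

#' Sample comparison pairs with exact ratio-bin quotas
#'
#' Draws `n_pairs` two-stimulus trials whose numerosity ratio (expressed as
#' min/max) falls in prescribed difficulty bins with *exact* per-bin counts
#' (`fraction * n_pairs` must be integral). Left/right assignment is
#' randomized; equal-numerosity pairs never occur.
#'
#' @param dataset stimulus `data.frame` (`n`, `size`, `spacing` columns).
#' @param n_pairs number of trials.
#' @param quotas `data.frame(lo, hi, fraction)`; fractions must sum to 1.
#' @return A `trial_pairs` data frame with `left`/`right` row indices into
#'   `dataset`, per-dimension ratios and `correct_side`.
#' @export
sample_comparison_pairs <- function(dataset, n_pairs,
                                    quotas = protocol_ratio_quotas()) {
  if (abs(sum(quotas$fraction) - 1) > 1e-9)
    stop("sample_comparison_pairs: quota fractions must sum to 1",
         call. = FALSE)
  counts <- quotas$fraction * n_pairs
  if (any(abs(counts - round(counts)) > 1e-9))
    stop("sample_comparison_pairs: fraction * n_pairs must be integral",
         call. = FALSE)
  counts <- round(counts)
  nlev <- sort(unique(dataset$n))
  # all ordered level pairs and their min/max ratio
  lp <- expand.grid(a = nlev, b = nlev)
  lp <- lp[lp$a != lp$b, ]
  lp$ratio <- pmin(lp$a, lp$b) / pmax(lp$a, lp$b)
  left <- integer(0); right <- integer(0)
  for (k in seq_len(nrow(quotas))) {
    ok <- lp$ratio >= quotas$lo[k] & lp$ratio < quotas$hi[k]
    if (!any(ok) && counts[k] > 0)
      stop("sample_comparison_pairs: no level pair satisfies bin [",
           quotas$lo[k], ", ", quotas$hi[k], ")", call. = FALSE)
    idx <- sample(which(ok), counts[k], replace = TRUE)
    for (i in idx) {
      li <- sample(which(dataset$n == lp$a[i]), 1)
      ri <- sample(which(dataset$n == lp$b[i]), 1)
      left <- c(left, li); right <- c(right, ri)
    }
  }
  p <- pair_frame(dataset, left, right)
  p[sample.int(nrow(p)), , drop = FALSE]
}

#' Sample uniform comparison pairs without replacement
#'
#' Draws ordered (left, right) image combinations uniformly without
#' replacement; pairs with equal numerosity are rejected and resampled.
#' This is the trial source for network simulations and synthetic
#' observers.
#'
#' @param dataset stimulus `data.frame`.
#' @param n_pairs number of pairs; must not exceed the number of distinct
#'   ordered combinations.
#' @return A `trial_pairs` data frame.
#' @export
sample_uniform_pairs <- function(dataset, n_pairs) {
  N <- nrow(dataset)
  if (length(unique(dataset$n)) < 2)
    stop("sample_uniform_pairs: need >= 2 numerosity levels", call. = FALSE)
  if (n_pairs > N * (N - 1))
    stop("sample_uniform_pairs: n_pairs exceeds available combinations",
         call. = FALSE)
  if (n_pairs == 0) return(pair_frame(dataset, integer(0), integer(0)))
  seen <- new.env(hash = TRUE, size = 2L * n_pairs)
  left <- integer(n_pairs); right <- integer(n_pairs)
  got <- 0L
  while (got < n_pairs) {
    m <- max(64L, 2L * (n_pairs - got))
    li <- sample.int(N, m, replace = TRUE)
    ri <- sample.int(N, m, replace = TRUE)
    for (j in seq_len(m)) {
      if (li[j] == ri[j]) next
      if (dataset$n[li[j]] == dataset$n[ri[j]]) next
      key <- paste0(li[j], "_", ri[j])
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      got <- got + 1L
      left[got] <- li[j]; right[got] <- ri[j]
      if (got == n_pairs) break
    }
  }
  pair_frame(dataset, left, right)
}

#' Label per-dimension congruency of trial pairs
#'
#' A non-numerical dimension is congruent when it varies in the same
#' direction as numerosity (sign of log ratio matches), incongruent when it
#' varies in the opposite direction, and neutral when its ratio is 1.
#'
#' @param pairs a `trial_pairs` data frame (`r_num != 1` on every row).
#' @return `pairs` with added `size_congruency` and `spacing_congruency`
#'   factors in `{congruent, incongruent, neutral}`.
#' @export
label_congruency <- function(pairs) {
  if (any(pairs$r_num == 1))
    stop("label_congruency: r_num must differ from 1", call. = FALSE)
  lab <- function(r) {
    s <- sign(log(r)) * sign(log(pairs$r_num))
    factor(ifelse(r == 1, "neutral",
                  ifelse(s > 0, "congruent", "incongruent")),
           levels = c("congruent", "incongruent", "neutral"))
  }
  pairs$size_congruency <- lab(pairs$r_size)
  pairs$spacing_congruency <- lab(pairs$r_spacing)
  pairs
}

#' Closed-form choice probability of the observer model
#'
#' Probability of choosing the right stimulus under the probit choice model
#' with guessing factor:
#' `P = (1 - gamma) * (pnorm(eta) - 1/2) + 1/2`, with
#' `eta = b_side + b_num*log2(r_num) + b_size*log2(r_size) +
#' b_spacing*log2(r_spacing)`.
#'
#' @param pairs `trial_pairs` data frame.
#' @param betas named numeric `(side, num, size, spacing)`.
#' @param gamma guessing rate in `[0, 1)`.
#' @return Numeric vector of per-trial probabilities.
#' @export
choice_probability <- function(pairs, betas, gamma = 0) {
  eta <- betas[["side"]] +
    betas[["num"]] * log2(pairs$r_num) +
    betas[["size"]] * log2(pairs$r_size) +
    betas[["spacing"]] * log2(pairs$r_spacing)
  (1 - gamma) * (stats::pnorm(eta) - 0.5) + 0.5
}

#' Simulate a synthetic observer on comparison trials
#'
#' Stands in for a human participant: draws one Bernoulli choice per trial
#' from the probit-with-guessing choice model, and (optionally) lognormal
#' response times so the outlier-filter stage can be exercised. Response
#' times have no model in the source protocol; the lognormal is a
#' conventional positive-skew choice.
#'
#' @param pairs `trial_pairs` data frame.
#' @param betas named numeric `(side, num, size, spacing)`.
#' @param gamma guessing rate in `[0, 1)`.
#' @param rt_model optional `list(meanlog=, sdlog=)` for response times (ms).
#' @param observer_id label stored with the dataset.
#' @return A `choice_data` data frame: the pair columns plus `chosen_side`,
#'   `correct`, optional `response_time`, `observer_id`.
#' @export
simulate_observer <- function(pairs, betas = c(side = 0, num = 2,
                                               size = 0.4, spacing = 0.3),
                              gamma = 0.01, rt_model = NULL,
                              observer_id = "synthetic") {
  if (gamma < 0 || gamma >= 1)
    stop("simulate_observer: gamma must be in [0, 1)", call. = FALSE)
  p <- choice_probability(pairs, betas, gamma)
  out <- as.data.frame(pairs)
  out$chosen_side <- ifelse(stats::runif(nrow(out)) < p, "right", "left")
  out$correct <- out$chosen_side == out$correct_side
  if (!is.null(rt_model))
    out$response_time <- stats::rlnorm(nrow(out), rt_model$meanlog,
                                       rt_model$sdlog)
  out$observer_id <- observer_id
  class(out) <- c("choice_data", "data.frame")
  out
}

#' Write a choice dataset as CSV
#' @param data `choice_data` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_choice_data <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  invisible(path)
}
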