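#' Random disjoint folds for cross-validation
#'
#' Partitions indices 1..n into k folds of near-equal size (differing by at
#' most one), uniformly at random, deterministically for a given seed.
#'
#' @param n Number of data points.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return A tibble with columns `index` and `fold`.
#' @export
make_folds <- function(n, k = 5L, seed = 1L) {
  n <- .assert_scalar_count(n, "n")
  k <- .assert_scalar_count(k, "k", min = 2)
  if (k > n) abort("k must not exceed n", class = "waterkrig_partition_error")
  perm <- withr::with_seed(as.integer(seed), sample.int(n))
  fold <- integer(n)
  fold[perm] <- rep(seq_len(k), length.out = n)
  tibble::tibble(index = seq_len(n), fold = fold)
}

#' Mean absolute error
#'
#' @param predicted,truth Numeric vectors of equal length.
#' @return Mean of `|predicted - truth|`.
#' @export
mae <- function(predicted, truth) {
  if (length(predicted) != length(truth) || !length(truth)) {
    abort("predicted and truth must be equal-length, non-empty",
          class = "waterkrig_dimension_error")
  }
  mean(abs(predicted - truth))
}

#' Predictive q-squared coefficient
#'
#' `q2 = 1 - sum((P - T)^2) / sum((M - T)^2)` with `M` the mean of the test
#' truths: 1 for perfect predictions, 0 for a model no better than predicting
#' the mean, negative when worse.
#'
#' @param predicted,truth Numeric vectors of equal length (>= 2).
#' @return A scalar <= 1.
#' @export
q_squared <- function(predicted, truth) {
  if (length(predicted) != length(truth) || length(truth) < 2) {
    abort("predicted and truth must be equal-length with >= 2 values",
          class = "waterkrig_dimension_error")
  }
  denom <- sum((mean(truth) - truth)^2)
  if (denom == 0) {
    abort("truth values are all identical; q2 undefined",
          class = "waterkrig_domain_error")
  }
  1 - sum((predicted - truth)^2) / denom
}

#' S-curve of absolute prediction errors
#'
#' The cumulative error distribution read the way the error S-curve plots it:
#' for each percentile, the absolute-error threshold below which that fraction
#' of test points falls. Percentiles use linear interpolation between order
#' statistics, and the default grid includes the median, 90- and
#' 95-percentiles.
#'
#' @param abs_errors Non-empty numeric vector of absolute errors.
#' @param percentiles Percentile grid in (0, 100].
#' @return A tibble with columns `percentile` and `abs_error`, monotone
#'   non-decreasing in `abs_error`.
#' @export
s_curve <- function(abs_errors,
                    percentiles = c(0.1, 0.5, 1, 2.5, 5, 10, 25, 50, 75, 90, 95, 99, 100)) {
  if (!length(abs_errors)) abort("no errors supplied", class = "waterkrig_domain_error")
  tibble::tibble(
    percentile = percentiles,
    abs_error = as.numeric(quantile(abs_errors, percentiles / 100, type = 7, names = FALSE))
  )
}

#' Cross-validate a kriging model with inverted train/test partitioning
#'
#' Implements the fivefold protocol used throughout the package's validation
#' reporting: the data are split into k random disjoint folds; each fold in
#' turn becomes the *training* set (1 part) and the union of the other folds
#' the *test* set (k-1 parts). With 5000 points and k = 5 this trains five
#' 1000-point models, each tested on its 4000 held-out points, so every point
#' trains exactly one model and is tested by the other four. Per-fold MAE and
#' q2 are aggregated as mean +/- standard deviation, and MAE is also reported
#' as a percentage of the full dataset's property range.
#'
#' @param data Data frame of features plus response (e.g. a [featurize()]
#'   table joined with labels).
#' @param response Response column name.
#' @param features Feature column names (default: all numeric except the
#'   response and `cluster`).
#' @param k Number of folds.
#' @param seed Seed for the fold split.
#' @param control A [krig_control()] for each fold's fit.
#' @param label Optional scheme/model label carried into the report.
#' @return An object of class `krig_cv`: list with `per_fold` (tibble of
#'   fold, n_train, n_test, mae, q2), `summary` (aggregates), `s_curve`
#'   (pooled percentile table), `range`, `label`, `seed`, and `models`.
#' @export
cross_validate <- function(data, response = "value", features = NULL, k = 5L,
                           seed = 1L, control = krig_control(), label = NULL) {
  if (!response %in% names(data)) {
    abort(sprintf("response column '%s' not found", response), class = "waterkrig_domain_error")
  }
  n <- nrow(data)
  folds <- make_folds(n, k, seed)
  truth_all <- data[[response]]
  rng <- range(truth_all)
  per_fold <- list()
  abs_err <- list()
  models <- list()
  for (f in seq_len(k)) {
    train_idx <- folds$index[folds$fold == f]
    test_idx <- setdiff(seq_len(n), train_idx)
    model <- tryCatch(
      krig_fit(data[train_idx, , drop = FALSE], response, features, control),
      error = function(e) {
        abort(sprintf("fold %d failed to fit: %s", f, conditionMessage(e)),
              class = "waterkrig_cv_error")
      })
    pred <- predict(model, data[test_idx, , drop = FALSE])
    truth <- truth_all[test_idx]
    per_fold[[f]] <- tibble::tibble(
      fold = f, n_train = length(train_idx), n_test = length(test_idx),
      mae = mae(pred, truth), q2 = q_squared(pred, truth))
    abs_err[[f]] <- abs(pred - truth)
    models[[f]] <- model
  }
  per_fold <- dplyr::bind_rows(per_fold)
  summary <- tibble::tibble(
    mae_mean = mean(per_fold$mae), mae_sd = sd(per_fold$mae),
    q2_mean = mean(per_fold$q2), q2_sd = sd(per_fold$q2),
    range = diff(rng), test_mean = mean(truth_all),
    mae_pct_range = mean(per_fold$mae) / diff(rng) * 100)
  structure(list(per_fold = per_fold, summary = summary,
                 s_curve = s_curve(unlist(abs_err)),
                 range = rng, label = label, k = k, seed = seed, models = models),
            class = "krig_cv")
}

#' @export
print.krig_cv <- function(x, ...) {
  cat(sprintf("<krig_cv> %s%d folds (train on 1 part, test on %d parts)\n",
              if (!is.null(x$label)) paste0(x$label, ": ") else "", x$k, x$k - 1))
  cat(sprintf("  MAE %.4g +/- %.2g | q2 %.3f +/- %.3f | MAE %.2f%% of range\n",
              x$summary$mae_mean, x$summary$mae_sd, x$summary$q2_mean,
              x$summary$q2_sd, x$summary$mae_pct_range))
  invisible(x)
}

#' @export
tidy.krig_cv <- function(x, ...) {
  out <- x$per_fold
  if (!is.null(x$label)) out <- dplyr::mutate(out, label = x$label, .before = 1)
  out
}

#' @export
glance.krig_cv <- function(x, ...) {
  out <- x$summary
  if (!is.null(x$label)) out <- dplyr::mutate(out, label = x$label, .before = 1)
  out
}

#' Plot the S-curve of a cross-validation report
#'
#' @param object A `krig_cv` object (or a percentile table from [s_curve()]
#'   for `plot_s_curve()`).
#' @param ... Unused.
#' @return A ggplot object: percentile of test points (y) against absolute
#'   prediction error (x, log scale).
#' @export
autoplot.krig_cv <- function(object, ...) {
  plot_s_curve(object$s_curve, label = object$label)
}

#' @rdname autoplot.krig_cv
#' @param curve A percentile table (`percentile`, `abs_error`), or several
#'   row-bound together with a `label` column.
#' @param label Optional curve label.
#' @export
plot_s_curve <- function(curve, label = NULL) {
  if (!is.null(label) && !"label" %in% names(curve)) curve$label <- label
  p <- ggplot2::ggplot(curve, ggplot2::aes(x = .data$abs_error, y = .data$percentile))
  p <- if ("label" %in% names(curve)) {
    p + ggplot2::geom_line(ggplot2::aes(colour = .data$label))
  } else {
    p + ggplot2::geom_line()
  }
  p + ggplot2::scale_x_log10() +
    ggplot2::labs(x = "absolute prediction error", y = "% of test points",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a theta/phi-space projection of slot oxygens
#'
#' Visualizes how tightly a feature scheme confines each slot: the azimuth and
#' polar angle of every slot oxygen across clusters, coloured by slot, with
#' the scheme's nodes overplotted.
#'
#' @param projection A table from [spatial_projection()].
#' @param nodes Optional node tibble to overlay (see [water_nodes()]).
#' @return A ggplot object.
#' @export
plot_projection <- function(projection, nodes = NULL) {
  p <- ggplot2::ggplot(projection,
                       ggplot2::aes(x = .data$phi, y = .data$theta,
                                    colour = factor(.data$slot))) +
    ggplot2::geom_point(alpha = 0.3, size = 0.6) +
    ggplot2::scale_y_reverse(limits = c(180, 0)) +
    ggplot2::coord_cartesian(xlim = c(-180, 180)) +
    ggplot2::labs(x = "phi (degrees)", y = "theta (degrees)", colour = "slot") +
    ggplot2::theme_minimal()
  if (!is.null(nodes)) {
    p <- p + ggplot2::geom_point(data = nodes,
                                 ggplot2::aes(x = .data$phi, y = .data$theta),
                                 inherit.aes = FALSE, shape = 5, size = 3)
  }
  p
}
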