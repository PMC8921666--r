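#' Build a cross-validation fold plan
#'
#' Seeded uniform random partition of the samples into `n_folds` near-equal
#' folds (sizes differ by at most one), with no tissue stratification. One
#' plan is built per dataset run and shared by every candidate signature and
#' every control draw, so per-cell-line absolute errors are paired across
#' models.
#'
#' @param sample_ids character vector of sample identifiers.
#' @param n_folds number of folds (default 3).
#' @param seed integer seed.
#' @return an object of class `fold_plan`: list with `assignment` (named
#'   integer fold index per sample), `n_folds`, `seed`.
#' @export
make_folds <- function(sample_ids, n_folds = 3L, seed = 1L) {
  n <- length(sample_ids)
  if (n < 2L * n_folds)
    stop(sprintf("%d samples cannot support %d-fold cross-validation",
                 n, n_folds))
  sizes <- rep(n %/% n_folds, n_folds) + (seq_len(n_folds) <= n %% n_folds)
  labels <- rep(seq_len(n_folds), times = sizes)
  set.seed(seed)
  assignment <- stats::setNames(labels[sample.int(n)], sample_ids)
  structure(list(assignment = assignment, n_folds = n_folds, seed = seed),
            class = "fold_plan")
}

#' Mean absolute error
#' @param observed,predicted equal-length numeric vectors.
#' @return mean of |observed - predicted|.
#' @export
mae <- function(observed, predicted) {
  if (length(observed) != length(predicted)) stop("length mismatch")
  if (length(observed) < 1L) stop("empty input")
  mean(abs(observed - predicted))
}

#' Out-of-sample R-squared
#'
#' 1 - sum((y - yhat)^2) / sum((y - mean(y))^2) with the mean taken over the
#' held-out observations themselves. Negative whenever the held-out mean is a
#' better predictor than the model.
#'
#' @param observed,predicted held-out observations and predictions.
#' @return out-of-sample R^2 (may be negative).
#' @export
r2_oos <- function(observed, predicted) {
  if (length(observed) != length(predicted)) stop("length mismatch")
  if (length(observed) < 3L) stop("need at least 3 held-out observations")
  tss <- sum((observed - mean(observed))^2)
  if (tss == 0) stop("zero variance in held-out observations")
  1 - sum((observed - predicted)^2) / tss
}

#' 95% confidence interval for the MAE
#'
#' A t-interval over the per-cell-line absolute errors:
#' mean(AE) +/- t(0.975, n-1) * sd(AE)/sqrt(n), with the lower bound floored
#' at zero.
#'
#' @param abs_errors numeric vector of absolute errors (n >= 3).
#' @return numeric c(low, high).
#' @export
mae_ci95 <- function(abs_errors) {
  n <- length(abs_errors)
  if (n < 3L) stop("need at least 3 absolute errors")
  m <- mean(abs_errors)
  half <- stats::qt(0.975, n - 1L) * stats::sd(abs_errors) / sqrt(n)
  c(low = max(0, m - half), high = m + half)
}

#' Cross-validate a signature model
#'
#' For each fold, the model family is fitted on the out-of-fold samples only
#' (all centering, loadings and coefficients learned from training data) and
#' applied to the held-out fold; held-out predictions are pooled over all
#' samples and summarised as per-cell-line absolute error (AE), MAE with its
#' 95% CI, out-of-sample R^2, and per-tissue MAE.
#'
#' @param em aligned [expr_matrix].
#' @param rs aligned [rs_table] (same samples, same order as `em`).
#' @param signature an [rs_signature] (NULL for `family = "intercept_only"`).
#' @param plan a [make_folds()] plan over exactly these samples.
#' @param family model family, see [rs_fit()].
#' @param min_tissue_n per-tissue summary threshold, see [tissue_mae()].
#' @param ... further arguments passed to [rs_fit()].
#' @return an object of class `rs_benchmark`: list with `samples` (data.frame
#'   sample_id, tissue, observed, predicted, ae, fold), `mae`, `mae_ci95`,
#'   `r2_oos`, `per_tissue`, `signature`, `family`, `plan`.
#' @export
cross_validate <- function(em, rs, signature = NULL, plan,
                           family = "pcr", min_tissue_n = 5L, ...) {
  stopifnot(inherits(plan, "fold_plan"))
  ids <- rs$sample_id
  if (!setequal(names(plan$assignment), ids))
    stop("fold plan does not cover exactly the aligned samples")
  fold <- plan$assignment[ids]
  pred <- stats::setNames(rep(NA_real_, length(ids)), ids)
  for (f in seq_len(plan$n_folds)) {
    train <- ids[fold != f]
    test <- ids[fold == f]
    if (length(train) < 4L)
      stop(sprintf("fold %d leaves only %d training samples", f,
                   length(train)))
    em_tr <- expr_matrix(em$values[, train, drop = FALSE],
                         tissue = em$tissue[train])
    rs_tr <- rs[match(train, rs$sample_id), , drop = FALSE]
    attr(rs_tr, "endpoint") <- attr(rs, "endpoint")
    class(rs_tr) <- class(rs)
    fit <- rs_fit(em_tr, rs_tr, signature, family = family, ...)
    em_te <- expr_matrix(em$values[, test, drop = FALSE],
                         tissue = em$tissue[test])
    pred[test] <- predict(fit, em_te)
  }
  obs <- stats::setNames(rs$value, ids)
  samples <- data.frame(sample_id = ids, tissue = unname(em$tissue[ids]),
                        observed = unname(obs), predicted = unname(pred),
                        ae = unname(abs(obs - pred)),
                        fold = unname(fold), stringsAsFactors = FALSE)
  res <- structure(list(
    samples = samples,
    mae = mae(samples$observed, samples$predicted),
    mae_ci95 = mae_ci95(samples$ae),
    r2_oos = r2_oos(samples$observed, samples$predicted),
    signature = signature, family = family, plan = plan,
    endpoint = endpoint_kind(rs)), class = "rs_benchmark")
  res$per_tissue <- if (any(!is.na(samples$tissue)))
    tissue_mae(res, min_n = min_tissue_n) else NULL
  res
}

#' @export
print.rs_benchmark <- function(x, ...) {
  cat(sprintf(
    "rs_benchmark: %s%s on %d cell lines (%d-fold CV, seed %d)\n",
    x$family,
    if (!is.null(x$signature))
      sprintf(" of '%s' (size %d)", x$signature$name, x$signature$size)
    else "", nrow(x$samples), x$plan$n_folds, x$plan$seed))
  cat(sprintf("  MAE = %.4f [%.4f, %.4f], out-of-sample R2 = %.3f\n",
              x$mae, x$mae_ci95[1L], x$mae_ci95[2L], x$r2_oos))
  invisible(x)
}

#' @export
summary.rs_benchmark <- function(object, ...) {
  print(object)
  if (!is.null(object$per_tissue)) {
    cat("  per-tissue MAE:\n")
    print(object$per_tissue, row.names = FALSE)
  }
  invisible(object)
}

#' @export
plot.rs_benchmark <- function(x, ...) {
  graphics::plot(x$samples$observed, x$samples$predicted,
                 xlab = sprintf("observed %s", x$endpoint),
                 ylab = sprintf("predicted %s", x$endpoint),
                 main = sprintf("%s, MAE = %.3f", x$family, x$mae), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' @export
residuals.rs_benchmark <- function(object, ...) {
  stats::setNames(object$samples$observed - object$samples$predicted,
                  object$samples$sample_id)
}

#' Draw a resampled control signature
#'
#' `size` genes drawn uniformly with replacement from the gene universe
#' (duplicates retained), the size-matched null predictor the benchmark
#' compares every candidate signature against.
#'
#' @param universe character vector of gene symbols (the measured genes).
#' @param size signature size (draws, counting duplicates).
#' @param seed integer seed.
#' @param name signature name (default records size and seed).
#' @return an [rs_signature] with source "resampled".
#' @export
resample_signature <- function(universe, size, seed,
                               name = sprintf("control_s%d_seed%d", size,
                                              seed)) {
  if (length(universe) < 1L) stop("empty gene universe")
  if (size < 1L) stop("size must be >= 1")
  set.seed(seed)
  rs_signature(name, sample(universe, size, replace = TRUE),
               source = "resampled")
}

#' Build a resampled-control ensemble at one signature size
#'
#' Draws `n_draws` control signatures of the given size, cross-validates each
#' with the principal-components-regression family under the SAME fold plan
#' as the candidates, and selects the median-accuracy (by MAE) signature.
#' For even `n_draws` the lower of the two middle order statistics is taken
#' (rank n_draws/2), so the selected control is always a real signature.
#'
#' @param em,rs aligned data, as for [cross_validate()].
#' @param size control signature size.
#' @param plan the shared [make_folds()] plan.
#' @param n_draws number of control draws (default 500).
#' @param seed master seed; draw i uses `child_seed(seed, "draw", i)` (offset
#'   by `size` so different sizes get independent draws).
#' @param ... passed to [cross_validate()] (and through it to [rs_fit()]).
#' @return an object of class `control_ensemble`: list with `size`,
#'   `n_draws`, `maes` (per-draw MAE), `draw_seeds`, `median_index`,
#'   `median_result` (the [cross_validate()] result of the selected
#'   signature), `median_mae`, `median_ci95`.
#' @export
build_control_ensemble <- function(em, rs, size, plan, n_draws = 500L,
                                   seed = 1L, ...) {
  universe <- rownames(em$values)
  draw_seeds <- vapply(seq_len(n_draws), function(i)
    child_seed(seed, sprintf("draw_size%d", size), i), integer(1L))
  maes <- numeric(n_draws)
  results <- vector("list", n_draws)
  for (i in seq_len(n_draws)) {
    sig <- resample_signature(universe, size, draw_seeds[i])
    results[[i]] <- cross_validate(em, rs, sig, plan, family = "pcr", ...)
    maes[i] <- results[[i]]$mae
  }
  ord <- order(maes)
  med_rank <- if (n_draws %% 2L == 0L) n_draws %/% 2L else (n_draws + 1L) %/% 2L
  median_index <- ord[med_rank]
  med <- results[[median_index]]
  structure(list(size = size, n_draws = n_draws, maes = maes,
                 draw_seeds = draw_seeds, median_index = median_index,
                 median_result = med, median_signature = med$signature,
                 median_mae = med$mae, median_ci95 = med$mae_ci95,
                 seed = seed),
            class = "control_ensemble")
}

#' @export
print.control_ensemble <- function(x, ...) {
  cat(sprintf(
    "control_ensemble: %d resampled signatures of size %d\n", x$n_draws,
    x$size))
  cat(sprintf("  MAE range [%.4f, %.4f]; median signature MAE = %.4f [%.4f, %.4f]\n",
              min(x$maes), max(x$maes), x$median_mae, x$median_ci95[1L],
              x$median_ci95[2L]))
  invisible(x)
}

#' Per-tissue mean absolute error
#'
#' MAE of the pooled held-out predictions within each tissue. Tissues with
#' `min_n` or fewer cell lines are retained in the table but flagged
#' (`small_n = TRUE`) and meant to be excluded from headline summaries;
#' unlabelled samples are omitted from the table (not from global metrics).
#'
#' @param result an [cross_validate()] result.
#' @param min_n flag threshold (default 5: tissues need more than 5 samples).
#' @return data.frame with columns tissue, n, mae, small_n.
#' @export
tissue_mae <- function(result, min_n = 5L) {
  s <- result$samples
  s <- s[!is.na(s$tissue), , drop = FALSE]
  if (nrow(s) == 0L) stop("no tissue labels present")
  agg <- stats::aggregate(ae ~ tissue, data = s, FUN = mean)
  cnt <- stats::aggregate(ae ~ tissue, data = s, FUN = length)
  out <- data.frame(tissue = agg$tissue, n = cnt$ae, mae = agg$ae,
                    small_n = cnt$ae <= min_n, stringsAsFactors = FALSE)
  out[order(-out$mae), , drop = FALSE]
}
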