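#' Paired TOST equivalence test on per-cell-line absolute errors
#'
#' Two one-sided tests on the paired differences d_i = AE_candidate_i -
#' AE_control_i (paired by cell line under the shared fold plan). The lower
#' test rejects H0: mean(d) <= -delta, the upper rejects H0: mean(d) >=
#' +delta; the two models are declared equivalent within +/- delta when both
#' one-sided p-values fall below `alpha`. Both the 90% CI (conventional TOST
#' display) and the (1 - 2*alpha) CI (decision-consistent at the testing
#' alpha) of the mean difference are reported.
#'
#' If the differences have zero variance the t statistics are undefined; the
#' verdict then falls back to the point estimate (equivalent iff |mean(d)| <
#' delta, p-values reported as the limits 0 or 1) with a warning.
#'
#' @param ae_candidate,ae_control per-cell-line absolute errors, equal
#'   length (>= 3), same sample order.
#' @param delta equivalence bound (default 0.1: SF2 fraction or Gy, matching
#'   the reliability of the clonogenic assay).
#' @param alpha one-sided test level (default 0.003, i.e. 0.05 corrected for
#'   16 comparisons).
#' @return an object of class `tost_result`: list with `mean_diff`, `se`,
#'   `n_pairs`, `delta`, `alpha`, `p_lower`, `p_upper`, `p_tost` (max of the
#'   two), `ci90`, `ci_decision` (the (1-2*alpha) CI), `equivalent`.
#' @export
tost_paired <- function(ae_candidate, ae_control, delta = 0.1,
                        alpha = 0.003) {
  n <- length(ae_candidate)
  if (length(ae_control) != n) stop("length mismatch between AE vectors")
  if (n < 3L) stop("need at least 3 pairs")
  if (delta <= 0) stop("delta must be positive")
  d <- ae_candidate - ae_control
  m <- mean(d)
  s <- stats::sd(d)
  df <- n - 1L
  if (s == 0) {
    warning("zero variance of paired differences; verdict from point estimate")
    inside <- abs(m) < delta
    p <- if (inside) 0 else 1
    return(structure(list(mean_diff = m, se = 0, n_pairs = n, delta = delta,
                          alpha = alpha, p_lower = p, p_upper = p,
                          p_tost = p, ci90 = c(m, m),
                          ci_decision = c(m, m), equivalent = inside),
                     class = "tost_result"))
  }
  se <- s / sqrt(n)
  t_low <- (m + delta) / se
  t_up <- (m - delta) / se
  p_lower <- stats::pt(t_low, df, lower.tail = FALSE)
  p_upper <- stats::pt(t_up, df, lower.tail = TRUE)
  ci90 <- m + c(-1, 1) * stats::qt(0.95, df) * se
  ci_dec <- m + c(-1, 1) * stats::qt(1 - alpha, df) * se
  structure(list(mean_diff = m, se = se, n_pairs = n, delta = delta,
                 alpha = alpha, p_lower = p_lower, p_upper = p_upper,
                 p_tost = max(p_lower, p_upper),
                 ci90 = ci90, ci_decision = ci_dec,
                 equivalent = (p_lower < alpha) && (p_upper < alpha)),
            class = "tost_result")
}

#' @export
print.tost_result <- function(x, ...) {
  cat(sprintf("Paired TOST: mean AE difference %.4f (n = %d), bounds +/- %g\n",
              x$mean_diff, x$n_pairs, x$delta))
  cat(sprintf("  p_lower = %.3g, p_upper = %.3g, p_tost = %.3g (alpha = %g)\n",
              x$p_lower, x$p_upper, x$p_tost, x$alpha))
  cat(sprintf("  90%% CI [%.4f, %.4f]; %s\n", x$ci90[1L], x$ci90[2L],
              if (x$equivalent) "EQUIVALENT" else "not equivalent"))
  invisible(x)
}

#' Multiple-comparison-corrected alpha
#'
#' Bonferroni division of the nominal level by the number of candidate
#' signatures compared, reported both exactly and rounded to 3 decimals
#' (0.05 over 16 comparisons gives 0.003125, conventionally quoted as
#' 0.003).
#'
#' @param nominal nominal alpha (default 0.05).
#' @param n_comparisons number of comparisons (>= 1).
#' @return list with `exact` and `rounded` (3 decimals).
#' @export
corrected_alpha <- function(nominal = 0.05, n_comparisons) {
  if (n_comparisons < 1L) stop("n_comparisons must be >= 1")
  exact <- nominal / n_comparisons
  list(exact = exact, rounded = round(exact, 3L))
}

#' Trend of control accuracy with signature size
#'
#' Ordinary least squares of median-control MAE on signature size; the slope
#' quantifies how much the random-gene null improves as more genes enter the
#' control signatures.
#'
#' @param sizes signature sizes (>= 3 distinct values).
#' @param median_maes median-control MAE at each size.
#' @return list of class `trend_result` with `slope` (MAE per gene),
#'   `intercept`, `p_value` (two-sided, slope), `n_points`.
#' @export
trend_mae_vs_size <- function(sizes, median_maes) {
  if (length(sizes) != length(median_maes)) stop("length mismatch")
  if (length(unique(sizes)) < 2L) stop("sizes are all equal")
  if (length(sizes) < 3L) stop("need at least 3 points")
  fit <- stats::lm(median_maes ~ sizes)
  sm <- stats::summary.lm(fit)$coefficients
  structure(list(slope = unname(sm["sizes", "Estimate"]),
                 intercept = unname(sm["(Intercept)", "Estimate"]),
                 p_value = unname(sm["sizes", "Pr(>|t|)"]),
                 n_points = length(sizes)),
            class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf("trend: slope %.3g per gene (p = %.3g, n = %d points)\n",
              x$slope, x$p_value, x$n_points))
  invisible(x)
}

#' Tissue endpoint deviation and variability versus tissue MAE
#'
#' For one model's per-tissue errors: correlates (i) the absolute deviation
#' of each tissue's mean endpoint from the grand mean and (ii) the
#' within-tissue endpoint SD, against the tissue's MAE. Tissues flagged
#' small (n <= min_n in [tissue_mae()]) are excluded. Outlying tissues drive
#' prediction error when radiosensitivity is tissue-structured.
#'
#' @param rs aligned [rs_table] with tissue labels.
#' @param tissue_tbl a [tissue_mae()] table for one model.
#' @param method "pearson" (default) or "spearman".
#' @return data.frame with one row per analysis (`deviation`, `sd`):
#'   estimate, p_value, n_tissues. Degenerate inputs (constant MAE) give NA
#'   with a message in the `note` column.
#' @export
tissue_rs_deviation_vs_mae <- function(rs, tissue_tbl,
                                       method = c("pearson", "spearman")) {
  method <- match.arg(method)
  tt <- tissue_tbl[!tissue_tbl$small_n, , drop = FALSE]
  if (nrow(tt) < 3L) stop("need at least 3 tissues passing min_n")
  grand <- mean(rs$value)
  by_tissue <- split(rs$value, rs$tissue)
  dev <- vapply(tt$tissue, function(t) abs(mean(by_tissue[[t]]) - grand),
                numeric(1L))
  sds <- vapply(tt$tissue, function(t) stats::sd(by_tissue[[t]]), numeric(1L))
  one <- function(x, label) {
    if (stats::sd(tt$mae) == 0 || stats::sd(x) == 0 || anyNA(x))
      return(data.frame(analysis = label, estimate = NA_real_,
                        p_value = NA_real_, n_tissues = nrow(tt),
                        note = "undefined (zero variance)",
                        stringsAsFactors = FALSE))
    ct <- stats::cor.test(x, tt$mae, method = method, exact = FALSE)
    data.frame(analysis = label, estimate = unname(ct$estimate),
               p_value = ct$p.value, n_tissues = nrow(tt), note = "",
               stringsAsFactors = FALSE)
  }
  rbind(one(dev, "deviation"), one(sds, "sd"))
}

#' Between-model MAE spread versus tissue sample size
#'
#' For each tissue, the SD of MAE across the benchmarked models measures how
#' much models disagree there; this spread is regressed on the tissue's
#' sample count. Tissues on the `exclude` list (e.g. one with an outlying
#' sample size) are dropped before fitting, and the exclusion is recorded in
#' the result.
#'
#' @param tissue_mae_by_model data.frame with columns tissue, model, n, mae
#'   (stacked [tissue_mae()] tables, one per model).
#' @param exclude character vector of tissue labels to exclude.
#' @return list of class `trend_result` with additional elements
#'   `per_tissue` (tissue, n, sd_mae) and `excluded`.
#' @export
mae_spread_vs_n <- function(tissue_mae_by_model, exclude = character(0)) {
  df <- tissue_mae_by_model[!(tissue_mae_by_model$tissue %in% exclude), ,
                            drop = FALSE]
  sds <- stats::aggregate(mae ~ tissue, data = df, FUN = stats::sd)
  ns <- stats::aggregate(n ~ tissue, data = df, FUN = max)
  per <- merge(sds, ns, by = "tissue")
  names(per) <- c("tissue", "sd_mae", "n")
  if (nrow(per) < 3L) stop("need at least 3 tissues after exclusion")
  fit <- stats::lm(sd_mae ~ n, data = per)
  sm <- stats::summary.lm(fit)$coefficients
  out <- structure(list(slope = unname(sm["n", "Estimate"]),
                        intercept = unname(sm["(Intercept)", "Estimate"]),
                        p_value = unname(sm["n", "Pr(>|t|)"]),
                        n_points = nrow(per), per_tissue = per,
                        excluded = exclude),
                   class = "trend_result")
  out
}
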