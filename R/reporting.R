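# Orchestration layer: one function per workflow stage (simulate, benchmark,
# equivalence), each driven by a plain configuration list (or YAML file) and
# writing tidy CSV tables stamped with the master seed and a configuration
# hash so identical runs are recognisably identical.

.load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  config
}

.num9 <- function(x) formatC(x, digits = 9, format = "g")

.write_stamped <- function(df, path, seed, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# master_seed=%d config_hash=%s", seed, hash), con)
  num <- vapply(df, is.numeric, logical(1L)) &
    !vapply(df, is.integer, logical(1L))
  df[num] <- lapply(df[num], .num9)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Simulate a synthetic radiogenomic dataset to disk
#'
#' Writes the expression matrix (TSV), radiosensitivity table (CSV), planted
#' signature (GMT) and a manifest (YAML) from which the dataset can be
#' regenerated bit-exactly.
#'
#' @param config a [synthetic_config()], a list of its arguments, or a YAML
#'   path holding them.
#' @param outdir output directory (created if needed).
#' @return invisibly, the [generate_dataset()] result.
#' @export
run_simulate <- function(config, outdir) {
  cfg <- if (inherits(config, "synthetic_config")) config
         else do.call(synthetic_config, .load_config(config))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  d <- generate_dataset(cfg)
  write_expression(d$em, file.path(outdir, "expression.tsv"))
  write_rs_table(d$rs, file.path(outdir, "rs.csv"))
  write_gmt(d$planted, file.path(outdir, "planted.gmt"))
  write_manifest(d$manifest, file.path(outdir, "manifest.yaml"))
  message(sprintf("simulated %d genes x %d samples (seed %d) into %s",
                  cfg$n_genes, cfg$n_samples, cfg$seed, outdir))
  invisible(d)
}

#' Benchmark candidate signatures against controls
#'
#' Runs every candidate signature (principal components regression by
#' default, per-signature family overrides allowed), the intercept-only null
#' model, and a resampled-control ensemble at each distinct candidate size
#' ("match-candidates" mode), all under ONE shared fold plan so per-cell-line
#' errors are paired. Writes per-sample, per-signature, per-tissue and
#' control-ensemble CSV tables when `outdir` is given.
#'
#' @param config list (or YAML path) with entries: `expression`, `rs`,
#'   `signatures` (file paths) or `data` (list with in-memory `em`, `rs`,
#'   `signatures`); `endpoint` ("SF2"/"MID", for file input); `seed` master
#'   seed; optional `n_folds` (3), `n_draws` (500), `control_sizes` (numeric,
#'   default match-candidates), `families` (named character vector of
#'   per-signature family overrides), `min_tissue_n` (5), `min_shared` (10).
#' @param outdir optional output directory for CSV tables.
#' @return an object of class `rs_benchmark_run`: list with `candidates`
#'   (named list of [cross_validate()] results), `intercept`, `controls`
#'   (named by size, [build_control_ensemble()] results), `plan`, `seed`,
#'   `config_hash`, `em`, `rs`.
#' @export
run_benchmark <- function(config, outdir = NULL) {
  config <- .load_config(config)
  seed <- as.integer(config$seed %||% 1L)
  n_folds <- config$n_folds %||% 3L
  n_draws <- config$n_draws %||% 500L
  min_tissue_n <- config$min_tissue_n %||% 5L
  hash <- config_hash(config[setdiff(names(config), "data")])
  if (!is.null(config$data)) {
    em <- config$data$em; rs <- config$data$rs; sigs <- config$data$signatures
  } else {
    em <- read_expression(config$expression)
    rs <- read_rs_table(config$rs, endpoint = config$endpoint %||% "SF2")
    em$tissue[rs$sample_id] <- rs$tissue
    sigs <- read_signatures(config$signatures,
                            source = config$source %||% "published")
  }
  al <- align_samples(em, rs, min_shared = config$min_shared %||% 10L)
  em <- al$em; rs <- al$rs
  if (sum(al$dropped) > 0)
    message(sprintf("alignment dropped %d expression / %d RS samples",
                    al$dropped[["em"]], al$dropped[["rs"]]))
  plan <- make_folds(rs$sample_id, n_folds = n_folds,
                     seed = child_seed(seed, "folds"))
  fam_over <- config$families %||% character(0)
  candidates <- stats::setNames(lapply(sigs, function(sg) {
    fam <- if (sg$name %in% names(fam_over)) fam_over[[sg$name]] else "pcr"
    cross_validate(em, rs, sg, plan, family = fam,
                   min_tissue_n = min_tissue_n)
  }), vapply(sigs, `[[`, "", "name"))
  intercept <- cross_validate(em, rs, NULL, plan, family = "intercept_only",
                              min_tissue_n = min_tissue_n)
  sizes <- config$control_sizes %||% control_sizes_for(sigs)
  controls <- stats::setNames(lapply(sizes, function(sz)
    build_control_ensemble(em, rs, sz, plan, n_draws = n_draws, seed = seed,
                           min_tissue_n = min_tissue_n)),
    as.character(sizes))
  run <- structure(list(candidates = candidates, intercept = intercept,
                        controls = controls, plan = plan, seed = seed,
                        config_hash = hash, em = em, rs = rs,
                        min_tissue_n = min_tissue_n),
                   class = "rs_benchmark_run")
  if (!is.null(outdir)) write_benchmark_tables(run, outdir)
  run
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.rs_benchmark_run <- function(x, ...) {
  cat(sprintf(
    "rs_benchmark_run: %d candidates, %d control sizes, seed %d\n",
    length(x$candidates), length(x$controls), x$seed))
  print(benchmark_summary_table(x), row.names = FALSE)
  invisible(x)
}

#' Per-signature summary table of a benchmark run
#' @param run an [run_benchmark()] result.
#' @return data.frame: signature, source, size, family, mae, ci_low,
#'   ci_high, r2_oos (candidates, intercept, control medians).
#' @export
benchmark_summary_table <- function(run) {
  row_of <- function(r, nm, src) data.frame(
    signature = nm, source = src,
    size = if (is.null(r$signature)) NA_integer_ else r$signature$size,
    family = r$family, mae = r$mae, ci_low = unname(r$mae_ci95[1L]),
    ci_high = unname(r$mae_ci95[2L]), r2_oos = r$r2_oos,
    stringsAsFactors = FALSE)
  cand <- do.call(rbind, lapply(names(run$candidates), function(nm)
    row_of(run$candidates[[nm]], nm, run$candidates[[nm]]$signature$source)))
  ctrl <- do.call(rbind, lapply(names(run$controls), function(sz)
    row_of(run$controls[[sz]]$median_result,
           sprintf("median_control_%s", sz), "resampled")))
  rbind(cand, row_of(run$intercept, "intercept_only", "null"), ctrl)
}

#' Write the tidy CSV tables of a benchmark run
#' @param run an [run_benchmark()] result.
#' @param outdir output directory.
#' @return invisibly, the paths written.
#' @export
write_benchmark_tables <- function(run, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) .write_stamped(df, file.path(outdir, name),
                                         run$seed, run$config_hash)
  per_sample <- do.call(rbind, c(
    lapply(names(run$candidates), function(nm)
      cbind(signature = nm, run$candidates[[nm]]$samples)),
    list(cbind(signature = "intercept_only", run$intercept$samples))))
  p1 <- w(per_sample, "per_sample.csv")
  p2 <- w(benchmark_summary_table(run), "per_signature.csv")
  per_tissue <- do.call(rbind, lapply(names(run$candidates), function(nm) {
    tt <- run$candidates[[nm]]$per_tissue
    if (is.null(tt)) NULL else cbind(signature = nm, tt)
  }))
  p3 <- if (!is.null(per_tissue)) w(per_tissue, "per_tissue.csv") else NULL
  controls <- do.call(rbind, lapply(run$controls, function(ce)
    data.frame(size = ce$size, draw = seq_len(ce$n_draws),
               draw_seed = ce$draw_seeds, mae = ce$maes,
               is_median = seq_len(ce$n_draws) == ce$median_index)))
  p4 <- w(controls, "controls.csv")
  invisible(c(p1, p2, p3, p4))
}

#' Equivalence analysis of a benchmark run
#'
#' For every candidate signature: a paired TOST against the size-matched
#' median control (alpha Bonferroni-corrected by the number of candidates
#' unless overridden). Adds the control MAE-versus-size trend, the
#' tissue-deviation correlations per candidate, and the between-model MAE
#' spread versus tissue sample size. Writes a report CSV and plots
#' (MAE-versus-size with the control band; a forest plot of MAE differences
#' with CIs) when `outdir` is given.
#'
#' @param run an [run_benchmark()] result.
#' @param delta equivalence bound (default 0.1).
#' @param nominal_alpha nominal level before correction (default 0.05).
#' @param alpha optional override of the corrected per-test alpha.
#' @param exclude_tissues tissues excluded from the MAE-spread regression
#'   (e.g. one with outlying sample size).
#' @param outdir optional output directory.
#' @return an object of class `rs_equivalence_run`: list with `report`
#'   (data.frame), `tost` (per-candidate [tost_paired()] results), `alpha`,
#'   `trend`, `tissue_assoc`, `spread`.
#' @export
run_equivalence <- function(run, delta = 0.1, nominal_alpha = 0.05,
                            alpha = NULL, exclude_tissues = character(0),
                            outdir = NULL) {
  stopifnot(inherits(run, "rs_benchmark_run"))
  n_cand <- length(run$candidates)
  ca <- corrected_alpha(nominal_alpha, n_cand)
  if (is.null(alpha)) alpha <- ca$exact
  tost <- lapply(names(run$candidates), function(nm) {
    r <- run$candidates[[nm]]
    sz <- as.character(r$signature$size)
    ce <- run$controls[[sz]]
    if (is.null(ce))
      stop("no control ensemble at size ", sz, " for signature ", nm)
    stopifnot(identical(r$samples$sample_id,
                        ce$median_result$samples$sample_id))
    tost_paired(r$samples$ae, ce$median_result$samples$ae, delta = delta,
                alpha = alpha)
  })
  names(tost) <- names(run$candidates)
  report <- do.call(rbind, lapply(names(tost), function(nm) {
    r <- run$candidates[[nm]]; tt <- tost[[nm]]
    ce <- run$controls[[as.character(r$signature$size)]]
    data.frame(signature = nm, size = r$signature$size,
               candidate_mae = r$mae, control_mae = ce$median_mae,
               mean_diff = tt$mean_diff, ci_low = tt$ci90[1L],
               ci_high = tt$ci90[2L], p_tost = tt$p_tost, alpha = alpha,
               equivalent = tt$equivalent, stringsAsFactors = FALSE)
  }))
  sizes <- vapply(run$controls, `[[`, 0L, "size")
  trend <- if (length(unique(sizes)) >= 3L)
    trend_mae_vs_size(sizes, vapply(run$controls, `[[`, 0, "median_mae"))
  else NULL
  tissue_assoc <- if (!is.null(run$candidates[[1L]]$per_tissue)) {
    out <- lapply(names(run$candidates), function(nm) {
      tt <- run$candidates[[nm]]$per_tissue
      res <- tryCatch(tissue_rs_deviation_vs_mae(run$rs, tt),
                      error = function(e) NULL)
      if (is.null(res)) NULL else cbind(signature = nm, res)
    })
    do.call(rbind, out)
  } else NULL
  spread <- tryCatch({
    stacked <- do.call(rbind, lapply(names(run$candidates), function(nm) {
      tt <- run$candidates[[nm]]$per_tissue
      if (is.null(tt)) NULL
      else cbind(model = nm, tt[!tt$small_n, c("tissue", "n", "mae")])
    }))
    if (is.null(stacked)) NULL else mae_spread_vs_n(stacked, exclude_tissues)
  }, error = function(e) NULL)
  res <- structure(list(report = report, tost = tost, alpha = alpha,
                        corrected = ca, delta = delta, trend = trend,
                        tissue_assoc = tissue_assoc, spread = spread,
                        seed = run$seed, config_hash = run$config_hash),
                   class = "rs_equivalence_run")
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    .write_stamped(report, file.path(outdir, "equivalence.csv"), run$seed,
                   run$config_hash)
    if (!is.null(tissue_assoc))
      .write_stamped(tissue_assoc, file.path(outdir, "tissue_assoc.csv"),
                     run$seed, run$config_hash)
    grDevices::pdf(file.path(outdir, "equivalence_plots.pdf"), width = 7,
                   height = 5)
    plot_mae_vs_size(run)
    plot_equivalence_forest(res)
    grDevices::dev.off()
  }
  res
}

#' @export
print.rs_equivalence_run <- function(x, ...) {
  cat(sprintf(
    "rs_equivalence_run: %d candidates, delta = %g, alpha = %g (Bonferroni-corrected: %g)\n",
    nrow(x$report), x$delta, x$alpha, x$corrected$exact))
  print(x$report, row.names = FALSE, digits = 4)
  if (!is.null(x$trend)) print(x$trend)
  invisible(x)
}

#' MAE versus signature size with the control band
#'
#' Candidate MAEs (points) over the median-control MAE curve (line) and its
#' 95% CI band, with the intercept-only MAE as a dashed reference.
#'
#' @param run an [run_benchmark()] result.
#' @export
plot_mae_vs_size <- function(run) {
  sizes <- vapply(run$controls, `[[`, 0L, "size")
  med <- vapply(run$controls, `[[`, 0, "median_mae")
  lo <- vapply(run$controls, function(ce) ce$median_ci95[[1L]], 0)
  hi <- vapply(run$controls, function(ce) ce$median_ci95[[2L]], 0)
  ord <- order(sizes)
  cand_sz <- vapply(run$candidates, function(r) r$signature$size, 0L)
  cand_mae <- vapply(run$candidates, `[[`, 0, "mae")
  ylim <- range(c(lo, hi, cand_mae, run$intercept$mae))
  graphics::plot(sizes[ord], med[ord], type = "n", log = "x",
                 xlab = "signature size (genes)", ylab = "MAE",
                 ylim = ylim, main = "Candidates vs resampled controls")
  graphics::polygon(c(sizes[ord], rev(sizes[ord])), c(lo[ord], rev(hi[ord])),
                    col = "grey85", border = NA)
  graphics::lines(sizes[ord], med[ord], col = "red", lwd = 2)
  graphics::abline(h = run$intercept$mae, col = "blue", lty = 2)
  graphics::points(cand_sz, cand_mae, pch = 19)
  graphics::legend("topright", bty = "n", cex = 0.8,
                   legend = c("candidate", "median control (95% CI)",
                              "intercept only"),
                   pch = c(19, NA, NA), lty = c(NA, 1, 2),
                   col = c("black", "red", "blue"))
  invisible(run)
}

#' Forest plot of candidate-minus-control MAE differences
#'
#' One row per candidate: mean paired AE difference with its 90% CI against
#' the equivalence bounds +/- delta.
#'
#' @param eq an [run_equivalence()] result.
#' @export
plot_equivalence_forest <- function(eq) {
  rp <- eq$report
  k <- nrow(rp)
  xlim <- range(c(rp$ci_low, rp$ci_high, -eq$delta, eq$delta))
  graphics::plot(rp$mean_diff, seq_len(k), xlim = xlim, yaxt = "n",
                 xlab = "MAE difference (candidate - control)", ylab = "",
                 pch = 19, main = sprintf("Equivalence within +/- %g",
                                          eq$delta))
  graphics::axis(2, at = seq_len(k), labels = rp$signature, las = 2,
                 cex.axis = 0.7)
  graphics::segments(rp$ci_low, seq_len(k), rp$ci_high, seq_len(k))
  graphics::abline(v = c(-eq$delta, eq$delta), lty = 2, col = "red")
  graphics::abline(v = 0, lty = 3, col = "grey50")
  invisible(eq)
}
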