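test_that("fold plans are balanced, seeded and deterministic", {
  p9 <- make_folds(paste0("s", 1:9), 3L, seed = 1L)
  expect_identical(sort(as.vector(table(p9$assignment))), c(3L, 3L, 3L))
  p10 <- make_folds(paste0("s", 1:10), 3L, seed = 1L)
  expect_identical(sort(as.vector(table(p10$assignment))), c(3L, 3L, 4L))
  expect_identical(make_folds(paste0("s", 1:10), 3L, seed = 7L)$assignment,
                   make_folds(paste0("s", 1:10), 3L, seed = 7L)$assignment)
  expect_error(make_folds(paste0("s", 1:5), 3L, seed = 1L), "cannot support")
})

test_that("error metrics match their definitions", {
  expect_equal(mae(c(1, 2, 4), c(1, 2, 3)), 1 / 3)
  expect_identical(mae(1:5, 1:5), 0)
  expect_error(mae(1:3, 1:4), "length")
  set.seed(3)
  o <- rnorm(100); p <- rnorm(100)
  expect_equal(mae(o, p), sum(abs(o - p)) / 100, tolerance = 1e-14)

  y <- c(0.1, 0.5, 0.9, 0.3)
  expect_equal(r2_oos(y, y), 1)
  expect_equal(r2_oos(y, rep(mean(y), 4)), 0)
  expect_equal(r2_oos(y, 2 * mean(y) - y), -3)   # mirrored predictions
  expect_error(r2_oos(rep(1, 5), rnorm(5)), "zero variance")
})

test_that("the MAE confidence interval is the t-interval over absolute errors", {
  expect_equal(unname(mae_ci95(rep(0.3, 6))), c(0.3, 0.3))
  ae <- c(0, 0, 0, 4)
  got <- mae_ci95(ae)
  oracle <- stats::t.test(ae)$conf.int
  expect_equal(unname(got), c(max(0, oracle[1]), oracle[2]),
               tolerance = 1e-12)
  # widens with dispersion at fixed mean
  narrow <- mae_ci95(c(0.8, 1.2, 0.9, 1.1))
  wide <- mae_ci95(c(0.2, 1.8, 0.5, 1.5))
  expect_gt(diff(wide), diff(narrow))
  expect_error(mae_ci95(c(1, 2)), "at least 3")
})

test_that("cross-validation pools held-out folds and matches a naive oracle", {
  d <- toy_dataset(seed = 19L, n_genes = 60L, n_samples = 30L,
                   planted_size = 5L)
  r <- cross_validate(d$em, d$rs, d$planted, d$plan, family = "pcr")
  # independent loop-over-folds oracle
  preds <- numeric(0)
  for (f in 1:3) {
    tr <- d$rs$sample_id[d$plan$assignment[d$rs$sample_id] != f]
    te <- d$rs$sample_id[d$plan$assignment[d$rs$sample_id] == f]
    m <- rs_fit(expr_matrix(d$em$values[, tr], tissue = d$em$tissue[tr]),
                rs_subset(d$rs, tr), d$planted, family = "pcr")
    preds[te] <- predict(m, expr_matrix(d$em$values[, te],
                                        tissue = d$em$tissue[te]))
  }
  oracle_mae <- mean(abs(d$rs$value - preds[d$rs$sample_id]))
  expect_equal(r$mae, oracle_mae, tolerance = 1e-12)
  expect_equal(r$samples$predicted, unname(preds[d$rs$sample_id]),
               tolerance = 1e-12)
  expect_equal(r$mae, mean(r$samples$ae), tolerance = 1e-15)
})

test_that("constant endpoints give zero error under the intercept model", {
  em <- toy_em(4L, 12L)
  rs <- rs_table(colnames(em$values), rep(0.5, 12), endpoint = "SF2")
  plan <- make_folds(rs$sample_id, 3L, seed = 2L)
  expect_error(cross_validate(em, rs, NULL, plan, family = "intercept_only"),
               "zero variance")  # r2_oos undefined on constant y
  # with near-constant y the MAE path itself is exact
  rs2 <- rs_table(colnames(em$values), rep(0.5, 12) + c(rep(0, 11), 1e-9),
                  endpoint = "SF2")
  r <- cross_validate(em, rs2, NULL, plan, family = "intercept_only")
  expect_lt(r$mae, 1e-9)
})

test_that("relabelling folds leaves pooled predictions unchanged", {
  d <- toy_dataset(seed = 37L, n_genes = 40L, n_samples = 24L,
                   planted_size = 4L)
  r1 <- cross_validate(d$em, d$rs, d$planted, d$plan, family = "pcr")
  plan2 <- d$plan
  plan2$assignment <- c(3L, 1L, 2L)[plan2$assignment]
  names(plan2$assignment) <- names(d$plan$assignment)
  r2 <- cross_validate(d$em, d$rs, d$planted, plan2, family = "pcr")
  expect_equal(r1$samples$predicted, r2$samples$predicted, tolerance = 1e-12)
})

test_that("resampled signatures draw with replacement, reproducibly", {
  uni <- paste0("G", 1:200)
  s <- resample_signature(uni, 10L, seed = 5L)
  expect_identical(s$size, 10L)
  expect_true(all(s$genes %in% uni))
  expect_identical(s$source, "resampled")
  expect_identical(resample_signature(uni, 10L, seed = 5L)$genes, s$genes)
  expect_error(resample_signature(character(0), 5L, 1L), "empty")
  # uniformity: frequencies of single-gene draws from a 4-gene universe
  small <- paste0("g", 1:4)
  n_draw <- 4000L
  draws <- vapply(seq_len(n_draw), function(i)
    resample_signature(small, 1L, seed = i)$genes, "")
  cnt <- table(factor(draws, levels = small))
  sd3 <- 3 * sqrt(n_draw * 0.25 * 0.75)
  expect_true(all(abs(cnt - n_draw / 4) < sd3))
})

test_that("control ensembles select the lower-median accuracy signature", {
  d <- toy_dataset(seed = 41L, n_genes = 60L, n_samples = 24L,
                   planted_size = 4L)
  ce5 <- build_control_ensemble(d$em, d$rs, 4L, d$plan, n_draws = 5L,
                                seed = 11L)
  expect_identical(ce5$median_mae, sort(ce5$maes)[3L])
  ce4 <- build_control_ensemble(d$em, d$rs, 4L, d$plan, n_draws = 4L,
                                seed = 11L)
  expect_identical(ce4$median_mae, sort(ce4$maes)[2L])  # lower-median rule
  expect_identical(ce4$median_result$mae, ce4$median_mae)
  # per-sample AEs of the selected signature are retained for pairing
  expect_identical(ce4$median_result$samples$sample_id, d$rs$sample_id)
})

test_that("benchmark runs are a pure function of data and master seed", {
  d <- toy_dataset(seed = 43L, n_genes = 50L, n_samples = 24L,
                   planted_size = 4L)
  ce1 <- build_control_ensemble(d$em, d$rs, 4L, d$plan, n_draws = 6L,
                                seed = 3L)
  ce2 <- build_control_ensemble(d$em, d$rs, 4L, d$plan, n_draws = 6L,
                                seed = 3L)
  expect_identical(ce1$maes, ce2$maes)
  expect_identical(ce1$median_signature$genes, ce2$median_signature$genes)
})

test_that("per-tissue errors aggregate back to the overall MAE", {
  # flagged small tissues stay in the table
  fake <- list(samples = data.frame(
    sample_id = paste0("s", 1:3), tissue = c("A", "A", "B"),
    observed = c(1, 1, 1), predicted = c(0.9, 0.7, 0.8),
    ae = c(0.1, 0.3, 0.2), fold = 1L))
  tt <- tissue_mae(fake, min_n = 5L)
  expect_equal(tt$mae[tt$tissue == "A"], 0.2)
  expect_equal(tt$mae[tt$tissue == "B"], 0.2)
  expect_true(all(tt$small_n))

  tis <- sample(rep(paste0("t", 1:8), length.out = 200))
  set.seed(51)
  fake2 <- list(samples = data.frame(
    sample_id = paste0("s", 1:200), tissue = tis,
    observed = rnorm(200), predicted = rnorm(200), fold = 1L))
  fake2$samples$ae <- abs(fake2$samples$observed - fake2$samples$predicted)
  tt2 <- tissue_mae(fake2, min_n = 5L)
  oracle <- tapply(fake2$samples$ae, fake2$samples$tissue, mean)
  expect_equal(tt2$mae, as.numeric(oracle[tt2$tissue]), tolerance = 1e-12)
  # conservation: weighted recombination equals the overall mean AE
  expect_equal(sum(tt2$n * tt2$mae) / sum(tt2$n), mean(fake2$samples$ae),
               tolerance = 1e-12)
  expect_error(tissue_mae(list(samples = within(fake$samples,
                                                tissue <- NA_character_))),
               "no tissue labels")
})
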