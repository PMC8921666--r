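test_that("single-gene PCR reduces to simple linear regression", {
  em <- toy_em(6L, 20L)
  rs <- toy_rs(em)
  sig <- rs_signature("one", "G3")
  m <- rs_fit(em, rs, sig, family = "pcr")
  expect_identical(m$n_components_used, 1L)
  lmfit <- stats::lm(rs$value ~ em$values["G3", ])
  expect_equal(unname(predict(m, em)),
               unname(stats::fitted(lmfit)), tolerance = 1e-10)
})

test_that("component count lands nearest the variance target, ties to fewer", {
  # build a 3-variable design with component variances 5, 3, 2 so the
  # cumulative fractions are exactly 0.5, 0.8, 1.0
  n <- 24L
  set.seed(21)
  M <- matrix(rnorm(n * 3), n, 3)
  M <- sweep(M, 2L, colMeans(M))          # centred before orthonormalising,
  U <- qr.Q(qr(M))                        # so U is centred and orthonormal
  V <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  X <- U %*% diag(sqrt(c(5, 3, 2))) %*% t(V)
  vals <- t(X) + 7
  dimnames(vals) <- list(paste0("G", 1:3), paste0("S", seq_len(n)))
  em <- expr_matrix(vals)
  rs <- toy_rs(em)
  m <- rs_fit(em, rs, rs_signature("v", paste0("G", 1:3)), family = "pcr")
  expect_identical(m$n_components_used, 2L)
  expect_equal(m$variance_covered, 0.8, tolerance = 1e-8)
})

test_that("full-variance PCR reproduces ordinary least squares", {
  set.seed(31)
  for (rep in 1:5) {
    d <- toy_dataset(seed = 100 + rep, n_genes = 60L, n_samples = 40L,
                     planted_size = 5L)
    m <- rs_fit(d$em, d$rs, d$planted, family = "pcr", variance_target = 1)
    X <- t(d$em$values[d$planted$genes, ])
    Xc <- sweep(X, 2L, colMeans(X))
    ols <- stats::lm.fit(cbind(1, Xc), d$rs$value)
    expect_equal(unname(predict(m, d$em)), unname(ols$fitted.values),
                 tolerance = 1e-8)
  }
})

test_that("held-out PCR predictions match a project-then-regress oracle", {
  d <- toy_dataset(seed = 9L, n_genes = 80L, n_samples = 30L,
                   planted_size = 6L)
  train <- d$rs$sample_id[1:20]; test <- d$rs$sample_id[21:30]
  em_tr <- expr_matrix(d$em$values[, train], tissue = d$em$tissue[train])
  m <- rs_fit(em_tr, rs_subset(d$rs, train), d$planted, family = "pcr")
  em_te <- expr_matrix(d$em$values[, test], tissue = d$em$tissue[test])
  got <- predict(m, em_te)
  # independent oracle: centre by training means, project on training
  # loadings from prcomp, regress scores
  Xtr <- t(em_tr$values[d$planted$genes, ])
  pc <- stats::prcomp(Xtr, center = TRUE, scale. = FALSE)
  cf <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  c_star <- which.min(abs(cf - 0.8))
  expect_identical(m$n_components_used, as.integer(c_star))
  sc <- pc$x[, seq_len(c_star), drop = FALSE]
  fit <- stats::lm.fit(cbind(1, sc), rs_subset(d$rs, train)$value)
  Xte <- sweep(t(em_te$values[d$planted$genes, ]), 2L, pc$center)
  pred <- drop(cbind(1, Xte %*% pc$rotation[, seq_len(c_star), drop = FALSE])
               %*% fit$coefficients)
  expect_equal(unname(got), unname(pred), tolerance = 1e-8)
})

test_that("a duplicated gene gives the same PCR predictions as the singleton", {
  # {G, G} duplicates the design column; PCA keeps one direction whose
  # scale is absorbed by the regression coefficient
  em <- toy_em(6L, 18L)
  rs <- toy_rs(em)
  m1 <- rs_fit(em, rs, rs_signature("s1", "G2"), family = "pcr")
  m2 <- rs_fit(em, rs, rs_signature("s2", c("G2", "G2")), family = "pcr")
  expect_identical(m2$signature$size, 2L)
  expect_equal(predict(m2, em), predict(m1, em), tolerance = 1e-8)
})

test_that("model families ignore gene and sample ordering", {
  d <- toy_dataset(seed = 13L, n_genes = 50L, n_samples = 24L,
                   planted_size = 4L)
  m <- rs_fit(d$em, d$rs, d$planted, family = "pcr")
  sig_rev <- rs_signature("rev", rev(d$planted$genes))
  m_rev <- rs_fit(d$em, d$rs, sig_rev, family = "pcr")
  expect_equal(predict(m_rev, d$em), predict(m, d$em), tolerance = 1e-8)
  perm <- rev(seq_len(ncol(d$em$values)))
  em_p <- expr_matrix(d$em$values[, perm], tissue = d$em$tissue[perm])
  rs_p <- rs_subset(d$rs, colnames(em_p$values))
  m_p <- rs_fit(em_p, rs_p, d$planted, family = "pcr")
  expect_equal(predict(m_p, d$em)[names(predict(m, d$em))], predict(m, d$em),
               tolerance = 1e-8)
})

test_that("rank regression uses within-sample average ranks and min-norm LS", {
  em <- toy_em(3L, 20L)
  em$values[, 1] <- c(5, 2, 9)    # ranks 2, 1, 3
  em$values[, 2] <- c(4, 4, 1)    # tied ranks 2.5, 2.5, 1
  rs <- toy_rs(em)
  sig <- rs_signature("rk", c("G1", "G2", "G3"))
  m <- rs_fit(em, rs, sig, family = "ranked_linear")
  R <- t(apply(t(em$values), 1L, rank))
  expect_equal(unname(R[1, ]), c(2, 1, 3))
  expect_equal(unname(R[2, ]), c(2.5, 2.5, 1))
  # fitted values match the SVD pseudo-inverse oracle
  A <- cbind(1, R)
  coef_oracle <- MASS::ginv(A) %*% rs$value
  expect_equal(unname(predict(m, em)), unname(drop(A %*% coef_oracle)),
               tolerance = 1e-8)
  # minimum-norm property
  expect_equal(sum(m$coef^2), sum(coef_oracle^2), tolerance = 1e-8)
  expect_error(rs_fit(em, rs, rs_signature("k1", "G1"),
                      family = "ranked_linear"), "at least 2")
})

test_that("injected coefficients bypass rank-regression fitting", {
  em <- toy_em(3L, 10L)
  rs <- toy_rs(em)
  sig <- rs_signature("inj", c("G1", "G2", "G3"))
  cf <- c("(Intercept)" = 0.5, G1 = 0.1, G2 = -0.2, G3 = 0.05)
  m <- rs_fit(em, rs, sig, family = "ranked_linear", coefficients = cf)
  R <- t(apply(t(em$values), 1L, rank))
  expect_equal(unname(predict(m, em)),
               unname(drop(cbind(1, R) %*% cf)), tolerance = 1e-12)
})

test_that("PLS-SVM fits are deterministic and cap the latent dimension", {
  d <- toy_dataset(seed = 17L, n_genes = 40L, n_samples = 24L,
                   planted_size = 8L)
  m1 <- rs_fit(d$em, d$rs, d$planted, family = "pls_svm")
  m2 <- rs_fit(d$em, d$rs, d$planted, family = "pls_svm")
  expect_identical(predict(m1, d$em), predict(m2, d$em))
  expect_identical(m1$n_latent, 5L)
  expect_error(rs_fit(d$em, d$rs, d$planted, family = "pls_svm",
                      n_latent = 9L), "exceeds")
})

test_that("the intercept-only model predicts the training mean exactly", {
  em <- toy_em(2L, 3L)
  rs <- rs_table(colnames(em$values), c(0.2, 0.4, 0.6), endpoint = "SF2")
  m <- rs_fit(NULL, rs, NULL, family = "intercept_only")
  expect_equal(unname(predict(m, em)), rep(0.4, 3))
  # test MAE is the mean deviation from the training mean, exactly
  em_te <- toy_em(2L, 5L, seed = 99L)
  rs_te <- toy_rs(em_te)
  expect_identical(mae(rs_te$value, predict(m, em_te)),
                   mean(abs(rs_te$value - mean(rs$value))))
})

test_that("missing signature genes fail with the gene names", {
  em <- toy_em(4L, 12L)
  rs <- toy_rs(em)
  expect_error(rs_fit(em, rs, rs_signature("bad", c("G1", "NOPE")),
                      family = "pcr"), "NOPE")
})

test_that("linear model artifacts round-trip through text serialisation", {
  d <- toy_dataset(seed = 23L, n_genes = 40L, n_samples = 20L,
                   planted_size = 4L)
  for (fam in c("pcr", "ranked_linear", "intercept_only")) {
    m <- rs_fit(d$em, d$rs, if (fam == "intercept_only") NULL else d$planted,
                family = fam)
    p <- withr::local_tempfile(fileext = ".yaml")
    write_rs_fit(m, p)
    back <- read_rs_fit(p)
    expect_equal(predict(back, d$em), predict(m, d$em), tolerance = 1e-10)
  }
  m_svm <- rs_fit(d$em, d$rs, d$planted, family = "pls_svm")
  expect_error(write_rs_fit(m_svm, tempfile()), "not text-serialisable")
})

test_that("SF2 predictions can be clamped to the unit interval", {
  d <- toy_dataset(seed = 29L, n_genes = 40L, n_samples = 20L,
                   planted_size = 4L)
  m <- rs_fit(d$em, d$rs, d$planted, family = "pcr", clamp = TRUE)
  pr <- predict(m, d$em)
  expect_true(all(pr >= 0 & pr <= 1))
})
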