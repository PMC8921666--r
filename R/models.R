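#' Fit a radiosensitivity prediction model
#'
#' The single fitting front-end for the four model families the benchmark
#' evaluates. All families share one contract: fit on a training expression
#' matrix and endpoint table, then [predict()] on held-out samples using only
#' parameters learned from the training data.
#'
#' Families:
#' \describe{
#'   \item{pcr}{Principal components regression: the signature's gene rows
#'     are centred on their training means (unscaled by default — covariance
#'     PCA on a common log2 scale), the number of components is chosen so the
#'     cumulative variance fraction is as close as possible to
#'     `variance_target` (ties broken toward fewer components, capped at
#'     min(n_train - 1, signature size)), and the endpoint is regressed on
#'     the component scores by ordinary least squares. This is the default
#'     family for signatures published without a usable model, and the family
#'     used for every resampled control.}
#'   \item{ranked_linear}{Linear regression on ranked expression: each
#'     sample's signature-gene values are replaced by their ranks (within the
#'     sample by default, average ranks on ties) and the endpoint is
#'     regressed on the rank matrix. Within-sample ranks sum to a constant,
#'     so the design is rank-deficient with an intercept; the minimum-norm
#'     least-squares solution is used. Published coefficients can be injected
#'     via `coefficients` for exact replication.}
#'   \item{pls_svm}{Partial least squares to `n_latent` latent score vectors
#'     (default 5, capped at min(n_train - 1, size)) followed by
#'     radial-kernel support-vector regression on the scores (cost 1,
#'     epsilon 0.1, kernel width 1/n_latent by default). Deterministic given
#'     the data and settings.}
#'   \item{intercept_only}{The negative-control null model: the training
#'     endpoint mean as a fixed prediction for every new sample.}
#' }
#'
#' @param em training [expr_matrix] (ignored for `intercept_only`).
#' @param rs training [rs_table], aligned to `em` (same samples; use
#'   [align_samples()]).
#' @param signature an [rs_signature]; all its genes (duplicates included)
#'   must be rows of `em`. Ignored for `intercept_only`.
#' @param family model family, see Details.
#' @param variance_target cumulative-variance target for pcr, in (0, 1\];
#'   default 0.8.
#' @param scale_genes scale genes to unit training variance before PCA
#'   (default FALSE).
#' @param ranking_axis "within_sample" (default) or "across_samples".
#' @param coefficients optional named numeric vector ("(Intercept)" plus one
#'   coefficient per signature gene, in signature order) injecting a
#'   published ranked_linear model instead of fitting.
#' @param n_latent number of PLS latent variables (default min(5, cap)).
#' @param svm_cost,svm_epsilon,svm_gamma support-vector regression
#'   hyperparameters; `svm_gamma` defaults to 1/n_latent.
#' @param clamp clamp predictions to the endpoint's physical range
#'   (\[0, 1\] for SF2); default FALSE — errors are computed on raw model
#'   output.
#' @param seed integer recorded in the fit for provenance (none of the
#'   families is stochastic, but the seed travels with the artifact).
#' @return an object of class `c("rs_<family>", "rs_fit")`.
#' @seealso [predict.rs_fit()], [cross_validate()]
#' @export
#' @examples
#' d <- generate_dataset(synthetic_config(n_genes = 60, n_samples = 30,
#'                                        planted_signature_size = 5, seed = 1))
#' m <- rs_fit(d$em, d$rs, d$planted, family = "pcr")
#' head(predict(m, d$em))
rs_fit <- function(em, rs, signature = NULL,
                   family = c("pcr", "ranked_linear", "pls_svm",
                              "intercept_only"),
                   variance_target = 0.8, scale_genes = FALSE,
                   ranking_axis = c("within_sample", "across_samples"),
                   coefficients = NULL,
                   n_latent = NULL, svm_cost = 1, svm_epsilon = 0.1,
                   svm_gamma = NULL, clamp = FALSE, seed = NA_integer_) {
  family <- match.arg(family)
  ranking_axis <- match.arg(ranking_axis)
  stopifnot(inherits(rs, "rs_table"))
  y <- rs$value
  n <- length(y)
  if (family == "intercept_only") {
    if (n < 1L) stop("empty training set")
    obj <- list(family = family, mean = mean(y),
                training_sample_ids = rs$sample_id)
  } else {
    stopifnot(inherits(em, "expr_matrix"), inherits(signature, "rs_signature"))
    if (!identical(colnames(em$values), rs$sample_id))
      stop("em and rs are not aligned; run align_samples() first")
    if (n < 6L) stop("at least 6 training samples are required")
    X <- .sig_matrix(em, signature)
    obj <- switch(family,
      pcr = .fit_pcr(X, y, variance_target, scale_genes),
      ranked_linear = .fit_ranked(X, y, ranking_axis, coefficients),
      pls_svm = .fit_pls_svm(X, y, n_latent, svm_cost, svm_epsilon, svm_gamma))
    obj$family <- family
    obj$training_sample_ids <- rs$sample_id
  }
  obj$signature <- signature
  obj$endpoint <- endpoint_kind(rs)
  obj$clamp <- clamp
  obj$seed <- seed
  class(obj) <- c(paste0("rs_", family), "rs_fit")
  obj
}

# samples x signature-genes design matrix; duplicated signature genes become
# duplicated columns (they legitimately re-weight the PCA of a resampled
# control drawn with replacement).
.sig_matrix <- function(em, signature) {
  missing <- setdiff(unique(signature$genes), rownames(em$values))
  if (length(missing))
    stop("signature genes absent from expression matrix: ",
         paste(missing, collapse = ", "))
  X <- t(em$values[signature$genes, , drop = FALSE])
  colnames(X) <- make.unique(signature$genes)
  X
}

.fit_pcr <- function(X, y, variance_target, scale_genes) {
  if (variance_target <= 0 || variance_target > 1)
    stop("variance_target must be in (0, 1]")
  n <- nrow(X); k <- ncol(X)
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  sds <- rep(1, k)
  if (scale_genes) {
    sds <- apply(Xc, 2L, stats::sd)
    sds[sds == 0] <- 1
    Xc <- sweep(Xc, 2L, sds, "/")
  }
  sv <- svd(Xc)
  vars <- sv$d^2
  pos <- vars > max(vars[1L], .Machine$double.eps) * 1e-12
  cumfrac <- cumsum(vars) / sum(vars)
  cap <- max(1L, min(n - 1L, k, sum(pos)))
  cand <- seq_len(cap)
  ncomp <- cand[which.min(abs(cumfrac[cand] - variance_target))]
  rotation <- sv$v[, seq_len(ncomp), drop = FALSE]
  scores <- Xc %*% rotation
  fit <- stats::lm.fit(cbind(1, scores), y)
  list(center = mu, scale = sds, scale_genes = scale_genes,
       rotation = rotation, coef = unname(fit$coefficients),
       n_components_used = ncomp, variance_covered = cumfrac[ncomp],
       variance_target = variance_target, fitted = unname(fit$fitted.values))
}

.rank_rows <- function(X) t(apply(X, 1L, rank, ties.method = "average"))

.fit_ranked <- function(X, y, ranking_axis, coefficients) {
  k <- ncol(X)
  if (ranking_axis == "within_sample" && k < 2L)
    stop("within-sample ranking needs at least 2 signature genes")
  if (!is.null(coefficients)) {
    need <- c("(Intercept)", colnames(X))
    if (!all(need %in% names(coefficients)))
      stop("injected coefficients must name (Intercept) and every signature gene")
    coefs <- unname(coefficients[need])
    return(list(coef = coefs, ranking_axis = ranking_axis, injected = TRUE,
                fitted = NULL))
  }
  R <- if (ranking_axis == "within_sample") .rank_rows(X)
       else apply(X, 2L, rank, ties.method = "average")
  A <- cbind(1, R)
  # minimum-norm least squares: within-sample ranks make A rank-deficient
  sv <- svd(A)
  tol <- max(sv$d) * max(dim(A)) * .Machine$double.eps
  dinv <- ifelse(sv$d > tol, 1 / sv$d, 0)
  coefs <- drop(sv$v %*% (dinv * crossprod(sv$u, y)))
  list(coef = coefs, ranking_axis = ranking_axis, injected = FALSE,
       fitted = unname(drop(A %*% coefs)))
}

.fit_pls_svm <- function(X, y, n_latent, svm_cost, svm_epsilon, svm_gamma) {
  n <- nrow(X); k <- ncol(X)
  cap <- min(n - 1L, k)
  if (is.null(n_latent)) n_latent <- min(5L, cap)
  else if (n_latent > cap)
    stop(sprintf("n_latent = %d exceeds min(n_train - 1, size) = %d",
                 n_latent, cap))
  if (n_latent < 1L) stop("n_latent must be >= 1")
  pls <- mixOmics::pls(X, y, ncomp = n_latent, scale = FALSE,
                       mode = "regression")
  scores <- unname(pls$variates$X[, seq_len(n_latent), drop = FALSE])
  if (is.null(svm_gamma)) svm_gamma <- 1 / n_latent
  svm <- e1071::svm(x = scores, y = y, type = "eps-regression",
                    kernel = "radial", cost = svm_cost,
                    epsilon = svm_epsilon, gamma = svm_gamma, scale = FALSE)
  list(pls = pls, svm = svm, n_latent = n_latent,
       hyperparameters = list(cost = svm_cost, epsilon = svm_epsilon,
                              gamma = svm_gamma),
       fitted = unname(stats::predict(svm, scores)))
}

#' Predict radiosensitivity for new samples
#'
#' Applies a fitted model to a test expression matrix. All centering,
#' loadings and coefficients come from the training data; the test matrix
#' only supplies the signature genes' expression. Predictions are raw model
#' output unless the fit was created with `clamp = TRUE`.
#'
#' @param object an [rs_fit()] object.
#' @param newdata an [expr_matrix] containing all signature genes.
#' @param ... unused.
#' @return named numeric vector of predicted endpoint values, one per sample
#'   of `newdata`.
#' @export
predict.rs_fit <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "expr_matrix"))
  out <- if (object$family == "intercept_only") {
    stats::setNames(rep(object$mean, ncol(newdata$values)),
                    colnames(newdata$values))
  } else {
    X <- .sig_matrix(newdata, object$signature)
    switch(object$family,
      pcr = {
        Xc <- sweep(X, 2L, object$center)
        if (object$scale_genes) Xc <- sweep(Xc, 2L, object$scale, "/")
        scores <- Xc %*% object$rotation
        stats::setNames(drop(cbind(1, scores) %*% object$coef), rownames(X))
      },
      ranked_linear = {
        R <- if (object$ranking_axis == "within_sample") .rank_rows(X)
             else apply(X, 2L, rank, ties.method = "average")
        stats::setNames(drop(cbind(1, R) %*% object$coef), rownames(X))
      },
      pls_svm = {
        p <- stats::predict(object$pls, newdata = X)
        scores <- unname(p$variates[, seq_len(object$n_latent), drop = FALSE])
        stats::setNames(unname(stats::predict(object$svm, scores)),
                        rownames(X))
      })
  }
  if (isTRUE(object$clamp) && identical(object$endpoint, "SF2"))
    out <- pmin(pmax(out, 0), 1)
  else if (isTRUE(object$clamp) && identical(object$endpoint, "MID"))
    out <- pmax(out, 0)
  out
}

#' @export
print.rs_fit <- function(x, ...) {
  cat(sprintf("rs_fit (%s)%s, endpoint %s, n_train = %d\n", x$family,
              if (!is.null(x$signature))
                sprintf(", signature '%s' (size %d)", x$signature$name,
                        x$signature$size) else "",
              x$endpoint, length(x$training_sample_ids)))
  if (x$family == "pcr")
    cat(sprintf("  components: %d (%.1f%% variance, target %.0f%%)\n",
                x$n_components_used, 100 * x$variance_covered,
                100 * x$variance_target))
  if (x$family == "intercept_only")
    cat(sprintf("  constant prediction: %.4f\n", x$mean))
  invisible(x)
}

#' @export
coef.rs_fit <- function(object, ...) {
  switch(object$family,
         intercept_only = c("(Intercept)" = object$mean),
         pcr = stats::setNames(object$coef,
                 c("(Intercept)",
                   paste0("PC", seq_len(object$n_components_used)))),
         ranked_linear = stats::setNames(object$coef,
                 c("(Intercept)", make.unique(object$signature$genes))),
         pls_svm = NULL)
}

#' @export
summary.rs_fit <- function(object, ...) {
  print(object)
  cf <- stats::coef(object)
  if (!is.null(cf)) {
    cat("  coefficients:\n")
    print(round(cf, 6))
  }
  invisible(object)
}

#' Serialise a fitted model to self-describing text
#'
#' Linear families (pcr, ranked_linear, intercept_only) round-trip exactly:
#' family, hyperparameters, the signature and all fitted parameters are
#' written as YAML. The pls_svm family carries support-vector state and is
#' not text-serialised; refit it from data.
#'
#' @param object an [rs_fit()] object.
#' @param path output file.
#' @export
write_rs_fit <- function(object, path) {
  if (object$family == "pls_svm")
    stop("pls_svm fits are not text-serialisable; refit from data")
  payload <- list(
    family = object$family, endpoint = object$endpoint,
    seed = object$seed, clamp = object$clamp,
    signature = if (is.null(object$signature)) NULL else
      object$signature[c("name", "genes", "source")],
    training_sample_ids = object$training_sample_ids)
  payload <- c(payload, switch(object$family,
    intercept_only = list(mean = object$mean),
    pcr = list(center = as.numeric(object$center), scale = object$scale,
               scale_genes = object$scale_genes,
               rotation = as.numeric(object$rotation),
               rotation_dim = dim(object$rotation), coef = object$coef,
               n_components_used = object$n_components_used,
               variance_covered = object$variance_covered,
               variance_target = object$variance_target),
    ranked_linear = list(coef = object$coef,
                         ranking_axis = object$ranking_axis,
                         injected = object$injected)))
  yaml::write_yaml(payload, path, precision = 15L)
  invisible(path)
}

#' Read a fitted model written by [write_rs_fit()]
#' @param path YAML file.
#' @return an [rs_fit()] object.
#' @export
read_rs_fit <- function(path) {
  p <- yaml::read_yaml(path)
  obj <- list(family = p$family, endpoint = p$endpoint, seed = p$seed,
              clamp = p$clamp, training_sample_ids = p$training_sample_ids,
              signature = if (is.null(p$signature)) NULL else
                rs_signature(p$signature$name, p$signature$genes,
                             p$signature$source))
  if (p$family == "intercept_only") obj$mean <- p$mean
  if (p$family == "pcr") {
    obj$center <- stats::setNames(as.numeric(p$center),
                                  make.unique(obj$signature$genes))
    obj$scale <- as.numeric(p$scale)
    obj$scale_genes <- p$scale_genes
    obj$rotation <- matrix(as.numeric(p$rotation), p$rotation_dim[[1L]],
                           p$rotation_dim[[2L]])
    obj$coef <- as.numeric(p$coef)
    obj$n_components_used <- p$n_components_used
    obj$variance_covered <- p$variance_covered
    obj$variance_target <- p$variance_target
  }
  if (p$family == "ranked_linear") {
    obj$coef <- as.numeric(p$coef)
    obj$ranking_axis <- p$ranking_axis
    obj$injected <- p$injected
  }
  class(obj) <- c(paste0("rs_", p$family), "rs_fit")
  obj
}
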