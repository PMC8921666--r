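#' Configuration for the synthetic radiogenomic generator
#'
#' Defines a matched expression + radiosensitivity dataset with the
#' statistical structure the benchmark assumes: tissue-structured correlated
#' log2 expression, per-cell-line linear-quadratic survival parameters
#' yielding the endpoint (SF2 or MID), tissue heterogeneity in the
#' endpoint's mean and spread, and an optional planted expression-to-endpoint
#' signal of tunable strength.
#'
#' Expression is a Gaussian latent-factor model:
#' value(g, i) = b_g + t(g, tissue(i)) + sum_f lambda(g, f) z(f, i) +
#' eps(g, i), with gene baselines b_g ~ N(baseline_mean, baseline_sd^2),
#' per-gene tissue offsets ~ N(0, tissue_effect_sd^2), factor scores
#' z ~ N(0, 1), loadings ~ N(0, loading_sd^2) and noise
#' ~ N(0, noise_sd^2).
#'
#' The endpoint is generated through the linear-quadratic transform so SF2
#' and MID respect their physical ranges: per sample,
#' log alpha_i = alpha_log_mean + effect_size * score_i + tissue offset
#' (~ N(0, alpha_tissue_sd^2)) + N(0, alpha_log_sd^2), with score_i the
#' standardised mean expression of the planted genes; beta_i =
#' beta_over_alpha * alpha_i; endpoint = SF2(alpha_i, beta_i) or
#' MID(alpha_i, beta_i). `effect_size = 0` makes the endpoint independent of
#' expression (null mode).
#'
#' @param n_genes number of genes.
#' @param n_samples number of cell lines; must equal `sum(tissues)`.
#' @param tissues named integer vector of per-tissue cell-line counts.
#' @param baseline_mean,baseline_sd gene baseline distribution (log2 units).
#' @param n_latent_factors,loading_sd latent-factor structure driving
#'   gene-gene correlation.
#' @param tissue_effect_sd SD of per-gene tissue offsets (log2 units).
#' @param noise_sd residual SD (log2 units).
#' @param planted_signature_size size of the planted signature.
#' @param effect_size strength of the planted expression-to-endpoint signal
#'   on the log-alpha scale per SD of score; 0 = null mode.
#' @param endpoint "SF2" or "MID".
#' @param alpha_log_mean,alpha_log_sd mean and residual SD of log alpha
#'   (alpha in Gy^-1).
#' @param alpha_tissue_sd SD of per-tissue offsets on log alpha (tissue
#'   heterogeneity of the endpoint).
#' @param beta_over_alpha fixed ratio tying beta to alpha (Gy^-1).
#' @param seed master seed; the expression, radiosensitivity and
#'   planted-signature stages each derive a child seed from it.
#' @return a validated list of class `synthetic_config`.
#' @seealso [generate_dataset()], [synthetic_config_full()]
#' @export
synthetic_config <- function(n_genes = 2000L, n_samples = 120L,
                             tissues = NULL,
                             baseline_mean = 7.5, baseline_sd = 1.5,
                             n_latent_factors = 10L, loading_sd = 0.55,
                             tissue_effect_sd = 0.5, noise_sd = 1,
                             planted_signature_size = 6L,
                             effect_size = 0,
                             endpoint = c("SF2", "MID"),
                             alpha_log_mean = log(0.3), alpha_log_sd = 0.3,
                             alpha_tissue_sd = 0.15, beta_over_alpha = 0.1,
                             seed = 1L) {
  endpoint <- match.arg(endpoint)
  if (is.null(tissues)) {
    k <- max(1L, min(6L, n_samples %/% 10L))
    base <- rep(n_samples %/% k, k)
    base[seq_len(n_samples %% k)] <- base[seq_len(n_samples %% k)] + 1L
    tissues <- stats::setNames(base, paste0("tissue", seq_len(k)))
  }
  cfg <- list(n_genes = as.integer(n_genes),
              n_samples = as.integer(n_samples),
              tissues = tissues,
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              n_latent_factors = as.integer(n_latent_factors),
              loading_sd = loading_sd, tissue_effect_sd = tissue_effect_sd,
              noise_sd = noise_sd,
              planted_signature_size = as.integer(planted_signature_size),
              effect_size = effect_size, endpoint = endpoint,
              alpha_log_mean = alpha_log_mean, alpha_log_sd = alpha_log_sd,
              alpha_tissue_sd = alpha_tissue_sd,
              beta_over_alpha = beta_over_alpha, seed = as.integer(seed))
  .validate_cfg(cfg)
  structure(cfg, class = "synthetic_config")
}

.validate_cfg <- function(cfg) {
  with(cfg, {
    if (n_genes < 1L || n_samples < 1L) stop("counts must be positive")
    if (sum(tissues) != n_samples)
      stop("tissue counts must sum to n_samples")
    if (is.null(names(tissues)) || any(!nzchar(names(tissues))))
      stop("tissues must be a named count vector")
    if (any(tissues < 1L)) stop("tissue counts must be positive")
    if (effect_size < 0) stop("effect_size must be >= 0")
    if (planted_signature_size > n_genes)
      stop("planted_signature_size exceeds n_genes")
    if (planted_signature_size < 1L) stop("planted_signature_size must be >= 1")
    if (any(c(baseline_sd, loading_sd, tissue_effect_sd, noise_sd,
              alpha_log_sd, alpha_tissue_sd) < 0))
      stop("standard deviations must be non-negative")
    if (beta_over_alpha < 0) stop("beta_over_alpha must be >= 0")
    if (n_latent_factors < 0) stop("n_latent_factors must be >= 0")
  })
  invisible(cfg)
}

#' Full-scale synthetic configuration
#'
#' The shipped full-scale preset mirrors the dimensions of the larger of the
#' two public radiogenomic panels the benchmark targets: 20 068 genes by 533
#' cell lines over 20 tissues with unequal representation (one dominant
#' tissue), endpoint MID. All other parameters as [synthetic_config()].
#'
#' @param ... overrides passed to [synthetic_config()].
#' @export
synthetic_config_full <- function(...) {
  counts <- c(lung = 90, large_intestine = 45, skin = 40, breast = 35,
              cns = 35, blood = 35, ovary = 30, pancreas = 28, stomach = 25,
              kidney = 24, liver = 22, oesophagus = 20, urinary_tract = 18,
              bone = 16, soft_tissue = 15, autonomic_ganglia = 14,
              endometrium = 13, pleura = 12, thyroid = 9, salivary_gland = 7)
  synthetic_config(n_genes = 20068L, n_samples = sum(counts),
                   tissues = counts, endpoint = "MID", ...)
}

.tissue_of <- function(cfg) {
  rep(names(cfg$tissues), times = cfg$tissues)
}

#' Generate a synthetic expression matrix
#'
#' Draws the latent-factor expression model defined by the configuration;
#' deterministic given `cfg$seed` (stage child seed "expression").
#'
#' @param cfg a [synthetic_config()].
#' @return an [expr_matrix] with gene ids g0001... and sample ids CL001...
#' @export
generate_expression <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(child_seed(cfg$seed, "expression"))
  G <- cfg$n_genes; N <- cfg$n_samples
  gene_ids <- sprintf("g%0*d", nchar(G), seq_len(G))
  sample_ids <- sprintf("CL%0*d", nchar(N), seq_len(N))
  tissue <- .tissue_of(cfg)
  b <- stats::rnorm(G, cfg$baseline_mean, cfg$baseline_sd)
  vals <- matrix(b, G, N)
  if (cfg$tissue_effect_sd > 0) {
    toff <- matrix(stats::rnorm(G * length(cfg$tissues), 0,
                                cfg$tissue_effect_sd),
                   G, length(cfg$tissues),
                   dimnames = list(NULL, names(cfg$tissues)))
    vals <- vals + toff[, tissue, drop = FALSE]
  }
  if (cfg$n_latent_factors > 0 && cfg$loading_sd > 0) {
    lambda <- matrix(stats::rnorm(G * cfg$n_latent_factors, 0,
                                  cfg$loading_sd), G, cfg$n_latent_factors)
    z <- matrix(stats::rnorm(cfg$n_latent_factors * N), cfg$n_latent_factors,
                N)
    vals <- vals + lambda %*% z
  }
  vals <- vals + matrix(stats::rnorm(G * N, 0, cfg$noise_sd), G, N)
  dimnames(vals) <- list(gene_ids, sample_ids)
  expr_matrix(vals, tissue = stats::setNames(tissue, sample_ids))
}

#' Generate radiosensitivity endpoints from expression
#'
#' Builds per-cell-line linear-quadratic parameters and transforms them to
#' the configured endpoint (see [synthetic_config()] for the model). With
#' `effect_size = 0` the endpoint is independent of expression; otherwise it
#' is driven by the standardised mean expression of the planted genes.
#'
#' @param cfg a [synthetic_config()].
#' @param em the [generate_expression()] matrix.
#' @param planted an [rs_signature]; its genes must be rows of `em`.
#' @return an [rs_table].
#' @export
generate_rs <- function(cfg, em, planted) {
  stopifnot(inherits(cfg, "synthetic_config"), inherits(em, "expr_matrix"),
            inherits(planted, "rs_signature"))
  missing <- setdiff(unique(planted$genes), rownames(em$values))
  if (length(missing))
    stop("planted genes absent from expression matrix: ",
         paste(missing, collapse = ", "))
  set.seed(child_seed(cfg$seed, "rs"))
  N <- ncol(em$values)
  score <- colMeans(em$values[planted$genes, , drop = FALSE])
  score <- as.numeric(scale(score))
  tissue <- .tissue_of(cfg)
  toff <- stats::setNames(stats::rnorm(length(cfg$tissues), 0,
                                       cfg$alpha_tissue_sd),
                          names(cfg$tissues))
  log_alpha <- cfg$alpha_log_mean + cfg$effect_size * score +
    toff[tissue] + stats::rnorm(N, 0, cfg$alpha_log_sd)
  alpha <- exp(log_alpha)
  beta <- cfg$beta_over_alpha * alpha
  value <- if (cfg$endpoint == "SF2") sf2(alpha, beta) else mid(alpha, beta)
  rs_table(colnames(em$values), unname(value), tissue = tissue,
           endpoint = cfg$endpoint)
}

#' Generate a complete synthetic radiogenomic dataset
#'
#' Draws the planted signature uniformly without replacement from the gene
#' universe (stage child seed "planted"), then composes
#' [generate_expression()] and [generate_rs()]. The returned manifest
#' (configuration plus planted genes) is sufficient to regenerate the
#' dataset bit-exactly.
#'
#' @param cfg a [synthetic_config()].
#' @return list with `em`, `rs`, `planted` and `manifest`.
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  em <- generate_expression(cfg)
  set.seed(child_seed(cfg$seed, "planted"))
  genes <- sample(rownames(em$values), cfg$planted_signature_size,
                  replace = FALSE)
  planted <- rs_signature(sprintf("planted_seed%d", cfg$seed), genes,
                          source = if (cfg$effect_size > 0) "published"
                                   else "resampled")
  rs <- generate_rs(cfg, em, planted)
  manifest <- list(config = unclass(cfg), planted_genes = planted$genes)
  list(em = em, rs = rs, planted = planted, manifest = manifest)
}

#' Effect size for a target generator signal strength
#'
#' Inverts the generator's variance decomposition on the log-alpha scale:
#' the planted linear predictor explains
#' R^2 = effect_size^2 / (effect_size^2 + alpha_log_sd^2 + alpha_tissue_sd^2)
#' of the log-alpha variance, so
#' effect_size = sqrt(R^2 / (1 - R^2) * (alpha_log_sd^2 +
#' alpha_tissue_sd^2)).
#'
#' @param r2 target fraction of log-alpha variance explained, in (0, 1).
#' @param cfg a [synthetic_config()] supplying the noise scales.
#' @return the effect size.
#' @export
effect_size_for_r2 <- function(r2, cfg) {
  if (r2 <= 0 || r2 >= 1) stop("r2 must be in (0, 1)")
  sqrt(r2 / (1 - r2) * (cfg$alpha_log_sd^2 + cfg$alpha_tissue_sd^2))
}

#' Write a dataset manifest
#' @param manifest the `manifest` element of [generate_dataset()].
#' @param path output YAML path.
#' @export
write_manifest <- function(manifest, path) {
  m <- manifest
  m$config$tissues <- as.list(m$config$tissues)
  # doubles are serialised at full precision (17 significant digits) so the
  # regenerated dataset is bit-identical
  m$config <- lapply(m$config, function(v)
    if (is.double(v)) sprintf("%.17g", v) else v)
  yaml::write_yaml(m, path)
  invisible(path)
}

#' Read a dataset manifest and regenerate the dataset
#' @param path manifest YAML path.
#' @return as [generate_dataset()].
#' @export
regenerate_from_manifest <- function(path) {
  m <- yaml::read_yaml(path)
  cf <- m$config
  num <- function(x) as.numeric(x)
  cfg <- synthetic_config(
    n_genes = cf$n_genes, n_samples = cf$n_samples,
    tissues = unlist(cf$tissues), baseline_mean = num(cf$baseline_mean),
    baseline_sd = num(cf$baseline_sd),
    n_latent_factors = cf$n_latent_factors,
    loading_sd = num(cf$loading_sd),
    tissue_effect_sd = num(cf$tissue_effect_sd),
    noise_sd = num(cf$noise_sd),
    planted_signature_size = cf$planted_signature_size,
    effect_size = num(cf$effect_size), endpoint = cf$endpoint,
    alpha_log_mean = num(cf$alpha_log_mean),
    alpha_log_sd = num(cf$alpha_log_sd),
    alpha_tissue_sd = num(cf$alpha_tissue_sd),
    beta_over_alpha = num(cf$beta_over_alpha), seed = cf$seed)
  out <- generate_dataset(cfg)
  if (!identical(out$planted$genes, as.character(m$planted_genes)))
    stop("manifest planted genes do not match regeneration")
  out
}
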