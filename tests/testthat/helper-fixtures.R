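# Small in-code fixtures shared across test files.

# tiny deterministic expression matrix: genes x samples
toy_em <- function(n_genes = 8L, n_samples = 12L, seed = 42L,
                   tissue = NULL) {
  set.seed(seed)
  vals <- matrix(rnorm(n_genes * n_samples, mean = 7, sd = 1.2), n_genes,
                 n_samples,
                 dimnames = list(paste0("G", seq_len(n_genes)),
                                 paste0("S", seq_len(n_samples))))
  expr_matrix(vals, tissue = tissue)
}

toy_rs <- function(em, seed = 43L, endpoint = "SF2", tissue = NULL) {
  set.seed(seed)
  n <- ncol(em$values)
  val <- if (endpoint == "SF2") runif(n, 0.2, 0.8) else runif(n, 0.5, 3)
  rs_table(colnames(em$values), val,
           tissue = if (is.null(tissue)) NA_character_ else tissue,
           endpoint = endpoint)
}

# a small aligned synthetic dataset with shared fold plan
toy_dataset <- function(seed = 7L, n_genes = 150L, n_samples = 30L,
                        planted_size = 5L, effect_size = 0) {
  cfg <- synthetic_config(n_genes = n_genes, n_samples = n_samples,
                          planted_signature_size = planted_size,
                          effect_size = effect_size, seed = seed)
  d <- generate_dataset(cfg)
  d$plan <- make_folds(d$rs$sample_id, 3L, seed = child_seed(seed, "folds"))
  d
}

# restrict an rs_table to given sample ids, keeping class/attributes
rs_subset <- function(rs, ids) {
  out <- rs[match(ids, rs$sample_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "endpoint") <- attr(rs, "endpoint")
  class(out) <- class(rs)
  out
}
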