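#' Planted-signature simulation study
#'
#' The package's self-validation experiment: for each master seed, generate a
#' synthetic dataset, cross-validate the planted signature (principal
#' components regression), the intercept-only null and a resampled-control
#' ensemble at the planted size under one shared fold plan, then test the
#' planted signature for TOST equivalence against the median control with
#' the bound calibrated to `delta_sd` endpoint standard deviations.
#'
#' In null mode (`effect_r2 = NULL`, generator effect size 0) the planted
#' signature carries no information, so it should be declared equivalent to
#' its size-matched median control and the intercept-only MAE should fall
#' inside the control ensemble's 5th-95th MAE percentile band. In signal
#' mode (`effect_r2` set, e.g. 0.7) the planted signature should beat the
#' median control by more than `delta_sd` endpoint SDs of MAE.
#'
#' @param seeds integer vector of master seeds, one dataset per seed.
#' @param effect_r2 NULL for null mode, or the target generator R^2 on the
#'   log-alpha scale (see [effect_size_for_r2()]).
#' @param n_draws control draws per ensemble (default 50 at study scale).
#' @param delta_sd equivalence bound in units of endpoint SD (default 0.1).
#' @param alpha TOST level (default 0.003).
#' @param cfg_args named list of [synthetic_config()] overrides applied to
#'   every seed (e.g. a smaller scale for quick checks).
#' @return data.frame, one row per seed: seed, endpoint_sd, candidate_mae,
#'   control_mae, intercept_mae, p_tost, equivalent, in_band (intercept MAE
#'   within the 5th-95th control percentile), beats (candidate MAE below
#'   control MAE by more than delta_sd*SD).
#' @export
planted_signal_study <- function(seeds, effect_r2 = NULL, n_draws = 50L,
                                 delta_sd = 0.1, alpha = 0.003,
                                 cfg_args = list()) {
  rows <- lapply(seeds, function(master) {
    cfg <- do.call(synthetic_config, c(list(seed = master), cfg_args))
    if (!is.null(effect_r2))
      cfg <- do.call(synthetic_config,
                     c(list(seed = master,
                            effect_size = effect_size_for_r2(effect_r2, cfg)),
                       cfg_args))
    d <- generate_dataset(cfg)
    plan <- make_folds(d$rs$sample_id, 3L, seed = child_seed(master, "folds"))
    cand <- cross_validate(d$em, d$rs, d$planted, plan, family = "pcr")
    null <- cross_validate(d$em, d$rs, NULL, plan, family = "intercept_only")
    ens <- build_control_ensemble(d$em, d$rs, d$planted$size, plan,
                                  n_draws = n_draws, seed = master)
    sdy <- stats::sd(d$rs$value)
    tt <- tost_paired(cand$samples$ae, ens$median_result$samples$ae,
                      delta = delta_sd * sdy, alpha = alpha)
    band <- stats::quantile(ens$maes, c(0.05, 0.95), names = FALSE)
    data.frame(seed = master, endpoint_sd = sdy, candidate_mae = cand$mae,
               control_mae = ens$median_mae, intercept_mae = null$mae,
               p_tost = tt$p_tost, equivalent = tt$equivalent,
               in_band = null$mae >= band[1L] && null$mae <= band[2L],
               beats = cand$mae < ens$median_mae - delta_sd * sdy)
  })
  do.call(rbind, rows)
}

#' Control sizes implied by a candidate signature list
#'
#' "Match-candidates" mode: one control-ensemble size per distinct candidate
#' signature size (the seven published plus nine cellular-process sizes give
#' sixteen).
#'
#' @param signatures list of [rs_signature] objects.
#' @return sorted integer vector of distinct sizes.
#' @export
control_sizes_for <- function(signatures) {
  sort(unique(vapply(signatures, `[[`, 0L, "size")))
}
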