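# Simulate -> fit -> tabulate harnesses: parameter recovery and the
# pedigree-error (extra-pair paternity) bias experiment.

# spec implied by the generating parameters of the focal trait
implied_spec <- function(params, fixed = NULL) {
  a <- if (params$V_A1 != params$V_A2 || params$r_xage != 1)
    "group_r1" else "iid"
  e <- if (params$V_E1 != params$V_E2) "group_diag" else "iid"
  model_spec(params$trait,
             fixed = fixed %||% default_fixed_effects(params$trait),
             random = list(additive = a, origin = "iid",
                           rearing = "iid", quartet = "iid"),
             residual = e)
}

# truth on the reporting scale of a fit of `spec` to data from `params`
truth_components <- function(params, spec) {
  a <- spec$random$additive
  th <- if (identical(a, "iid")) c(V_A = params$V_A1) else
    c(V_A_young = params$V_A1, V_A_old = params$V_A2,
      cov_A = params$r_xage * sqrt(params$V_A1 * params$V_A2))
  th <- c(th, V_O = params$V_O, V_R = params$V_R, V_Q = params$V_Q)
  if (spec$residual == "iid") c(th, V_E = params$V_E1) else
    c(th, V_E_young = params$V_E1, V_E_old = params$V_E2)
}

fit_study <- function(study, spec, use_recorded = FALSE,
                      n_starts = 3, hessian = TRUE) {
  ped <- if (use_recorded) study$pedigree_recorded else study$pedigree
  ped <- prune_pedigree(ped, study$phenotypes$id)
  A <- relationship_matrix(ped)
  fit_reml(build_matrices(study$phenotypes, spec, A),
           n_starts = n_starts, hessian = hessian)
}

#' Parameter-recovery experiment
#'
#' Repeatedly simulates studies from known generating parameters, fits
#' the matching animal model to each, and tabulates the mean estimate,
#' Monte-Carlo standard error and relative bias of every variance
#' component.  Boundary-pinned estimates are included at their bound
#' (they are genuine REML estimates of near-zero components).
#'
#' @param params [trait_params] of the focal trait (its covariate
#'   chain, if any, is simulated with default parameters).
#' @param design a [design_config].
#' @param n_reps number of replicates (>= 2).
#' @param seed base seed; replicate r uses `seed + r`.
#' @param spec model fitted to each replicate; defaults to the
#'   structure implied by `params`.
#' @param n_starts optimisation starts per fit.
#' @return List of class `recovery_report`: `table` (one row per
#'   component: truth, mean, mc_se, relative bias %), `estimates`
#'   (replicate x component matrix), `n_failed`, `flagged` (TRUE when
#'   > 20% of replicates failed to converge).
#' @export
recovery_experiment <- function(params, design, n_reps = 20, seed = 1,
                                spec = NULL, n_starts = 3) {
  stopifnot(inherits(params, "trait_params"),
            inherits(design, "design_config"), n_reps >= 2)
  if (is.null(spec)) spec <- implied_spec(params)
  study_params <- default_study_params(params$trait)
  study_params[[params$trait]] <- params
  truth <- truth_components(params, spec)

  rows <- vector("list", n_reps)
  conv <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    st <- simulate_study(design, study_params, seed = seed + r)
    fit <- fit_reml(build_matrices(
      st$phenotypes, spec,
      relationship_matrix(prune_pedigree(st$pedigree,
                                         st$phenotypes$id))),
      n_starts = n_starts, hessian = FALSE)
    conv[r] <- fit$converged
    rows[[r]] <- fit$theta[names(truth)]
  }
  est <- do.call(rbind, rows[conv])
  mean_est <- colMeans(est)
  mc_se <- apply(est, 2, stats::sd) / sqrt(nrow(est))
  tab <- data.frame(component = names(truth), truth = unname(truth),
                    mean = unname(mean_est), mc_se = unname(mc_se),
                    rel_bias_pct = ifelse(truth != 0,
                      100 * (unname(mean_est) - unname(truth)) /
                        unname(truth), NA_real_),
                    stringsAsFactors = FALSE)
  structure(list(table = tab, estimates = est,
                 n_reps = n_reps, n_failed = sum(!conv),
                 flagged = mean(!conv) > 0.2,
                 design = design, params = params, spec = spec),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Parameter recovery over", x$n_reps - x$n_failed,
      "converged replicates")
  if (x$n_failed) cat(" (", x$n_failed, "failed",
                      if (x$flagged) "-- FLAGGED", ")")
  cat("\n")
  tab <- x$table
  tab[-1] <- lapply(tab[-1], signif, 4)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Pedigree-error (extra-pair paternity) bias experiment
#'
#' Quantifies how misassigned paternities bias the estimated
#' young-minus-old heritability difference.  Each replicate simulates
#' a study from the true pedigree, corrupts the *recorded* pedigree by
#' giving a fraction of nests one extra-pair chick, and fits the
#' age-structured model twice: against the true and against the
#' corrupted relationship matrix.  The report gives the mean relative
#' bias (in %) of `h2_young - h2_old` attributable to the pedigree
#' error, its Monte-Carlo SE, and the direction of the effect
#' (attenuation of the difference is "conservative").  Optionally the
#' unstructured model is also fitted to report the bias of the
#' cross-age genetic correlation.
#'
#' @param params [trait_params] of the focal (age-structured) trait.
#' @param design a [design_config].
#' @param nest_epp_rate probability a nest holds one extra-pair chick.
#' @param n_reps replicates (>= 2).
#' @param seed base seed.
#' @param n_starts optimisation starts per fit.
#' @param fit_r_xage also fit the unstructured genetic covariance and
#'   report the bias of the cross-age correlation (doubles the cost;
#'   default FALSE).
#' @return List of class `epp_bias_report`: `table` (per-replicate
#'   h2 differences), `mean_rel_bias_pct`, `mc_se_rel_bias_pct`,
#'   `direction` (`"downward"` when the estimated difference shrinks),
#'   `r_xage` (optional summary), `n_failed`, `flagged`.
#' @export
epp_bias_experiment <- function(params, design, nest_epp_rate = 0.20,
                                n_reps = 50, seed = 1, n_starts = 3,
                                fit_r_xage = FALSE) {
  stopifnot(inherits(params, "trait_params"),
            inherits(design, "design_config"), n_reps >= 2)
  spec <- implied_spec(params)
  if (!identical(spec$random$additive, "group_r1"))
    spec$random$additive <- "group_r1"
  study_params <- default_study_params(params$trait)
  study_params[[params$trait]] <- params

  h2diff <- function(fit) {
    heritability(fit, "young")$h2 - heritability(fit, "old")$h2
  }
  rows <- vector("list", n_reps)
  rx <- vector("list", n_reps)
  conv <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    st <- simulate_study(design, study_params, seed = seed + r)
    st <- inject_extra_pair_paternity(st, nest_epp_rate,
                                      seed = seed + r)
    f_true <- fit_study(st, spec, use_recorded = FALSE,
                        n_starts = n_starts, hessian = FALSE)
    f_corr <- fit_study(st, spec, use_recorded = TRUE,
                        n_starts = n_starts, hessian = FALSE)
    conv[r] <- f_true$converged && f_corr$converged
    rows[[r]] <- c(d_true = h2diff(f_true), d_corrupt = h2diff(f_corr),
                   n_epp = nrow(st$epp_log))
    if (fit_r_xage) {
      su <- spec; su$random$additive <- "group_unstructured"
      r_of <- function(fit) {
        th <- fit$theta
        th[["cov_A"]] / sqrt(th[["V_A_young"]] * th[["V_A_old"]])
      }
      rx[[r]] <- c(r_true = r_of(fit_study(st, su, FALSE, n_starts,
                                           hessian = FALSE)),
                   r_corrupt = r_of(fit_study(st, su, TRUE, n_starts,
                                              hessian = FALSE)))
    }
  }
  tab <- as.data.frame(do.call(rbind, rows[conv]))
  md_true <- mean(tab$d_true)
  rel <- 100 * (tab$d_corrupt - tab$d_true) / abs(md_true)
  out <- list(table = tab,
              mean_rel_bias_pct = mean(rel),
              mc_se_rel_bias_pct = stats::sd(rel) / sqrt(length(rel)),
              direction = if (mean(tab$d_corrupt - tab$d_true) *
                                sign(md_true) <= 0)
                "downward" else "upward",
              nest_epp_rate = nest_epp_rate,
              offspring_epp_rate = mean(tab$n_epp) /
                nrow(simulate_study(design, study_params,
                                    seed = seed)$phenotypes),
              n_reps = n_reps, n_failed = sum(!conv),
              flagged = mean(!conv) > 0.2)
  if (fit_r_xage) {
    rxt <- as.data.frame(do.call(rbind, rx[conv]))
    out$r_xage <- c(mean_true = mean(rxt$r_true),
                    mean_corrupt = mean(rxt$r_corrupt),
                    bias = mean(rxt$r_corrupt - rxt$r_true))
  }
  structure(out, class = "epp_bias_report")
}

#' @export
print.epp_bias_report <- function(x, ...) {
  cat(sprintf(paste0(
    "Pedigree-error bias experiment (%d replicates, nest EPP rate ",
    "%.2f, ~%.1f%% offspring)\n",
    "mean h2_young - h2_old: true %.3f, corrupted %.3f\n",
    "relative bias of the difference: %.2f%% +/- %.2f%% (%s)\n"),
    x$n_reps - x$n_failed, x$nest_epp_rate,
    100 * x$offspring_epp_rate,
    mean(x$table$d_true), mean(x$table$d_corrupt),
    x$mean_rel_bias_pct, x$mc_se_rel_bias_pct, x$direction))
  if (!is.null(x$r_xage))
    cat(sprintf("cross-age correlation: true %.3f, corrupted %.3f\n",
                x$r_xage[["mean_true"]], x$r_xage[["mean_corrupt"]]))
  invisible(x)
}
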