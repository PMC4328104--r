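#' Likelihood-ratio test between nested REML fits
#'
#' Compares two models fitted by REML to the same records.  The
#' statistic is twice the difference in restricted log-likelihoods and
#' is referred to a chi-square distribution whose degrees of freedom
#' equal the difference in the number of (co)variance parameters.
#' Because a variance tested against zero lies on the boundary of its
#' parameter space, the large-sample null distribution is a 50:50
#' mixture of chi-square distributions, and the mixture p-value is
#' exactly half the plain df = 1 p-value; the plain p-value is the
#' more conservative choice and is the default.  Both are always
#' reported.
#'
#' @param fit_complex,fit_simple `reml_fit` objects for nested
#'   specifications (checked with [is_nested()]).
#' @param mode which p-value populates `$p`: `"plain"` (default) or
#'   `"mixture"`.
#' @return A list of class `lrt_result`: `delta_logL`, `statistic`
#'   (negative differences are clipped to zero with a warning), `df`,
#'   `p_plain`, `p_mixture`, `p`, `mode`.
#' @examples
#' # a log-likelihood difference of 2.88 on 1 df:
#' # statistic 5.76, mixture p ~ 0.008, plain p ~ 0.016
#' @export
lrt <- function(fit_complex, fit_simple, mode = c("plain", "mixture")) {
  mode <- match.arg(mode)
  stopifnot(inherits(fit_complex, "reml_fit"),
            inherits(fit_simple, "reml_fit"))
  if (!is_nested(fit_simple$spec, fit_complex$spec))
    stop("lrt: models are not nested (", format(fit_simple$spec),
         " vs ", format(fit_complex$spec), ")")
  if (fit_complex$n != fit_simple$n)
    stop("lrt: fits use different numbers of records")
  df <- n_variance_params(fit_complex$spec) -
    n_variance_params(fit_simple$spec)
  delta <- fit_complex$logL - fit_simple$logL
  stat <- 2 * delta
  if (stat < 0) {
    if (stat < -1e-6)
      warning(sprintf(
        "lrt: negative statistic (%.3g) clipped to 0; the complex %s",
        stat, "model may not have converged"))
    stat <- 0
  }
  p_plain <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  p_mixture <- p_plain / 2
  structure(list(delta_logL = delta, statistic = stat, df = df,
                 p_plain = p_plain, p_mixture = p_mixture,
                 p = if (mode == "plain") p_plain else p_mixture,
                 mode = mode,
                 label_complex = format(fit_complex$spec),
                 label_simple = format(fit_simple$spec)),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf(paste0("LRT: %s  vs  %s\n",
                     "  dlogL = %.3f, statistic = %.3f, df = %d\n",
                     "  p (plain chi^2) = %.4g, p (mixture) = %.4g",
                     "  [mode: %s]\n"),
              x$label_complex, x$label_simple, x$delta_logL,
              x$statistic, x$df, x$p_plain, x$p_mixture, x$mode))
  invisible(x)
}

#' Wald chi-square test of a fixed-effect term
#'
#' Tests the joint nullity of the GLS coefficients belonging to one
#' fixed-effect term, using the coefficient block and the
#' corresponding block of the fixed-effect covariance matrix:
#' \eqn{W = b' \Sigma_b^{-1} b \sim \chi^2_{df}} with df the number of
#' columns of the term.
#'
#' @param fit a `reml_fit`.
#' @param term name of a fixed-effect term in the model.
#' @return List with `term`, `statistic`, `df`, `p`, `coef`.
#' @export
wald_fixed <- function(fit, term) {
  stopifnot(inherits(fit, "reml_fit"))
  j <- match(term, fit$terms)
  if (is.na(j))
    stop("wald_fixed: term '", term, "' is not in the model (terms: ",
         paste(fit$terms, collapse = ", "), ")")
  idx <- which(fit$assign == j)
  if (!length(idx))
    stop("wald_fixed: term '", term,
         "' contributed no columns (dropped or constant)")
  b <- fit$beta[idx]
  Vb <- fit$beta_cov[idx, idx, drop = FALSE]
  stat <- as.numeric(crossprod(b, solve(Vb, b)))
  list(term = term, statistic = stat, df = length(idx),
       p = stats::pchisq(stat, df = length(idx), lower.tail = FALSE),
       coef = b)
}

#' Narrow-sense heritability with delta-method standard error
#'
#' Computes h2 = V_A / (sum of all variance components) for a maternal
#' age group (or pooled, for homogeneous models).  Group-specific
#' components (additive, residual, and any group-structured nest
#' effects) contribute their group's variance; shared components enter
#' both groups.  The standard error propagates the REML covariance of
#' the component estimates through the ratio by a first-order delta
#' method; components pinned at the parameter-space boundary are
#' treated as constants (the reported SE conditions on them).
#'
#' @param fit a `reml_fit`.
#' @param group `"pooled"` for homogeneous-V_A models, else `"young"`
#'   or `"old"`.
#' @return List of class `heritability` with `group`, `h2`, `se`,
#'   `components` (named vector entering the denominator).
#' @export
heritability <- function(fit, group = c("pooled", "young", "old")) {
  group <- match.arg(group)
  stopifnot(inherits(fit, "reml_fit"))
  if (!fit$converged)
    warning("heritability: fit did not converge")
  th <- fit$theta
  pick <- function(code) {
    # group-specific name if present, else shared, else absent
    gn <- paste0("V_", code, "_", group)
    if (group != "pooled" && gn %in% names(th)) return(gn)
    sn <- paste0("V_", code)
    if (sn %in% names(th)) return(sn)
    if (group == "pooled" &&
        paste0("V_", code, "_young") %in% names(th))
      stop("heritability: model has age-specific ", code,
           " variance; use group = 'young' or 'old'")
    NA_character_
  }
  if (is.na(pick("A")))
    stop("heritability: model has no additive genetic component")
  codes <- c("A", "O", "R", "Q", "E")
  nms <- vapply(codes, pick, "")
  nms <- nms[!is.na(nms)]
  comps <- th[nms]
  if (!"A" %in% substr(names(nms), 1, 1)) # defensive; A checked above
    stop("heritability: additive component missing")
  tot <- sum(comps)
  va <- comps[[1L]]
  h2 <- va / tot
  # delta method: d(va/tot)/dva = (tot - va)/tot^2; d/dother = -va/tot^2
  grad <- rep(-va / tot^2, length(comps))
  grad[1L] <- (tot - va) / tot^2
  names(grad) <- nms
  free <- nms[!fit$boundary[nms]]
  se <- if (length(free)) {
    Sg <- fit$theta_cov[free, free, drop = FALSE]
    if (anyNA(Sg)) NA_real_ else {
      v <- as.numeric(crossprod(grad[free], Sg %*% grad[free]))
      sqrt(max(v, 0))
    }
  } else 0
  structure(list(group = group, h2 = h2, se = se,
                 components = comps), class = "heritability")
}

#' @export
print.heritability <- function(x, ...) {
  cat(sprintf("h2 (%s) = %.3f +/- %.3f\n", x$group, x$h2, x$se))
  cat("components:\n")
  print(signif(x$components, 4))
  invisible(x)
}
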