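# Dense-matrix REML for the age-structured animal model.
#
# Every random term contributes a covariance of the form G[g_i, g_j] * C_ij
# where C is the term's record-level kernel (A-submatrix or same-level
# indicator) and G is a 2x2 "age" matrix over maternal age classes:
#   iid                 G = v * J           (J = all-ones)
#   group_r1            G = s s'            (correlation fixed at 1)
#   group_unstructured  G = L L'            (L lower-triangular 2x2)
# The residual adds v_E (iid) or v_E[g] (group_diag) to the diagonal.
# Gradients use tr(P dV) and Py' dV Py contracted through the 2x2 dG,
# so one O(n^2) pass per term per evaluation.

# --- parameter layout -------------------------------------------------

term_code <- c(additive = "A", origin = "O", rearing = "R",
               quartet = "Q")

theta_layout <- function(m) {
  out <- list()
  add <- function(name, term, role, transform = "log") {
    out[[length(out) + 1L]] <<- list(name = name, term = term,
                                     role = role, transform = transform)
  }
  for (k in m$kernels) {
    tc <- term_code[[k$term]]
    switch(k$kind,
      iid = add(paste0("V_", tc), k$term, "var"),
      group_r1 = {
        add(paste0("s_", tc, "_young"), k$term, "s1")
        add(paste0("s_", tc, "_old"), k$term, "s2")
      },
      group_unstructured = {
        add(paste0("L_", tc, "_11"), k$term, "l11")
        add(paste0("L_", tc, "_21"), k$term, "l21", "id")
        add(paste0("L_", tc, "_22"), k$term, "l22")
      })
  }
  if (m$resid == "iid") add("V_E", "residual", "var") else {
    add("V_E_young", "residual", "ve1")
    add("V_E_old", "residual", "ve2")
  }
  names(out) <- vapply(out, `[[`, "", "name")
  out
}

# 2x2 age matrix of a kernel given its natural parameters
kernel_G <- function(kind, th) {
  switch(kind,
         iid = matrix(th[1L], 2, 2),
         group_r1 = tcrossprod(c(th[1L], th[2L])),
         group_unstructured = {
           L <- matrix(c(th[1L], th[2L], 0, th[3L]), 2, 2)
           tcrossprod(L)
         })
}

# derivative of G wrt each natural parameter of the kernel
kernel_dG <- function(kind, th) {
  switch(kind,
    iid = list(matrix(1, 2, 2)),
    group_r1 = list(matrix(c(2 * th[1L], th[2L], th[2L], 0), 2, 2),
                    matrix(c(0, th[1L], th[1L], 2 * th[2L]), 2, 2)),
    group_unstructured = list(
      matrix(c(2 * th[1L], th[2L], th[2L], 0), 2, 2),
      matrix(c(0, th[1L], th[1L], 2 * th[2L]), 2, 2),
      matrix(c(0, 0, 0, 2 * th[3L]), 2, 2)))
}

kernel_param_names <- function(layout, term) {
  names(layout)[vapply(layout, function(p) p$term == term, logical(1))]
}

build_V <- function(m, nat) {
  layout <- theta_layout(m)
  n <- m$n
  V <- matrix(0, n, n)
  g <- m$group
  for (k in m$kernels) {
    th <- nat[kernel_param_names(layout, k$term)]
    if (k$kind == "iid") {
      V <- V + th[[1L]] * k$C
    } else {
      G <- kernel_G(k$kind, th)
      V <- V + G[g, g] * k$C
    }
  }
  dv <- if (m$resid == "iid") rep(nat[["V_E"]], n) else
    c(nat[["V_E_young"]], nat[["V_E_old"]])[g]
  diag(V) <- diag(V) + dv
  V
}

# Core REML quantities at a natural parameter point.  with_grad adds
# the projection matrix P and Py needed for the analytic gradient.
reml_core <- function(m, nat, with_grad = FALSE) {
  V <- build_V(m, nat)
  U <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(U)) return(NULL)
  X <- m$X; y <- m$y
  n <- m$n; p <- ncol(X)
  z <- backsolve(U, cbind(X, y), transpose = TRUE)
  zX <- z[, seq_len(p), drop = FALSE]
  zy <- z[, p + 1L]
  XtViX <- crossprod(zX)
  cX <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(cX)) return(NULL)
  XtViy <- crossprod(zX, zy)
  beta <- backsolve(cX, backsolve(cX, XtViy, transpose = TRUE))
  yPy <- sum(zy^2) - sum(XtViy * beta)
  logdetV <- 2 * sum(log(diag(U)))
  logdetX <- 2 * sum(log(diag(cX)))
  logL <- -0.5 * (logdetV + logdetX + yPy + (n - p) * log(2 * pi))
  out <- list(logL = logL, beta = as.numeric(beta),
              beta_cov = chol2inv(cX), U = U, cX = cX, zX = zX,
              zy = zy)
  if (with_grad) out <- add_projection(out)
  out
}

# augment a core with the REML projection pieces needed for gradients
add_projection <- function(core) {
  if (!is.null(core$P)) return(core)
  Vi <- chol2inv(core$U)
  ViX <- backsolve(core$U, core$zX)
  B <- ViX %*% backsolve(core$cX,
                         backsolve(core$cX, t(ViX), transpose = TRUE))
  core$P <- Vi - B
  core$Py <- as.numeric(backsolve(core$U, core$zy) - ViX %*% core$beta)
  core
}

# analytic gradient of the restricted log-likelihood wrt the natural
# parameters: dlogL/dtheta = -1/2 [ tr(P dV) - Py' dV Py ]
reml_grad_nat <- function(m, nat, core = NULL) {
  layout <- theta_layout(m)
  if (is.null(core)) core <- reml_core(m, nat)
  if (is.null(core)) return(rep(NA_real_, length(layout)))
  core <- add_projection(core)
  P <- core$P; w <- core$Py
  g <- m$group
  i1 <- g == 1L; i2 <- g == 2L
  grad <- stats::setNames(numeric(length(layout)), names(layout))
  for (k in m$kernels) {
    pn <- kernel_param_names(layout, k$term)
    th <- nat[pn]
    if (k$kind == "iid") {
      Cw <- k$C %*% w
      grad[pn] <- -0.5 * (sum(P * k$C) - sum(w * Cw))
      next
    }
    PC <- P * k$C
    w1 <- w * i1; w2 <- w * i2
    Cw1 <- k$C %*% w1; Cw2 <- k$C %*% w2
    Tm <- matrix(c(sum(PC[i1, i1]), sum(PC[i2, i1]),
                   sum(PC[i1, i2]), sum(PC[i2, i2])), 2, 2)
    Qm <- matrix(c(sum(w1 * Cw1), sum(w2 * Cw1),
                   sum(w1 * Cw2), sum(w2 * Cw2)), 2, 2)
    dGs <- kernel_dG(k$kind, th)
    for (j in seq_along(pn))
      grad[pn[j]] <- -0.5 * (sum(dGs[[j]] * Tm) - sum(dGs[[j]] * Qm))
  }
  dP <- diag(P)
  if (m$resid == "iid") {
    grad[["V_E"]] <- -0.5 * (sum(dP) - sum(w^2))
  } else {
    grad[["V_E_young"]] <- -0.5 * (sum(dP[i1]) - sum(w[i1]^2))
    grad[["V_E_old"]] <- -0.5 * (sum(dP[i2]) - sum(w[i2]^2))
  }
  grad
}

#' Restricted log-likelihood of an animal model
#'
#' Evaluates the REML criterion
#' \deqn{\ell_R = -\tfrac12\left[\log|V| + \log|X'V^{-1}X| + y'Py
#'   + (n - p)\log 2\pi\right]}
#' at a given set of natural variance parameters, where
#' \eqn{V = \sum_k (G_k[g_i,g_j] \circ C_k) + R} and \eqn{P} is the
#' REML projection.  The additive constant is fixed, so likelihood
#' differences between models fitted to the same records are exact.
#'
#' @param m a `model_matrices` object from [build_matrices()].
#' @param theta named numeric vector of natural parameters; see
#'   [theta_template()] for the expected names.
#' @return The restricted log-likelihood (scalar), or `-Inf` when V is
#'   not positive definite at `theta`.
#' @export
reml_loglik <- function(m, theta) {
  stopifnot(inherits(m, "model_matrices"))
  layout <- theta_layout(m)
  miss <- setdiff(names(layout), names(theta))
  if (length(miss))
    stop("reml_loglik: missing parameter(s): ",
         paste(miss, collapse = ", "))
  core <- reml_core(m, theta[names(layout)])
  if (is.null(core)) -Inf else core$logL
}

#' Template of natural variance parameters for a model
#'
#' @param m a `model_matrices` object.
#' @param value fill value.
#' @return Named numeric vector with one entry per natural parameter
#'   (variances `V_*`, rank-one scales `s_*`, Cholesky entries `L_*`).
#' @export
theta_template <- function(m, value = NA_real_) {
  stopifnot(inherits(m, "model_matrices"))
  stats::setNames(rep(value, length(theta_layout(m))),
                  names(theta_layout(m)))
}

# --- fitting ----------------------------------------------------------

# report-scale components and their Jacobian wrt natural parameters
report_map <- function(m, nat) {
  layout <- theta_layout(m)
  vals <- c(); jac <- list()
  emit <- function(name, value, dnat) {
    vals[[name]] <<- value
    d <- stats::setNames(numeric(length(layout)), names(layout))
    d[names(dnat)] <- dnat
    jac[[name]] <<- d
  }
  for (k in m$kernels) {
    tc <- term_code[[k$term]]
    pn <- kernel_param_names(layout, k$term)
    th <- nat[pn]
    switch(k$kind,
      iid = emit(paste0("V_", tc), th[[1L]],
                 stats::setNames(1, pn[1L])),
      group_r1 = {
        emit(paste0("V_", tc, "_young"), th[[1L]]^2,
             stats::setNames(2 * th[[1L]], pn[1L]))
        emit(paste0("V_", tc, "_old"), th[[2L]]^2,
             stats::setNames(2 * th[[2L]], pn[2L]))
        emit(paste0("cov_", tc), th[[1L]] * th[[2L]],
             stats::setNames(c(th[[2L]], th[[1L]]), pn))
      },
      group_unstructured = {
        l11 <- th[[1L]]; l21 <- th[[2L]]; l22 <- th[[3L]]
        emit(paste0("V_", tc, "_young"), l11^2,
             stats::setNames(2 * l11, pn[1L]))
        emit(paste0("V_", tc, "_old"), l21^2 + l22^2,
             stats::setNames(c(2 * l21, 2 * l22), pn[2:3]))
        emit(paste0("cov_", tc), l11 * l21,
             stats::setNames(c(l21, l11), pn[1:2]))
      })
  }
  if (m$resid == "iid") {
    emit("V_E", nat[["V_E"]], stats::setNames(1, "V_E"))
  } else {
    emit("V_E_young", nat[["V_E_young"]],
         stats::setNames(1, "V_E_young"))
    emit("V_E_old", nat[["V_E_old"]], stats::setNames(1, "V_E_old"))
  }
  list(theta = unlist(vals), jacobian = do.call(rbind, jac))
}

#' Fit an animal model by REML
#'
#' Maximises the restricted log-likelihood over a transformed
#' parameterisation (log scale for variances and rank-one scales,
#' Cholesky entries for the unstructured 2x2 genetic covariance, so
#' every iterate is positive semi-definite by construction) with
#' box-constrained quasi-Newton iterations and analytic gradients.
#' Multiple starts are used (an equal split of the phenotypic variance
#' plus deterministically jittered variants) and the best optimum kept.
#' Variance components are bounded below at `1e-8 * var(y)`; components
#' that finish at the bound are reported there and flagged.
#'
#' The covariance of the estimates is obtained from the observed
#' information (central finite differences of the analytic gradient) at
#' the optimum, excluding boundary-pinned parameters, and transformed
#' to the reporting scale (variances and covariances).
#'
#' @param m a `model_matrices` from [build_matrices()].
#' @param n_starts number of optimisation starts (default 3).
#' @param control passed to [stats::optim()] `L-BFGS-B` (default
#'   `list(factr = 1e7, maxit = 200)`).
#' @param hessian compute the observed-information covariance of the
#'   estimates (default TRUE); skip it in simulation loops that only
#'   use point estimates.
#' @return An object of class `reml_fit`: list with `theta` (named
#'   variance/covariance estimates on the reporting scale), `theta_se`,
#'   `theta_cov`, `logL`, `beta`, `beta_cov`, `beta_names`, `assign`,
#'   `converged`, `boundary` (named logical over `theta`), `n`,
#'   `n_params`, `spec`.
#' @export
fit_reml <- function(m, n_starts = 3, control = list(),
                     hessian = TRUE) {
  stopifnot(inherits(m, "model_matrices"))
  layout <- theta_layout(m)
  p <- length(layout)
  vy <- stats::var(m$y)
  lbv <- 1e-8 * vy
  control <- utils::modifyList(list(factr = 1e7, maxit = 200L), control)

  roles <- vapply(layout, `[[`, "", "role")
  transforms <- vapply(layout, `[[`, "", "transform")
  lower_nat <- ifelse(roles %in% c("var", "ve1", "ve2"), lbv,
                ifelse(roles %in% c("s1", "s2", "l11"), sqrt(lbv),
                 ifelse(roles == "l22", 1e-6 * sqrt(vy), -20 * sqrt(vy))))
  upper_nat <- ifelse(roles %in% c("var", "ve1", "ve2"), 1e3 * vy,
                      ifelse(transforms == "id", 20 * sqrt(vy),
                             sqrt(1e3 * vy)))
  lg <- transforms == "log"
  to_t <- function(nat) {
    t <- nat; t[lg] <- log(nat[lg]); t
  }
  to_nat <- function(t) {
    nat <- t; nat[lg] <- exp(t[lg])
    stats::setNames(nat, names(layout))
  }
  lower_t <- to_t(lower_nat); upper_t <- to_t(upper_nat)

  # cache: L-BFGS-B calls gr at points where fn was just evaluated,
  # so the Cholesky factor is reused (fn itself stays projection-free)
  cache <- new.env(parent = emptyenv())
  fn <- function(t) {
    nat <- to_nat(t)
    core <- reml_core(m, nat)
    if (is.null(core) || !is.finite(core$logL)) return(1e10)
    assign("t", t, envir = cache)
    assign("core", core, envir = cache)
    -core$logL
  }
  gr <- function(t) {
    core <- if (!is.null(cache$t) && isTRUE(all(cache$t == t)))
      cache$core else reml_core(m, to_nat(t))
    if (is.null(core)) return(rep(0, p))
    nat <- to_nat(t)
    gnat <- reml_grad_nat(m, nat, core)
    gt <- ifelse(transforms == "log", gnat * nat, gnat)
    -gt
  }

  # starts: equal split of the phenotypic variance among components,
  # plus deterministic jitters
  rv <- stats::var(stats::lm.fit(m$X, m$y)$residuals)
  v0 <- max(rv, 10 * lbv) / (length(m$kernels) + 1L)
  start_nat <- vapply(seq_along(layout), function(j) {
    switch(roles[j],
           var = , ve1 = , ve2 = v0,
           s1 = , s2 = , l11 = sqrt(v0),
           l21 = 0.3 * sqrt(v0),
           l22 = 0.8 * sqrt(v0))
  }, numeric(1))
  jitters <- list(rep(1, p),
                  rep_len(c(4, 0.25), p),
                  rep_len(c(0.25, 4), p))
  best <- NULL
  for (s in seq_len(min(n_starts, length(jitters)))) {
    f <- jitters[[s]]
    nat_s <- ifelse(transforms == "log",
                    pmin(pmax(start_nat * ifelse(roles %in%
                      c("s1", "s2", "l11", "l22"), sqrt(f), f),
                      lower_nat * 1.01), upper_nat * 0.99),
                    start_nat * ifelse(f > 1, 1.5, 0.5))
    opt <- tryCatch(
      stats::optim(to_t(nat_s), fn, gr, method = "L-BFGS-B",
                   lower = lower_t, upper = upper_t,
                   control = utils::modifyList(control,
                     list(factr = max(control$factr, 1e9)))),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best))
    stop("fit_reml: all optimisation starts failed")
  # polish from the best start with a tight tolerance so that nested
  # models pinned at a boundary reproduce the simpler optimum exactly
  conv_flag <- best$convergence == 0L
  polish <- tryCatch(
    stats::optim(best$par, fn, gr, method = "L-BFGS-B",
                 lower = lower_t, upper = upper_t,
                 control = utils::modifyList(control,
                                             list(factr = 100,
                                                  maxit = 500L))),
    error = function(e) NULL)
  if (!is.null(polish) && polish$value <= best$value) {
    # the polish run exhausting maxit is expected at factr = 10; it
    # does not overturn convergence of the main run
    conv_flag <- conv_flag || polish$convergence == 0L
    best <- polish
  }

  nat_hat <- to_nat(best$par)
  # a variance below 1e-5 of the phenotypic variance is a boundary
  # solution for all practical purposes (reported as 0, flagged)
  tau_v <- 1e-5 * vy
  pinned <- ifelse(roles %in% c("var", "ve1", "ve2"),
                   nat_hat < tau_v,
                   ifelse(roles %in% c("s1", "s2", "l11", "l22"),
                          nat_hat < sqrt(tau_v), FALSE))
  names(pinned) <- names(layout)

  # components held at the lower bound are true boundary solutions:
  # snap them to zero (the bound is a strictly interior surrogate) so
  # the restricted likelihood of a pinned model equals that of the
  # nested model without the component
  if (any(pinned)) {
    logL_orig <- -best$value
    nat_orig <- nat_hat
    nat0 <- nat_hat
    nat0[pinned] <- 0
    core0 <- reml_core(m, nat0)
    if (!is.null(core0)) {
      nat_hat <- nat0
      # re-optimise the free parameters with the pinned ones held at
      # zero, so the constrained optimum matches the nested model's
      fidx <- which(!pinned)
      if (length(fidx)) {
        lgf <- lg[fidx]
        nat_of <- function(tf) {
          nat <- nat_hat
          v <- tf; v[lgf] <- exp(tf[lgf])
          nat[fidx] <- v
          nat
        }
        fn2 <- function(tf) {
          core <- reml_core(m, nat_of(tf))
          if (is.null(core) || !is.finite(core$logL)) return(1e10)
          assign("t2", tf, envir = cache)
          assign("core2", core, envir = cache)
          -core$logL
        }
        gr2 <- function(tf) {
          core <- if (!is.null(cache$t2) &&
                        isTRUE(all(cache$t2 == tf))) cache$core2 else
            NULL
          nat <- nat_of(tf)
          g <- reml_grad_nat(m, nat, core)[fidx]
          gt <- g; gt[lgf] <- g[lgf] * nat[fidx][lgf]
          -gt
        }
        opt2 <- tryCatch(
          stats::optim(best$par[fidx], fn2, gr2, method = "L-BFGS-B",
                       lower = lower_t[fidx], upper = upper_t[fidx],
                       control = list(factr = 100, maxit = 200L)),
          error = function(e) NULL)
        if (!is.null(opt2) && -opt2$value >= core0$logL)
          nat_hat <- nat_of(opt2$par)
      }
      # revert if constraining to the boundary genuinely costs
      # likelihood (the component was small but interior)
      chk <- reml_core(m, nat_hat)
      if (is.null(chk) || chk$logL < logL_orig - 1e-6) {
        nat_hat <- nat_orig
        pinned[] <- FALSE
      }
    }
  }
  core <- reml_core(m, nat_hat, with_grad = TRUE)
  converged <- conv_flag && !is.null(core)

  rm_ <- report_map(m, nat_hat)
  theta <- rm_$theta
  J <- rm_$jacobian

  free <- which(!pinned)
  theta_cov <- matrix(NA_real_, length(theta), length(theta),
                      dimnames = list(names(theta), names(theta)))
  if (hessian && length(free)) {
    H <- matrix(NA_real_, length(free), length(free))
    for (jj in seq_along(free)) {
      j <- free[jj]
      h <- max(1e-4 * abs(nat_hat[j]), 1e-6 * sqrt(vy))
      up <- nat_hat; up[j] <- up[j] + h
      dn <- nat_hat; dn[j] <- max(dn[j] - h, lower_nat[j])
      gu <- reml_grad_nat(m, up)
      gd <- reml_grad_nat(m, dn)
      H[jj, ] <- (gu[free] - gd[free]) / (up[j] - dn[j])
    }
    H <- (H + t(H)) / 2
    info <- -H
    cov_nat <- tryCatch(solve(info), error = function(e) {
      eg <- eigen(info, symmetric = TRUE)
      pos <- eg$values > max(eg$values) * 1e-10
      eg$vectors[, pos, drop = FALSE] %*%
        diag(1 / eg$values[pos], sum(pos)) %*%
        t(eg$vectors[, pos, drop = FALSE])
    })
    Jf <- J[, free, drop = FALSE]
    theta_cov <- Jf %*% cov_nat %*% t(Jf)
    dimnames(theta_cov) <- list(names(theta), names(theta))
  }

  # flag report components whose underlying parameters are all pinned
  boundary <- apply(J != 0, 1L, function(r) all(pinned[r]))

  structure(list(theta = theta,
                 theta_se = sqrt(pmax(diag(theta_cov), 0)),
                 theta_cov = theta_cov,
                 logL = core$logL,
                 beta = stats::setNames(core$beta, colnames(m$X)),
                 beta_cov = core$beta_cov,
                 beta_names = colnames(m$X), assign = m$assign,
                 terms = m$terms,
                 converged = converged, boundary = boundary,
                 nat = nat_hat, pinned = pinned,
                 n = m$n, n_params = p, spec = m$spec),
            class = "reml_fit")
}

#' @export
print.reml_fit <- function(x, digits = 4, ...) {
  cat("REML animal model fit: ", format(x$spec), "  (trait: ",
      x$spec$trait, ")\n", sep = "")
  cat(sprintf("log restricted likelihood: %.3f   n = %d   %s\n",
              x$logL, x$n,
              if (x$converged) "converged" else "NOT converged"))
  se <- x$theta_se
  tab <- data.frame(estimate = signif(x$theta, digits),
                    se = ifelse(x$boundary, NA, signif(se, digits)),
                    boundary = ifelse(x$boundary, "at bound", ""))
  print(tab, ...)
  invisible(x)
}
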