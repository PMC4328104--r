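test_that("model matrices use treatment coding and drop redundant columns", {
  st <- tiny_study(n_quartets = 2, brood = 5, seed = 8)
  ph <- st$phenotypes
  spec <- model_spec("tarsus", fixed = c("maternal_age", "sex"),
                     random = list(origin = "iid"))
  m <- build_matrices(ph, spec)
  # intercept + 1 column per 2-level factor
  expect_equal(ncol(m$X), 3)
  expect_equal(colnames(m$X),
               c("(Intercept)", "maternal_ageyoung", "sexmale"))
  # duplicated factor: second copy dropped, rank unchanged
  spec2 <- model_spec("tarsus",
                      fixed = c("maternal_age", "sex", "maternal_age"),
                      random = list(origin = "iid"))
  expect_warning(m2 <- build_matrices(ph, spec2), "rank-deficient")
  expect_equal(qr(m2$X)$rank, ncol(m2$X))
  expect_equal(ncol(m2$X), 3)
  # covariates are centred
  stm <- tiny_study("mass", n_quartets = 2, brood = 5, seed = 8)
  spec3 <- model_spec("mass", fixed = c("sex", "tarsus"),
                      random = list(origin = "iid"))
  m3 <- build_matrices(stm$phenotypes, spec3)
  expect_equal(mean(m3$X[, "tarsus"]), 0)
  # unknown trait and missing id errors
  expect_error(build_matrices(ph, model_spec("nope")), "trait column")
  specA <- model_spec("tarsus", random = list(additive = "iid"))
  A <- study_A(st)
  expect_error(build_matrices(ph, specA, A[1:3, 1:3]), "absent from A")
})

test_that("REML matches the closed-form balanced one-way oracle", {
  set.seed(314)
  g <- 12; k <- 6
  group <- rep(sprintf("n%02d", 1:g), each = k)
  y <- rnorm(g) [match(group, unique(group))] * sqrt(0.5) +
    rnorm(g * k, sd = sqrt(0.3))
  ph <- data.frame(id = sprintf("i%03d", seq_along(y)), t = y,
                   nest_of_origin = group,
                   maternal_age = rep(c("young", "old"),
                                      length.out = g * k))
  spec <- model_spec("t", fixed = character(0),
                     random = list(origin = "iid"))
  m <- build_matrices(ph, spec)
  fit <- fit_reml(m)
  oracle <- balanced_oneway_reml(y, group)
  expect_equal(unname(fit$theta[["V_O"]]), oracle$sigma_u,
               tolerance = 1e-6)
  expect_equal(unname(fit$theta[["V_E"]]), oracle$sigma_e,
               tolerance = 1e-6)
  # the fitted maximum is the oracle maximum
  th <- theta_template(m)
  th["V_O"] <- oracle$sigma_u; th["V_E"] <- oracle$sigma_e
  expect_equal(fit$logL, reml_loglik(m, th), tolerance = 1e-8)
})

test_that("variance estimates agree with lme4 on identity-kernel models", {
  skip_if_not_installed("lme4")
  st <- tiny_study(n_quartets = 5, brood = 6, seed = 15)
  ph <- st$phenotypes
  spec <- model_spec("tarsus",
                     fixed = c("year", "maternal_age", "manipulation",
                               "sex"),
                     random = list(origin = "iid", rearing = "iid",
                                   quartet = "iid"))
  fit <- fit_reml(build_matrices(ph, spec))
  lf <- lme4::lmer(
    tarsus ~ year + maternal_age + manipulation + sex +
      (1 | nest_of_origin) + (1 | nest_of_rearing) + (1 | quartet),
    data = ph, REML = TRUE,
    control = lme4::lmerControl(check.conv.singular = "ignore"))
  vc <- as.data.frame(lme4::VarCorr(lf))
  ref <- stats::setNames(vc$vcov, vc$grp)
  expect_equal(unname(fit$theta[["V_O"]]),
               unname(ref[["nest_of_origin"]]), tolerance = 1e-4)
  expect_equal(unname(fit$theta[["V_R"]]),
               unname(ref[["nest_of_rearing"]]), tolerance = 1e-4)
  expect_equal(unname(fit$theta[["V_Q"]]),
               unname(ref[["quartet"]]), tolerance = 1e-3)
  expect_equal(unname(fit$theta[["V_E"]]),
               unname(ref[["Residual"]]), tolerance = 1e-4)
  expect_equal(fit$logL, as.numeric(stats::logLik(lf)),
               tolerance = 1e-6)
  # GLS fixed effects agree too
  expect_equal(unname(fit$beta), unname(lme4::fixef(lf)),
               tolerance = 1e-4)
})

test_that("the analytic gradient matches numerical differentiation", {
  st <- tiny_study(n_quartets = 2, brood = 5, seed = 23)
  A <- study_A(st)
  spec <- model_spec("tarsus",
                     random = list(additive = "group_r1",
                                   origin = "iid", rearing = "iid"),
                     residual = "group_diag")
  m <- build_matrices(st$phenotypes, spec, A)
  th <- theta_template(m)
  th[] <- c(0.35, 0.2, 0.07, 0.12, 0.2, 0.15)
  g <- agemodel:::reml_grad_nat(m, th)
  gn <- vapply(seq_along(th), function(j) {
    h <- 1e-6
    up <- th; up[j] <- up[j] + h
    dn <- th; dn[j] <- dn[j] - h
    (reml_loglik(m, up) - reml_loglik(m, dn)) / (2 * h)
  }, numeric(1))
  expect_equal(unname(g), gn, tolerance = 1e-5)
})

test_that("likelihood respects nesting and scale equivariance", {
  st <- tiny_study(n_quartets = 3, brood = 5, seed = 33)
  A <- study_A(st)
  ph <- st$phenotypes

  # group_r1 at s1 = s2 = sqrt(v) equals the homogeneous model at v
  spec_r1 <- model_spec("tarsus",
                        random = list(additive = "group_r1",
                                      origin = "iid", rearing = "iid"))
  spec_iid <- model_spec("tarsus",
                         random = list(additive = "iid",
                                       origin = "iid", rearing = "iid"))
  m1 <- build_matrices(ph, spec_r1, A)
  m0 <- build_matrices(ph, spec_iid, A)
  v <- 0.2
  th1 <- theta_template(m1)
  th1[c("s_A_young", "s_A_old")] <- sqrt(v)
  th1[c("V_O", "V_R", "V_E")] <- c(0.05, 0.1, 0.15)
  th0 <- theta_template(m0)
  th0["V_A"] <- v; th0[c("V_O", "V_R", "V_E")] <- c(0.05, 0.1, 0.15)
  expect_equal(reml_loglik(m1, th1), reml_loglik(m0, th0),
               tolerance = 1e-10)

  # doubling y: variance estimates scale by 4, logL shifts by
  # -(n - p) log 2 at the rescaled optimum
  fit0 <- fit_reml(m0)
  ph2 <- ph; ph2$tarsus <- 2 * ph2$tarsus
  fit2 <- fit_reml(build_matrices(ph2, spec_iid, A))
  expect_equal(unname(fit2$theta), unname(4 * fit0$theta),
               tolerance = 1e-3)
  np <- fit0$n - length(fit0$beta)
  expect_equal(fit2$logL, fit0$logL - np * log(2), tolerance = 1e-4)
})

test_that("fits are invariant to record order and reparameterisation", {
  st <- tiny_study(n_quartets = 3, brood = 5, seed = 44)
  A <- study_A(st)
  ph <- st$phenotypes
  spec <- model_spec("tarsus",
                     random = list(additive = "iid", origin = "iid",
                                   rearing = "iid"))
  fit_a <- fit_reml(build_matrices(ph, spec, A))
  set.seed(1)
  fit_b <- fit_reml(build_matrices(ph[sample(nrow(ph)), ], spec, A))
  expect_equal(fit_a$theta, fit_b$theta, tolerance = 1e-6)
  expect_equal(fit_a$logL, fit_b$logL, tolerance = 1e-8)

  # unstructured fit with r at the boundary r = 1 matches group_r1
  # (simulate strongly rank-1 genetic structure)
  pg <- default_trait_params("pha")
  pg$covariate <- NULL
  stg <- simulate_study(design_config(n_quartets = 6,
                                      nestlings_per_nest = 6,
                                      years = c("y1", "y2")),
                        pg, seed = 55)
  Ag <- study_A(stg)
  s_r1 <- model_spec("pha", fixed = c("year", "maternal_age"),
                     random = list(additive = "group_r1",
                                   origin = "iid", rearing = "iid",
                                   quartet = "iid"))
  s_un <- s_r1; s_un$random$additive <- "group_unstructured"
  f_r1 <- fit_reml(build_matrices(stg$phenotypes, s_r1, Ag))
  f_un <- fit_reml(build_matrices(stg$phenotypes, s_un, Ag))
  expect_gte(f_un$logL, f_r1$logL - 1e-6)
  r_hat <- f_un$theta[["cov_A"]] /
    sqrt(f_un$theta[["V_A_young"]] * f_un$theta[["V_A_old"]])
  if (r_hat > 0.999)
    expect_equal(f_un$logL, f_r1$logL, tolerance = 1e-4)
})

test_that("true-zero variance components pin at the boundary with a flag", {
  p <- trait_params("t", mean = 1, V_A1 = 0, V_A2 = 0, r_xage = 1,
                    V_O = 0, V_R = 0.2, V_Q = 0, V_E1 = 0.3)
  st <- simulate_study(design_config(n_quartets = 4,
                                     nestlings_per_nest = 6),
                       p, seed = 66)
  A <- study_A(st)
  spec <- model_spec("t", fixed = c("maternal_age"),
                     random = list(additive = "iid", origin = "iid",
                                   rearing = "iid", quartet = "iid"))
  fit <- fit_reml(build_matrices(st$phenotypes, spec, A))
  expect_true(fit$boundary[["V_Q"]])
  expect_lt(fit$theta[["V_Q"]], 1e-6)
  expect_true(is.na(fit$theta_se[["V_Q"]]) ||
                fit$boundary[["V_Q"]])
  # non-zero components not pinned
  expect_false(fit$boundary[["V_R"]])
  expect_false(fit$boundary[["V_E"]])
  # single small replicate: V_R is recovered only to ~1 sampling SE
  expect_gt(unname(fit$theta[["V_R"]]), 0.05)
  expect_lt(unname(fit$theta[["V_R"]]), 0.4)
})
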