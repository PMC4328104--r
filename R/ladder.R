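# Model ladders: per-trait sequences of nested variance structures of
# increasing complexity, and the pairwise comparisons between them.

ladder_random <- function(q = FALSE, r = FALSE, o = FALSE,
                          a = "none", rk = "iid", ok = "iid") {
  out <- list()
  if (q) out$quartet <- "iid"
  if (r) out$rearing <- rk
  if (o) out$origin <- ok
  if (a != "none") out$additive <- a
  out
}

#' Model sequence and comparisons for a trait's ladder
#'
#' Returns the ordered list of model specifications fitted for a
#' trait, numbered as in the analysis ladder, together with the
#' pairwise comparisons (complex vs simple) evaluated by likelihood-
#' ratio tests.  Tarsus uses 8 models (no quartet term beyond model 2,
#' which tests it); body mass uses 5; the immune response (PHA) uses
#' 12, including the unconstrained cross-age genetic covariance
#' (model 9) and age-heterogeneous rearing/origin structures
#' (models 10--12).
#'
#' @param trait `"tarsus"`, `"mass"` or `"pha"`.
#' @param fixed fixed-effect columns shared by every model in the
#'   ladder (default [default_fixed_effects()]).
#' @return List with `models` (named list of [model_spec]) and
#'   `comparisons` (list of `c(complex, simple)` model numbers).
#' @export
ladder_definition <- function(trait = c("tarsus", "mass", "pha"),
                              fixed = NULL) {
  trait <- match.arg(trait)
  if (is.null(fixed)) fixed <- default_fixed_effects(trait)
  ms <- function(random, residual = "iid")
    model_spec(trait, fixed = fixed, random = random,
               residual = residual)
  if (trait == "tarsus") {
    models <- list(
      `1` = ms(ladder_random()),
      `2` = ms(ladder_random(q = TRUE)),
      `3` = ms(ladder_random(r = TRUE)),
      `4` = ms(ladder_random(r = TRUE, o = TRUE)),
      `5` = ms(ladder_random(r = TRUE, o = TRUE, a = "iid")),
      `6` = ms(ladder_random(r = TRUE, o = TRUE, a = "group_r1")),
      `7` = ms(ladder_random(r = TRUE, o = TRUE, a = "iid"),
               residual = "group_diag"),
      `8` = ms(ladder_random(r = TRUE, o = TRUE, a = "group_r1"),
               residual = "group_diag"))
    comparisons <- list(c(2, 1), c(3, 1), c(4, 3), c(5, 4), c(6, 5),
                        c(7, 5), c(8, 7), c(8, 6))
  } else if (trait == "mass") {
    models <- list(
      `1` = ms(ladder_random()),
      `2` = ms(ladder_random(q = TRUE)),
      `3` = ms(ladder_random(q = TRUE, r = TRUE)),
      `4` = ms(ladder_random(q = TRUE, r = TRUE, o = TRUE)),
      `5` = ms(ladder_random(q = TRUE, r = TRUE, o = TRUE, a = "iid")))
    comparisons <- list(c(2, 1), c(3, 2), c(4, 3), c(5, 4))
  } else {
    base <- function(a, rk = "iid", ok = "iid", residual = "iid")
      ms(ladder_random(q = TRUE, r = TRUE, o = TRUE, a = a,
                       rk = rk, ok = ok), residual = residual)
    models <- list(
      `1` = ms(ladder_random()),
      `2` = ms(ladder_random(q = TRUE)),
      `3` = ms(ladder_random(q = TRUE, r = TRUE)),
      `4` = ms(ladder_random(q = TRUE, r = TRUE, o = TRUE)),
      `5` = base("iid"),
      `6` = base("group_r1"),
      `7` = base("iid", residual = "group_diag"),
      `8` = base("group_r1", residual = "group_diag"),
      `9` = base("group_unstructured"),
      `10` = base("group_r1", rk = "group_r1", ok = "group_r1"),
      `11` = base("group_r1", rk = "group_r1"),
      `12` = base("group_r1", ok = "group_r1"))
    comparisons <- list(c(2, 1), c(3, 2), c(4, 3), c(5, 4), c(6, 5),
                        c(7, 5), c(8, 6), c(8, 7), c(9, 6), c(10, 6),
                        c(11, 6), c(12, 6))
  }
  list(models = models, comparisons = comparisons)
}

#' Fit a trait's full model ladder
#'
#' Fits every model of [ladder_definition()] for the trait and
#' evaluates the declared likelihood-ratio comparisons.  The selected
#' model follows a forward rule: starting from the simplest model, a
#' comparison whose simple member is the currently selected model and
#' whose p-value falls below `alpha` promotes its complex member.
#'
#' @param phenotypes analysis phenotype table.
#' @param A relationship matrix covering all record ids.
#' @param trait `"tarsus"`, `"mass"` or `"pha"`.
#' @param fixed optional fixed-effect override.
#' @param alpha selection threshold (default 0.05).
#' @param mode p-value convention for selection, see [lrt()].
#' @param n_starts optimisation starts per model.
#' @return List of class `ladder_report`: `fits` (named by model
#'   number), `tests` (data frame shaped like a variance-component LRT
#'   table), `selected` (model number as character), `trait`.
#' @export
model_ladder <- function(phenotypes, A, trait, fixed = NULL,
                         alpha = 0.05, mode = c("plain", "mixture"),
                         n_starts = 3) {
  mode <- match.arg(mode)
  if (!trait %in% c("tarsus", "mass", "pha"))
    stop("model_ladder: unknown trait '", trait, "'")
  if (!trait %in% names(phenotypes))
    stop("model_ladder: trait column '", trait, "' absent")
  def <- ladder_definition(trait, fixed = fixed)
  fits <- lapply(def$models, function(sp)
    fit_reml(build_matrices(phenotypes, sp,
                            A = if ("additive" %in% names(sp$random))
                              A else NULL),
             n_starts = n_starts))
  tests <- lapply(def$comparisons, function(cmp) {
    lr <- lrt(fits[[as.character(cmp[1])]], fits[[as.character(cmp[2])]],
              mode = mode)
    data.frame(model = format(fits[[as.character(cmp[1])]]$spec),
               no = cmp[1], test = paste(cmp[1], "versus", cmp[2]),
               logL = fits[[as.character(cmp[1])]]$logL,
               delta_logL = lr$delta_logL, df = lr$df,
               p_plain = lr$p_plain, p_mixture = lr$p_mixture,
               stringsAsFactors = FALSE)
  })
  tests <- do.call(rbind, tests)

  selected <- "1"
  for (i in seq_along(def$comparisons)) {
    cmp <- def$comparisons[[i]]
    pv <- if (mode == "plain") tests$p_plain[i] else tests$p_mixture[i]
    if (as.character(cmp[2]) == selected && pv < alpha)
      selected <- as.character(cmp[1])
  }
  structure(list(fits = fits, tests = tests, selected = selected,
                 trait = trait, alpha = alpha, mode = mode),
            class = "ladder_report")
}

#' @export
print.ladder_report <- function(x, ...) {
  cat("Likelihood-ratio ladder for trait '", x$trait, "' (",
      length(x$fits), " models)\n\n", sep = "")
  tab <- x$tests
  tab$logL <- sprintf("%.2f", tab$logL)
  tab$delta_logL <- sprintf("%.2f", tab$delta_logL)
  tab$p_plain <- format.pval(tab$p_plain, digits = 3, eps = 1e-3)
  tab$p_mixture <- format.pval(tab$p_mixture, digits = 3, eps = 1e-3)
  print(tab, row.names = FALSE)
  cat("\nSelected model (forward rule, alpha =", x$alpha, ", mode =",
      x$mode, "):", x$selected, "=",
      format(x$fits[[x$selected]]$spec), "\n")
  invisible(x)
}
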