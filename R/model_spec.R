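#' Specify an animal model
#'
#' Declares the response, fixed effects and random-effect variance
#' structures of an animal model on the cross-fostered design.  Random
#' terms are drawn from `additive` (covariance proportional to the
#' pedigree relationship matrix A), `origin`, `rearing` and `quartet`
#' (iid nest/block effects).  Each term carries a variance structure:
#'
#' * `"iid"` -- one variance, shared across maternal age classes;
#' * `"group_r1"` -- age-specific variances with the cross-age
#'   correlation fixed at unity (G = s s', 2 parameters);
#' * `"group_unstructured"` -- full 2x2 PSD covariance matrix
#'   (3 parameters; additive term only).
#'
#' The residual is `"iid"` (one variance) or `"group_diag"` (one
#' residual variance per maternal age class, zero cross-covariance).
#'
#' @param trait response column name in the phenotype table.
#' @param fixed character vector of fixed-effect columns; character or
#'   factor columns are treatment-coded (reference = first sorted
#'   level), numeric columns enter centred as covariates.
#' @param random named list mapping term names (`additive`, `origin`,
#'   `rearing`, `quartet`) to structure strings.
#' @param residual `"iid"` or `"group_diag"`.
#' @param group_by column defining the two variance groups (the
#'   genetic mother's age class).
#' @return A list of class `model_spec`.
#' @examples
#' model_spec("pha", fixed = c("year", "maternal_age", "manipulation", "mass"),
#'            random = list(additive = "group_r1", origin = "iid",
#'                          rearing = "iid", quartet = "iid"))
#' @export
model_spec <- function(trait,
                       fixed = c("year", "maternal_age", "manipulation"),
                       random = list(additive = "iid", origin = "iid",
                                     rearing = "iid", quartet = "iid"),
                       residual = c("iid", "group_diag"),
                       group_by = "maternal_age") {
  residual <- match.arg(residual)
  ok_terms <- c("additive", "origin", "rearing", "quartet")
  ok_kinds <- c("iid", "group_r1", "group_unstructured")
  if (length(random)) {
    if (is.null(names(random)) || !all(names(random) %in% ok_terms))
      stop("model_spec: random terms must be named among: ",
           paste(ok_terms, collapse = ", "))
    kinds <- unlist(random)
    if (!all(kinds %in% ok_kinds))
      stop("model_spec: unknown variance structure: ",
           paste(setdiff(kinds, ok_kinds), collapse = ", "))
    if (any(kinds == "group_unstructured" &
              names(random) != "additive"))
      stop("model_spec: group_unstructured is supported for the ",
           "additive term only")
  }
  structure(list(trait = trait, fixed = fixed,
                 random = random[intersect(ok_terms, names(random))],
                 residual = residual, group_by = group_by),
            class = "model_spec")
}

# number of (co)variance parameters, ladder counting convention
#' Number of variance parameters of a model specification
#' @param spec a [model_spec].
#' @return Integer count of free (co)variance parameters.
#' @export
n_variance_params <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  k <- vapply(spec$random, function(s)
    switch(s, iid = 1L, group_r1 = 2L, group_unstructured = 3L),
    integer(1))
  sum(k) + if (spec$residual == "iid") 1L else 2L
}

# compact term-code label, e.g. "E Q R O Age(A)"
#' @export
format.model_spec <- function(x, ...) {
  code <- c(additive = "A", origin = "O", rearing = "R", quartet = "Q")
  lab <- if (x$residual == "iid") "E" else "Age(E)"
  for (term in c("quartet", "rearing", "origin", "additive")) {
    if (!term %in% names(x$random)) next
    tc <- code[[term]]
    lab <- paste(lab, switch(x$random[[term]],
                             iid = tc,
                             group_r1 = paste0("Age(", tc, ")"),
                             group_unstructured = paste0("Age(", tc, ")*")))
  }
  lab
}

#' @export
print.model_spec <- function(x, ...) {
  cat("Animal model for '", x$trait, "': ", format(x), "\n",
      "  fixed: ", paste(x$fixed, collapse = " + "), "\n",
      "  variance parameters: ", n_variance_params(x), "\n", sep = "")
  invisible(x)
}

structure_rank <- function(kind) {
  switch(kind, none = 0L, iid = 1L, group_r1 = 2L,
         group_unstructured = 3L)
}

#' Test whether one model specification nests inside another
#'
#' `simple` is nested in `complex` when they share the response and
#' fixed effects and every random/residual structure of `simple` is a
#' constrained version of the corresponding structure in `complex`
#' (none < iid < group_r1 < group_unstructured; residual iid <
#' group_diag).
#'
#' @param simple,complex [model_spec] objects.
#' @return Logical.
#' @export
is_nested <- function(simple, complex) {
  stopifnot(inherits(simple, "model_spec"),
            inherits(complex, "model_spec"))
  if (!identical(simple$trait, complex$trait)) return(FALSE)
  if (!identical(simple$fixed, complex$fixed)) return(FALSE)
  terms <- union(names(simple$random), names(complex$random))
  for (term in terms) {
    rs <- structure_rank(simple$random[[term]] %||% "none")
    rc <- structure_rank(complex$random[[term]] %||% "none")
    if (rs > rc) return(FALSE)
  }
  rs <- if (simple$residual == "iid") 1L else 2L
  rc <- if (complex$residual == "iid") 1L else 2L
  if (rs > rc) return(FALSE)
  n_variance_params(complex) > n_variance_params(simple)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default fixed effects per trait
#'
#' Year, maternal age and brood-size manipulation enter every model;
#' sex is added for the size traits (tarsus, mass), tarsus length is a
#' covariate in the mass model, and body mass is a covariate in the
#' immune-response (PHA) model.
#'
#' @param trait one of `"tarsus"`, `"mass"`, `"pha"`.
#' @return Character vector of column names.
#' @export
default_fixed_effects <- function(trait = c("tarsus", "mass", "pha")) {
  trait <- match.arg(trait)
  switch(trait,
         tarsus = c("year", "maternal_age", "manipulation", "sex"),
         mass = c("year", "maternal_age", "manipulation", "sex",
                  "tarsus"),
         pha = c("year", "maternal_age", "manipulation", "mass"))
}
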