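#' Build model matrices for a REML fit
#'
#' Assembles the response vector, the fixed-effects design matrix
#' (treatment coding with deterministic reference levels, centred
#' covariates, redundant columns dropped left-to-right) and, for each
#' random term, the marginal covariance kernel of the records: the
#' submatrix of the relationship matrix A for the additive term, and
#' same-level indicator matrices for nest-of-origin, nest-of-rearing
#' and quartet.  Group-structured terms carry the records' maternal
#' age class.
#'
#' Records with a missing response or missing values in any used
#' column are dropped.
#'
#' @param phenotypes data frame with one row per record (the analysis
#'   table of a study).
#' @param spec a [model_spec].
#' @param A relationship matrix from [relationship_matrix()]; required
#'   when the spec has an additive term and must cover every record id.
#' @return A list of class `model_matrices` with elements `y`, `X`,
#'   `assign` (term index per X column), `terms`, `kernels`, `resid`,
#'   `group` (integer 1 = young, 2 = old), `ids`, `n`.
#' @export
build_matrices <- function(phenotypes, spec, A = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  if (!spec$trait %in% names(phenotypes))
    stop("build_matrices: trait column '", spec$trait,
         "' absent from phenotype table")
  miss <- setdiff(c(spec$fixed, spec$group_by, "id"), names(phenotypes))
  if (length(miss))
    stop("build_matrices: column(s) missing from phenotype table: ",
         paste(miss, collapse = ", "))

  used <- unique(c("id", spec$trait, spec$fixed, spec$group_by,
                   intersect(c("nest_of_origin", "nest_of_rearing",
                               "quartet"), names(phenotypes))))
  ph <- phenotypes[stats::complete.cases(phenotypes[used]), , drop = FALSE]
  n <- nrow(ph)
  if (n == 0L) stop("build_matrices: no complete records")
  y <- as.numeric(ph[[spec$trait]])

  # fixed design: intercept, treatment-coded factors, centred covariates
  X <- matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)"))
  assign <- 0L
  for (j in seq_along(spec$fixed)) {
    v <- ph[[spec$fixed[j]]]
    if (is.numeric(v)) {
      cols <- matrix(v - mean(v), n, 1L,
                     dimnames = list(NULL, spec$fixed[j]))
    } else {
      f <- factor(v, levels = sort(unique(as.character(v))))
      if (nlevels(f) < 2L) next
      cols <- stats::model.matrix(~f)[, -1L, drop = FALSE]
      colnames(cols) <- paste0(spec$fixed[j], levels(f)[-1L])
    }
    X <- cbind(X, cols)
    assign <- c(assign, rep(j, ncol(cols)))
  }
  # drop rank-deficient columns deterministically, left to right
  keep <- logical(ncol(X))
  r <- 0L
  for (k in seq_len(ncol(X))) {
    if (qr(X[, c(which(keep), k), drop = FALSE])$rank > r) {
      keep[k] <- TRUE; r <- r + 1L
    }
  }
  if (!all(keep))
    warning("build_matrices: dropped ", sum(!keep),
            " rank-deficient fixed-effect column(s): ",
            paste(colnames(X)[!keep], collapse = ", "))
  assign <- assign[keep]
  X <- X[, keep, drop = FALSE]

  grp_lab <- as.character(ph[[spec$group_by]])
  glev <- c("young", "old")
  if (!all(grp_lab %in% glev))
    stop("build_matrices: group column '", spec$group_by,
         "' must contain only 'young'/'old'")
  g <- match(grp_lab, glev)

  kernels <- list()
  for (term in names(spec$random)) {
    if (term == "additive") {
      if (is.null(A))
        stop("build_matrices: additive term requires a relationship ",
             "matrix A")
      bad <- setdiff(ph$id, rownames(A))
      if (length(bad))
        stop("build_matrices: record id(s) absent from A: ",
             paste(utils::head(bad, 5L), collapse = ", "),
             if (length(bad) > 5L) " ...")
      C <- A[ph$id, ph$id, drop = FALSE]
    } else {
      col <- switch(term, origin = "nest_of_origin",
                    rearing = "nest_of_rearing", quartet = "quartet")
      if (!col %in% names(ph))
        stop("build_matrices: column '", col, "' required by random ",
             "term '", term, "' is absent")
      f <- as.character(ph[[col]])
      C <- (outer(f, f, "==")) * 1
    }
    dimnames(C) <- NULL
    kernels[[term]] <- list(term = term, kind = spec$random[[term]],
                            C = C)
  }
  structure(list(y = y, X = X, assign = assign, terms = spec$fixed,
                 kernels = kernels, resid = spec$residual, group = g,
                 ids = ph$id, n = n, spec = spec),
            class = "model_matrices")
}
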