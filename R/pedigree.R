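#' Construct a validated, topologically sorted pedigree
#'
#' A pedigree is a data frame with columns `id`, `dam`, `sire` (character;
#' `NA` for an unknown parent), ordered so that every parent precedes every
#' one of its offspring.  Parents that appear only in the `dam`/`sire`
#' columns are inserted as founder records (both parents unknown).
#'
#' Validation enforces the structural rules an animal model relies on:
#' unique non-empty ids, no self-parenting, no cycles, and sex consistency
#' (no label may be used both as a dam and as a sire anywhere in the
#' pedigree -- a violation almost always indicates swapped columns).
#'
#' @param id,dam,sire character vectors of equal length; `dam`/`sire`
#'   entries that are `NA`, empty, or in `missing_codes` are unknown.
#' @param missing_codes values (besides `NA`) interpreted as "unknown
#'   parent"; default `c("", "NA", "0")`.
#' @return An object of class `pedigree`: a data frame with columns
#'   `id`, `dam`, `sire`, topologically sorted, with attribute `founders`.
#' @examples
#' ped <- pedigree(id = "C", dam = "A", sire = "B")
#' ped$id  # founders A, B precede C
#' @export
pedigree <- function(id, dam = NA_character_, sire = NA_character_,
                     missing_codes = c("", "NA", "0")) {
  id <- as.character(id)
  n <- length(id)
  dam <- rep_len(as.character(dam), n)
  sire <- rep_len(as.character(sire), n)
  dam[dam %in% missing_codes] <- NA_character_
  sire[sire %in% missing_codes] <- NA_character_
  dam <- trimws(dam); sire <- trimws(sire); id <- trimws(id)
  dam[dam == ""] <- NA_character_; sire[sire == ""] <- NA_character_

  if (any(is.na(id) | id == ""))
    stop("pedigree: empty or missing individual id")
  if (anyDuplicated(id))
    stop("pedigree: duplicated id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  self <- which(id == dam | id == sire)
  if (length(self))
    stop("pedigree: individual(s) recorded as own parent: ",
         paste(id[self], collapse = ", "))

  dams <- stats::na.omit(unique(dam))
  sires <- stats::na.omit(unique(sire))
  both <- intersect(dams, sires)
  if (length(both))
    stop("pedigree: label(s) used as both dam and sire ",
         "(likely swapped columns): ", paste(both, collapse = ", "))

  # auto-insert founders for parents without their own record
  parents <- unique(c(dams, sires))
  missing_rec <- setdiff(parents, id)
  if (length(missing_rec)) {
    id <- c(id, missing_rec)
    dam <- c(dam, rep(NA_character_, length(missing_rec)))
    sire <- c(sire, rep(NA_character_, length(missing_rec)))
  }

  ord <- ped_toposort(id, dam, sire)
  out <- data.frame(id = id[ord], dam = dam[ord], sire = sire[ord],
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, class = c("pedigree", "data.frame"),
            founders = out$id[is.na(out$dam) & is.na(out$sire)])
}

# Kahn's algorithm on parent -> offspring edges; reports a cycle chain
# on failure.  Returns an ordering of indices into id.
ped_toposort <- function(id, dam, sire) {
  n <- length(id)
  di <- match(dam, id)
  si <- match(sire, id)
  indeg <- (!is.na(di)) + (!is.na(si))
  children <- vector("list", n)
  for (i in seq_len(n)) {
    if (!is.na(di[i])) children[[di[i]]] <- c(children[[di[i]]], i)
    if (!is.na(si[i])) children[[si[i]]] <- c(children[[si[i]]], i)
  }
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue)) {
    # pop the smallest original index for a deterministic order
    queue <- sort(queue)
    v <- queue[1L]; queue <- queue[-1L]
    ord <- c(ord, v)
    for (w in children[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  if (length(ord) < n) {
    left <- setdiff(seq_len(n), ord)
    # walk parent links among the leftovers to show one cycle
    chain <- left[1L]
    repeat {
      nxt <- di[chain[length(chain)]]
      if (is.na(nxt) || !(nxt %in% left)) nxt <- si[chain[length(chain)]]
      if (is.na(nxt)) break
      if (nxt %in% chain) { chain <- c(chain, nxt); break }
      chain <- c(chain, nxt)
    }
    stop("pedigree: cycle detected involving: ",
         paste(id[chain], collapse = " -> "))
  }
  ord
}

#' Read a pedigree from a CSV file
#'
#' The file must have a header with columns `id`, `dam`, `sire`;
#' additional columns are ignored.  Empty fields, `NA` and `0` are
#' treated as unknown parents (configurable).
#'
#' @param path path to a CSV file.
#' @inheritParams pedigree
#' @return A [pedigree] object.
#' @export
read_pedigree <- function(path, missing_codes = c("", "NA", "0")) {
  df <- utils::read.csv(path, colClasses = "character",
                        stringsAsFactors = FALSE)
  need <- c("id", "dam", "sire")
  if (!all(need %in% names(df)))
    stop("pedigree file must have columns id, dam, sire; found: ",
         paste(names(df), collapse = ", "))
  pedigree(df$id, df$dam, df$sire, missing_codes = missing_codes)
}

#' @export
print.pedigree <- function(x, ...) {
  cat("Pedigree with", nrow(x), "individuals (",
      length(attr(x, "founders")), "founders )\n")
  print.data.frame(utils::head(as.data.frame(x), 10L), ...)
  if (nrow(x) > 10L) cat("...", nrow(x) - 10L, "more rows\n")
  invisible(x)
}

#' Additive (numerator) relationship matrix
#'
#' Computes the matrix A of expected additive relationships (twice the
#' kinship) over all pedigree members by the recursive tabular method:
#' for individual i with parents d, s (taken in pedigree order),
#' \deqn{a_{ij} = (a_{jd} + a_{js})/2, \qquad a_{ii} = 1 + a_{ds}/2,}
#' with an unknown parent contributing zero.  Diagonal entries equal
#' 1 + F where F is the individual's inbreeding coefficient.
#'
#' @param ped a [pedigree].
#' @return A symmetric numeric matrix with dimnames equal to `ped$id`.
#' @examples
#' ped <- pedigree(id = c("C", "D"), dam = c("A", "A"), sire = c("B", "B"))
#' relationship_matrix(ped)["C", "D"]  # full sibs: 0.5
#' @export
relationship_matrix <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  di <- match(ped$dam, ped$id)
  si <- match(ped$sire, ped$id)
  if (any(stats::na.omit(di) >= seq_len(n)[!is.na(di)]) ||
      any(stats::na.omit(si) >= seq_len(n)[!is.na(si)]))
    stop("relationship_matrix: pedigree is not topologically sorted")
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    d <- di[i]; s <- si[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      ad <- if (is.na(d)) 0 else A[j, d]
      as_ <- if (is.na(s)) 0 else A[j, s]
      v <- 0.5 * (ad + as_)
      A[j, i] <- v
      A[i, j] <- v
    }
    A[i, i] <- 1 + if (is.na(d) || is.na(s)) 0 else 0.5 * A[d, s]
  }
  A
}

#' Write a relationship matrix as labelled CSV
#'
#' @param A matrix from [relationship_matrix()].
#' @param path output file.
#' @export
write_relationship_matrix <- function(A, path) {
  df <- data.frame(id = rownames(A), A, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Prune a pedigree to phenotyped individuals and their ancestors
#'
#' Keeps every phenotyped individual together with its full ancestor
#' closure and drops everyone else.  Relationships among retained
#' individuals are unchanged by pruning.
#'
#' @param ped a [pedigree].
#' @param phenotyped character vector of ids carrying phenotypes; labels
#'   absent from the pedigree are dropped with a warning.
#' @return A re-sorted [pedigree] containing the closure.
#' @export
prune_pedigree <- function(ped, phenotyped) {
  stopifnot(inherits(ped, "pedigree"))
  phenotyped <- unique(as.character(phenotyped))
  unknown <- setdiff(phenotyped, ped$id)
  if (length(unknown)) {
    warning("prune_pedigree: ignoring ", length(unknown),
            " phenotyped label(s) absent from the pedigree")
    phenotyped <- setdiff(phenotyped, unknown)
  }
  if (!length(phenotyped))
    stop("prune_pedigree: no informative individuals ",
         "(empty intersection of phenotyped ids and pedigree)")
  di <- match(ped$dam, ped$id)
  si <- match(ped$sire, ped$id)
  keep <- logical(nrow(ped))
  frontier <- match(phenotyped, ped$id)
  while (length(frontier)) {
    keep[frontier] <- TRUE
    up <- unique(stats::na.omit(c(di[frontier], si[frontier])))
    frontier <- up[!keep[up]]
  }
  pedigree(ped$id[keep], ped$dam[keep], ped$sire[keep])
}

#' Pedigree summary statistics
#'
#' Counts the pedigree links that are informative for a given set of
#' phenotyped individuals: maternities/paternities (phenotyped
#' individuals with a known dam/sire) and mean maternal/paternal sibship
#' sizes (mean number of phenotyped offspring per known dam or sire).
#'
#' @inheritParams prune_pedigree
#' @return A list of class `pedigree_stats` with elements
#'   `n_informative`, `n_maternities`, `n_paternities`,
#'   `mean_maternal_sibship`, `mean_paternal_sibship`.
#' @export
pedigree_stats <- function(ped, phenotyped) {
  stopifnot(inherits(ped, "pedigree"))
  phenotyped <- intersect(unique(as.character(phenotyped)), ped$id)
  rows <- ped[ped$id %in% phenotyped, , drop = FALSE]
  mat <- !is.na(rows$dam)
  pat <- !is.na(rows$sire)
  msib <- if (any(mat)) mean(table(rows$dam[mat])) else 0
  psib <- if (any(pat)) mean(table(rows$sire[pat])) else 0
  structure(list(n_informative = length(phenotyped),
                 n_maternities = sum(mat),
                 n_paternities = sum(pat),
                 mean_maternal_sibship = msib,
                 mean_paternal_sibship = psib),
            class = "pedigree_stats")
}

#' @export
print.pedigree_stats <- function(x, ...) {
  cat(sprintf(paste0("Informative individuals: %d\n",
                     "Maternities: %d (mean sibship %.2f)\n",
                     "Paternities: %d (mean sibship %.2f)\n"),
              x$n_informative, x$n_maternities, x$mean_maternal_sibship,
              x$n_paternities, x$mean_paternal_sibship))
  invisible(x)
}
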