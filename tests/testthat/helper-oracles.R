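# Shared fixtures and independent oracles used across test files.

# trio: two founders and their offspring
trio <- function() pedigree(id = "C", dam = "A", sire = "B")

# full-sib pair plus an inbred offspring of the two sibs
# (D male, C female so the dam/sire disjointness rule is respected)
inbred_ped <- function() {
  pedigree(id = c("C", "D", "X"), dam = c("A", "A", "C"),
           sire = c("B", "B", "D"))
}

# Gene-dropping Monte-Carlo oracle for additive relationships:
# founders get unique alleles, each offspring inherits one random
# allele per parent, and a_ij is estimated as twice the probability
# that a random allele from i is identical by descent to a random
# allele from j (vectorised over replicates).
gene_drop_A <- function(ped, n_rep = 2e5) {
  n <- nrow(ped)
  di <- match(ped$dam, ped$id)
  si <- match(ped$sire, ped$id)
  al1 <- vector("list", n)  # maternal allele per replicate
  al2 <- vector("list", n)  # paternal allele per replicate
  next_allele <- 0L
  for (i in seq_len(n)) {
    if (is.na(di[i])) {
      al1[[i]] <- rep.int(next_allele <- next_allele + 1L, n_rep)
    } else {
      pickm <- stats::runif(n_rep) < 0.5
      al1[[i]] <- ifelse(pickm, al1[[di[i]]], al2[[di[i]]])
    }
    if (is.na(si[i])) {
      al2[[i]] <- rep.int(next_allele <- next_allele + 1L, n_rep)
    } else {
      pickp <- stats::runif(n_rep) < 0.5
      al2[[i]] <- ifelse(pickp, al1[[si[i]]], al2[[si[i]]])
    }
  }
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) for (j in i:n) {
    # mean over the four allele-pair comparisons = kinship f_ij
    f <- (mean(al1[[i]] == al1[[j]]) + mean(al1[[i]] == al2[[j]]) +
            mean(al2[[i]] == al1[[j]]) + mean(al2[[i]] == al2[[j]])) / 4
    if (i == j) {
      # a_ii = 1 + F, F = P(the two alleles of i are IBD)
      A[i, i] <- 1 + mean(al1[[i]] == al2[[i]])
    } else {
      A[i, j] <- A[j, i] <- 2 * f
    }
  }
  A
}

# Closed-form REML for the balanced one-way random-effects layout
# (g groups of size k): between/within mean squares give the REML
# variance estimates, and the restricted likelihood has a closed form.
balanced_oneway_reml <- function(y, group) {
  k <- as.integer(table(group))
  stopifnot(length(unique(k)) == 1L)
  k <- k[1L]
  g <- length(unique(group))
  ybar_i <- tapply(y, group, mean)
  ybar <- mean(y)
  mswithin <- sum((y - ybar_i[group])^2) / (g * (k - 1))
  msbetween <- k * sum((ybar_i - ybar)^2) / (g - 1)
  sigma_e <- mswithin
  sigma_u <- max((msbetween - mswithin) / k, 0)
  list(sigma_u = sigma_u, sigma_e = sigma_e)
}

# small study used by several files (kept tiny so full-ladder tests
# stay fast)
tiny_study <- function(trait = "tarsus", n_quartets = 3, brood = 5,
                       seed = 42, years = c("y1", "y2")) {
  simulate_study(design_config(n_quartets = n_quartets,
                               nestlings_per_nest = brood,
                               years = years),
                 default_study_params(trait), seed = seed)
}

study_A <- function(st, recorded = FALSE) {
  ped <- if (recorded) st$pedigree_recorded else st$pedigree
  relationship_matrix(prune_pedigree(ped, st$phenotypes$id))
}
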