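#' Configuration of the quartet cross-fostering design
#'
#' Describes the field design emulated by the generator: broods matched
#' in quartets of four nests (two young-mother and two old-mother
#' nests), split-brood cross-fostering between age-discordant nest
#' pairs, and brood-size manipulation in which two nests per quartet
#' (one per maternal age class) are enlarged with donor nestlings from
#' nests outside the quartets.
#'
#' @param n_quartets number of quartets (blocks of 4 nests).
#' @param nestlings_per_nest brood size per nest: a single count, a
#'   vector recycled over nests, or a function `f(n_nests)` returning a
#'   vector of counts.
#' @param enlargement_size donor nestlings added to each enlarged nest.
#' @param years labels over which quartets are distributed evenly
#'   (all four nests of a quartet share a year).
#' @param sex_ratio probability that a nestling is male.
#' @param donor_young_fraction probability a donor-nest mother is young
#'   (donor nestlings are excluded from the analysis table either way).
#' @param recruitment_rate probability that an experimental nestling
#'   recruits into the breeding population of a later year.  Recruits
#'   fill parent slots of later-year broods when age and sex permit
#'   (young mothers were born the previous year, old mothers at least
#'   two years back, fathers any earlier year); remaining slots are
#'   filled by fresh founders.  Recruitment creates the cross-cohort
#'   pedigree links that let additive genetic variance be separated
#'   from nest-of-origin variance.
#' @return A list of class `design_config`.
#' @export
design_config <- function(n_quartets = 25,
                          nestlings_per_nest = 10,
                          enlargement_size = 3,
                          years = c("y1", "y2", "y3"),
                          sex_ratio = 0.5,
                          donor_young_fraction = 0.5,
                          recruitment_rate = 0.2) {
  stopifnot(n_quartets >= 1, enlargement_size >= 0,
            sex_ratio >= 0, sex_ratio <= 1, length(years) >= 1,
            recruitment_rate >= 0, recruitment_rate <= 1)
  structure(list(n_quartets = as.integer(n_quartets),
                 nestlings_per_nest = nestlings_per_nest,
                 enlargement_size = as.integer(enlargement_size),
                 years = as.character(years),
                 sex_ratio = sex_ratio,
                 donor_young_fraction = donor_young_fraction,
                 recruitment_rate = recruitment_rate),
            class = "design_config")
}

#' Generating parameters for one trait
#'
#' Fixed effects and variance components used to simulate a trait on
#' the cross-fostered design.  The additive genetic term is governed by
#' a 2x2 covariance matrix G over the two maternal age classes, built
#' from the age-specific variances `V_A1` (young), `V_A2` (old) and the
#' cross-age genetic correlation `r_xage`; a homogeneous genetic effect
#' is the special case `V_A1 == V_A2`, `r_xage == 1`.
#'
#' @param trait trait name (column name in the phenotype table).
#' @param mean trait grand mean (trait units).
#' @param beta_year named numeric: additive year deviations.
#' @param beta_age_old fixed deviation of old-mother offspring.
#' @param beta_manip_enlarged fixed deviation in enlarged broods.
#' @param beta_sex_male fixed deviation of males (0 disables a sex term).
#' @param covariate name of a covariate trait entering the model as a
#'   fixed regression (e.g. body mass for the immune-response model), or
#'   `NULL`.
#' @param beta_covariate slope on the centred covariate.
#' @param V_A1,V_A2 additive genetic variances expressed by offspring of
#'   young / old mothers (trait units squared).
#' @param r_xage cross-age genetic correlation in `[-1, 1]`.
#' @param V_O,V_R,V_Q nest-of-origin, nest-of-rearing and quartet
#'   variances.
#' @param V_E1,V_E2 residual variances for young- / old-mother
#'   offspring (equal for a homogeneous residual).
#' @return A list of class `trait_params`.
#' @export
trait_params <- function(trait, mean = 0, beta_year = NULL,
                         beta_age_old = 0, beta_manip_enlarged = 0,
                         beta_sex_male = 0, covariate = NULL,
                         beta_covariate = 0,
                         V_A1 = 0, V_A2 = V_A1, r_xage = 1,
                         V_O = 0, V_R = 0, V_Q = 0,
                         V_E1 = 0, V_E2 = V_E1) {
  stopifnot(V_A1 >= 0, V_A2 >= 0, abs(r_xage) <= 1,
            V_O >= 0, V_R >= 0, V_Q >= 0, V_E1 >= 0, V_E2 >= 0)
  G <- age_G(V_A1, V_A2, r_xage)
  if (min(eigen(G, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
    stop("trait_params: G matrix built from (V_A1, V_A2, r_xage) ",
         "is not positive semi-definite")
  structure(list(trait = trait, mean = mean, beta_year = beta_year,
                 beta_age_old = beta_age_old,
                 beta_manip_enlarged = beta_manip_enlarged,
                 beta_sex_male = beta_sex_male,
                 covariate = covariate, beta_covariate = beta_covariate,
                 V_A1 = V_A1, V_A2 = V_A2, r_xage = r_xage,
                 V_O = V_O, V_R = V_R, V_Q = V_Q,
                 V_E1 = V_E1, V_E2 = V_E2),
            class = "trait_params")
}

age_G <- function(V_A1, V_A2, r_xage) {
  cv <- r_xage * sqrt(V_A1 * V_A2)
  matrix(c(V_A1, cv, cv, V_A2), 2, 2,
         dimnames = list(c("young", "old"), c("young", "old")))
}

#' Default generating parameters per trait
#'
#' Variance components follow the fitted components reported for a wild
#' blue tit cross-fostering experiment: tarsus length (mm) and body
#' mass (g) with homogeneous additive genetic variance, and PHA wing-web
#' swelling (mm) with maternal age-specific additive genetic variance
#' (young >> old) and cross-age genetic correlation fixed at unity.
#' Fixed-effect sizes are small realistic values; maternal age itself
#' has no mean effect.
#'
#' @param trait one of `"tarsus"`, `"mass"`, `"pha"`.
#' @return A [trait_params] object.
#' @export
default_trait_params <- function(trait = c("tarsus", "mass", "pha")) {
  trait <- match.arg(trait)
  switch(trait,
    tarsus = trait_params("tarsus", mean = 16.17,
                          beta_year = c(y1 = -0.05, y2 = 0, y3 = 0.05),
                          beta_age_old = 0, beta_manip_enlarged = -0.08,
                          beta_sex_male = 0.25,
                          V_A1 = 0.15, V_A2 = 0.15, r_xage = 1,
                          V_O = 0, V_R = 0.11, V_Q = 0, V_E1 = 0.15),
    mass = trait_params("mass", mean = 10.6,
                        beta_year = c(y1 = -0.1, y2 = 0, y3 = 0.1),
                        beta_age_old = 0, beta_manip_enlarged = -0.35,
                        beta_sex_male = 0.2,
                        covariate = "tarsus", beta_covariate = 0.6,
                        V_A1 = 0.28, V_A2 = 0.28, r_xage = 1,
                        V_O = 0, V_R = 0.38, V_Q = 0, V_E1 = 0.29),
    pha = trait_params("pha", mean = 0.78,
                       beta_year = c(y1 = -0.02, y2 = 0.02),
                       beta_age_old = 0, beta_manip_enlarged = 0.02,
                       beta_sex_male = 0,
                       covariate = "mass", beta_covariate = 0.03,
                       V_A1 = 0.06, V_A2 = 0.01, r_xage = 1,
                       V_O = 0, V_R = 0.01, V_Q = 0.001, V_E1 = 0.02))
}

#' Default generating parameters for a trait and its covariate chain
#'
#' Returns the list of [trait_params] needed to simulate `trait`
#' including every covariate it conditions on (mass requires tarsus;
#' PHA requires mass, hence also tarsus), in simulation order.
#'
#' @inheritParams default_trait_params
#' @return Named list of [trait_params].
#' @export
default_study_params <- function(trait = c("tarsus", "mass", "pha")) {
  trait <- match.arg(trait)
  chain <- switch(trait, tarsus = "tarsus",
                  mass = c("tarsus", "mass"),
                  pha = c("tarsus", "mass", "pha"))
  stats::setNames(lapply(chain, default_trait_params), chain)
}

brood_sizes <- function(cfg, n_nests) {
  b <- cfg$nestlings_per_nest
  if (is.function(b)) b <- b(n_nests)
  b <- as.integer(rep_len(b, n_nests))
  if (any(b < 2L)) stop("generate_design: brood size must be >= 2")
  b
}

#' Generate the experimental design skeleton
#'
#' Builds breeding pairs (founders, or recruits from earlier-year
#' broods), quartets, the split-brood cross-fostering assignment and
#' the brood-size manipulation, but no phenotypes.  Within each
#' quartet the two
#' young-mother nests are paired at random with the two old-mother
#' nests; for each nest of a pair, half of the brood (rounded down)
#' moves to the partner nest.  Two nests per quartet -- one per age
#' class -- are enlarged with `enlargement_size` donor nestlings whose
#' nest of origin lies outside the quartet.
#'
#' @param cfg a [design_config].
#' @param seed optional integer seed (sets the R RNG).
#' @return A list of class `study_design` with elements `nests` (one
#'   row per nest: id, mother, father, mother_age, quartet, year,
#'   enlarged), `nestlings` (one row per nestling: id, dam, sire,
#'   maternal_age, sex, nest_of_origin, nest_of_rearing, quartet, year,
#'   manipulation, is_donor) and `pedigree` (a [pedigree] over parents
#'   and nestlings).
#' @export
generate_design <- function(cfg = design_config(), seed = NULL) {
  stopifnot(inherits(cfg, "design_config"))
  if (!is.null(seed)) set.seed(seed)
  nq <- cfg$n_quartets
  qid <- sprintf("Q%02d", seq_len(nq))
  yr_lev <- cfg$years
  qyear <- rep_len(yr_lev, nq)

  nests <- do.call(rbind, lapply(seq_len(nq), function(q) {
    data.frame(nest = sprintf("%s.N%d", qid[q], 1:4),
               mother = sprintf("%s.N%d.F", qid[q], 1:4),
               father = sprintf("%s.N%d.M", qid[q], 1:4),
               mother_age = c("young", "young", "old", "old"),
               quartet = qid[q], year = qyear[q],
               stringsAsFactors = FALSE)
  }))
  # one enlarged nest per age class per quartet
  nests$enlarged <- FALSE
  for (q in qid) {
    iy <- which(nests$quartet == q & nests$mother_age == "young")
    io <- which(nests$quartet == q & nests$mother_age == "old")
    nests$enlarged[c(sample(iy, 1L), sample(io, 1L))] <- TRUE
  }

  b <- brood_sizes(cfg, nrow(nests))
  # process years in order so later-year parents can be recruits from
  # earlier experimental broods (cross-cohort pedigree links)
  nestlings <- NULL
  pool <- data.frame(id = character(0), sex = character(0),
                     natal = character(0), cohort = integer(0),
                     stringsAsFactors = FALSE)
  for (yi in seq_along(yr_lev)) {
    rows <- which(nests$year == yr_lev[yi])
    if (!length(rows)) next
    for (i in rows) {
      ne <- nests[i, ]
      # mother: young mothers were born the previous year, old mothers
      # at least two years back
      coh_ok <- if (ne$mother_age == "young") yi - 1L else
        seq_len(max(yi - 2L, 0L))
      cand <- which(pool$sex == "female" & pool$cohort %in% coh_ok)
      if (length(cand)) {
        pick <- if (length(cand) == 1L) cand else sample(cand, 1L)
        nests$mother[i] <- pool$id[pick]
        mother_natal <- pool$natal[pick]
        pool <- pool[-pick, , drop = FALSE]
      } else mother_natal <- NA_character_
      cand <- which(pool$sex == "male" & pool$cohort < yi &
                      (is.na(mother_natal) | pool$natal != mother_natal))
      if (length(cand)) {
        pick <- if (length(cand) == 1L) cand else sample(cand, 1L)
        nests$father[i] <- pool$id[pick]
        pool <- pool[-pick, , drop = FALSE]
      }
      chicks <- data.frame(
        id = sprintf("%s.C%02d", ne$nest, seq_len(b[i])),
        dam = nests$mother[i], sire = nests$father[i],
        maternal_age = ne$mother_age,
        sex = ifelse(stats::runif(b[i]) < cfg$sex_ratio,
                     "male", "female"),
        nest_of_origin = ne$nest, nest_of_rearing = ne$nest,
        quartet = ne$quartet, year = ne$year,
        is_donor = FALSE, stringsAsFactors = FALSE)
      nestlings <- rbind(nestlings, chicks)
      # each nestling recruits into the breeding pool with the
      # population recruitment probability
      rec <- stats::runif(b[i]) < cfg$recruitment_rate
      if (any(rec))
        pool <- rbind(pool,
                      data.frame(id = chicks$id[rec],
                                 sex = chicks$sex[rec],
                                 natal = ne$nest, cohort = yi,
                                 stringsAsFactors = FALSE))
    }
  }

  # split-brood cross-fostering within random young-old nest pairs
  for (q in qid) {
    ny <- sample(nests$nest[nests$quartet == q &
                              nests$mother_age == "young"])
    no <- sample(nests$nest[nests$quartet == q &
                              nests$mother_age == "old"])
    for (p in 1:2) {
      pair <- c(ny[p], no[p])
      for (k in 1:2) {
        from <- pair[k]; to <- pair[3L - k]
        idx <- which(nestlings$nest_of_origin == from)
        mv <- sample(idx, floor(length(idx) / 2))
        nestlings$nest_of_rearing[mv] <- to
      }
    }
  }

  # donor nestlings for the brood-size manipulation
  donors <- NULL
  enl <- nests$nest[nests$enlarged]
  if (cfg$enlargement_size > 0L && length(enl)) {
    donors <- do.call(rbind, lapply(seq_along(enl), function(j) {
      target <- enl[j]
      dn <- sprintf("D%02d", j)
      q <- nests$quartet[nests$nest == target]
      age <- if (stats::runif(1) < cfg$donor_young_fraction)
        "young" else "old"
      data.frame(id = sprintf("%s.C%02d", dn, seq_len(cfg$enlargement_size)),
                 dam = paste0(dn, ".F"), sire = paste0(dn, ".M"),
                 maternal_age = age,
                 sex = ifelse(stats::runif(cfg$enlargement_size) <
                                cfg$sex_ratio, "male", "female"),
                 nest_of_origin = dn, nest_of_rearing = target,
                 quartet = q,
                 year = nests$year[nests$nest == target],
                 is_donor = TRUE, stringsAsFactors = FALSE)
    }))
    nestlings <- rbind(nestlings, donors)
  }

  nestlings$manipulation <-
    ifelse(nestlings$nest_of_rearing %in% enl, "enlarged", "control")
  ped <- pedigree(nestlings$id, nestlings$dam, nestlings$sire)
  structure(list(config = cfg, nests = nests, nestlings = nestlings,
                 pedigree = ped),
            class = "study_design")
}

#' Simulate age-specific breeding values over a pedigree
#'
#' Draws the stacked vector of (young-expressed, old-expressed)
#' breeding values for all pedigree members from a zero-mean
#' multivariate normal with covariance \eqn{G \otimes A}, realised as
#' \eqn{L_A Z L_G'} with `L_A`, `L_G` Cholesky factors of the
#' relationship matrix and of the 2x2 age covariance matrix and `Z` an
#' iid standard normal matrix.
#'
#' @param ped a [pedigree].
#' @param params a [trait_params] (supplies `V_A1`, `V_A2`, `r_xage`).
#' @param A optional precomputed relationship matrix for `ped`.
#' @return Numeric matrix (individuals x 2) with columns `young`,
#'   `old` and rownames `ped$id`.
#' @export
simulate_breeding_values <- function(ped, params, A = NULL) {
  stopifnot(inherits(ped, "pedigree"), inherits(params, "trait_params"))
  if (is.null(A)) A <- relationship_matrix(ped)
  G <- age_G(params$V_A1, params$V_A2, params$r_xage)
  n <- nrow(A)
  LA <- t(chol(A + diag(1e-10, n)))
  eg <- eigen(G, symmetric = TRUE)
  LG <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), 2) %*% t(eg$vectors)
  Z <- matrix(stats::rnorm(2 * n), n, 2)
  bv <- LA %*% Z %*% LG
  dimnames(bv) <- list(ped$id, c("young", "old"))
  bv
}

#' Simulate phenotypes on a generated design
#'
#' Adds, for one trait, fixed effects plus the expressed breeding value
#' (the young column for offspring of young genetic mothers, old
#' otherwise), iid nest-of-origin, nest-of-rearing and quartet effects,
#' and a residual whose variance may differ between maternal age
#' classes.  If the trait declares a covariate, that column must
#' already exist in `pheno` and enters centred.
#'
#' @param design a `study_design` from [generate_design()].
#' @param params a [trait_params].
#' @param bv breeding-value matrix from [simulate_breeding_values()].
#' @param pheno data frame of nestling rows being built up (used for
#'   covariate lookup); defaults to `design$nestlings`.
#' @return `pheno` with a new trait column, plus attributes recording
#'   the simulated nest/quartet effects.
#' @export
simulate_phenotypes <- function(design, params, bv,
                                pheno = design$nestlings) {
  stopifnot(inherits(design, "study_design"),
            inherits(params, "trait_params"))
  n <- nrow(pheno)
  old <- pheno$maternal_age == "old"
  a <- ifelse(old, bv[pheno$id, "old"], bv[pheno$id, "young"])

  o_lev <- unique(pheno$nest_of_origin)
  r_lev <- unique(pheno$nest_of_rearing)
  q_lev <- unique(pheno$quartet)
  o_eff <- stats::setNames(stats::rnorm(length(o_lev), 0,
                                        sqrt(params$V_O)), o_lev)
  r_eff <- stats::setNames(stats::rnorm(length(r_lev), 0,
                                        sqrt(params$V_R)), r_lev)
  q_eff <- stats::setNames(stats::rnorm(length(q_lev), 0,
                                        sqrt(params$V_Q)), q_lev)
  e <- stats::rnorm(n, 0, ifelse(old, sqrt(params$V_E2),
                                 sqrt(params$V_E1)))

  mu <- rep(params$mean, n)
  if (!is.null(params$beta_year)) {
    by <- params$beta_year[pheno$year]
    by[is.na(by)] <- 0
    mu <- mu + by
  }
  mu <- mu + params$beta_age_old * old +
    params$beta_manip_enlarged * (pheno$manipulation == "enlarged") +
    params$beta_sex_male * (pheno$sex == "male")
  if (!is.null(params$covariate)) {
    cv <- pheno[[params$covariate]]
    if (is.null(cv))
      stop("simulate_phenotypes: covariate '", params$covariate,
           "' not yet simulated")
    mu <- mu + params$beta_covariate * (cv - mean(cv))
  }
  pheno[[params$trait]] <- as.numeric(mu + a + o_eff[pheno$nest_of_origin] +
    r_eff[pheno$nest_of_rearing] + q_eff[pheno$quartet] + e)
  attr(pheno, paste0("effects_", params$trait)) <-
    list(origin = o_eff, rearing = r_eff, quartet = q_eff)
  pheno
}

#' Simulate a complete cross-fostering study
#'
#' Runs [generate_design()], draws breeding values for each requested
#' trait from its age-structured G (x) A covariance, and simulates
#' phenotypes.  Traits are simulated in an order that respects
#' covariate dependencies (a trait's covariate is simulated first).
#' Donor nestlings are generated (they exist in the pedigree and in the
#' rearing nests) but excluded from the analysis phenotype table.
#'
#' @param cfg a [design_config].
#' @param params a [trait_params] or list of them.
#' @param seed optional integer seed; the whole study is a
#'   deterministic function of `(cfg, params, seed)`.
#' @return A list of class `study`: `pedigree` (true), `pedigree_recorded`
#'   (equal to `pedigree` until EPP corruption), `phenotypes` (analysis
#'   table, donors excluded), `design`, `truth` (generating params and
#'   breeding values per trait), `epp_log` (empty data frame).
#' @examples
#' st <- simulate_study(design_config(n_quartets = 2, nestlings_per_nest = 6),
#'                      default_trait_params("tarsus"), seed = 1)
#' nrow(st$phenotypes)  # 2 quartets x 4 nests x 6 nestlings
#' @export
simulate_study <- function(cfg = design_config(),
                           params = default_trait_params("tarsus"),
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (inherits(params, "trait_params")) params <- list(params)
  names(params) <- vapply(params, `[[`, "", "trait")

  # order traits so covariates are simulated before their dependants
  order_traits <- function(ps) {
    done <- character(0)
    while (length(done) < length(ps)) {
      ready <- vapply(ps, function(p)
        !(p$trait %in% done) &&
          (is.null(p$covariate) || p$covariate %in% done ||
             !(p$covariate %in% names(ps))), logical(1))
      if (!any(ready)) stop("simulate_study: circular covariate chain")
      done <- c(done, names(ps)[ready])
    }
    done
  }

  design <- generate_design(cfg)
  ped <- design$pedigree
  A <- relationship_matrix(ped)
  pheno <- design$nestlings
  truth <- list(params = params, breeding_values = list())
  for (tr in order_traits(params)) {
    p <- params[[tr]]
    if (!is.null(p$covariate) && is.null(pheno[[p$covariate]]))
      stop("simulate_study: covariate '", p$covariate, "' of trait '",
           tr, "' has no trait_params and is not simulated")
    bv <- simulate_breeding_values(ped, p, A = A)
    pheno <- simulate_phenotypes(design, p, bv, pheno)
    truth$breeding_values[[tr]] <- bv
  }
  analysis <- pheno[!pheno$is_donor, , drop = FALSE]
  rownames(analysis) <- NULL
  structure(list(pedigree = ped, pedigree_recorded = ped,
                 phenotypes = analysis, design = design, truth = truth,
                 epp_log = data.frame(offspring = character(0),
                                      recorded_sire = character(0),
                                      true_sire = character(0))),
            class = "study")
}

#' @export
print.study <- function(x, ...) {
  cat("Cross-fostering study:", x$design$config$n_quartets, "quartets,",
      nrow(x$phenotypes), "experimental nestlings,",
      nrow(x$pedigree), "pedigree members\n")
  cat("Traits:", paste(names(x$truth$params), collapse = ", "), "\n")
  if (nrow(x$epp_log))
    cat("EPP-corrupted recorded pedigree:", nrow(x$epp_log),
        "substituted sires\n")
  invisible(x)
}

#' Corrupt the recorded pedigree with extra-pair paternity
#'
#' For each experimental breeding nest, with probability
#' `nest_epp_rate`, one randomly chosen nestling of that nest has its
#' *recorded* sire replaced by a different breeding male drawn at
#' random.  The true pedigree (and hence the simulated breeding
#' values) is untouched; only `pedigree_recorded` changes, so fitting
#' against it emulates field data with misassigned paternities.  The
#' expected offspring-level prevalence is roughly
#' `nest_epp_rate / brood_size`.
#'
#' @param study a `study` from [simulate_study()].
#' @param nest_epp_rate probability that a nest contains one extra-pair
#'   young (default 0.20).
#' @param seed optional integer seed.
#' @return The study with `pedigree_recorded` rebuilt and `epp_log`
#'   listing every substitution.
#' @export
inject_extra_pair_paternity <- function(study, nest_epp_rate = 0.20,
                                        seed = NULL) {
  stopifnot(inherits(study, "study"),
            nest_epp_rate >= 0, nest_epp_rate <= 1)
  if (!is.null(seed)) set.seed(seed)
  ph <- study$phenotypes
  nests <- unique(ph$nest_of_origin)
  males <- unique(ph$sire)
  ped <- study$pedigree
  rec_sire <- stats::setNames(ped$sire, ped$id)
  log_rows <- list()
  descendants <- function(id0) {
    # forward closure: recruits can appear as parents, so a random
    # replacement sire must not descend from the victim
    out <- id0
    repeat {
      kids <- ped$id[(!is.na(ped$dam) & ped$dam %in% out) |
                       (!is.na(ped$sire) & ped$sire %in% out)]
      kids <- setdiff(kids, out)
      if (!length(kids)) return(out)
      out <- c(out, kids)
    }
  }
  for (ne in nests) {
    if (stats::runif(1) >= nest_epp_rate) next
    ids <- ph$id[ph$nest_of_origin == ne]
    victim <- if (length(ids) == 1L) ids else sample(ids, 1L)
    true_sire <- rec_sire[[victim]]
    other <- setdiff(males, c(true_sire, descendants(victim)))
    if (!length(other)) next
    new_sire <- if (length(other) == 1L) other else sample(other, 1L)
    rec_sire[[victim]] <- new_sire
    log_rows[[length(log_rows) + 1L]] <-
      data.frame(offspring = victim, recorded_sire = new_sire,
                 true_sire = true_sire, stringsAsFactors = FALSE)
  }
  study$pedigree_recorded <- pedigree(ped$id, ped$dam,
                                      unname(rec_sire[ped$id]))
  study$epp_log <- if (length(log_rows)) do.call(rbind, log_rows) else
    study$epp_log
  study
}

#' Write a study to disk as plain-text files
#'
#' Writes `pedigree.csv` (the recorded pedigree), `phenotypes.csv` and
#' `truth.json` (generating parameters and the EPP log) to `dir`.
#'
#' @param study a `study`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(study$pedigree_recorded),
                   file.path(dir, "pedigree.csv"), row.names = FALSE,
                   quote = FALSE, na = "")
  utils::write.csv(study$phenotypes, file.path(dir, "phenotypes.csv"),
                   row.names = FALSE, quote = FALSE, na = "")
  truth <- lapply(study$truth$params, function(p)
    p[!vapply(p, is.null, logical(1))])
  jsonlite::write_json(list(params = truth,
                            epp_log = study$epp_log),
                       file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
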