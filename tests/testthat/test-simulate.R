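test_that("generated designs obey the quartet and manipulation rules", {
  cfg <- design_config(n_quartets = 4, nestlings_per_nest = 6,
                       years = c("y1", "y2"))
  d <- generate_design(cfg, seed = 1)
  # 2 young + 2 old nests per quartet; exactly 2 enlarged, one per class
  for (q in unique(d$nests$quartet)) {
    nq <- d$nests[d$nests$quartet == q, ]
    expect_equal(sort(nq$mother_age), c("old", "old", "young", "young"))
    expect_equal(sum(nq$enlarged), 2)
    expect_equal(sort(nq$mother_age[nq$enlarged]), c("old", "young"))
  }
  exp_chicks <- d$nestlings[!d$nestlings$is_donor, ]
  expect_equal(nrow(exp_chicks), 4 * 4 * 6)
  # donors: 3 per enlarged nest, origin outside the quartet
  don <- d$nestlings[d$nestlings$is_donor, ]
  expect_equal(nrow(don), 4 * 2 * 3)
  expect_false(any(don$nest_of_origin %in% d$nests$nest))
  expect_true(all(don$nest_of_rearing %in%
                    d$nests$nest[d$nests$enlarged]))
  # manipulation labels follow the rearing nest
  expect_equal(exp_chicks$manipulation,
               ifelse(exp_chicks$nest_of_rearing %in%
                        d$nests$nest[d$nests$enlarged],
                      "enlarged", "control"))
})

test_that("split-brood cross-fostering moves half of each brood within quartets", {
  for (brood in c(5, 6, 9)) {
    st <- tiny_study(n_quartets = 3, brood = brood, seed = brood)
    ph <- st$phenotypes
    for (ne in unique(ph$nest_of_origin)) {
      rows <- ph[ph$nest_of_origin == ne, ]
      moved <- sum(rows$nest_of_origin != rows$nest_of_rearing)
      expect_equal(moved, floor(brood / 2))
      # rearing stays inside the quartet, in an age-discordant nest
      expect_equal(unique(rows$quartet),
                   unique(ph$quartet[ph$nest_of_rearing %in%
                                       rows$nest_of_rearing]))
    }
    # every moved chick is reared by the opposite maternal age class
    d <- st$design
    rear_age <- d$nests$mother_age[match(ph$nest_of_rearing,
                                         d$nests$nest)]
    moved <- ph$nest_of_origin != ph$nest_of_rearing
    expect_true(all(ph$maternal_age[moved] != rear_age[moved]))
    expect_true(all(ph$maternal_age[!moved] == rear_age[!moved]))
  }
})

test_that("a 25-quartet design reaches the target study size", {
  cfg <- design_config(n_quartets = 25, nestlings_per_nest = 11)
  d <- generate_design(cfg, seed = 2)
  n_exp <- sum(!d$nestlings$is_donor)
  expect_equal(n_exp, 1100)  # ~1,092 experimental nestlings
})

test_that("studies are byte-identical under the same seed", {
  cfg <- design_config(n_quartets = 2, nestlings_per_nest = 5,
                       years = "y1")
  p <- default_study_params("tarsus")
  s1 <- simulate_study(cfg, p, seed = 10)
  s2 <- simulate_study(cfg, p, seed = 10)
  expect_identical(s1$phenotypes, s2$phenotypes)
  expect_identical(as.data.frame(s1$pedigree),
                   as.data.frame(s2$pedigree))
  s3 <- simulate_study(cfg, p, seed = 11)
  expect_false(identical(s1$phenotypes$tarsus, s3$phenotypes$tarsus))
})

test_that("breeding values follow the G (x) A covariance", {
  # rank-1 G with equal variances: both columns identical
  ped <- trio()
  p1 <- trait_params("t", V_A1 = 0.4, V_A2 = 0.4, r_xage = 1)
  set.seed(1)
  bv <- simulate_breeding_values(ped, p1)
  expect_equal(bv[, "young"], bv[, "old"], tolerance = 1e-6)

  # founder replicates: empirical covariance of (a_young, a_old) -> G
  n <- 4000
  pedf <- pedigree(id = paste0("f", seq_len(n)))
  p2 <- trait_params("t", V_A1 = 0.5, V_A2 = 0.2, r_xage = 0.6)
  set.seed(2)
  bv2 <- simulate_breeding_values(pedf, p2)
  emp <- stats::cov(bv2)
  G <- matrix(c(0.5, 0.6 * sqrt(0.1), 0.6 * sqrt(0.1), 0.2), 2)
  expect_equal(unname(emp), G, tolerance = 0.12)

  # full sibs: covariance of expressed values = G/2 across age classes
  nfam <- 3000
  ped2 <- pedigree(id = c(sprintf("c%da", 1:nfam), sprintf("c%db", 1:nfam)),
                   dam = rep(sprintf("m%d", 1:nfam), 2),
                   sire = rep(sprintf("p%d", 1:nfam), 2))
  set.seed(3)
  bv3 <- simulate_breeding_values(ped2, p2)
  a1 <- bv3[sprintf("c%da", 1:nfam), "young"]
  a2 <- bv3[sprintf("c%db", 1:nfam), "old"]
  # 3 Monte-Carlo SEs of a covariance estimate at this n is ~0.018
  expect_lt(abs(stats::cov(a1, a2) - G[1, 2] / 2), 0.02)

  expect_error(trait_params("t", V_A1 = 1, r_xage = 2))
})

test_that("phenotypes decompose into the generating components", {
  cfg <- design_config(n_quartets = 3, nestlings_per_nest = 6)
  # all variances and effects zero -> all phenotypes equal the mean
  p0 <- trait_params("flat", mean = 5)
  st0 <- simulate_study(cfg, p0, seed = 4)
  expect_equal(st0$phenotypes$flat, rep(5, nrow(st0$phenotypes)))

  # law of total variance at large n: sample variance ~ sum of
  # components (fixed effects all zero)
  cfg_big <- design_config(n_quartets = 120, nestlings_per_nest = 10,
                           years = "y1")
  pv <- trait_params("t", mean = 0, V_A1 = 0.3, V_A2 = 0.3,
                     r_xage = 1, V_O = 0.2, V_R = 0.25, V_Q = 0.1,
                     V_E1 = 0.15)
  stv <- simulate_study(cfg_big, pv, seed = 5)
  tot <- 0.3 + 0.2 + 0.25 + 0.1 + 0.15
  expect_equal(stats::var(stv$phenotypes$t), tot, tolerance = 0.12)

  # age-specific G: young-mother offspring show larger total variance
  pg <- default_trait_params("pha")
  pg$covariate <- NULL
  stg <- simulate_study(design_config(n_quartets = 60,
                                      nestlings_per_nest = 8,
                                      years = c("y1", "y2")),
                        pg, seed = 6)
  vy <- stats::var(stg$phenotypes$pha[stg$phenotypes$maternal_age ==
                                        "young"])
  vo <- stats::var(stg$phenotypes$pha[stg$phenotypes$maternal_age ==
                                        "old"])
  expect_gt(vy, vo)
})

test_that("maternal age is balanced across rearing environments", {
  # genetic mother's age class is independent of the rearing nest's
  # class by construction of the split-brood design
  st <- tiny_study(n_quartets = 20, brood = 8, seed = 12)
  ph <- st$phenotypes
  d <- st$design
  rear_age <- d$nests$mother_age[match(ph$nest_of_rearing,
                                       d$nests$nest)]
  tab <- table(ph$maternal_age, rear_age)
  p <- suppressWarnings(stats::chisq.test(tab)$p.value)
  # halves split evenly, so counts are near-identical by design
  expect_gt(p, 1e-3)
  expect_lt(abs(tab["young", "young"] - tab["young", "old"]), 2)
})

test_that("extra-pair paternity corrupts only the recorded pedigree", {
  st <- tiny_study(n_quartets = 6, brood = 6, seed = 21)
  st0 <- inject_extra_pair_paternity(st, nest_epp_rate = 0, seed = 1)
  expect_identical(as.data.frame(st0$pedigree_recorded),
                   as.data.frame(st0$pedigree))
  expect_equal(nrow(st0$epp_log), 0)

  st1 <- inject_extra_pair_paternity(st, nest_epp_rate = 1, seed = 1)
  # every nest affected once: one mismatch per origin nest
  n_nests <- length(unique(st$phenotypes$nest_of_origin))
  expect_equal(nrow(st1$epp_log), n_nests)
  rec <- stats::setNames(st1$pedigree_recorded$sire,
                         st1$pedigree_recorded$id)
  tru <- stats::setNames(st1$pedigree$sire, st1$pedigree$id)
  mismatch <- names(tru)[!is.na(tru) & !is.na(rec[names(tru)]) &
                           rec[names(tru)] != tru]
  expect_setequal(mismatch, st1$epp_log$offspring)
  expect_equal(st1$epp_log$true_sire,
               unname(tru[st1$epp_log$offspring]))
  # true pedigree untouched
  expect_identical(as.data.frame(st1$pedigree),
                   as.data.frame(st$pedigree))

  # rate 0.2 on many nests: offspring prevalence ~ rate / brood size
  st2 <- tiny_study(n_quartets = 25, brood = 10, seed = 22)
  st2 <- inject_extra_pair_paternity(st2, nest_epp_rate = 0.2,
                                     seed = 2)
  prev <- nrow(st2$epp_log) / nrow(st2$phenotypes)
  expect_gt(prev, 0.005)
  expect_lt(prev, 0.05)
})

test_that("study files round-trip through disk", {
  st <- tiny_study(n_quartets = 2, brood = 5, seed = 31)
  dir <- tempfile()
  write_study(st, dir)
  expect_true(all(file.exists(file.path(dir,
    c("pedigree.csv", "phenotypes.csv", "truth.json")))))
  ped <- read_pedigree(file.path(dir, "pedigree.csv"))
  expect_setequal(ped$id, st$pedigree$id)
  ph <- utils::read.csv(file.path(dir, "phenotypes.csv"))
  expect_equal(nrow(ph), nrow(st$phenotypes))
  expect_equal(ph$tarsus, st$phenotypes$tarsus, tolerance = 1e-12)
})
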