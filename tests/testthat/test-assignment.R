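comps <- naf_compartments()

sep_markers <- marker_profiles(  # strongly separated, ordered enrichment
  plastid = c(60, 25, 10, 5), cytosol = c(15, 50, 25, 10),
  vacuole = c(5, 10, 25, 60))

test_that("pairwise slopes enumerate all detected fraction pairs", {
  s <- pairwise_slopes(normalize_profile(c(25, 25, 25, 25)))
  expect_equal(nrow(s), 6)
  expect_true(all(s$delta == 0))

  s <- pairwise_slopes(normalize_profile(c(10, 20, 30, 40)))
  got <- setNames(s$delta, paste(s$i, s$j))
  expect_equal(got, c("1 2" = 10, "1 3" = 20, "1 4" = 30,
                      "2 3" = 10, "2 4" = 20, "3 4" = 10))

  expect_equal(nrow(pairwise_slopes(normalize_profile(runif(6) + 1))), 15)

  # pairs built over detected fractions only
  s <- pairwise_slopes(normalize_profile(c(30, NA, 50, 20)))
  expect_equal(nrow(s), 3)
  expect_setequal(paste(s$i, s$j), c("1 3", "1 4", "3 4"))

  # < 2 detected routes to the single-fraction special case
  s <- pairwise_slopes(normalize_profile(c(NA, 4, NA)))
  expect_equal(nrow(s), 0)
  expect_equal(attr(s, "single_fraction"), 2L)
})

test_that("psi distances are absolute slope differences per compartment", {
  met <- pairwise_slopes(normalize_profile(c(30, NA, 50, 20)))
  mks <- lapply(sep_markers, pairwise_slopes)
  psi <- psi_distances(met, mks)
  expect_equal(nrow(psi), 3)
  for (cc in comps) expect_true(all(psi[[cc]] >= 0))
  # direct |a - b| spot check on pair (1, 3)
  r <- which(psi$i == 1 & psi$j == 3)
  expect_equal(psi$plastid[r], abs(met$delta[met$i == 1 & met$j == 3] -
                                     (10 - 60)))

  # identical profiles give zero distance everywhere
  met2 <- pairwise_slopes(sep_markers$plastid)
  psi2 <- psi_distances(met2, mks)
  expect_true(all(psi2$plastid == 0))

  # missing pair in a marker set is an internal consistency error
  broken <- mks
  broken$cytosol <- broken$cytosol[-1, ]
  expect_error(psi_distances(met2, broken), "missing fraction pair")

  # orientation symmetry: reversing the fraction axis leaves psi unchanged
  met_r <- pairwise_slopes(normalize_profile(rev(c(30, NA, 50, 20))))
  mks_r <- lapply(sep_markers, function(p)
    pairwise_slopes(normalize_profile(rev(p$percents))))
  psi_r <- psi_distances(met_r, mks_r)
  for (cc in comps) expect_equal(sort(psi_r[[cc]]), sort(psi[[cc]]))
})

test_that("per-pair hits follow the minimum + strict multi-bound rule", {
  cfg <- algorithm_config()
  expect_equal(assign_pair_hits(c(plastid = 2, cytosol = 9, vacuole = 20), cfg),
               c(plastid = 3, cytosol = 2, vacuole = 0))
  # full tie: every compartment is minimal
  expect_equal(assign_pair_hits(c(plastid = 4, cytosol = 4, vacuole = 4), cfg),
               c(plastid = 3, cytosol = 3, vacuole = 3))
  # strict boundaries: 5 - 0 < 5 is false, 10 - 0 < 10 is false
  expect_equal(assign_pair_hits(c(plastid = 0, cytosol = 5, vacuole = 10), cfg),
               c(plastid = 3, cytosol = 2, vacuole = 0))
  # non-strict variant flips exactly the boundary cases
  cfg_le <- algorithm_config(strict_inequality = FALSE)
  expect_equal(assign_pair_hits(c(plastid = 0, cytosol = 5, vacuole = 10),
                                cfg_le),
               c(plastid = 3, cytosol = 3, vacuole = 1))
  # min-plus-bounds adds one separate hit for the (first) arg-min
  cfg_mpb <- algorithm_config(scheme = "min-plus-bounds")
  expect_equal(assign_pair_hits(c(plastid = 4, cytosol = 4, vacuole = 4),
                                cfg_mpb),
               c(plastid = 4, cytosol = 3, vacuole = 3))
  expect_error(assign_pair_hits(c(plastid = -1, cytosol = 0, vacuole = 0),
                                cfg),
               "non-negative")
})

test_that("arg-min dominance and bound monotonicity hold on random psi", {
  set.seed(42)
  for (k in 1:100) {
    psi <- setNames(runif(3, 0, 30), comps)
    hits <- assign_pair_hits(psi, algorithm_config())
    expect_equal(unname(hits[which.min(psi)]), 3)  # minimum dominance
    expect_true(all(hits >= 0 & hits <= 3))
    # enlarging a bound never decreases any count
    grown <- assign_pair_hits(psi, algorithm_config(bounds = c(5, 9, 14)))
    expect_true(all(grown >= hits))
    wider <- assign_pair_hits(psi, algorithm_config(bounds = c(5, 7.5, 10, 12)))
    expect_true(all(wider >= hits))
  }
})

test_that("single-fraction special case follows the highest marker", {
  mk <- marker_profiles(plastid = c(10, 40, 50), cytosol = c(40, 30, 30),
                        vacuole = c(50, 30, 20))
  hits <- single_fraction_hits(3, mk, algorithm_config())
  expect_equal(hits, c(plastid = 3, cytosol = 0, vacuole = 0))

  tied <- marker_profiles(plastid = c(40, 30, 30), cytosol = c(40, 30, 30),
                          vacuole = c(20, 40, 40))
  expect_equal(single_fraction_hits(1, tied, algorithm_config()),
               c(plastid = 3, cytosol = 3, vacuole = 0))
  expect_equal(single_fraction_hits(
    1, tied, algorithm_config(tie_policy = "split")),
    c(plastid = 1.5, cytosol = 1.5, vacuole = 0))

  all_tied <- marker_profiles(plastid = c(50, 50), cytosol = c(50, 50),
                              vacuole = c(50, 50))
  d <- metabolite_distribution(normalize_profile(c(NA, 7), "m"), all_tied)
  expect_equal(unname(d$percents), rep(100 / 3, 3))
  expect_true(d$single_fraction)
})

test_that("metabolite distributions normalize hits to percents", {
  # profile identical to the plastid marker, markers far apart -> 100/0/0
  d <- metabolite_distribution(sep_markers$plastid, sep_markers)
  expect_equal(unname(d$percents), c(100, 0, 0))

  # identical marker profiles -> full tie on every pair
  tie <- marker_profiles(plastid = c(40, 30, 20, 10),
                         cytosol = c(40, 30, 20, 10),
                         vacuole = c(40, 30, 20, 10))
  d <- metabolite_distribution(normalize_profile(c(1, 5, 2, 8), "m"), tie)
  expect_equal(unname(d$percents), rep(100 / 3, 3), tolerance = 1e-12)

  # single detected pair engineered to psi = {2, 9, 20} -> hits 3/2/0 -> 60/40/0
  mk <- marker_profiles(plastid = c(26, 24, 25, 25),
                        cytosol = c(17, 26, 28, 29),
                        vacuole = c(15, 35, 25, 25))
  d <- metabolite_distribution(normalize_profile(c(5, 5, NA, NA), "m"), mk)
  expect_equal(d$pair_count, 1)
  expect_equal(unname(d$hits), c(3, 2, 0))
  expect_equal(unname(d$percents), c(60, 40, 0))

  expect_error(metabolite_distribution(normalize_profile(c(1, 2), "m"),
                                       sep_markers),
               "fraction axis")
})

test_that("hit tables equal the brute-force oracle on random instances", {
  set.seed(1234)
  for (k in 1:60) {
    f <- sample(3:6, 1)
    mkp <- random_marker_percents(f)
    mk <- marker_profiles(lapply(mkp, identity))
    raw <- random_raw_profile(f)
    d <- metabolite_distribution(normalize_profile(raw, "m"), mk)
    expect_equal(d$hits, oracle_hit_table(raw, mkp))
  }
})

test_that("compartment label permutations permute the output identically", {
  set.seed(77)
  for (k in 1:20) {
    f <- 5
    mkp <- random_marker_percents(f)
    raw <- random_raw_profile(f, allow_na = FALSE)
    base <- metabolite_distribution(
      normalize_profile(raw, "m"), marker_profiles(mkp))
    perm <- sample(comps)
    permuted <- mkp
    names(permuted) <- comps[match(names(mkp), perm)]
    d <- metabolite_distribution(
      normalize_profile(raw, "m"), marker_profiles(permuted))
    for (cc in comps) {
      expect_equal(unname(d$percents[comps[match(cc, perm)]]),
                   unname(base$percents[cc]))
    }
  }
})

test_that("replicate aggregation reports mean and n-1 standard deviation", {
  r1 <- c(plastid = 60, cytosol = 40, vacuole = 0)
  r2 <- c(plastid = 40, cytosol = 60, vacuole = 0)
  agg <- aggregate_replicates(list(r1, r2))
  expect_equal(unname(agg$mean), c(50, 50, 0))
  expect_equal(unname(agg$sd), c(sqrt(200), sqrt(200), 0))  # 14.142...
  expect_equal(sum(agg$mean), 100, tolerance = 1e-12)

  agg <- aggregate_replicates(list(r1, r1, r1))
  expect_equal(unname(agg$sd), c(0, 0, 0))

  agg <- aggregate_replicates(list(r1))
  expect_true(agg$single_replicate)
  expect_equal(unname(agg$sd), c(0, 0, 0))
})

test_that("absolute levels scale by whole-tissue means with propagated SD", {
  rel <- list(metabolite_id = "m",
              mean = c(plastid = 50, cytosol = 50, vacuole = 0),
              sd = c(plastid = 0, cytosol = 0, vacuole = 0))
  ab <- absolute_subcellular_levels(rel, 10, 0)
  expect_equal(unname(ab$level), c(5, 5, 0))
  expect_equal(unname(ab$sd), c(0, 0, 0))
  expect_equal(sum(ab$level), 10, tolerance = 1e-12)

  rel <- list(metabolite_id = "m",
              mean = c(plastid = 100, cytosol = 0, vacuole = 0),
              sd = c(plastid = 0, cytosol = 0, vacuole = 0))
  ab <- absolute_subcellular_levels(rel, 7.3, 1.1)
  expect_equal(unname(ab$level), c(7.3, 0, 0))
  expect_equal(unname(ab$sd), c(1.1, 0, 0))

  rel <- list(metabolite_id = "m",
              mean = c(plastid = 60, cytosol = 40, vacuole = 0),
              sd = c(plastid = 6, cytosol = 4, vacuole = 0))
  ab <- absolute_subcellular_levels(rel, 10, 1)
  expect_equal(unname(ab$level), c(6, 4, 0))
  expect_equal(unname(ab$sd), c(6 * sqrt(0.02), 4 * sqrt(0.02), 0))

  expect_error(absolute_subcellular_levels(rel, NA), "positive")
})

test_that("experiment-level assignment conserves totals", {
  sim <- generate_experiment(synthetic_config(n_metabolites = 6,
                                              n_conditions = 2, seed = 5))
  a <- assign_experiment(sim$experiment, whole_tissue = sim$whole_tissue)
  # every relative distribution sums to 100
  for (key in unique(paste(a$summary$condition, a$summary$metabolite))) {
    sub <- a$summary[paste(a$summary$condition, a$summary$metabolite) == key, ]
    expect_equal(sum(sub$mean), 100, tolerance = 1e-9)
    wt <- sim$whole_tissue[paste(sim$whole_tissue$condition,
                                 sim$whole_tissue$analyte_id) == key, ]
    expect_equal(sum(sub$abs_level), wt$mean, tolerance = 1e-9)
  }
  pr <- a$per_replicate
  for (key in unique(paste(pr$condition, pr$replicate, pr$metabolite))) {
    sub <- pr[paste(pr$condition, pr$replicate, pr$metabolite) == key, ]
    expect_equal(sum(sub$percent), 100, tolerance = 1e-9)
  }
})
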