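test_that("allele detection applies read-count and frequency thresholds", {
  obs <- make_obs(list(
    c(T = 98, C = 2),    # both detected
    c(T = 99, C = 1),    # C fails the >1 read rule
    c(T = 397, C = 3),   # C at 0.0075 fails the 0.01 frequency rule
    c(C = 50, G = 50),   # reference-independent polymorphism
    c(T = 100)))         # monomorphic
  det <- detect_alleles(obs)
  arr <- det$detected[["sp1"]][, "S1", ]
  expect_equal(unname(rowSums(arr)), c(2, 1, 1, 2, 1))
  expect_true(arr["1", "C"] && arr["1", "T"])
  expect_false(arr["2", "C"])
  expect_false(arr["3", "C"])
  poly <- polymorphic_sites(det, "sp1")
  expect_equal(unname(poly[, "S1"]), c(TRUE, FALSE, FALSE, TRUE, FALSE))
})

test_that("detection is monotone when depth rises at fixed frequencies", {
  base <- make_obs(list(c(T = 95, C = 5), c(T = 80, C = 12, G = 8)))
  scaled <- base
  for (b in c("A", "C", "G", "T")) scaled[[b]] <- scaled[[b]] * 10
  scaled$depth <- scaled$depth * 10
  d1 <- detect_alleles(base)$detected[["sp1"]]
  d2 <- detect_alleles(scaled)$detected[["sp1"]]
  expect_true(all(d2[d1])) # nothing detected before is lost
})

test_that("polymorphism fractions and per-sample summaries", {
  expect_equal(fraction_polymorphic(0, 1000), 0)
  expect_equal(fraction_polymorphic(50, 10000), 0.5)
  expect_error(fraction_polymorphic(1, 0), "positive")
  obs <- rbind(make_obs(list(c(T = 50, C = 50), c(T = 100)), "S1"),
               make_obs(list(c(T = 100), c(A = 60, G = 40)), "S2"))
  det <- detect_alleles(obs)
  summ <- polymorphism_summary(det, "sp1", core_len_filtered = 200)
  expect_equal(summ$n_polymorphic, c(1L, 1L))
  expect_equal(summ$fraction, c(0.5, 0.5))
  # mask removes non-analyzable sites from the counts
  mask <- matrix(c(FALSE, TRUE, TRUE, TRUE), 2,
                 dimnames = list(c("1", "2"), c("S1", "S2")))
  summ2 <- polymorphism_summary(det, "sp1", 200, mask)
  expect_equal(summ2$n_polymorphic, c(0L, 1L))
})

test_that("single-strain noise-free simulation has zero polymorphism", {
  mod <- species_model("sp", n_variant_sites = 300, n_strains = 2, seed = 44)
  obs <- simulate_allele_observations(
    mod, setNames(1, mod$strain_ids[1]), depth = 200, error_rate = 0,
    seed = 4)
  det <- detect_alleles(obs)
  expect_equal(sum(polymorphic_sites(det, "sp")), 0L)
  # two-strain 50/50, no error: every differentiating site is polymorphic
  obs2 <- simulate_allele_observations(
    mod, setNames(c(0.5, 0.5), mod$strain_ids), depth = 200,
    error_rate = 0, seed = 5)
  det2 <- detect_alleles(obs2)
  poly <- polymorphic_sites(det2, "sp")[, "S1"]
  differing <- mod$haplotypes[1, ] != mod$haplotypes[2, ]
  expect_equal(unname(poly), unname(differing))
  expect_equal(fraction_polymorphic(sum(poly), mod$core_length),
               100 * sum(differing) / mod$core_length)
})

test_that("cumulative curves end at the union regardless of order", {
  poly <- cbind(S1 = c(rep(TRUE, 10), rep(FALSE, 30)),
                S2 = c(rep(FALSE, 20), rep(TRUE, 20)))
  rownames(poly) <- as.character(1:40)
  curve <- cumulative_polymorphic_curve(poly, 100, n_orders = 10, seed = 1)
  expect_equal(curve$mean_cumulative_fraction[2], 30) # 30 sites / 100 bases
  # order-invariance of the final point across seeds
  curve2 <- cumulative_polymorphic_curve(poly, 100, n_orders = 10, seed = 99)
  expect_equal(curve$mean_cumulative_fraction[2],
               curve2$mean_cumulative_fraction[2])
  one <- cumulative_polymorphic_curve(poly[, 1, drop = FALSE], 100)
  expect_equal(one$mean_cumulative_fraction, 10)
})

test_that("shared-site rule: the worked two-sample example", {
  # site where the samples share only one allele (C): not shared
  s1 <- make_det(list("CG"))
  s2 <- make_det(list("TC"))
  one <- shared_fraction(s1, s2)
  expect_equal(one$n_union, 1L)
  expect_equal(one$n_shared, 0L)
  # {C,T} vs {T,C}: intersection of size 2, shared
  s1b <- make_det(list("CT"))
  two <- shared_fraction(s1b, s2)
  expect_equal(two$n_shared, 1L)
  expect_equal(two$distance, 0)
  # empty universe: distance 0 with warning
  expect_warning(z <- shared_fraction(make_det(list("T")),
                                      make_det(list("T"))), "no polymorphic")
  expect_equal(z$distance, 0)
})

test_that("shared fraction equals brute-force set enumeration", {
  set.seed(55)
  for (i in 1:100) {
    n_sites <- sample(3:30, 1)
    sets1 <- lapply(seq_len(n_sites), function(...)
      sample(c("A", "C", "G", "T"), sample(0:3, 1)))
    sets2 <- lapply(seq_len(n_sites), function(...)
      sample(c("A", "C", "G", "T"), sample(0:3, 1)))
    d1 <- make_det(vapply(sets1, paste, character(1), collapse = ""))
    d2 <- make_det(vapply(sets2, paste, character(1), collapse = ""))
    ours <- suppressWarnings(shared_fraction(d1, d2))
    oracle <- oracle_shared(sets1, sets2)
    expect_equal(ours$n_shared, oracle$n_shared)
    expect_equal(ours$n_union, oracle$n_union)
  }
  # symmetry
  d1 <- make_det(list("AC", "G", "AT"))
  d2 <- make_det(list("CA", "GT", "A"))
  expect_equal(shared_fraction(d1, d2), shared_fraction(d2, d1))
})

test_that("distance matrix is symmetric, zero-diagonal and bounded", {
  mod <- species_model("sp", n_variant_sites = 150, n_strains = 4, seed = 66)
  mixes <- list(S1 = c(0.5, 0.5, 0, 0), S2 = c(0, 0, 0.5, 0.5),
                S3 = c(0.4, 0.6, 0, 0))
  obs <- do.call(rbind, lapply(names(mixes), function(s) {
    m <- setNames(mixes[[s]], mod$strain_ids)
    simulate_allele_observations(mod, m[m > 0] / sum(m[m > 0]),
                                 depth = 300, error_rate = 0,
                                 sample_id = s, seed = match(s, names(mixes)))
  }))
  det <- detect_alleles(obs)
  d <- snv_distance_matrix(det, "sp")
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 3))
  expect_true(all(d >= 0 & d <= 1))
  # samples from the same strain pair are closer than disjoint pools
  expect_lt(d["S1", "S3"], d["S1", "S2"])
  expect_error(snv_distance_matrix(detect_alleles(
    obs[obs$sample_id != "S3", ]), "sp"), "3 samples")
})

test_that("snv_filters excludes weak species and low-coverage genes", {
  scen <- community_scenario(
    species = data.frame(species_id = c("hi", "lo"),
                         baseline = c(1, 0.05),
                         state_multiplier = c(1, 1)),
    coverage_noise = "none", colony_sd = 0, seed = 70)
  sim <- simulate_dataset(scen)
  fits <- fit_terminus_all(sim$gene_coverage)
  expect_message(
    filt <- snv_filters(sim$gene_coverage, fits, sim$allele_obs),
    "skipped.*lo")
  expect_true("hi" %in% names(filt$species))
  expect_false("lo" %in% names(filt$species))
  fs <- filt$species[["hi"]]
  # noise-free full-coverage species: every site analyzable, full core length
  expect_true(all(fs$mask))
  expect_equal(unname(fs$core_len_filtered[1]),
               sim$models[["hi"]]$core_length)
})
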