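test_that("species model honors counts and is deterministic", {
  m1 <- species_model("sp", n_genes = 10, n_core = 4, n_variant_sites = 100,
                      n_strains = 3, seed = 5)
  m2 <- species_model("sp", n_genes = 10, n_core = 4, n_variant_sites = 100,
                      n_strains = 3, seed = 5)
  expect_identical(m1, m2)
  expect_equal(sum(m1$genes$is_core), 4L)
  expect_equal(dim(m1$haplotypes), c(3L, 100L))
  expect_true(all(m1$haplotypes %in% c("A", "C", "G", "T")))
  expect_true(all(m1$genes$start_fraction >= 0 &
                    m1$genes$start_fraction < 1))
  # core genes span the position range (terminus fitting needs both arms)
  core_pos <- m1$genes$start_fraction[m1$genes$is_core]
  expect_lt(min(core_pos), 0.3)
  expect_gt(max(core_pos), 0.7)
  expect_error(species_model("sp", n_core = 0), "core")
})

test_that("community simulation produces the paired design", {
  scen <- community_scenario(n_locations = 5, colonies_per_location = 3,
                             seed = 3)
  comm <- simulate_community(scen)
  expect_equal(nrow(comm$samples), 30L)
  expect_equal(length(unique(comm$samples$colony_id)), 15L)
  expect_silent(validate_samples(comm$samples))
  # state multiplier 1, colony noise still shared: pairs equal
  scen1 <- community_scenario(
    species = data.frame(species_id = "sp1", baseline = 1,
                         state_multiplier = 1), seed = 4)
  comm1 <- simulate_community(scen1)
  nurse <- comm1$samples$sample_id[comm1$samples$state == "nurse"]
  pair <- sub("^N_", "F_", nurse)
  expect_equal(comm1$true_abundance[nurse, 1], comm1$true_abundance[pair, 1],
               ignore_attr = TRUE)
  # zero overlap: no strain shared between the state pools
  scen0 <- community_scenario(strain_pool_overlap = 0, seed = 5)
  comm0 <- simulate_community(scen0)
  for (p in comm0$strain_pools) {
    expect_length(intersect(p$nurse, p$forager), 0)
  }
  scen_full <- community_scenario(strain_pool_overlap = 1, seed = 6)
  commf <- simulate_community(scen_full)
  expect_identical(commf$strain_pools[[1]]$nurse,
                   commf$strain_pools[[1]]$forager)
})

test_that("gene coverage follows the V-shaped gradient", {
  mod <- species_model("sp", n_genes = 40, n_core = 30, seed = 8)
  # ptr = 1, no noise: flat at depth * abundance
  gc <- simulate_gene_coverage(mod, c(S1 = 0.5), ptr = 1,
                               depth_per_unit = 100, noise = "none")
  expect_true(all(gc$coverage == 50))
  # ptr = 5: expected Ori coverage is 5x the terminus coverage
  gc5 <- simulate_gene_coverage(mod, c(S1 = 1), ptr = 5,
                                depth_per_unit = 20, noise = "none")
  # noise-free coverage equals the V formula everywhere: trough 20, peak 100
  expected <- 20 + (100 - 20) * abs(2 * gc5$position_fraction - 1)
  expect_equal(gc5$coverage, expected)
  expect_error(simulate_gene_coverage(mod, c(S1 = -1), ptr = 2), "negative")
  # Poisson law-of-large-numbers: 10000 genes at mean 30 within 1%
  big <- species_model("big", n_genes = 10000, n_core = 10000,
                       n_variant_sites = 0, seed = 9)
  gcp <- simulate_gene_coverage(big, c(S1 = 1), ptr = 1,
                                depth_per_unit = 30, seed = 10)
  expect_equal(mean(gcp$coverage), 30, tolerance = 0.01)
})

test_that("allele observations follow the mixed-multinomial model", {
  mod <- species_model("sp", n_variant_sites = 200, n_strains = 2, seed = 12)
  # single strain, no error: monomorphic at the strain allele
  obs1 <- simulate_allele_observations(
    mod, setNames(1, mod$strain_ids[1]), depth = 50, error_rate = 0, seed = 1)
  counts <- as.matrix(obs1[, c("A", "C", "G", "T")])
  expect_true(all(rowSums(counts > 0) == 1))
  expect_true(all(obs1$depth == 50))
  hap <- mod$haplotypes[1, ]
  top <- c("A", "C", "G", "T")[max.col(counts)]
  expect_equal(top, unname(hap))
  # 50/50 two strains, no error: sites differing between strains split 100/100
  obs2 <- simulate_allele_observations(
    mod, setNames(c(0.5, 0.5), mod$strain_ids), depth = 200,
    error_rate = 0, seed = 2)
  diff_sites <- which(mod$haplotypes[1, ] != mod$haplotypes[2, ])
  c2 <- as.matrix(obs2[, c("A", "C", "G", "T")])
  exp_counts <- t(vapply(seq_len(nrow(c2)), function(i) {
    e <- setNames(rep(0, 4), c("A", "C", "G", "T"))
    e[mod$haplotypes[1, i]] <- e[mod$haplotypes[1, i]] + 100
    e[mod$haplotypes[2, i]] <- e[mod$haplotypes[2, i]] + 100
    e
  }, numeric(4)))
  expect_equal(colMeans(abs(c2 - exp_counts)), setNames(rep(0, 4),
               c("A", "C", "G", "T")), tolerance = 12) # multinomial noise
  expect_true(all(rowSums(c2[diff_sites, ]) == 200))
  # error mass: non-haplotype alleles at ~ eps/3 at high depth
  obs3 <- simulate_allele_observations(
    mod, setNames(1, mod$strain_ids[1]), depth = 1e6,
    error_rate = 0.01, seed = 3)
  c3 <- as.matrix(obs3[, c("A", "C", "G", "T")])
  freq_err <- vapply(seq_len(nrow(c3)), function(i) {
    mean(c3[i, setdiff(c("A", "C", "G", "T"), mod$haplotypes[1, i])]) / 1e6
  }, numeric(1))
  expect_equal(mean(freq_err), 0.01 / 3, tolerance = 0.02)
  expect_error(simulate_allele_observations(mod, numeric(0), 10), "empty")
  expect_error(
    simulate_allele_observations(mod, setNames(c(0.6, 0.6),
                                               mod$strain_ids), 10),
    "sum to 1")
})

test_that("OG coverage tracks abundance, carriage and planted folds", {
  scen <- community_scenario(
    species = data.frame(species_id = "sp1", baseline = 1,
                         state_multiplier = 1),
    strain_pool_overlap = 1, og_noise_sd = 0, seed = 20)
  comm <- simulate_community(scen)
  planted <- data.frame(species_id = "sp1", og_id = "planted_1",
                        enriched_state = "forager", fold = 4)
  og <- simulate_og_coverage(comm$models, comm$true_abundance,
                             comm$strain_mixtures, comm$samples,
                             planted = planted, noise_sd = 0)
  # core OGs (carried by all strains) track species abundance exactly
  core <- og[og$is_single_copy_core & og$og_id == comm$models[[1]]$core_ogs[1], ]
  ab <- comm$true_abundance[core$sample_id, 1]
  expect_equal(core$coverage / ab, rep(10, nrow(core)), ignore_attr = TRUE)
  # planted OG: forager/nurse ratio is exactly the fold (multiplier 1)
  pl <- og[og$og_id == "planted_1", ]
  nurse <- comm$samples$sample_id[comm$samples$state == "nurse"]
  pair <- sub("^N_", "F_", nurse)
  ratio <- pl$coverage[match(pair, pl$sample_id)] /
    pl$coverage[match(nurse, pl$sample_id)]
  expect_equal(ratio, rep(4, 15), ignore_attr = TRUE)
})

test_that("full dataset simulation is byte-deterministic", {
  scen <- community_scenario(seed = 77)
  d1 <- simulate_dataset(scen)
  d2 <- simulate_dataset(scen)
  expect_identical(d1, d2)
  out1 <- file.path(tempdir(), "sim1"); out2 <- file.path(tempdir(), "sim2")
  write_simulation(d1, out1)
  write_simulation(d2, out2)
  f1 <- list.files(out1)
  expect_setequal(f1, list.files(out2))
  for (f in f1) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)), label = f)
  }
})

test_that("scenario validation rejects out-of-range parameters", {
  expect_error(community_scenario(sequencing_error = 0.1), "0.05")
  expect_error(community_scenario(strain_pool_overlap = 2), "overlap")
  expect_error(community_scenario(ptr = 0.5), "ptr")
  expect_error(community_scenario(
    species = data.frame(species_id = "a", baseline = 1,
                         state_multiplier = -1)), "positive")
})
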