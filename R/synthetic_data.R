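#' Build a synthetic species model
#'
#' Creates a bacterial species for simulation: a gene catalog with genomic
#' positions (as fractions of the circular genome, origin at 0, terminus at
#' 0.5), a set of single-copy core genes spanning the full position range
#' (required for terminus-coverage fitting), variant sites on the
#' concatenated core-genome coordinate system, and a pool of strains, each
#' with a full haplotype over the variant sites and a set of accessory
#' orthologous groups (OGs). Core OGs are carried by every strain.
#'
#' @param species_id label.
#' @param genome_length genome size in bases (default 2e6).
#' @param n_genes number of gene families (default 120).
#' @param n_core number of single-copy core gene families (>= 1).
#' @param n_variant_sites number of core-genome variant sites.
#' @param n_strains number of strains in the species pool.
#' @param n_accessory_ogs accessory OG universe size.
#' @param n_core_ogs number of single-copy core OGs (default 25).
#' @param accessory_prob per-strain carriage probability of each accessory
#'   OG (default 0.5).
#' @param seed optional seed; when `NULL` the current RNG stream is used.
#' @return object of class `species_model`.
#' @export
species_model <- function(species_id, genome_length = 2e6, n_genes = 120L,
                          n_core = 80L, n_variant_sites = 400L,
                          n_strains = 4L, n_accessory_ogs = 30L,
                          n_core_ogs = 25L, accessory_prob = 0.5,
                          seed = NULL) {
  if (n_core < 1L) stop("need at least one single-copy core gene")
  if (n_genes < n_core) stop("n_genes must be >= n_core")
  if (n_strains < 1L || n_variant_sites < 0L) stop("counts must be >= 1")
  if (!is.null(seed)) set.seed(seed)

  # core genes on an even grid with jitter so they span [0, 1)
  core_pos <- (seq_len(n_core) - 1L) / n_core +
    stats::runif(n_core, 0, 0.5 / n_core)
  n_other <- n_genes - n_core
  other_pos <- stats::runif(n_other)
  genes <- data.frame(
    gene_id = sprintf("%s_g%04d", species_id, seq_len(n_genes)),
    start_fraction = c(core_pos, other_pos),
    length = round(stats::runif(n_genes, 600, 1500)),
    is_core = rep(c(TRUE, FALSE), c(n_core, n_other)),
    stringsAsFactors = FALSE)
  core_length <- sum(genes$length[genes$is_core])

  positions <- sort(sample.int(core_length, min(n_variant_sites, core_length)))
  ns <- length(positions)
  ref <- sample(ALLELE_BASES, ns, replace = TRUE)
  haplotypes <- matrix("", nrow = n_strains, ncol = ns)
  alt1 <- character(ns)
  for (i in seq_len(ns)) {
    n_alleles <- if (stats::runif(1) < 0.95) 2L else 3L
    alleles <- c(ref[i], sample(setdiff(ALLELE_BASES, ref[i]),
                                n_alleles - 1L))
    alt1[i] <- alleles[2]
    haplotypes[, i] <- sample(alleles, n_strains, replace = TRUE)
  }
  strain_ids <- sprintf("%s_s%d", species_id, seq_len(n_strains))
  rownames(haplotypes) <- strain_ids
  acc_ogs <- if (n_accessory_ogs > 0)
    sprintf("%s_acc%04d", species_id, seq_len(n_accessory_ogs)) else character(0)
  core_ogs <- sprintf("%s_core%03d", species_id, seq_len(n_core_ogs))
  accessory <- lapply(strain_ids, function(s) {
    acc_ogs[stats::runif(length(acc_ogs)) < accessory_prob]
  })
  names(accessory) <- strain_ids

  structure(list(
    species_id = species_id, genome_length = genome_length, genes = genes,
    core_length = core_length,
    variant_sites = data.frame(position = positions, ref_allele = ref,
                               alt_allele = alt1, stringsAsFactors = FALSE),
    strain_ids = strain_ids, haplotypes = haplotypes,
    accessory_ogs = accessory, core_ogs = core_ogs,
    accessory_universe = acc_ogs), class = "species_model")
}

#' @export
print.species_model <- function(x, ...) {
  cat("<species_model>", x$species_id, "-", nrow(x$genes), "genes (",
      sum(x$genes$is_core), "core ),", nrow(x$variant_sites),
      "variant sites,", length(x$strain_ids), "strains\n")
  invisible(x)
}

#' Define a community simulation scenario
#'
#' Encodes the study design the simulator emulates: two host behavioral
#' states (nurse/forager) sampled as pairs from colonies nested in
#' locations, per-species abundance multipliers between states, origin-to-
#' terminus coverage gradients, state-biased strain pools, sequencing
#' error, and a qPCR standard curve. Defaults follow the study design
#' (5 locations x 3 colonies = 15 colonies, 30 pooled samples).
#'
#' @param n_locations,colonies_per_location sampling design (default 5 x 3).
#' @param species data.frame with `species_id`, `baseline` (relative
#'   abundance scale of the nurse state) and `state_multiplier` (forager =
#'   nurse x multiplier). Default: four species with multipliers spanning
#'   the strong-to-null range reported for honeybee gut species.
#' @param pool_size strains in each state's pool.
#' @param strain_pool_overlap fraction of the pool shared between the
#'   nurse and forager pools (0 = disjoint, 1 = identical).
#' @param mixture_concentration Dirichlet concentration of within-colony
#'   strain mixtures (larger = more even, less colony-to-colony variance).
#' @param ptr origin/terminus coverage ratio (>= 1).
#' @param depth_per_unit terminus read depth of a species at abundance 1.
#' @param snv_depth read depth per variant site in the pooled pileup.
#' @param sequencing_error per-base substitution rate in \[0, 0.05\].
#' @param coverage_noise "poisson" or "none" for gene coverage counts.
#' @param colony_sd lognormal sigma of the colony effect shared by the two
#'   samples of a colony (default 0.2).
#' @param og_noise_sd lognormal sigma of OG coverage noise (0 = noise-free).
#' @param planted_differential_ogs data.frame (`species_id`, `og_id`,
#'   `enriched_state`, `fold`) of OGs planted with a state effect; `NULL`
#'   for none.
#' @param qpcr_slope,qpcr_intercept,qpcr_sd_ct standard curve (cycles per
#'   log10 copies; cycles; replicate Ct noise).
#' @param copies_per_unit 16S copies contributed per abundance unit.
#' @param dna_yield_ng total DNA yield per sample (ng).
#' @param seed integer seed; fully determines all outputs.
#' @return object of class `community_scenario`.
#' @export
community_scenario <- function(n_locations = 5L, colonies_per_location = 3L,
                               species = NULL, pool_size = 3L,
                               strain_pool_overlap = 0.5,
                               mixture_concentration = 10,
                               ptr = 2, depth_per_unit = 100,
                               snv_depth = 200, sequencing_error = 0.001,
                               coverage_noise = c("poisson", "none"),
                               colony_sd = 0.2, og_noise_sd = 0.3,
                               planted_differential_ogs = NULL,
                               qpcr_slope = -3.4, qpcr_intercept = 38,
                               qpcr_sd_ct = 0.1, copies_per_unit = 1e6,
                               dna_yield_ng = 10, seed = 42L) {
  if (is.null(species)) {
    species <- data.frame(
      species_id = c("Firm5_2", "Firm5_4", "Bifido_1.2", "Snod_1"),
      baseline = c(1.0, 0.8, 0.6, 0.4),
      state_multiplier = c(0.15, 0.6, 0.2, 1.0),
      stringsAsFactors = FALSE)
  }
  coverage_noise <- match.arg(coverage_noise)
  if (any(species$state_multiplier <= 0) || any(species$baseline <= 0)) {
    stop("baselines and state multipliers must be positive")
  }
  if (sequencing_error < 0 || sequencing_error > 0.05) {
    stop("sequencing_error must lie in [0, 0.05]")
  }
  if (strain_pool_overlap < 0 || strain_pool_overlap > 1) {
    stop("strain_pool_overlap must lie in [0, 1]")
  }
  if (ptr < 1) stop("ptr must be >= 1")
  structure(list(
    n_locations = as.integer(n_locations),
    colonies_per_location = as.integer(colonies_per_location),
    species = species, pool_size = as.integer(pool_size),
    strain_pool_overlap = strain_pool_overlap,
    mixture_concentration = mixture_concentration, ptr = ptr,
    depth_per_unit = depth_per_unit, snv_depth = snv_depth,
    sequencing_error = sequencing_error, coverage_noise = coverage_noise,
    colony_sd = colony_sd, og_noise_sd = og_noise_sd,
    planted_differential_ogs = planted_differential_ogs,
    qpcr_slope = qpcr_slope, qpcr_intercept = qpcr_intercept,
    qpcr_sd_ct = qpcr_sd_ct, copies_per_unit = copies_per_unit,
    dna_yield_ng = dna_yield_ng, seed = as.integer(seed)),
    class = "community_scenario")
}

# number of strains a species needs so both state pools of size m exist
# with s = round(overlap * m) strains shared
scenario_n_strains <- function(scenario) {
  m <- scenario$pool_size
  s <- round(scenario$strain_pool_overlap * m)
  2L * m - as.integer(s)
}

# Dirichlet draw via normalized gammas
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g <- rep(1, length(alpha))
  g / sum(g)
}

#' Simulate the paired community design
#'
#' Draws the sample table (one nurse and one forager pool per colony),
#' true species abundances (forager = nurse baseline x state multiplier,
#' with a lognormal colony effect shared by the colony's two samples), and
#' per-sample strain mixtures (Dirichlet draws within the state's strain
#' pool).
#'
#' @param scenario a [community_scenario()].
#' @param models named list of [species_model()]s (one per scenario
#'   species); built automatically when `NULL`.
#' @param seed optional seed (defaults to the scenario seed).
#' @return list with `samples`, `models`, `true_abundance` (matrix samples
#'   x species), `strain_mixtures` (data.frame `species_id`, `sample_id`,
#'   `strain_id`, `proportion`), and per-state pool membership
#'   `strain_pools`.
#' @export
simulate_community <- function(scenario, models = NULL, seed = scenario$seed) {
  if (!inherits(scenario, "community_scenario")) stop("invalid scenario")
  if (!is.null(seed)) set.seed(seed)
  spp <- scenario$species
  n_strains <- scenario_n_strains(scenario)
  if (is.null(models)) {
    models <- lapply(spp$species_id, function(id)
      species_model(id, n_strains = n_strains))
    names(models) <- spp$species_id
  }

  colonies <- expand.grid(colony = seq_len(scenario$colonies_per_location),
                          location = seq_len(scenario$n_locations))
  colony_id <- sprintf("L%dC%d", colonies$location, colonies$colony)
  samples <- data.frame(
    sample_id = c(paste0("N_", colony_id), paste0("F_", colony_id)),
    state = rep(c("nurse", "forager"), each = nrow(colonies)),
    colony_id = rep(colony_id, 2),
    location_id = rep(sprintf("L%d", colonies$location), 2),
    n_guts = 20L,
    pool_mass = rep(c(1200, 420), each = nrow(colonies)) *
      exp(stats::rnorm(2 * nrow(colonies), 0, 0.1)),
    dna_yield = scenario$dna_yield_ng,
    stringsAsFactors = FALSE)

  # colony effect shared by the pair, per species
  colony_eff <- matrix(
    exp(stats::rnorm(nrow(colonies) * nrow(spp), 0, scenario$colony_sd)),
    nrow = nrow(colonies), dimnames = list(colony_id, spp$species_id))
  abund <- matrix(NA_real_, nrow(samples), nrow(spp),
                  dimnames = list(samples$sample_id, spp$species_id))
  for (i in seq_len(nrow(samples))) {
    m <- if (samples$state[i] == "forager") spp$state_multiplier else 1
    abund[i, ] <- spp$baseline * m * colony_eff[samples$colony_id[i], ]
  }

  # state strain pools with configured overlap
  m <- scenario$pool_size
  s <- round(scenario$strain_pool_overlap * m)
  strain_pools <- lapply(models, function(mod) {
    ids <- mod$strain_ids
    list(nurse = ids[seq_len(m)], forager = ids[seq(m - s + 1L, 2L * m - s)])
  })

  mix <- list()
  for (sp in spp$species_id) {
    for (i in seq_len(nrow(samples))) {
      pool <- strain_pools[[sp]][[samples$state[i]]]
      p <- rdirichlet1(rep(scenario$mixture_concentration / length(pool),
                           length(pool)))
      mix[[length(mix) + 1L]] <- data.frame(
        species_id = sp, sample_id = samples$sample_id[i],
        strain_id = pool, proportion = p, stringsAsFactors = FALSE)
    }
  }
  list(samples = samples, models = models, true_abundance = abund,
       strain_mixtures = do.call(rbind, mix), strain_pools = strain_pools)
}

#' Simulate per-gene read coverage with an Ori-Ter gradient
#'
#' Expected coverage of a gene at genome position fraction x is V-shaped:
#' a linear decline from the origin (x = 0) to the terminus (x = 0.5) and
#' a symmetric rise back to x = 1. The trough (terminus) value is
#' `depth_per_unit` times the species' true abundance and the peak is
#' `ptr` times the trough. Counts are Poisson unless `noise = "none"`.
#'
#' @param model a [species_model()].
#' @param abundance named numeric vector of true abundances per sample.
#' @param ptr origin/terminus coverage ratio (>= 1).
#' @param depth_per_unit terminus depth at abundance 1.
#' @param noise "poisson" or "none".
#' @param seed optional seed.
#' @return data.frame (`species_id`, `gene_family_id`, `position_fraction`,
#'   `is_single_copy_core`, `gene_length`, `sample_id`, `coverage`).
#' @export
simulate_gene_coverage <- function(model, abundance, ptr,
                                   depth_per_unit = 100,
                                   noise = c("poisson", "none"),
                                   seed = NULL) {
  noise <- match.arg(noise)
  if (ptr < 1) stop("ptr must be >= 1")
  if (any(abundance < 0)) stop("abundance must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  genes <- model$genes
  out <- lapply(names(abundance), function(s) {
    ter <- depth_per_unit * abundance[[s]]
    ori <- ptr * ter
    mu <- ter + (ori - ter) * abs(2 * genes$start_fraction - 1)
    cov <- if (noise == "poisson") stats::rpois(length(mu), mu) else mu
    data.frame(species_id = model$species_id,
               gene_family_id = genes$gene_id,
               position_fraction = genes$start_fraction,
               is_single_copy_core = genes$is_core,
               gene_length = genes$length,
               sample_id = s, coverage = cov, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Simulate pooled allele observations at variant sites
#'
#' Per site, read counts are Multinomial(depth, p) where p mixes the
#' strain haplotype alleles by the sample's strain proportions, with a
#' uniform substitution-error mass epsilon spread over the three
#' non-template bases.
#'
#' @param model a [species_model()].
#' @param mixture named proportion vector over strain ids (sums to 1), or
#'   a strain-mixture data.frame covering several samples (columns
#'   `sample_id`, `strain_id`, `proportion`).
#' @param depth per-site read depth.
#' @param error_rate per-base substitution rate.
#' @param sample_id label used when `mixture` is a plain vector.
#' @param seed optional seed.
#' @return allele-observation data.frame (`species_id`, `site`,
#'   `ref_allele`, `sample_id`, `A`, `C`, `G`, `T`, `depth`).
#' @export
simulate_allele_observations <- function(model, mixture, depth,
                                         error_rate = 0, sample_id = "S1",
                                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.data.frame(mixture)) {
    if ("species_id" %in% names(mixture)) {
      mixture <- mixture[mixture$species_id == model$species_id, , drop = FALSE]
    }
    parts <- split(mixture, mixture$sample_id)
    out <- lapply(names(parts), function(s) {
      p <- stats::setNames(parts[[s]]$proportion, parts[[s]]$strain_id)
      simulate_allele_observations(model, p, depth, error_rate, s)
    })
    return(do.call(rbind, out))
  }
  if (length(mixture) == 0L) stop("empty strain mixture")
  if (abs(sum(mixture) - 1) > 1e-8) stop("mixture proportions must sum to 1")
  hap <- model$haplotypes[names(mixture), , drop = FALSE]
  ns <- ncol(hap)
  probs <- matrix(0, nrow = ns, ncol = 4, dimnames = list(NULL, ALLELE_BASES))
  for (b in ALLELE_BASES) {
    ind <- hap == b
    probs[, b] <- colSums(mixture * ((1 - error_rate) * ind +
                                       (error_rate / 3) * !ind))
  }
  counts <- t(apply(probs, 1, function(p) stats::rmultinom(1, depth, p)[, 1]))
  colnames(counts) <- ALLELE_BASES
  data.frame(species_id = model$species_id,
             site = model$variant_sites$position,
             ref_allele = model$variant_sites$ref_allele,
             sample_id = sample_id, counts,
             depth = rowSums(counts), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Simulate orthologous-group coverage
#'
#' Raw OG coverage is proportional to the species' true abundance times
#' the summed proportion of the sample's strains carrying the OG. Core
#' OGs are carried by all strains; accessory OGs follow the strain
#' content of the model; planted differential OGs additionally receive a
#' multiplicative fold in samples of their enriched state. Noise is
#' multiplicative lognormal with sigma `noise_sd`.
#'
#' @param models named list of [species_model()]s.
#' @param true_abundance matrix samples x species.
#' @param strain_mixtures data.frame (`species_id`, `sample_id`,
#'   `strain_id`, `proportion`).
#' @param samples sample table (for the state of each sample).
#' @param planted optional data.frame (`species_id`, `og_id`,
#'   `enriched_state`, `fold`); planted OGs are presence-modulated
#'   constructs added on top of the model's OG content.
#' @param og_scale coverage per abundance unit per fully-carried OG.
#' @param noise_sd lognormal sigma (0 = noise-free).
#' @param seed optional seed.
#' @return data.frame (`species_id`, `og_id`, `is_single_copy_core`,
#'   `sample_id`, `coverage`).
#' @export
simulate_og_coverage <- function(models, true_abundance, strain_mixtures,
                                 samples, planted = NULL, og_scale = 10,
                                 noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (sp in names(models)) {
    mod <- models[[sp]]
    mix <- strain_mixtures[strain_mixtures$species_id == sp, , drop = FALSE]
    acc <- mod$accessory_universe
    # carriage matrix: accessory OG x strain
    carr <- vapply(mod$strain_ids,
                   function(st) acc %in% mod$accessory_ogs[[st]],
                   logical(length(acc)))
    if (length(acc) == 1L) carr <- matrix(carr, nrow = 1)
    for (s in rownames(true_abundance)) {
      ab <- true_abundance[s, sp]
      msub <- mix[mix$sample_id == s, , drop = FALSE]
      og_ids <- c(mod$core_ogs, acc)
      acc_frac <- if (length(acc))
        as.vector(carr[, msub$strain_id, drop = FALSE] %*% msub$proportion)
      else numeric(0)
      frac <- c(rep(1, length(mod$core_ogs)), acc_frac)
      cov <- ab * og_scale * frac
      df <- data.frame(species_id = sp, og_id = og_ids,
                       is_single_copy_core = rep(c(TRUE, FALSE),
                         c(length(mod$core_ogs),
                           length(mod$accessory_universe))),
                       sample_id = s, coverage = cov,
                       stringsAsFactors = FALSE)
      if (!is.null(planted)) {
        pl <- planted[planted$species_id == sp, , drop = FALSE]
        if (nrow(pl)) {
          state <- samples$state[match(s, samples$sample_id)]
          fold <- ifelse(pl$enriched_state == state, pl$fold, 1)
          df <- rbind(df, data.frame(
            species_id = sp, og_id = pl$og_id, is_single_copy_core = FALSE,
            sample_id = s, coverage = ab * og_scale * 0.5 * fold,
            stringsAsFactors = FALSE))
        }
      }
      if (noise_sd > 0) {
        df$coverage <- df$coverage *
          exp(stats::rnorm(nrow(df), 0, noise_sd))
      }
      rows[[length(rows) + 1L]] <- df
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate triplicate qPCR measurements from true copy numbers
#'
#' Ct = intercept + slope * log10(copies) + Normal(0, sd_ct), the inverse
#' of the standard-curve copy-number formula, emitted in triplicate.
#'
#' @param copies named vector of true 16S copy numbers (> 0).
#' @param slope,intercept standard curve (slope non-zero).
#' @param sd_ct replicate Ct standard deviation.
#' @param n_reps replicates per sample (default 3).
#' @param seed optional seed.
#' @return data.frame `sample_id`, `target`, `ct1`..`ctN`, `slope`,
#'   `intercept`.
#' @export
simulate_qpcr <- function(copies, slope, intercept, sd_ct = 0, n_reps = 3L,
                          seed = NULL) {
  if (slope == 0) stop("slope must be non-zero")
  if (any(copies <= 0)) stop("copies must be positive")
  if (!is.null(seed)) set.seed(seed)
  ct <- sapply(copies, function(cp)
    intercept + slope * log10(cp) + stats::rnorm(n_reps, 0, sd_ct))
  ct <- matrix(ct, nrow = n_reps)
  out <- data.frame(sample_id = names(copies), target = "16S",
                    t(ct), slope = slope, intercept = intercept,
                    stringsAsFactors = FALSE, row.names = NULL)
  names(out)[3:(2 + n_reps)] <- paste0("ct", seq_len(n_reps))
  out
}

#' Simulate a complete synthetic dataset
#'
#' Runs every generator under the scenario's single seed, in a fixed
#' order, so the whole dataset is a deterministic function of the
#' scenario.
#'
#' @param scenario a [community_scenario()].
#' @return list with `scenario`, `samples`, `models`, `true_abundance`,
#'   `strain_mixtures`, `strain_pools`, `gene_coverage`, `allele_obs`,
#'   `og_coverage`, `qpcr`, `true_loads`.
#' @export
simulate_dataset <- function(scenario) {
  set.seed(scenario$seed)
  comm <- simulate_community(scenario, seed = NULL)
  gene_cov <- do.call(rbind, lapply(comm$models, function(mod)
    simulate_gene_coverage(mod, comm$true_abundance[, mod$species_id],
                           scenario$ptr, scenario$depth_per_unit,
                           scenario$coverage_noise)))
  allele_obs <- do.call(rbind, lapply(comm$models, function(mod)
    simulate_allele_observations(mod, comm$strain_mixtures,
                                 scenario$snv_depth,
                                 scenario$sequencing_error)))
  og_cov <- simulate_og_coverage(comm$models, comm$true_abundance,
                                 comm$strain_mixtures, comm$samples,
                                 scenario$planted_differential_ogs,
                                 noise_sd = scenario$og_noise_sd)
  copies <- rowSums(comm$true_abundance) * scenario$copies_per_unit
  qpcr <- simulate_qpcr(stats::setNames(copies, rownames(comm$true_abundance)),
                        scenario$qpcr_slope, scenario$qpcr_intercept,
                        scenario$qpcr_sd_ct)
  rownames(gene_cov) <- rownames(allele_obs) <- NULL
  list(scenario = scenario, samples = comm$samples, models = comm$models,
       true_abundance = comm$true_abundance,
       strain_mixtures = comm$strain_mixtures,
       strain_pools = comm$strain_pools,
       gene_coverage = gene_cov, allele_obs = allele_obs,
       og_coverage = og_cov, qpcr = qpcr,
       true_loads = copies / scenario$dna_yield_ng)
}

#' Write a simulated dataset to a directory of plain-text inputs
#'
#' Emits the tables the pipeline stages consume: sample metadata TSV, gene
#' coverage TSV, allele observations as TSV and minimal VCF, core-region
#' BED (0-based half-open, one interval per species core genome), OG
#' coverage TSV, qPCR CSV, and a ground-truth JSON.
#'
#' @param sim result of [simulate_dataset()].
#' @param outdir output directory (created if needed).
#' @return named vector of written paths, invisibly.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    samples = file.path(outdir, "samples.tsv"),
    gene_coverage = file.path(outdir, "gene_coverage.tsv"),
    allele_obs = file.path(outdir, "allele_observations.tsv"),
    vcf = file.path(outdir, "allele_observations.vcf"),
    core_bed = file.path(outdir, "core_regions.bed"),
    og_coverage = file.path(outdir, "og_coverage.tsv"),
    qpcr = file.path(outdir, "qpcr.csv"),
    truth = file.path(outdir, "truth.json"))
  write_tsv_table(sim$samples, paths["samples"])
  write_tsv_table(sim$gene_coverage, paths["gene_coverage"])
  write_tsv_table(sim$allele_obs, paths["allele_obs"])
  write_allele_vcf(sim$allele_obs, paths["vcf"])
  bed <- do.call(rbind, lapply(sim$models, function(mod)
    data.frame(chrom = mod$species_id, start = 0L, end = mod$core_length)))
  utils::write.table(bed, paths["core_bed"], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  write_tsv_table(sim$og_coverage, paths["og_coverage"])
  data.table::fwrite(sim$qpcr, paths["qpcr"])
  truth <- list(
    seed = sim$scenario$seed,
    species = sim$scenario$species,
    true_abundance = as.data.frame(sim$true_abundance),
    true_loads = as.list(sim$true_loads),
    strain_pools = sim$strain_pools,
    planted_differential_ogs = sim$scenario$planted_differential_ogs)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
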