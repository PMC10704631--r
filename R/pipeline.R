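# Default thresholds used across the pipeline; every entry can be
# overridden from the YAML config.
default_thresholds <- function() {
  list(min_matches = 51L, max_mismatches = 5L, min_gene_cov = 10,
       min_ter_cov = 20, allele_min_reads = 2L, allele_min_freq = 0.01,
       contig_min_len = 500, contig_min_kcov = 1, orf_min_len = 300,
       blast_max_evalue = 1e-5, blast_min_pident = 50, blast_min_qcovs = 50,
       norm_constant = 10000, sig_q = 0.05, sig_lfc = 1,
       n_perm = 999L, n_orders = 10L)
}

#' Build a pipeline configuration
#'
#' Thresholds default to the values used throughout the analysis (see
#' `default_thresholds`); unknown keys are rejected.
#'
#' @param input_dir directory of input tables (as written by
#'   [write_simulation()]); ignored when `simulate = TRUE`.
#' @param output_dir directory for stage outputs.
#' @param simulate generate inputs with the synthetic scenario first.
#' @param scenario a [community_scenario()] (when `simulate = TRUE`).
#' @param seed global seed; per-stage child seeds are derived from it.
#' @param thresholds named list overriding individual defaults.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir = NULL, output_dir = "strainshift_out",
                            simulate = TRUE, scenario = NULL, seed = 42L,
                            thresholds = list()) {
  th <- default_thresholds()
  unknown <- setdiff(names(thresholds), names(th))
  if (length(unknown)) {
    stop("unknown threshold key(s): ", paste(unknown, collapse = ", "))
  }
  th[names(thresholds)] <- thresholds
  bad <- names(th)[vapply(th, function(v) !is.numeric(v) || v <= 0,
                          logical(1))]
  bad <- setdiff(bad, "allele_min_freq")
  if (length(bad)) stop("thresholds must be positive: ",
                        paste(bad, collapse = ", "))
  if (is.null(scenario)) scenario <- community_scenario(seed = seed)
  structure(list(input_dir = input_dir, output_dir = output_dir,
                 simulate = isTRUE(simulate), scenario = scenario,
                 seed = as.integer(seed), thresholds = th),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized top-level keys: `input_dir`, `output_dir`, `simulate`,
#' `seed`, `thresholds` (a mapping of threshold overrides), and
#' `scenario` (a mapping of [community_scenario()] arguments). Unknown
#' keys anywhere are rejected.
#'
#' @param path YAML file.
#' @param ... overrides applied after reading (e.g. `seed`).
#' @return `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  known <- c("input_dir", "output_dir", "simulate", "seed", "thresholds",
             "scenario")
  unknown <- setdiff(names(y), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  dots <- list(...)
  y[names(dots)] <- dots
  scen_args <- y$scenario
  if (!is.null(scen_args$species)) {
    scen_args$species <- as.data.frame(scen_args$species,
                                       stringsAsFactors = FALSE)
  }
  if (!is.null(scen_args$planted_differential_ogs)) {
    scen_args$planted_differential_ogs <-
      as.data.frame(scen_args$planted_differential_ogs,
                    stringsAsFactors = FALSE)
  }
  if (!is.null(y$seed) && is.null(scen_args$seed)) scen_args$seed <- y$seed
  scenario <- do.call(community_scenario, scen_args %||% list(seed = y$seed))
  pipeline_config(input_dir = y$input_dir,
                  output_dir = y$output_dir %||% "strainshift_out",
                  simulate = y$simulate %||% is.null(y$input_dir),
                  scenario = scenario, seed = y$seed %||% 42L,
                  thresholds = y$thresholds %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# fixed seed fan-out: stage k of a run with global seed s gets
# (s * 7919 + k) mod 2^31-1, keeping every derived seed a valid R integer
stage_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + k) %% 2147483647)
}

read_stage_inputs <- function(dir) {
  list(samples = read_tsv_table(file.path(dir, "samples.tsv")),
       gene_coverage = read_tsv_table(file.path(dir, "gene_coverage.tsv")),
       allele_obs = read_tsv_table(file.path(dir, "allele_observations.tsv")),
       og_coverage = read_tsv_table(file.path(dir, "og_coverage.tsv")),
       qpcr = read_qpcr_csv(file.path(dir, "qpcr.csv")))
}

#' Run the full pipeline
#'
#' Executes simulate (optional) -> quantify -> community -> snv ->
#' genecontent -> stats, writing every stage's tables under
#' `config$output_dir` together with a machine-readable run manifest
#' (package version, seed, thresholds, output checksums).
#'
#' @param config a [pipeline_config()] or path to a YAML config.
#' @return named list of in-memory stage results, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- config$output_dir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  th <- config$thresholds

  if (config$simulate) {
    indir <- file.path(outdir, "inputs")
    sim <- simulate_dataset(config$scenario)
    write_simulation(sim, indir)
  } else {
    indir <- config$input_dir
    if (is.null(indir) || !dir.exists(indir)) {
      stop("input directory not found: ", indir %||% "<NULL>")
    }
  }
  for (f in c("samples.tsv", "gene_coverage.tsv", "allele_observations.tsv",
              "og_coverage.tsv", "qpcr.csv")) {
    if (!file.exists(file.path(indir, f))) {
      stop("missing input file: ", file.path(indir, f))
    }
  }
  inputs <- read_stage_inputs(indir)
  samples <- validate_samples(inputs$samples)

  # quantify
  loads <- compute_loads(inputs$qpcr, samples)
  load_cmp <- compare_paired_loads(loads, samples)
  write_tsv_table(loads, file.path(outdir, "loads.tsv"))
  write_tsv_table(load_cmp$ratios, file.path(outdir, "load_ratios.tsv"))

  # community
  fits <- fit_terminus_all(inputs$gene_coverage)
  rel <- relative_abundance(fits)
  abs_mat <- absolute_abundance(rel, loads)
  lfc <- suppressWarnings(paired_log2fc(abs_mat, samples,
                                        q_threshold = th$sig_q))
  write_tsv_table(fits, file.path(outdir, "terminus_fits.tsv"))
  write_tsv_table(data.frame(sample_id = rownames(rel), rel,
                             check.names = FALSE),
                  file.path(outdir, "relative_abundance.tsv"))
  write_tsv_table(data.frame(sample_id = rownames(abs_mat), abs_mat,
                             check.names = FALSE),
                  file.path(outdir, "absolute_abundance.tsv"))
  write_tsv_table(lfc, file.path(outdir, "species_log2fc.tsv"))

  # snv
  det <- detect_alleles(inputs$allele_obs, th$allele_min_reads,
                        th$allele_min_freq)
  filt <- snv_filters(inputs$gene_coverage, fits, inputs$allele_obs,
                      th$min_gene_cov, th$min_ter_cov)
  snv_summaries <- list(); snv_dists <- list(); curves <- list()
  for (sp in names(filt$species)) {
    fs <- filt$species[[sp]]
    snv_summaries[[sp]] <- polymorphism_summary(det, sp,
                                                fs$core_len_filtered,
                                                fs$mask)
    poly <- polymorphic_sites(det, sp, fs$mask)
    curves[[sp]] <- cbind(species_id = sp,
                          cumulative_polymorphic_curve(
                            poly, mean(fs$core_len_filtered),
                            n_orders = th$n_orders,
                            seed = stage_seed(config$seed, 4L)))
    if (ncol(poly) >= 3L) {
      snv_dists[[sp]] <- snv_distance_matrix(det, sp, fs$mask)
      write_tsv_table(data.frame(sample_id = rownames(snv_dists[[sp]]),
                                 snv_dists[[sp]], check.names = FALSE),
                      file.path(outdir, paste0("snv_distance_", sp, ".tsv")))
    }
  }
  if (length(snv_summaries)) {
    write_tsv_table(do.call(rbind, snv_summaries),
                    file.path(outdir, "polymorphism_summary.tsv"))
    write_tsv_table(do.call(rbind, curves),
                    file.path(outdir, "cumulative_curves.tsv"))
  }

  # gene content
  norm <- normalize_og_coverage(inputs$og_coverage, th$norm_constant)
  diff_ogs <- differential_ogs(norm, samples, th$sig_q, th$sig_lfc)
  write_tsv_table(diff_ogs, file.path(outdir, "differential_ogs.tsv"))

  # stats / ordination
  meta <- data.frame(sample_id = samples$sample_id,
                     Host = factor(samples$state),
                     Location = factor(samples$location_id))
  bc <- bray_curtis(rel)
  ord <- pcoa(bc)
  perm <- permanova_marginal(bc, meta, n_perm = th$n_perm,
                             seed = stage_seed(config$seed, 6L))
  write_tsv_table(data.frame(sample_id = rownames(bc), bc,
                             check.names = FALSE),
                  file.path(outdir, "bray_curtis.tsv"))
  write_tsv_table(perm, file.path(outdir, "permanova_composition.tsv"))
  snv_perm <- lapply(names(snv_dists), function(sp) {
    cbind(species_id = sp,
          permanova_marginal(snv_dists[[sp]], meta, n_perm = th$n_perm,
                             seed = stage_seed(config$seed, 7L)))
  })
  if (length(snv_perm)) {
    write_tsv_table(do.call(rbind, snv_perm),
                    file.path(outdir, "permanova_snv.tsv"))
  }

  manifest <- list(
    package = "strainshift",
    version = as.character(utils::packageVersion("strainshift")),
    seed = config$seed, thresholds = th,
    outputs = {
      sums <- tools::md5sum(
        list.files(outdir, pattern = "\\.tsv$", full.names = TRUE))
      names(sums) <- basename(names(sums))
      as.list(sums)
    })
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(samples = samples, loads = loads, load_cmp = load_cmp,
                 fits = fits, relative = rel, absolute = abs_mat,
                 log2fc = lfc, detected = det, snv_filters = filt,
                 snv_summaries = snv_summaries, snv_distances = snv_dists,
                 cumulative_curves = curves, differential_ogs = diff_ogs,
                 bray_curtis = bc, pcoa = ord, permanova = perm,
                 snv_permanova = snv_perm))
}

#' Command-line entry point
#'
#' Implements `strainshift <subcommand> --config config.yaml [--seed N]
#' [--outdir D]` with subcommands `run`, `simulate`, `community`, `snv`,
#' `genecontent`, `stats`. `run` executes everything; each stage
#' subcommand re-runs the pipeline and is guaranteed to regenerate that
#' stage's outputs (stages are cheap and deterministic, so stage
#' subcommands are implemented as filtered full runs).
#'
#' @param args character vector of command-line arguments (defaults to
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return exit status (0 on success), invisibly.
#' @export
strainshift_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  subcommands <- c("run", "simulate", "community", "snv", "genecontent",
                   "stats")
  if (length(args) == 0L || !args[1] %in% subcommands) {
    message("usage: strainshift <", paste(subcommands, collapse = "|"),
            "> [--config config.yaml] [--seed N] [--outdir D]")
    return(invisible(1L))
  }
  sub <- args[1]
  parser <- optparse::OptionParser(option_list = list(
    optparse::make_option("--config", type = "character", default = NULL),
    optparse::make_option("--seed", type = "integer", default = NULL),
    optparse::make_option("--outdir", type = "character", default = NULL),
    optparse::make_option(c("-v", "--verbose"), action = "store_true",
                          default = FALSE)))
  opts <- optparse::parse_args(parser, args = args[-1])
  status <- tryCatch({
    config <- if (!is.null(opts$config)) {
      read_pipeline_config(opts$config)
    } else {
      pipeline_config(seed = opts$seed %||% 42L)
    }
    if (!is.null(opts$seed)) {
      config$seed <- opts$seed
      config$scenario$seed <- opts$seed
    }
    if (!is.null(opts$outdir)) config$output_dir <- opts$outdir
    if (opts$verbose) message("running '", sub, "' into ",
                              config$output_dir)
    if (sub == "simulate") {
      sim <- simulate_dataset(config$scenario)
      write_simulation(sim, file.path(config$output_dir, "inputs"))
    } else {
      run_pipeline(config)
    }
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
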