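# Internal: cast an allele-observation data.frame for one species into a
# 3-d logical detection array (site x sample x base) plus count arrays.
obs_count_array <- function(obs) {
  sites <- sort(unique(obs$site))
  samples <- sort(unique(obs$sample_id))
  arr <- array(0, dim = c(length(sites), length(samples), 4),
               dimnames = list(site = as.character(sites),
                               sample = samples, base = ALLELE_BASES))
  si <- match(obs$site, sites)
  sa <- match(obs$sample_id, samples)
  for (b in seq_along(ALLELE_BASES)) {
    arr[cbind(si, sa, b)] <- obs[[ALLELE_BASES[b]]]
  }
  arr
}

#' Detect alleles in pooled allele observations
#'
#' An allele is considered detected at a site in a sample when it is
#' supported by at least `min_reads` reads (i.e. more than one read, with
#' the default of 2) and its within-site frequency is at least
#' `min_freq`. The rule applies to the reference allele exactly as to
#' alternates. The frequency denominator is the total read count at the
#' site.
#'
#' @param obs allele-observation data.frame (`species_id`, `site`,
#'   `sample_id`, `A`, `C`, `G`, `T`; see
#'   [read_allele_observations()]).
#' @param min_reads minimum supporting reads (default 2).
#' @param min_freq minimum allele frequency (default 0.01).
#' @return list of class `detected_alleles` with `detected` (logical array
#'   site x sample x base per species, in a named list), and the
#'   thresholds used.
#' @export
detect_alleles <- function(obs, min_reads = 2L, min_freq = 0.01) {
  per_species <- split(obs, obs$species_id)
  detected <- lapply(per_species, function(df) {
    counts <- obs_count_array(df)
    depth <- apply(counts, c(1, 2), sum)
    freq_floor <- array(rep(depth * min_freq, 4), dim = dim(counts))
    det <- (counts >= min_reads) & (counts >= freq_floor)
    dimnames(det) <- dimnames(counts)
    det
  })
  structure(list(detected = detected, min_reads = min_reads,
                 min_freq = min_freq), class = "detected_alleles")
}

#' Polymorphic sites per sample
#'
#' A site is polymorphic in a sample when at least two alleles are
#' detected there, regardless of the reference allele.
#'
#' @param det a `detected_alleles` object from [detect_alleles()].
#' @param species_id which species to summarize.
#' @param mask optional logical matrix (site x sample, dimnames matching
#'   the detection array) marking sites analyzable in each sample (e.g.
#'   gene coverage >= 10x); non-analyzable sites are never polymorphic.
#' @return logical matrix site x sample of polymorphism calls.
#' @export
polymorphic_sites <- function(det, species_id, mask = NULL) {
  arr <- det$detected[[species_id]]
  if (is.null(arr)) stop("no detections for species ", species_id)
  n_det <- apply(arr, c(1, 2), sum)
  poly <- n_det >= 2L
  if (!is.null(mask)) {
    mask <- mask[rownames(poly), colnames(poly), drop = FALSE]
    poly <- poly & mask
  }
  poly
}

#' Fraction of polymorphic sites
#'
#' Percentage of polymorphic sites over the filtered single-copy
#' core-genome length (only bases of core genes passing the coverage
#' filter count in the denominator).
#'
#' @param n_polymorphic number of polymorphic sites.
#' @param core_len_filtered filtered core-genome length in bases (> 0).
#' @return percent fraction.
#' @export
fraction_polymorphic <- function(n_polymorphic, core_len_filtered) {
  if (any(core_len_filtered <= 0)) stop("core length must be positive")
  100 * n_polymorphic / core_len_filtered
}

#' Per-sample polymorphism summary for one species
#'
#' @param det `detected_alleles` object.
#' @param species_id species label.
#' @param core_len_filtered filtered core-genome length (bases); a scalar
#'   or a named per-sample vector.
#' @param mask optional site x sample analyzability mask.
#' @return data.frame `species_id`, `sample_id`, `n_polymorphic`,
#'   `core_len_filtered`, `fraction` (percent).
#' @export
polymorphism_summary <- function(det, species_id, core_len_filtered,
                                 mask = NULL) {
  poly <- polymorphic_sites(det, species_id, mask)
  n <- colSums(poly)
  len <- if (length(core_len_filtered) == 1L) {
    rep(core_len_filtered, length(n))
  } else {
    unname(core_len_filtered[colnames(poly)])
  }
  data.frame(species_id = species_id, sample_id = colnames(poly),
             n_polymorphic = unname(n), core_len_filtered = len,
             fraction = fraction_polymorphic(unname(n), len),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Mean cumulative polymorphic-site curve over random sample orders
#'
#' For each of `n_orders` random orders of the samples, computes the
#' running size of the union of polymorphic sites after adding each
#' sample (as a percent of the core-genome length), then averages the
#' curves. The final point is order-invariant: the union over all
#' samples.
#'
#' @param poly logical site x sample polymorphism matrix (from
#'   [polymorphic_sites()]).
#' @param core_len_filtered denominator length in bases.
#' @param n_orders number of random orders (default 10).
#' @param seed optional seed.
#' @return data.frame `k` (number of samples), `mean_cumulative_fraction`
#'   (percent).
#' @export
cumulative_polymorphic_curve <- function(poly, core_len_filtered,
                                         n_orders = 10L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- ncol(poly)
  if (n < 1L) stop("need at least one sample")
  acc <- matrix(0, n_orders, n)
  for (o in seq_len(n_orders)) {
    ord <- sample.int(n)
    seen <- rep(FALSE, nrow(poly))
    for (k in seq_len(n)) {
      seen <- seen | poly[, ord[k]]
      acc[o, k] <- sum(seen)
    }
  }
  data.frame(k = seq_len(n),
             mean_cumulative_fraction =
               fraction_polymorphic(colMeans(acc), core_len_filtered))
}

#' Shared polymorphic sites between two samples
#'
#' The site universe of a pair is the set of sites polymorphic in at
#' least one of the two samples (optionally restricted to sites
#' analyzable in both). A site is shared when the two samples' detected
#' allele sets intersect in at least two alleles; sharing a single allele
#' does not count. The shared fraction is n_shared / n_union and the
#' distance is 1 - shared fraction; an empty universe gives distance 0
#' with a warning (no evidence of difference).
#'
#' @param det1,det2 logical site x base detection matrices of the two
#'   samples (aligned rows).
#' @return list `n_shared`, `n_union`, `shared_fraction`, `distance`.
#' @export
shared_fraction <- function(det1, det2) {
  if (!all(dim(det1) == dim(det2))) stop("detection matrices must align")
  poly1 <- rowSums(det1) >= 2L
  poly2 <- rowSums(det2) >= 2L
  universe <- poly1 | poly2
  shared <- universe & rowSums(det1 & det2) >= 2L
  n_union <- sum(universe)
  n_shared <- sum(shared)
  if (n_union == 0L) {
    warning("no polymorphic sites in the pair; distance set to 0")
    return(list(n_shared = 0L, n_union = 0L, shared_fraction = 1,
                distance = 0))
  }
  sf <- n_shared / n_union
  list(n_shared = n_shared, n_union = n_union, shared_fraction = sf,
       distance = 1 - sf)
}

#' Shared-polymorphic-site distance matrix for one species
#'
#' Computes 1 - shared fraction between every pair of samples. When a
#' site x sample analyzability mask is given, sites not analyzable (below
#' the per-gene coverage floor) in either member of a pair are excluded
#' from that pair's universe, so asymmetric missingness cannot inflate
#' the distance. The result is symmetric with zero diagonal and values
#' in \[0, 1\]; it is not guaranteed to satisfy the triangle inequality.
#'
#' @param det `detected_alleles` object.
#' @param species_id species label.
#' @param mask optional logical site x sample matrix.
#' @return symmetric distance matrix (samples x samples).
#' @export
snv_distance_matrix <- function(det, species_id, mask = NULL) {
  arr <- det$detected[[species_id]]
  if (is.null(arr)) stop("no detections for species ", species_id)
  samples <- dimnames(arr)$sample
  n <- length(samples)
  if (n < 3L) stop("need at least 3 samples")
  d <- matrix(0, n, n, dimnames = list(samples, samples))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d1 <- arr[, i, ]; d2 <- arr[, j, ]
      if (!is.null(mask)) {
        ok <- mask[rownames(d1), samples[i]] & mask[rownames(d2), samples[j]]
        d1 <- d1 & ok; d2 <- d2 & ok
      }
      sf <- suppressWarnings(shared_fraction(d1, d2))
      d[i, j] <- d[j, i] <- sf$distance
    }
  }
  d
}

#' Species and site filters for the SNV analysis
#'
#' Builds, from the gene-coverage table and terminus fits, (a) the set of
#' species passing the terminus-coverage floor in every sample (species
#' with <= `min_ter_cov` terminus coverage are skipped with a message),
#' and (b) per species: a site x sample analyzability mask marking sites
#' whose gene has >= `min_gene_cov` coverage in that sample, plus the
#' filtered core-genome length per sample.
#'
#' @param gene_cov gene-coverage table (needs `gene_length`).
#' @param fits terminus fits from [fit_terminus_all()].
#' @param obs allele-observation table (for site -> gene placement on the
#'   concatenated core-genome coordinate system).
#' @param min_gene_cov per-gene coverage floor (default 10).
#' @param min_ter_cov species terminus-coverage floor (default 20,
#'   exclusive).
#' @return list per retained species: `mask` (site x sample),
#'   `core_len_filtered` (named per sample), plus `skipped` species.
#' @export
snv_filters <- function(gene_cov, fits, obs, min_gene_cov = 10,
                        min_ter_cov = 20) {
  species <- unique(fits$species_id)
  min_ter <- tapply(fits$ter_coverage, fits$species_id, min)
  keep <- names(min_ter)[min_ter > min_ter_cov]
  skipped <- setdiff(species, keep)
  if (length(skipped)) {
    message("species below ", min_ter_cov, "x terminus coverage skipped: ",
            paste(skipped, collapse = ", "))
  }
  out <- list(skipped = skipped, species = list())
  for (sp in keep) {
    gc <- gene_cov[gene_cov$species_id == sp & gene_cov$is_single_copy_core, ]
    genes <- unique(gc[, c("gene_family_id", "gene_length")])
    # concatenated core-genome coordinates in catalog order
    ends <- cumsum(genes$gene_length)
    starts <- c(0, utils::head(ends, -1)) + 1
    sp_obs <- obs[obs$species_id == sp, , drop = FALSE]
    sites <- sort(unique(sp_obs$site))
    gene_of_site <- genes$gene_family_id[
      findInterval(sites, starts, rightmost.closed = FALSE)]
    samples <- sort(unique(sp_obs$sample_id))
    covm <- matrix(0, nrow(genes), length(samples),
                   dimnames = list(genes$gene_family_id, samples))
    idx <- cbind(match(gc$gene_family_id, genes$gene_family_id),
                 match(gc$sample_id, samples))
    ok_row <- !is.na(idx[, 2])
    covm[idx[ok_row, , drop = FALSE]] <- gc$coverage[ok_row]
    pass <- covm >= min_gene_cov
    mask <- pass[gene_of_site, , drop = FALSE]
    rownames(mask) <- as.character(sites)
    len_f <- colSums(genes$gene_length * pass)
    out$species[[sp]] <- list(mask = mask, core_len_filtered = len_f)
  }
  out
}
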