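#' Infer terminus coverage by segmented regression
#'
#' Fits a continuous two-segment piecewise-linear least-squares model of
#' per-gene-family coverage against genome position fraction, with the
#' breakpoint searched on a grid (step `grid_step`) and refined by
#' continuous optimization around the best grid point. The terminus
#' coverage is the fitted value at the breakpoint; the origin coverage is
#' the mean of the fitted values at positions 0 and 1. The fit is declared
#' invalid — and the method falls back to the median of the core-family
#' coverages — when fewer than 8 gene families are available, the
#' breakpoint falls outside `valid_window`, the fitted origin coverage
#' does not exceed the terminus coverage (flat or inverted profiles), or
#' the fitted terminus is negative.
#'
#' @param position numeric vector of gene positions in \[0, 1).
#' @param coverage matching coverage values (mean read depth).
#' @param grid_step breakpoint grid resolution (default 0.01).
#' @param valid_window admissible breakpoint range (default c(0.3, 0.7),
#'   operationalizing "terminus near mid-replichore").
#' @param species_id,sample_id labels carried into the result.
#' @return one-row data.frame (`species_id`, `sample_id`, `method`
#'   ("segmented" or "median"), `breakpoint`, `ter_coverage`,
#'   `ori_coverage`, `valid`).
#' @export
fit_terminus_coverage <- function(position, coverage, grid_step = 0.01,
                                  valid_window = c(0.3, 0.7),
                                  species_id = NA_character_,
                                  sample_id = NA_character_) {
  if (length(position) != length(coverage)) {
    stop("position and coverage must have equal length")
  }
  ok <- !is.na(position) & !is.na(coverage)
  position <- position[ok]; coverage <- coverage[ok]
  med_fit <- data.frame(species_id = species_id, sample_id = sample_id,
                        method = "median", breakpoint = NA_real_,
                        ter_coverage = stats::median(coverage),
                        ori_coverage = NA_real_, valid = FALSE,
                        stringsAsFactors = FALSE)
  if (length(position) < 8L) {
    warning("fewer than 8 gene families; using median coverage")
    return(med_fit)
  }
  rss_at <- function(b) {
    X <- cbind(1, position, pmax(position - b, 0))
    fit <- stats::lm.fit(X, coverage)
    sum(fit$residuals^2)
  }
  grid <- seq(grid_step, 1 - grid_step, by = grid_step)
  rss <- vapply(grid, rss_at, numeric(1))
  b0 <- grid[which.min(rss)]
  opt <- stats::optimize(rss_at,
                         lower = max(grid_step / 10, b0 - grid_step),
                         upper = min(1 - grid_step / 10, b0 + grid_step))
  b <- if (opt$objective < min(rss)) opt$minimum else b0
  X <- cbind(1, position, pmax(position - b, 0))
  cf <- stats::lm.fit(X, coverage)$coefficients
  cf[is.na(cf)] <- 0
  predict_at <- function(x) cf[1] + cf[2] * x + cf[3] * pmax(x - b, 0)
  ter <- unname(predict_at(b))
  ori <- unname((predict_at(0) + predict_at(1)) / 2)
  valid <- b >= valid_window[1] && b <= valid_window[2] &&
    ori > ter && ter >= 0
  if (!valid) {
    med_fit$breakpoint <- b
    med_fit$ori_coverage <- ori
    return(med_fit)
  }
  data.frame(species_id = species_id, sample_id = sample_id,
             method = "segmented", breakpoint = b, ter_coverage = ter,
             ori_coverage = ori, valid = TRUE, stringsAsFactors = FALSE)
}

#' Fit terminus coverage for every species and sample of a coverage table
#'
#' Uses the single-copy core gene families only, summarizing each
#' (species, sample) with [fit_terminus_coverage()].
#'
#' @param gene_cov gene-coverage data.frame (`species_id`,
#'   `gene_family_id`, `position_fraction`, `is_single_copy_core`,
#'   `sample_id`, `coverage`).
#' @param ... passed to [fit_terminus_coverage()].
#' @return data.frame of fits, one row per (species, sample).
#' @export
fit_terminus_all <- function(gene_cov, ...) {
  core <- gene_cov[gene_cov$is_single_copy_core, , drop = FALSE]
  parts <- split(core, list(core$species_id, core$sample_id), drop = TRUE)
  out <- lapply(parts, function(df) {
    suppressWarnings(
      fit_terminus_coverage(df$position_fraction, df$coverage,
                            species_id = df$species_id[1],
                            sample_id = df$sample_id[1], ...))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Relative species abundance from terminus coverages
#'
#' Per sample, divides each species' terminus coverage by the summed
#' terminus coverage of all species. Species with zero coverage get 0.
#'
#' @param fits terminus-fit data.frame from [fit_terminus_all()].
#' @return matrix samples x species of proportions (rows sum to 1).
#' @export
relative_abundance <- function(fits) {
  samples <- unique(fits$sample_id)
  species <- unique(fits$species_id)
  mat <- matrix(0, length(samples), length(species),
                dimnames = list(samples, species))
  for (i in seq_len(nrow(fits))) {
    mat[fits$sample_id[i], fits$species_id[i]] <- fits$ter_coverage[i]
  }
  if (any(mat < 0)) stop("negative terminus coverage")
  rs <- rowSums(mat)
  if (any(rs == 0)) {
    stop("sample(s) with all-zero coverage: ",
         paste(samples[rs == 0], collapse = ", "))
  }
  sweep(mat, 1, rs, "/")
}

#' Absolute species abundance
#'
#' Multiplies each sample's relative abundances by its normalized
#' bacterial load (16S copies per ng total DNA).
#'
#' @param rel relative-abundance matrix (samples x species).
#' @param loads data.frame with `sample_id` and `copies_per_ng`.
#' @return matrix samples x species of absolute abundances.
#' @export
absolute_abundance <- function(rel, loads) {
  idx <- match(rownames(rel), loads$sample_id)
  if (anyNA(idx)) {
    stop("missing load for sample(s): ",
         paste(rownames(rel)[is.na(idx)], collapse = ", "))
  }
  rel * loads$copies_per_ng[idx]
}

#' Paired per-species log2 fold changes between host states
#'
#' For each species, computes the per-colony log2(forager/nurse) of
#' absolute abundance, its median, a paired Wilcoxon signed-rank p-value
#' on the abundances, and Storey/BH q-values across species. Colonies with
#' a zero nurse (or forager) abundance give infinite log2 fold changes;
#' these are kept in the table but excluded from the median with a
#' warning.
#'
#' @param abs_mat absolute-abundance matrix (samples x species).
#' @param samples paired sample table.
#' @param q_threshold significance threshold on q (default 0.05).
#' @return data.frame per species: `species_id`, `median_log2fc`, `p`,
#'   `q`, `n_pairs`, `significant`.
#' @export
paired_log2fc <- function(abs_mat, samples, q_threshold = 0.05) {
  validate_samples(samples)
  nurse <- samples[samples$state == "nurse", ]
  forager <- samples[samples$state == "forager", ]
  forager <- forager[match(nurse$colony_id, forager$colony_id), ]
  res <- lapply(colnames(abs_mat), function(sp) {
    nv <- abs_mat[nurse$sample_id, sp]
    fv <- abs_mat[forager$sample_id, sp]
    lfc <- log2(fv / nv)
    finite <- is.finite(lfc)
    if (!all(finite)) {
      warning("infinite log2FC in species ", sp,
              " excluded from the median")
    }
    wt <- wilcoxon_signed_rank_paired(fv, nv)
    data.frame(species_id = sp,
               median_log2fc = stats::median(lfc[finite]),
               p = wt$p.value, n_pairs = length(nv),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- qvalues(out$p)
  out$significant <- out$q < q_threshold
  per_colony <- sapply(colnames(abs_mat), function(sp)
    log2(abs_mat[forager$sample_id, sp] / abs_mat[nurse$sample_id, sp]))
  rownames(per_colony) <- nurse$colony_id
  attr(out, "per_colony") <- per_colony
  out
}

#' Aggregate a species abundance matrix to phylotypes
#'
#' @param mat abundance matrix (samples x species).
#' @param phylotype_map named character vector, species -> phylotype.
#' @return matrix samples x phylotypes; row sums are preserved.
#' @export
phylotype_aggregate <- function(mat, phylotype_map) {
  missing <- setdiff(colnames(mat), names(phylotype_map))
  if (length(missing)) {
    stop("unmapped species: ", paste(missing, collapse = ", "))
  }
  groups <- phylotype_map[colnames(mat)]
  t(rowsum(t(mat), group = groups))
}

#' Shannon diversity within one phylotype
#'
#' Renormalizes the phylotype's species proportions within each sample
#' and computes H = -sum(p * ln p), then a paired nurse/forager Wilcoxon
#' signed-rank test on H. Samples where the phylotype is absent give an
#' undefined H (NA) and are excluded from the test pairwise.
#'
#' @param mat species abundance matrix (relative or absolute).
#' @param phylotype_map named character vector, species -> phylotype.
#' @param phylotype which phylotype to summarize (needs >= 2 species).
#' @param samples optional paired sample table; when supplied the paired
#'   test is run.
#' @return list with `H` (named per sample) and, when `samples` is given,
#'   `p.value`.
#' @export
shannon_within_phylotype <- function(mat, phylotype_map, phylotype,
                                     samples = NULL) {
  members <- names(phylotype_map)[phylotype_map == phylotype]
  members <- intersect(members, colnames(mat))
  if (length(members) < 2L) stop("phylotype needs >= 2 species")
  sub <- mat[, members, drop = FALSE]
  H <- apply(sub, 1, function(v) {
    tot <- sum(v)
    if (tot == 0) return(NA_real_)
    p <- v[v > 0] / tot
    -sum(p * log(p))
  })
  out <- list(H = H)
  if (!is.null(samples)) {
    validate_samples(samples)
    nurse <- samples[samples$state == "nurse", ]
    forager <- samples[samples$state == "forager", ]
    forager <- forager[match(nurse$colony_id, forager$colony_id), ]
    hn <- H[nurse$sample_id]; hf <- H[forager$sample_id]
    keep <- !is.na(hn) & !is.na(hf)
    out$p.value <- wilcoxon_signed_rank_paired(hf[keep], hn[keep])$p.value
  }
  out
}
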