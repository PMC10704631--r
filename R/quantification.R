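#' Absolute gene copy number from qPCR cycle thresholds
#'
#' Inverts a previously determined standard curve:
#' copies = 10^((Ct - intercept) / slope). Replicate Cts are averaged
#' before the power transform (mean-of-Ct, the standard qPCR practice
#' matching a log-linear amplification model).
#'
#' @param ct numeric vector of cycle-threshold replicates for one reaction.
#' @param slope standard-curve slope in cycles per log10 copies (non-zero;
#'   negative for ordinary amplification).
#' @param intercept standard-curve intercept in cycles (Ct of one copy).
#' @return estimated copy number (scalar).
#' @examples
#' gene_copy_number(8, slope = -1, intercept = 10) # 100
#' @export
gene_copy_number <- function(ct, slope, intercept) {
  if (length(ct) < 1L || anyNA(ct)) stop("need at least one non-missing Ct")
  if (slope == 0) stop("slope must be non-zero")
  10^((mean(ct) - intercept) / slope)
}

#' Normalized bacterial load
#'
#' Normalizes absolute 16S rRNA gene copies by the total DNA yield of the
#' pooled gut sample, giving copies per ng total DNA (the per-sample
#' bacterial-load measure; host-gene normalization is deliberately not
#' offered).
#'
#' @param copies_16s absolute 16S copy number (>= 0).
#' @param dna_ng total DNA yield in ng (> 0).
#' @return list with `copies_16s` and `copies_per_ng`.
#' @export
bacterial_load <- function(copies_16s, dna_ng) {
  if (any(dna_ng <= 0)) stop("dna_ng must be positive")
  if (any(copies_16s < 0)) stop("copies must be non-negative")
  list(copies_16s = copies_16s, copies_per_ng = copies_16s / dna_ng)
}

#' Compute per-sample loads from a qPCR table
#'
#' @param qpcr data.frame with columns `sample_id`, `target`, Ct replicate
#'   columns (`ct1`, `ct2`, ... as available), `slope`, `intercept`.
#' @param samples sample table carrying `sample_id` and `dna_yield` (ng).
#' @param target which qPCR target to use (default "16S").
#' @return data.frame `sample_id`, `copies_16s`, `copies_per_ng`, `ct_sd`.
#' @export
compute_loads <- function(qpcr, samples, target = "16S") {
  q <- qpcr[qpcr$target == target, , drop = FALSE]
  if (nrow(q) == 0L) stop("no qPCR rows for target ", target)
  ct_cols <- grep("^ct[0-9]+$", names(q), value = TRUE)
  if (!length(ct_cols)) stop("no Ct replicate columns (ct1, ct2, ...)")
  res <- lapply(seq_len(nrow(q)), function(i) {
    ct <- as.numeric(q[i, ct_cols])
    ct <- ct[!is.na(ct)]
    copies <- gene_copy_number(ct, q$slope[i], q$intercept[i])
    yield <- samples$dna_yield[match(q$sample_id[i], samples$sample_id)]
    if (is.na(yield)) stop("no dna_yield for sample ", q$sample_id[i])
    data.frame(sample_id = q$sample_id[i], copies_16s = copies,
               copies_per_ng = bacterial_load(copies, yield)$copies_per_ng,
               ct_sd = if (length(ct) > 1) stats::sd(ct) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Paired nurse/forager load comparison
#'
#' Computes the per-colony nurse/forager load ratio (so a value of 2.6
#' means the forager load is 2.6-fold lower than the nurse load of the
#' same colony), their mean, and a two-sided paired Wilcoxon signed-rank
#' p-value on the loads.
#'
#' @param loads data.frame with `sample_id` and `copies_per_ng`.
#' @param samples paired sample table (see [validate_samples()]).
#' @return list with `ratios` (data.frame `colony_id`, `ratio`),
#'   `mean_ratio`, `p.value`, and `underpowered` (TRUE when fewer than 6
#'   pairs, where a two-sided exact signed-rank p below 0.05 is impossible).
#' @export
compare_paired_loads <- function(loads, samples) {
  validate_samples(samples)
  merged <- merge(samples, loads, by = "sample_id")
  if (nrow(merged) != nrow(samples)) stop("loads missing for some samples")
  nurse <- merged[merged$state == "nurse", ]
  forager <- merged[merged$state == "forager", ]
  forager <- forager[match(nurse$colony_id, forager$colony_id), ]
  ratios <- data.frame(colony_id = nurse$colony_id,
                       ratio = nurse$copies_per_ng / forager$copies_per_ng,
                       stringsAsFactors = FALSE)
  wt <- wilcoxon_signed_rank_paired(forager$copies_per_ng,
                                    nurse$copies_per_ng)
  list(ratios = ratios, mean_ratio = mean(ratios$ratio),
       p.value = wt$p.value, underpowered = nrow(ratios) < 6L)
}

#' Read a qPCR export CSV
#'
#' @param path CSV with columns `sample_id`, `target`, `ct1`..`ct3`,
#'   `slope`, `intercept`.
#' @return data.frame.
#' @export
read_qpcr_csv <- function(path) {
  as.data.frame(data.table::fread(path, sep = ","))
}
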