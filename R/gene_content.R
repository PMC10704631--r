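#' Filter assembled contigs
#'
#' Keeps contigs with length >= `min_len` and k-mer coverage >= `min_kcov`
#' (inclusive thresholds).
#'
#' @param records data.frame with columns `length` and `kmer_coverage`.
#' @param min_len minimum length in bp (default 500).
#' @param min_kcov minimum k-mer coverage (default 1).
#' @return filtered data.frame.
#' @export
filter_contigs <- function(records, min_len = 500, min_kcov = 1) {
  stopifnot(all(c("length", "kmer_coverage") %in% names(records)))
  records[records$length >= min_len & records$kmer_coverage >= min_kcov, ,
          drop = FALSE]
}

#' Filter predicted ORFs
#'
#' Keeps complete ORFs (Prodigal partial flag "00") of at least `min_len`
#' bp; partial ORFs are removed regardless of length.
#'
#' @param orfs data.frame with columns `partial` (character flag, "00" =
#'   complete) and `length` (bp).
#' @param min_len minimum ORF length (default 300).
#' @return filtered data.frame.
#' @export
filter_orfs <- function(orfs, min_len = 300) {
  stopifnot(all(c("partial", "length") %in% names(orfs)))
  orfs[as.character(orfs$partial) == "00" & orfs$length >= min_len, ,
       drop = FALSE]
}

#' Assign a contig to a species by ORF-hit voting
#'
#' Rule A: a species hit by at least 80% of the contig's ORFs wins. Rule
#' B: a species hit by at least 10% of the ORFs wins when no ORF hits any
#' other species. Contigs satisfying neither rule (non-unanimous) are
#' unassigned; a tie under rule A is also unassigned.
#'
#' @param orf_hits list (one element per ORF) of character vectors of
#'   species hit by that ORF (may be empty).
#' @param rule_a_frac,rule_b_frac the two voting fractions (defaults 0.8
#'   and 0.1).
#' @param strict_a when TRUE, rule A additionally requires that no ORF
#'   hits any other species (the stricter reading; default FALSE).
#' @return species label, or `NA_character_` when unassigned.
#' @export
assign_contig <- function(orf_hits, rule_a_frac = 0.8, rule_b_frac = 0.1,
                          strict_a = FALSE) {
  n <- length(orf_hits)
  if (n == 0L) stop("contig has no ORFs")
  species <- unique(unlist(orf_hits))
  if (!length(species)) return(NA_character_)
  frac <- vapply(species, function(sp)
    mean(vapply(orf_hits, function(h) sp %in% h, logical(1))), numeric(1))
  sole <- vapply(species, function(sp)
    all(vapply(orf_hits, function(h) length(h) == 0L || identical(h, sp) ||
                 all(h == sp), logical(1))), logical(1))
  a_ok <- frac >= rule_a_frac
  if (strict_a) a_ok <- a_ok & sole
  if (sum(a_ok) == 1L) return(species[a_ok])
  if (sum(a_ok) > 1L) return(NA_character_) # tie
  b_ok <- frac >= rule_b_frac & sole
  if (sum(b_ok) == 1L) return(species[b_ok])
  NA_character_
}

#' Assign all contigs from filtered blast hits
#'
#' @param hits filtered blast-hit data.frame (`query_orf`,
#'   `subject_species`); see [filter_blast_hits()].
#' @param orfs ORF table with `orf_id` and `contig_id` (post
#'   [filter_orfs()]).
#' @param ... passed to [assign_contig()].
#' @return data.frame `contig_id`, `species_id` (NA = unassigned/removed).
#' @export
assign_contigs <- function(hits, orfs, ...) {
  hit_map <- split(hits$subject_species, hits$query_orf)
  parts <- split(orfs$orf_id, orfs$contig_id)
  res <- vapply(parts, function(orf_ids) {
    oh <- lapply(orf_ids, function(o) unique(hit_map[[o]]))
    oh <- lapply(oh, function(h) if (is.null(h)) character(0) else h)
    assign_contig(oh, ...)
  }, character(1))
  data.frame(contig_id = names(parts), species_id = unname(res),
             stringsAsFactors = FALSE)
}

#' Aggregate ORF coverage into orthologous-group coverage
#'
#' Sums per-sample read coverage over the ORFs of each OG, restricted to
#' ORFs on contigs assigned to the OG's species. ORFs mapping to more
#' than one OG are an input error.
#'
#' @param orf_cov data.frame (`orf_id`, `sample_id`, `coverage`).
#' @param og_membership data.frame (`orf_id`, `og_id`, optionally
#'   `is_single_copy_core`).
#' @param orfs ORF table (`orf_id`, `contig_id`).
#' @param assignments contig assignments from [assign_contigs()].
#' @return data.frame (`species_id`, `og_id`, `is_single_copy_core`,
#'   `sample_id`, `coverage`).
#' @export
aggregate_og_coverage <- function(orf_cov, og_membership, orfs, assignments) {
  if (anyDuplicated(og_membership$orf_id)) {
    dup <- og_membership$orf_id[duplicated(og_membership$orf_id)]
    stop("ORF(s) in more than one OG: ", paste(unique(dup), collapse = ", "))
  }
  orfs$species_id <- assignments$species_id[
    match(orfs$contig_id, assignments$contig_id)]
  merged <- merge(orf_cov, orfs[, c("orf_id", "species_id")], by = "orf_id")
  merged <- merge(merged, og_membership, by = "orf_id")
  merged <- merged[!is.na(merged$species_id), , drop = FALSE]
  if (!"is_single_copy_core" %in% names(merged)) {
    merged$is_single_copy_core <- FALSE
  }
  dt <- data.table::as.data.table(merged)
  out <- dt[, list(coverage = sum(coverage),
                   is_single_copy_core = any(is_single_copy_core)),
            by = c("species_id", "og_id", "sample_id")]
  as.data.frame(out[, c("species_id", "og_id", "is_single_copy_core",
                        "sample_id", "coverage"), with = FALSE])
}

#' Normalize OG coverage by single-copy core OGs
#'
#' For each (species, sample), multiplies every OG's coverage by
#' `constant / sum(core-OG coverage)`, so the summed coverage of the
#' single-copy core OGs becomes exactly `constant`. (species, sample)
#' pairs with zero core coverage are dropped with a warning. Idempotent.
#'
#' @param mat OG-coverage data.frame (`species_id`, `og_id`,
#'   `is_single_copy_core`, `sample_id`, `coverage`).
#' @param constant normalization constant (default 10000).
#' @return data.frame like `mat` with normalized `coverage`.
#' @export
normalize_og_coverage <- function(mat, constant = 10000) {
  parts <- split(mat, list(mat$species_id, mat$sample_id), drop = TRUE)
  out <- lapply(parts, function(df) {
    core_sum <- sum(df$coverage[df$is_single_copy_core])
    if (core_sum <= 0) {
      warning("zero core coverage for ", df$species_id[1], " / ",
              df$sample_id[1], "; dropped")
      return(NULL)
    }
    df$coverage <- df$coverage * constant / core_sum
    df
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Differential OG content between host states
#'
#' For each (species, OG): a paired Wilcoxon signed-rank test on the
#' normalized coverage of the nurse versus forager sample of each colony
#' (OGs absent from a sample count as coverage 0), the log2 fold change
#' of the forager mean over the nurse mean, and q-values computed jointly
#' across all OGs of all species. An OG is significant when q <
#' `q_threshold` and |log2FC| >= `lfc_threshold`; infinite fold changes
#' (presence/absence OGs) satisfy the fold criterion.
#'
#' @param norm_mat normalized OG-coverage data.frame.
#' @param samples paired sample table.
#' @param q_threshold,lfc_threshold the significance rule (defaults 0.05
#'   and 1).
#' @param test_core include single-copy core OGs in testing (default
#'   FALSE; they are the normalization anchor and flat by construction).
#' @return data.frame per (species, OG): `species_id`, `og_id`,
#'   `mean_nurse`, `mean_forager`, `log2fc`, `p`, `q`, `significant`,
#'   `enriched_state`.
#' @export
differential_ogs <- function(norm_mat, samples, q_threshold = 0.05,
                             lfc_threshold = 1, test_core = FALSE) {
  validate_samples(samples)
  nurse <- samples[samples$state == "nurse", ]
  forager <- samples[samples$state == "forager", ]
  forager <- forager[match(nurse$colony_id, forager$colony_id), ]
  if (!test_core) {
    norm_mat <- norm_mat[!norm_mat$is_single_copy_core, , drop = FALSE]
  }
  dt <- data.table::as.data.table(norm_mat)
  wide <- data.table::dcast(dt, species_id + og_id ~ sample_id,
                            value.var = "coverage", fill = 0)
  miss <- setdiff(samples$sample_id, names(wide))
  for (m in miss) wide[[m]] <- 0
  nm <- as.matrix(wide[, nurse$sample_id, with = FALSE])
  fm <- as.matrix(wide[, forager$sample_id, with = FALSE])
  res <- data.frame(species_id = wide$species_id, og_id = wide$og_id,
                    mean_nurse = rowMeans(nm), mean_forager = rowMeans(fm),
                    stringsAsFactors = FALSE)
  res$log2fc <- log2(res$mean_forager / res$mean_nurse)
  res$p <- vapply(seq_len(nrow(res)), function(i)
    wilcoxon_signed_rank_paired(fm[i, ], nm[i, ])$p.value, numeric(1))
  res$q <- qvalues(res$p)
  fold_ok <- !is.nan(res$log2fc) & abs(res$log2fc) >= lfc_threshold
  res$significant <- res$q < q_threshold & fold_ok
  res$enriched_state <- ifelse(!res$significant, NA_character_,
                               ifelse(res$log2fc > 0, "forager", "nurse"))
  res
}

#' COG-category enrichment among significant OGs
#'
#' For each species and COG category, a two-sided Fisher exact test on
#' the 2x2 table {significant vs not} x {category vs other}, with
#' q-values across all (species, category) tests.
#'
#' @param results output of [differential_ogs()].
#' @param annotations data.frame (`og_id`, `cog_category`; one-letter
#'   classes, NA for unannotated).
#' @return data.frame `species_id`, `cog_category`, `n_sig_in`,
#'   `n_sig_out`, `n_other_in`, `n_other_out`, `odds_ratio`, `p`, `q`.
#' @export
cog_enrichment <- function(results, annotations) {
  results$cog_category <- annotations$cog_category[
    match(results$og_id, annotations$og_id)]
  parts <- split(results, results$species_id)
  rows <- list()
  for (df in parts) {
    cats <- sort(unique(stats::na.omit(df$cog_category)))
    for (cc in cats) {
      in_cat <- !is.na(df$cog_category) & df$cog_category == cc
      tab <- matrix(c(sum(df$significant & in_cat),
                      sum(df$significant & !in_cat),
                      sum(!df$significant & in_cat),
                      sum(!df$significant & !in_cat)), 2, byrow = TRUE)
      ft <- fisher_exact_2x2(tab)
      rows[[length(rows) + 1L]] <- data.frame(
        species_id = df$species_id[1], cog_category = cc,
        n_sig_in = tab[1, 1], n_sig_out = tab[1, 2],
        n_other_in = tab[2, 1], n_other_out = tab[2, 2],
        odds_ratio = ft$odds_ratio, p = ft$p.value,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(species_id = character(), cog_category = character(),
                      p = numeric(), q = numeric()))
  }
  out$q <- qvalues(out$p)
  rownames(out) <- NULL
  out
}
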