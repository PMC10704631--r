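#' Alignment match length from a CIGAR string
#'
#' Sums the lengths of the alignment-match operations (`M`, `=`, `X`) of
#' each CIGAR string. Soft/hard clips, insertions and deletions do not
#' count. bwa-mem emits `M` operations that include mismatched bases, so
#' this is the "alignment length" a mapping filter acts on; mismatches are
#' handled separately through the NM tag.
#'
#' @param cigar character vector of CIGAR strings.
#' @return integer vector of match lengths.
#' @examples
#' cigar_match_length(c("100M", "30M20S", "25M10I25M")) # 100 30 50
#' @export
cigar_match_length <- function(cigar) {
  bad <- !grepl("^([0-9]+[MIDNSHP=X])+$", cigar)
  if (any(bad)) {
    stop("malformed CIGAR: ", paste(unique(cigar[bad]), collapse = ", "))
  }
  ops <- GenomicAlignments::explodeCigarOps(cigar)
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)
  vapply(seq_along(cigar), function(i) {
    sum(lens[[i]][ops[[i]] %in% c("M", "=", "X")])
  }, integer(1))
}

#' Filter alignment records
#'
#' Applies the mapping filters used throughout the pipeline: alignments
#' with 50 or fewer matched bases (per [cigar_match_length()]) are removed,
#' supplementary/chimeric alignments (SAM flag 0x800) are removed, and in
#' SNV mode records with more than `max_mismatches` mismatches (NM tag)
#' are removed. Idempotent.
#'
#' @param records data.frame with columns `cigar` and `flag`, plus `nm`
#'   when `max_mismatches` is set.
#' @param min_matches minimum match length to keep (default 51, i.e. strictly
#'   more than 50 matches).
#' @param max_mismatches optional NM ceiling (SNV mode uses 5); `NULL`
#'   disables the mismatch filter.
#' @param drop_supplementary drop records with flag bit 0x800 (default TRUE).
#' @return the filtered data.frame.
#' @export
filter_alignments <- function(records, min_matches = 51L,
                              max_mismatches = NULL,
                              drop_supplementary = TRUE) {
  stopifnot(is.data.frame(records), all(c("cigar", "flag") %in% names(records)))
  if (nrow(records) == 0L) return(records)
  keep <- cigar_match_length(records$cigar) >= min_matches
  if (drop_supplementary) {
    keep <- keep & bitwAnd(as.integer(records$flag), 0x800L) == 0L
  }
  if (!is.null(max_mismatches)) {
    if (!"nm" %in% names(records) || anyNA(records$nm)) {
      stop("NM (mismatch count) required when max_mismatches is set")
    }
    keep <- keep & records$nm <= max_mismatches
  }
  records[keep, , drop = FALSE]
}

#' Read alignments from a SAM or BAM file
#'
#' Returns the fields [filter_alignments()] needs (read id, target, flag,
#' CIGAR, NM tag). SAM input is converted on the fly.
#'
#' @param path SAM or BAM file.
#' @return data.frame with columns `read_id`, `target_id`, `flag`, `cigar`,
#'   `nm` (NA when the tag is absent).
#' @export
read_sam_alignments <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  bam <- path
  if (!grepl("\\.bam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  res <- Rsamtools::scanBam(
    bam,
    param = Rsamtools::ScanBamParam(
      what = c("qname", "rname", "flag", "cigar"), tag = "NM"))[[1]]
  data.frame(read_id = res$qname,
             target_id = as.character(res$rname),
             flag = res$flag,
             cigar = res$cigar,
             nm = if (is.null(res$tag$NM)) NA_integer_ else res$tag$NM,
             stringsAsFactors = FALSE)
}

#' Filter tabular blast hits
#'
#' Strict thresholds as conventionally applied to outfmt-6-style hits:
#' evalue < `max_evalue`, pident > `min_pident`, qcovs > `min_qcovs`.
#'
#' @param records data.frame with columns `evalue`, `pident`, `qcovs`.
#' @param max_evalue,min_pident,min_qcovs thresholds (defaults 1e-5, 50, 50).
#' @return the filtered data.frame.
#' @export
filter_blast_hits <- function(records, max_evalue = 1e-5, min_pident = 50,
                              min_qcovs = 50) {
  stopifnot(all(c("evalue", "pident", "qcovs") %in% names(records)))
  records[records$evalue < max_evalue &
            records$pident > min_pident &
            records$qcovs > min_qcovs, , drop = FALSE]
}

# The allele-observation layout used across the package: one row per
# (species, core-genome site, sample) with per-base read counts.
ALLELE_BASES <- c("A", "C", "G", "T")

#' Read pooled allele observations from a VCF
#'
#' Parses a VCF with per-allele read counts (FORMAT fields `RO` for the
#' reference allele and `AO`, one value per alternate allele), decomposes
#' multi-allelic records into one observation per allele, keeps only
#' single-nucleotide alleles (indels and complex alleles are dropped), and
#' restricts sites to the supplied core regions. Coordinates in the
#' returned table are 1-based (VCF convention).
#'
#' @param vcf_path VCF file (v4.2, plain text or bgzipped).
#' @param core_regions optional `GRanges` (or data.frame with `chrom`,
#'   `start`, `end`, 0-based half-open) restricting sites; `NULL` keeps all.
#' @return data.frame with columns `species_id` (the VCF contig), `site`,
#'   `ref_allele`, `sample_id`, `A`, `C`, `G`, `T`, `depth`.
#' @export
read_allele_observations <- function(vcf_path, core_regions = NULL) {
  vcf <- VariantAnnotation::readVcf(vcf_path)
  geno <- VariantAnnotation::geno(vcf)
  if (!all(c("RO", "AO") %in% names(geno))) {
    stop("VCF must carry RO and AO per-allele read counts")
  }
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  ref <- as.character(rr$REF)
  alts <- VariantAnnotation::alt(vcf) # DNAStringSetList, one set per record
  samples <- colnames(vcf)
  ro <- geno$RO
  ao <- geno$AO

  out <- vector("list", length(rr))
  for (i in seq_along(rr)) {
    if (nchar(ref[i]) != 1L || !ref[i] %in% ALLELE_BASES) next
    alt_i <- as.character(alts[[i]])
    counts <- matrix(0, nrow = length(samples), ncol = 4,
                     dimnames = list(samples, ALLELE_BASES))
    counts[, ref[i]] <- as.numeric(ro[i, ])
    for (k in seq_along(alt_i)) {
      a <- alt_i[k]
      if (nchar(a) != 1L || !a %in% ALLELE_BASES) next # drop non-SNV alleles
      ao_ik <- vapply(seq_along(samples), function(s) {
        v <- ao[i, s][[1]]
        if (length(v) >= k && !is.na(v[k])) as.numeric(v[k]) else 0
      }, numeric(1))
      counts[, a] <- counts[, a] + ao_ik
    }
    out[[i]] <- data.frame(species_id = chrom[i], site = pos[i],
                           ref_allele = ref[i], sample_id = samples,
                           counts, stringsAsFactors = FALSE, row.names = NULL)
  }
  obs <- do.call(rbind, out)
  if (is.null(obs)) {
    obs <- data.frame(species_id = character(), site = integer(),
                      ref_allele = character(), sample_id = character(),
                      A = numeric(), C = numeric(), G = numeric(),
                      T = numeric())
  }
  if (!is.null(core_regions)) {
    gr <- if (inherits(core_regions, "GRanges")) core_regions else
      GenomicRanges::GRanges(core_regions$chrom,
                             IRanges::IRanges(core_regions$start + 1L,
                                              core_regions$end))
    sites <- GenomicRanges::GRanges(obs$species_id,
                                    IRanges::IRanges(obs$site, obs$site))
    obs <- obs[IRanges::overlapsAny(sites, gr), , drop = FALSE]
  }
  obs$depth <- obs$A + obs$C + obs$G + obs$T
  rownames(obs) <- NULL
  obs
}

#' Write allele observations as a minimal multi-sample VCF
#'
#' One record per site with all observed alternate alleles and per-sample
#' `RO:AO` counts (VCF v4.2). The inverse of [read_allele_observations()]
#' on the package's own tables.
#'
#' @param obs allele-observation data.frame (see
#'   [read_allele_observations()] for the layout).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_allele_vcf <- function(obs, path) {
  samples <- sort(unique(obs$sample_id))
  key <- interaction(obs$species_id, obs$site, drop = TRUE)
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=RO,Number=1,Type=Integer,Description=\"Reference allele observation count\">",
    "##FORMAT=<ID=AO,Number=A,Type=Integer,Description=\"Alternate allele observation count\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  body <- vapply(split(obs, key), function(df) {
    ref <- df$ref_allele[1]
    tot <- colSums(df[, ALLELE_BASES, drop = FALSE])
    alt <- setdiff(ALLELE_BASES[tot > 0], ref)
    if (!length(alt)) alt <- setdiff(ALLELE_BASES, ref)[1] # monomorphic site
    fields <- vapply(samples, function(s) {
      row <- df[df$sample_id == s, , drop = FALSE]
      if (nrow(row) == 0L) {
        cnt <- stats::setNames(rep(0, 4), ALLELE_BASES)
      } else {
        cnt <- unlist(row[1, ALLELE_BASES])
      }
      paste0(cnt[ref], ":", paste(cnt[alt], collapse = ","))
    }, character(1))
    paste(c(df$species_id[1], df$site[1], ".", ref,
            paste(alt, collapse = ","), ".", "PASS", ".", "RO:AO", fields),
          collapse = "\t")
  }, character(1))
  ord <- order(vapply(split(obs, key), function(df) df$species_id[1],
                      character(1)),
               vapply(split(obs, key), function(df) df$site[1], numeric(1)))
  writeLines(c(header, body[ord]), path)
  invisible(path)
}

#' Read core-gene regions from a BED file
#'
#' @param path BED file (0-based half-open) of single-copy core-gene
#'   intervals on the per-species core-genome coordinate system.
#' @return `GRanges`.
#' @export
read_core_regions_bed <- function(path) {
  rtracklayer::import(path, format = "BED")
}

#' Read and write tab-separated tables
#'
#' Thin wrappers over data.table with the package's conventions (header
#' row, no quoting, tab separator).
#'
#' @param path file path.
#' @param x data.frame to write.
#' @return `read_tsv_table`: a data.frame; `write_tsv_table`: `path`,
#'   invisibly.
#' @export
read_tsv_table <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
}

#' @rdname read_tsv_table
#' @export
write_tsv_table <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Validate a paired sample table
#'
#' Checks the paired two-state design: exactly one nurse and one forager
#' record per colony, positive pool masses and DNA yields when present.
#'
#' @param samples data.frame with columns `sample_id`, `state`
#'   ("nurse"/"forager"), `colony_id`, `location_id`.
#' @return `samples`, invisibly, or an error describing the defect.
#' @export
validate_samples <- function(samples) {
  need <- c("sample_id", "state", "colony_id", "location_id")
  if (!all(need %in% names(samples))) {
    stop("sample table needs columns: ", paste(need, collapse = ", "))
  }
  if (!all(samples$state %in% c("nurse", "forager"))) {
    stop("state must be 'nurse' or 'forager'")
  }
  tab <- table(samples$colony_id, samples$state)
  if (!all(tab == 1L)) {
    bad <- rownames(tab)[rowSums(tab != 1L) > 0]
    stop("unpaired colonies: ", paste(bad, collapse = ", "))
  }
  for (col in intersect(c("pool_mass", "dna_yield"), names(samples))) {
    if (any(samples[[col]] <= 0)) stop(col, " must be positive")
  }
  invisible(samples)
}
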