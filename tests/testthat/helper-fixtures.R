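# Shared in-code fixtures for the test suite. Everything is generated at
# test time; nothing is read from disk except files the tests write.

# paired sample table: n_pairs colonies over up to 5 locations
make_samples <- function(n_pairs = 15L, n_locations = 5L) {
  loc <- rep(seq_len(n_locations), length.out = n_pairs)
  colony <- sprintf("L%dC%d", loc, stats::ave(loc, loc, FUN = seq_along))
  data.frame(
    sample_id = c(paste0("N_", colony), paste0("F_", colony)),
    state = rep(c("nurse", "forager"), each = n_pairs),
    colony_id = rep(colony, 2),
    location_id = rep(sprintf("L%d", loc), 2),
    stringsAsFactors = FALSE)
}

# allele-observation rows from a compact spec: list of site -> named counts
make_obs <- function(counts_by_site, sample_id = "S1", species_id = "sp1",
                     ref = "T") {
  rows <- lapply(seq_along(counts_by_site), function(i) {
    cnt <- counts_by_site[[i]]
    full <- stats::setNames(rep(0, 4), c("A", "C", "G", "T"))
    full[names(cnt)] <- cnt
    data.frame(species_id = species_id, site = i, ref_allele = ref,
               sample_id = sample_id, A = full[["A"]], C = full[["C"]],
               G = full[["G"]], T = full[["T"]],
               depth = sum(full), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# detection matrix (sites x ACGT) from a list of allele-set strings
make_det <- function(allele_sets) {
  m <- matrix(FALSE, length(allele_sets), 4,
              dimnames = list(as.character(seq_along(allele_sets)),
                              c("A", "C", "G", "T")))
  for (i in seq_along(allele_sets)) {
    m[i, strsplit(allele_sets[[i]], "")[[1]]] <- TRUE
  }
  m
}

# brute-force shared-polymorphic-site oracle working on explicit sets
oracle_shared <- function(sets1, sets2) {
  poly1 <- vapply(sets1, function(s) length(s) >= 2, logical(1))
  poly2 <- vapply(sets2, function(s) length(s) >= 2, logical(1))
  universe <- which(poly1 | poly2)
  shared <- sum(vapply(universe, function(i)
    length(intersect(sets1[[i]], sets2[[i]])) >= 2, logical(1)))
  list(n_shared = shared, n_union = length(universe))
}

# exact two-sided signed-rank p by enumerating all 2^n sign patterns
oracle_wilcoxon_exact <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  W_all <- signs %*% r
  p_low <- mean(W_all <= W_obs)
  p_high <- mean(W_all >= W_obs)
  min(1, 2 * min(p_low, p_high))
}
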