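#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test for paired observations. Zero differences are
#' dropped (the classical Wilcoxon convention). When the number of non-zero
#' differences is at most 25 and the absolute differences carry no tied
#' ranks, the p-value is computed from the exact null distribution of the
#' rank sum; otherwise a normal approximation with continuity and tie
#' correction is used.
#'
#' @param x,y numeric vectors of equal length (e.g. forager and nurse values
#'   of the same colonies, in matching order).
#' @param exact_max largest number of non-zero differences for which the
#'   exact null distribution is used (default 25, covering the study design
#'   of 15 pairs). With tied ranks the exact distribution is computed by a
#'   dynamic program over sign patterns conditional on the observed ranks.
#' @return list with `statistic` (W, the positive-rank sum), `p.value`
#'   (two-sided), and `n` (non-zero differences used).
#' @examples
#' wilcoxon_signed_rank_paired(c(1, 2, 3), c(0, 0, 0))$p.value # 0.25
#' @export
wilcoxon_signed_rank_paired <- function(x, y, exact_max = 25L) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 1L) stop("need at least one pair")
  d <- x - y
  d <- d[!is.na(d) & d != 0]
  n <- length(d)
  if (n == 0L) {
    return(list(statistic = 0, p.value = 1, n = 0L))
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exact_max) {
    # exact null: convolve the sign-flip distribution of the (possibly
    # tied) ranks; doubling makes all ranks integer
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    dist <- numeric(total + 1L) # counts over achievable 2W values
    dist[1] <- 1
    for (rk in r2) {
      shifted <- c(numeric(rk), dist[seq_len(total + 1L - rk)])
      dist <- dist + shifted
    }
    dist <- dist / 2^n
    w2 <- as.integer(round(2 * W))
    p_low <- sum(dist[seq_len(w2 + 1L)])
    p_high <- sum(dist[seq(w2 + 1L, total + 1L)])
    p <- 2 * min(p_low, p_high)
  } else {
    mu <- n * (n + 1) / 4
    tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tab^3 - tab) / 48
    cc <- if (W == mu) 0 else sign(W - mu) * 0.5
    z <- (W - mu - cc) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(statistic = W, p.value = min(p, 1), n = n)
}

#' Storey q-values with Benjamini-Hochberg fallback
#'
#' Converts p-values to q-values (positive false discovery rate). For m >=
#' 100 tests the null proportion pi0 is estimated on the lambda grid
#' 0.05..0.95 with cubic-spline smoothing (Storey & Tibshirani); for fewer
#' tests pi0 is fixed at 1, which reduces the procedure to
#' Benjamini-Hochberg. Output is monotone non-decreasing in p and bounded
#' by 1.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return numeric vector of q-values, same order as `p`.
#' @export
qvalues <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1] and be non-missing")
  }
  m <- length(p)
  if (m < 100L) {
    pi0 <- 1
  } else {
    lambda <- seq(0.05, 0.95, by = 0.05)
    pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
    fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
    pi0 <- stats::predict(fit, x = max(lambda))$y
    pi0 <- min(max(pi0, 1 / m), 1)
  }
  o <- order(p)
  q_sorted <- pi0 * m * p[o] / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value summing hypergeometric probabilities of all tables
#' with the observed margins whose probability does not exceed the observed
#' table's (with a small relative tolerance, as is conventional).
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return list with `odds_ratio` (sample odds ratio ad/bc, possibly `Inf`
#'   or `NaN` for zero cells) and `p.value`.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("need a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("cells must be non-negative integers")
  }
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  orat <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  if (r1 == 0 || r2 == 0 || c1 == 0 || sum(tab[, 2]) == 0) {
    return(list(odds_ratio = orat, p.value = 1))
  }
  support <- max(0, c1 - r2):min(c1, r1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  list(odds_ratio = orat, p.value = min(p, 1))
}

#' Bray-Curtis dissimilarity matrix
#'
#' d(x, y) = 1 - 2 * sum(min(x, y)) / (sum(x) + sum(y)), computed between
#' all row pairs of a non-negative abundance matrix.
#'
#' @param mat numeric matrix, samples in rows.
#' @return symmetric matrix of dissimilarities with zero diagonal and the
#'   row names of `mat` as labels.
#' @export
bray_curtis <- function(mat) {
  mat <- as.matrix(mat)
  if (any(mat < 0)) stop("abundances must be non-negative")
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  rs <- rowSums(mat)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      denom <- rs[i] + rs[j]
      if (denom == 0) {
        warning("two all-zero rows: distance set to 0")
        dij <- 0
      } else {
        dij <- 1 - 2 * sum(pmin(mat[i, ], mat[j, ])) / denom
      }
      d[i, j] <- d[j, i] <- dij
    }
  }
  d
}

#' Principal coordinate analysis (classical MDS)
#'
#' Gower double-centering of -D^2/2 followed by eigendecomposition. Axes
#' with eigenvalues at or below a numerical tolerance are dropped from the
#' coordinates; negative eigenvalues are reported unaltered (no Lingoes or
#' Cailliez correction).
#'
#' @param d symmetric distance matrix with zero diagonal.
#' @param tol eigenvalues below `tol * max(eigenvalue)` are treated as null.
#' @return list with `coordinates` (n x k matrix, columns scaled by
#'   sqrt(eigenvalue)), `eigenvalues` (all n of them, decreasing), and
#'   `proportion_explained` (positive eigenvalues over their sum).
#' @export
pcoa <- function(d, tol = 1e-9) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n != ncol(d) || max(abs(d - t(d))) > 1e-8) {
    stop("distance matrix must be square and symmetric")
  }
  G <- gower_center(d)
  eig <- eigen(G, symmetric = TRUE)
  ev <- eig$values
  thr <- tol * max(abs(ev), 1)
  keep <- which(ev > thr)
  coords <- if (length(keep)) {
    sweep(eig$vectors[, keep, drop = FALSE], 2, sqrt(ev[keep]), "*")
  } else {
    matrix(0, n, 0)
  }
  rownames(coords) <- rownames(d)
  if (ncol(coords)) colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  pos <- ev[ev > thr]
  list(coordinates = coords,
       eigenvalues = ev,
       proportion_explained = if (length(pos)) pos / sum(pos) else numeric(0))
}

# Gower-centered inner-product matrix of a distance matrix:
# G = J (-D^2/2) J with J = I - 11'/n. tr(G) is the total sum of squares.
gower_center <- function(d) {
  n <- nrow(d)
  A <- -0.5 * d^2
  J <- diag(n) - matrix(1 / n, n, n)
  J %*% A %*% J
}

# Hat (projection) matrix of a model matrix via QR; returns the projector,
# its rank, and the pivoted column indices left out when rank-deficient.
hat_matrix <- function(X) {
  qr_x <- qr(X)
  r <- qr_x$rank
  Q <- qr.Q(qr_x)[, seq_len(r), drop = FALSE]
  list(H = tcrossprod(Q), rank = r,
       dropped = if (r < ncol(X)) colnames(X)[qr_x$pivot[(r + 1):ncol(X)]]
                 else character(0))
}

#' Marginal-term PERMANOVA
#'
#' Permutational multivariate analysis of variance on a distance matrix,
#' partitioning sums of squares by the marginal (type-III-style) effect of
#' each term: SS(term) = tr(H_full G) - tr(H_reduced G) where G is the
#' Gower-centered inner-product matrix and H are hat matrices of the full
#' and the term-deleted design. Pseudo-F statistics are referenced against
#' free permutations of the sample labels; omega-squared effect sizes are
#' reported as (SS_term - df_term * MS_resid) / (SS_total + MS_resid).
#'
#' @param d symmetric distance matrix with labels matching
#'   `metadata`'s rows (or its `sample_id` column).
#' @param metadata data.frame of factors; one row per sample.
#' @param formula right-hand-side formula of terms to test
#'   (default `~ Host + Location`).
#' @param n_perm number of permutations (default 999).
#' @param seed optional integer seed for the permutation stream.
#' @return data.frame with one row per term plus Residual and Total rows:
#'   `term`, `df`, `SS`, `R2`, `omega2`, `F`, `p`.
#' @export
permanova_marginal <- function(d, metadata, formula = ~ Host + Location,
                               n_perm = 999L, seed = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 4L) stop("need at least 4 samples")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix must be symmetric")
  if (!is.null(rownames(d)) && "sample_id" %in% names(metadata)) {
    metadata <- metadata[match(rownames(d), metadata$sample_id), , drop = FALSE]
  }
  if (nrow(metadata) != n) stop("metadata rows must match distance matrix")
  if (!is.null(seed)) set.seed(seed)

  terms_obj <- stats::terms(formula)
  term_labels <- attr(terms_obj, "term.labels")
  if (!length(term_labels)) stop("formula has no terms")
  mf <- stats::model.frame(formula, data = metadata)
  if (anyNA(mf)) stop("factor columns must be complete")
  X_full <- stats::model.matrix(formula, data = mf)
  assign_full <- attr(X_full, "assign")
  full <- hat_matrix(X_full)
  if (full$rank < ncol(X_full)) {
    stop("aliased (confounded) design columns: ",
         paste(full$dropped, collapse = ", "))
  }
  G <- gower_center(d)
  ss_total <- sum(diag(G))
  ss_resid_fun <- function(Gp, H) sum(diag(Gp)) - sum(H * Gp)

  # per-term reduced-design hat matrices (term deleted, everything else kept)
  reduced <- lapply(seq_along(term_labels), function(k) {
    keep <- assign_full != k
    hat_matrix(X_full[, keep, drop = FALSE])
  })
  df_terms <- vapply(seq_along(term_labels),
                     function(k) full$rank - reduced[[k]]$rank, numeric(1))
  df_resid <- n - full$rank
  if (df_resid <= 0) stop("no residual degrees of freedom")

  stat_fun <- function(Gp) {
    ss_r <- ss_resid_fun(Gp, full$H)
    ss_t <- vapply(reduced, function(rd) sum(full$H * Gp) - sum(rd$H * Gp),
                   numeric(1))
    Fv <- (ss_t / df_terms) / (ss_r / df_resid)
    list(ss = ss_t, ss_resid = ss_r, F = Fv)
  }
  obs <- stat_fun(G)

  exceed <- rep(0L, length(term_labels))
  for (b in seq_len(n_perm)) {
    p <- sample.int(n)
    Fp <- stat_fun(G[p, p])$F
    exceed <- exceed + (Fp >= obs$F - 1e-12)
  }
  pvals <- (1 + exceed) / (1 + n_perm)

  ms_resid <- obs$ss_resid / df_resid
  omega2 <- (obs$ss - df_terms * ms_resid) / (ss_total + ms_resid)
  out <- data.frame(
    term = c(term_labels, "Residual", "Total"),
    df = c(df_terms, df_resid, n - 1),
    SS = c(obs$ss, obs$ss_resid, ss_total),
    R2 = c(obs$ss / ss_total, obs$ss_resid / ss_total, 1),
    omega2 = c(omega2, NA, NA),
    F = c(obs$F, NA, NA),
    p = c(pvals, NA, NA),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
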