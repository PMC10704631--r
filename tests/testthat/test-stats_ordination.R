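test_that("signed-rank test matches hand-derived exact values", {
  expect_equal(wilcoxon_signed_rank_paired(1:5, 1:5)$p.value, 1)
  # n = 3, all positive differences: 2 / 2^3
  expect_equal(wilcoxon_signed_rank_paired(c(1, 2, 3), c(0, 0, 0))$p.value,
               0.25)
  # n = 15, all one sign: 2 / 2^15
  expect_equal(wilcoxon_signed_rank_paired(rep(0, 15), 1:15)$p.value,
               2 / 2^15)
  expect_equal(wilcoxon_signed_rank_paired(c(0, 0), c(0, 0))$p.value, 1)
})

test_that("signed-rank test agrees with stats::wilcox.test", {
  set.seed(101)
  for (i in 1:20) {
    n <- sample(5:20, 1)
    x <- rnorm(n); y <- rnorm(n)
    ours <- wilcoxon_signed_rank_paired(x, y)
    ref <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                               correct = TRUE))
    expect_equal(ours$p.value, ref$p.value, tolerance = 1e-10,
                 info = paste("iteration", i))
  }
  # with tied ranks the exact sign-pattern distribution is used
  x <- c(1, 1, 2, 2, 3, 3, -4, 4); y <- rep(0, 8)
  ours <- wilcoxon_signed_rank_paired(x, y)
  expect_equal(ours$p.value, oracle_wilcoxon_exact(x, y), tolerance = 1e-12)
  # beyond the exact cutoff: normal approximation with tie correction
  set.seed(3)
  xl <- sample(1:6, 30, replace = TRUE); yl <- rep(0, 30)
  ours_l <- wilcoxon_signed_rank_paired(xl, yl)
  ref_l <- suppressWarnings(stats::wilcox.test(xl, yl, paired = TRUE))
  expect_equal(ours_l$p.value, ref_l$p.value, tolerance = 1e-10)
})

test_that("qvalues: BH fallback, monotonicity, Storey <= BH", {
  expect_identical(qvalues(numeric(0)), numeric(0))
  expect_equal(qvalues(rep(1, 10)), rep(1, 10))
  expect_equal(qvalues(0.03), 0.03) # single p, pi0 = 1
  set.seed(7)
  p <- runif(50)
  expect_equal(qvalues(p), stats::p.adjust(p, "BH")) # m < 100 reduces to BH
  p_big <- runif(1000)
  q_st <- qvalues(p_big)
  q_bh <- stats::p.adjust(p_big, "BH")
  expect_true(all(q_st <= q_bh + 1e-12))
  expect_true(all(diff(q_st[order(p_big)]) >= -1e-12))
  expect_true(all(q_st >= 0 & q_st <= 1))
  expect_error(qvalues(c(0.5, 1.2)), "0, 1")
})

test_that("fisher exact matches enumeration and stats::fisher.test", {
  expect_equal(fisher_exact_2x2(matrix(c(2, 0, 0, 2), 2))$p.value, 1 / 3)
  expect_equal(fisher_exact_2x2(matrix(c(1, 1, 1, 1), 2))$p.value, 1)
  expect_equal(fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2))$p.value, 1)
  set.seed(11)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 5), 2)
    ours <- fisher_exact_2x2(tab)$p.value
    ref <- stats::fisher.test(tab)$p.value
    expect_equal(ours, ref, tolerance = 1e-9, info = paste(tab, collapse = ","))
  }
})

test_that("bray-curtis matches hand values and vegan", {
  expect_equal(bray_curtis(rbind(c(6, 2), c(2, 2)))[1, 2], 1 / 3)
  expect_equal(bray_curtis(rbind(c(1, 0), c(0, 1)))[1, 2], 1) # disjoint
  expect_equal(bray_curtis(rbind(c(3, 4), c(3, 4)))[1, 2], 0) # identical
  skip_if_not_installed("vegan")
  set.seed(5)
  m <- matrix(runif(40), 8)
  expect_equal(as.vector(as.dist(bray_curtis(m))),
               as.vector(vegan::vegdist(m, "bray")), tolerance = 1e-12)
})

test_that("pcoa: hand 2x2 case, Euclidean exactness, ape agreement", {
  res <- pcoa(matrix(c(0, 2, 2, 0), 2))
  expect_equal(sort(res$coordinates[, 1]), c(-1, 1))
  expect_equal(res$eigenvalues[1], 2)
  expect_equal(pcoa(matrix(0, 3, 3))$coordinates, matrix(0, 3, 0),
               ignore_attr = TRUE)
  # distances among plane points are reproduced exactly
  set.seed(13)
  pts <- matrix(rnorm(20), 10)
  d <- as.matrix(dist(pts))
  coords <- pcoa(d)$coordinates
  expect_equal(as.matrix(dist(coords)), d, ignore_attr = TRUE,
               tolerance = 1e-9)
  skip_if_not_installed("ape")
  ref <- ape::pcoa(d)
  ours <- pcoa(d)
  k <- ncol(ref$vectors)
  expect_equal(abs(ours$coordinates[, 1:k]), abs(ref$vectors[, 1:k]),
               ignore_attr = TRUE, tolerance = 1e-6)
  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("marginal PERMANOVA matches direct SS oracle and vegan", {
  # single-term oracle on 6 samples: SS_between from group means of the
  # Gower-centered matrix; here computed independently from distances
  set.seed(17)
  pts <- matrix(rnorm(12), 6)
  g <- factor(rep(c("a", "b"), each = 3))
  d <- as.matrix(dist(pts))
  meta <- data.frame(Host = g)
  res <- permanova_marginal(d, meta, formula = ~ Host, n_perm = 99, seed = 1)
  # direct computation: for Euclidean distances SS are ANOVA sums of squares
  ss_total <- sum(scale(pts, scale = FALSE)^2)
  fit <- lm(pts ~ g)
  ss_resid <- sum(fit$residuals^2)
  expect_equal(res$SS[res$term == "Total"], ss_total, tolerance = 1e-9)
  expect_equal(res$SS[res$term == "Residual"], ss_resid, tolerance = 1e-9)
  expect_equal(res$SS[res$term == "Host"], ss_total - ss_resid,
               tolerance = 1e-9)

  skip_if_not_installed("vegan")
  set.seed(23)
  n <- 16
  meta2 <- data.frame(Host = factor(rep(c("n", "f"), 8)),
                      Location = factor(rep(1:4, each = 4)))
  d2 <- as.matrix(vegan::vegdist(matrix(runif(n * 5) +
    rep(as.integer(meta2$Host) / 4, 5), n), "bray"))
  ours <- permanova_marginal(d2, meta2, n_perm = 99, seed = 2)
  ref <- vegan::adonis2(as.dist(d2) ~ Host + Location, data = meta2,
                        permutations = 99, by = "margin")
  expect_equal(ours$SS[1:2], ref$SumOfSqs[1:2], tolerance = 1e-8)
  expect_equal(ours$F[1:2], ref$F[1:2], tolerance = 1e-8)
  expect_equal(ours$df[1:2], ref$Df[1:2])
})

test_that("PERMANOVA rejects aliased designs and perfect separation hits the floor", {
  meta <- data.frame(Host = factor(rep(c("a", "b"), each = 4)),
                     Location = factor(rep(c("x", "y"), each = 4)))
  d <- as.matrix(dist(matrix(rnorm(16), 8)))
  expect_error(permanova_marginal(d, meta, n_perm = 9), "aliased")
  # two tight, far-apart groups (10 + 10 so a matching label permutation
  # is essentially never drawn): p at the permutation floor
  set.seed(19)
  pts <- rbind(matrix(rnorm(40, 0, 0.01), 10),
               matrix(rnorm(40, 50, 0.01), 10))
  meta2 <- data.frame(Host = factor(rep(c("a", "b"), each = 10)))
  res <- permanova_marginal(as.matrix(dist(pts)), meta2,
                            formula = ~ Host, n_perm = 999, seed = 3)
  expect_equal(res$p[1], 1 / 1000)
})

test_that("statistics are invariant to sample ordering", {
  set.seed(31)
  pts <- matrix(rnorm(24), 12)
  meta <- data.frame(sample_id = paste0("s", 1:12),
                     Host = factor(rep(c("a", "b"), 6)),
                     Location = factor(rep(1:3, each = 4)))
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(meta$sample_id, meta$sample_id)
  perm <- sample(12)
  r1 <- permanova_marginal(d, meta, n_perm = 49, seed = 5)
  r2 <- permanova_marginal(d[perm, perm], meta, n_perm = 49, seed = 5)
  expect_equal(r1$SS, r2$SS, tolerance = 1e-9)
  expect_equal(r1$F, r2$F, tolerance = 1e-9)
})
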