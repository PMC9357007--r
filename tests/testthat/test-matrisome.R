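make_small_sim <- function(seed = 1, ...) {
  simulate_abundance(n_per_cluster = 10, n_null = 20, n_reps = 4,
                     seed = seed, ...)
}

test_that("presence filter applies the 70 percent threshold exactly", {
  m <- matrix(1, 3, 29)
  m[1, 1:9] <- NA   # present 20/29 = 69.0% -> removed
  m[2, 1:8] <- NA   # present 21/29 = 72.4% -> retained
  out <- filter_presence(m, 0.70)
  expect_equal(nrow(out), 2)
  expect_equal(attr(out, "n_removed"), 1L)
  expect_equal(nrow(filter_presence(m, 0)), 3)  # min_frac 0 is the identity
})

test_that("log2 median-centring removes per-sample scale", {
  set.seed(2)
  m <- matrix(2^rnorm(60, 20), 10, 6)
  tr <- normalise_abundance(m)
  expect_equal(apply(tr, 2, stats::median), rep(0, 6), ignore_attr = TRUE)
  ## doubling all raw values changes nothing after centring
  expect_equal(normalise_abundance(m * 2), tr, tolerance = 1e-12)
  ## constant column centres to zero
  cm <- matrix(4, 5, 2)
  expect_true(all(normalise_abundance(cm) == 0))
  expect_error(normalise_abundance(matrix(c(-1, 2), 1)), "positive")

  z <- zscore_rows(matrix(rnorm(30), 5, 6))
  expect_equal(rowMeans(z), rep(0, 5), tolerance = 1e-9)
  expect_equal(apply(z, 1, stats::sd), rep(1, 5), tolerance = 1e-9)
})

test_that("row-wise ANOVA matches oneway.test and flags degenerates", {
  sim <- make_small_sim(seed = 3, missing_rate = 0.1)
  norm <- normalise_abundance(sim$matrix)
  res <- multi_sample_anova(norm, sim$design)
  grp <- factor(paste(sim$design$tissue, sim$design$stage, sep = "."))
  for (i in c(1, 5, 17, 30)) {
    y <- norm[i, ]; keep <- !is.na(y)
    ref <- stats::oneway.test(y[keep] ~ grp[keep], var.equal = TRUE)
    expect_equal(res$F[i], unname(ref$statistic), tolerance = 1e-10)
    expect_equal(res$p[i], ref$p.value, tolerance = 1e-10)
  }
  ## zero within-group variance is untestable, not significant
  m0 <- matrix(rep(c(1, 2, 3, 4, 5, 6), each = 4), 1, byrow = TRUE)
  colnames(m0) <- sim$design$sample_id[1:24]
  d0 <- sim$design[1:24, ]
  r0 <- multi_sample_anova(m0, d0)
  expect_true(r0$untestable[1] || !r0$significant[1])

  ## a strong planted shift is detected at tiny q
  sim2 <- make_small_sim(seed = 4, effect_size = 3, noise_sd = 0.3,
                         missing_rate = 0)
  res2 <- multi_sample_anova(normalise_abundance(sim2$matrix), sim2$design)
  planted <- sim2$truth[rownames(sim2$matrix)] != "null"
  expect_gt(mean(res2$significant[planted]), 0.9)
})

test_that("ANOVA reduces to the squared Welch-free two-sample t", {
  set.seed(9)
  m <- matrix(rnorm(40), 2, 20)
  design <- data.frame(sample_id = paste0("s", 1:20),
                       tissue = rep(c("healthy", "tumour"), each = 10),
                       stage = "early", replicate = rep(1:10, 2))
  f <- fibrarch:::row_oneway_f(m, design$tissue)
  tt <- stats::t.test(m[1, 1:10], m[1, 11:20], var.equal = TRUE)
  expect_equal(f$F[1], unname(tt$statistic)^2, tolerance = 1e-10)
})

test_that("volcano statistics match the Welch formula and its symmetry", {
  sim <- make_small_sim(seed = 5, missing_rate = 0)
  norm <- normalise_abundance(sim$matrix)
  res <- two_group_volcano(norm, sim$design, stage = "late")
  sel <- sim$design$stage == "late"
  for (i in c(2, 11, 25)) {
    yh <- norm[i, sel & sim$design$tissue == "healthy"]
    yt <- norm[i, sel & sim$design$tissue == "tumour"]
    ref <- stats::t.test(yt, yh)  # Welch by default
    expect_equal(res$t[i], unname(ref$statistic), tolerance = 1e-10)
    expect_equal(res$p[i], ref$p.value, tolerance = 1e-10)
    expect_equal(res$log2fc[i], mean(yt) - mean(yh), tolerance = 1e-12)
  }
  ## swapping tissue labels negates the fold change, p unchanged
  flipped <- sim$design
  flipped$tissue <- ifelse(flipped$tissue == "healthy", "tumour", "healthy")
  res_f <- two_group_volcano(norm, flipped, stage = "late")
  expect_equal(res_f$log2fc, -res$log2fc, tolerance = 1e-12)
  expect_equal(res_f$p, res$p, tolerance = 1e-12)
})

test_that("BH adjustment equals the step-up oracle exactly", {
  set.seed(10)
  for (rep in 1:20) {
    p <- runif(sample(5:200, 1))
    expect_equal(stats::p.adjust(p, method = "BH"), oracle_bh(p),
                 tolerance = 1e-14)
  }
})

test_that("temporal clustering recovers planted profiles with stable labels", {
  sim <- simulate_abundance(n_per_cluster = 30, n_null = 0, n_reps = 5,
                            effect_size = 2, noise_sd = 0.5,
                            missing_rate = 0.1, seed = 6)
  norm <- normalise_abundance(filter_presence(sim$matrix))
  prof <- condition_profiles(norm, sim$design)
  cl <- temporal_cluster(prof, k = 4)
  ari <- mclust::adjustedRandIndex(cl$labels,
                                   sim$truth[names(cl$labels)])
  expect_gte(ari, 0.9)

  ## duplicated rows land together; k = 1 collapses everything
  dup <- prof[c(1, 1, 2, 3, 4, 5), ]
  rownames(dup) <- paste0("r", 1:6)
  cld <- temporal_cluster(dup, k = 3)
  expect_equal(unname(cld$labels["r1"]), unname(cld$labels["r2"]))
  expect_equal(length(unique(temporal_cluster(prof, k = 1)$labels)), 1)
  expect_error(temporal_cluster(prof[1:3, ], k = 4), "exceeds")

  ## canonical numbering: C1 has the highest tumour-late median z
  tl <- cl$cluster_medians[, ncol(cl$cluster_medians)]
  expect_equal(order(vapply(paste0("C", 1:4), function(cc)
    mean(cl$profiles_z[cl$labels == cc, 6]), numeric(1)),
    decreasing = TRUE), 1:4)
  expect_length(tl, 4)
})

test_that("cluster labels are invariant to protein row order", {
  sim <- simulate_abundance(n_per_cluster = 15, n_null = 10, n_reps = 4,
                            missing_rate = 0, seed = 7)
  norm <- normalise_abundance(sim$matrix)
  prof <- condition_profiles(norm, sim$design)
  cl1 <- temporal_cluster(prof, k = 4)
  set.seed(8); perm <- sample(nrow(prof))
  cl2 <- temporal_cluster(prof[perm, ], k = 4)
  expect_equal(cl1$labels[rownames(prof)], cl2$labels[rownames(prof)])
})

test_that("category enrichment agrees with hypergeometric enumeration", {
  labels <- stats::setNames(rep(c("C1", "C2"), each = 10), paste0("P", 1:20))
  ann <- data.frame(protein = paste0("P", 1:20),
                    category = rep(c("collagens", "proteoglycans"),
                                   times = 10))
  res <- category_enrichment(labels, ann)
  for (i in seq_len(nrow(res))) {
    want <- oracle_fisher_p(res$in_cluster_in_cat[i],
                            res$in_cluster_out_cat[i],
                            res$out_cluster_in_cat[i],
                            res$out_cluster_out_cat[i])
    expect_equal(res$p[i], want, tolerance = 1e-9)
  }
  ## balanced table: no association
  expect_true(all(res$p == 1))

  ## perfectly associated table matches the tail enumeration
  lab2 <- stats::setNames(rep(c("C1", "C2"), each = 10), paste0("Q", 1:20))
  ann2 <- data.frame(protein = paste0("Q", 1:20),
                     category = rep(c("collagens", "secreted factors"),
                                    each = 10))
  r2 <- category_enrichment(lab2, ann2)
  i <- which(r2$cluster == "C1" & r2$category == "collagens")
  expect_equal(r2$p[i], oracle_fisher_p(10, 0, 0, 10), tolerance = 1e-9)

  expect_error(category_enrichment(labels, ann[1:5, ]), "unannotated")
})

test_that("PCA summary isolates planted factors and degenerate lines", {
  ## samples exactly on a line: PC1 carries everything
  line <- outer(rnorm(20), seq(-1, 1, length.out = 6))
  rownames(line) <- paste0("P", 1:20)
  colnames(line) <- paste0("s", 1:6)
  pc <- pca_summary(line)
  expect_equal(pc$var_explained[1], 1, tolerance = 1e-9)

  ## rotation of the feature space leaves the spectrum unchanged
  set.seed(11)
  x <- matrix(rnorm(20 * 8), 20, 8)
  q <- qr.Q(qr(matrix(rnorm(400), 20)))
  expect_equal(pca_summary(x)$var_explained,
               pca_summary(q %*% x)$var_explained, tolerance = 1e-9)

  expect_error(pca_summary(x[, 1, drop = FALSE]), "two samples")
})
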