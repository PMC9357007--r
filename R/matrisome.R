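## Temporal matrisome proteomics pipeline: presence filtering, log2
## median-centring, row-wise differential-abundance statistics with
## Benjamini-Hochberg control, hierarchical temporal clustering over the
## six tissue-stage condition medians, Fisher category enrichment and PCA.

validate_design <- function(m, design) {
  need <- c("sample_id", "tissue", "stage")
  if (!all(need %in% names(design)))
    stop_data("design needs columns: ", paste(need, collapse = ", "))
  if (!all(design$tissue %in% c("healthy", "tumour")))
    stop_data("tissue must be 'healthy' or 'tumour'")
  if (!all(as.character(design$stage) %in% c("early", "mid", "late")))
    stop_data("stage must be 'early', 'mid' or 'late'")
  if (ncol(m) != nrow(design))
    stop_data("matrix columns and design rows disagree")
  invisible(design)
}

design_groups <- function(design) {
  factor(paste(design$tissue, design$stage, sep = "."),
         levels = condition_levels())
}

#' Filter proteins by presence across samples
#'
#' Retains proteins quantified (non-missing) in at least `min_frac` of all
#' samples; the default 0.70 keeps only robustly identified proteins.
#'
#' @param m proteins x samples matrix (NA = missing).
#' @param min_frac minimum presence fraction (default 0.70).
#' @return The filtered matrix, with attribute `n_removed`.
#' @export
filter_presence <- function(m, min_frac = 0.70) {
  if (!is.matrix(m)) stop_data("m must be a matrix")
  pres <- rowMeans(!is.na(m))
  keep <- pres >= min_frac
  out <- m[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  if (!nrow(out)) warning("presence filter removed every protein", call. = FALSE)
  out
}

#' Log2 transform and per-sample median centring
#'
#' @param m proteins x samples matrix of raw positive intensities
#'   (NA = missing).
#' @return The log2-transformed matrix with each column centred on its
#'   median (computed over non-missing entries).
#' @export
normalise_abundance <- function(m) {
  if (!is.matrix(m)) stop_data("m must be a matrix")
  if (any(m <= 0, na.rm = TRUE)) stop_data("intensities must be positive")
  lg <- log2(m)
  sweep(lg, 2, apply(lg, 2, stats::median, na.rm = TRUE))
}

#' Condition-median profiles
#'
#' Collapses samples to the median per tissue-stage condition, giving one
#' six-value temporal profile per protein (condition order: healthy
#' early/mid/late, then tumour early/mid/late).
#'
#' @param m transformed proteins x samples matrix.
#' @param design sample design (see [simulate_abundance()]).
#' @return proteins x 6 matrix of condition medians.
#' @export
condition_profiles <- function(m, design) {
  validate_design(m, design)
  g <- design_groups(design)
  sapply(levels(g), function(lv)
    apply(m[, g == lv, drop = FALSE], 1, stats::median, na.rm = TRUE))
}

#' Row z-scores
#'
#' @param m numeric matrix.
#' @return `m` with each row scaled to mean 0, SD 1. Zero-variance rows
#'   become all zero.
#' @export
zscore_rows <- function(m) {
  mu <- rowMeans(m, na.rm = TRUE)
  sd_ <- apply(m, 1, stats::sd, na.rm = TRUE)
  sd_[sd_ == 0 | is.na(sd_)] <- Inf
  (m - mu) / sd_
}

## vectorised one-way ANOVA over matrix rows; groups is a factor.
## Returns F, df1, df2, p; rows with < 2 groups having >= 2 obs, or zero
## residual variance, are NA (untestable).
row_oneway_f <- function(m, groups) {
  groups <- droplevels(as.factor(groups))
  pres <- !is.na(m)
  x <- m; x[!pres] <- 0
  k_sum <- sapply(levels(groups), function(lv)
    rowSums(x[, groups == lv, drop = FALSE]))
  k_n <- sapply(levels(groups), function(lv)
    rowSums(pres[, groups == lv, drop = FALSE]))
  if (is.null(dim(k_sum))) { k_sum <- t(k_sum); k_n <- t(k_n) }
  usable <- k_n >= 2
  g_used <- rowSums(usable)
  n_tot <- rowSums(k_n * usable)
  grand <- rowSums(ifelse(usable, k_sum, 0)) / n_tot
  k_mean <- ifelse(usable, k_sum / pmax(k_n, 1), NA)
  ss_between <- rowSums(ifelse(usable, k_n * (k_mean - grand)^2, 0))
  ## within-group SS: sum x^2 - sum n_g mean_g^2 over usable groups
  x2 <- x^2
  k_sum2 <- sapply(levels(groups), function(lv)
    rowSums(x2[, groups == lv, drop = FALSE]))
  if (is.null(dim(k_sum2))) k_sum2 <- t(k_sum2)
  ss_within <- rowSums(ifelse(usable, k_sum2 - k_n * k_mean^2, 0))
  df1 <- g_used - 1
  df2 <- n_tot - g_used
  ok <- df1 >= 1 & df2 >= 1 & ss_within > 0
  f <- ifelse(ok, (ss_between / df1) / (ss_within / df2), NA_real_)
  p <- ifelse(ok, stats::pf(f, df1, df2, lower.tail = FALSE), NA_real_)
  data.frame(F = f, df1 = df1, df2 = df2, p = p,
             untestable = !ok, row.names = rownames(m))
}

#' Multi-sample (one-way) ANOVA across tissue-stage groups
#'
#' Tests each protein for any abundance difference across the six
#' tissue-stage groups on transformed values, with Benjamini-Hochberg
#' q-values. Missing values are dropped per protein; proteins without at
#' least two groups of two or more observations (or with zero residual
#' variance) are flagged untestable and never significant.
#'
#' @param m transformed proteins x samples matrix (see
#'   [normalise_abundance()]).
#' @param design sample design table.
#' @param fdr significance level on the q-value (default 0.05).
#' @return data.frame with per-protein `F`, `df1`, `df2`, `p`, `q`,
#'   `untestable` and `significant`.
#' @export
multi_sample_anova <- function(m, design, fdr = 0.05) {
  validate_design(m, design)
  res <- row_oneway_f(m, design_groups(design))
  res$q <- NA_real_
  test <- !res$untestable
  res$q[test] <- stats::p.adjust(res$p[test], method = "BH")
  res$significant <- !res$untestable & !is.na(res$q) & res$q <= fdr
  res
}

## vectorised Welch t over rows for a two-level factor
row_welch_t <- function(m, f2) {
  lv <- levels(droplevels(as.factor(f2)))
  if (length(lv) != 2) stop_data("exactly two groups required")
  split_stats <- function(lvl) {
    sub <- m[, f2 == lvl, drop = FALSE]
    n <- rowSums(!is.na(sub))
    mu <- rowMeans(sub, na.rm = TRUE)
    v <- apply(sub, 1, stats::var, na.rm = TRUE)
    list(n = n, mu = mu, v = v)
  }
  a <- split_stats(lv[1]); b <- split_stats(lv[2])
  ok <- a$n >= 2 & b$n >= 2 & (a$v + b$v) > 0 &
    !is.na(a$v) & !is.na(b$v)
  se2 <- a$v / a$n + b$v / b$n
  t_ <- (b$mu - a$mu) / sqrt(se2)
  df <- se2^2 / ((a$v / a$n)^2 / (a$n - 1) + (b$v / b$n)^2 / (b$n - 1))
  p <- 2 * stats::pt(abs(t_), df, lower.tail = FALSE)
  data.frame(log2fc = b$mu - a$mu, t = ifelse(ok, t_, NA_real_),
             df = ifelse(ok, df, NA_real_), p = ifelse(ok, p, NA_real_),
             untestable = !ok, row.names = rownames(m))
}

#' Healthy-vs-tumour volcano statistics at one stage
#'
#' Per-protein Welch t-test between the healthy and tumour groups at the
#' chosen stage, on transformed values. The log2 fold change is the
#' tumour-minus-healthy difference of group means; q-values are
#' Benjamini-Hochberg.
#'
#' @param m transformed proteins x samples matrix.
#' @param design sample design table.
#' @param stage `"early"`, `"mid"` or `"late"`.
#' @param fdr significance level (default 0.05).
#' @return data.frame with `log2fc`, `t`, `df`, `p`, `q`, `untestable`,
#'   `significant`.
#' @export
two_group_volcano <- function(m, design, stage = c("early", "mid", "late"),
                              fdr = 0.05) {
  stage <- match.arg(stage)
  validate_design(m, design)
  sel <- design$stage == stage
  sub <- m[, sel, drop = FALSE]
  f2 <- factor(design$tissue[sel], levels = c("healthy", "tumour"))
  res <- row_welch_t(sub, f2)
  res$q <- NA_real_
  test <- !res$untestable
  res$q[test] <- stats::p.adjust(res$p[test], method = "BH")
  res$significant <- !res$untestable & !is.na(res$q) & res$q <= fdr
  res
}

#' Temporal clustering of condition profiles
#'
#' Agglomerative hierarchical clustering (Euclidean distance,
#' configurable linkage, default average) of per-protein z-scored
#' condition-median profiles, cut into `k` clusters. Cluster labels are
#' canonicalised by descending mean tumour-late z-score, so C1..Ck are
#' stable across runs and seed orders. Proteins with a fully missing
#' condition are excluded and reported.
#'
#' @param profiles proteins x 6 matrix of condition medians (see
#'   [condition_profiles()]); z-scored internally.
#' @param k number of clusters (default 4).
#' @param linkage hclust method (default "average").
#' @return An object of class `temporal_clusters`: list with `labels`
#'   (named "C1".."Ck"), `profiles_z`, `cluster_medians` (k x 6),
#'   `dendrogram` (the hclust tree) and `excluded` (protein ids dropped
#'   for missing conditions).
#' @export
temporal_cluster <- function(profiles, k = 4, linkage = "average") {
  if (!is.matrix(profiles)) stop_data("profiles must be a matrix")
  complete <- stats::complete.cases(profiles)
  excluded <- rownames(profiles)[!complete]
  pr <- profiles[complete, , drop = FALSE]
  if (k > nrow(pr)) stop_data("k exceeds the number of clusterable proteins")
  z <- zscore_rows(pr)
  tree <- stats::hclust(stats::dist(z, method = "euclidean"),
                        method = linkage)
  raw <- stats::cutree(tree, k = k)
  ## canonical numbering: descending mean tumour-late z
  tl <- ncol(z)  # condition order ends at tumour.late
  means <- vapply(seq_len(k), function(cl) mean(z[raw == cl, tl]), numeric(1))
  remap <- order(means, decreasing = TRUE)
  labels <- paste0("C", match(raw, remap))
  names(labels) <- rownames(z)
  medians <- t(vapply(seq_len(k), function(ci)
    apply(z[labels == paste0("C", ci), , drop = FALSE], 2, stats::median),
    numeric(ncol(z))))
  rownames(medians) <- paste0("C", seq_len(k))
  structure(list(labels = labels, profiles_z = z,
                 cluster_medians = medians, dendrogram = tree,
                 excluded = excluded, k = k, linkage = linkage),
            class = "temporal_clusters")
}

#' @export
print.temporal_clusters <- function(x, ...) {
  cat(sprintf("temporal clustering: %d proteins into %d clusters (%s linkage)\n",
              length(x$labels), x$k, x$linkage))
  print(table(x$labels))
  invisible(x)
}

#' @export
plot.temporal_clusters <- function(x, ...) {
  med <- x$cluster_medians
  graphics::matplot(t(med), type = "b", pch = 16, lty = 1,
                    xlab = "condition", ylab = "median z", xaxt = "n", ...)
  graphics::axis(1, at = seq_len(ncol(med)), labels = colnames(med) %||%
                   condition_levels(), las = 2, cex.axis = 0.7)
  graphics::legend("topleft", legend = rownames(med), col = seq_len(nrow(med)),
                   lty = 1, bty = "n")
  invisible(x)
}

#' Matrisome-category enrichment per temporal cluster
#'
#' For every cluster x category pair, tests the 2 x 2 table (in cluster
#' and in category vs the margins) with a two-sided Fisher exact test;
#' p-values are Benjamini-Hochberg adjusted across all pairs.
#'
#' @param clusters a `temporal_clusters` object, or a named vector of
#'   cluster labels.
#' @param annotation data.frame with columns `protein` and `category`
#'   (see [synthetic_matrisome_annotation()]).
#' @return data.frame with `cluster`, `category`, the table cells
#'   `in_cluster_in_cat`, `in_cluster_out_cat`, `out_cluster_in_cat`,
#'   `out_cluster_out_cat`, `p` and `q`.
#' @export
category_enrichment <- function(clusters, annotation) {
  labels <- if (inherits(clusters, "temporal_clusters")) clusters$labels
            else clusters
  if (is.null(names(labels))) stop_data("cluster labels must be named")
  cat_map <- stats::setNames(annotation$category, annotation$protein)
  unann <- setdiff(names(labels), names(cat_map))
  if (length(unann))
    stop_data("unannotated proteins: ", paste(utils::head(unann, 3),
                                              collapse = ", "))
  cats <- cat_map[names(labels)]
  if (any(table(cats) == 0)) stop_data("empty category")
  grid <- expand.grid(cluster = sort(unique(labels)),
                      category = sort(unique(cats)),
                      stringsAsFactors = FALSE)
  cells <- t(mapply(function(cl, ct) {
    a <- sum(labels == cl & cats == ct)
    b <- sum(labels == cl & cats != ct)
    c_ <- sum(labels != cl & cats == ct)
    d <- sum(labels != cl & cats != ct)
    c(a, b, c_, d, stats::fisher.test(matrix(c(a, b, c_, d), 2,
                                             byrow = TRUE))$p.value)
  }, grid$cluster, grid$category))
  grid$in_cluster_in_cat <- cells[, 1]
  grid$in_cluster_out_cat <- cells[, 2]
  grid$out_cluster_in_cat <- cells[, 3]
  grid$out_cluster_out_cat <- cells[, 4]
  grid$p <- cells[, 5]
  grid$q <- stats::p.adjust(grid$p, method = "BH")
  grid
}

#' PCA of samples over complete-case proteins
#'
#' SVD-based principal component analysis of the transformed matrix,
#' restricted to proteins present in all samples. Samples are the
#' observations; protein loadings identify the strongest contributors per
#' component.
#'
#' @param m transformed proteins x samples matrix.
#' @param n_top number of top-|loading| proteins reported per PC
#'   (default 10).
#' @return An object of class `pca_summary`: list with `scores` (samples
#'   x PC), `loadings` (proteins x PC), `var_explained`, `top_loadings`
#'   (list per PC) and `n_proteins_used`.
#' @export
pca_summary <- function(m, n_top = 10) {
  if (!is.matrix(m)) stop_data("m must be a matrix")
  if (ncol(m) < 2) stop_data("at least two samples required")
  complete <- stats::complete.cases(m)
  x <- m[complete, , drop = FALSE]
  if (nrow(x) < 2) stop_data("fewer than two complete-case proteins")
  pc <- stats::prcomp(t(x), center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  npc <- min(ncol(pc$x), 2L)
  top <- lapply(seq_len(npc), function(i) {
    lo <- pc$rotation[, i]
    lo[order(abs(lo), decreasing = TRUE)][seq_len(min(n_top, length(lo)))]
  })
  names(top) <- paste0("PC", seq_len(npc))
  structure(list(scores = pc$x, loadings = pc$rotation,
                 var_explained = ve, top_loadings = top,
                 n_proteins_used = nrow(x)),
            class = "pca_summary")
}

#' @export
print.pca_summary <- function(x, ...) {
  cat(sprintf("PCA over %d complete-case proteins; variance explained: %s\n",
              x$n_proteins_used,
              paste(sprintf("PC%d %.1f%%", seq_len(min(3, length(x$var_explained))),
                            100 * x$var_explained[seq_len(min(3, length(x$var_explained)))]),
                    collapse = ", ")))
  invisible(x)
}
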