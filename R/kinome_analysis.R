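# Downstream kinome statistics: depletion and dilution enrichment metrics,
# replicate handling, per-gene two-sample t-tests with Benjamini-Hochberg
# correction, sample clustering, cross-dataset correlation, and the
# harmonization transforms for phosphosite and RNA matrices.

#' Serial-depletion identification and abundance metrics
#'
#' For a kinases-by-rounds matrix (round 0 = original pulldown), counts
#' identified kinases per round (non-missing, and at least `detection_floor`
#' when given) and computes identification and summed-abundance fractions
#' relative to round 0.
#'
#' @param matrix Linear [quant_matrix()] with rounds as samples, round 0
#'   first.
#' @param detection_floor Optional abundance floor for "identified".
#' @return Tibble: `round`, `n_identified`, `identified_fraction`,
#'   `abundance`, `abundance_fraction`.
#' @export
depletion_metrics <- function(matrix, detection_floor = NULL) {
  stopifnot(inherits(matrix, "quant_matrix"))
  m <- unclass(matrix)
  identified <- !is.na(m)
  if (!is.null(detection_floor))
    identified <- identified & m >= detection_floor
  counts <- colSums(identified)
  if (counts[1] == 0) stop("no kinase identified in round 0")
  m0 <- m
  m0[!identified] <- NA
  sums <- colSums(m0, na.rm = TRUE)
  tibble(round = colnames(m), n_identified = unname(counts),
         identified_fraction = unname(counts / counts[1]),
         abundance = unname(sums),
         abundance_fraction = unname(sums / sums[1]))
}

#' Enrichment linearity over a dilution series
#'
#' Fits a zero-intercept regression of total abundance (e.g. total iBAQ)
#' against protein input and reports the slope and R-squared; when the
#' per-gene matrix is supplied, genes whose own zero-intercept fit falls
#' below `r2_threshold` are flagged as saturating.
#'
#' @param totals Per-level totals (same order as `inputs_ug`, >= 3 levels).
#' @param inputs_ug Input amounts in micrograms.
#' @param gene_matrix Optional linear [quant_matrix()] (genes x levels).
#' @param r2_threshold Per-gene proportionality threshold (default 0.95).
#' @return List: `slope`, `r2`, and `gene_flags` (tibble: gene, r2,
#'   saturating) when `gene_matrix` is given.
#' @export
dilution_linearity <- function(totals, inputs_ug, gene_matrix = NULL,
                               r2_threshold = 0.95) {
  if (length(totals) != length(inputs_ug) || length(totals) < 3)
    stop("need totals for at least 3 input levels")
  slope <- sum(inputs_ug * totals) / sum(inputs_ug^2)
  r2 <- zero_intercept_r2(inputs_ug, totals)
  gene_flags <- NULL
  if (!is.null(gene_matrix)) {
    g_r2 <- apply(unclass(gene_matrix), 1, function(y) {
      ok <- !is.na(y)
      if (sum(ok) < 3) return(NA_real_)
      zero_intercept_r2(inputs_ug[ok], y[ok])
    })
    gene_flags <- tibble(gene = rownames(gene_matrix), r2 = unname(g_r2),
                         saturating = !is.na(g_r2) & g_r2 < r2_threshold)
  }
  list(slope = slope, r2 = r2, gene_flags = gene_flags)
}

#' Average technical replicates and apply the minimum-sample filter
#'
#' Technical replicate columns are averaged on the log2 scale into one column
#' per biological sample; genes observed in fewer than `min_samples`
#' biological samples are dropped.
#'
#' @param matrix log2 [quant_matrix()] with replicate-run columns.
#' @param replicate_map Tibble with `column` (matrix column) and `sample`
#'   (biological sample id); must cover every column.
#' @param min_samples Minimum biological samples with an observation
#'   (default 10).
#' @return log2 [quant_matrix()], genes x biological samples.
#' @export
prepare_samples <- function(matrix, replicate_map, min_samples = 10) {
  stopifnot(inherits(matrix, "quant_matrix"))
  if (qm_scale(matrix) != "log2")
    stop("prepare_samples expects a log2 matrix")
  missing_cols <- setdiff(colnames(matrix), replicate_map$column)
  if (length(missing_cols) > 0)
    stop("replicate map does not cover column(s): ",
         paste(missing_cols, collapse = ", "))
  samples <- unique(replicate_map$sample)
  empty <- vapply(samples, function(s) {
    sum(replicate_map$column[replicate_map$sample == s] %in%
          colnames(matrix)) == 0
  }, TRUE)
  if (any(empty))
    stop("replicate group(s) of size 0: ",
         paste(samples[empty], collapse = ", "))
  avg <- sapply(samples, function(s) {
    cols <- replicate_map$column[replicate_map$sample == s]
    sub <- unclass(matrix)[, cols, drop = FALSE]
    v <- rowMeans(sub, na.rm = TRUE)
    v[rowSums(!is.na(sub)) == 0] <- NA
    v
  })
  keep <- rowSums(!is.na(avg)) >= min_samples
  quant_matrix(avg[keep, , drop = FALSE], "log2")
}

#' Per-gene two-sample differential test with BH correction
#'
#' Two-sided Student's (pooled variance) or Welch's t-test per gene between
#' two subtype groups on a log2 matrix, with Benjamini-Hochberg adjustment
#' across all tested genes. Genes lacking two observations per group are
#' reported as untested (`NA` statistics), not errors. When both groups are
#' constant and equal the test is degenerate; the gene is reported with
#' `t = 0`, `p = 1`.
#'
#' @param matrix log2 [quant_matrix()], genes x biological samples.
#' @param groups Named character vector: subtype label per sample (exactly
#'   two levels; the first level sorted alphabetically is "group A" for the
#'   fold-change sign, so `basal` vs `luminal` gives `log2_fc =
#'   mean(basal) - mean(luminal)`).
#' @param test `"student"` or `"welch"`.
#' @param alpha Raw-p significance threshold for the `significant` flag
#'   (default 0.05, uncorrected, matching discovery-count conventions;
#'   BH-adjusted p is reported alongside).
#' @return Tibble: gene, n per group, group means, `log2_fc`, `fold_change`,
#'   `t`, `p_value`, `p_adj`, `direction` (`up_in_<groupA>` /
#'   `up_in_<groupB>` or `NA` for a zero difference), `significant`.
#' @export
differential_expression <- function(matrix, groups,
                                    test = c("student", "welch"),
                                    alpha = 0.05) {
  stopifnot(inherits(matrix, "quant_matrix"))
  if (qm_scale(matrix) != "log2")
    stop("differential_expression expects a log2 matrix")
  test <- match.arg(test)
  groups <- groups[colnames(matrix)]
  if (anyNA(groups)) stop("groups must label every sample column")
  levels <- sort(unique(groups))
  if (length(levels) != 2) stop("exactly two group levels required")
  a_cols <- names(groups)[groups == levels[1]]
  b_cols <- names(groups)[groups == levels[2]]
  m <- unclass(matrix)
  res <- lapply(rownames(m), function(g) {
    x <- m[g, a_cols]; x <- x[!is.na(x)]
    y <- m[g, b_cols]; y <- y[!is.na(y)]
    if (length(x) < 2 || length(y) < 2) {
      return(tibble(gene = g, n_a = length(x), n_b = length(y),
                    mean_a = NA_real_, mean_b = NA_real_,
                    log2_fc = NA_real_, fold_change = NA_real_,
                    t = NA_real_, p_value = NA_real_))
    }
    d <- mean(x) - mean(y)
    tt <- tryCatch(
      stats::t.test(x, y, var.equal = (test == "student")),
      error = function(e) NULL)
    if (is.null(tt)) {
      # zero variance in both groups: degenerate test
      stat <- if (d == 0) 0 else sign(d) * Inf
      p <- if (d == 0) 1 else 0
    } else {
      stat <- unname(tt$statistic)
      p <- tt$p.value
    }
    tibble(gene = g, n_a = length(x), n_b = length(y),
           mean_a = mean(x), mean_b = mean(y), log2_fc = d,
           fold_change = 2^d, t = stat, p_value = p)
  })
  out <- dplyr::bind_rows(res)
  out$p_adj <- NA_real_
  tested <- !is.na(out$p_value)
  out$p_adj[tested] <- stats::p.adjust(out$p_value[tested], method = "BH")
  out$direction <- ifelse(is.na(out$log2_fc) | out$log2_fc == 0,
                          NA_character_,
                          ifelse(out$log2_fc > 0,
                                 paste0("up_in_", levels[1]),
                                 paste0("up_in_", levels[2])))
  out$significant <- tested & out$p_value < alpha
  out
}

impute_gene_min <- function(m) {
  for (i in seq_len(nrow(m))) {
    miss <- is.na(m[i, ])
    if (any(miss) && !all(miss)) m[i, miss] <- min(m[i, ], na.rm = TRUE)
  }
  if (anyNA(m)) stop("gene(s) missing in every sample; filter first")
  m
}

#' Cluster samples by kinase profile
#'
#' Hierarchical clustering uses correlation distance (1 - Pearson between
#' samples) with average linkage; k-means runs on per-gene z-scored values
#' with a fixed seed and multiple restarts. Missing values are imputed to the
#' per-gene minimum for distance computation only.
#'
#' @param matrix [quant_matrix()] (genes x samples), any scale.
#' @param method `"hierarchical"` or `"kmeans"`.
#' @param k Number of clusters (<= number of samples).
#' @param seed RNG seed for k-means restarts.
#' @param nstart k-means restarts (default 25).
#' @return List with `labels` (named integer cluster per sample) and either
#'   `hclust` (the dendrogram object) or `kmeans` (the fit).
#' @export
cluster_samples <- function(matrix, method = c("hierarchical", "kmeans"),
                            k = 2, seed = 1, nstart = 25) {
  stopifnot(inherits(matrix, "quant_matrix"))
  method <- match.arg(method)
  if (k > ncol(matrix)) stop("k exceeds the number of samples")
  m <- impute_gene_min(unclass(matrix))
  if (method == "hierarchical") {
    d <- stats::as.dist(1 - stats::cor(m))
    hc <- stats::hclust(d, method = "average")
    labels <- stats::cutree(hc, k = k)
    list(labels = labels, hclust = hc)
  } else {
    if (k == ncol(m)) {
      # degenerate: every sample is its own cluster
      return(list(labels = stats::setNames(seq_len(ncol(m)), colnames(m)),
                  kmeans = NULL))
    }
    sds <- apply(m, 1, stats::sd)
    z <- (m[sds > 0, , drop = FALSE] - rowMeans(m[sds > 0, , drop = FALSE])) /
      sds[sds > 0]
    fit <- with_seed(seed, stats::kmeans(t(z), centers = k, nstart = nstart))
    list(labels = fit$cluster, kmeans = fit)
  }
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same samples;
#' 1 means identical partitions (up to label permutation), 0 is the expected
#' agreement of random labelings.
#'
#' @param a,b Cluster label vectors of equal length.
#' @return Numeric ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}

#' Per-gene correlation between two quantification platforms
#'
#' Pearson correlation per shared gene across shared samples (requiring at
#' least `min_shared` complete pairs), summarized by the median.
#'
#' @param matrix_a,matrix_b [quant_matrix()] objects.
#' @param min_shared Minimum complete sample pairs per gene (default 3).
#' @return List with `per_gene` (tibble: gene, n, r) and `median_r`.
#' @export
cross_dataset_correlation <- function(matrix_a, matrix_b, min_shared = 3) {
  genes <- intersect(rownames(matrix_a), rownames(matrix_b))
  samples <- intersect(colnames(matrix_a), colnames(matrix_b))
  if (length(genes) == 0) stop("no shared genes between datasets")
  if (length(samples) < min_shared) stop("fewer than ", min_shared,
                                         " shared samples")
  a <- unclass(matrix_a)[genes, samples, drop = FALSE]
  b <- unclass(matrix_b)[genes, samples, drop = FALSE]
  rows <- lapply(genes, function(g) {
    ok <- !is.na(a[g, ]) & !is.na(b[g, ])
    if (sum(ok) < min_shared)
      return(tibble(gene = g, n = sum(ok), r = NA_real_))
    tibble(gene = g, n = sum(ok), r = stats::cor(a[g, ok], b[g, ok]))
  })
  per_gene <- dplyr::bind_rows(rows)
  list(per_gene = per_gene,
       median_r = stats::median(per_gene$r, na.rm = TRUE))
}

#' Roll phosphosite values up to genes
#'
#' Per gene and sample, the mean over non-missing sites — a coarse estimate
#' of relative protein phosphorylation status.
#'
#' @param site_matrix [quant_matrix()] with site ids as rows.
#' @param site_gene_map Tibble with `site`, `gene`.
#' @return [quant_matrix()] genes x samples (same scale).
#' @export
phospho_rollup <- function(site_matrix, site_gene_map) {
  stopifnot(inherits(site_matrix, "quant_matrix"))
  idx <- match(rownames(site_matrix), site_gene_map$site)
  if (anyNA(idx)) stop("site(s) missing from site->gene map")
  genes <- sort(unique(site_gene_map$gene[idx]))
  m <- unclass(site_matrix)
  out <- t(sapply(genes, function(g) {
    sub <- m[site_gene_map$gene[idx] == g, , drop = FALSE]
    v <- colMeans(sub, na.rm = TRUE)
    v[colSums(!is.na(sub)) == 0] <- NA
    v
  }))
  colnames(out) <- colnames(site_matrix)
  quant_matrix(out, qm_scale(site_matrix))
}

#' Median-ratio log2 transform of an RNA TPM matrix
#'
#' Per gene: `log2((tpm + pc) / median_over_samples(tpm + pc))`, so every
#' gene's row median becomes 0 and values are log2 ratios to the cohort-
#' typical expression.
#'
#' @param tpm Non-negative matrix (genes x samples) or [quant_matrix()].
#' @param pseudocount Added before the ratio (default 1).
#' @return log2 [quant_matrix()].
#' @export
rna_transform <- function(tpm, pseudocount = 1) {
  m <- unclass(tpm) + pseudocount
  if (any(m <= 0, na.rm = TRUE)) stop("tpm + pseudocount must be positive")
  med <- apply(m, 1, stats::median, na.rm = TRUE)
  quant_matrix(log2(m / med), "log2")
}
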