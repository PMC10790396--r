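test_that("depletion metrics compute identification and abundance fractions", {
  v <- cbind(round0 = c(A = 10, B = 20, C = 30, D = 40, E = 900),
             round1 = c(8, 15, 22, 35, NA))
  m <- quant_matrix(v, "linear")
  dm <- depletion_metrics(m)
  expect_equal(dm$identified_fraction, c(1, 0.8))  # 4 of 5
  expect_equal(dm$abundance_fraction[2], 80 / 1000)

  v2 <- cbind(round0 = c(A = 600, B = 400), round1 = c(A = 180, B = 100))
  dm2 <- depletion_metrics(quant_matrix(v2, "linear"))
  expect_equal(dm2$abundance_fraction[2], 0.28)

  # geometric model, no floor: round-1 abundance fraction is exactly 0.30
  d <- gen_depletion_series(depletion_spec(binding_fraction = 0.7,
                                           detection_floor = 0, seed = 13))
  dm3 <- depletion_metrics(d$matrix)
  expect_equal(dm3$abundance_fraction[2], 0.3, tolerance = 1e-12)
  expect_equal(dm3$identified_fraction, rep(1, 3))
  empty <- quant_matrix(cbind(round0 = c(A = NA_real_), round1 = c(A = 1)),
                        "linear")
  expect_error(depletion_metrics(empty), "round 0")
})

test_that("dilution linearity fits zero-intercept response and flags saturation", {
  inputs <- c(12.5, 25, 50, 100, 200)
  lin <- dilution_linearity(7 * inputs, inputs)
  expect_equal(lin$r2, 1.0)
  expect_equal(lin$slope, 7)
  flat <- dilution_linearity(rep(100, 5), inputs)
  expect_lt(flat$r2, 0.5)
  expect_error(dilution_linearity(c(1, 2), c(1, 2)), "3 input levels")

  d <- gen_dilution_series(inputs, n_genes = 10, saturating_genes = c("G1", "G2"),
                           K = 25, seed = 3)
  res <- dilution_linearity(colSums(unclass(d$areas)), inputs,
                            gene_matrix = d$areas)
  flags <- setNames(res$gene_flags$saturating, res$gene_flags$gene)
  expect_true(all(flags[c("G1", "G2")]))
  expect_false(any(flags[paste0("G", 3:10)]))
})

test_that("replicate averaging and the minimum-sample filter behave", {
  genes <- c("G1", "G2")
  cols <- as.vector(outer(paste0("s", 1:16), c("_r1", "_r2"), paste0))
  v <- matrix(5, 2, 32, dimnames = list(genes, cols))
  v["G1", c("s1_r1", "s1_r2")] <- c(4, 6)  # duplicates average to 5
  v["G2", c(paste0("s", 8:16, "_r1"),
            paste0("s", 8:16, "_r2"))] <- NA  # G2 seen in 7 samples only
  rmap <- tibble::tibble(column = cols,
                         sample = rep(paste0("s", 1:16), times = 2))
  m <- quant_matrix(v, "log2")
  out <- prepare_samples(m, rmap, min_samples = 10)
  expect_equal(unclass(out)["G1", "s1"], 5)
  # G2 visible in 9 biological samples only -> dropped at min 10
  obs_g2 <- sum(vapply(paste0("s", 1:16), function(s)
    any(!is.na(v["G2", rmap$column[rmap$sample == s]])), TRUE))
  expect_lt(obs_g2, 10)
  expect_false("G2" %in% rownames(out))
  all_kept <- prepare_samples(m, rmap, min_samples = 0)
  expect_setequal(rownames(all_kept), genes)
  bad_map <- rmap[-(1:2), ]
  expect_error(prepare_samples(m, bad_map, 10), "does not cover")
})

test_that("the per-gene t-test matches closed forms and labels direction", {
  v <- rbind(G1 = c(1, 2, 3, 4, 5, 6))
  colnames(v) <- paste0("s", 1:6)
  m <- quant_matrix(v, "log2")
  groups <- setNames(rep(c("basal", "luminal"), each = 3), colnames(v))
  de <- differential_expression(m, groups, test = "student")
  # pooled-variance t with df = 4: t = (2 - 5) / sqrt(1 * (1/3 + 1/3))
  t_expected <- -3 / sqrt(2 / 3)
  expect_equal(de$t, t_expected, tolerance = 1e-6)
  expect_equal(de$p_value, 2 * pt(t_expected, df = 4), tolerance = 1e-6)
  expect_equal(de$p_value, 0.02131, tolerance = 1e-3)
  expect_equal(de$direction, "up_in_luminal")
  expect_equal(de$fold_change, 2^-3)

  # identical constant groups: guarded degenerate case
  vid <- rbind(G1 = rep(2, 6)); colnames(vid) <- colnames(v)
  de_id <- differential_expression(quant_matrix(vid, "log2"), groups)
  expect_equal(de_id$p_value, 1)
  expect_equal(de_id$fold_change, 1)
  expect_true(is.na(de_id$direction))

  # insufficient observations: untested, not an error
  vna <- rbind(G1 = c(1, NA, NA, 4, 5, 6)); colnames(vna) <- colnames(v)
  de_na <- differential_expression(quant_matrix(vna, "log2"), groups)
  expect_true(is.na(de_na$p_value))

  # Welch and Student agree on balanced equal-variance data directionally
  de_w <- differential_expression(m, groups, test = "welch")
  expect_equal(sign(de_w$t), sign(de$t))
})

test_that("BH adjustment equals the brute-force step-up oracle", {
  p4 <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(p.adjust(p4, "BH"), rep(0.04, 4))
  expect_equal(bh_oracle(p4), rep(0.04, 4))
  set.seed(99)
  for (i in 1:50) {
    p <- runif(sample(3:40, 1))
    expect_equal(p.adjust(p, "BH"), bh_oracle(p), tolerance = 1e-12)
  }
  # adjusted p never below raw p in the diffexp table
  tt <- run_cohort_diffexp(cohort_spec(n_kinases = 30, n_differential = 10,
                                       seed = 2))
  expect_true(all(tt$p_adj >= tt$p_value - 1e-12, na.rm = TRUE))
  # direction always matches the sign of the mean difference
  expect_true(all(ifelse(tt$log2_fc > 0, tt$direction == "up_in_basal",
                         tt$direction == "up_in_luminal")[tt$log2_fc != 0],
                  na.rm = TRUE))
})

test_that("clustering recovers planted subtypes and is deterministic", {
  co <- gen_cohort_matrix(cohort_spec(n_kinases = 50, n_differential = 30,
                                      log2_effect = 3, seed = 17))
  pm <- prepare_samples(cohort_log2(co), co$replicate_map, min_samples = 10)
  truth_labels <- co$groups[colnames(pm)]
  hc <- cluster_samples(pm, "hierarchical", k = 2)
  expect_equal(adjusted_rand_index(hc$labels, truth_labels), 1.0)
  km <- cluster_samples(pm, "kmeans", k = 2, seed = 7)
  expect_equal(adjusted_rand_index(km$labels, truth_labels), 1.0)
  km2 <- cluster_samples(pm, "kmeans", k = 2, seed = 7)
  expect_identical(km$labels, km2$labels)
  # k = n samples: every sample its own cluster
  kn <- cluster_samples(pm, "kmeans", k = ncol(pm), seed = 1)
  expect_equal(length(unique(kn$labels)), ncol(pm))
  expect_error(cluster_samples(pm, "kmeans", k = ncol(pm) + 1), "exceeds")
})

test_that("the package ARI agrees with the mclust reference", {
  skip_if_not_installed("mclust")
  set.seed(5)
  for (i in 1:20) {
    a <- sample(1:3, 30, replace = TRUE)
    b <- sample(1:3, 30, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
  expect_equal(adjusted_rand_index(1:5, c(2, 3, 4, 5, 1)), 1)
})

test_that("cross-dataset correlation is affine-invariant and null-calibrated", {
  co <- gen_cohort_matrix(cohort_spec(n_kinases = 20, n_differential = 5,
                                      seed = 3))
  a <- cohort_log2(co)
  b <- quant_matrix(2 * unclass(a) + 1, "log2")
  cc <- cross_dataset_correlation(a, b)
  expect_equal(cc$median_r, 1.0, tolerance = 1e-12)
  expect_true(all(abs(cc$per_gene$r - 1) < 1e-12))

  set.seed(11)
  meds <- vapply(1:10, function(i) {
    x <- matrix(rnorm(100 * 16), 100, 16,
                dimnames = list(paste0("g", 1:100), paste0("s", 1:16)))
    y <- matrix(rnorm(100 * 16), 100, 16, dimnames = dimnames(x))
    cross_dataset_correlation(quant_matrix(x, "log2"),
                              quant_matrix(y, "log2"))$median_r
  }, 0)
  expect_lt(max(abs(meds)), 0.15)

  # genes with too few shared complete pairs are excluded from the summary
  x <- matrix(rnorm(32), 2, 16, dimnames = list(c("g1", "g2"), paste0("s", 1:16)))
  y <- x; y["g2", 3:16] <- NA
  cc2 <- cross_dataset_correlation(quant_matrix(x, "log2"),
                                   quant_matrix(abs(y), "log2"))
  expect_error(cross_dataset_correlation(
    quant_matrix(x[1, , drop = FALSE] |> `rownames<-`("zz"), "log2"),
    quant_matrix(abs(y), "log2")), "no shared genes")
})

test_that("phospho rollup and RNA median-ratio transform", {
  sv <- rbind(site1 = c(1, 2), site2 = c(3, 6), site3 = c(NA, 10))
  colnames(sv) <- c("s1", "s2")
  smap <- tibble::tibble(site = rownames(sv), gene = c("G1", "G1", "G2"))
  pr <- phospho_rollup(quant_matrix(sv, "log2"), smap)
  expect_equal(unclass(pr)["G1", ], c(s1 = 2, s2 = 4))
  expect_true(is.na(unclass(pr)["G2", "s1"]))
  expect_equal(unclass(pr)["G2", "s2"], 10)  # single site passes through

  tpm <- rbind(G1 = c(10, 20, 40), G2 = c(7, 7, 7))
  colnames(tpm) <- paste0("s", 1:3)
  rt <- rna_transform(tpm, pseudocount = 0)
  expect_equal(unname(unclass(rt)["G1", ]), c(-1, 0, 1))
  expect_equal(unname(unclass(rt)["G2", ]), c(0, 0, 0))
  # row medians are zero by construction for every gene
  set.seed(2)
  big <- matrix(rexp(50 * 9, 0.1), 50, 9,
                dimnames = list(paste0("g", 1:50), paste0("s", 1:9)))
  rt2 <- rna_transform(big)
  expect_true(all(abs(apply(unclass(rt2), 1, median)) < 1e-12))
})
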