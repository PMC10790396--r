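test_that("boundary detection matches the Gaussian 5%-of-apex closed form", {
  dt <- 0.01
  tr <- make_gaussian_group(1000, apex = 10, sigma = 0.05, dt = dt)
  b <- detect_boundaries(tr, smooth_points = 1)
  width <- b$end_rt - b$start_rt
  expect_equal(width, 2 * 0.05 * sqrt(2 * log(20)), tolerance = dt / width * 1.5)
  # smoothing changes the boundary by at most a couple of samples
  b2 <- detect_boundaries(tr)
  expect_lt(abs((b2$end_rt - b2$start_rt) - width), 3 * dt)
  # flat zero trace: no peak, distinct from an error
  expect_null(detect_boundaries(make_trace(c(0, 1, 2, 3), rep(0, 4))))
})

test_that("boundary excludes an interference region away from the apex", {
  g <- gen_chromatograms(chrom_spec(n_peptides = 1, transitions_per_peptide = 2,
                                    apex_rt = 10, seed = 4,
                                    true_transition_areas = list(c(100, 100))))
  pep <- g$truth$peptide[1]
  gi <- gen_chromatograms(chrom_spec(n_peptides = 1, transitions_per_peptide = 2,
                                     apex_rt = 10, seed = 4,
                                     true_transition_areas = list(c(100, 100)),
                                     interference = data.frame(
                                       peptide = pep, fragment = "y3+",
                                       offset = 0.6, amplitude = 400)))
  b <- detect_boundaries(gi$traces)
  expect_gt(b$start_rt, 10 - 0.3)
  expect_lt(b$end_rt, 10 + 0.6 - 4 * 0.05)  # interference apex stays outside
})

test_that("trapezoidal integration matches closed forms", {
  tri <- make_trace(c(0, 1, 2), c(0, 100, 0))
  expect_equal(integrate_area(tri, list(start_rt = 0, end_rt = 2)), 100)
  expect_equal(integrate_area(make_trace(c(0, 1, 2), c(0, 0, 0)),
                              list(start_rt = 0, end_rt = 2)), 0)
  expect_error(integrate_area(tri, list(start_rt = -1, end_rt = 2)), "outside")

  A <- 5e4; sigma <- 0.05
  times <- seq(8, 12, by = 0.002)
  gauss <- make_trace(times, A * exp(-(times - 10)^2 / (2 * sigma^2)))
  got <- integrate_area(gauss, list(start_rt = 8, end_rt = 12))
  expect_equal(got, A * sigma * sqrt(2 * pi), tolerance = 0.01)

  # additivity over a partition of the boundary
  left <- integrate_area(gauss, list(start_rt = 8, end_rt = 10.0013))
  right <- integrate_area(gauss, list(start_rt = 10.0013, end_rt = 12))
  expect_equal(left + right, got, tolerance = 1e-9)

  # invariance to finer resampling
  times2 <- seq(8, 12, by = 0.001)
  gauss2 <- make_trace(times2, A * exp(-(times2 - 10)^2 / (2 * sigma^2)))
  expect_equal(integrate_area(gauss2, list(start_rt = 8, end_rt = 12)), got,
               tolerance = 0.01)
})

test_that("top-6 rule keeps the strongest concordant transitions", {
  # triangles with exact areas 10..80 -> top six sum to exactly 330
  areas <- seq(10, 80, by = 10)
  tr <- dplyr::bind_rows(lapply(seq_along(areas), function(j) {
    make_trace(c(0, 1, 2), c(0, areas[j], 0), fragment = sprintf("y%02d+", j))
  }))
  b <- list(start_rt = 0, end_rt = 2)
  cf <- concordance_filter(tr, b)
  expect_identical(cf$peptide_area, 330)
  expect_equal(nrow(cf$used), 6L)
  expect_setequal(cf$excluded$reason, "below_top_n")

  # only four transitions, all concordant -> all four used
  tr4 <- dplyr::bind_rows(lapply(1:4, function(j) {
    make_trace(c(0, 1, 2), c(0, 10 * j, 0), fragment = sprintf("y%02d+", j))
  }))
  cf4 <- concordance_filter(tr4, b)
  expect_equal(nrow(cf4$used), 4L)
  expect_identical(cf4$peptide_area, 100)
})

test_that("shape-discordant transitions are excluded with a reason", {
  # apex shifted by 3 sampling intervals on a broad peak: shape still
  # correlates above the cut, so the apex-displacement rule is what fires
  tr <- make_gaussian_group(rep(100, 7), apex = 10, sigma = 0.1,
                            dt = 0.01, apex_shift = c(rep(0, 6), 0.03))
  b <- detect_boundaries(tr)
  cf <- concordance_filter(tr, b)
  expect_equal(cf$excluded$fragment, "y09+")
  expect_equal(cf$excluded$reason, "apex_shift")

  # apex shifted by 5 intervals: excluded (apex and/or shape disagreement)
  tr5 <- make_gaussian_group(c(100, 100, 100, 100), apex = 10, sigma = 0.05,
                             dt = 0.01, apex_shift = c(0, 0, 0, 0.05))
  cf5 <- concordance_filter(tr5, detect_boundaries(tr5))
  expect_equal(cf5$excluded$fragment, "y06+")
  expect_true(cf5$excluded$reason %in% c("apex_shift", "low_concordance"))
  expect_equal(nrow(cf5$used), 3L)
})

test_that("peptide area grows when a concordant transition joins the top set", {
  areas <- c(50, 40, 30, 20)
  tr <- dplyr::bind_rows(lapply(seq_along(areas), function(j)
    make_trace(c(0, 1, 2), c(0, areas[j], 0), fragment = sprintf("y%02d+", j))))
  b <- list(start_rt = 0, end_rt = 2)
  base_area <- concordance_filter(tr, b)$peptide_area
  plus <- dplyr::bind_rows(tr, make_trace(c(0, 1, 2), c(0, 25, 0),
                                          fragment = "y99+"))
  expect_gte(concordance_filter(plus, b)$peptide_area, base_area)
})

test_that("noiseless planted areas survive the full quantification path", {
  sp <- chrom_spec(n_peptides = 3, transitions_per_peptide = 8,
                   apex_rt = c(8, 10, 12), noise_sd = 0, seed = 21)
  g <- gen_chromatograms(sp)
  q <- quantify_peptides(g$traces)
  truth6 <- g$truth |>
    dplyr::group_by(peptide) |>
    dplyr::summarise(a6 = sum(sort(true_area, decreasing = TRUE)[1:6]))
  m <- merge(q, truth6)
  expect_equal(m$peptide_area, m$a6, tolerance = 0.005)
  expect_true(all(m$n_used == 6L))
})

test_that("rollup sums peptides per gene and keeps absence as missing", {
  pq <- tibble::tibble(sample_id = c("s1", "s1", "s2"),
                       peptide = c("PEPA", "PEPB", "PEPA"),
                       peptide_area = c(100, 200, 150))
  map <- tibble::tibble(peptide = c("PEPA", "PEPB"), gene = c("EGFR", "EGFR"))
  m <- rollup_protein(pq, map)
  expect_equal(m["EGFR", "s1"], 300)
  expect_equal(m["EGFR", "s2"], 150)  # one peptide missing -> remaining one
  map2 <- tibble::tibble(peptide = c("PEPA", "PEPB", "PEPB"),
                         gene = c("EGFR", "EGFR", "RET"))
  expect_error(rollup_protein(pq, map2), "more than one gene")
  # gene with no detected peptide stays missing
  pq3 <- tibble::tibble(sample_id = "s1", peptide = "PEPA",
                        peptide_area = NA_real_)
  m3 <- rollup_protein(pq3, map)
  expect_true(is.na(m3["EGFR", "s1"]))
})

test_that("median normalization equalizes sample medians and preserves ratios", {
  v <- rbind(A = c(1, 2, 4), B = c(2, 4, 8), C = c(4, 8, 16))
  colnames(v) <- c("s1", "s2", "s3")
  m <- quant_matrix(v, "linear")  # medians 2, 4, 8
  nl <- normalize_log(m)
  meds <- apply(unclass(nl), 2, median)
  expect_equal(unname(meds), rep(2, 3), tolerance = 1e-9)  # log2(4)
  # within-sample gene ratios unchanged (pure shift in log space)
  expect_equal(unclass(nl)["B", ] - unclass(nl)["A", ], c(s1 = 1, s2 = 1, s3 = 1))
  # equal medians: no-op up to log2
  eq <- quant_matrix(rbind(A = c(2, 2), B = c(8, 8)) |>
                       `colnames<-`(c("x", "y")), "linear")
  nl_eq <- normalize_log(eq)
  expect_equal(as.vector(unclass(nl_eq)), as.vector(log2(unclass(eq))))
  allna <- quant_matrix(cbind(s1 = c(A = 1, B = 2), s2 = c(NA, NA)), "linear")
  expect_error(normalize_log(allna), "s2")
})

test_that("iBAQ divides by theoretical peptide counts and totals scale with input", {
  db <- structure(list(
    sequences = c(P1 = strrep("AAAAAAK", 10), P2 = "AAAAAAAAAA"),
    genes = c(P1 = "G1", P2 = "G2")), class = "fasta_db")
  v <- cbind(s1 = c(G1 = 1000, G2 = 50))
  ib <- compute_ibaq(quant_matrix(v, "linear"), db)
  expect_equal(ib$peptide_counts[["G1"]], 10L)
  expect_equal(unclass(ib$ibaq)["G1", "s1"], 100)
  expect_equal(unclass(ib$ibaq)["G2", "s1"], 50)  # single peptide: identity

  d <- gen_dilution_series(c(12.5, 25, 50, 100, 200), n_genes = 15, seed = 2)
  fdb <- gen_fasta_db(rownames(d$areas), seed = 3)
  tot <- compute_ibaq(d$areas, fdb)$totals
  expect_equal(unname(tot["ug100"] / tot["ug50"]), 2.0, tolerance = 0.05)
})

test_that("replicate CV matches closed forms and the lognormal calibration", {
  expect_equal(compute_cv(c(90, 110)), (20 / sqrt(2)) / 100, tolerance = 1e-9)
  expect_equal(compute_cv(c(5, 5, 5)), 0)
  expect_true(is.na(compute_cv(c(0, 0))))
  set.seed(77)
  sdlog <- sqrt(log(1 + 0.1^2))
  reps <- matrix(rlnorm(120 * 18, log(1e5), sdlog), nrow = 120)
  s <- cv_summary(reps)
  expect_gt(s$mean_cv, 0.07)
  expect_lt(s$mean_cv, 0.13)
  expect_true(s$range[1] >= 0 && s$range[2] < 0.3)
})

test_that("a planted two-fold change survives quantification at modest noise", {
  mk <- function(scale, seed) {
    sp <- chrom_spec(n_peptides = 1, transitions_per_peptide = 6, apex_rt = 10,
                     true_transition_areas = list(rep(1e5 * scale, 6)),
                     noise_sd = 3e3, seed = seed)
    gen_chromatograms(sp)$traces
  }
  a <- quantify_peptides(mk(1, 31))$peptide_area
  b <- quantify_peptides(mk(2, 32))$peptide_area
  expect_equal(b / a, 2, tolerance = 0.1)
})
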