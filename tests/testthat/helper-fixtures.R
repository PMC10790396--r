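# Shared fixtures and independent oracles. Oracles deliberately use a
# different algorithm than the implementation they check.

# Canonical trace tibble from time/intensity vectors.
make_trace <- function(time, intensity, fragment = "y3+", peptide = "ELVISLIVESK",
                       sample_id = "S1", charge = 2L, is_heavy = FALSE) {
  tibble::tibble(sample_id = sample_id, peptide = peptide, charge = charge,
                 fragment = fragment, time = time, intensity = intensity,
                 is_heavy = is_heavy)
}

# A group of Gaussian transitions with exact analytic areas on a fine grid.
make_gaussian_group <- function(areas, apex = 10, sigma = 0.05, dt = 0.005,
                                half_window = 2, apex_shift = rep(0, length(areas)),
                                peptide = "ELVISLIVESK") {
  times <- seq(apex - half_window, apex + half_window, by = dt)
  dplyr::bind_rows(lapply(seq_along(areas), function(j) {
    y <- areas[j] / (sigma * sqrt(2 * pi)) *
      exp(-(times - apex - apex_shift[j])^2 / (2 * sigma^2))
    make_trace(times, y, fragment = sprintf("y%02d+", j + 2), peptide = peptide)
  }))
}

# Brute-force Benjamini-Hochberg step-up: q_i = min over j >= i of p_(j)*m/j,
# computed by explicit double loop (no cummin, no p.adjust).
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    best <- Inf
    for (j in i:m) best <- min(best, p[o[j]] * m / j)
    q[o[i]] <- min(best, 1)
  }
  q
}

# Exhaustive tryptic-digest oracle: enumerate every residue position, mark
# cut points, count substrings in the length window.
digest_count_oracle <- function(seq, min_len = 7, max_len = 30) {
  aa <- strsplit(seq, "")[[1]]
  n <- length(aa)
  starts <- 1L
  count <- 0L
  for (i in seq_len(n)) {
    cut_here <- (aa[i] == "K" || aa[i] == "R") &&
      (i == n || aa[i + 1] != "P")
    if (cut_here || i == n) {
      len <- i - starts + 1L
      if (len >= min_len && len <= max_len) count <- count + 1L
      starts <- i + 1L
    }
  }
  count
}

random_aa_seq <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len, replace = TRUE),
        collapse = "")
}

# log2 matrix straight from a generated linear cohort matrix (the generators
# plant no loading differences, so no between-sample normalization is needed
# before testing).
cohort_log2 <- function(cohort) {
  quant_matrix(log2(unclass(cohort$matrix)), "log2")
}

# One full recovery run on a generated cohort: replicate averaging, filter,
# per-gene Student's t.
run_cohort_diffexp <- function(spec, min_samples = 10, test = "student") {
  co <- gen_cohort_matrix(spec)
  pm <- prepare_samples(cohort_log2(co), co$replicate_map,
                        min_samples = min_samples)
  de <- differential_expression(pm, co$groups, test = test)
  merge(de, co$truth, by = "gene")
}
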