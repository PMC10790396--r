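# Seeded generators with planted ground truth for every input the pipeline
# consumes: transition chromatograms, dilution and serial-depletion series,
# two-subtype cohort matrices, IS-PRM spectral streams, PSM archives and
# protein FASTA. Each generator is a pure function of its spec: the RNG state
# is localized, so the same seed always reproduces the same output.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

random_peptides <- function(n, min_len = 8, max_len = 14) {
  body_aa <- setdiff(AA_CANONICAL, c("K", "R", "P"))
  vapply(seq_len(n), function(i) {
    len <- sample(min_len:max_len, 1)
    paste0(paste(sample(body_aa, len - 1, replace = TRUE), collapse = ""),
           sample(c("K", "R"), 1))
  }, "")
}

# SILAC-style label masses: 13C6,15N2-lysine and 13C6,15N4-arginine.
LABEL_MASS <- c(K = 8.014199, R = 10.008269)

#' Heavy-to-light precursor mass offset
#'
#' Mass offset (m/z units) from a heavy isotope-labeled peptide to its light
#' endogenous twin, assuming a single C-terminal labeled K or R. Negative by
#' convention: light m/z = heavy m/z + offset.
#'
#' @param peptide Peptide sequence ending in K or R.
#' @param charge Precursor charge.
#' @return Negative m/z offset.
#' @export
label_mass_offset <- function(peptide, charge) {
  last <- substring(peptide, nchar(peptide), nchar(peptide))
  if (!last %in% names(LABEL_MASS))
    stop("peptide must end in K or R for a C-terminal label: ", peptide)
  -LABEL_MASS[[last]] / charge
}

#' Chromatogram generator specification
#'
#' Describes a set of synthetic PRM transition chromatograms: Gaussian elution
#' peaks with known analytic areas, optional i.i.d. noise, optional
#' interference peaks, and optional heavy-standard twins.
#'
#' @param n_peptides Number of peptides.
#' @param transitions_per_peptide Fragment traces per peptide (default 8).
#' @param apex_rt Apex retention time(s), minutes; recycled to `n_peptides`.
#' @param peak_sigma Gaussian peak width (minutes, default 0.05).
#' @param sampling_interval Time grid spacing (minutes, default 0.01); must be
#'   smaller than `peak_sigma`.
#' @param rt_window Scheduled window width per peptide (minutes, default 4);
#'   must contain apex +/- 4 sigma.
#' @param true_transition_areas Optional matrix/list of planted areas
#'   (peptides x transitions); drawn lognormally when `NULL`.
#' @param noise_sd Additive Gaussian noise sd on intensities (default 0).
#' @param interference Optional data.frame with columns `peptide`,
#'   `fragment` (`NA` = all fragments), `offset` (minutes from apex),
#'   `amplitude` (peak height); adds a same-width Gaussian interference peak.
#' @param heavy Also emit heavy-labeled twin traces with identical areas.
#' @param peptides Optional fixed peptide sequences (length `n_peptides`);
#'   drawn from the seed when `NULL`. Fixing them lets several samples share
#'   an assay panel while noise differs by seed.
#' @param seed RNG seed.
#' @return A `chrom_spec` list.
#' @export
chrom_spec <- function(n_peptides = 1, transitions_per_peptide = 8,
                       apex_rt = 10, peak_sigma = 0.05,
                       sampling_interval = 0.01, rt_window = 4,
                       true_transition_areas = NULL, noise_sd = 0,
                       interference = NULL, heavy = FALSE, peptides = NULL,
                       seed = 1) {
  if (sampling_interval >= peak_sigma)
    stop("sampling_interval must be smaller than peak_sigma (undersampling)")
  if (rt_window / 2 < 4 * peak_sigma)
    stop("rt_window must contain apex +/- 4 sigma")
  if (!is.null(true_transition_areas) && any(unlist(true_transition_areas) <= 0))
    stop("true transition areas must be positive")
  structure(list(n_peptides = n_peptides,
                 transitions_per_peptide = transitions_per_peptide,
                 apex_rt = rep_len(apex_rt, n_peptides),
                 peak_sigma = peak_sigma,
                 sampling_interval = sampling_interval,
                 rt_window = rt_window,
                 true_transition_areas = true_transition_areas,
                 noise_sd = noise_sd, interference = interference,
                 heavy = heavy, peptides = peptides, seed = seed),
            class = "chrom_spec")
}

gaussian_trace <- function(times, apex, sigma, area) {
  area / (sigma * sqrt(2 * pi)) * exp(-(times - apex)^2 / (2 * sigma^2))
}

#' Generate synthetic transition chromatograms with planted areas
#'
#' Each trace is a Gaussian elution peak scaled so that its analytic area
#' equals the planted area, sampled on a regular grid over the scheduled
#' window, plus optional additive noise (clamped at zero) and optional
#' interference peaks. Heavy twins carry the same planted areas.
#'
#' @param spec A [chrom_spec()].
#' @param sample_id Sample id stamped on every trace.
#' @return List with `traces` (canonical transition tibble) and `truth`
#'   (tibble: peptide, fragment, is_heavy, true_area, apex_rt).
#' @export
gen_chromatograms <- function(spec, sample_id = "S1") {
  stopifnot(inherits(spec, "chrom_spec"))
  with_seed(spec$seed, {
    peptides <- if (is.null(spec$peptides)) {
      random_peptides(spec$n_peptides)
    } else {
      stopifnot(length(spec$peptides) == spec$n_peptides)
      spec$peptides
    }
    k <- spec$transitions_per_peptide
    areas <- spec$true_transition_areas
    if (is.null(areas)) {
      areas <- matrix(stats::rlnorm(spec$n_peptides * k, log(1e5), 0.5),
                      nrow = spec$n_peptides)
    } else {
      areas <- matrix(unlist(areas), nrow = spec$n_peptides, byrow = TRUE)
      stopifnot(ncol(areas) == k)
    }
    frag_labels <- paste0("y", seq_len(k) + 2, "+")
    trace_list <- list()
    truth_list <- list()
    labels <- if (spec$heavy) c(FALSE, TRUE) else FALSE
    for (i in seq_len(spec$n_peptides)) {
      apex <- spec$apex_rt[i]
      half <- spec$rt_window / 2
      times <- seq(apex - half, apex + half, by = spec$sampling_interval)
      for (j in seq_len(k)) {
        signal <- gaussian_trace(times, apex, spec$peak_sigma, areas[i, j])
        intf <- spec$interference
        if (!is.null(intf)) {
          hit <- intf$peptide == peptides[i] &
            (is.na(intf$fragment) | intf$fragment == frag_labels[j])
          for (r in which(hit)) {
            signal <- signal + intf$amplitude[r] *
              exp(-(times - apex - intf$offset[r])^2 / (2 * spec$peak_sigma^2))
          }
        }
        for (hv in labels) {
          y <- signal
          if (spec$noise_sd > 0)
            y <- pmax(0, y + stats::rnorm(length(y), 0, spec$noise_sd))
          trace_list[[length(trace_list) + 1]] <- tibble(
            sample_id = sample_id, peptide = peptides[i], charge = 2L,
            fragment = frag_labels[j], time = times, intensity = y,
            is_heavy = hv)
          truth_list[[length(truth_list) + 1]] <- tibble(
            peptide = peptides[i], fragment = frag_labels[j], is_heavy = hv,
            true_area = areas[i, j], apex_rt = apex)
        }
      }
    }
    list(traces = dplyr::bind_rows(trace_list),
         truth = dplyr::bind_rows(truth_list))
  })
}

#' Generate a dilution series with linear and saturating genes
#'
#' Emulates enrichment response curves across protein input amounts: linear
#' genes have area proportional to input, saturating genes follow
#' `area = A * input / (input + K)` (Michaelis-like bead saturation).
#' Multiplicative lognormal noise at `noise_cv` is applied per measurement.
#'
#' @param inputs_ug Input amounts in micrograms, e.g. `c(12.5, 25, 50, 100, 200)`.
#' @param n_genes Number of genes.
#' @param saturating_genes Character vector of gene names (from `G1..Gn`) that
#'   saturate, or an integer count (the first k genes).
#' @param K Saturation constant in micrograms (default 25).
#' @param noise_cv Technical CV of the multiplicative noise (default 0).
#' @param seed RNG seed.
#' @return List with `areas` (linear [quant_matrix()], genes x levels; sample
#'   ids `"ug<input>"`), `truth` (gene, type, base response, K), and
#'   `inputs_ug`.
#' @export
gen_dilution_series <- function(inputs_ug, n_genes = 20,
                                saturating_genes = character(), K = 25,
                                noise_cv = 0, seed = 1) {
  if (any(inputs_ug <= 0)) stop("input levels must be positive")
  genes <- paste0("G", seq_len(n_genes))
  if (is.numeric(saturating_genes))
    saturating_genes <- utils::head(genes, saturating_genes)
  stopifnot(all(saturating_genes %in% genes))
  with_seed(seed, {
    base <- stats::rlnorm(n_genes, log(1e4), 1)
    names(base) <- genes
    expected <- sapply(inputs_ug, function(u) {
      ifelse(genes %in% saturating_genes,
             base * u / (u + K) * (max(inputs_ug) + K),  # comparable magnitude
             base * u)
    })
    sdlog <- sqrt(log(1 + noise_cv^2))
    noise <- if (noise_cv > 0) {
      matrix(stats::rlnorm(length(expected), -sdlog^2 / 2, sdlog),
             nrow = n_genes)
    } else 1
    values <- expected * noise
    dimnames(values) <- list(genes, paste0("ug", inputs_ug))
    list(areas = quant_matrix(values, "linear"),
         truth = tibble(gene = genes,
                        type = ifelse(genes %in% saturating_genes,
                                      "saturating", "linear"),
                        base = unname(base),
                        K = ifelse(genes %in% saturating_genes, K, NA_real_)),
         inputs_ug = inputs_ug)
  })
}

#' Serial-depletion generator specification
#'
#' A kinome enrichment repeated on the supernatant of the previous round with
#' a constant per-round binding fraction `f`: the round-k capture of a kinase
#' with total abundance `A` is `A * f * (1 - f)^k` (geometric decay). A
#' kinase is "identified" in a round when its captured abundance reaches the
#' detection floor. The default abundance spread (lognormal, `sdlog` 1.9045)
#' and floor (`exp(meanlog - 2.9507)`) are calibrated so that, under f = 0.7,
#' identification falls to 84% of the round-0 count after one depletion and
#' 59% after two, the decay characteristic of kinobead depletion experiments.
#'
#' @param n_kinases Number of kinases (default 330, giving ~300 identified in
#'   round 0).
#' @param binding_fraction Per-round capture fraction `f` in (0, 1), default 0.7.
#' @param n_rounds Rounds including the original pulldown (default 3).
#' @param abundance_meanlog,abundance_sdlog Lognormal parameters of total
#'   kinase abundance.
#' @param detection_floor Captured abundance below which a kinase is not
#'   identified; default `exp(abundance_meanlog - 2.9507)`.
#' @param noise_cv Multiplicative measurement CV (default 0 = noiseless).
#' @param seed RNG seed.
#' @return A `depletion_spec` list.
#' @export
depletion_spec <- function(n_kinases = 330, binding_fraction = 0.7,
                           n_rounds = 3, abundance_meanlog = log(1e6),
                           abundance_sdlog = 1.9045,
                           detection_floor = exp(abundance_meanlog - 2.9507),
                           noise_cv = 0, seed = 1) {
  if (binding_fraction <= 0 || binding_fraction >= 1)
    stop("binding_fraction must be in (0, 1)")
  structure(list(n_kinases = n_kinases, binding_fraction = binding_fraction,
                 n_rounds = n_rounds, abundance_meanlog = abundance_meanlog,
                 abundance_sdlog = abundance_sdlog,
                 detection_floor = detection_floor, noise_cv = noise_cv,
                 seed = seed),
            class = "depletion_spec")
}

#' Generate a serial-depletion abundance matrix
#'
#' @param spec A [depletion_spec()].
#' @return List with `matrix` (linear [quant_matrix()], kinases x rounds,
#'   samples `"round0"..`; cells below the detection floor are `NA`), `truth`
#'   (gene, total abundance, per-round expected capture) and the spec.
#' @export
gen_depletion_series <- function(spec) {
  stopifnot(inherits(spec, "depletion_spec"))
  with_seed(spec$seed, {
    genes <- paste0("KIN", seq_len(spec$n_kinases))
    A <- stats::rlnorm(spec$n_kinases, spec$abundance_meanlog,
                       spec$abundance_sdlog)
    f <- spec$binding_fraction
    rounds <- seq_len(spec$n_rounds) - 1L
    expected <- outer(A, rounds, function(a, k) a * f * (1 - f)^k)
    sdlog <- sqrt(log(1 + spec$noise_cv^2))
    values <- if (spec$noise_cv > 0) {
      expected * matrix(stats::rlnorm(length(expected), -sdlog^2 / 2, sdlog),
                        nrow = spec$n_kinases)
    } else expected
    values[values < spec$detection_floor] <- NA
    dimnames(values) <- list(genes, paste0("round", rounds))
    list(matrix = quant_matrix(values, "linear"),
         truth = tibble(gene = genes, abundance = A),
         spec = spec)
  })
}

#' Two-subtype cohort generator specification
#'
#' Describes a synthetic basal-vs-luminal kinase abundance cohort measured in
#' technical replicates: per-gene base abundances are lognormal, planted
#' differential genes get a `log2_effect` shift of the subtype mean (up in
#' basal for the first `n_up_basal`, up in luminal for the rest), every
#' replicate measurement is multiplied by lognormal technical noise at the
#' stated CV, and cells go missing completely at random.
#'
#' @param n_basal,n_luminal Biological samples per subtype (>= 2 each).
#' @param n_kinases Genes in the matrix.
#' @param n_differential Planted differential genes (<= `n_kinases`).
#' @param log2_effect Absolute log2 mean shift of differential genes.
#' @param n_up_basal How many of the differential genes are up in basal
#'   (default half, rounded down).
#' @param base_meanlog,base_sdlog Lognormal parameters of base abundance.
#' @param technical_cv Technical CV of replicate noise (default 0.10).
#' @param technical_replicates Replicates per biological sample (default 2).
#' @param missing_rate MCAR missingness per cell (default 0).
#' @param seed RNG seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_basal = 8, n_luminal = 8, n_kinases = 100,
                        n_differential = 36, log2_effect = 2,
                        n_up_basal = n_differential %/% 2,
                        base_meanlog = log(1e5), base_sdlog = 1,
                        technical_cv = 0.10, technical_replicates = 2,
                        missing_rate = 0, seed = 1) {
  if (n_basal < 2 || n_luminal < 2)
    stop("need at least 2 samples per subtype")
  if (n_differential > n_kinases)
    stop("n_differential exceeds n_kinases")
  if (n_up_basal > n_differential) stop("n_up_basal exceeds n_differential")
  if (technical_cv < 0) stop("technical_cv must be >= 0")
  structure(list(n_basal = n_basal, n_luminal = n_luminal,
                 n_kinases = n_kinases, n_differential = n_differential,
                 log2_effect = log2_effect, n_up_basal = n_up_basal,
                 base_meanlog = base_meanlog, base_sdlog = base_sdlog,
                 technical_cv = technical_cv,
                 technical_replicates = technical_replicates,
                 missing_rate = missing_rate, seed = seed),
            class = "cohort_spec")
}

#' Generate a two-subtype cohort matrix with planted truth
#'
#' @param spec A [cohort_spec()].
#' @return List with `matrix` (linear [quant_matrix()], genes x replicate
#'   columns named `<sample>_rep<i>`), `replicate_map` (tibble: column,
#'   sample), `groups` (named subtype per biological sample) and `truth`
#'   (tibble: gene, differential flag, direction `up_in_basal`/`up_in_luminal`
#'   or `NA`).
#' @export
gen_cohort_matrix <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    genes <- paste0("KIN", seq_len(spec$n_kinases))
    bio <- c(paste0("basal", sprintf("%02d", seq_len(spec$n_basal))),
             paste0("luminal", sprintf("%02d", seq_len(spec$n_luminal))))
    groups <- stats::setNames(rep(c("basal", "luminal"),
                                  c(spec$n_basal, spec$n_luminal)), bio)
    base <- stats::rlnorm(spec$n_kinases, spec$base_meanlog, spec$base_sdlog)
    diff_idx <- seq_len(spec$n_differential)
    direction <- rep(NA_character_, spec$n_kinases)
    direction[diff_idx] <- c(rep("up_in_basal", spec$n_up_basal),
                             rep("up_in_luminal",
                                 spec$n_differential - spec$n_up_basal))
    # symmetric half-effect on each subtype mean
    shift <- matrix(0, spec$n_kinases, length(bio))
    half <- spec$log2_effect / 2
    is_basal <- groups[bio] == "basal"
    shift[direction == "up_in_basal" & !is.na(direction), is_basal] <- half
    shift[direction == "up_in_basal" & !is.na(direction), !is_basal] <- -half
    shift[direction == "up_in_luminal" & !is.na(direction), is_basal] <- -half
    shift[direction == "up_in_luminal" & !is.na(direction), !is_basal] <- half
    biological <- base * 2^shift
    reps <- spec$technical_replicates
    cols <- as.vector(t(outer(bio, seq_len(reps),
                              function(s, r) paste0(s, "_rep", r))))
    sdlog <- sqrt(log(1 + spec$technical_cv^2))
    values <- matrix(NA_real_, spec$n_kinases, length(cols),
                     dimnames = list(genes, cols))
    for (s in seq_along(bio)) {
      for (r in seq_len(reps)) {
        noise <- if (spec$technical_cv > 0) {
          stats::rlnorm(spec$n_kinases, -sdlog^2 / 2, sdlog)
        } else 1
        values[, (s - 1) * reps + r] <- biological[, s] * noise
      }
    }
    if (spec$missing_rate > 0) {
      drop <- stats::runif(length(values)) < spec$missing_rate
      values[drop] <- NA
    }
    list(matrix = quant_matrix(values, "linear"),
         replicate_map = tibble(column = cols,
                                sample = rep(bio, each = reps)),
         groups = groups,
         truth = tibble(gene = genes,
                        differential = !is.na(direction),
                        direction = direction))
  })
}

#' Generate an IS-PRM spectral stream with planted truth
#'
#' Emits a time-ordered stream of survey scans for an internal-standard
#' triggered acquisition run. Each target contributes one survey appearance of
#' its heavy precursor (with optional ppm jitter) at its elution apex; its
#' heavy MS2 contains the full listed product-ion set. Decoy precursors match
#' a target's m/z but emit at most 3 of the 6 listed product ions, so the
#' >= 4-ion trigger rule must never fire on them. Light (endogenous) signal
#' exists only for targets in `endogenous_present`.
#'
#' @param n_targets Number of heavy targets (>= 1).
#' @param endogenous_present Character vector of target peptides (or indices)
#'   with endogenous light signal; default all.
#' @param ppm_jitter_sd Gaussian sd of the observed precursor m/z error (ppm).
#' @param decoy_rate Expected decoys per target (Poisson).
#' @param seed RNG seed.
#' @param rt_window Scheduling window minutes (default 4).
#' @return List with `stream` (list of survey scans: `time`, `precursors`
#'   tibble (mz, intensity, scan_ref), `ms2` product tables and `light_signal`
#'   lookup), `inclusion` (tibble of inclusion entries with list-column
#'   `product_ion_mzs`), and `truth` (tibble: peptide, endogenous,
#'   light_total_intensity).
#' @export
gen_isprm_stream <- function(n_targets, endogenous_present = NULL,
                             ppm_jitter_sd = 0, decoy_rate = 0, seed = 1,
                             rt_window = 4) {
  if (n_targets < 1) stop("n_targets must be >= 1")
  with_seed(seed, {
    peptides <- random_peptides(n_targets)
    if (is.null(endogenous_present)) endogenous_present <- peptides
    if (is.numeric(endogenous_present))
      endogenous_present <- peptides[endogenous_present]
    charge <- 2L
    heavy_mz <- stats::runif(n_targets, 400, 1000)
    offset <- vapply(peptides, label_mass_offset, 0, charge = charge)
    apex <- sort(stats::runif(n_targets, 5, 40))
    n_products <- 6L
    product_mzs <- lapply(seq_len(n_targets), function(i)
      sort(stats::runif(n_products, 200, 1400)))
    inclusion <- tibble(
      peptide = peptides, heavy_mz = heavy_mz, charge = charge,
      product_ion_mzs = product_mzs, mass_offset_mz = unname(offset),
      rt_start = apex - rt_window / 2, rt_end = apex + rt_window / 2)

    jitter <- function(mz) mz * (1 + stats::rnorm(length(mz), 0, ppm_jitter_sd) * 1e-6)
    scans <- list()
    light_signal <- stats::setNames(vector("list", n_targets), peptides)
    truth_light <- numeric(n_targets)
    for (i in seq_len(n_targets)) {
      hv_int <- stats::rlnorm(1, log(1e7), 0.3)
      ms2 <- tibble(mz = jitter(product_mzs[[i]]),
                    intensity = stats::rlnorm(n_products, log(1e6), 0.4))
      scan <- list(time = apex[i],
                   precursors = tibble(mz = jitter(heavy_mz[i]),
                                       intensity = hv_int,
                                       id = paste0("hv_", i)),
                   ms2 = stats::setNames(list(ms2), paste0("hv_", i)))
      if (peptides[i] %in% endogenous_present) {
        li <- tibble(mz = jitter(product_mzs[[i]] + offset[i] * 0),
                     intensity = stats::rlnorm(n_products, log(5e5), 0.4))
        # light product ions share fragment m/z except for label-bearing ones;
        # the simulator quantifies from the listed (shared) set.
        light_signal[[peptides[i]]] <- li
        truth_light[i] <- sum(li$intensity)
      } else {
        light_signal[[peptides[i]]] <- tibble(mz = numeric(), intensity = numeric())
      }
      n_decoys <- if (decoy_rate > 0) stats::rpois(1, decoy_rate) else 0L
      if (n_decoys > 0) {
        for (d in seq_len(n_decoys)) {
          k <- sample(0:3, 1)  # decoys emit <= 3 listed ions by construction
          dm <- if (k > 0) sample(product_mzs[[i]], k) else numeric()
          # filler ions are rejection-sampled away from every listed mass so
          # the <=3-listed contract cannot be broken by chance collisions
          filler <- numeric(0)
          while (length(filler) < 4) {
            cand <- stats::runif(8, 200, 1400)
            ok <- vapply(cand, function(mz)
              all(abs(mz - product_mzs[[i]]) / product_mzs[[i]] * 1e6 > 50),
              TRUE)
            filler <- c(filler, cand[ok])
          }
          filler <- filler[1:4]
          dm2 <- tibble(mz = c(jitter(dm), filler),
                        intensity = stats::rlnorm(length(dm) + 4, log(8e5), 0.4))
          id <- paste0("decoy_", i, "_", d)
          scan$precursors <- dplyr::bind_rows(
            scan$precursors,
            tibble(mz = jitter(heavy_mz[i]), intensity = stats::rlnorm(1, log(5e6), 0.3),
                   id = id))
          scan$ms2[[id]] <- dm2
        }
      }
      scans[[i]] <- scan
    }
    list(stream = list(scans = scans, light_signal = light_signal),
         inclusion = inclusion,
         truth = tibble(peptide = peptides,
                        endogenous = peptides %in% endogenous_present,
                        decoy_ids = I(lapply(seq_len(n_targets), function(i)
                          grep(paste0("^decoy_", i, "_"),
                               scans[[i]]$precursors$id, value = TRUE))),
                        light_total_intensity = truth_light))
  })
}

#' Generate a PSM archive with planted "good" panel peptides
#'
#' For each gene, plants `n_good` clean candidates (high ion score, low
#' modification fraction, fully tryptic, unshared) among peptides that each
#' violate one selection rule, so that rule-based panel design has a known
#' answer.
#'
#' @param n_genes Number of genes.
#' @param n_good Clean candidates per gene (default 3).
#' @param n_bad Rule-violating candidates per gene (default 4).
#' @param seed RNG seed.
#' @return List with `psms` (tibble in [read_psm_table()] layout, list-column
#'   `gene_ids`) and `truth` (tibble: gene, peptide, planted_good).
#' @export
gen_psm_archive <- function(n_genes = 10, n_good = 3, n_bad = 4, seed = 1) {
  with_seed(seed, {
    rows <- list()
    truth <- list()
    for (g in seq_len(n_genes)) {
      gene <- paste0("KIN", g)
      peps <- random_peptides(n_good + n_bad)
      for (i in seq_along(peps)) {
        good <- i <= n_good
        psm <- as.integer(round(stats::rlnorm(1, log(200), 0.5))) + 5L
        rec <- tibble(
          peptide = peps[i],
          gene_ids = list(gene),
          psm_count = psm,
          modified_psm_count = as.integer(floor(psm * stats::runif(1, 0, 0.05))),
          best_ion_score = stats::runif(1, 40, 90),
          missed_cleavages = 0L,
          is_subpeptide_of_miscleaved = FALSE,
          shared_with_mouse = FALSE,
          covers_all_isoforms = TRUE,
          q_value = stats::runif(1, 0, 0.04))
        if (!good) {
          defect <- (i - n_good - 1) %% 4
          if (defect == 0) rec$best_ion_score <- stats::runif(1, 5, 19)
          if (defect == 1) rec$modified_psm_count <- as.integer(ceiling(psm * 0.2))
          if (defect == 2) rec$missed_cleavages <- 1L
          if (defect == 3) rec$gene_ids <- list(c(gene, paste0("KIN", g %% n_genes + 1)))
        }
        rows[[length(rows) + 1]] <- rec
        truth[[length(truth) + 1]] <- tibble(gene = gene, peptide = peps[i],
                                             planted_good = good)
      }
    }
    list(psms = dplyr::bind_rows(rows), truth = dplyr::bind_rows(truth))
  })
}

#' Generate a protein FASTA database for a gene set
#'
#' Random canonical-residue sequences (one accession per gene) for iBAQ
#' denominators; written with Biostrings so [read_fasta_db()] round-trips.
#'
#' @param genes Gene symbols.
#' @param length_range Protein length range (residues).
#' @param seed RNG seed.
#' @return A `fasta_db` object (see [read_fasta_db()]).
#' @export
gen_fasta_db <- function(genes, length_range = c(300, 800), seed = 1) {
  with_seed(seed, {
    seqs <- vapply(seq_along(genes), function(i) {
      len <- sample(length_range[1]:length_range[2], 1)
      paste(sample(AA_CANONICAL, len, replace = TRUE), collapse = "")
    }, "")
    acc <- paste0("SYN", sprintf("%04d", seq_along(genes)))
    names(seqs) <- acc
    structure(list(sequences = seqs,
                   genes = stats::setNames(genes, acc)),
              class = "fasta_db")
  })
}

#' Write a `fasta_db` to a FASTA file
#' @param db A `fasta_db`.
#' @param path Output path.
#' @export
write_fasta_db <- function(db, path) {
  stopifnot(inherits(db, "fasta_db"))
  x <- Biostrings::AAStringSet(db$sequences)
  names(x) <- paste0(names(db$sequences), " GN=", unname(db$genes))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
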