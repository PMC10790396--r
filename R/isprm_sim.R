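# Internal-standard triggered PRM acquisition logic, replayed as a
# deterministic event loop: survey scan -> ppm match of heavy standards on
# the inclusion list -> pseudo-spectral product-ion matching -> if at least
# four listed product ions are found, a light (endogenous) MS2 at the
# defined mass offset. Instrument physics (AGC, injection time) is not
# modeled; scheduling is event-driven.

#' Relative mass-tolerance match
#'
#' `TRUE` iff `|observed - target| / target * 1e6 <= tol_ppm`.
#'
#' @param observed_mz,target_mz Positive m/z values (vectorized).
#' @param tol_ppm Tolerance in parts per million.
#' @return Logical.
#' @export
ppm_match <- function(observed_mz, target_mz, tol_ppm) {
  if (any(observed_mz <= 0) || any(target_mz <= 0))
    stop("m/z values must be positive")
  abs(observed_mz - target_mz) / target_mz * 1e6 <= tol_ppm
}

#' Select survey-scan precursors against an inclusion list
#'
#' Precursors matching any inclusion entry within `tol_ppm` and reaching the
#' intensity threshold are isolated, capped at `max_ions` by descending
#' intensity.
#'
#' @param precursors Tibble with `mz`, `intensity` and an `id` column.
#' @param inclusion Inclusion tibble (needs `peptide`, `heavy_mz`).
#' @param tol_ppm Precursor tolerance (default 10 ppm, survey mode).
#' @param intensity_min Intensity threshold (default 1e5).
#' @param max_ions Isolation cap per survey scan (default 70).
#' @return Tibble of isolated precursors with a `peptide` column giving the
#'   best-matching (smallest ppm error) inclusion entry.
#' @export
survey_select <- function(precursors, inclusion, tol_ppm = 10,
                          intensity_min = 1e5, max_ions = 70) {
  if (nrow(inclusion) == 0 || nrow(precursors) == 0) {
    return(tibble(mz = numeric(), intensity = numeric(), id = character(),
                  peptide = character()))
  }
  best <- vapply(precursors$mz, function(mz) {
    err <- abs(mz - inclusion$heavy_mz) / inclusion$heavy_mz * 1e6
    i <- which.min(err)
    if (err[i] <= tol_ppm) i else NA_integer_
  }, 0L)
  keep <- !is.na(best) & precursors$intensity >= intensity_min
  out <- precursors[keep, , drop = FALSE]
  out$peptide <- inclusion$peptide[best[keep]]
  out <- out[order(-out$intensity), , drop = FALSE]
  utils::head(out, max_ions)
}

#' Pseudo-spectral matching of a heavy MS2 against listed product ions
#'
#' Counts how many of the entry's listed product-ion m/z values are present
#' in the scan within `tol_ppm`; the light-scan trigger fires iff at least
#' `min_ions` are found.
#'
#' @param ms2 Tibble of product peaks (`mz`, `intensity`).
#' @param product_ion_mzs Numeric vector of listed product-ion m/z (>= 4).
#' @param tol_ppm Product-ion tolerance (default 10 ppm).
#' @param min_ions Trigger threshold (default 4).
#' @return List: `matched_count`, `triggered`.
#' @export
pseudo_spectral_match <- function(ms2, product_ion_mzs, tol_ppm = 10,
                                  min_ions = 4) {
  if (length(product_ion_mzs) < min_ions)
    stop("inclusion entry lists fewer product ions (",
         length(product_ion_mzs), ") than the trigger threshold")
  matched <- vapply(product_ion_mzs, function(mz) {
    nrow(ms2) > 0 && any(ppm_match(ms2$mz, mz, tol_ppm))
  }, TRUE)
  list(matched_count = sum(matched), triggered = sum(matched) >= min_ions)
}

#' Replay an IS-PRM acquisition over a spectral stream
#'
#' Runs the event loop over time-ordered survey scans: precursor selection
#' against the inclusion list (heavy tolerance, default 3 ppm), heavy MS2
#' pseudo-spectral matching, and — only when the trigger fires — a light MS2
#' at `heavy_mz + mass_offset_mz` whose quantity is the summed intensity of
#' listed product ions found in the endogenous signal. Every decision is
#' logged; light events can only follow a satisfied trigger by construction,
#' and the log makes that auditable.
#'
#' @param sim Output of [gen_isprm_stream()] (or a list with the same
#'   `stream`/`inclusion` shape).
#' @param precursor_tol_ppm Heavy precursor match tolerance (default 3).
#' @param product_tol_ppm Product-ion match tolerance (default 10).
#' @param min_ions Trigger threshold (default 4).
#' @param intensity_min Survey intensity threshold (default 1e5).
#' @param max_ions Isolation cap (default 70).
#' @return List with `log` (tibble: time, kind, peptide, precursor_id,
#'   matched_product_count, triggered) and `quantities` (named light
#'   quantities per target peptide; `NA` when never triggered).
#' @export
run_acquisition <- function(sim, precursor_tol_ppm = 3, product_tol_ppm = 10,
                            min_ions = 4, intensity_min = 1e5, max_ions = 70) {
  scans <- sim$stream$scans
  inclusion <- sim$inclusion
  times <- vapply(scans, `[[`, 0, "time")
  if (is.unsorted(times, strictly = FALSE))
    stop("spectral stream is not time-ordered")
  log_rows <- list()
  quantities <- stats::setNames(rep(NA_real_, nrow(inclusion)),
                                inclusion$peptide)
  for (scan in scans) {
    log_rows[[length(log_rows) + 1]] <- tibble(
      time = scan$time, kind = "survey", peptide = NA_character_,
      precursor_id = NA_character_,
      matched_product_count = NA_integer_, triggered = NA)
    isolated <- survey_select(scan$precursors, inclusion,
                              tol_ppm = precursor_tol_ppm,
                              intensity_min = intensity_min,
                              max_ions = max_ions)
    for (i in seq_len(nrow(isolated))) {
      pep <- isolated$peptide[i]
      entry <- inclusion[inclusion$peptide == pep, ]
      ms2 <- scan$ms2[[isolated$id[i]]]
      psm <- pseudo_spectral_match(ms2, entry$product_ion_mzs[[1]],
                                   tol_ppm = product_tol_ppm,
                                   min_ions = min_ions)
      log_rows[[length(log_rows) + 1]] <- tibble(
        time = scan$time, kind = "heavy_ms2", peptide = pep,
        precursor_id = isolated$id[i],
        matched_product_count = psm$matched_count, triggered = psm$triggered)
      if (psm$triggered) {
        light <- sim$stream$light_signal[[pep]]
        qty <- 0
        if (!is.null(light) && nrow(light) > 0) {
          hit <- vapply(entry$product_ion_mzs[[1]], function(mz) {
            m <- ppm_match(light$mz, mz, product_tol_ppm)
            if (any(m)) max(light$intensity[m]) else 0
          }, 0)
          qty <- sum(hit)
        }
        quantities[pep] <- sum(quantities[pep], qty, na.rm = TRUE)
        log_rows[[length(log_rows) + 1]] <- tibble(
          time = scan$time, kind = "light_ms2", peptide = pep,
          precursor_id = isolated$id[i],
          matched_product_count = NA_integer_, triggered = TRUE)
      }
    }
  }
  list(log = dplyr::bind_rows(log_rows), quantities = quantities)
}

#' Total-ion-current normalization
#'
#' Divides each sample's quantities by its total ion current (a proxy for
#' total peptide input after enrichment) and rescales by the mean TIC so
#' magnitudes stay comparable to the input scale.
#'
#' @param quantities Numeric matrix (features x samples) or vector (one
#'   feature across samples).
#' @param tic Positive per-sample total ion current, matching the samples.
#' @return Normalized quantities, same shape as the input.
#' @export
tic_normalize <- function(quantities, tic) {
  if (any(tic <= 0)) stop("TIC must be positive for every sample")
  scale <- mean(tic) / tic
  if (is.matrix(quantities)) {
    if (ncol(quantities) != length(tic))
      stop("tic length must match sample count")
    sweep(quantities, 2, scale, `*`)
  } else {
    if (length(quantities) != length(tic))
      stop("tic length must match sample count")
    quantities * scale
  }
}
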