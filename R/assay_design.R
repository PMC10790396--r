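# Rule-based PRM panel design: candidate peptides per gene are excluded or
# deprioritized by spectral-evidence rules, the survivors ranked by observed
# PSM count, and the shortlist then judged on dilution response curves
# (linearity, peak symmetry, interference) before the final 2-4 peptides per
# gene are fixed.

#' Panel-design selection criteria
#'
#' @param min_ion_score Minimum best Mascot-style ion score (default 20;
#'   candidates below are excluded as `low_score`).
#' @param max_modified_fraction Maximum fraction of PSMs carrying a
#'   modification (default 0.10; above is excluded as `modified_fraction`).
#' @param allow_missed_cleavage Keep candidates with missed cleavages
#'   (default `FALSE`).
#' @param exclude_subpeptides_of_miscleaved Exclude peptides that are
#'   subsequences of frequently miscleaved forms (default `TRUE`).
#' @param exclude_shared_genes Exclude sequences shared across gene products
#'   (default `TRUE`).
#' @param deprioritize_mouse_shared Deprioritize (not exclude) peptides whose
#'   sequence is conserved in mouse — relevant when xenograft stroma
#'   contributes murine background (default `TRUE`).
#' @param shortlist_size Range of peptides per gene advanced to response
#'   evaluation (default 3-6).
#' @param final_size Range of peptides per gene in the final panel
#'   (default 2-4).
#' @return A `selection_criteria` list.
#' @export
selection_criteria <- function(min_ion_score = 20,
                               max_modified_fraction = 0.10,
                               allow_missed_cleavage = FALSE,
                               exclude_subpeptides_of_miscleaved = TRUE,
                               exclude_shared_genes = TRUE,
                               deprioritize_mouse_shared = TRUE,
                               shortlist_size = c(3, 6),
                               final_size = c(2, 4)) {
  stopifnot(max_modified_fraction >= 0, max_modified_fraction <= 1,
            length(shortlist_size) == 2, length(final_size) == 2)
  structure(list(min_ion_score = min_ion_score,
                 max_modified_fraction = max_modified_fraction,
                 allow_missed_cleavage = allow_missed_cleavage,
                 exclude_subpeptides_of_miscleaved = exclude_subpeptides_of_miscleaved,
                 exclude_shared_genes = exclude_shared_genes,
                 deprioritize_mouse_shared = deprioritize_mouse_shared,
                 shortlist_size = shortlist_size, final_size = final_size),
            class = "selection_criteria")
}

#' Apply selection rules to one gene's candidate peptides
#'
#' Exclusion reasons accumulate in a fixed order (`low_score`,
#' `modified_fraction`, `missed_cleavage`, `subpeptide_of_miscleaved`,
#' `shared_gene`); the final status is independent of rule order since every
#' violated rule is recorded. Mouse-shared peptides and peptides not covering
#' all isoforms are deprioritized rather than excluded: they are ranked after
#' every clean candidate and enter the shortlist only when clean candidates
#' do not fill it. Survivors are ranked by PSM count (descending) and the top
#' of the combined ranking, up to the shortlist upper bound, is marked
#' `shortlisted`; clean survivors below the cut carry reason
#' `below_shortlist`.
#'
#' @param records PSM records for a single gene (tibble from
#'   [read_psm_table()] / [gen_psm_archive()]).
#' @param criteria A [selection_criteria()].
#' @return Tibble: `peptide`, `status` (`excluded`/`deprioritized`/
#'   `shortlisted`), `reasons` (list-column), `rank` (by PSM count among
#'   non-excluded; `NA` for excluded), `psm_count`.
#' @export
filter_candidates <- function(records, criteria = selection_criteria()) {
  if (nrow(records) == 0) {
    return(tibble(peptide = character(), status = character(),
                  reasons = list(), rank = integer(), psm_count = integer()))
  }
  n_gene <- vapply(records$gene_ids, length, 0L)
  reasons <- lapply(seq_len(nrow(records)), function(i) {
    r <- character()
    if (records$best_ion_score[i] < criteria$min_ion_score)
      r <- c(r, "low_score")
    if (records$psm_count[i] > 0 &&
        records$modified_psm_count[i] / records$psm_count[i] >
          criteria$max_modified_fraction)
      r <- c(r, "modified_fraction")
    if (!criteria$allow_missed_cleavage && records$missed_cleavages[i] > 0)
      r <- c(r, "missed_cleavage")
    if (criteria$exclude_subpeptides_of_miscleaved &&
        records$is_subpeptide_of_miscleaved[i])
      r <- c(r, "subpeptide_of_miscleaved")
    if (criteria$exclude_shared_genes && n_gene[i] > 1)
      r <- c(r, "shared_gene")
    r
  })
  excluded <- vapply(reasons, length, 0L) > 0
  deprior <- !excluded &
    ((criteria$deprioritize_mouse_shared & records$shared_with_mouse) |
       !records$covers_all_isoforms)
  reasons[deprior & records$shared_with_mouse] <-
    lapply(reasons[deprior & records$shared_with_mouse], c, "mouse_shared")
  reasons[deprior & !records$covers_all_isoforms] <-
    lapply(reasons[deprior & !records$covers_all_isoforms], c, "not_all_isoforms")

  status <- ifelse(excluded, "excluded",
                   ifelse(deprior, "deprioritized", "clean"))
  # clean candidates first, each tier by PSM count descending
  ord <- order(excluded, deprior, -records$psm_count, records$peptide)
  rank <- rep(NA_integer_, nrow(records))
  rank[ord[!excluded[ord]]] <- seq_len(sum(!excluded))
  cut <- criteria$shortlist_size[2]
  shortlisted <- !excluded & rank <= cut
  status[shortlisted] <- "shortlisted"
  status[status == "clean"] <- "deprioritized"
  reasons[!excluded & !shortlisted & !deprior] <-
    lapply(reasons[!excluded & !shortlisted & !deprior], c, "below_shortlist")
  tibble(peptide = records$peptide, status = status, reasons = reasons,
         rank = rank, psm_count = records$psm_count)
}

zero_intercept_r2 <- function(x, y) {
  b <- sum(x * y) / sum(x^2)
  ss_res <- sum((y - b * x)^2)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) return(if (ss_res == 0) 1 else 0)
  1 - ss_res / ss_tot
}

#' Evaluate a candidate peptide's dilution response curve
#'
#' A good PRM candidate scales proportionally with protein input, elutes as a
#' narrow symmetric peak, and shows no non-specific interfering peak in its
#' scheduling window. Linearity is the R-squared of a zero-intercept fit of
#' area against input; symmetry is the left/right half-area ratio at the
#' apex; interference is any local maximum outside the integration boundary
#' exceeding a fraction of the apex.
#'
#' @param areas Numeric peptide areas, one per input level.
#' @param inputs_ug Input amounts (same order, >= 3 levels).
#' @param traces Optional canonical transition tibble at one input level for
#'   the shape checks; when absent, symmetry and interference default to
#'   passing and the verdict rests on linearity alone.
#' @param r2_min Linearity threshold (default 0.95).
#' @param symmetry_range Acceptable half-area ratio (default `c(0.67, 1.5)`).
#' @param interference_frac Local maxima above this fraction of the apex,
#'   outside the boundary, flag interference (default 0.20).
#' @return List: `linearity_r2`, `symmetry` (ratio or `NA`),
#'   `interference_flag`, `pass`.
#' @export
evaluate_response <- function(areas, inputs_ug, traces = NULL, r2_min = 0.95,
                              symmetry_range = c(0.67, 1.5),
                              interference_frac = 0.20) {
  if (length(areas) != length(inputs_ug) || length(areas) < 3)
    stop("need areas for at least 3 input levels")
  r2 <- zero_intercept_r2(inputs_ug, areas)
  symmetry <- NA_real_
  interference <- FALSE
  if (!is.null(traces)) {
    b <- detect_boundaries(traces)
    if (!is.null(b)) {
      total <- stats::aggregate(intensity ~ time, data = traces, FUN = sum)
      total <- total[order(total$time), ]
      apex_i <- which.max(total$intensity)
      apex_t <- total$time[apex_i]
      left <- integrate_area(
        tibble(time = total$time, intensity = total$intensity),
        list(start_rt = b$start_rt, end_rt = apex_t))
      right <- integrate_area(
        tibble(time = total$time, intensity = total$intensity),
        list(start_rt = apex_t, end_rt = b$end_rt))
      symmetry <- if (right > 0) left / right else Inf
      y <- total$intensity
      n <- length(y)
      is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] &
                    y[2:(n - 1)] >= y[3:n], FALSE)
      outside <- total$time < b$start_rt | total$time > b$end_rt
      interference <- any(is_max & outside &
                            y > interference_frac * y[apex_i])
    }
  }
  symmetric <- is.na(symmetry) ||
    (symmetry >= symmetry_range[1] && symmetry <= symmetry_range[2])
  list(linearity_r2 = r2, symmetry = symmetry,
       interference_flag = interference,
       pass = r2 >= r2_min && symmetric && !interference)
}

#' Assemble the final PRM panel
#'
#' Per gene, shortlisted peptides that pass response evaluation are ranked by
#' linearity then PSM count and the top `final_size` upper bound retained.
#' Genes with no passing peptide are reported in the shortfall table rather
#' than silently dropped.
#'
#' @param verdicts Tibble from [filter_candidates()] with a `gene` column
#'   (bind rows over genes).
#' @param assessments Tibble with `gene`, `peptide`, `linearity_r2`, `pass`
#'   (from [evaluate_response()] per peptide).
#' @param criteria A [selection_criteria()].
#' @return List with `panel` (tibble: gene, peptide, panel_rank,
#'   linearity_r2, psm_count) and `shortfall` (tibble: gene, n_shortlisted).
#' @export
final_panel <- function(verdicts, assessments, criteria = selection_criteria()) {
  stopifnot("gene" %in% names(verdicts))
  short <- verdicts[verdicts$status == "shortlisted", ]
  merged <- merge(short, assessments, by = c("gene", "peptide"))
  passing <- merged[merged$pass, ]
  panel_rows <- list()
  shortfall <- list()
  for (g in unique(short$gene)) {
    pg <- passing[passing$gene == g, ]
    if (nrow(pg) == 0) {
      shortfall[[g]] <- tibble(gene = g,
                               n_shortlisted = sum(short$gene == g))
      next
    }
    pg <- pg[order(-pg$linearity_r2, -pg$psm_count, pg$peptide), ]
    pg <- utils::head(pg, criteria$final_size[2])
    panel_rows[[g]] <- tibble(gene = g, peptide = pg$peptide,
                              panel_rank = seq_len(nrow(pg)),
                              linearity_r2 = pg$linearity_r2,
                              psm_count = pg$psm_count)
  }
  list(panel = if (length(panel_rows)) dplyr::bind_rows(panel_rows) else
         tibble(gene = character(), peptide = character(),
                panel_rank = integer(), linearity_r2 = numeric(),
                psm_count = integer()),
       shortfall = if (length(shortfall)) dplyr::bind_rows(shortfall) else
         tibble(gene = character(), n_shortlisted = integer()))
}
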