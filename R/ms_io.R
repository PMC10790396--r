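#' @importFrom dplyr %>% arrange group_by ungroup mutate filter summarise n
#' @importFrom tibble tibble as_tibble
NULL

AA_CANONICAL <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Column-name dialect for transition reports
#'
#' Transition chromatogram reports arrive as long-format CSV with one row per
#' (fragment trace, time point). Export schemas differ between tools, so the
#' mapping from file columns to the canonical fields is configurable. The
#' defaults mirror common Skyline chromatogram export headers.
#'
#' @param sample,peptide,charge,fragment,time,intensity,heavy Column names in
#'   the CSV holding, respectively, the sample/run id, peptide sequence,
#'   precursor charge, fragment-ion label, retention time (minutes),
#'   intensity, and the isotope label ("heavy"/"light" or logical).
#' @return A named character vector usable as the `dialect` argument of
#'   [read_transition_report()] and [write_transition_report()].
#' @export
transition_dialect <- function(sample = "FileName",
                               peptide = "PeptideSequence",
                               charge = "PrecursorCharge",
                               fragment = "FragmentIon",
                               time = "RetentionTime",
                               intensity = "Intensity",
                               heavy = "IsotopeLabelType") {
  c(sample_id = sample, peptide = peptide, charge = charge,
    fragment = fragment, time = time, intensity = intensity,
    is_heavy = heavy)
}

validate_traces <- function(tr) {
  stopifnot(is.data.frame(tr))
  required <- c("sample_id", "peptide", "charge", "fragment", "time",
                "intensity", "is_heavy")
  missing <- setdiff(required, names(tr))
  if (length(missing) > 0)
    stop("transition table missing column(s): ", paste(missing, collapse = ", "))
  if (any(!is.finite(tr$intensity)) || any(tr$intensity < 0))
    stop("intensities must be finite and >= 0")
  bad_pep <- unique(tr$peptide[!grepl("^[A-Z]{5,40}$", tr$peptide)])
  if (length(bad_pep) > 0)
    stop("invalid peptide sequence(s): ", paste(utils::head(bad_pep, 3), collapse = ", "))
  if (any(tr$charge < 1)) stop("charge must be a positive integer")
  key <- interaction(tr$sample_id, tr$peptide, tr$charge, tr$fragment,
                     tr$is_heavy, drop = TRUE)
  for (k in levels(key)) {
    tt <- sort(tr$time[key == k])
    if (length(tt) < 2)
      stop("trace ", k, " has fewer than 2 time points")
    if (any(diff(tt) <= 0))
      stop("non-monotone retention times in trace ", k)
  }
  invisible(tr)
}

#' Read a long-format transition chromatogram report
#'
#' Reads a Skyline-style long CSV (one row per trace time point), resolves the
#' column dialect, validates trace invariants (finite non-negative intensity,
#' strictly increasing retention times, at least two points per trace) and
#' returns a canonical tibble sorted by trace and time.
#'
#' @param path CSV file path.
#' @param dialect Named character vector from [transition_dialect()].
#' @return A tibble with columns `sample_id`, `peptide`, `charge`, `fragment`,
#'   `time` (minutes), `intensity`, `is_heavy` (logical).
#' @export
read_transition_report <- function(path, dialect = transition_dialect()) {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  missing <- setdiff(unname(dialect), names(raw))
  if (length(missing) > 0)
    stop("transition report ", path, " missing required column(s): ",
         paste(missing, collapse = ", "))
  tr <- as_tibble(raw[, unname(dialect)])
  names(tr) <- names(dialect)
  if (!is.logical(tr$is_heavy))
    tr$is_heavy <- tolower(as.character(tr$is_heavy)) %in% c("heavy", "true", "1")
  tr$charge <- as.integer(tr$charge)
  validate_traces(tr)
  tr[order(tr$sample_id, tr$peptide, tr$charge, tr$fragment, tr$is_heavy,
           tr$time), , drop = FALSE]
}

#' Write a transition chromatogram report
#'
#' Inverse of [read_transition_report()]; `read(write(x))` reproduces `x`.
#'
#' @param traces Canonical transition tibble.
#' @param path Output CSV path.
#' @param dialect Column dialect to write under.
#' @export
write_transition_report <- function(traces, path, dialect = transition_dialect()) {
  validate_traces(traces)
  out <- traces[order(traces$sample_id, traces$peptide, traces$charge,
                      traces$fragment, traces$is_heavy, traces$time), ]
  out <- as.data.frame(out[, names(dialect)])
  out$is_heavy <- ifelse(out$is_heavy, "heavy", "light")
  names(out) <- unname(dialect)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a PSM archive table
#'
#' Reads per-peptide spectral evidence (TSV) used by the panel-design rules:
#' PSM counts, modified-PSM counts, best ion score, missed cleavages and the
#' flags consumed by [filter_candidates()]. Records above the q-value cutoff
#' (5% FDR) are dropped and the drop count reported via a message.
#'
#' @param path TSV path. `gene_ids` may hold several symbols separated by ";".
#' @param q_max FDR cutoff on `q_value` (default 0.05).
#' @return Tibble of retained records; `gene_ids` is a list-column of
#'   character vectors.
#' @export
read_psm_table <- function(path, q_max = 0.05) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("peptide", "gene_ids", "psm_count", "modified_psm_count",
                "best_ion_score", "missed_cleavages",
                "is_subpeptide_of_miscleaved", "shared_with_mouse",
                "covers_all_isoforms", "q_value")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0)
    stop("PSM table missing column(s): ", paste(missing, collapse = ", "))
  if (nrow(raw) == 0) {
    warning("empty PSM table: ", path)
    raw$gene_ids <- list()
    return(as_tibble(raw))
  }
  if (any(raw$modified_psm_count > raw$psm_count))
    stop("modified_psm_count exceeds psm_count for peptide(s): ",
         paste(raw$peptide[raw$modified_psm_count > raw$psm_count], collapse = ", "))
  if (any(raw$q_value < 0 | raw$q_value > 1))
    stop("q_value outside [0, 1]")
  keep <- raw$q_value <= q_max
  if (any(!keep))
    message(sum(!keep), " PSM record(s) dropped at q > ", q_max)
  out <- as_tibble(raw[keep, , drop = FALSE])
  out$gene_ids <- strsplit(out$gene_ids, ";", fixed = TRUE)
  out
}

#' Write a PSM archive table
#' @param psms Tibble as returned by [read_psm_table()].
#' @param path Output TSV path.
#' @export
write_psm_table <- function(psms, path) {
  out <- as.data.frame(psms)
  out$gene_ids <- vapply(psms$gene_ids, paste, "", collapse = ";")
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# --- tryptic digestion ------------------------------------------------------

#' Fully tryptic in-silico digestion
#'
#' Cleaves after K or R except when the next residue is P (zero missed
#' cleavages) and returns the resulting peptides in N-to-C order.
#'
#' @param sequence Upper-case amino-acid sequence.
#' @return Character vector of tryptic peptides.
#' @export
tryptic_peptides <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1 || nchar(sequence) == 0)
    stop("sequence must be a single non-empty string")
  aa <- strsplit(sequence, "")[[1]]
  n <- length(aa)
  # cut after position i when aa[i] is K/R and aa[i+1] is not P
  cuts <- which(aa %in% c("K", "R"))
  cuts <- cuts[cuts < n & aa[pmin(cuts + 1L, n)] != "P"]
  bounds <- c(0L, cuts, n)
  substring(sequence, utils::head(bounds, -1) + 1L, bounds[-1])
}

#' Count theoretical tryptic peptides (iBAQ denominator)
#'
#' Number of fully tryptic peptides of `sequence` with length between
#' `min_len` and `max_len` residues. Used as the denominator of iBAQ
#' (intensity-based absolute quantification): protein intensity divided by the
#' number of theoretically observable tryptic peptides.
#'
#' @param sequence Amino-acid sequence.
#' @param min_len,max_len Inclusive peptide length bounds (defaults 7 and 30,
#'   the usual observability window).
#' @return Integer count.
#' @export
tryptic_digest <- function(sequence, min_len = 7, max_len = 30) {
  peps <- tryptic_peptides(sequence)
  len <- nchar(peps)
  sum(len >= min_len & len <= max_len)
}

# --- quant matrices ---------------------------------------------------------

#' Construct a gene-by-sample quantification matrix
#'
#' A thin validated wrapper around a numeric matrix: rows are gene symbols,
#' columns are sample ids, and a `scale` attribute records whether values are
#' linear abundances or log2. Missing cells (`NA`) mean "not identified",
#' which the pipeline treats as absence, never as zero.
#'
#' @param values Numeric matrix with unique rownames (genes) and colnames
#'   (samples).
#' @param scale `"linear"` or `"log2"`. Linear matrices must be non-negative.
#' @return A `quant_matrix` object.
#' @export
quant_matrix <- function(values, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("quant matrix requires gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene symbol(s): ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample id(s)")
  if (scale == "linear" && any(values < 0, na.rm = TRUE))
    stop("negative values in a linear-scale matrix")
  structure(values, scale = scale, class = c("quant_matrix", "matrix", "array"))
}

#' @export
print.quant_matrix <- function(x, ...) {
  cat("quant_matrix:", nrow(x), "genes x", ncol(x), "samples,",
      attr(x, "scale"), "scale,",
      sum(is.na(x)), "missing cells\n")
  print(utils::head(unclass(x), 5L))
  invisible(x)
}

qm_scale <- function(m) attr(m, "scale")

#' Write a quantification matrix as TSV
#'
#' Genes as rows, samples as columns; the scale is recorded in a leading
#' `# scale=` comment line, and missing values are written as empty cells
#' (absence, distinct from 0).
#'
#' @param matrix A [quant_matrix()].
#' @param path Output TSV path.
#' @export
write_quant_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "quant_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# scale=", qm_scale(matrix)), con)
  df <- data.frame(gene = rownames(matrix), unclass(matrix),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}

#' Read a quantification matrix written by [write_quant_matrix()]
#' @param path TSV path with a `# scale=` header comment.
#' @return A [quant_matrix()]; empty cells become `NA`.
#' @export
read_quant_matrix <- function(path) {
  first <- readLines(path, n = 1)
  scale <- sub("^# scale=", "", first)
  if (identical(scale, first))
    stop("missing '# scale=' header in ", path)
  df <- utils::read.delim(path, skip = 1, check.names = FALSE,
                          stringsAsFactors = FALSE, na.strings = "")
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df$gene
  quant_matrix(values, scale = scale)
}

# --- FASTA ------------------------------------------------------------------

#' Load protein sequences with gene annotations
#'
#' Reads a FASTA file via Biostrings and parses each header for an accession
#' (first whitespace-delimited token, or the middle field of a
#' `db|ACC|NAME` UniProt-style header) and a gene symbol from a `GN=` tag.
#' Sequences may contain only the 20 canonical residues plus X.
#'
#' @param path FASTA path.
#' @return A `fasta_db`: list with `sequences` (named character, by accession)
#'   and `genes` (accession to gene symbol map).
#' @export
read_fasta_db <- function(path) {
  aas <- Biostrings::readAAStringSet(path)
  headers <- names(aas)
  seqs <- as.character(aas)
  acc <- vapply(headers, function(h) {
    tok <- strsplit(h, "\\s+")[[1]][1]
    parts <- strsplit(tok, "|", fixed = TRUE)[[1]]
    if (length(parts) >= 2) parts[2] else tok
  }, "", USE.NAMES = FALSE)
  gene <- vapply(headers, function(h) {
    m <- regmatches(h, regexpr("GN=[^ ]+", h))
    if (length(m) == 1) sub("^GN=", "", m) else NA_character_
  }, "", USE.NAMES = FALSE)
  bad <- grepl(paste0("[^", paste(c(AA_CANONICAL, "X"), collapse = ""), "]"), seqs)
  if (any(bad))
    stop("non-canonical residues in: ", paste(acc[bad], collapse = ", "))
  names(seqs) <- acc
  genes <- stats::setNames(gene, acc)
  structure(list(sequences = seqs, genes = genes), class = "fasta_db")
}

#' Look up one sequence per gene symbol
#' @param db A `fasta_db`.
#' @param genes Gene symbols to resolve.
#' @return Named character vector of sequences; errors listing any gene with
#'   no sequence.
#' @export
fasta_gene_sequences <- function(db, genes) {
  stopifnot(inherits(db, "fasta_db"))
  idx <- match(genes, db$genes)
  if (anyNA(idx))
    stop("gene(s) absent from FASTA: ", paste(genes[is.na(idx)], collapse = ", "))
  stats::setNames(unname(db$sequences[idx]), genes)
}
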