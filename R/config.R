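#' Read a pipeline configuration file
#'
#' YAML configuration with one section per pipeline stage (e.g.
#' `transition_dialect`, `quantification`, `design`, `isprm`, `diffexp`);
#' values present in the file override the supplied defaults, section by
#' section.
#'
#' @param path YAML file path.
#' @param defaults Named list of default sections.
#' @return Named list of merged sections.
#' @export
read_config <- function(path, defaults = list()) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read configuration files")
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a YAML mapping: ", path)
  out <- defaults
  for (section in names(cfg)) {
    if (is.list(cfg[[section]]) && is.list(out[[section]])) {
      out[[section]] <- utils::modifyList(out[[section]], cfg[[section]])
    } else {
      out[[section]] <- cfg[[section]]
    }
  }
  out
}
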