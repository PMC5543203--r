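#' Write a table as CSV with a provenance header
#'
#' Provenance (seed, config hash, package version) is written as leading
#' `#`-comment lines so the file remains a plain CSV.
#'
#' @param x data frame (its `provenance` attribute is used when present).
#' @param path output file.
#' @param prov optional provenance list, see [provenance()].
#' @export
write_csv_prov <- function(x, path, prov = attr(x, "provenance")) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(prov))
    for (k in names(prov))
      writeLines(sprintf("# %s: %s", k, format(prov[[k]])), con)
  utils::write.csv(as.data.frame(x), con, row.names = FALSE)
  invisible(path)
}

#' Read a CSV written by [write_csv_prov()]
#' @param path file path.
#' @return data frame; provenance lines are attached as attribute.
#' @export
read_csv_prov <- function(path) {
  lines <- readLines(path)
  prov <- grep("^#", lines, value = TRUE)
  df <- utils::read.csv(text = paste(grep("^#", lines, value = TRUE,
                                          invert = TRUE), collapse = "\n"),
                        stringsAsFactors = FALSE)
  attr(df, "provenance_lines") <- prov
  df
}

#' Write a cell map as JSON (one record per nucleus)
#' @param map a `cellmap`.
#' @param path output file.
#' @export
write_cellmap_json <- function(map, path) {
  stopifnot(inherits(map, "cellmap"))
  obj <- list(width = map$width, height = map$height,
              microns_per_pixel = map$microns_per_pixel,
              seed = map$seed,
              true_ki67_fraction = map$true_ki67_fraction,
              degenerate = map$degenerate,
              stain_contrast = map$stain_contrast,
              provenance = provenance(map$seed, list()),
              nuclei = map$nuclei)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Read a cell map from JSON
#' @param path file written by [write_cellmap_json()].
#' @return a `cellmap`.
#' @export
read_cellmap_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  nuc <- as.data.frame(obj$nuclei)
  structure(list(width = obj$width, height = obj$height,
                 microns_per_pixel = obj$microns_per_pixel,
                 nuclei = nuc, seed = obj$seed,
                 true_ki67_fraction = obj$true_ki67_fraction %||% NA_real_,
                 degenerate = isTRUE(obj$degenerate),
                 streaming = FALSE,
                 stain_contrast = obj$stain_contrast %||% 1,
                 config = NULL),
            class = "cellmap")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Scalar fields override the [pipeline_config()] defaults; nested blocks
#' `cohort`, `thresholds`, `grid` override the corresponding sub-configs.
#'
#' @param path a .yaml/.yml or .json file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_ki67("the 'yaml' package is required for YAML configs",
                "ki67cta_config_error")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  cohort <- do.call(cohort_config, raw$cohort %||% list())
  thresholds <- do.call(triage_thresholds, raw$thresholds %||% list())
  grid <- do.call(grid_spec, raw$grid %||% list())
  args <- raw[setdiff(names(raw), c("cohort", "thresholds", "grid"))]
  do.call(pipeline_config,
          c(args, list(cohort = cohort, thresholds = thresholds,
                       grid = grid)))
}
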