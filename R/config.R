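#' Default toolkit configuration
#'
#' Every threshold used by the toolkit lives in one nested configuration
#' list; the defaults are the values used in the original TAS-Seq analyses
#' (DBEC gates, knee-window, QC filters). A YAML file read with
#' [read_config()] overrides any subset of fields.
#'
#' @return Nested list of configuration values with a `schema_version` field.
#' @export
default_config <- function() {
  list(
    schema_version = 1L,
    tags = list(cb = "CB", umi = "UB", gene = "GN"),
    cell_calling = list(window = 5L, method = "inflection",
                        boundary = "inclusive"),
    dbec = list(
      depth_mode = "shallow",
      select_log2max_gt = 8,
      comp_mean_gt = c(shallow = 5.5, deep = 6),
      diff_gt = c(shallow = 5, deep = 5.5),
      k_range = c(1L, 2L, 3L),
      mean_scale = "transformed",
      include_zeros = FALSE,
      em = list(max_iter = 500L, tol = 1e-8, n_restarts = 5L, seed = 1L)
    ),
    hashtag = list(min_total = 10L, singlet_ratio = 3),
    qc = list(
      mito_patterns = c("^mt-", "^MT-"),
      ribo_patterns = c("^Rp[sl]", "^RP[SL]"),
      rrna_patterns = c("^Rn[0-9]*s", "rRNA"),
      mito_max = 0.25,
      min_cells = 5L,
      min_genes = 500L
    ),
    normalize = list(scale_factor = 1e6),
    hvg = list(mean_cutoff = c(0.1, Inf), dispersion_cutoff = c(0.5, Inf),
               n_bins = 20L),
    kl = list(n_bins = 100L, epsilon = 1e-9),
    pseudobulk = list(total = 1e7)
  )
}

#' Read a YAML configuration file
#'
#' Values in the file override the defaults field-by-field (recursively);
#' unknown fields are an error so typos do not silently fall back to
#' defaults.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return Full configuration list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  if (!is.null(user$schema_version) && user$schema_version != cfg$schema_version) {
    stop("read_config: unsupported schema_version ", user$schema_version)
  }
  merge_config(cfg, user, path = "config")
}

merge_config <- function(base, override, path) {
  for (nm in names(override)) {
    if (!nm %in% names(base)) {
      stop("read_config: unknown field '", path, "$", nm, "'")
    }
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]],
                                 paste0(path, "$", nm))
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Write a machine-readable run summary
#'
#' Each CLI run emits a JSON summary (records read and skipped, cells
#' called, genes corrected, ...) so pipelines can audit a run without
#' parsing logs.
#'
#' @param summary Named list of counts and settings.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_run_summary <- function(summary, path) {
  summary$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(summary, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
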