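#' Declare a table schema
#'
#' A schema is a named list mapping column name to type ("numeric",
#' "integer", "character", "factor") with optional units recorded for
#' documentation. Only declared columns are validated; extra columns pass
#' through untouched.
#'
#' @param ... `name = "type"` pairs, or `name = c("type", "unit")`
#' @return a `table_schema` object
#' @export
table_schema <- function(...) {
  cols <- list(...)
  if (length(cols) == 0L || is.null(names(cols)) || any(names(cols) == ""))
    stop("table_schema: all columns must be named", call. = FALSE)
  spec <- lapply(cols, function(x) {
    x <- as.character(x)
    list(type = x[1], unit = if (length(x) > 1) x[2] else NA_character_)
  })
  structure(spec, class = "table_schema")
}

#' Read a delimited table and validate it against a schema
#'
#' Missing values stay `NA`; rows are never silently dropped. Numeric
#' columns containing non-numeric text raise an error naming the first
#' offending row.
#'
#' @param path CSV (or TSV if `sep = "\t"`) file with a header row
#' @param schema optional `table_schema`; required columns must be present
#' @param sep field separator, inferred from the extension by default
#' @return a data.frame
#' @export
read_table <- function(path, schema = NULL, sep = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(sep)) sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""),
                          colClasses = "character", check.names = FALSE)
  if (!is.null(schema)) {
    stopifnot(inherits(schema, "table_schema"))
    missing_cols <- setdiff(names(schema), names(df))
    if (length(missing_cols) > 0L)
      stop("schema error: required column(s) missing: ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    for (nm in names(schema)) {
      ty <- schema[[nm]]$type
      raw <- df[[nm]]
      if (ty %in% c("numeric", "integer")) {
        conv <- suppressWarnings(as.numeric(raw))
        bad <- which(!is.na(raw) & is.na(conv))
        if (length(bad) > 0L)
          stop(sprintf("parse error: column '%s' non-numeric at row %d ('%s')",
                       nm, bad[1], raw[bad[1]]), call. = FALSE)
        df[[nm]] <- if (ty == "integer") as.integer(round(conv)) else conv
      } else if (ty == "factor") {
        df[[nm]] <- factor(raw)
      }
    }
  }
  # columns not covered by the schema: best-effort numeric conversion
  for (nm in setdiff(names(df), names(schema))) {
    conv <- suppressWarnings(as.numeric(df[[nm]]))
    if (!any(!is.na(df[[nm]]) & is.na(conv))) df[[nm]] <- conv
  }
  df
}

#' Write a table as delimited text
#' @param table data.frame
#' @param path output path (`.tsv` switches to tab separation)
#' @return `path`, invisibly
#' @export
write_table <- function(table, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(table, path, sep = sep, row.names = FALSE,
                     quote = FALSE, na = "NA")
  invisible(path)
}

#' Pipeline configuration
#'
#' Central knobs of the analysis cascade with the defaults used throughout:
#' one-tailed voxel threshold z > 1.64, cluster alpha 0.05 with 10,000
#' Monte-Carlo iterations, 5,000 bootstrap draws, 10,000 permutations,
#' 8-mm FWHM smoothing for the cluster null, top 5% gene fraction, 3-mm
#' sample-assignment radius and the amyloid positivity cutoff of 1.324 DVR.
#'
#' @param voxel_z_threshold one-tailed voxel-level z threshold
#' @param cluster_alpha family-wise cluster alpha in (0,1)
#' @param n_mc_iterations Monte-Carlo iterations for the cluster null
#' @param n_boot bootstrap draws for mediation
#' @param n_perm permutations / random draws for gene-level nulls
#' @param smoothing_fwhm_mm Gaussian FWHM assumed for the cluster null
#' @param top_fraction top gene fraction in (0,1)
#' @param sample_assign_max_dist_mm assignment radius for atlas samples
#' @param abeta_cutoff_dvr amyloid positivity threshold (PiB DVR)
#' @param rng_seed integer master seed
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(voxel_z_threshold = 1.64,
                            cluster_alpha = 0.05,
                            n_mc_iterations = 10000L,
                            n_boot = 5000L,
                            n_perm = 10000L,
                            smoothing_fwhm_mm = 8.0,
                            top_fraction = 0.05,
                            sample_assign_max_dist_mm = 3.0,
                            abeta_cutoff_dvr = 1.324,
                            rng_seed = 1L) {
  cfg <- list(voxel_z_threshold = voxel_z_threshold,
              cluster_alpha = cluster_alpha,
              n_mc_iterations = as.integer(n_mc_iterations),
              n_boot = as.integer(n_boot),
              n_perm = as.integer(n_perm),
              smoothing_fwhm_mm = smoothing_fwhm_mm,
              top_fraction = top_fraction,
              sample_assign_max_dist_mm = sample_assign_max_dist_mm,
              abeta_cutoff_dvr = abeta_cutoff_dvr,
              rng_seed = as.integer(rng_seed))
  if (cfg$cluster_alpha <= 0 || cfg$cluster_alpha >= 1)
    stop("cluster_alpha must lie in (0,1)", call. = FALSE)
  if (cfg$top_fraction <= 0 || cfg$top_fraction >= 1)
    stop("top_fraction must lie in (0,1)", call. = FALSE)
  counts <- c(cfg$n_mc_iterations, cfg$n_boot, cfg$n_perm)
  if (any(counts < 1L)) stop("iteration counts must be >= 1", call. = FALSE)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Load a pipeline configuration from YAML
#' @param path YAML file whose keys match [pipeline_config()] arguments
#' @return a `pipeline_config`
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(pipeline_config, vals)
}

#' Derive a deterministic sub-seed from a master seed
#'
#' All randomness flows from one master seed; each stage derives its own
#' stream with a stage label so that re-running a stage alone reproduces
#' its output bit-exactly.
#'
#' @param seed integer master seed
#' @param label character stage label
#' @return integer sub-seed in [0, 2^31)
#' @export
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h * 9973) %% 2147483647)
}

#' Write a run manifest recording config, seed and stage provenance
#' @param path output JSON path
#' @param stage stage name
#' @param config a `pipeline_config` (or any list)
#' @param seed the seed actually used
#' @param extra optional named list of extra provenance fields
#' @return `path`, invisibly
#' @export
write_manifest <- function(path, stage, config, seed, extra = list()) {
  manifest <- c(list(stage = stage, seed = seed,
                     config = unclass(config),
                     timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
                extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
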