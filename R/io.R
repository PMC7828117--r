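# Long-format observation tables (comma-separated, NONMEM-style header)
# and the run configuration. One table format serves PK and PD data: the
# TYPE column discriminates plasma / lung / bioluminescence records, dose
# rows carry EVID = 1 with AMT set, observation rows EVID = 0.

.obs_required <- c("ID", "ARM", "TIME", "TYPE", "DV", "CENS", "ULIM",
                   "AMT", "EVID")

#' Read / write a long-format observation table
#'
#' `read_observations()` validates the required columns, numeric types and
#' the censoring contract (a censored record must carry an upper limit);
#' unknown columns are preserved. Records with `DV = 0` on observation
#' rows are loaded but flagged in an `EXCLUDE` column, mirroring the rule
#' that zero measured concentrations are excluded from fitting.
#'
#' @param path CSV file path.
#' @return Validated data frame; write returns `path` invisibly.
#' @export
read_observations <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.obs_required, names(df))
  if (length(miss))
    stop("read_observations: missing required column(s): ",
         paste(miss, collapse = ", "))
  if (nrow(df) == 0L) return(df)
  for (col in c("TIME", "DV", "ULIM", "AMT")) {
    v <- df[[col]]
    if (!is.numeric(v) && !all(is.na(v))) {
      conv <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & v != "" & is.na(conv))
      if (length(bad))
        stop("read_observations: non-numeric ", col, " in row ", bad[1L])
      df[[col]] <- conv
    }
  }
  bad <- which(df$EVID == 0 & df$CENS == 1 & !is.finite(df$ULIM))
  if (length(bad))
    stop("read_observations: censored record without ULIM in row ", bad[1L])
  df$EXCLUDE <- df$EVID == 0 & !is.na(df$DV) & df$DV == 0
  df
}

#' @rdname read_observations
#' @param records data frame with at least the required columns.
#' @export
write_observations <- function(records, path) {
  miss <- setdiff(.obs_required, names(records))
  if (length(miss))
    stop("write_observations: missing required column(s): ",
         paste(miss, collapse = ", "))
  records$EXCLUDE <- NULL
  write.csv(records, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

.config_sections <- c("parameters", "geometry", "design", "estimation",
                      "simulation", "seeds")

#' Load a run configuration
#'
#' JSON configuration with sections `parameters` (flat symbol-name
#' overrides plus `body_weight`), `geometry`, `design`, `estimation`,
#' `simulation` and `seeds`; an empty or absent section falls back to the
#' built-in defaults ([nanomsc_params()] and the standard study designs).
#' Unknown sections or unknown parameter keys are rejected rather than
#' silently ignored.
#'
#' @param path JSON file path, or `NULL` for pure defaults.
#' @return List with `params` (full parameter set) and the raw sections.
#' @export
load_config <- function(path = NULL) {
  cfg <- if (is.null(path)) list()
  else jsonlite::read_json(path, simplifyVector = TRUE)
  bad <- setdiff(names(cfg), .config_sections)
  if (length(bad))
    stop("load_config: unknown section(s): ", paste(bad, collapse = ", "))
  params <- nanomsc_params()
  pars <- cfg$parameters
  if (!is.null(pars)) {
    if (!is.null(pars$body_weight)) {
      if (pars$body_weight <= 0) stop("load_config: body_weight must be > 0")
      params$body_weight <- pars$body_weight
      pars$body_weight <- NULL
    }
    if (length(pars)) params <- unflatten_params(unlist(pars), params)
  }
  geo <- cfg$geometry
  if (!is.null(geo) && length(geo)) {
    g <- unclass(params$geometry)
    bad <- setdiff(names(geo), c(names(g), "dynamic"))
    if (length(bad))
      stop("load_config: unknown geometry key(s): ", paste(bad, collapse = ", "))
    g[names(geo)] <- geo
    params$geometry <- tumor_geometry(g$VT, g$Rtumor, g$Rcap, g$RKrogh,
                                      isTRUE(g$dynamic))
  }
  list(params = params, design = cfg$design, estimation = cfg$estimation,
       simulation = cfg$simulation, seeds = cfg$seeds)
}

#' Write a run manifest
#'
#' Records the inputs, seeds and package version of a pipeline stage so
#' every written artifact is reproducible from its manifest.
#'
#' @param path JSON output path.
#' @param stage stage label.
#' @param seed seed(s) in effect.
#' @param inputs named list of input descriptions (paths, truth values).
#' @export
write_manifest <- function(path, stage, seed, inputs = list()) {
  jsonlite::write_json(
    list(stage = stage, seed = seed, inputs = inputs,
         package = as.character(utils::packageVersion("nanomsc")),
         r_version = R.version.string),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
  invisible(path)
}
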