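#' Load model configuration from a file
#'
#' Reads a flat key/value document (YAML or JSON, detected from the
#' extension) holding [qc_params()] fields.  Missing keys are filled from
#' the nominal preset; unknown keys are rejected; the convenience key `tau`
#' (mixing time in days) is resolved to `ff_scale = 7.5 / tau` and may not
#' be combined with an explicit `ff_scale`.  All parameter invariants are
#' validated, and every violation is reported at once.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.  An empty document
#'   yields exactly the nominal preset.
#' @return A `qc_params` object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
          else if (ext == "json") jsonlite::fromJSON(path,
                                                     simplifyVector = TRUE)
          else stop("unsupported config format: .", ext, call. = FALSE)
  if (is.null(vals)) vals <- list()
  if (length(vals) > 0 && (is.null(names(vals)) || any(names(vals) == "")))
    stop("config must be a flat key/value document", call. = FALSE)
  base <- qc_params()
  known <- c(names(base), "tau")
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0)
    stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  if ("tau" %in% names(vals)) {
    if ("ff_scale" %in% names(vals))
      stop("specify either 'tau' or 'ff_scale', not both", call. = FALSE)
    tau <- vals$tau
    if (!is.numeric(tau) || length(tau) != 1 || !is.finite(tau) || tau <= 0)
      stop("'tau' must be a positive number", call. = FALSE)
    vals$ff_scale <- 7.5 / tau
    vals$tau <- NULL
  }
  if (length(vals) == 0) return(base)
  do.call(qc_params_update, c(list(base), vals))
}

#' Write model configuration to a file
#'
#' Round-trip counterpart of [load_config()]: `load_config(write_config(p))`
#' reproduces `p` exactly.
#'
#' @param params A [qc_params()] object.
#' @param path Output path (`.yaml`/`.yml` or `.json`).
#' @return `path`, invisibly.
#' @export
write_config <- function(params, path) {
  stopifnot(inherits(params, "qc_params"))
  ext <- tolower(tools::file_ext(path))
  vals <- unclass(params)
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(vals, path, precision = 17)
  } else if (ext == "json") {
    writeLines(jsonlite::toJSON(vals, auto_unbox = TRUE, digits = NA), path)
  } else stop("unsupported config format: .", ext, call. = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' Records the configuration snapshot, package version, master seed and
#' output inventory of a run so it can be replayed bit-identically.
#'
#' @param dir Output directory (created if missing).
#' @param params A `qc_params` object.
#' @param master_seed Master seed of the run.
#' @param settings Named list of extra run settings.
#' @param files Character vector of output files in `dir`.
#' @return The manifest path, invisibly.
#' @export
write_manifest <- function(dir, params, master_seed, settings = list(),
                           files = character(0)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package = "mitoqc",
    version = as.character(utils::packageVersion("mitoqc")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    master_seed = master_seed,
    child_seed_rule = "child_seed(master, k) = (master + 1000003*k) mod 2147483629 + 1",
    params = unclass(params),
    settings = settings,
    files = files)
  path <- file.path(dir, "manifest.json")
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), path)
  invisible(path)
}
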