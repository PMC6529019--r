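#' Load a configuration bundle from YAML or JSON
#'
#' Reads a declarative configuration file (format chosen by the file
#' extension: `.yaml`/`.yml` or `.json`) and builds a validated
#' [config_bundle][figure_preset()].  A file may simply name a `preset`,
#' optionally overriding individual fields; unknown keys are rejected
#' with an error naming the offending key, and every default that was
#' filled in is reported via `message()` when `verbose = TRUE`.
#'
#' @param path Path to the configuration file.
#' @param verbose Report filled-in defaults (default `FALSE`).
#'
#' @return A `config_bundle`.
#' @seealso [write_config()], [figure_preset()]
#' @export
load_config <- function(path, verbose = FALSE) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
                yaml = , yml = yaml::read_yaml(path),
                json = jsonlite::read_json(path, simplifyVector = TRUE),
                stop("unsupported config format '.", ext,
                     "' (use .yaml, .yml or .json)"))
  config_from_list(raw, verbose = verbose)
}

config_keys <- c("preset", "e_params", "i_params", "couplings", "drive",
                 "cross", "pulse", "simulation", "analysis")
pop_keys <- c("tau", "eta_bar", "delta", "n", "v_th", "v_r")
coup_keys <- c("j_ee", "j_ei", "j_ie", "j_ii", "tau_s")
cross_keys <- c("g_ee", "g_ie", "delay", "weak_threshold")
drive_keys <- c("start", "i_ext_e", "i_ext_i")

config_from_list <- function(raw, verbose = FALSE) {
  if (!is.list(raw)) stop("configuration must be a mapping")
  bad <- setdiff(names(raw), config_keys)
  if (length(bad))
    stop("schema violation: unknown configuration key '", bad[1], "'")
  check_keys <- function(x, allowed, where) {
    bad <- setdiff(names(x), allowed)
    if (length(bad))
      stop("schema violation: unknown key '", bad[1], "' in ", where)
  }
  defaults_used <- character(0)

  if (!is.null(raw$preset)) {
    bundle <- figure_preset(raw$preset)
  } else {
    bundle <- structure(list(e_params = NULL, i_params = NULL,
                             couplings = NULL, drive = constant_drive(),
                             cross = NULL, pulse = NULL, extra = list(),
                             name = "custom"),
                        class = "config_bundle")
    defaults_used <- c(defaults_used, "drive (zero)")
  }
  mk_pop <- function(x, base, where) {
    check_keys(x, pop_keys, where)
    a <- function(k, d) x[[k]] %||% (if (!is.null(base)) base[[k]] else d)
    tryCatch(
      population_params(a("tau", 10), a("eta_bar", -5), a("delta", 1),
                        a("n", 1000L), a("v_th", 500), a("v_r", -500)),
      error = function(e)
        stop("schema violation in ", where, ": ", conditionMessage(e),
             call. = FALSE))
  }
  if (!is.null(raw$e_params))
    bundle$e_params <- mk_pop(raw$e_params, bundle$e_params, "e_params")
  if (!is.null(raw$i_params))
    bundle$i_params <- mk_pop(raw$i_params, bundle$i_params, "i_params")
  if (!is.null(raw$couplings)) {
    check_keys(raw$couplings, coup_keys, "couplings")
    b <- bundle$couplings
    a <- function(k, d) raw$couplings[[k]] %||% (if (!is.null(b)) b[[k]] else d)
    bundle$couplings <- tryCatch(
      synaptic_couplings(a("j_ee", 0), a("j_ei", 0), a("j_ie", 0),
                         a("j_ii", 0), a("tau_s", 1)),
      error = function(e)
        stop("schema violation in couplings: ", conditionMessage(e),
             call. = FALSE))
  }
  if (!is.null(raw$drive)) {
    check_keys(raw$drive, drive_keys, "drive")
    bundle$drive <- drive_protocol(raw$drive$start %||% 0,
                                   raw$drive$i_ext_e %||% 0,
                                   raw$drive$i_ext_i %||% 0)
  }
  if (!is.null(raw$cross)) {
    check_keys(raw$cross, cross_keys, "cross")
    b <- bundle$cross
    a <- function(k, d) raw$cross[[k]] %||% (if (!is.null(b)) b[[k]] else d)
    bundle$cross <- cross_coupling(a("g_ee", 0), a("g_ie", 0), a("delay", 0),
                                   a("weak_threshold", 0.5))
  }
  if (!is.null(raw$pulse)) bundle$pulse <- as.list(raw$pulse)
  if (!is.null(raw$simulation)) bundle$simulation <- as.list(raw$simulation)
  if (!is.null(raw$analysis)) bundle$analysis <- as.list(raw$analysis)
  if (is.null(bundle$e_params) || is.null(bundle$i_params) ||
      is.null(bundle$couplings))
    stop("schema violation: configuration must define e_params, i_params ",
         "and couplings (directly or through a preset)")
  if (verbose && length(defaults_used))
    message("defaults filled in: ", paste(defaults_used, collapse = ", "))
  bundle
}

#' Write a configuration bundle to YAML or JSON
#'
#' Serialises a `config_bundle` so that [load_config()] reproduces it
#' exactly (round-trip identity).
#'
#' @param bundle A `config_bundle`.
#' @param path Output path ending in `.yaml`, `.yml` or `.json`.
#' @return `path`, invisibly.
#' @export
write_config <- function(bundle, path) {
  stopifnot(inherits(bundle, "config_bundle"))
  pop <- function(p) list(tau = p$tau, eta_bar = p$eta_bar, delta = p$delta,
                          n = p$n, v_th = p$v_th, v_r = p$v_r)
  out <- list(
    e_params = pop(bundle$e_params),
    i_params = pop(bundle$i_params),
    couplings = list(j_ee = bundle$couplings$j_ee, j_ei = bundle$couplings$j_ei,
                     j_ie = bundle$couplings$j_ie, j_ii = bundle$couplings$j_ii,
                     tau_s = bundle$couplings$tau_s),
    drive = list(start = bundle$drive$start,
                 i_ext_e = bundle$drive$i_ext_e,
                 i_ext_i = bundle$drive$i_ext_i))
  if (!is.null(bundle$cross))
    out$cross <- list(g_ee = bundle$cross$g_ee, g_ie = bundle$cross$g_ie,
                      delay = bundle$cross$delay,
                      weak_threshold = bundle$cross$weak_threshold)
  if (!is.null(bundle$pulse)) out$pulse <- bundle$pulse
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         yaml = , yml = yaml::write_yaml(out, path),
         json = jsonlite::write_json(out, path, auto_unbox = TRUE,
                                     digits = NA),
         stop("unsupported config format '.", ext, "'"))
  invisible(path)
}

#' Write analysis results to CSV/JSON with a manifest
#'
#' Serialises a result object to plain-text files in `directory` and
#' writes a `manifest.json` recording the files, their MD5 hashes, the
#' package version and an optional seed, so that deterministic analyses
#' can be checked for byte-identical reproduction.
#'
#' Supported objects: `rate_trace`, `spike_raster`, `mf_trajectory`,
#' `limit_cycle`, `adjoint_prc`, `coupling_functions`,
#' `coupled_trajectory`, plain data.frames (e.g. bifurcation diagrams,
#' PRCs).
#'
#' @param result The object to serialise.
#' @param directory Output directory (must exist).
#' @param name Base file name (default derived from the class).
#' @param seed Optional seed to record in the manifest.
#'
#' @return The manifest, invisibly (list with `files`, `md5`, `version`).
#' @export
write_outputs <- function(result, directory, name = NULL, seed = NULL) {
  if (!dir.exists(directory))
    stop("output directory does not exist: ", directory)
  name <- name %||% class(result)[1]
  files <- character(0)
  wcsv <- function(df, suffix) {
    f <- file.path(directory, paste0(name, "_", suffix, ".csv"))
    utils::write.csv(df, f, row.names = FALSE)
    files <<- c(files, f)
  }
  wjson <- function(x, suffix) {
    f <- file.path(directory, paste0(name, "_", suffix, ".json"))
    jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA, null = "null")
    files <<- c(files, f)
  }
  if (inherits(result, "rate_trace")) {
    wcsv(as.data.frame(result), "rates")
  } else if (inherits(result, "spike_raster")) {
    wcsv(data.frame(
      neuron_id = c(result$id_e, result$id_i),
      population = rep(c("E", "I"), c(length(result$t_e), length(result$t_i))),
      spike_time_ms = c(result$t_e, result$t_i)), "raster")
  } else if (inherits(result, "mf_trajectory")) {
    wcsv(data.frame(time_ms = result$t, result$states), "trajectory")
  } else if (inherits(result, "limit_cycle")) {
    wcsv(data.frame(phase_index = seq_along(result$t) - 1L, t = result$t,
                    result$states), "cycle")
    wjson(list(period = result$period,
               closure_residual = result$closure_residual), "cycle_header")
  } else if (inherits(result, "adjoint_prc")) {
    wcsv(data.frame(phase_index = seq_along(result$t) - 1L, t = result$t,
                    result$Z), "adjoint")
    wjson(list(period = result$period,
               normalization_residual = result$normalization_residual,
               periodicity_residual = result$periodicity_residual),
          "adjoint_header")
  } else if (inherits(result, "coupling_functions")) {
    df <- data.frame(phase = result$theta, H = result$H)
    if (!is.null(result$G)) df$G <- result$G
    wcsv(df, "coupling")
    wjson(list(period = result$period, delay = result$delay,
               g_ee = result$cross$g_ee, g_ie = result$cross$g_ie),
          "coupling_header")
  } else if (inherits(result, "coupled_trajectory")) {
    wcsv(data.frame(time_ms = result$t, result$states), "coupled")
  } else if (is.data.frame(result)) {
    wcsv(result, "table")
  } else {
    stop("write_outputs: no serialisation for class '", class(result)[1], "'")
  }
  manifest <- list(files = basename(files),
                   md5 = unname(tools::md5sum(files)),
                   version = as.character(utils::packageVersion("gammalock")),
                   seed = seed)
  jsonlite::write_json(manifest, file.path(directory,
                                           paste0(name, "_manifest.json")),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
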