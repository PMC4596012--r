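# Configuration and serialization plumbing: model configs keyed by the
# published parameter symbols, trajectory CSVs and reproducibility manifests.

#' Read a model configuration
#'
#' Reads a flat key-value YAML or JSON file keyed by the published parameter
#' symbols (e.g. `Na-g`, `A-V_l`, `BK-k_1`); missing keys fall back to the
#' base-model defaults. Synapse keys `P_AMPAR`, `NAR` and `Mg_o` are also
#' recognized. Unknown keys raise an error listing the valid names; explicit
#' values outside the sampling range are accepted with a warning.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `cahom_model`.
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg)) cfg <- list()
  tab <- parameter_table()
  syn_keys <- c("P_AMPAR", "NAR", "Mg_o")
  unknown <- setdiff(names(cfg), c(tab$symbol, syn_keys))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         "; valid keys: ", paste(c(tab$symbol, syn_keys), collapse = ", "))
  }
  pars <- cfg[names(cfg) %in% tab$symbol]
  names(pars) <- tab$name[match(names(pars), tab$symbol)]
  model <- build_model(pars)
  if (!is.null(cfg$NAR)) model$synapse$nar <- cfg$NAR
  if (!is.null(cfg$P_AMPAR)) model$synapse$p_ampar <- cfg$P_AMPAR
  if (!is.null(cfg$Mg_o)) model$concentrations$mg_out <- cfg$Mg_o
  model
}

#' Write a model configuration
#'
#' Writes the 48 parameters (published symbols and units) plus the synapse
#' settings as flat YAML or JSON; [read_model_config()] round-trips it.
#'
#' @param model A `cahom_model`.
#' @param path Output path (`.yaml` or `.json` decides the format).
#' @return `path`, invisibly.
#' @export
write_model_config <- function(model, path) {
  tab <- parameter_table()
  vals <- stats::setNames(
    lapply(tab$name, function(nm) model$params[[nm]]), tab$symbol)
  vals$P_AMPAR <- model$synapse$p_ampar
  vals$NAR <- model$synapse$nar
  vals$Mg_o <- model$concentrations$mg_out
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(vals, path)
  }
  invisible(path)
}

#' Write a trajectory trace as CSV
#'
#' @param trace Trace data.frame from [simulate()] (`time_ms`, `v_mV`,
#'   `ca_nM`, ...).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(trace, path, row.names = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' JSON manifest recording the full model configuration, the seed, integrator
#' settings and package version, sufficient to reproduce a deterministic run
#' bit-identically.
#'
#' @param model A `cahom_model`.
#' @param path Output JSON path.
#' @param seed Run seed.
#' @param dt Integration step, ms.
#' @param extra Optional named list of additional entries (e.g. per-model
#'   error strings of a partially failed population run).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(model, path, seed = NA_integer_, dt = 0.025,
                           extra = list()) {
  tab <- parameter_table()
  manifest <- c(list(
    package = "cahomsim",
    version = as.character(utils::packageVersion("cahomsim")),
    seed = seed, dt_ms = dt,
    parameters = stats::setNames(
      lapply(tab$name, function(nm) model$params[[nm]]), tab$symbol),
    synapse = list(P_AMPAR = model$synapse$p_ampar, NAR = model$synapse$nar,
                   Mg_o = model$concentrations$mg_out)
  ), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
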