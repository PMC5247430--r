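# Configuration and the customizable lab-guidelines document. The config is
# a small YAML file naming the database location, the active login and the
# path of the laboratory's guidelines document (naming conventions, storage
# organization, accepted upload formats, ...).

#' Default configuration file location
#'
#' `~/.config/seedledger/config.yml`, overridable with the
#' `SEEDLEDGER_CONFIG` environment variable or a `--config` CLI flag.
#'
#' @return A file path.
#' @export
default_config_path <- function() {
  env <- Sys.getenv("SEEDLEDGER_CONFIG", "")
  if (nzchar(env)) return(env)
  file.path(path.expand("~"), ".config", "seedledger", "config.yml")
}

#' Load / save the configuration
#'
#' @param path Config file path.
#' @param config A list with any of `database`, `login`, `guidelines`.
#' @return `load_config()` returns the config list (empty if the file does
#'   not exist); `save_config()` the path, invisibly.
#' @export
load_config <- function(path = default_config_path()) {
  if (!file.exists(path)) return(list())
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) list() else cfg
}

#' @rdname load_config
#' @export
save_config <- function(config, path = default_config_path()) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Open the laboratory guidelines document
#'
#' Returns the content of the configured guidelines document. On first use —
#' before a path is configured — a setup prompt (classed condition
#' `seedledger_setup_prompt`) asks for the document; configuring a new path
#' later serves the newer version.
#'
#' @param config A config list (see [load_config()]).
#' @return The document content: lines of text for text media, raw bytes
#'   otherwise.
#' @export
show_lab_guidelines <- function(config = load_config()) {
  path <- config$guidelines
  if (is.null(path) || !nzchar(path)) {
    sl_abort("setup_prompt",
             "no lab-guidelines document configured yet; set `guidelines:` in the config to your lab's manual")
  }
  if (!file.exists(path)) {
    sl_abort("not_found_error",
             sprintf("the configured guidelines document '%s' does not exist", path))
  }
  if (grepl("\\.(txt|md|rst)$", path, ignore.case = TRUE)) {
    readLines(path, warn = FALSE)
  } else {
    readBin(path, what = "raw", n = file.size(path))
  }
}

#' @rdname show_lab_guidelines
#' @param path Path of the (new version of the) guidelines document.
#' @export
set_lab_guidelines <- function(path, config = load_config()) {
  if (!file.exists(path)) {
    sl_abort("not_found_error", sprintf("no document at '%s'", path))
  }
  config$guidelines <- path
  config
}
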