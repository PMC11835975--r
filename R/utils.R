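# Shared internal helpers: config reading, seed derivation, small checks.

read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg)) stop("empty config file: ", path)
  if (!is.list(cfg)) stop("config must be a mapping: ", path)
  cfg
}

#' Derive a named sub-seed from an experiment seed
#'
#' One experiment-level seed fans out to independent named streams (e.g.
#' "jitter", "dropout", "init") so each randomized component is reproducible
#' on its own. The derivation is a small deterministic hash kept below 2^31.
#'
#' @param seed Integer experiment seed.
#' @param name Character stream name.
#' @return A single integer usable with [set.seed()].
#' @export
derive_seed <- function(seed, name) {
  stopifnot(length(seed) == 1L, is.finite(seed), is.character(name))
  h <- as.numeric(seed) %% 2147483647
  for (code in utf8ToInt(name)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 1 && x == floor(x)
}

check_names <- function(cfg, allowed, where) {
  bad <- setdiff(names(cfg), allowed)
  if (length(bad))
    stop(sprintf("unknown %s keys: %s", where, paste(bad, collapse = ", ")))
  invisible(cfg)
}
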