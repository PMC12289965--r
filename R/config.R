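# Canonical JSON: named lists sorted by key recursively, numbers at full
# precision, scalars unboxed. Equal content hashes equally regardless of key
# order in the source file.
canonical_json <- function(x) {
  sort_rec <- function(v) {
    if (is.list(v) && !is.null(names(v)) && length(v) > 0) {
      v <- v[order(names(v))]
      lapply(v, sort_rec)
    } else if (is.list(v)) lapply(v, sort_rec) else v
  }
  as.character(jsonlite::toJSON(sort_rec(x), auto_unbox = TRUE, digits = NA,
                                null = "null"))
}

#' Hash a configuration
#'
#' Deterministic 32-bit FNV-1a hash over the canonicalized JSON encoding;
#' invariant to key order.
#'
#' @param x a list (configuration content).
#' @return an 8-hex-digit character scalar.
#' @export
config_hash <- function(x) {
  hash_hex(fnv1a32(canonical_json(x)))
}

# Allowed keys per config section; values give the documented defaults.
config_schema <- function() {
  list(
    sim = unclass(sim_config()),
    train = unclass(train_config()),
    initial_scan = unclass(scan_settings("FLUOR", 0.1)),
    optimized_scan = unclass(scan_settings("FLUOR", 0.5, n_frames = 3L)),
    trigger_mode = "IMMEDIATE",
    seed = 0L,
    paths = list(out_dir = ".", model = NULL, dataset = NULL)
  )
}

#' Load a session configuration
#'
#' Strict JSON schema: every key must be known (unknown keys are fatal,
#' protecting unattended runs), types must match the documented defaults,
#' missing keys take their defaults, and a deterministic content hash is
#' computed. An empty file yields all defaults.
#'
#' @param path JSON file path.
#' @return a `session_config` list with a `config_hash` attribute field.
#' @export
load_config <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  user <- if (nzchar(trimws(txt))) jsonlite::fromJSON(txt,
                                                      simplifyVector = TRUE)
          else list()
  if (!is.list(user)) stop("config must be a JSON object")
  schema <- config_schema()
  bad <- setdiff(names(user), names(schema))
  if (length(bad))
    stop("unknown config key: ", paste(sQuote(bad), collapse = ", "))

  merged <- schema
  for (key in names(user)) {
    dflt <- schema[[key]]
    val <- user[[key]]
    if (is.list(dflt) && length(names(dflt))) {
      if (!is.list(val))
        stop(sprintf("config key '%s' must be an object", key))
      inner_bad <- setdiff(names(val), names(dflt))
      if (length(inner_bad))
        stop(sprintf("unknown config key: '%s.%s'", key, inner_bad[1]))
      for (k2 in names(val)) {
        check_config_type(val[[k2]], dflt[[k2]], paste0(key, ".", k2))
        merged[[key]][[k2]] <- val[[k2]]
      }
    } else {
      check_config_type(val, dflt, key)
      merged[[key]] <- val
    }
  }
  merged$config_hash <- config_hash(merged[setdiff(names(merged),
                                                   "config_hash")])
  class(merged) <- "session_config"
  merged
}

check_config_type <- function(value, default, key) {
  if (is.null(default)) return(invisible(TRUE))  # untyped (path slots)
  ok <- if (is.numeric(default)) is.numeric(value)
        else if (is.character(default)) is.character(value)
        else if (is.logical(default)) is.logical(value)
        else TRUE
  if (!ok)
    stop(sprintf("config key '%s' has the wrong type (expected %s)",
                 key, class(default)[1]))
  invisible(TRUE)
}
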