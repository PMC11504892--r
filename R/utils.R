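#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

## Structured conditions. Every user-facing failure carries one of these
## classes so callers (and the CLI exit-code mapping) can react by category:
##   mirdiag_io_error     - missing/unreadable/unwritable paths
##   mirdiag_format_error - a file exists but violates its dialect
##   mirdiag_domain_error - inputs are well-formed but scientifically invalid
##   mirdiag_config_error - a configuration object violates its invariants
stop_mirdiag <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "mirdiag_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

stop_io     <- function(msg, ...) stop_mirdiag("mirdiag_io_error", msg, ...)
stop_format <- function(msg, ...) stop_mirdiag("mirdiag_format_error", msg, ...)
stop_domain <- function(msg, ...) stop_mirdiag("mirdiag_domain_error", msg, ...)
stop_config <- function(msg, ...) stop_mirdiag("mirdiag_config_error", msg, ...)

CLASS_LEVELS <- c("negative", "positive")

as_class_factor <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (!all(labels %in% CLASS_LEVELS)) {
    stop_domain("class labels must be 'negative'/'positive'; saw: %s",
                paste(setdiff(unique(labels), CLASS_LEVELS), collapse = ", "))
  }
  factor(labels, levels = CLASS_LEVELS)
}

## Deterministic numeric rendering used by all text writers: enough digits to
## round-trip an IEEE double, never locale-dependent.
num_chr <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("?")
    s <- sprintf("%.17g", v)
    # prefer the shortest representation that still round-trips
    for (d in 10:16) {
      cand <- sprintf(paste0("%.", d, "g"), v)
      if (as.numeric(cand) == v) return(cand)
    }
    s
  }, character(1))
  out
}

## md5 of an arbitrary R object via its canonical YAML rendering (base tools
## only hashes files, so render to a tempfile first)
config_hash <- function(x) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  writeLines(yaml::as.yaml(x), tf)
  unname(tools::md5sum(tf))
}
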