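# Internal helpers: classed conditions so callers can distinguish parse,
# configuration, data, sizing and design failures programmatically.

ns_stop <- function(class, fmt, ...) {
  msg <- if (...length() > 0L) sprintf(fmt, ...) else fmt
  stop(errorCondition(msg, class = c(class, "neemscreen_error")))
}

ns_warn <- function(class, fmt, ...) {
  msg <- if (...length() > 0L) sprintf(fmt, ...) else fmt
  warning(warningCondition(msg, class = c(class, "neemscreen_warning")))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

assert_scalar_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    ns_stop("ns_config_error", "`%s` must be a single integer >= %d", name, min)
  }
  as.integer(x)
}

assert_probability <- function(x, name, max = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > max) {
    ns_stop("ns_config_error", "`%s` must be a probability in [0, %s]", name, format(max))
  }
  as.numeric(x)
}

# File connection that transparently handles gzip by extension.
ns_connection <- function(path, mode = "rt") {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}
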